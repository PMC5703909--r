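#' Measure the axial extent of a signal from a profile
#'
#' Applies the threshold `t = background + alpha * (max(profile) -
#' background)` to one cell/channel profile, takes maximal runs of bins
#' above `t`, merges runs separated by gaps of at most `max_gap` bins,
#' drops runs shorter than `min_run` bins, and refines each interval end
#' to sub-bin precision by linearly interpolating the threshold crossing
#' between neighboring bin centers (profile ends clamp to s = 0 or 1).
#'
#' @param profile Profile tibble for one cell and channel
#'   ([extract_profile()]).
#' @param background Background intensity (same units as the profile);
#'   see [estimate_background()].
#' @param alpha Threshold fraction of the background-subtracted per-cell
#'   maximum, in (0, 1). Default 0.3.
#' @param max_gap,min_run Run merging/pruning in bins.
#' @return A one-row tibble: `cell_id`, `channel`, `intervals`
#'   (list-column tibble of `s_start`, `s_end`), `n_intervals`,
#'   `total_um`, `fraction` (of cell length), `polarity`
#'   ([classify_polarity()]), `length_um`.
#' @export
measure_extent <- function(profile, background = 0, alpha = 0.3,
                           max_gap = 2L, min_run = 3L) {
  stopifnot(alpha > 0, alpha < 1,
            length(unique(profile$cell_id)) == 1L,
            length(unique(profile$channel)) == 1L)
  profile <- arrange(profile, .data$bin)
  v <- profile$intensity
  s <- profile$s
  L <- profile$length_um[1]
  mx <- max(v)
  empty <- tibble(s_start = double(), s_end = double())
  if (mx <= background) {
    return(tibble(cell_id = profile$cell_id[1],
                  channel = profile$channel[1],
                  intervals = list(empty), n_intervals = 0L,
                  total_um = 0, fraction = 0, polarity = "none",
                  length_um = L))
  }
  t <- background + alpha * (mx - background)
  above <- v > t
  runs <- run_intervals(above)
  runs <- merge_runs(runs, max_gap)
  runs <- runs[runs[, 2] - runs[, 1] + 1L >= min_run, , drop = FALSE]
  ivs <- empty
  if (nrow(runs) > 0) {
    ivs <- tibble(
      s_start = vapply(runs[, 1], function(b)
        refine_crossing(s, v, b, t, left = TRUE), numeric(1)),
      s_end = vapply(runs[, 2], function(b)
        refine_crossing(s, v, b, t, left = FALSE), numeric(1)))
  }
  total <- sum(ivs$s_end - ivs$s_start) * L
  frac <- min(1, sum(ivs$s_end - ivs$s_start))
  tibble(cell_id = profile$cell_id[1], channel = profile$channel[1],
         intervals = list(ivs), n_intervals = nrow(ivs),
         total_um = total, fraction = frac,
         polarity = classify_polarity(ivs, any_signal = TRUE),
         length_um = L)
}

run_intervals <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

merge_runs <- function(runs, max_gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, 1] - out[nrow(out), 2] - 1L <= max_gap)
      out[nrow(out), 2] <- runs[i, 2]
    else out <- rbind(out, runs[i, ])
  }
  out
}

# sub-bin interval end: linear interpolation of the threshold crossing
# between the boundary bin center and its outside neighbor
refine_crossing <- function(s, v, b, t, left) {
  n <- length(s)
  if (left) {
    if (b == 1L) return(0)
    frac <- (v[b] - t) / (v[b] - v[b - 1L])
    s[b] - frac * (s[b] - s[b - 1L])
  } else {
    if (b == n) return(1)
    frac <- (v[b] - t) / (v[b] - v[b + 1L])
    s[b] + frac * (s[b + 1L] - s[b])
  }
}

#' Measure extents for many profiles
#'
#' @param profiles Long profile tibble (possibly several cells/channels).
#' @param background Scalar or named per-channel background vector.
#' @inheritParams measure_extent
#' @return Row-bound [measure_extent()] results.
#' @export
measure_extents <- function(profiles, background = 0, alpha = 0.3,
                            max_gap = 2L, min_run = 3L) {
  profiles |>
    dplyr::group_split(.data$cell_id, .data$channel) |>
    purrr::map(function(p) {
      bg <- if (length(background) > 1) background[[p$channel[1]]] else
        background
      measure_extent(p, bg, alpha, max_gap, min_run)
    }) |>
    bind_rows()
}

#' Classify the polarity pattern of a set of axial intervals
#'
#' An interval is "polar" if one of its ends lies within the polar band
#' (s <= `polar_band` or s >= 1 - `polar_band`). Two polar intervals at
#' opposite poles give `bipolar`; one polar interval gives `unipolar`; a
#' non-polar interval overlapping the midcell band gives `midcell`;
#' above-threshold signal without a qualifying interval is `diffuse`; no
#' signal is `none`.
#'
#' @param intervals Tibble of `s_start`, `s_end`.
#' @param polar_band Polar band half-width in s units (default 0.15).
#' @param midcell_band Midcell band as `c(lo, hi)` (default 0.4-0.6).
#' @param any_signal Whether any above-threshold signal existed (to
#'   distinguish `diffuse` from `none`).
#' @return One of `"unipolar"`, `"bipolar"`, `"midcell"`, `"diffuse"`,
#'   `"none"`.
#' @export
classify_polarity <- function(intervals, polar_band = 0.15,
                              midcell_band = c(0.4, 0.6),
                              any_signal = TRUE) {
  if (nrow(intervals) == 0L) return(if (any_signal) "diffuse" else "none")
  at_a <- intervals$s_start <= polar_band
  at_b <- intervals$s_end >= 1 - polar_band
  polar <- at_a | at_b
  if (any(at_a) && any(at_b) && sum(polar) >= 2L) return("bipolar")
  if (sum(polar) >= 1L) return("unipolar")
  mid <- intervals$s_start <= midcell_band[2] &
    intervals$s_end >= midcell_band[1]
  if (any(mid & !polar)) return("midcell")
  "diffuse"
}

#' Relate foci to the nucleoid edges
#'
#' For each focus, the signed distance to the nearest nucleoid edge,
#' normalized to nucleoid length: `min(s - s_start, s_end - s) /
#' (s_end - s_start)`. Non-negative values mean the focus lies inside the
#' nucleoid (0 = exactly at an edge, 0.5 = at the nucleoid center);
#' negative values lie outside. Multi-interval nucleoids are reduced to
#' their spanning interval (union hull) and flagged; cells with no
#' nucleoid signal give NA relations, flagged.
#'
#' @param foci Focus tibble with `cell_id`, `s`.
#' @param extents Nucleoid extent tibble from [measure_extents()] (one
#'   row per cell).
#' @return A tibble: `cell_id`, `s`, `edge_distance` (fraction of
#'   nucleoid length, signed), `inside`, `flag`.
#' @export
relate_foci_to_nucleoid <- function(foci, extents) {
  rows <- lapply(seq_len(nrow(foci)), function(i) {
    cid <- foci$cell_id[i]; sfoc <- foci$s[i]
    ext <- extents[extents$cell_id == cid, ]
    flag <- NA_character_
    if (nrow(ext) != 1L || ext$n_intervals[1] == 0L) {
      return(tibble(cell_id = cid, s = sfoc, edge_distance = NA_real_,
                    inside = NA, flag = "no_nucleoid"))
    }
    ivs <- ext$intervals[[1]]
    if (nrow(ivs) > 1L) {
      flag <- "multi_interval_union"
      ivs <- tibble(s_start = min(ivs$s_start), s_end = max(ivs$s_end))
    }
    nl <- ivs$s_end - ivs$s_start
    d <- min(sfoc - ivs$s_start, ivs$s_end - sfoc) / nl
    tibble(cell_id = cid, s = sfoc, edge_distance = d, inside = d >= 0,
           flag = flag)
  })
  bind_rows(rows)
}

#' Estimate the field background as the mode of out-of-mask pixels
#'
#' Pixels outside every cell mask are rounded to integers and the most
#' frequent value is returned — robust to cell density, unlike a mean.
#'
#' @param image Channel matrix.
#' @param mask Integer label matrix (0 = background).
#' @return Scalar background estimate (photons/px).
#' @export
estimate_background <- function(image, mask) {
  v <- round(image[mask == 0L])
  if (length(v) == 0L) abort("mask covers the whole field")
  tb <- table(v)
  as.numeric(names(tb)[which.max(tb)])
}

#' Integrated background-subtracted intensity per cell
#'
#' Emulates a DNA-content readout: the sum of `pixel - background` over
#' each cell mask, floored at zero.
#'
#' @param image Channel matrix.
#' @param mask Integer label matrix.
#' @param background Scalar background (photons/px); default estimated
#'   with [estimate_background()].
#' @return A tibble: `cell_id`, `area_px`, `intensity`.
#' @export
integrated_cell_intensity <- function(image, mask,
                                      background = estimate_background(image, mask)) {
  stopifnot(all(dim(image) == dim(mask)))
  labs <- sort(unique(mask[mask > 0L]))
  tibble(cell_id = labs,
         area_px = vapply(labs, function(l) sum(mask == l), integer(1)),
         intensity = vapply(labs, function(l)
           max(0, sum(image[mask == l] - background)), numeric(1)))
}
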