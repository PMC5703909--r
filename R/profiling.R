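#' Extract an axial fluorescence profile for one cell
#'
#' Every in-mask pixel of the cell is assigned to exactly one of `n_bins`
#' equal axial bins by its fractional coordinate `s`; the profile value is
#' the mean pixel intensity per bin. Empty bins are filled by linear
#' interpolation from their neighbors (leading/trailing empty bins copy the
#' nearest valid bin) and flagged in the `interpolated` column.
#'
#' @param image 2D numeric channel matrix.
#' @param mask Integer label matrix.
#' @param geometry Single-row geometry tibble for the cell.
#' @param channel Channel name recorded in the output.
#' @param n_bins Number of axial bins (>= 10).
#' @return A tibble, one row per bin: `cell_id`, `channel`, `bin`, `s`
#'   (bin center), `x_um`, `intensity`, `interpolated`, `length_um`.
#' @export
extract_profile <- function(image, mask, geometry, channel = "ch",
                            n_bins = 100L) {
  stopifnot(is.matrix(image), is.matrix(mask), all(dim(image) == dim(mask)),
            nrow(geometry) == 1L)
  if (n_bins < 10L) abort("`n_bins` must be >= 10")
  idx <- which(mask == geometry$cell_id)
  if (length(idx) == 0L) abort("cell_id not present in mask")
  pr <- ((idx - 1L) %% nrow(mask)) + 1L
  pc <- ((idx - 1L) %/% nrow(mask)) + 1L
  s <- axial_coordinate(pr, pc, geometry)$s
  bin <- pmin(n_bins, pmax(1L, ceiling(s * n_bins)))
  vals <- rep(NA_real_, n_bins)
  agg <- tapply(image[idx], bin, mean)
  vals[as.integer(names(agg))] <- agg
  empty <- is.na(vals)
  if (sum(!empty) < n_bins / 2)
    abort("cell too small for requested profile resolution")
  if (any(empty)) {
    ok <- which(!empty)
    vals <- stats::approx(ok, vals[ok], xout = seq_len(n_bins),
                          rule = 2)$y
  }
  s_mid <- (seq_len(n_bins) - 0.5) / n_bins
  tibble(cell_id = geometry$cell_id, channel = channel,
         bin = seq_len(n_bins), s = s_mid,
         x_um = s_mid * geometry$length_um,
         intensity = vals, interpolated = empty,
         length_um = geometry$length_um)
}

#' Extract profiles for all cells and channels of a field
#'
#' @param channels Named list of channel matrices (e.g. `field$channels`).
#' @param mask Integer label matrix.
#' @param geometry Geometry tibble from [extract_geometry()].
#' @param n_bins Axial bins per profile.
#' @param on_error `"skip"` (drop cells too small for `n_bins`, with a
#'   warning) or `"abort"`.
#' @return Long tibble of profiles (see [extract_profile()]).
#' @export
extract_profiles <- function(channels, mask, geometry, n_bins = 100L,
                             on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  if (is.matrix(channels)) channels <- list(ch = channels)
  out <- list(); nskip <- 0L
  for (nm in names(channels)) {
    for (i in seq_len(nrow(geometry))) {
      p <- tryCatch(
        extract_profile(channels[[nm]], mask, geometry[i, ], nm, n_bins),
        error = function(e) if (on_error == "abort") stop(e) else NULL)
      if (is.null(p)) nskip <- nskip + 1L else out[[length(out) + 1L]] <- p
    }
  }
  if (nskip > 0L) warn(sprintf("%d cell/channel profile(s) skipped", nskip))
  bind_rows(out)
}

#' Orient profiles so all channels of a cell share one flip flag
#'
#' Rules: `"brighter_half_first"` reverses a cell's profiles iff the
#' integrated intensity of the first axial half, summed over the cell's
#' channels, is less than that of the second half (exact ties are not
#' reversed); `"by_reference_channel"`
#' applies the same comparison to `reference` and flips every channel of
#' the cell accordingly; `"none"` leaves profiles untouched. The flip is a
#' reversal of the intensity vector over the bin grid; applying it twice
#' restores the original.
#'
#' @param profiles Long profile tibble from [extract_profiles()].
#' @param rule Orientation rule.
#' @param reference Reference channel name (for `"by_reference_channel"`;
#'   defaults to the deciding channel = each profile's own channel for
#'   `"brighter_half_first"`).
#' @return The profiles tibble with reversed intensities where flipped and
#'   a logical `flipped` column.
#' @export
orient_profile <- function(profiles,
                           rule = c("brighter_half_first",
                                    "by_reference_channel", "none"),
                           reference = NULL) {
  rule <- match.arg(rule)
  if (rule == "none") return(mutate(profiles, flipped = FALSE))
  decide <- function(df) {
    # first half = bins with s < 0.5; reverse iff strictly dimmer
    sum(df$intensity[df$s < 0.5]) < sum(df$intensity[df$s >= 0.5])
  }
  if (rule == "by_reference_channel") {
    if (is.null(reference)) abort("`reference` channel required")
    ref <- dplyr::filter(profiles, .data$channel == reference)
    if (nrow(ref) == 0L) abort("reference channel not found in profiles")
    flips <- ref |> group_by(.data$cell_id) |>
      summarise(flipped = decide(dplyr::pick(dplyr::everything())))
  } else {
    # one flag per cell, decided on the summed intensity over all its
    # channels; a strict inequality makes the orientation canonical
    # (reversing the input flips the decision, exact ties are never
    # reversed) and reduces to the per-profile rule for one channel
    flips <- profiles |> group_by(.data$cell_id) |>
      summarise(flipped = decide(dplyr::pick(dplyr::everything())))
  }
  profiles |> left_join(flips, by = "cell_id") |>
    group_by(.data$cell_id, .data$channel) |>
    mutate(intensity = if (.data$flipped[1])
      rev(.data$intensity) else .data$intensity,
      interpolated = if (.data$flipped[1])
        rev(.data$interpolated) else .data$interpolated) |>
    ungroup()
}

#' Build a population demograph
#'
#' Stacks per-cell axial profiles of one channel into a matrix whose rows
#' are cells sorted by ascending cell length (shortest at the top, ties
#' broken by `cell_id`) and whose columns are the shared normalized-length
#' bins. Rows are min-max normalized to \[0, 1\] by default; a constant row
#' maps to all zeros.
#'
#' @param profiles Long profile tibble (one channel, uniform `n_bins`).
#' @param channel Channel to use when `profiles` holds several.
#' @param normalize `"minmax"` (default) or `"raw"`.
#' @return A `demograph` object: list with `$matrix` (cells x bins),
#'   `$cells` (tibble: `row`, `cell_id`, `length_um`), `$channel`,
#'   `$normalize`.
#' @export
build_demograph <- function(profiles, channel = NULL,
                            normalize = c("minmax", "raw")) {
  normalize <- match.arg(normalize)
  if (!is.null(channel))
    profiles <- dplyr::filter(profiles, .data$channel == !!channel)
  if (nrow(profiles) == 0L) abort("no profiles to stack")
  chs <- unique(profiles$channel)
  if (length(chs) != 1L) abort("profiles span several channels; pick one")
  nb <- unique(tapply(profiles$bin, profiles$cell_id, length))
  if (length(nb) != 1L) abort("profiles have differing n_bins")
  meta <- profiles |> dplyr::distinct(.data$cell_id, .data$length_um) |>
    arrange(.data$length_um, .data$cell_id) |>
    mutate(row = row_number(), .before = 1)
  m <- matrix(NA_real_, nrow(meta), nb)
  for (i in seq_len(nrow(meta))) {
    v <- profiles$intensity[profiles$cell_id == meta$cell_id[i]][
      order(profiles$bin[profiles$cell_id == meta$cell_id[i]])]
    if (normalize == "minmax") {
      rng <- range(v)
      v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else
        rep(0, length(v))
    }
    m[i, ] <- v
  }
  structure(list(matrix = m, cells = meta, channel = chs,
                 normalize = normalize),
            class = "demograph")
}

#' @export
print.demograph <- function(x, ...) {
  cat(sprintf("<demograph> %d cells x %d bins, channel '%s' (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$channel, x$normalize))
  cat(sprintf("  lengths %.2f-%.2f um, shortest cell on top\n",
              min(x$cells$length_um), max(x$cells$length_um)))
  invisible(x)
}

#' Plot a demograph
#'
#' Cells are stacked with the shortest at the top and the longest at the
#' bottom; the x axis is normalized cell length.
#'
#' @param object A `demograph`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot demograph
#' @export
autoplot.demograph <- function(object, ...) {
  nb <- ncol(object$matrix)
  df <- tibble(
    row = rep(seq_len(nrow(object$matrix)), times = nb),
    s = rep((seq_len(nb) - 0.5) / nb, each = nrow(object$matrix)),
    intensity = as.vector(object$matrix))
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(name = "norm.\nintensity") +
    ggplot2::labs(x = "normalized cell length",
                  y = "cells (sorted by length)",
                  title = object$channel) +
    ggplot2::theme_minimal()
}
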