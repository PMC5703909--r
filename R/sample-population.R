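#' Sample a ground-truth population of rod-shaped cells
#'
#' Places `n_cells` straight spherocylinders in the field by rejection
#' sampling (uniform center, orientation uniform on \[0, pi)), rejecting any
#' candidate whose footprint, dilated by 1 px, touches an already placed
#' cell or the field border. For every channel the per-cell ground truth
#' (focus axial fractions, patch and nucleoid intervals, DNA content) is
#' drawn according to its [channel_spec()].
#'
#' All randomness comes from the session RNG, seeded here with
#' `config$seed` unless `use_seed = FALSE`; identical configs therefore give
#' identical truths. Draw order is documented: per cell, first geometry
#' (length, then placement attempts), then channel truths in channel order.
#'
#' @param config A [sim_config()].
#' @param use_seed Seed the RNG with `config$seed` first (default `TRUE`).
#' @param max_tries Placement attempts per cell before giving up.
#'
#' @return An object of class `ground_truth`: a list with tibbles
#'   `$cells` (one row per cell: id, poles, length, width, DNA content),
#'   `$foci` (one row per true focus: `cell_id`, `channel`, `s`, `row`,
#'   `col`), `$intervals` (one row per true axial interval: `cell_id`,
#'   `channel`, `kind`, `s_start`, `s_end`, `density`), and the `$config`.
#' @export
sample_population <- function(config, use_seed = TRUE, max_tries = 500L) {
  stopifnot(inherits(config, "sim_config"))
  if (use_seed) set.seed(config$seed)
  nr <- config$field_shape[1]; nc <- config$field_shape[2]
  px <- config$pixel_size
  half_w_px <- config$cell_width / 2 / px
  # keep the PSF tail and the footprint inside the field
  margin <- ceiling(5 * config$psf_sigma) + 2

  occupied <- matrix(FALSE, nr, nc)

  cells <- vector("list", config$n_cells)
  foci <- list(); intervals <- list()

  for (i in seq_len(config$n_cells)) {
    len_um <- draw_length(config$cell_length)
    len_px <- len_um / px
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      theta <- runif(1, 0, pi)
      u <- c(cos(theta), sin(theta))              # (row, col) direction
      half <- len_px / 2
      ctr <- c(runif(1, 1 + margin + half, nr - margin - half),
               runif(1, 1 + margin + half, nc - margin - half))
      if (any(!is.finite(ctr))) next              # cell longer than field
      pa <- ctr - half * u; pb <- ctr + half * u
      # 2-px dilation on both the candidate and the stamped occupancy
      # guarantees >= 4 px between footprints, so PSF-blurred neighbors
      # stay separable by global thresholding
      fp <- spherocylinder_pixels(pa, pb, half_w_px + 2, nr, nc)
      if (length(fp) == 0L) next
      if (any(occupied[fp])) next
      occupied[fp] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      abort(sprintf(
        "could not place cell %d after %d tries: field too small for n_cells",
        i, max_tries))
    # deterministic pole ordering: pole_a has the smaller row (ties: column)
    if (pb[1] < pa[1] || (pb[1] == pa[1] && pb[2] < pa[2])) {
      tmp <- pa; pa <- pb; pb <- tmp
    }
    cells[[i]] <- tibble(
      cell_id = i,
      pole_a_row = pa[1], pole_a_col = pa[2],
      pole_b_row = pb[1], pole_b_col = pb[2],
      length_um = len_um, width_um = config$cell_width,
      dna_content = 1
    )
    # channel truths, in channel order
    nuc_int <- c(NA_real_, NA_real_)
    for (ch in config$channels) {
      tr <- draw_channel_truth(ch, len_um, nuc_int)
      if (!is.null(tr$nucleoid)) {
        nuc_int <- c(tr$nucleoid$s_start, tr$nucleoid$s_end)
        cells[[i]]$dna_content <- tr$dna_content
      }
      if (!is.null(tr$foci_s) && length(tr$foci_s) > 0) {
        pos <- outer(tr$foci_s, pb - pa) + rep(pa, each = length(tr$foci_s))
        foci[[length(foci) + 1L]] <- tibble(
          cell_id = i, channel = ch$name, s = tr$foci_s,
          row = pos[, 1], col = pos[, 2])
      }
      if (!is.null(tr$intervals) && nrow(tr$intervals) > 0)
        intervals[[length(intervals) + 1L]] <-
          mutate(tr$intervals, cell_id = i, channel = ch$name,
                 .before = 1)
    }
  }

  structure(list(
    cells = if (config$n_cells) bind_rows(cells) else empty_cells_tbl(),
    foci = if (length(foci)) bind_rows(foci) else
      tibble(cell_id = integer(), channel = character(), s = double(),
             row = double(), col = double()),
    intervals = if (length(intervals)) bind_rows(intervals) else
      tibble(cell_id = integer(), channel = character(), kind = character(),
             s_start = double(), s_end = double(), density = double()),
    config = config
  ), class = "ground_truth")
}

empty_cells_tbl <- function() {
  tibble(cell_id = integer(), pole_a_row = double(), pole_a_col = double(),
         pole_b_row = double(), pole_b_col = double(), length_um = double(),
         width_um = double(), dna_content = double())
}

draw_length <- function(spec) {
  if (spec[[1]] == "uniform") runif(1, spec[[2]], spec[[3]])
  else max(0.5, rnorm(1, spec[[2]], spec[[3]]))
}

# pixel indices (column-major, 1-based) of a spherocylinder footprint:
# points within `radius` px of the segment shrunk by `radius` at both ends,
# so the rounded caps end exactly at the poles
spherocylinder_pixels <- function(pa, pb, radius, nr, nc) {
  u <- pb - pa; L <- sqrt(sum(u^2))
  if (L <= 2 * radius) {  # degenerate: ball at center
    a <- b <- (pa + pb) / 2
  } else {
    un <- u / L
    a <- pa + radius * un; b <- pb - radius * un
  }
  r0 <- max(1L, floor(min(a[1], b[1]) - radius)); r1 <- min(nr, ceiling(max(a[1], b[1]) + radius))
  c0 <- max(1L, floor(min(a[2], b[2]) - radius)); c1 <- min(nc, ceiling(max(a[2], b[2]) + radius))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  pr <- rep(rows, times = length(cols)); pc <- rep(cols, each = length(rows))
  d2 <- point_segment_dist2(pr, pc, a, b)
  idx <- which(d2 <= radius^2)
  (pc[idx] - 1L) * nr + pr[idx]
}

point_segment_dist2 <- function(pr, pc, a, b) {
  ab <- b - a; ab2 <- sum(ab^2)
  if (ab2 == 0) return((pr - a[1])^2 + (pc - a[2])^2)
  t <- pmin(1, pmax(0, ((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / ab2))
  (pr - (a[1] + t * ab[1]))^2 + (pc - (a[2] + t * ab[2]))^2
}

# one channel's truth for one cell; nuc_int is the nucleoid interval drawn
# earlier in channel order (NA if none), used by uniform_over_nucleoid
draw_channel_truth <- function(ch, len_um, nuc_int) {
  out <- list()
  if (ch$kind == "foci") {
    k <- sample(0:3, 1, prob = ch$n_foci_prob)
    s <- numeric(0)
    if (k > 0) {
      if (ch$rule == "polar_band") {
        uu <- runif(k, ch$f_lo, ch$f_hi)
        from_b <- runif(k) < 0.5
        s <- ifelse(from_b, 1 - uu, uu)
      } else if (ch$rule == "symmetric_pair") {
        # mirrored placement: one band draw per pair, foci at u and 1 - u;
        # odd focus counts place the unpaired focus at a fresh band draw
        s <- numeric(0)
        while (length(s) + 2 <= k) {
          u0 <- runif(1, ch$f_lo, ch$f_hi)
          s <- c(s, u0, 1 - u0)
        }
        if (length(s) < k) s <- c(s, runif(1, ch$f_lo, ch$f_hi))
      } else { # uniform_over_nucleoid
        lo <- if (is.finite(nuc_int[1])) nuc_int[1] else 0
        hi <- if (is.finite(nuc_int[2])) nuc_int[2] else 1
        s <- runif(k, lo, hi)
      }
    }
    out$foci_s <- sort(s)
  } else if (ch$kind == "patch") {
    draw_len <- function() {
      l <- if (length(ch$patch_length_um) == 2)
        runif(1, ch$patch_length_um[1], ch$patch_length_um[2])
      else ch$patch_length_um[1]
      min(l / len_um, 1)
    }
    ivs <- switch(ch$polarity,
      unipolar = {
        f <- draw_len()
        if (runif(1) < 0.5) tibble(s_start = 0, s_end = f)
        else tibble(s_start = 1 - f, s_end = 1)
      },
      bipolar = {
        f1 <- draw_len(); f2 <- draw_len()
        if (f1 + f2 >= 1)  # patches meet in a short cell: one full interval
          tibble(s_start = 0, s_end = 1)
        else tibble(s_start = c(0, 1 - f2), s_end = c(f1, 1))
      },
      midcell = {
        f <- draw_len()
        tibble(s_start = max(0, 0.5 - f / 2), s_end = min(1, 0.5 + f / 2))
      })
    out$intervals <- mutate(ivs, kind = "patch", density = ch$amplitude,
                            .before = 1)
  } else if (ch$kind == "nucleoid") {
    ctr <- 0.5 + ch$center_offset
    half <- ch$nucleoid_fraction / 2
    s0 <- max(0, ctr - half); s1 <- min(1, ctr + half)
    mode <- if (length(ch$content_modes) > 1)
      sample(ch$content_modes, 1) else ch$content_modes[1]
    mult <- if (ch$content_cv > 0) {
      sdlog <- sqrt(log(1 + ch$content_cv^2))
      exp(rnorm(1, -sdlog^2 / 2, sdlog))
    } else 1
    out$dna_content <- mode * mult
    out$nucleoid <- list(s_start = s0, s_end = s1)
    out$intervals <- tibble(kind = "nucleoid", s_start = s0, s_end = s1,
                            density = ch$amplitude * mode * mult)
  } else { # uniform
    out$intervals <- tibble(kind = "uniform", s_start = 0, s_end = 1,
                            density = ch$amplitude)
  }
  out
}
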