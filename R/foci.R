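#' Default focus-detection parameters
#'
#' Difference-of-Gaussians band centered on the PSF scale, a 5-sigma
#' detection threshold above the per-cell background, a minimum candidate
#' separation of two PSF sigmas, and a fitted-sigma acceptance band of
#' 0.5-2 PSF sigmas.
#'
#' @param psf_sigma PSF sigma in px.
#' @param k_sd Detection threshold in units of the per-cell noise SD.
#' @return A named list of parameters for [detect_foci()].
#' @export
focus_params <- function(psf_sigma = 1.3, k_sd = 5) {
  list(dog_sigmas = c(psf_sigma, 2 * psf_sigma),
       k_sd = k_sd,
       min_separation_px = 2 * psf_sigma,
       sigma_band = c(0.5, 2) * psf_sigma,
       fit_halfwidth = 3L)
}

#' Detect diffraction-limited foci with sub-pixel localization
#'
#' Pipeline: difference-of-Gaussians bandpass over the field; candidate
#' local maxima inside each cell mask above
#' `local background + k_sd * noise_sd` (background and noise estimated
#' per cell as the median and MAD of in-mask bandpass values); candidates
#' closer than `min_separation_px` merged keeping the brighter; a 2D
#' Gaussian (center, amplitude, sigma, offset) fitted to a 7x7 window of
#' the raw image by Levenberg-Marquardt least squares; fits with sigma
#' outside `sigma_band`, non-positive amplitude, or non-convergence are
#' rejected. Each accepted focus is assigned to the cell whose mask
#' contains the fitted center (centers on background are dropped) and gets
#' an axial position via [axial_coordinate()].
#'
#' @param image Raw channel matrix.
#' @param mask Integer label matrix.
#' @param geometry Geometry tibble ([extract_geometry()]).
#' @param params Parameter list from [focus_params()].
#' @param channel Channel name recorded in the output.
#' @return A tibble, one row per focus: `cell_id`, `channel`, `row`,
#'   `col` (sub-pixel), `s`, `x_um`, `amplitude` (fitted peak above local
#'   offset), `fit_sigma`, `quality` (1 - SS_res/SS_tot in the fit
#'   window).
#' @export
detect_foci <- function(image, mask, geometry, params = focus_params(),
                        channel = "ch") {
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)))
  dog <- as.matrix(EBImage::gblur(image, params$dog_sigmas[1])) -
    as.matrix(EBImage::gblur(image, params$dog_sigmas[2]))
  locmax <- local_maxima(dog)
  out <- list()
  for (i in seq_len(nrow(geometry))) {
    cid <- geometry$cell_id[i]
    idx <- which(mask == cid)
    if (length(idx) == 0L) next
    bg <- median(dog[idx]); nsd <- mad(dog[idx])
    if (nsd == 0) nsd <- stats::sd(dog[idx])
    cand <- idx[locmax[idx] & dog[idx] > bg + params$k_sd * nsd]
    if (length(cand) == 0L) next
    cr <- ((cand - 1L) %% nrow(mask)) + 1L
    cc <- ((cand - 1L) %/% nrow(mask)) + 1L
    keep <- merge_candidates(cr, cc, dog[cand], params$min_separation_px)
    for (j in keep) {
      fit <- fit_gaussian2d(image, cr[j], cc[j], params)
      if (is.null(fit)) next
      fr <- round(fit$row); fc <- round(fit$col)
      if (fr < 1 || fr > nrow(mask) || fc < 1 || fc > ncol(mask)) next
      owner <- mask[fr, fc]
      if (owner == 0L) next
      g <- geometry[geometry$cell_id == owner, ]
      if (nrow(g) != 1L) next
      ax <- axial_coordinate(fit$row, fit$col, g)
      out[[length(out) + 1L]] <- tibble(
        cell_id = owner, channel = channel,
        row = fit$row, col = fit$col, s = ax$s, x_um = ax$x_um,
        amplitude = fit$amplitude, fit_sigma = fit$sigma,
        quality = fit$quality)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L)
    res <- tibble(cell_id = integer(), channel = character(),
                  row = double(), col = double(), s = double(),
                  x_um = double(), amplitude = double(),
                  fit_sigma = double(), quality = double())
  # a focus may be reached from two cells' candidate lists; deduplicate
  dup <- duplicated(paste(res$cell_id, round(res$row * 10),
                          round(res$col * 10)))
  arrange(res[!dup, ], .data$cell_id, .data$s)
}

# strict-or-equal 8-neighborhood maxima (plateaus allowed)
local_maxima <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- x
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (x >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  res
}

# greedy merge: order by strength, drop candidates within min_sep of a kept one
merge_candidates <- function(r, c, strength, min_sep) {
  ord <- order(strength, decreasing = TRUE)
  kept <- integer(0)
  for (j in ord) {
    if (length(kept) == 0L ||
        all((r[kept] - r[j])^2 + (c[kept] - c[j])^2 >= min_sep^2))
      kept <- c(kept, j)
  }
  kept
}

# isotropic 2D Gaussian + offset over a (2h+1)^2 window; NULL on rejection
fit_gaussian2d <- function(image, r0, c0, params) {
  h <- params$fit_halfwidth
  nr <- nrow(image); nc <- ncol(image)
  rows <- max(1L, r0 - h):min(nr, r0 + h)
  cols <- max(1L, c0 - h):min(nc, c0 + h)
  if (length(rows) < 5L || length(cols) < 5L) return(NULL)
  z <- image[rows, cols]
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  zz <- as.vector(z)
  off0 <- min(zz); amp0 <- max(zz) - off0
  if (amp0 <= 0) return(NULL)
  sig0 <- mean(params$sigma_band)
  resid_fn <- function(p) {
    zz - (p[4] + p[3] *
            exp(-((rr - p[1])^2 + (cc - p[2])^2) / (2 * p[5]^2)))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(r0, c0, amp0, off0, sig0), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  sig <- abs(p[5])
  if (p[3] <= 0 || sig < params$sigma_band[1] || sig > params$sigma_band[2])
    return(NULL)
  if (abs(p[1] - r0) > h || abs(p[2] - c0) > h) return(NULL)
  ss_res <- sum(fit$fvec^2); ss_tot <- sum((zz - mean(zz))^2)
  list(row = p[1], col = p[2], amplitude = p[3], sigma = sig,
       quality = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}
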