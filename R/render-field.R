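#' Render a synthetic multi-channel fluorescence field
#'
#' For each channel an ideal photon map is built from the ground truth —
#' diffraction-limited foci as analytic 2D Gaussians of total mass equal to
#' their configured amplitude, extended signals (patch, nucleoid, uniform)
#' as their footprint regions at the configured photon density convolved
#' with the Gaussian PSF — then the background is added, the map is Poisson
#' sampled (shot noise), and Gaussian read noise is added.
#'
#' @param truths A `ground_truth` object from [sample_population()].
#' @param config The matching [sim_config()]; defaults to `truths$config`.
#' @param noise Disable to obtain the noiseless expected photon map.
#'
#' @return A `sim_field` list: `$channels`, a named list of photon matrices
#'   (rows x cols); `$mask`, an integer label matrix (0 = background, one
#'   spherocylinder component per `cell_id`); `$truths`; `$config`.
#' @export
render_field <- function(truths, config = truths$config, noise = TRUE) {
  stopifnot(inherits(truths, "ground_truth"), inherits(config, "sim_config"))
  nr <- config$field_shape[1]; nc <- config$field_shape[2]
  px <- config$pixel_size
  half_w_px <- config$cell_width / 2 / px

  cells <- truths$cells
  if (nrow(cells) > 0) {
    bad <- cells$pole_a_row < 1 | cells$pole_a_row > nr |
      cells$pole_b_row < 1 | cells$pole_b_row > nr |
      cells$pole_a_col < 1 | cells$pole_a_col > nc |
      cells$pole_b_col < 1 | cells$pole_b_col > nc
    if (any(bad))
      abort("ground truth references coordinates outside field_shape")
  }

  # label mask + per-pixel axial fraction (reused for interval painting)
  mask <- matrix(0L, nr, nc)
  smap <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nrow(cells))) {
    pa <- c(cells$pole_a_row[i], cells$pole_a_col[i])
    pb <- c(cells$pole_b_row[i], cells$pole_b_col[i])
    idx <- spherocylinder_pixels(pa, pb, half_w_px, nr, nc)
    mask[idx] <- cells$cell_id[i]
    pr <- ((idx - 1L) %% nr) + 1L; pc <- ((idx - 1L) %/% nr) + 1L
    ab <- pb - pa
    sf <- ((pr - pa[1]) * ab[1] + (pc - pa[2]) * ab[2]) / sum(ab^2)
    smap[idx] <- pmin(1, pmax(0, sf))
  }

  channels <- setNames(vector("list", length(config$channels)),
                       names(config$channels))
  for (nm in names(config$channels)) {
    ext <- matrix(0, nr, nc)
    ivs <- dplyr::filter(truths$intervals, .data$channel == nm)
    for (j in seq_len(nrow(ivs))) {
      idx <- which(mask == ivs$cell_id[j] &
                   smap >= ivs$s_start[j] & smap <= ivs$s_end[j])
      ext[idx] <- ext[idx] + ivs$density[j]
    }
    if (any(ext > 0))
      ext <- as.matrix(EBImage::gblur(ext, sigma = config$psf_sigma))
    fc <- dplyr::filter(truths$foci, .data$channel == nm)
    spec <- config$channels[[nm]]
    for (j in seq_len(nrow(fc)))
      ext <- add_gaussian_spot(ext, fc$row[j], fc$col[j],
                               spec$amplitude, config$psf_sigma)
    lambda <- ext + config$background
    if (noise) {
      img <- matrix(rpois(nr * nc, lambda), nr, nc)
      if (config$read_noise_sd > 0)
        img <- img + matrix(rnorm(nr * nc, 0, config$read_noise_sd), nr, nc)
      channels[[nm]] <- img
    } else channels[[nm]] <- lambda
  }

  structure(list(channels = channels, mask = mask, truths = truths,
                 config = config), class = "sim_field")
}

# add an analytic 2D Gaussian of total mass `total` at subpixel (r0, c0);
# window of +-5 sigma keeps truncation below 1e-6 of the mass
add_gaussian_spot <- function(img, r0, c0, total, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(5 * sigma)
  rows <- max(1L, floor(r0 - w)):min(nr, ceiling(r0 + w))
  cols <- max(1L, floor(c0 - w)):min(nc, ceiling(c0 + w))
  gr <- exp(-(rows - r0)^2 / (2 * sigma^2))
  gc <- exp(-(cols - c0)^2 / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] +
    (total / (2 * pi * sigma^2)) * outer(gr, gc)
  img
}

#' Simulate a complete field in one call
#'
#' Convenience wrapper: [sample_population()] then [render_field()].
#'
#' @inheritParams sample_population
#' @inheritParams render_field
#' @return A `sim_field` (see [render_field()]).
#' @export
simulate_field <- function(config, noise = TRUE) {
  render_field(sample_population(config), config, noise = noise)
}

#' Write a simulated field to disk
#'
#' Writes one 16-bit TIFF per channel, a 16-bit label-mask TIFF, the
#' ground-truth CSVs ([write_truth()]) and a YAML echo of the configuration.
#'
#' @param field A `sim_field` from [render_field()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_field <- function(field, dir) {
  stopifnot(inherits(field, "sim_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(field$channels)) {
    img <- pmin(pmax(round(field$channels[[nm]]), 0), 65535)
    tiff::writeTIFF(img / 65535, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16)
  }
  tiff::writeTIFF(field$mask / 65535, file.path(dir, "mask.tif"),
                  bits.per.sample = 16)
  write_truth(field$truths, dir)
  cfg <- field$config
  cfg$channels <- lapply(cfg$channels, unclass)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a field written by [write_field()]
#'
#' @param dir Directory produced by [write_field()].
#' @return A list with `$channels` (named photon matrices), `$mask`
#'   (integer labels) and `$truths` (if present).
#' @export
read_field <- function(dir) {
  tifs <- setdiff(list.files(dir, pattern = "\\.tif$"), "mask.tif")
  channels <- setNames(
    lapply(file.path(dir, tifs),
           function(f) round(tiff::readTIFF(f) * 65535)),
    sub("\\.tif$", "", tifs))
  mask <- NULL
  if (file.exists(file.path(dir, "mask.tif")))
    mask <- matrix(as.integer(round(tiff::readTIFF(file.path(dir, "mask.tif")) *
                                      65535)),
                   nrow = nrow(channels[[1]]) %||% 0)
  truths <- if (file.exists(file.path(dir, "truth_cells.csv")))
    read_truth(dir) else NULL
  list(channels = channels, mask = mask, truths = truths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ground truth tables to CSV
#'
#' Three plain CSVs: `truth_cells.csv` (one row per cell),
#' `truth_foci.csv` (one row per focus) and `truth_intervals.csv` (one row
#' per axial interval). Numeric columns round-trip losslessly through
#' [read_truth()] (15 significant digits).
#'
#' @param truths A `ground_truth` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truths, dir) {
  stopifnot(inherits(truths, "ground_truth"))
  if (nrow(truths$cells) == 0) abort("empty ground truth")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    df <- as.data.frame(lapply(df, function(x)
      if (is.double(x)) formatC(x, digits = 15, format = "g") else x),
      stringsAsFactors = FALSE)
    write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  }
  wr(truths$cells, "truth_cells.csv")
  wr(truths$foci, "truth_foci.csv")
  wr(truths$intervals, "truth_intervals.csv")
  invisible(dir)
}

#' Read ground truth tables written by [write_truth()]
#'
#' @param dir Directory holding the `truth_*.csv` files.
#' @return A `ground_truth` object (without `$config`).
#' @export
read_truth <- function(dir) {
  rd <- function(f) as_tibble(read.csv(file.path(dir, f),
                                       stringsAsFactors = FALSE))
  structure(list(cells = rd("truth_cells.csv"),
                 foci = rd("truth_foci.csv"),
                 intervals = rd("truth_intervals.csv"),
                 config = NULL),
            class = "ground_truth")
}
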