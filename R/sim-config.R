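#' Specify one synthetic fluorescence channel
#'
#' A channel is rendered from one of four signal kinds commonly seen in
#' rod-shaped bacteria: diffraction-limited `foci` (e.g. ParB-YFP marking
#' chromosomal origins), elongated subpolar `patch` signals (e.g. bactofilin
#' or ParA scaffolds), a centered `nucleoid` region (DAPI-like), or a
#' `uniform` cytoplasmic signal.
#'
#' Amplitude units differ by kind: for `foci` the amplitude is the *total*
#' integrated photon count of one spot; for the extended kinds it is
#' photons/px added over the signal region. This makes photon conservation
#' exact for spots and keeps extended signals independent of cell size.
#'
#' @param name Channel name (used as the channel key throughout the pipeline).
#' @param kind One of `"foci"`, `"patch"`, `"nucleoid"`, `"uniform"`.
#' @param amplitude Photons (foci: total per spot; others: photons/px).
#' @param n_foci_prob For `kind = "foci"`: probability weights over focus
#'   counts 0..3 (length 4, will be normalized).
#' @param rule Focus positional rule: `"polar_band"` (each focus placed
#'   independently, a fraction `u ~ U(f_lo, f_hi)` of cell length from a
#'   randomly chosen pole), `"symmetric_pair"` (one band draw `u` per cell,
#'   foci mirrored at `s = u` and `s = 1 - u`), or
#'   `"uniform_over_nucleoid"` (uniform over the nucleoid interval; requires
#'   a nucleoid channel, else uniform over the whole cell).
#' @param f_lo,f_hi Polar band limits as fractions of cell length from the
#'   nearest pole; `0 <= f_lo <= f_hi <= 0.5`.
#' @param patch_length_um For `kind = "patch"`: patch length in µm (scalar or
#'   length-2 range sampled uniformly per patch).
#' @param polarity For `kind = "patch"`: `"unipolar"`, `"bipolar"` or
#'   `"midcell"`.
#' @param nucleoid_fraction For `kind = "nucleoid"`: fraction of cell length
#'   occupied, in (0, 1].
#' @param center_offset For `kind = "nucleoid"`: center offset as a fraction
#'   of cell length (0 = centered).
#' @param content_cv For `kind = "nucleoid"`: coefficient of variation of the
#'   per-cell DNA-content multiplier (lognormal, mean 1).
#' @param content_modes For `kind = "nucleoid"`: optional vector of relative
#'   DNA contents sampled uniformly per cell (e.g. `c(1, 2)` for a mixed
#'   1N/2N population); multiplies the content multiplier.
#'
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(name, kind = c("foci", "patch", "nucleoid", "uniform"),
                         amplitude = 1000,
                         n_foci_prob = c(0, 0, 1, 0),
                         rule = c("symmetric_pair", "polar_band",
                                  "uniform_over_nucleoid"),
                         f_lo = 0.15, f_hi = 0.25,
                         patch_length_um = c(1, 2),
                         polarity = c("bipolar", "unipolar", "midcell"),
                         nucleoid_fraction = 0.5, center_offset = 0,
                         content_cv = 0, content_modes = 1) {
  kind <- match.arg(kind)
  rule <- match.arg(rule)
  polarity <- match.arg(polarity)
  stopifnot(is.character(name), nchar(name) > 0, amplitude >= 0)
  if (kind == "foci") {
    if (length(n_foci_prob) != 4 || any(n_foci_prob < 0) || sum(n_foci_prob) <= 0)
      abort("`n_foci_prob` must be 4 non-negative weights over counts 0..3")
    if (!(f_lo >= 0 && f_lo <= f_hi && f_hi <= 0.5))
      abort("polar band requires 0 <= f_lo <= f_hi <= 0.5")
  }
  if (kind == "nucleoid") {
    if (!(nucleoid_fraction > 0 && nucleoid_fraction <= 1))
      abort("`nucleoid_fraction` must be in (0, 1]")
    stopifnot(content_cv >= 0, all(content_modes > 0))
  }
  if (kind == "patch") stopifnot(all(patch_length_um > 0))
  structure(list(
    name = name, kind = kind, amplitude = amplitude,
    n_foci_prob = n_foci_prob / sum(n_foci_prob), rule = rule,
    f_lo = f_lo, f_hi = f_hi,
    patch_length_um = patch_length_um, polarity = polarity,
    nucleoid_fraction = nucleoid_fraction, center_offset = center_offset,
    content_cv = content_cv, content_modes = content_modes
  ), class = "channel_spec")
}

#' Configure a synthetic field of rod-shaped cells
#'
#' Defaults resemble 100x/1.4NA widefield imaging of *Myxococcus xanthus*:
#' 65 nm pixels, a PSF sigma of 1.3 px (~85 nm), 0.7 µm wide cells with
#' lengths uniform on 3-12 µm.
#'
#' @param n_cells Number of cells to place.
#' @param field_shape Field size in pixels, `c(rows, cols)`.
#' @param pixel_size Pixel size in µm/px.
#' @param cell_length Length distribution: `list("uniform", min, max)` or
#'   `list("normal", mean, sd)`, in µm.
#' @param cell_width Cell width (spherocylinder diameter) in µm.
#' @param psf_sigma Gaussian PSF sigma in px.
#' @param background Background level in photons/px.
#' @param read_noise_sd Gaussian read-noise SD in photons.
#' @param seed Integer seed; applied by [sample_population()].
#' @param channels List of [channel_spec()] objects.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 50,
                       field_shape = c(1024, 1024),
                       pixel_size = 0.065,
                       cell_length = list("uniform", 3, 12),
                       cell_width = 0.7,
                       psf_sigma = 1.3,
                       background = 100,
                       read_noise_sd = 2,
                       seed = 1L,
                       channels = list(channel_spec("parb", "foci"))) {
  stopifnot(n_cells >= 0, length(field_shape) == 2, all(field_shape >= 32),
            pixel_size > 0, psf_sigma > 0, cell_width > 0,
            background >= 0, read_noise_sd >= 0)
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  stopifnot(length(channels) >= 1,
            all(vapply(channels, inherits, logical(1), "channel_spec")))
  nm <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("channel names must be unique")
  dist <- cell_length[[1]]
  if (!dist %in% c("uniform", "normal"))
    abort("`cell_length` distribution must be 'uniform' or 'normal'")
  if (dist == "uniform" && !(cell_length[[2]] > 0 &&
                             cell_length[[3]] >= cell_length[[2]]))
    abort("uniform cell_length needs 0 < min <= max")
  if (dist == "normal" && cell_length[[2]] <= 0)
    abort("normal cell_length needs positive mean")
  structure(list(
    n_cells = as.integer(n_cells), field_shape = as.integer(field_shape),
    pixel_size = pixel_size, cell_length = cell_length,
    cell_width = cell_width, psf_sigma = psf_sigma,
    background = background, read_noise_sd = read_noise_sd,
    seed = as.integer(seed), channels = setNames(channels, nm)
  ), class = "sim_config")
}

#' Focus amplitude giving a target peak signal-to-noise ratio
#'
#' SNR is defined as the peak spot intensity above background divided by the
#' background shot-noise SD, `sqrt(background)`. The returned value is the
#' total integrated photon count `snr * sqrt(background) * 2 * pi * sigma^2`.
#'
#' @param snr Target peak SNR.
#' @param background Background photons/px.
#' @param psf_sigma PSF sigma in px.
#' @return Total photons for [channel_spec()] `amplitude` (kind `"foci"`).
#' @export
amplitude_for_snr <- function(snr, background = 100, psf_sigma = 1.3) {
  snr * sqrt(background) * 2 * pi * psf_sigma^2
}

#' Extended-source amplitude (photons/px) for a target SNR
#'
#' @inheritParams amplitude_for_snr
#' @return Photons/px for patch/nucleoid/uniform channels.
#' @export
density_for_snr <- function(snr, background = 100) snr * sqrt(background)
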