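# shared synthetic fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, .fixture_env)) assign(key, build(), .fixture_env)
  get(key, .fixture_env)
}

# 50-cell four-channel field at peak SNR 10: ParB-like symmetric focus
# pairs, DAPI-like nucleoid at half cell length, bipolar subpolar patches,
# and a uniform cytoplasmic channel for segmentation
std_config <- function(seed = 101L) {
  sim_config(
    n_cells = 50, field_shape = c(1024, 1024), seed = seed,
    channels = list(
      channel_spec("parb", "foci", amplitude = amplitude_for_snr(10),
                   n_foci_prob = c(0, 0, 1, 0), rule = "symmetric_pair"),
      channel_spec("dapi", "nucleoid", amplitude = density_for_snr(10),
                   nucleoid_fraction = 0.5),
      channel_spec("patch", "patch", amplitude = density_for_snr(10),
                   polarity = "bipolar", patch_length_um = c(1, 2)),
      channel_spec("cyto", "uniform", amplitude = density_for_snr(10))))
}

std_field <- function() memo("std_field", function() {
  simulate_field(std_config())
})

std_geometry <- function() memo("std_geometry", function() {
  f <- std_field()
  extract_geometry(f$mask, f$config$pixel_size)
})

std_profiles <- function() memo("std_profiles", function() {
  f <- std_field()
  extract_profiles(f$channels, f$mask, std_geometry(), n_bins = 100)
})

# single straight horizontal cell mask + geometry, for constructed examples
toy_cell <- function(nrow = 40, ncol = 160, rows = 16:25, cols = 21:140,
                     pixel_size = 0.065) {
  mask <- matrix(0L, nrow, ncol)
  mask[rows, cols] <- 1L
  geo <- extract_geometry(mask, pixel_size)
  list(mask = mask, geo = geo)
}

# brute-force two-sided Mann-Whitney p by full enumeration of group-a
# assignments (tie-free data): distance of U from its null mean
mw_enum_p <- function(a, b) {
  x <- c(a, b); na <- length(a); n <- length(x)
  rk <- rank(x)
  u_of <- function(idx) sum(rk[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  mid <- na * length(b) / 2
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# direct two-pass Pearson formula, independent of stats::cor
pcc_direct <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# wild-type-like population: symmetric ParB focus pairs 15-25% of cell
# length from the poles, peak SNR 10
wt_config <- function(n_cells = 150, seed = 201L) {
  sim_config(
    n_cells = n_cells, field_shape = c(2048, 2048), seed = seed,
    channels = channel_spec("parb", "foci",
                            amplitude = amplitude_for_snr(10),
                            n_foci_prob = c(0, 0, 1, 0),
                            rule = "symmetric_pair"))
}

# segregation-mutant-like population: focus pairs scattered uniformly over
# a half-length nucleoid
mut_config <- function(n_cells = 150, seed = 202L) {
  sim_config(
    n_cells = n_cells, field_shape = c(2048, 2048), seed = seed,
    channels = list(
      channel_spec("dapi", "nucleoid", amplitude = density_for_snr(10),
                   nucleoid_fraction = 0.5),
      channel_spec("parb", "foci", amplitude = amplitude_for_snr(10),
                   n_foci_prob = c(0, 0, 1, 0),
                   rule = "uniform_over_nucleoid")))
}

# full focus pipeline on a rendered field: geometry, detection, metrics
run_focus_pipeline <- function(fld) {
  g <- extract_geometry(fld$mask, fld$config$pixel_size)
  foci <- detect_foci(fld$channels$parb, fld$mask, g,
                      focus_params(fld$config$psf_sigma), "parb")
  list(geometry = g, foci = foci,
       metrics = compute_segregation_metrics(foci, g))
}

wt_run <- function() memo("wt_run", function() {
  fld <- simulate_field(wt_config())
  c(list(field = fld), run_focus_pipeline(fld))
})

mut_run <- function() memo("mut_run", function() {
  fld <- simulate_field(mut_config())
  c(list(field = fld), run_focus_pipeline(fld))
})

# greedy truth matching for recall/precision/axial-error measurement
match_foci <- function(detected, truth, geometry, radius_px = 3) {
  n_tp <- 0L; axial_err <- c()
  for (i in seq_len(nrow(truth))) {
    cand <- detected[detected$cell_id == truth$cell_id[i], ]
    if (nrow(cand) == 0L) next
    d <- sqrt((cand$row - truth$row[i])^2 + (cand$col - truth$col[i])^2)
    if (min(d) <= radius_px) {
      n_tp <- n_tp + 1L
      j <- which.min(d)
      ax <- unlist(geometry[geometry$cell_id == truth$cell_id[i],
                            c("axis_row", "axis_col")])
      axial_err <- c(axial_err,
                     (cand$row[j] - truth$row[i]) * ax[1] +
                     (cand$col[j] - truth$col[i]) * ax[2])
    }
  }
  list(recall = n_tp / nrow(truth),
       precision = n_tp / nrow(detected),
       axial_rmse_px = sqrt(mean(axial_err^2)))
}
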