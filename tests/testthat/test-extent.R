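boxcar_profile <- function(lo, hi, nb = 100, amp = 10, bg = 0, L = 6,
                           cell_id = 1L, channel = "dapi") {
  s <- (seq_len(nb) - 0.5) / nb
  tibble::tibble(cell_id = cell_id, channel = channel, bin = seq_len(nb),
                 s = s, x_um = s * L,
                 intensity = ifelse(s >= lo & s <= hi, amp, bg),
                 interpolated = FALSE, length_um = L)
}

test_that("boxcar extents are recovered to within a bin", {
  p <- boxcar_profile(0.25, 0.75)
  e <- measure_extent(p, background = 0, alpha = 0.3)
  expect_equal(e$n_intervals, 1L)
  expect_equal(e$fraction, 0.5, tolerance = 0.01)  # one bin width
  iv <- e$intervals[[1]]
  expect_equal(iv$s_start, 0.25, tolerance = 0.01)
  expect_equal(iv$s_end, 0.75, tolerance = 0.01)

  # everywhere above threshold: full-length extent
  pf <- boxcar_profile(0, 1)
  expect_equal(measure_extent(pf, 0, 0.3)$fraction, 1)

  # flat background-only profile: none
  p0 <- boxcar_profile(0.25, 0.75, amp = 5, bg = 5)
  e0 <- measure_extent(p0, background = 5, alpha = 0.3)
  expect_equal(e0$polarity, "none")
  expect_equal(e0$n_intervals, 0L)
  expect_equal(e0$fraction, 0)
})

test_that("short runs are dropped and small gaps merged", {
  p <- boxcar_profile(0.2, 0.6)
  p$intensity[38:39] <- 0           # 2-bin gap: merged
  p$intensity[90] <- 10             # 1-bin blip: dropped
  e <- measure_extent(p, 0, 0.3)
  expect_equal(e$n_intervals, 1L)
  expect_equal(e$intervals[[1]]$s_end, 0.6, tolerance = 0.01)
})

test_that("polarity classification follows the band rules", {
  iv <- function(...) tibble::tibble(s_start = c(...)[c(TRUE, FALSE)],
                                     s_end = c(...)[c(FALSE, TRUE)])
  expect_equal(classify_polarity(iv(0, 0.2, 0.8, 1)), "bipolar")
  expect_equal(classify_polarity(iv(0, 0.25)), "unipolar")
  expect_equal(classify_polarity(iv(0.42, 0.58)), "midcell")
  expect_equal(classify_polarity(iv(0.25, 0.35)), "diffuse")
  expect_equal(classify_polarity(iv(), any_signal = FALSE), "none")

  # mirror invariance for the symmetric classes
  expect_equal(classify_polarity(iv(1 - 0.2, 1, 0, 0.2)), "bipolar")
  expect_equal(classify_polarity(iv(1 - 0.58, 1 - 0.42)), "midcell")
  expect_equal(classify_polarity(iv(0.75, 1)), "unipolar")
})

test_that("focus-to-nucleoid relations use the signed edge distance", {
  ext <- measure_extent(boxcar_profile(0.25, 0.75), 0, 0.3)
  foci <- tibble::tibble(cell_id = 1L, s = c(0.25, 0.5, 0.35, 0.15))
  rel <- relate_foci_to_nucleoid(foci, ext)
  expect_equal(rel$edge_distance[1], 0, tolerance = 0.02)
  expect_true(rel$inside[1])
  expect_equal(rel$edge_distance[2], 0.5, tolerance = 0.02)
  expect_equal(rel$edge_distance[3], 0.2, tolerance = 0.03)
  expect_lt(rel$edge_distance[4], 0)       # outside
  expect_false(rel$inside[4])

  # missing nucleoid: flagged, not an error
  rel0 <- relate_foci_to_nucleoid(
    tibble::tibble(cell_id = 9L, s = 0.5), ext)
  expect_true(is.na(rel0$edge_distance))
  expect_equal(rel0$flag, "no_nucleoid")
})

test_that("integrated intensities recover area and DNA-content ratios", {
  # blank cell
  m <- matrix(0L, 30, 30); m[10:20, 10:20] <- 1L
  expect_equal(integrated_cell_intensity(matrix(5, 30, 30), m, 5)$intensity,
               0)
  # noiseless uniform cell: A * (v - b)
  img <- matrix(2, 30, 30); img[m == 1L] <- 9
  expect_equal(integrated_cell_intensity(img, m, 2)$intensity, 121 * 7)

  # two equal-length cells with DNA contents 1 and 2 at SNR 10
  cfg <- sim_config(n_cells = 2, field_shape = c(512, 512), seed = 77L,
                    cell_length = list("uniform", 8, 8),
                    channels = channel_spec("dapi", "nucleoid",
                                            amplitude = density_for_snr(10)))
  tr <- sample_population(cfg)
  tr$cells$dna_content <- c(1, 2)
  tr$intervals$density <- cfg$channels$dapi$amplitude * tr$cells$dna_content
  fld <- render_field(tr, cfg)
  bg <- estimate_background(fld$channels$dapi, fld$mask)
  ii <- integrated_cell_intensity(fld$channels$dapi, fld$mask, bg)
  expect_equal(ii$intensity[2] / ii$intensity[1], 2, tolerance = 0.05)
})

test_that("nucleoid fractions and patch lengths are recovered on synthetic data", {
  fld <- std_field()
  prof <- std_profiles()
  tru <- fld$truths

  bg_d <- estimate_background(fld$channels$dapi, fld$mask)
  ext_d <- measure_extents(dplyr::filter(prof, channel == "dapi"), bg_d)
  true_frac <- with(dplyr::filter(tru$intervals, channel == "dapi"),
                    setNames(s_end - s_start, cell_id))
  err <- abs(ext_d$fraction - true_frac[as.character(ext_d$cell_id)])
  expect_gte(mean(err <= 0.03), 0.95)

  bg_p <- estimate_background(fld$channels$patch, fld$mask)
  ext_p <- measure_extents(dplyr::filter(prof, channel == "patch"), bg_p)
  tol_um <- 2 * fld$config$psf_sigma * fld$config$pixel_size
  tru_p <- dplyr::filter(tru$intervals, channel == "patch")
  n_checked <- 0
  for (i in seq_len(nrow(ext_p))) {
    ivs <- ext_p$intervals[[i]]
    tvs <- dplyr::filter(tru_p, cell_id == ext_p$cell_id[i])
    if (nrow(ivs) != nrow(tvs)) next  # merged/duplicated calls not compared
    ivs <- ivs[order(ivs$s_start), ]; tvs <- tvs[order(tvs$s_start), ]
    L <- ext_p$length_um[i]
    expect_lte(max(abs((ivs$s_end - ivs$s_start) -
                       (tvs$s_end - tvs$s_start)) * L), tol_um)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 0.9 * nrow(ext_p))

  # mirror invariance: reversing a profile preserves fraction and class
  p1 <- dplyr::filter(prof, channel == "dapi",
                      cell_id == ext_d$cell_id[1])
  p1r <- dplyr::mutate(p1, intensity = rev(intensity))
  e1 <- measure_extent(p1, bg_d); e1r <- measure_extent(p1r, bg_d)
  expect_equal(e1r$fraction, e1$fraction, tolerance = 1e-9)
  expect_equal(e1r$polarity, e1$polarity)
})
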