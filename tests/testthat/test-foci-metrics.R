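test_that("background-only cells yield no foci at the default threshold", {
  set.seed(31)
  tc <- toy_cell()
  img <- matrix(rpois(length(tc$mask), 100), nrow(tc$mask))
  foci <- detect_foci(img, tc$mask, tc$geo, focus_params(1.3))
  expect_equal(nrow(foci), 0L)
})

test_that("noiseless spots are localized to centipixel accuracy", {
  tc <- toy_cell()
  img <- matrix(100, nrow(tc$mask), ncol(tc$mask))
  img <- rodmetrics:::add_gaussian_spot(img, 20.3, 61.7, 3000, 1.3)
  foci <- detect_foci(img, tc$mask, tc$geo, focus_params(1.3))
  expect_equal(nrow(foci), 1L)
  expect_lt(abs(foci$row - 20.3), 0.05)
  expect_lt(abs(foci$col - 61.7), 0.05)
  expect_equal(foci$fit_sigma, 1.3, tolerance = 0.02)
})

test_that("well-separated spot pairs at SNR 10 are both recovered", {
  set.seed(33)
  tc <- toy_cell()
  lam <- matrix(100, nrow(tc$mask), ncol(tc$mask))
  amp <- amplitude_for_snr(10, 100, 1.3)
  truth <- rbind(c(20.6, 50.2), c(20.1, 50.2 + 8 * 1.3))  # 8 sigma apart
  for (i in 1:2)
    lam <- rodmetrics:::add_gaussian_spot(lam, truth[i, 1], truth[i, 2],
                                          amp, 1.3)
  img <- matrix(rpois(length(lam), lam), nrow(lam))
  foci <- detect_foci(img, tc$mask, tc$geo, focus_params(1.3))
  expect_equal(nrow(foci), 2L)
  foci <- foci[order(foci$col), ]
  for (i in 1:2) {
    expect_lt(abs(foci$row[i] - truth[i, 1]), 0.5)
    expect_lt(abs(foci$col[i] - truth[i, 2]), 0.5)
  }
})

test_that("segregation metrics reproduce the defining formulas exactly", {
  geo <- tibble::tibble(cell_id = 1:5, length_um = c(10, 10, 10, 4, 10))
  foci <- tibble::tibble(
    cell_id = c(1, 1, 2, 2, 3, 5, 5, 5),
    s = c(0.25, 0.75, 0.1, 0.7, 0.37, 0.2, 0.5, 0.9))
  m <- compute_segregation_metrics(foci, geo)

  # symmetric pair: D1 = D2 = 2.5, D = 5 -> S = 100, D_min = 25
  expect_equal(m$S[1], 100, tolerance = 1e-12)
  expect_equal(m$D_min[1], 25, tolerance = 1e-12)
  expect_equal(m$d_um[1], 5, tolerance = 1e-12)

  # foci at 1 and 7 um in a 10 um cell: S = 75, D_min = 10
  expect_equal(m$d1_um[2], 1, tolerance = 1e-12)
  expect_equal(m$d2_um[2], 3, tolerance = 1e-12)
  expect_equal(m$S[2], 75, tolerance = 1e-12)
  expect_equal(m$D_min[2], 10, tolerance = 1e-12)

  # one focus: S = 0 by definition, any position, any length
  expect_identical(m$S[3], 0)
  expect_equal(m$D_min[3], 37, tolerance = 1e-12)

  # no foci: both undefined
  expect_true(is.na(m$S[4]) && is.na(m$D_min[4]))
  expect_equal(m$n_foci[4], 0L)

  # three foci: S undefined, D_min from the focus nearest a pole
  expect_true(is.na(m$S[5]))
  expect_equal(m$D_min[5], 10, tolerance = 1e-12)
  expect_equal(m$flag[5], "multi_focus")
})

test_that("coincident foci are flagged rather than dividing by zero", {
  geo <- tibble::tibble(cell_id = 1L, length_um = 8)
  foci <- tibble::tibble(cell_id = c(1, 1), s = c(0.4, 0.4))
  m <- compute_segregation_metrics(foci, geo)
  expect_true(is.na(m$S))
  expect_equal(m$flag, "coincident_foci")
})

test_that("S and D_min are mirror- and scale-invariant and in range", {
  set.seed(35)
  for (i in 1:2000) {
    L <- runif(1, 2, 15)
    s2 <- sort(runif(2))
    geo <- tibble::tibble(cell_id = 1L, length_um = L)
    m <- compute_segregation_metrics(tibble::tibble(cell_id = 1L, s = s2),
                                     geo)
    # range
    expect_true(is.na(m$S) || (m$S > 0 && m$S <= 100 + 1e-9))
    expect_true(m$D_min >= 0 && m$D_min <= 50 + 1e-9)
    # mirror
    mm <- compute_segregation_metrics(
      tibble::tibble(cell_id = 1L, s = 1 - s2), geo)
    expect_equal(mm$S, m$S, tolerance = 1e-9)
    expect_equal(mm$D_min, m$D_min, tolerance = 1e-9)
    # scale
    ms <- compute_segregation_metrics(
      tibble::tibble(cell_id = 1L, s = s2),
      tibble::tibble(cell_id = 1L, length_um = 3.7 * L))
    expect_equal(ms$S, m$S, tolerance = 1e-9)
    expect_equal(ms$D_min, m$D_min, tolerance = 1e-9)
    # S = 100 iff D1 = D2
    if (!is.na(m$S) && abs(m$d1_um - m$d2_um) < 1e-12)
      expect_equal(m$S, 100, tolerance = 1e-9)
  }
})

test_that("population tallies count focus-number classes correctly", {
  geo <- tibble::tibble(cell_id = 1:5, length_um = rep(10, 5))
  foci <- tibble::tibble(
    cell_id = c(1, 2, 2, 3, 3, 4, 4, 4),
    s = c(0.2, 0.2, 0.8, 0.3, 0.7, 0.1, 0.5, 0.9))
  pm <- population_metrics(compute_segregation_metrics(foci, geo))
  expect_equal(pm$tally$pct, c(20, 20, 40, 20))
  expect_equal(sum(pm$tally$n), 5L)
  expect_equal(nrow(pm$s_values), 2L)  # only the two 2-focus cells

  # no two-focus cells: warning, empty table, no error
  pm0 <- suppressWarnings(population_metrics(
    compute_segregation_metrics(
      tibble::tibble(cell_id = 1L, s = 0.3),
      tibble::tibble(cell_id = 1L, length_um = 5))))
  expect_equal(nrow(pm0$s_values), 0L)
  expect_warning(population_metrics(
    compute_segregation_metrics(
      tibble::tibble(cell_id = 1L, s = 0.3),
      tibble::tibble(cell_id = 1L, length_um = 5))), "qualify")
})

test_that("detection on a synthetic population recovers the truth", {
  fld <- std_field()
  g <- std_geometry()
  foci <- detect_foci(fld$channels$parb, fld$mask, g,
                      focus_params(fld$config$psf_sigma), "parb")
  tru <- fld$truths$foci
  match_r <- 3  # px
  n_tp <- 0; errs <- c()
  for (i in seq_len(nrow(tru))) {
    cand <- foci[foci$cell_id == tru$cell_id[i], ]
    if (nrow(cand) == 0) next
    d <- sqrt((cand$row - tru$row[i])^2 + (cand$col - tru$col[i])^2)
    if (min(d) <= match_r) {
      n_tp <- n_tp + 1
      j <- which.min(d)
      ax <- c(g$axis_row[g$cell_id == tru$cell_id[i]],
              g$axis_col[g$cell_id == tru$cell_id[i]])
      errs <- c(errs, (cand$row[j] - tru$row[i]) * ax[1] +
                      (cand$col[j] - tru$col[i]) * ax[2])
    }
  }
  expect_gte(n_tp / nrow(tru), 0.95)            # recall
  expect_gte(n_tp / nrow(foci), 0.95)           # precision
  expect_lte(sqrt(mean(errs^2)), 0.5)           # axial RMSE, px
})
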