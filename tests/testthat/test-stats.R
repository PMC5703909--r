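test_that("box-plot summaries use interpolated percentiles", {
  s <- boxplot_summary(1:5)
  expect_equal(s$median, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  expect_equal(s$n, 5L)

  sc <- boxplot_summary(rep(7, 10))
  expect_true(all(unlist(sc[1, 1:5]) == 7))

  s1 <- boxplot_summary(4.2)
  expect_true(all(unlist(s1[1, 1:5]) == 4.2))
  expect_equal(s1$n, 1L)

  expect_error(boxplot_summary(numeric(0)), "no finite")
  expect_warning(boxplot_summary(c(1, NA, 3)), "dropped")

  # percentile monotonicity on random inputs
  set.seed(51)
  for (i in 1:100) {
    v <- rnorm(sample(1:60, 1))
    q <- unlist(boxplot_summary(v)[1, c("p5", "q25", "median", "q75", "p95")])
    expect_true(all(diff(q) >= 0))
  }
})

test_that("Mann-Whitney results match enumeration and identities", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  # identical groups with ties: approximation path, p = 1
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$method, "normal_approx")
  expect_equal(r2$p, 1)

  # U(A,B) + U(B,A) = n_a * n_b
  set.seed(52)
  for (i in 1:50) {
    a <- rnorm(sample(2:12, 1)); b <- rnorm(sample(2:12, 1))
    expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U,
                 length(a) * length(b))
  }

  # exact p equals brute-force permutation enumeration (tie-free, n <= 7)
  set.seed(53)
  for (na in 1:7) for (nb in 1:7) {
    x <- sample(seq_len(100), na + nb)  # distinct -> tie-free
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    r <- mann_whitney(a, b)
    expect_equal(r$method, "exact")
    expect_equal(r$p, mw_enum_p(a, b), tolerance = 1e-12)
  }

  # tidiers
  td <- tidy(mann_whitney(c(1, 2), c(3, 4)))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("U", "p", "n_a", "n_b", "method", "significant"))
  expect_identical(td, glance(mann_whitney(c(1, 2), c(3, 4))))
})

test_that("intensity histograms conserve counts and resolve bimodality", {
  h <- intensity_histogram(rep(2.5, 10), bins = c(0, 1, 2, 3, 4))
  expect_equal(h$count, c(0, 0, 10, 0))

  set.seed(54)
  v <- rnorm(500, 10, 2)
  expect_equal(sum(intensity_histogram(v, 25)$count), 500L)
  vna <- c(v, NA, Inf)
  h2 <- intensity_histogram(vna, 25)
  expect_equal(sum(h2$count), 500L)
  expect_equal(attr(h2, "dropped"), 2L)

  # bin convention: left-closed, right-open, last bin closed
  h3 <- intensity_histogram(c(0, 1, 2), bins = c(0, 1, 2))
  expect_equal(h3$count, c(1, 2))

  # 1N/2N DNA-content mixture, CV 10%: modes differ by a factor of 2
  set.seed(55)
  dna <- c(rnorm(500, 1, 0.1), rnorm(500, 2, 0.2))
  hh <- intensity_histogram(dna, 40)
  m1 <- hh$mid[hh$mid < 1.5][which.max(hh$count[hh$mid < 1.5])]
  m2 <- hh$mid[hh$mid >= 1.5][which.max(hh$count[hh$mid >= 1.5])]
  expect_equal(m2 / m1, 2, tolerance = 0.1)
})

test_that("strain comparisons test each group against the reference", {
  set.seed(56)
  base <- rnorm(50, 20, 3)
  tbl <- tibble::tibble(
    strain = rep(c("WT", "mutA", "mutB"), each = 50),
    D_min = c(base, base + 15, rnorm(50, 20, 3)))
  cmp <- compare_strains(tbl, "D_min", reference = "WT")
  expect_equal(cmp$n_comparisons, 2L)
  expect_equal(sort(cmp$tests$group), c("mutA", "mutB"))
  expect_true(cmp$tests$significant[cmp$tests$group == "mutA"])
  expect_false(cmp$tests$significant[cmp$tests$group == "mutB"])
  expect_equal(nrow(cmp$summary), 3L)

  # identical groups are not significant at alpha = 0.001
  tbl2 <- tibble::tibble(strain = rep(c("a", "b"), each = 30),
                         pcc = rep(rnorm(30), 2))
  expect_false(compare_strains(tbl2, "pcc")$tests$significant)

  # row-order invariance
  shuf <- tbl[sample(nrow(tbl)), ]
  cmp2 <- compare_strains(shuf, "D_min", reference = "WT")
  expect_equal(cmp2$summary, cmp$summary)
  expect_equal(cmp2$tests, cmp$tests)

  # S comparisons drop cells without exactly two foci
  tbl3 <- tibble::tibble(strain = rep(c("WT", "mut"), each = 6),
                         n_foci = rep(c(1L, 2L, 2L), 4),
                         S = rep(c(0, 90, 95), 4))
  cmp3 <- compare_strains(tbl3, "S", reference = "WT")
  expect_equal(cmp3$summary$n, c(4L, 4L))

  gg <- ggplot2::autoplot(cmp)
  expect_s3_class(gg, "ggplot")
})
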