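# brute-force kappa: expand a 2x2 table into label vectors and compute
# Po and Pe from first principles
kappa_oracle <- function(tab) {
  a <- rep(c("L", "L", "H", "H"), times = c(tab[1, 1], tab[1, 2],
                                            tab[2, 1], tab[2, 2]))
  b <- rep(c("L", "H", "L", "H"), times = c(tab[1, 1], tab[1, 2],
                                            tab[2, 1], tab[2, 2]))
  n <- length(a)
  po <- mean(a == b)
  pe <- sum(vapply(c("L", "H"), function(l) mean(a == l) * mean(b == l),
                   numeric(1)))
  (po - pe) / (1 - pe)
}

test_that("cohen_kappa matches the expansion oracle on random tables", {
  tabs <- withr::with_seed(17, lapply(1:25, function(i) {
    matrix(sample(0:30, 4, replace = TRUE), 2, 2)
  }))
  for (tab in tabs) {
    if (sum(tab) == 0) next
    pe <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
    if (abs(1 - pe) < 1e-12) next
    expect_equal(cohen_kappa(tab)$kappa, kappa_oracle(tab), tolerance = 1e-12)
    # symmetry
    expect_equal(cohen_kappa(t(tab))$kappa, cohen_kappa(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("kappa handles perfect, degenerate and invalid tables", {
  expect_equal(cohen_kappa(matrix(c(10, 0, 0, 10), 2, 2))$kappa, 1)
  # kappa = 1 iff off-diagonals are zero (Pe < 1)
  expect_lt(cohen_kappa(matrix(c(10, 1, 0, 10), 2, 2))$kappa, 1)
  # degenerate rule: both raters constant
  expect_equal(cohen_kappa(matrix(c(5, 0, 0, 0), 2, 2))$kappa, 1)
  expect_equal(cohen_kappa(matrix(c(0, 5, 0, 0), 2, 2))$kappa, 0)
  expect_error(cohen_kappa(matrix(c(-1, 0, 0, 1), 2, 2)), "input error")
  expect_error(cohen_kappa(matrix(0, 2, 2)), "empty")
})

test_that("kappa bands follow the Landis-Koch cut points", {
  expect_identical(kappa_band(0.1), "slight")
  expect_identical(kappa_band(0.40), "fair")
  expect_identical(kappa_band(0.41), "moderate")
  expect_identical(kappa_band(0.677), "substantial")
  expect_identical(kappa_band(0.9), "near-perfect")
  expect_identical(kappa_band(-0.2), "poor")
})

test_that("Allred dichotomisation splits at 6/7", {
  expect_identical(dichotomise_allred(c(0, 6, 7, 8)),
                   c("LOW", "LOW", "HIGH", "HIGH"))
  expect_error(dichotomise_allred(9), "input error")
  expect_error(dichotomise_allred(3.5), "input error")
})

test_that("pooled-mean H dichotomisation reproduces the reference categories", {
  cases <- reference_study_data("cases")
  h <- as.matrix(cases[, c("h_visual", "h_digital", "h_hsi")])
  cat <- dichotomise_hscore(h, "POOLED_ALL")
  code <- ifelse(cat == "HIGH", 2L, 1L)
  expect_equal(unname(code[, "h_visual"]), c(2, 2, 2, 2, 1, 1))
  expect_equal(unname(code[, "h_digital"]), c(2, 1, 1, 2, 1, 1))
  expect_equal(attr(cat, "threshold"), mean(h))
  # all-equal values sit at, not above, the threshold: all LOW
  same <- matrix(100, 4, 2)
  expect_true(all(dichotomise_hscore(same) == "LOW"))
})

test_that("spearman_rho equals Pearson on average ranks, ties included", {
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 9, 7, 8)
  expect_equal(spearman_rho(x, y), stats::cor(rank(x), rank(y)))
  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "zero rank variance")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:2, 1:2), "input error")
})

test_that("exact Wilcoxon p equals literal enumeration over sign patterns", {
  x <- c(4.1, 2.0, 7.3, 1.1, 9.8, 3.3)
  y <- c(1.2, 3.5, 2.2, 0.4, 4.4, 5.1)
  got <- wilcoxon_signed_rank(x, y, "EXACT")
  d <- x - y
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:63, function(bits) {
    signs <- as.integer(intToBits(bits))[1:6]
    sum(r[signs == 1])
  }, numeric(1))
  p_oracle <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  expect_equal(got$p, p_oracle)
  expect_equal(got$statistic, w_obs)
  # agreement with the classical distribution in the tie-free case
  expect_equal(got$p, stats::wilcox.test(x, y, paired = TRUE,
                                         exact = TRUE)$p.value)
})

test_that("exact Wilcoxon handles ties and zeros by the stated conventions", {
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p, 1)
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$statistic, 0)
  # tied |differences| get average ranks; enumeration still exact
  x <- c(3, 5, 9, 4)
  y <- c(1, 3, 2, 8)  # |d| = 2 2 7 4 -> ranks 1.5 1.5 4 3
  got <- wilcoxon_signed_rank(x, y, "EXACT")
  r <- c(1.5, 1.5, 4, 3)
  signs_obs <- c(1, 1, 1, 0)
  w_obs <- sum(r[signs_obs == 1])
  ws <- vapply(0:15, function(bits) {
    s <- as.integer(intToBits(bits))[1:4]
    sum(r[s == 1])
  }, numeric(1))
  expect_equal(got$p, min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))))
})

test_that("normal approximation tracks the exact p at moderate n", {
  withr::with_seed(29, {
    for (rep in 1:10) {
      x <- rnorm(15); y <- rnorm(15)
      pe <- wilcoxon_signed_rank(x, y, "EXACT")$p
      pa <- wilcoxon_signed_rank(x, y, "NORMAL_APPROX")$p
      expect_lt(abs(pe - pa), 0.05)
    }
  })
})

test_that("shapiro_wilk flags skew and accepts near-normal samples", {
  skewed <- withr::with_seed(8, c(rep(0, 45), rexp(5, 0.2) + 5))
  expect_lt(shapiro_wilk(skewed)$p, 0.05)
  normalish <- withr::with_seed(9, rnorm(50))
  expect_gt(shapiro_wilk(normalish)$W, 0.9)
  expect_error(shapiro_wilk(c(1, 2)), "input error")
  expect_warning(res <- shapiro_wilk(rep(3, 10)), "constant")
  expect_true(is.na(res$W))
})

test_that("build_report assembles pairwise agreement end to end", {
  cases <- reference_study_data("cases")
  h <- as.matrix(cases[, c("h_visual", "h_digital", "h_hsi")])
  a <- as.matrix(cases[, c("allred_visual", "allred_digital", "allred_hsi")])
  colnames(h) <- colnames(a) <- c("VISUAL", "DIGITAL", "HSI")
  rep <- build_report(h, a)
  vd <- rep$pairs[rep$pairs$method_a == "VISUAL" &
                  rep$pairs$method_b == "DIGITAL", ]
  expect_equal(vd$kappa_allred, 0.4, tolerance = 0.005)
  expect_equal(vd$kappa_h, 0.4, tolerance = 0.005)
  dh <- rep$pairs[rep$pairs$method_a == "DIGITAL" &
                  rep$pairs$method_b == "HSI", ]
  expect_equal(dh$kappa_allred, 0.4, tolerance = 0.005)
  expect_equal(rep$means$mean_h, c(206.67, 123.38, 174.57), tolerance = 0.01)
  # self-agreement degenerates to perfect scores
  self <- build_report(h[, c(1, 1)], a[, c(1, 1)])
  expect_equal(self$pairs$kappa_allred, 1)
  expect_equal(self$pairs$kappa_h, 1)
  expect_equal(self$pairs$spearman_h, 1)
  expect_equal(self$pairs$wilcoxon_p_h, 1)
  # serialisation writes the three artefacts
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("concordance_pairs.csv",
                                               "method_means.csv",
                                               "concordance.json")))))
  expect_error(build_report(h[1, , drop = FALSE], a[1, , drop = FALSE]),
               "input error")
})

test_that("visual-vs-digital six-case Wilcoxon is exactly 2/64", {
  # every visual-digital difference is positive, so the two-sided exact p
  # from the 64-pattern null is its minimum attainable value
  cases <- reference_study_data("cases")
  res <- wilcoxon_signed_rank(cases$h_visual, cases$h_digital, "EXACT")
  expect_equal(res$p, 2 / 64)
  expect_equal(res$statistic, 21)
})
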