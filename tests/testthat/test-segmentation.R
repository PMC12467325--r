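make_absorbance_core <- function(seed = 7, noise_sd = 0) {
  cfg <- pipeline_config(noise_sd = noise_sd, seed = seed - 1L)
  core <- simulate_cores(cfg, 1)[[1]]
  list(absb = reflectance_to_absorbance(
         crop_spectral_window(core$cube, 520, 725)),
       truth = core$truth)
}

test_that("roi_set rejects overlap, empties and unknown classes", {
  m1 <- matrix(FALSE, 4, 4); m1[1, 1] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[2, 2] <- TRUE
  expect_s3_class(roi_set(list(DKK3_POSITIVE = m1, NUCLEI = m2)), "roi_set")
  expect_error(roi_set(list(DKK3_POSITIVE = m1, NUCLEI = m1)), "overlap")
  expect_error(roi_set(list(DKK3_POSITIVE = matrix(FALSE, 4, 4))), "empty")
  expect_error(roi_set(list(TUMOUR = m1)), "roi error")
})

test_that("fit_pca matches a dense eigendecomposition oracle", {
  cube <- spectral_cube(
    withr::with_seed(21, array(runif(6 * 6 * 10, 0, 2), c(6, 6, 10))),
    seq(500, 590, 10), "ABSORBANCE")
  model <- fit_pca(cube, 10)
  x <- matrix(cube$data, 36, 10)
  eig <- eigen(stats::cov(x), symmetric = TRUE)
  expect_equal(model$explained_variance,
               eig$values / sum(eig$values), tolerance = 1e-10)
  for (j in 1:10) {
    v <- eig$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_equal(model$loadings[, j], v, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # orthonormal loadings
  g <- crossprod(model$loadings)
  expect_equal(g, diag(10), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a rank-2 cube concentrates all variance in two components", {
  wl <- seq(500, 590, 10)
  b1 <- sin(seq_along(wl)); b2 <- cos(seq_along(wl))
  coef <- withr::with_seed(3, matrix(runif(50 * 2), 50, 2))
  x <- coef %*% rbind(b1, b2) + 1.5
  cube <- spectral_cube(array(x, c(10, 5, length(wl))), wl, "ABSORBANCE")
  model <- fit_pca(cube, 4)
  expect_equal(sum(model$explained_variance[1:2]), 1, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected by fit_pca", {
  const <- spectral_cube(array(0.7, c(4, 4, 5)), seq(500, 540, 10),
                         "ABSORBANCE")
  expect_error(fit_pca(const, 2), "degenerate-variance")
  cube <- tiny_cube(4, 4, seq(500, 540, 10))
  expect_error(fit_pca(reflectance_to_absorbance(cube), 6),
               "exceeds band count")
  expect_error(fit_pca(cube, 2), "ABSORBANCE")
})

test_that("PCA reconstruction with all components is lossless", {
  core <- make_absorbance_core(seed = 31)
  absb <- core$absb
  model <- fit_pca(absb, length(absb$wavelengths))
  x <- matrix(absb$data, ncol = length(absb$wavelengths))
  centred <- sweep(x, 2, model$center)
  recon <- (centred %*% model$loadings) %*% t(model$loadings)
  expect_equal(recon, centred, tolerance = 1e-8)
})

test_that("false colour is shape-correct, bounded and sign-stable", {
  core <- make_absorbance_core(seed = 32)
  model <- fit_pca(core$absb, 3)
  img <- pca_false_colour(core$absb, model)
  expect_equal(dim(img), c(128, 128, 3))
  expect_true(all(img >= 0 & img <= 1))
  # flipping loading signs upstream is undone by the sign convention
  flipped <- model
  flipped$loadings <- -model$loadings
  for (j in 1:3) {
    i <- which.max(abs(flipped$loadings[, j]))
    if (flipped$loadings[i, j] < 0) flipped$loadings[, j] <- -flipped$loadings[, j]
  }
  expect_equal(pca_false_colour(core$absb, flipped), img)
  expect_error(pca_false_colour(core$absb, fit_pca(core$absb, 2)),
               ">= 3 components")
})

test_that("PCA segmentation recovers ground truth on noiseless cubes", {
  core <- make_absorbance_core(seed = 33)
  rois <- rois_from_truth(core$truth)
  model <- fit_pca(core$absb, 3)
  lab <- pca_segment(core$absb, model, rois, 3)
  acc <- mean(lab$classes == core$truth$label_image)
  expect_gte(acc, 0.99)
  # training-ROI pixels specifically
  for (cl in names(rois)) {
    expect_gte(mean(lab$classes[rois[[cl]]] == cl), 0.99)
  }
  # determinism
  lab2 <- pca_segment(core$absb, model, rois, 3)
  expect_identical(lab$classes, lab2$classes)
})

test_that("extract_references equals the tier-weighted mean of DAB spectra", {
  core <- make_absorbance_core(seed = 34)
  rois <- rois_from_truth(core$truth)
  refs <- extract_references(core$absb, rois)
  x <- matrix(core$absb$data, ncol = length(core$absb$wavelengths))
  idx <- as.vector(core$truth$label_image == "DKK3_POSITIVE")
  expect_equal(refs$spectra$DKK3_POSITIVE, colMeans(x[idx, , drop = FALSE]))
  # single-pixel ROI returns that pixel's spectrum
  single <- matrix(FALSE, 128, 128)
  pix <- which(core$truth$label_image == "NUCLEI", arr.ind = TRUE)[1, ]
  single[pix[1], pix[2]] <- TRUE
  refs1 <- extract_references(core$absb,
                              roi_set(list(NUCLEI = single)))
  expect_equal(refs1$spectra$NUCLEI, core$absb$data[pix[1], pix[2], ])
})

test_that("correlation classification recovers ground truth and honours min_corr", {
  core <- make_absorbance_core(seed = 35)
  rois <- rois_from_truth(core$truth)
  refs <- extract_references(core$absb, rois)
  lab <- cf_classify(core$absb, refs, min_corr = 0.8)
  expect_gte(mean(lab$classes == core$truth$label_image), 0.99)

  # a positive affine transform of a reference correlates at exactly 1
  wl <- refs$wavelengths
  r <- refs$spectra$DKK3_POSITIVE
  probe <- spectral_cube(array(2.5 * r + 0.3, c(1, 1, length(wl))), wl,
                         "ABSORBANCE")
  lab1 <- cf_classify(probe, refs, min_corr = 0.8)
  expect_identical(as.vector(lab1$classes), "DKK3_POSITIVE")
  expect_equal(lab1$scores$DKK3_POSITIVE[1, 1], 1)

  # the reflection of a reference about its mean correlates at -1 and,
  # against a library holding only that reference, stays unclassified
  neg <- spectral_cube(array(2 * mean(r) - r + max(r), c(1, 1, length(wl))),
                       wl, "ABSORBANCE")
  dab_only <- structure(list(spectra = refs$spectra["DKK3_POSITIVE"],
                             wavelengths = wl), class = "reference_library")
  labn <- cf_classify(neg, dab_only, min_corr = 0.8)
  expect_equal(labn$scores$DKK3_POSITIVE[1, 1], -1)
  expect_identical(as.vector(labn$classes), "UNCLASSIFIED")
})

test_that("a zero-variance pixel gets correlation 0, never an error", {
  wl <- seq(520, 570, 10)
  refs <- structure(list(
    spectra = list(DKK3_POSITIVE = sin(seq_along(wl)),
                   NUCLEI = cos(seq_along(wl)),
                   BACKGROUND = seq_along(wl) * 0.01),
    wavelengths = wl), class = "reference_library")
  flat <- spectral_cube(array(0.4, c(2, 2, length(wl))), wl, "ABSORBANCE")
  lab <- cf_classify(flat, refs, min_corr = 0.5)
  expect_true(all(lab$classes == "UNCLASSIFIED"))
  expect_true(all(lab$scores$DKK3_POSITIVE == 0))
})

test_that("both classifiers agree with each other on noiseless cubes", {
  core <- make_absorbance_core(seed = 36)
  rois <- rois_from_truth(core$truth)
  refs <- extract_references(core$absb, rois)
  cf <- cf_classify(core$absb, refs, 0.8)
  pc <- pca_segment(core$absb, fit_pca(core$absb, 3), rois, 3)
  expect_gte(mean(cf$classes == pc$classes), 0.95)
})

test_that("tie-breaking follows the fixed class order", {
  # two references that are exact negatives give equal correlation to an
  # orthogonal probe; DKK3_POSITIVE precedes NUCLEI in the class order
  wl <- seq(520, 550, 10)
  v <- c(1, -1, 1, -1)
  refs <- structure(list(
    spectra = list(DKK3_POSITIVE = v + 2, NUCLEI = v + 2),
    wavelengths = wl), class = "reference_library")
  probe <- spectral_cube(array(v + 5, c(1, 1, 4)), wl, "ABSORBANCE")
  lab <- cf_classify(probe, refs, min_corr = 0.5)
  expect_identical(as.vector(lab$classes), "DKK3_POSITIVE")
})
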