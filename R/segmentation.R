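#' Construct a set of annotation ROIs
#'
#' One boolean mask per tissue class (`DKK3_POSITIVE`, `NUCLEI`,
#' `BACKGROUND`); masks must be pairwise disjoint and non-empty.
#'
#' @param masks Named list of logical matrices sharing one spatial shape.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks) {
  classes <- c("DKK3_POSITIVE", "NUCLEI", "BACKGROUND")
  if (!all(names(masks) %in% classes) || length(masks) == 0) {
    stop(sprintf("roi error: masks must be named from {%s}",
                 paste(classes, collapse = ", ")), call. = FALSE)
  }
  shp <- dim(masks[[1]])
  total <- matrix(0L, shp[1], shp[2])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), shp)) {
      stop("roi error: masks must share one shape", call. = FALSE)
    }
    if (!any(m)) stop(sprintf("roi error: empty ROI for %s", nm), call. = FALSE)
    total <- total + m
  }
  if (any(total > 1L)) stop("roi error: ROIs overlap", call. = FALSE)
  structure(masks, class = "roi_set")
}

#' ROIs derived from generator ground truth
#'
#' Turns a `ground_truth` label image into an `roi_set`, one mask per class
#' present. Used to train/anchor the classifiers on synthetic data exactly
#' as hand-drawn annotation ROIs would on real tissue.
#'
#' @param truth A `ground_truth` (or a bare character label matrix).
#' @return An `roi_set`.
#' @export
rois_from_truth <- function(truth) {
  labels <- if (inherits(truth, "ground_truth")) truth$label_image else truth
  classes <- intersect(c("DKK3_POSITIVE", "NUCLEI", "BACKGROUND"),
                       unique(as.vector(labels)))
  roi_set(stats::setNames(lapply(classes, function(cl) labels == cl), classes))
}

#' Fit a PCA model to the pixel spectra of a cube
#'
#' Principal components of the mean-centred pixel spectra: eigenvectors of
#' the band-wise covariance matrix, ordered by eigenvalue. The cube must be
#' in absorbance form, where Beer-Lambert stain mixing is linear. The sign
#' of each loading is fixed so its largest-magnitude entry is positive,
#' making false-colour output reproducible across fits.
#'
#' @param cube A `spectral_cube` with `signal_kind = "ABSORBANCE"`.
#' @param n_components Number of components to keep (default 3).
#' @return An object of class `spectral_pca`: `center` (mean spectrum),
#'   `loadings` (bands x components, orthonormal), `explained_variance`
#'   (fractions of total variance, non-increasing), `wavelengths`.
#' @export
fit_pca <- function(cube, n_components = 3) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$signal_kind != "ABSORBANCE") {
    stop("fit_pca expects an ABSORBANCE cube", call. = FALSE)
  }
  x <- cube_matrix(cube)
  if (n_components > ncol(x)) {
    stop("parameter error: n_components exceeds band count", call. = FALSE)
  }
  if (nrow(x) < n_components) {
    stop("parameter error: fewer pixels than components", call. = FALSE)
  }
  center <- colMeans(x)
  total_var <- sum(apply(x, 2, stats::var))
  if (!is.finite(total_var) || total_var < 1e-20) {
    stop("degenerate-variance error: cube is spatially constant", call. = FALSE)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-|entry| of each loading is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  structure(
    list(center = center, loadings = loadings,
         explained_variance = p$sdev[seq_len(k)]^2 / total_var,
         wavelengths = cube$wavelengths),
    class = "spectral_pca")
}

pca_scores <- function(cube, model, n_components = ncol(model$loadings)) {
  x <- cube_matrix(cube)
  if (length(model$center) != ncol(x)) {
    stop("cube and PCA model disagree on band count", call. = FALSE)
  }
  sweep(x, 2, model$center) %*% model$loadings[, seq_len(n_components),
                                               drop = FALSE]
}

#' False-colour composite from the first three principal components
#'
#' Maps PC1/PC2/PC3 scores to the red/green/blue channels, each rescaled by
#' a 1st-99th percentile stretch to \[0, 1\].
#'
#' @param cube An ABSORBANCE `spectral_cube` on the model's axis.
#' @param model A `spectral_pca` with at least 3 components.
#' @return Array `rows x cols x 3` with values in \[0, 1\].
#' @export
pca_false_colour <- function(cube, model) {
  if (ncol(model$loadings) < 3) {
    stop("parameter error: false colour needs >= 3 components", call. = FALSE)
  }
  s <- pca_scores(cube, model, 3)
  shp <- spatial_shape(cube)
  out <- array(0, dim = c(shp[1], shp[2], 3))
  for (j in 1:3) {
    q <- stats::quantile(s[, j], c(0.01, 0.99), names = FALSE)
    ch <- if (q[2] > q[1]) (s[, j] - q[1]) / (q[2] - q[1]) else s[, j] * 0
    out[, , j] <- matrix(pmin(pmax(ch, 0), 1), shp[1], shp[2])
  }
  out
}

new_label_map <- function(classes, scores = list()) {
  structure(list(classes = classes, scores = scores), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(as.vector(x$classes), levels = LABEL_CLASSES))
  cat("<label_map>", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' PCA-based tissue segmentation
#'
#' Projects every pixel into PC-score space and assigns the class of the
#' nearest class centroid, where centroids are derived from the
#' annotation-ROI pixels. Ties are broken by the fixed class order
#' `DKK3_POSITIVE < NUCLEI < BACKGROUND`.
#'
#' Two distances are available. The default, `"angular"`, measures the
#' spectral angle between a pixel's raw (uncentred) projection onto the
#' loadings and each class centroid direction; because it ignores
#' amplitude, all staining intensities of one chromogen share a direction,
#' so a class whose concentration spans weak-to-strong tiers is still a
#' single centroid. `"euclidean"` is the minimal textbook rule — distance
#' to the mean centred PC score of each ROI — but a class with a wide
#' amplitude spread can then lie closer to another class's centroid at its
#' low-amplitude end.
#'
#' @param cube An ABSORBANCE `spectral_cube` on the model's axis.
#' @param model A `spectral_pca`.
#' @param rois An `roi_set` with all three classes.
#' @param n_components Number of score dimensions to use.
#' @param distance `"angular"` (default) or `"euclidean"`.
#' @return A `label_map`; `scores` holds one distance image per class.
#' @export
pca_segment <- function(cube, model, rois, n_components = 3,
                        distance = c("angular", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(inherits(rois, "roi_set"))
  if (n_components > ncol(model$loadings)) {
    stop("parameter error: n_components exceeds model components", call. = FALSE)
  }
  x <- cube_matrix(cube)
  loadings <- model$loadings[, seq_len(n_components), drop = FALSE]
  s <- if (distance == "angular") x %*% loadings
       else sweep(x, 2, model$center) %*% loadings
  shp <- spatial_shape(cube)
  classes <- names(rois)
  dists <- matrix(NA_real_, nrow(s), length(classes))
  if (distance == "angular") {
    sn <- sqrt(rowSums(s^2))
    for (j in seq_along(classes)) {
      idx <- as.vector(rois[[classes[j]]])
      centroid <- colMeans(s[idx, , drop = FALSE])
      cn <- sqrt(sum(centroid^2))
      cosine <- ifelse(sn * cn > 0, as.vector(s %*% centroid) / (sn * cn), 0)
      dists[, j] <- 1 - cosine
    }
  } else {
    for (j in seq_along(classes)) {
      idx <- as.vector(rois[[classes[j]]])
      centroid <- colMeans(s[idx, , drop = FALSE])
      dists[, j] <- sqrt(rowSums(sweep(s, 2, centroid)^2))
    }
  }
  ord <- order(match(classes, LABEL_CLASSES))
  dists <- dists[, ord, drop = FALSE]
  classes <- classes[ord]
  pick <- max.col(-dists, ties.method = "first")
  lab <- matrix(classes[pick], shp[1], shp[2])
  score_imgs <- stats::setNames(
    lapply(seq_along(classes),
           function(j) matrix(dists[, j], shp[1], shp[2])), classes)
  new_label_map(lab, score_imgs)
}

#' Extract per-class reference spectra from ROIs
#'
#' The mean spectrum of each ROI on the (windowed, absorbance) cube, the
#' reference signatures that correlation-function classification compares
#' unknown pixels against.
#'
#' @param cube A `spectral_cube` (absorbance recommended).
#' @param rois An `roi_set`.
#' @return An object of class `reference_library`: named list `spectra`
#'   plus `wavelengths`.
#' @export
extract_references <- function(cube, rois) {
  stopifnot(inherits(rois, "roi_set"))
  spectra <- lapply(stats::setNames(names(rois), names(rois)),
                    function(cl) mean_spectrum(cube, rois[[cl]]))
  structure(list(spectra = spectra, wavelengths = cube$wavelengths),
            class = "reference_library")
}

#' Correlation-function pixel classification
#'
#' Computes the similarity between every pixel spectrum and each reference
#' spectrum and assigns the best-matching class when the best similarity
#' reaches `min_corr`; otherwise the pixel is `UNCLASSIFIED`. Pearson
#' correlation (default) is invariant to positive affine rescaling of a
#' pixel's spectrum, so staining concentration does not affect class
#' assignment, only spectral shape does. A pixel with zero spectral variance
#' has correlation defined as 0 with every reference. Ties are broken by the
#' fixed class order.
#'
#' @param cube A `spectral_cube` windowed to the reference axis.
#' @param refs A `reference_library`.
#' @param min_corr Acceptance threshold in \[-1, 1\] (default 0.8).
#' @param method `"pearson"` (default) or `"cosine"`.
#' @return A `label_map`; `scores` holds one similarity image per class.
#' @export
cf_classify <- function(cube, refs, min_corr = 0.8,
                        method = c("pearson", "cosine")) {
  method <- match.arg(method)
  stopifnot(inherits(refs, "reference_library"))
  if (!isTRUE(all.equal(cube$wavelengths, refs$wavelengths))) {
    stop("cube and reference library are on different wavelength axes",
         call. = FALSE)
  }
  x <- cube_matrix(cube)
  classes <- names(refs$spectra)
  ord <- order(match(classes, LABEL_CLASSES))
  classes <- classes[ord]
  if (method == "pearson") {
    x0 <- x - rowMeans(x)
    xn <- sqrt(rowSums(x0^2))
  } else {
    x0 <- x
    xn <- sqrt(rowSums(x0^2))
  }
  sims <- matrix(0, nrow(x), length(classes))
  for (j in seq_along(classes)) {
    r <- refs$spectra[[classes[j]]]
    r0 <- if (method == "pearson") r - mean(r) else r
    rn <- sqrt(sum(r0^2))
    s <- as.vector(x0 %*% r0)
    denom <- xn * rn
    sims[, j] <- ifelse(denom > 0, s / denom, 0)
  }
  pick <- max.col(sims, ties.method = "first")
  best <- sims[cbind(seq_len(nrow(sims)), pick)]
  lab <- ifelse(best >= min_corr, classes[pick], "UNCLASSIFIED")
  shp <- spatial_shape(cube)
  score_imgs <- stats::setNames(
    lapply(seq_along(classes),
           function(j) matrix(sims[, j], shp[1], shp[2])), classes)
  new_label_map(matrix(lab, shp[1], shp[2]), score_imgs)
}
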