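#' Interpretation band for a kappa value
#'
#' Landis-Koch agreement bands: below 0 poor, 0.00-0.20 slight, 0.21-0.40
#' fair, 0.41-0.60 moderate, 0.61-0.80 substantial, above 0.80 near-perfect.
#'
#' @param kappa Kappa value in \[-1, 1\].
#' @return Character band label.
#' @export
kappa_band <- function(kappa) {
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "near-perfect"
}

#' Cohen's kappa from an agreement table
#'
#' Chance-corrected agreement between two categorical raters:
#' `kappa = (Po - Pe) / (1 - Pe)` with observed agreement `Po = trace/total`
#' and chance agreement `Pe = sum(row_i * col_i) / total^2`. In the
#' degenerate case `Pe = 1` (both raters constant), kappa is defined as 1
#' when `Po = 1` and 0 otherwise.
#'
#' @param table Square matrix of non-negative integer counts; rows = rater A
#'   categories, columns = rater B categories.
#' @return List of class `cohen_kappa`: `kappa`, `band`, `po`, `pe`, `table`.
#' @export
cohen_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) {
    stop("input error: agreement table must be square", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("input error: counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(table)
  if (total < 1) stop("input error: empty table", call. = FALSE)
  po <- sum(diag(table)) / total
  pe <- sum(rowSums(table) * colSums(table)) / total^2
  kappa <- if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) 1 else 0
  } else {
    (po - pe) / (1 - pe)
  }
  structure(list(kappa = kappa, band = kappa_band(kappa), po = po, pe = pe,
                 table = table),
            class = "cohen_kappa")
}

#' @export
print.cohen_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s agreement); Po = %.3f, Pe = %.3f, n = %d\n",
              x$kappa, x$band, x$po, x$pe, sum(x$table)))
  invisible(x)
}

# kappa from two paired category vectors on fixed levels
kappa_from_vectors <- function(a, b, levels) {
  cohen_kappa(table(factor(a, levels = levels), factor(b, levels = levels)))
}

#' Dichotomise an Allred score
#'
#' `LOW` for totals 0-6, `HIGH` for 7-8.
#'
#' @param score Integer Allred total(s) in 0-8.
#' @return Character vector of `"LOW"`/`"HIGH"`.
#' @export
dichotomise_allred <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 8) ||
      any(score != round(score))) {
    stop("input error: Allred totals must be integers in 0-8", call. = FALSE)
  }
  ifelse(score <= 6, "LOW", "HIGH")
}

#' Dichotomise H-scores about the mean
#'
#' Classifies H-scores as `HIGH` when strictly above a mean threshold:
#' either the pooled mean over every method and case (`POOLED_ALL`, default)
#' or each method's own mean (`PER_METHOD`).
#'
#' @param values Numeric matrix or data frame, cases x methods.
#' @param pooling `"POOLED_ALL"` or `"PER_METHOD"`.
#' @return Character matrix of `"LOW"`/`"HIGH"` with the threshold(s) in
#'   attribute `"threshold"`.
#' @export
dichotomise_hscore <- function(values, pooling = c("POOLED_ALL", "PER_METHOD")) {
  pooling <- match.arg(pooling)
  values <- as.matrix(values)
  if (length(values) == 0) stop("input error: no values", call. = FALSE)
  thr <- if (pooling == "POOLED_ALL") rep(mean(values), ncol(values))
         else colMeans(values)
  out <- vapply(seq_len(ncol(values)),
                function(j) ifelse(values[, j] > thr[j], "HIGH", "LOW"),
                character(nrow(values)))
  out <- matrix(out, nrow(values), ncol(values),
                dimnames = dimnames(values))
  attr(out, "threshold") <- if (pooling == "POOLED_ALL") thr[1] else thr
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average-rank-transformed vectors (ties get
#' mean ranks).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\], or `NA` (with a warning) when either vector has
#'   zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("input error: need equal lengths >= 3", call. = FALSE)
  }
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    warning("spearman_rho undefined: zero rank variance")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

# exact null distribution of twice the positive-rank sum, by iterated
# convolution over the (doubled, hence integer) signed ranks; equivalent to
# enumerating all 2^n sign assignments
signrank_exact_counts <- function(double_ranks) {
  s <- sum(double_ranks)
  counts <- numeric(s + 1)
  counts[1] <- 1
  for (r in double_ranks) {
    shifted <- c(numeric(r), counts[seq_len(s + 1 - r)])
    counts <- counts + shifted
  }
  counts  # counts[w + 1] = number of sign patterns with 2*W+ == w
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (classical convention) and tied absolute differences receive average
#' ranks. In `EXACT` mode the p-value is computed from the full permutation
#' distribution over all `2^n` sign assignments of the ranked absolute
#' differences (evaluated by convolution, so it is practical far beyond the
#' sizes where literal enumeration is); `NORMAL_APPROX` uses the
#' tie-corrected normal approximation with continuity correction. When all
#' differences are zero the test is degenerate: statistic 0, p = 1.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param mode `"EXACT"` (default) or `"NORMAL_APPROX"`.
#' @return List: `statistic` (positive-rank sum W+), `p` (two-sided),
#'   `n` (pairs after zero removal), `mode`.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("EXACT", "NORMAL_APPROX")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) {
    stop("input error: x and y must be paired (equal lengths)", call. = FALSE)
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p = 1, n = 0L, mode = mode))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (mode == "EXACT") {
    dr <- as.integer(round(2 * r))
    counts <- signrank_exact_counts(dr)
    total <- 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p = p, n = n, mode = mode)
}

#' Shapiro-Wilk normality test
#'
#' Reported as a descriptive gate on score distributions; the pipeline
#' always runs the non-parametric suite regardless of the outcome.
#'
#' @param x Numeric vector, 3 <= n <= 5000.
#' @return List with `W` and `p`, or both `NA` (with a warning) for
#'   constant input.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000) {
    stop("input error: Shapiro-Wilk needs 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    warning("shapiro_wilk undefined for constant input")
    return(list(W = NA_real_, p = NA_real_))
  }
  res <- stats::shapiro.test(x)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Method-concordance report for paired scores
#'
#' For every pair of scoring methods: Cohen's kappa on the dichotomised
#' Allred totals (low 0-6 / high 7-8) and on mean-dichotomised H-scores,
#' Spearman's rho and the exact two-sided Wilcoxon signed-rank p on the raw
#' H-scores, plus per-method means and Shapiro-Wilk normality gates.
#'
#' @param h_scores Data frame/matrix, cases x methods, of H-scores.
#' @param allred_scores Data frame/matrix, cases x methods, of Allred totals
#'   (same method columns).
#' @param pooling Dichotomisation pooling for H-scores, see
#'   [dichotomise_hscore()].
#' @return Object of class `concordance_report`: `pairs` data frame
#'   (`method_a`, `method_b`, `kappa_allred`, `band_allred`, `kappa_h`,
#'   `band_h`, `spearman_h`, `wilcoxon_p_h`), `means`, `h_categories`,
#'   `allred_categories`, `h_threshold`, `shapiro`.
#' @export
build_report <- function(h_scores, allred_scores,
                         pooling = c("POOLED_ALL", "PER_METHOD")) {
  pooling <- match.arg(pooling)
  h <- as.matrix(h_scores)
  a <- as.matrix(allred_scores)
  if (ncol(h) < 2 || nrow(h) < 2) {
    stop("input error: need >= 2 methods and >= 2 cases", call. = FALSE)
  }
  if (!identical(dim(h), dim(a))) {
    stop("input error: H and Allred tables must have matching shape",
         call. = FALSE)
  }
  if (anyNA(h) || anyNA(a)) {
    stop("input error: missing values in paired scores", call. = FALSE)
  }
  methods <- colnames(h)
  if (is.null(methods)) methods <- paste0("method", seq_len(ncol(h)))
  h_cat <- dichotomise_hscore(h, pooling)
  a_cat <- matrix(dichotomise_allred(a), nrow(a), ncol(a),
                  dimnames = dimnames(a))
  lv <- c("LOW", "HIGH")
  combos <- utils::combn(seq_along(methods), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    ka <- kappa_from_vectors(a_cat[, i], a_cat[, j], lv)
    kh <- kappa_from_vectors(h_cat[, i], h_cat[, j], lv)
    wx <- wilcoxon_signed_rank(h[, i], h[, j],
                               mode = if (nrow(h) <= 50) "EXACT"
                                      else "NORMAL_APPROX")
    data.frame(method_a = methods[i], method_b = methods[j],
               kappa_allred = ka$kappa, band_allred = ka$band,
               kappa_h = kh$kappa, band_h = kh$band,
               spearman_h = spearman_rho(h[, i], h[, j]),
               wilcoxon_p_h = wx$p)
  }))
  means <- data.frame(method = methods,
                      mean_h = colMeans(h), mean_allred = colMeans(a))
  shapiro <- if (nrow(h) >= 3) {
    data.frame(method = methods,
               W = vapply(seq_along(methods), function(j) {
                 if (stats::var(h[, j]) == 0) NA_real_
                 else shapiro_wilk(h[, j])$W
               }, numeric(1)),
               p = vapply(seq_along(methods), function(j) {
                 if (stats::var(h[, j]) == 0) NA_real_
                 else shapiro_wilk(h[, j])$p
               }, numeric(1)))
  } else NULL
  structure(list(pairs = pairs, means = means, h_categories = h_cat,
                 allred_categories = a_cat,
                 h_threshold = attr(h_cat, "threshold"), shapiro = shapiro),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Method concordance\n")
  cat(sprintf("H-score dichotomisation threshold: %.2f\n",
              x$h_threshold[1]))
  print(x$pairs, row.names = FALSE, digits = 3)
  cat("\nPer-method means:\n")
  print(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a concordance report to CSV and JSON
#'
#' @param report A `concordance_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$pairs, file.path(dir, "concordance_pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(report$means, file.path(dir, "method_means.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(pairs = report$pairs, means = report$means,
         h_threshold = report$h_threshold),
    file.path(dir, "concordance.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
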