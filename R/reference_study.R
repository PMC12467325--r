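#' Bundled reference scoring data
#'
#' The package bundles the published summary data of a DKK-3 TMA study in
#' which 97 oral squamous cell carcinoma cores were Allred-scored visually
#' and by digital image analysis, and six representative cases were
#' additionally scored from hyperspectral images. Three fixtures are
#' available:
#' \describe{
#'   \item{`"contingency"`}{the 2x2 visual-vs-digital dichotomised-Allred
#'     agreement table over the 97-core cohort.}
#'   \item{`"cases"`}{per-case H-scores and Allred totals for the six cases
#'     under the visual, digital and HSI methods.}
#'   \item{`"dichotomised"`}{the published per-case low/high (1/2) category
#'     vectors for the six cases.}
#'   \item{`"reported"`}{the published summary statistics (kappas, means,
#'     Spearman's rho, core count) used for side-by-side comparison.}
#' }
#'
#' @param which One of `"contingency"`, `"cases"`, `"dichotomised"`,
#'   `"reported"`.
#' @return A data frame (or, for `"contingency"`, a 2x2 integer matrix).
#' @export
reference_study_data <- function(which = c("contingency", "cases",
                                           "dichotomised", "reported")) {
  which <- match.arg(which)
  path <- function(f) system.file("extdata", f, package = "hsiscore",
                                  mustWork = TRUE)
  switch(which,
    contingency = {
      df <- utils::read.csv(path("reference_allred_contingency.csv"))
      m <- as.matrix(df[, c("digital_LOW", "digital_HIGH")])
      dimnames(m) <- list(visual = c("LOW", "HIGH"),
                          digital = c("LOW", "HIGH"))
      m
    },
    cases = utils::read.csv(path("reference_case_scores.csv")),
    dichotomised = utils::read.csv(path("reference_dichotomised.csv")),
    reported = utils::read.csv(path("reference_reported_values.csv"))
  )
}

#' Recompute the reference study's agreement statistics
#'
#' Recomputes, from the bundled fixtures, every published summary quantity
#' that is derivable from them and lays each beside its published value:
#' Cohen's kappa from the 97-core contingency table, the six-case per-method
#' means, the mean-threshold H-score dichotomisation, the per-pair kappas on
#' dichotomised scores, Spearman's rho, the Wilcoxon signed-rank p-values
#' and the representative-core count.
#'
#' Two published values are known not to follow from the published per-case
#' data and are flagged rather than silently replaced: the visual-vs-HSI
#' kappa (published 0.42; unweighted kappa on the published category vectors
#' gives 0.25) and the visual-vs-HSI Spearman rho (published 0.67; the six
#' published H-score pairs give a much smaller value). Both rows carry
#' `agrees = FALSE` and a note.
#'
#' @param out_dir Optional directory to write `reference_comparison.csv`
#'   into.
#' @param tol Agreement tolerance on the recomputed-vs-published comparison
#'   (default 0.005 on kappas and correlations, scaled for means).
#' @return Data frame of class `reference_comparison`: `quantity`,
#'   `computed`, `printed`, `agrees`, `note`.
#' @export
reproduce_reference_results <- function(out_dir = NULL, tol = 0.005) {
  cont <- reference_study_data("contingency")
  cases <- reference_study_data("cases")
  dich <- reference_study_data("dichotomised")
  reported <- reference_study_data("reported")
  printed <- stats::setNames(reported$printed, reported$quantity)

  h <- as.matrix(cases[, c("h_visual", "h_digital", "h_hsi")])
  a <- as.matrix(cases[, c("allred_visual", "allred_digital", "allred_hsi")])
  colnames(h) <- colnames(a) <- c("VISUAL", "DIGITAL", "HSI")
  report <- build_report(h, a)

  manifest <- generate_tma_manifest(c(30, 30, 30, 16), 9, seed = 1)

  lv <- c("1", "2")
  kap_pub <- function(x, y) kappa_from_vectors(as.character(x),
                                               as.character(y), lv)$kappa
  rows <- list(
    list("kappa_allred_visual_digital_cohort",
         cohen_kappa(cont)$kappa, "97-core contingency table"),
    list("mean_h_visual", mean(h[, "VISUAL"]), ""),
    list("mean_h_digital", mean(h[, "DIGITAL"]), ""),
    list("mean_h_hsi", mean(h[, "HSI"]), ""),
    list("mean_allred_visual", mean(a[, "VISUAL"]), ""),
    list("mean_allred_digital", mean(a[, "DIGITAL"]), ""),
    list("mean_allred_hsi", mean(a[, "HSI"]), ""),
    list("kappa_allred_visual_digital_cases",
         kap_pub(dich$allred_visual, dich$allred_digital),
         "from published category vectors"),
    list("kappa_allred_digital_hsi_cases",
         kap_pub(dich$allred_digital, dich$allred_hsi),
         "from published category vectors"),
    list("kappa_allred_visual_hsi_cases",
         kap_pub(dich$allred_visual, dich$allred_hsi),
         "published 0.42 is not reproduced by unweighted kappa on the published vectors"),
    list("kappa_h_visual_digital_cases",
         kap_pub(dich$h_visual, dich$h_digital),
         "from published category vectors"),
    list("kappa_h_digital_hsi_cases",
         kap_pub(dich$h_digital, dich$h_hsi),
         "from published category vectors"),
    list("kappa_h_visual_hsi_cases",
         kap_pub(dich$h_visual, dich$h_hsi),
         "published 0.42 is not reproduced by unweighted kappa on the published vectors"),
    list("spearman_h_visual_hsi", spearman_rho(h[, "VISUAL"], h[, "HSI"]),
         "published 0.67 is not reproduced from the six published H-score pairs"),
    list("representative_cores", sum(manifest$representative),
         "3 x 30 + 16 cores, nine excluded")
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    p <- unname(printed[[r[[1]]]])
    scale_tol <- if (abs(p) > 1) max(tol, 0.005 * abs(p)) else tol
    data.frame(quantity = r[[1]], computed = r[[2]], printed = p,
               agrees = abs(r[[2]] - p) <= scale_tol, note = r[[3]])
  }))
  class(out) <- c("reference_comparison", class(out))
  attr(out, "recomputed_h_categories") <- report$h_categories
  attr(out, "report") <- report
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "reference_comparison.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.reference_comparison <- function(x, ...) {
  cat("Recomputed vs published reference-study statistics\n")
  df <- as.data.frame(x)
  df$computed <- round(df$computed, 4)
  print(df, row.names = FALSE, right = FALSE)
  if (any(!x$agrees)) {
    cat("\nFlagged discrepancies (published value not derivable from the published data):\n")
    for (i in which(!x$agrees)) {
      cat(sprintf("  - %s: computed %.3f vs published %.3f. %s\n",
                  x$quantity[i], x$computed[i], x$printed[i], x$note[i]))
    }
  }
  invisible(x)
}
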