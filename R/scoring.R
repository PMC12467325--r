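# Simultaneous 8-connected label propagation: starting from a labelled
# nucleus image (0 = unlabelled), grow labels outward for `radius`
# iterations over the pixels allowed by `allowed`. A pixel is claimed at the
# iteration equal to its chessboard distance from the nearest nucleus, so
# the result is a nearest-nucleus partition; simultaneous ties go to the
# smaller nucleus id.
propagate_labels <- function(nucleus_labels, radius, allowed) {
  lab <- nucleus_labels
  nr <- nrow(lab); nc <- ncol(lab)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (it in seq_len(radius)) {
    cand <- matrix(Inf, nr, nc)
    for (s in shifts) {
      shifted <- matrix(0, nr, nc)
      r_src <- max(1, 1 - s[1]):min(nr, nr - s[1])
      c_src <- max(1, 1 - s[2]):min(nc, nc - s[2])
      shifted[r_src + s[1], c_src + s[2]] <- lab[r_src, c_src]
      shifted[shifted == 0] <- Inf
      cand <- pmin(cand, shifted)
    }
    new <- lab == 0 & allowed & is.finite(cand)
    lab[new] <- cand[new]
  }
  lab
}

#' Delineate cells from a label map
#'
#' Nuclei are the 8-connected components of `NUCLEI` pixels with at least
#' `min_nucleus_px` pixels. Each cell's cytoplasm is the set of
#' `DKK3_POSITIVE` pixels within a ring of `ring_radius` px (chessboard
#' distance) of its nucleus, with every pixel assigned to its nearest
#' nucleus only, so cells partition the stained area without double
#' counting. The cell's DAB optical density is the mean of `od_image` over
#' its cytoplasm pixels (0 when it has none, i.e. an unstained cell).
#'
#' @param labels A `label_map` (or bare character label matrix).
#' @param od_image Numeric matrix of per-pixel DAB OD, e.g. mean absorbance
#'   over 520-650 nm; same shape as the label image.
#' @param min_nucleus_px Minimum nucleus size in px (default 4).
#' @param ring_radius Cytoplasm ring radius in px (default 3).
#' @return Data frame with one row per cell: `cell_id`, `row`, `col`
#'   (nucleus centroid), `nucleus_px`, `cytoplasm_px`, `mean_od`.
#' @export
segment_cells <- function(labels, od_image, min_nucleus_px = 4,
                          ring_radius = 3) {
  classes <- if (inherits(labels, "label_map")) labels$classes else labels
  stopifnot(identical(dim(classes), dim(od_image)))
  nuc_mask <- classes == "NUCLEI"
  empty <- data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
                      nucleus_px = integer(0), cytoplasm_px = integer(0),
                      mean_od = numeric(0))
  if (!any(nuc_mask)) return(empty)
  comp <- EBImage::bwlabel(nuc_mask)
  comp <- matrix(as.integer(comp), nrow(classes), ncol(classes))
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= min_nucleus_px)
  if (length(keep) == 0) return(empty)
  # compact ids 1..k in original component order (top-left first)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  nuc_lab <- matrix(0L, nrow(classes), ncol(classes))
  nuc_lab[comp > 0] <- remap[comp[comp > 0]]
  dkk_mask <- classes == "DKK3_POSITIVE"
  cyto_lab <- propagate_labels(nuc_lab, ring_radius, allowed = !nuc_mask)
  cyto_lab[nuc_lab > 0] <- 0L  # cytoplasm excludes the nucleus itself
  cells <- lapply(seq_along(keep), function(k) {
    nuc_idx <- which(nuc_lab == k)
    rows <- ((nuc_idx - 1L) %% nrow(classes)) + 1L
    cols <- ((nuc_idx - 1L) %/% nrow(classes)) + 1L
    cyto_idx <- which(cyto_lab == k & dkk_mask)
    data.frame(
      cell_id = k, row = mean(rows), col = mean(cols),
      nucleus_px = length(nuc_idx), cytoplasm_px = length(cyto_idx),
      mean_od = if (length(cyto_idx) > 0) mean(od_image[cyto_idx]) else 0)
  })
  do.call(rbind, cells)
}

#' Default DAB optical-density thresholds
#'
#' OD bin edges separating negative/weak/moderate/strong staining, applied
#' to a cell's mean DAB OD over 520-650 nm. Exposed so users can recalibrate
#' for their optics.
#'
#' @export
DEFAULT_OD_THRESHOLDS <- c(weak = 0.2, moderate = 0.45, strong = 0.9)

#' Bin a DAB optical density into an intensity tier
#'
#' Lower-inclusive, half-open bins: `NEGATIVE` below `t_weak`, `WEAK` in
#' \[t_weak, t_moderate), `MODERATE` in \[t_moderate, t_strong), `STRONG`
#' at or above `t_strong`.
#'
#' @param mean_od Non-negative OD value(s).
#' @param thresholds Named vector `c(weak=, moderate=, strong=)` with
#'   `0 < weak < moderate < strong`.
#' @return Character vector of tiers (see [TIERS]).
#' @export
bin_intensity <- function(mean_od, thresholds = DEFAULT_OD_THRESHOLDS) {
  t <- thresholds
  if (!(t[["weak"]] > 0 && t[["weak"]] < t[["moderate"]] &&
        t[["moderate"]] < t[["strong"]])) {
    stop("thresholds must satisfy 0 < weak < moderate < strong", call. = FALSE)
  }
  if (any(mean_od < 0)) stop("mean_od must be non-negative", call. = FALSE)
  out <- rep("NEGATIVE", length(mean_od))
  out[mean_od >= t[["weak"]]] <- "WEAK"
  out[mean_od >= t[["moderate"]]] <- "MODERATE"
  out[mean_od >= t[["strong"]]] <- "STRONG"
  out
}

#' H-score from staining fractions
#'
#' `H = 1 * %weak + 2 * %moderate + 3 * %strong`, where the percentages are
#' of all tumour cells; ranges from 0 (no staining) to 300 (100% of cells
#' strongly stained).
#'
#' @param pct_weak,pct_moderate,pct_strong Percentages in \[0, 100\] whose
#'   sum must not exceed 100.
#' @return H-score in \[0, 300\].
#' @export
compute_h_score <- function(pct_weak, pct_moderate, pct_strong) {
  f <- c(pct_weak, pct_moderate, pct_strong)
  if (any(f < 0) || any(f > 100)) {
    stop("input error: fractions must lie in [0, 100]", call. = FALSE)
  }
  if (sum(f) > 100 + 1e-9) {
    stop("input error: fractions sum to more than 100", call. = FALSE)
  }
  1 * pct_weak + 2 * pct_moderate + 3 * pct_strong
}

#' Allred score from positivity and mean intensity
#'
#' The Allred system sums a proportion score (PS, 0-5) for the percentage of
#' positive tumour cells and an intensity score (IS, 0-3) for the core's
#' staining intensity category. PS bins (lower-inclusive as written):
#' 0 at 0%; 1 in (0, 1)%; 2 in \[1, 10\]%; 3 in (10, 33\]%; 4 in (33, 66\]%;
#' 5 above 66%. The IS is the mean tier of positive cells
#' (weak = 1, moderate = 2, strong = 3) rounded half-up.
#'
#' @param pct_positive Percentage of positive cells, \[0, 100\].
#' @param mean_positive_tier Mean numeric tier of the positive cells; ignored
#'   when `pct_positive` is 0.
#' @return List with `ps`, `is`, `total` (`ps + is`, in `{0} U {2..8}`).
#' @export
compute_allred <- function(pct_positive, mean_positive_tier = NA_real_) {
  if (!is.finite(pct_positive) || pct_positive < 0 || pct_positive > 100) {
    stop("input error: pct_positive must lie in [0, 100]", call. = FALSE)
  }
  if (pct_positive == 0) {
    return(list(ps = 0L, is = 0L, total = 0L))
  }
  ps <- if (pct_positive < 1) 1L
        else if (pct_positive <= 10) 2L
        else if (pct_positive <= 33) 3L
        else if (pct_positive <= 66) 4L
        else 5L
  if (!is.finite(mean_positive_tier) ||
      mean_positive_tier < 1 || mean_positive_tier > 3) {
    stop("input error: mean_positive_tier must lie in [1, 3]", call. = FALSE)
  }
  is <- as.integer(floor(mean_positive_tier + 0.5))  # round half-up
  list(ps = ps, is = is, total = ps + is)
}

#' Score one core from its cell records
#'
#' Tier fractions are counts over all detected cells; the H-score and Allred
#' score follow from them. When a `label_map` is supplied, the positive-area
#' percentage is DKK3-positive pixels over the tissue area (DKK3-positive +
#' nuclei + cytoplasm-eligible ring pixels). An empty cell list yields an
#' all-zero score flagged non-representative.
#'
#' @param cells Data frame from [segment_cells()]; a `tier` column is used
#'   if present, otherwise tiers are binned from `mean_od`.
#' @param core_id Core identifier.
#' @param labels Optional `label_map` for the area fraction.
#' @param thresholds OD thresholds for [bin_intensity()].
#' @param ring_radius Ring radius used for the cytoplasm-eligible area.
#' @return One-row data frame: `core_id`, `n_cells`, `pct_weak`,
#'   `pct_moderate`, `pct_strong`, `pct_positive`, `h_score`, `allred_ps`,
#'   `allred_is`, `allred_total`, `positive_area_pct`, `representative`.
#' @export
score_core <- function(cells, core_id = "core", labels = NULL,
                       thresholds = DEFAULT_OD_THRESHOLDS, ring_radius = 3) {
  area_pct <- NA_real_
  if (!is.null(labels)) {
    classes <- if (inherits(labels, "label_map")) labels$classes else labels
    nuc_mask <- classes == "NUCLEI"
    dkk <- sum(classes == "DKK3_POSITIVE")
    if (any(nuc_mask)) {
      comp <- EBImage::bwlabel(nuc_mask)
      comp <- matrix(as.integer(comp), nrow(classes), ncol(classes))
      ring <- propagate_labels(comp, ring_radius, allowed = !nuc_mask)
      eligible <- sum(ring > 0 & !nuc_mask & classes != "DKK3_POSITIVE")
    } else eligible <- 0
    tissue <- dkk + sum(nuc_mask) + eligible
    area_pct <- if (tissue > 0) 100 * dkk / tissue else 0
  }
  if (is.null(cells) || nrow(cells) == 0) {
    return(data.frame(core_id = core_id, n_cells = 0L, pct_weak = 0,
                      pct_moderate = 0, pct_strong = 0, pct_positive = 0,
                      h_score = 0, allred_ps = 0L, allred_is = 0L,
                      allred_total = 0L,
                      positive_area_pct = if (is.na(area_pct)) 0 else area_pct,
                      representative = FALSE))
  }
  tier <- if ("tier" %in% names(cells)) cells$tier
          else bin_intensity(cells$mean_od, thresholds)
  n <- nrow(cells)
  pw <- 100 * sum(tier == "WEAK") / n
  pm <- 100 * sum(tier == "MODERATE") / n
  ps_frac <- 100 * sum(tier == "STRONG") / n
  pct_pos <- pw + pm + ps_frac
  h <- compute_h_score(pw, pm, ps_frac)
  tier_num <- c(WEAK = 1, MODERATE = 2, STRONG = 3)[tier[tier != "NEGATIVE"]]
  allred <- compute_allred(pct_pos, if (length(tier_num)) mean(tier_num)
                                    else NA_real_)
  data.frame(core_id = core_id, n_cells = n, pct_weak = pw, pct_moderate = pm,
             pct_strong = ps_frac, pct_positive = pct_pos, h_score = h,
             allred_ps = allred$ps, allred_is = allred$is,
             allred_total = allred$total, positive_area_pct = area_pct,
             representative = TRUE)
}
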