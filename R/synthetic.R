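#' Construct an endmember spectrum
#'
#' An endmember is the pure absorbance signature of one tissue constituent,
#' modelled as a sum of Gaussian peaks in optical density:
#' `A(lambda) = sum_j peak_od_j * exp(-((lambda - center_j)^2) / (2 width_j^2))`.
#'
#' @param name One of `"DAB"`, `"HEMATOXYLIN"`, `"BACKGROUND"`.
#' @param peaks Data frame with columns `center` (nm), `width` (nm, Gaussian
#'   sigma) and `peak_od` (OD at the peak, non-negative).
#' @return An object of class `endmember`.
#' @export
endmember <- function(name = c("DAB", "HEMATOXYLIN", "BACKGROUND"), peaks) {
  name <- match.arg(name)
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "width", "peak_od") %in% names(peaks)))
  if (any(peaks$peak_od < 0)) {
    stop("parameter error: negative peak OD", call. = FALSE)
  }
  if (any(peaks$width <= 0)) {
    stop("parameter error: peak width must be positive", call. = FALSE)
  }
  if (name == "BACKGROUND" && sum(peaks$peak_od) > 0.02) {
    stop("parameter error: BACKGROUND peak OD must be <= 0.02", call. = FALSE)
  }
  structure(list(name = name, peaks = peaks), class = "endmember")
}

#' Evaluate an endmember on a wavelength axis
#'
#' @param e An `endmember`.
#' @param wavelengths Wavelength axis in nm.
#' @return Non-negative OD vector, one value per wavelength.
#' @export
eval_endmember <- function(e, wavelengths) {
  stopifnot(inherits(e, "endmember"))
  od <- numeric(length(wavelengths))
  for (j in seq_len(nrow(e$peaks))) {
    od <- od + e$peaks$peak_od[j] *
      exp(-0.5 * ((wavelengths - e$peaks$center[j]) / e$peaks$width[j])^2)
  }
  od
}

#' Build the default endmember library
#'
#' Defaults emulate transmitted-light IHC spectra: DAB (the brown chromogen)
#' as a broad band centred at 560 nm so that its absorbance is concentrated
#' in 520-650 nm, hematoxylin (nuclear counterstain) as a narrower band at
#' 600 nm, and a near-transparent background with a very weak broad tilt
#' (peak OD 0.015). The tilt, rather than a perfectly flat zero spectrum,
#' gives unstained pixels a definite spectral shape so correlation-based
#' classification is defined for them; its amplitude is negligible against
#' any stain signal.
#'
#' @param params Optional named list overriding the per-endmember peak
#'   tables (names `DAB`, `HEMATOXYLIN`, `BACKGROUND`).
#' @return Named list of `endmember` objects.
#' @export
build_endmember_library <- function(params = NULL) {
  defaults <- list(
    DAB = data.frame(center = 560, width = 80, peak_od = 1.1),
    HEMATOXYLIN = data.frame(center = 600, width = 45, peak_od = 0.65),
    BACKGROUND = data.frame(center = 700, width = 200, peak_od = 0.015)
  )
  if (!is.null(params)) defaults[names(params)] <- params
  lapply(stats::setNames(names(defaults), names(defaults)),
         function(nm) endmember(nm, defaults[[nm]]))
}

# Deterministic largest-remainder apportionment of `total` units over
# non-negative weights. Ties in remainders go to the earlier index.
largest_remainder <- function(weights, total) {
  if (total == 0L) return(integer(length(weights)))
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic tissue layout
#'
#' Places `n_cells` non-overlapping disc-shaped cells (a nuclear disc inside
#' a cytoplasmic disc) uniformly at random in the image, then deterministically
#' apportions the positive-cell count and its weak/moderate/strong split by
#' largest remainder, so the implied H-score of the layout is exact rather
#' than a sampling outcome. Tier-to-cell assignment is a seeded permutation.
#'
#' @param shape Image shape, `c(rows, cols)`.
#' @param n_cells Number of cells (>= 1).
#' @param percent_positive Percentage of cells with any DAB staining.
#' @param tier_mix Percentages of positive cells that are weak/moderate/strong;
#'   must sum to 100.
#' @param nucleus_radius,cytoplasm_radius Disc radii in px;
#'   `cytoplasm_radius > nucleus_radius >= 1`.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `tissue_layout` with a `cells` data frame
#'   (`row`, `col`, `nucleus_radius`, `cytoplasm_radius`, `tier`).
#' @export
generate_layout <- function(shape = c(128, 128), n_cells = 50,
                            percent_positive = 70,
                            tier_mix = c(weak = 30, moderate = 40, strong = 30),
                            nucleus_radius = 3, cytoplasm_radius = 5,
                            seed = 1) {
  stopifnot(n_cells >= 1, length(tier_mix) == 3)
  if (abs(sum(tier_mix) - 100) > 1e-9) {
    stop("tier_mix must sum to 100", call. = FALSE)
  }
  if (!(cytoplasm_radius > nucleus_radius) || nucleus_radius < 1) {
    stop("need cytoplasm_radius > nucleus_radius >= 1", call. = FALSE)
  }
  n_pos <- largest_remainder(c(percent_positive, 100 - percent_positive),
                             n_cells)[1]
  tier_counts <- largest_remainder(tier_mix, n_pos)
  tiers <- c(rep("WEAK", tier_counts[1]), rep("MODERATE", tier_counts[2]),
             rep("STRONG", tier_counts[3]), rep("NEGATIVE", n_cells - n_pos))
  r <- cytoplasm_radius
  lo <- r + 1
  if (shape[1] < 2 * lo || shape[2] < 2 * lo) {
    stop("layout error: image too small for the cell radius", call. = FALSE)
  }
  cells <- withr::with_seed(seed, {
    rows <- numeric(0); cols <- numeric(0)
    tries <- 0L; max_tries <- 200L * n_cells
    min_d2 <- (2 * r + 1)^2
    while (length(rows) < n_cells && tries < max_tries) {
      tries <- tries + 1L
      cr <- sample(lo:(shape[1] - lo), 1)
      cc <- sample(lo:(shape[2] - lo), 1)
      if (length(rows) == 0 ||
          all((rows - cr)^2 + (cols - cc)^2 >= min_d2)) {
        rows <- c(rows, cr); cols <- c(cols, cc)
      }
    }
    if (length(rows) < n_cells) {
      stop(sprintf(
        "layout error: placed only %d of %d non-overlapping cells; try fewer cells or a larger image",
        length(rows), n_cells), call. = FALSE)
    }
    data.frame(row = rows, col = cols,
               nucleus_radius = nucleus_radius,
               cytoplasm_radius = cytoplasm_radius,
               tier = sample(tiers))
  })
  structure(list(shape = as.integer(shape), cells = cells, seed = seed,
                 percent_positive = percent_positive, tier_mix = tier_mix),
            class = "tissue_layout")
}

#' Scores implied by a layout's ground truth
#'
#' Tier fractions are percentages of all cells; the implied H-score is
#' `1 * %weak + 2 * %moderate + 3 * %strong`.
#'
#' @param layout A `tissue_layout` (or a `ground_truth`).
#' @return List with `pct_weak`, `pct_moderate`, `pct_strong`,
#'   `pct_positive`, `h_score`.
#' @export
implied_scores <- function(layout) {
  tiers <- if (inherits(layout, "tissue_layout")) layout$cells$tier
           else layout$cell_tiers
  n <- length(tiers)
  f <- vapply(c("WEAK", "MODERATE", "STRONG"),
              function(t) 100 * sum(tiers == t) / n, numeric(1))
  list(pct_weak = f[[1]], pct_moderate = f[[2]], pct_strong = f[[3]],
       pct_positive = sum(f),
       h_score = 1 * f[[1]] + 2 * f[[2]] + 3 * f[[3]])
}

disc_pixels <- function(center_row, center_col, radius, shape) {
  r <- floor(radius)
  rows <- max(1, center_row - r):min(shape[1], center_row + r)
  cols <- max(1, center_col - r):min(shape[2], center_col + r)
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - center_row)^2 + (g$col - center_col)^2 <= radius^2
  g[keep, , drop = FALSE]
}

#' Render a layout into a hyperspectral cube with ground truth
#'
#' Transmitted-light acquisition is emulated with base-10 Beer-Lambert
#' mixing: per pixel, `R(lambda) = 10^(-sum_e c_e A_e(lambda))`, where the
#' DAB concentration over a positive cell's cytoplasm is set by its tier,
#' hematoxylin is fixed over every nucleus, and all remaining pixels
#' (including negative-cell cytoplasm, which carries no chromogen) show the
#' background endmember. Additive Gaussian noise of sd `noise_sd` is applied
#' in the reflectance domain, then clipped to \[0, 1.5\].
#'
#' @param layout A `tissue_layout`.
#' @param endmembers Endmember library from [build_endmember_library()].
#' @param wavelengths Wavelength axis (default 500-1000 nm at 5 nm).
#' @param tier_concentrations Named DAB concentration multipliers for
#'   WEAK < MODERATE < STRONG (defaults 0.3 / 0.7 / 1.2).
#' @param hematoxylin_concentration Nuclear hematoxylin concentration.
#' @param noise_sd Reflectance-domain Gaussian noise sd (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return List with `cube` (a REFLECTANCE `spectral_cube`) and `truth`
#'   (class `ground_truth`: `label_image`, `cell_tiers`, `tier_fractions`
#'   in percent of positive cells, `percent_positive`, `implied_h_score`).
#' @export
render_cube <- function(layout, endmembers = build_endmember_library(),
                        wavelengths = seq(500, 1000, by = 5),
                        tier_concentrations = c(WEAK = 0.3, MODERATE = 0.7,
                                                STRONG = 1.2),
                        hematoxylin_concentration = 0.8,
                        noise_sd = 0, seed = layout$seed + 1L) {
  stopifnot(inherits(layout, "tissue_layout"), noise_sd >= 0)
  if (!all(c("WEAK", "MODERATE", "STRONG") %in% names(tier_concentrations))) {
    stop("parameter error: tier_concentrations needs WEAK, MODERATE, STRONG",
         call. = FALSE)
  }
  tc <- tier_concentrations
  if (!(tc[["WEAK"]] < tc[["MODERATE"]] && tc[["MODERATE"]] < tc[["STRONG"]])) {
    stop("parameter error: tier_concentrations must increase WEAK < MODERATE < STRONG",
         call. = FALSE)
  }
  if (!all(c("DAB", "HEMATOXYLIN", "BACKGROUND") %in% names(endmembers))) {
    stop("parameter error: endmember library incomplete", call. = FALSE)
  }
  wavelengths <- wavelength_axis(wavelengths)
  shape <- layout$shape
  npix <- prod(shape)
  c_dab <- numeric(npix)
  c_hem <- numeric(npix)
  labels <- matrix("BACKGROUND", shape[1], shape[2])
  for (i in seq_len(nrow(layout$cells))) {
    cell <- layout$cells[i, ]
    cyto <- disc_pixels(cell$row, cell$col, cell$cytoplasm_radius, shape)
    nuc <- disc_pixels(cell$row, cell$col, cell$nucleus_radius, shape)
    cyto_idx <- (cyto$col - 1L) * shape[1] + cyto$row
    nuc_idx <- (nuc$col - 1L) * shape[1] + nuc$row
    ring_idx <- setdiff(cyto_idx, nuc_idx)
    if (cell$tier != "NEGATIVE") {
      c_dab[ring_idx] <- tc[[cell$tier]]
      labels[ring_idx] <- "DKK3_POSITIVE"
    }
    c_hem[nuc_idx] <- hematoxylin_concentration
    labels[nuc_idx] <- "NUCLEI"
  }
  a_dab <- eval_endmember(endmembers$DAB, wavelengths)
  a_hem <- eval_endmember(endmembers$HEMATOXYLIN, wavelengths)
  a_bg <- eval_endmember(endmembers$BACKGROUND, wavelengths)
  bg_ind <- as.numeric(c_dab == 0 & c_hem == 0)
  od <- outer(c_dab, a_dab) + outer(c_hem, a_hem) + outer(bg_ind, a_bg)
  refl <- 10^(-od)
  if (noise_sd > 0) {
    refl <- refl + withr::with_seed(seed,
      matrix(stats::rnorm(length(refl), sd = noise_sd), nrow(refl)))
  }
  refl <- pmin(pmax(refl, 0), 1.5)
  cube <- spectral_cube(matrix_to_cube_data(refl, shape), wavelengths,
                        "REFLECTANCE",
                        meta = list(generator = "render_cube", seed = seed,
                                    noise_sd = noise_sd))
  tiers <- layout$cells$tier
  n_pos <- sum(tiers != "NEGATIVE")
  tier_fractions <- if (n_pos > 0) {
    vapply(c("WEAK", "MODERATE", "STRONG"),
           function(t) 100 * sum(tiers == t) / n_pos, numeric(1))
  } else c(WEAK = 0, MODERATE = 0, STRONG = 0)
  truth <- structure(
    list(label_image = labels, cell_tiers = tiers,
         tier_fractions = tier_fractions,
         percent_positive = 100 * n_pos / length(tiers),
         implied_h_score = implied_scores(layout)$h_score),
    class = "ground_truth")
  list(cube = cube, truth = truth)
}

#' Generate a tissue-microarray core manifest
#'
#' Emulates a TMA study layout: a list of arrays with given core counts, of
#' which a fixed number of cores are flagged non-representative (e.g. cores
#' without sufficient tumour tissue) by a seeded draw.
#'
#' @param arrays Integer vector of core counts per array
#'   (default `c(30, 30, 30, 16)`).
#' @param n_nonrepresentative Number of cores to flag (default 9).
#' @param seed Integer seed for the flagged-core draw.
#' @return Data frame with `array_id`, `core_id`, `representative`.
#' @export
generate_tma_manifest <- function(arrays = c(30, 30, 30, 16),
                                  n_nonrepresentative = 9, seed = 1) {
  if (any(arrays < 0) || n_nonrepresentative < 0) {
    stop("parameter error: counts must be non-negative", call. = FALSE)
  }
  total <- sum(arrays)
  if (n_nonrepresentative > total) {
    stop("parameter error: cannot flag more cores than exist", call. = FALSE)
  }
  manifest <- data.frame(
    array_id = rep(seq_along(arrays), arrays),
    core_id = unlist(lapply(arrays, seq_len), use.names = FALSE),
    representative = TRUE
  )
  if (n_nonrepresentative > 0 && total > 0) {
    flagged <- withr::with_seed(seed, sample(total, n_nonrepresentative))
    manifest$representative[flagged] <- FALSE
  }
  manifest
}
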