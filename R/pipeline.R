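#' Build a pipeline configuration
#'
#' Collects every tunable parameter of the simulate/analyse pipeline with
#' its default. All randomness in a run flows from `seed` (core `i` uses
#' `seed + i` for layout and `seed + i + 500000` for noise), so two runs
#' with an equal config are identical.
#'
#' @param wavelengths Acquisition wavelength axis in nm.
#' @param window Analysis window `c(lo, hi)` in nm for classification.
#' @param od_window Window for the per-pixel DAB OD measurement.
#' @param endmembers Endmember library ([build_endmember_library()]).
#' @param tier_concentrations DAB concentration multipliers per tier.
#' @param hematoxylin_concentration Nuclear hematoxylin concentration.
#' @param noise_sd Reflectance noise sd.
#' @param shape,n_cells,percent_positive,tier_mix,nucleus_radius,cytoplasm_radius
#'   Layout parameters, see [generate_layout()].
#' @param classifier `"cf"`, `"pca"`, or `"both"`.
#' @param min_corr Correlation-classifier acceptance threshold.
#' @param similarity `"pearson"` or `"cosine"` for [cf_classify()].
#' @param n_components PCA components for segmentation.
#' @param od_thresholds Intensity-bin OD thresholds.
#' @param min_nucleus_px,ring_radius Cell-delineation parameters.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(wavelengths = seq(500, 1000, by = 5),
                            window = c(520, 725),
                            od_window = c(520, 650),
                            endmembers = build_endmember_library(),
                            tier_concentrations = c(WEAK = 0.3, MODERATE = 0.7,
                                                    STRONG = 1.2),
                            hematoxylin_concentration = 0.8,
                            noise_sd = 0.02,
                            shape = c(128, 128), n_cells = 50,
                            percent_positive = 70,
                            tier_mix = c(weak = 30, moderate = 40, strong = 30),
                            nucleus_radius = 3, cytoplasm_radius = 5,
                            classifier = c("cf", "pca", "both"),
                            min_corr = 0.8,
                            similarity = c("pearson", "cosine"),
                            n_components = 3,
                            od_thresholds = DEFAULT_OD_THRESHOLDS,
                            min_nucleus_px = 4, ring_radius = 3,
                            seed = 1) {
  config <- list(
    wavelengths = wavelengths, window = window, od_window = od_window,
    endmembers = endmembers, tier_concentrations = tier_concentrations,
    hematoxylin_concentration = hematoxylin_concentration,
    noise_sd = noise_sd, shape = shape, n_cells = n_cells,
    percent_positive = percent_positive, tier_mix = tier_mix,
    nucleus_radius = nucleus_radius, cytoplasm_radius = cytoplasm_radius,
    classifier = match.arg(classifier), min_corr = min_corr,
    similarity = match.arg(similarity), n_components = n_components,
    od_thresholds = od_thresholds, min_nucleus_px = min_nucleus_px,
    ring_radius = ring_radius, seed = as.integer(seed))
  class(config) <- "pipeline_config"
  validate_config(config)
  config
}

#' Validate a pipeline configuration
#'
#' Checks every module's preconditions up front so a run fails before any
#' stage executes, naming the offending key.
#'
#' @param config A `pipeline_config`.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  fail <- function(key, msg) {
    stop(sprintf("config error in '%s': %s", key, msg), call. = FALSE)
  }
  tryCatch(wavelength_axis(config$wavelengths),
           error = function(e) fail("wavelengths", conditionMessage(e)))
  if (config$window[1] >= config$window[2]) fail("window", "need lo < hi")
  if (!any(config$wavelengths >= config$window[1] &
           config$wavelengths <= config$window[2])) {
    fail("window", "window contains no bands of the axis")
  }
  if (config$od_window[1] >= config$od_window[2]) fail("od_window", "need lo < hi")
  if (config$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (config$n_cells < 1) fail("n_cells", "must be >= 1")
  if (abs(sum(config$tier_mix) - 100) > 1e-9) fail("tier_mix", "must sum to 100")
  if (config$percent_positive < 0 || config$percent_positive > 100) {
    fail("percent_positive", "must lie in [0, 100]")
  }
  if (config$cytoplasm_radius <= config$nucleus_radius) {
    fail("cytoplasm_radius", "must exceed nucleus_radius")
  }
  if (config$min_corr < -1 || config$min_corr > 1) {
    fail("min_corr", "must lie in [-1, 1]")
  }
  t <- config$od_thresholds
  if (!(t[["weak"]] > 0 && t[["weak"]] < t[["moderate"]] &&
        t[["moderate"]] < t[["strong"]])) {
    fail("od_thresholds", "need 0 < weak < moderate < strong")
  }
  tc <- config$tier_concentrations
  if (!(tc[["WEAK"]] < tc[["MODERATE"]] && tc[["MODERATE"]] < tc[["STRONG"]])) {
    fail("tier_concentrations", "must increase WEAK < MODERATE < STRONG")
  }
  invisible(config)
}

core_layout_seed <- function(config, i) config$seed + i
core_noise_seed <- function(config, i) config$seed + i + 500000L

#' Simulate a batch of synthetic cores in memory
#'
#' @param config A `pipeline_config`.
#' @param n_cores Number of cores to generate.
#' @return List of per-core lists: `core_id`, `cube`, `truth`, `layout`.
#' @export
simulate_cores <- function(config, n_cores) {
  validate_config(config)
  lapply(seq_len(n_cores), function(i) {
    layout <- generate_layout(
      shape = config$shape, n_cells = config$n_cells,
      percent_positive = config$percent_positive, tier_mix = config$tier_mix,
      nucleus_radius = config$nucleus_radius,
      cytoplasm_radius = config$cytoplasm_radius,
      seed = core_layout_seed(config, i))
    r <- render_cube(layout, endmembers = config$endmembers,
                     wavelengths = config$wavelengths,
                     tier_concentrations = config$tier_concentrations,
                     hematoxylin_concentration = config$hematoxylin_concentration,
                     noise_sd = config$noise_sd,
                     seed = core_noise_seed(config, i))
    list(core_id = sprintf("core_%03d", i), cube = r$cube, truth = r$truth,
         layout = layout)
  })
}

#' Simulate cores and write them to disk
#'
#' Writes, per core, an ENVI cube, a ground-truth label PNG (with legend)
#' and a cell-tier CSV, plus a batch `manifest.csv`. Fully reproducible:
#' the same config and seed give byte-identical CSV output.
#'
#' @param config A `pipeline_config`.
#' @param n_cores Number of cores.
#' @param out_dir Writable output directory.
#' @return The manifest data frame, invisibly.
#' @export
run_simulate <- function(config, n_cores, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cores <- simulate_cores(config, n_cores)
  rows <- lapply(cores, function(core) {
    cube_file <- file.path(out_dir, paste0(core$core_id, ".envi"))
    truth_file <- file.path(out_dir, paste0(core$core_id, "_truth.png"))
    tier_file <- file.path(out_dir, paste0(core$core_id, "_tiers.csv"))
    write_cube(core$cube, cube_file, "ENVI")
    write_label_image(core$truth$label_image, truth_file)
    utils::write.csv(
      data.frame(cell = seq_along(core$truth$cell_tiers),
                 tier = core$truth$cell_tiers),
      tier_file, row.names = FALSE)
    data.frame(core_id = core$core_id, cube_file = basename(cube_file),
               truth_file = basename(truth_file),
               implied_h_score = core$truth$implied_h_score,
               percent_positive = core$truth$percent_positive)
  })
  manifest <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(core_id = character(0), cube_file = character(0),
               truth_file = character(0), implied_h_score = numeric(0),
               percent_positive = numeric(0))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Analyse one core
#'
#' The full spectral scoring chain: window the cube to the analysis range,
#' convert to absorbance, extract per-class reference spectra from the ROIs,
#' classify pixels (correlation functions and/or PCA nearest-centroid),
#' measure per-pixel DAB OD as the mean absorbance over the OD window,
#' delineate cells and score the core.
#'
#' @param cube A REFLECTANCE `spectral_cube`.
#' @param rois An `roi_set` (e.g. [rois_from_truth()] on synthetic data).
#' @param config A `pipeline_config`.
#' @param core_id Core identifier.
#' @return List: `scores` (one row per classifier route), `labels` (named
#'   list of `label_map`s), `cells` (per-route cell tables).
#' @export
analyse_core <- function(cube, rois, config = pipeline_config(),
                         core_id = "core") {
  win <- crop_spectral_window(cube, config$window[1], config$window[2])
  absb <- reflectance_to_absorbance(win)
  od_band <- absb$wavelengths >= config$od_window[1] &
    absb$wavelengths <= config$od_window[2]
  od_image <- matrix(rowMeans(cube_matrix(absb)[, od_band, drop = FALSE]),
                     dim(absb$data)[1], dim(absb$data)[2])
  routes <- if (config$classifier == "both") c("cf", "pca") else config$classifier
  labels <- list()
  cells <- list()
  scores <- list()
  for (route in routes) {
    lab <- if (route == "cf") {
      refs <- extract_references(absb, rois)
      cf_classify(absb, refs, min_corr = config$min_corr,
                  method = config$similarity)
    } else {
      model <- fit_pca(absb, n_components = config$n_components)
      pca_segment(absb, model, rois, n_components = config$n_components)
    }
    cl <- segment_cells(lab, od_image,
                        min_nucleus_px = config$min_nucleus_px,
                        ring_radius = config$ring_radius)
    sc <- score_core(cl, core_id = core_id, labels = lab,
                     thresholds = config$od_thresholds,
                     ring_radius = config$ring_radius)
    sc$classifier <- route
    labels[[route]] <- lab
    cells[[route]] <- cl
    scores[[route]] <- sc
  }
  list(scores = do.call(rbind, scores), labels = labels, cells = cells)
}

#' Analyse a batch of cores
#'
#' Runs [analyse_core()] over in-memory cores (from [simulate_cores()]) or
#' a directory written by [run_simulate()]. A failing core is logged,
#' flagged non-representative and skipped; the batch continues.
#'
#' @param config A `pipeline_config`.
#' @param cores List from [simulate_cores()]; ignored when `cube_dir` given.
#' @param cube_dir Directory holding `manifest.csv` and per-core files.
#' @param out_dir Optional directory for the score table
#'   (`core_scores.csv`) and, with `classifier = "both"`, the
#'   between-classifier kappa (`classifier_agreement.csv`).
#' @return Data frame of per-core scores (one row per core and classifier
#'   route), with the generator-implied H-score attached when ground truth
#'   is available.
#' @export
run_analyse <- function(config, cores = NULL, cube_dir = NULL,
                        out_dir = NULL) {
  validate_config(config)
  if (is.null(cores)) {
    if (is.null(cube_dir)) stop("supply cores or cube_dir", call. = FALSE)
    manifest <- utils::read.csv(file.path(cube_dir, "manifest.csv"))
    cores <- lapply(seq_len(nrow(manifest)), function(i) {
      truth_labels <- read_label_image(
        file.path(cube_dir, manifest$truth_file[i]))
      list(core_id = manifest$core_id[i],
           cube = read_cube(file.path(cube_dir, manifest$cube_file[i]), "ENVI"),
           truth = structure(list(label_image = truth_labels,
                                  implied_h_score = manifest$implied_h_score[i]),
                             class = "ground_truth"))
    })
  }
  rows <- lapply(cores, function(core) {
    res <- tryCatch({
      rois <- rois_from_truth(core$truth)
      analyse_core(core$cube, rois, config, core_id = core$core_id)$scores
    }, error = function(e) {
      message(sprintf("[analyse] core %s failed and was skipped: %s",
                      core$core_id, conditionMessage(e)))
      sc <- score_core(NULL, core_id = core$core_id)
      sc$classifier <- config$classifier
      sc
    })
    if (!is.null(core$truth$implied_h_score)) {
      res$implied_h_score <- core$truth$implied_h_score
    }
    res
  })
  scores <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scores, file.path(out_dir, "core_scores.csv"),
                     row.names = FALSE)
    if (config$classifier == "both") {
      wide_h <- stats::reshape(
        scores[, c("core_id", "classifier", "allred_total")],
        idvar = "core_id", timevar = "classifier", direction = "wide")
      ka <- kappa_from_vectors(
        dichotomise_allred(wide_h$allred_total.cf),
        dichotomise_allred(wide_h$allred_total.pca), c("LOW", "HIGH"))
      utils::write.csv(
        data.frame(comparison = "cf_vs_pca_allred", kappa = ka$kappa,
                   band = ka$band),
        file.path(out_dir, "classifier_agreement.csv"), row.names = FALSE)
    }
  }
  scores
}
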