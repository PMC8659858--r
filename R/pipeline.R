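#' Canonical predictor names of the full candidate table
#'
#' The frozen column contract of the candidate feature table: 61
#' point-cloud metrics plus the tree-detection summaries `H` (mean top
#' height) and `W` (mean crown width), 17 vegetation indices, 24 texture
#' features (`<band>_<feature>`), the terrain factors `h` and `slope`,
#' and the plot area `area` — 107 predictors in total. The detected tree
#' count `N` is computed but not part of the predictor contract.
#'
#' @return character vector of 107 names.
#' @export
candidate_predictor_names <- function() {
  pls <- percentile_levels()
  c(paste0("H_", pls),
    paste0("H_", c("max", "min", "mean", "med", "std", "var", "mad",
                   "skew", "kurt", "crr", "cv")),
    paste0("H_d", 0:9),
    paste0("I_", pls),
    paste0("I_", c("max", "min", "mean", "med", "std", "var", "mad",
                   "skew", "kurt", "cv")),
    "H", "W",
    vegetation_index_names(),
    as.vector(t(outer(c("R", "G", "B"), glcm_feature_names(),
                      paste, sep = "_"))),
    "h", "slope", "area")
}

#' Build the full candidate feature table of a landscape
#'
#' Runs the complete extraction chain for every plot: height
#' normalization and the 61 point-cloud metrics, CHM rasterization and
#' tree detection (H, W, N), vegetation indices and GLCM textures from
#' the RGB tile, terrain factors from the DEM, and the plot area. The
#' response column `M` is the observed stand volume (m3/ha).
#'
#' @param landscape a [generate_landscape()] result (or a read dataset
#'   shaped like one: fields `dem`, `stand$plots`, `clouds`, `tiles`).
#' @param cutoff_m understory cutoff for the cloud metrics, m.
#' @param chm_pixel_m CHM cell size, m.
#' @return data.frame with `plot_id`, `M`, `N`, and the 107 predictors of
#'   [candidate_predictor_names()] (the 41 optical columns are omitted
#'   for a landscape generated without RGB tiles); attribute `locations`
#'   holds the plot centres (m).
#' @export
build_feature_table <- function(landscape, cutoff_m = 2, chm_pixel_m = 0.5) {
  plots <- landscape$stand$plots
  dem <- landscape$dem
  slope_grid <- horn_slope(dem)
  optical <- !is.null(landscape$tiles)
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    id <- plots$plot_id[i]
    cloud <- normalize_heights(landscape$clouds[[id]], dem = dem)
    m61 <- cloud_metrics(cloud, cutoff_m = cutoff_m)
    chm <- rasterize_chm(cloud, pixel_m = chm_pixel_m)
    det <- detect_trees(chm, min_height_m = cutoff_m)
    opt <- if (optical) {
      tile <- landscape$tiles[[id]]
      c(vegetation_indices(tile), tile_texture_features(tile))
    }
    tf <- terrain_factors(dem, c(plots$center_x[i], plots$center_y[i]),
                          slope_grid)
    c(m61, H = det$H, W = det$W, opt, tf, area = plots$area_ha[i],
      N = as.numeric(det$N))
  })
  feat <- as.data.frame(do.call(rbind, rows))
  cols <- candidate_predictor_names()
  if (!optical)
    cols <- setdiff(cols, c(vegetation_index_names(),
                            as.vector(t(outer(c("R", "G", "B"),
                                              glcm_feature_names(),
                                              paste, sep = "_")))))
  out <- cbind(data.frame(plot_id = plots$plot_id,
                          M = plots$observed_m3ha),
               feat[, c(cols, "N")])
  attr(out, "locations") <- as.matrix(plots[, c("center_x", "center_y")])
  out
}

#' Run the full estimation pipeline on a synthetic landscape
#'
#' simulate -> extract -> screen -> fit -> evaluate -> report. Generates
#' the landscape from `config`, builds the 107-predictor candidate table,
#' writes the screening report, fits the three base learners and their
#' residual-kriging hybrids on all plots (variogram report with one row
#' per learner: family, range, nugget, partial sill, sill effect), runs
#' leave-one-out cross-validation of all six models, and writes every
#' artifact under `out_dir`.
#'
#' @param config a [landscape_config()].
#' @param out_dir output directory.
#' @param learners learners to evaluate.
#' @param screen_in_fold logical: re-screen predictors within each CV
#'   fold (honest CV, default) or once globally.
#' @param threshold,alpha screening parameters.
#' @return list of class `vk_run`: `features`, `screening`, `variogram`
#'   (data.frame), `cv` ([loo_cv()] result), `files`.
#' @export
run_pipeline <- function(config = landscape_config(), out_dir = tempfile(),
                         learners = c("rf", "svr", "ann"),
                         screen_in_fold = TRUE, threshold = 0.4,
                         alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  landscape <- generate_landscape(config)
  feat <- build_feature_table(landscape)
  tab <- feat[, setdiff(names(feat), c("plot_id", "N"))]
  loc_km <- attr(feat, "locations") / 1000

  sc <- screen_features(tab, threshold = threshold, alpha = alpha)
  utils::write.csv(sc$result, file.path(out_dir, "screening.csv"),
                   row.names = FALSE, quote = FALSE)

  # full-data hybrid fits provide the residual variogram report
  vario_rows <- list(); rf_full <- NULL
  for (lrn in learners) {
    cfg <- learner_config(lrn, seed = config$seed)
    fit <- suppressWarnings(fit_learner(
      cfg, sc$table[, -1, drop = FALSE], sc$table$M))
    if (lrn == "rf") rf_full <- fit
    hyb <- hybrid_fit(fit, sc$table[, -1, drop = FALSE], sc$table$M, loc_km)
    v <- hyb$variogram
    vario_rows[[lrn]] <- data.frame(
      residual = paste0("R_", toupper(lrn)), model = v$family,
      range_km = v$range, nugget = v$nugget, partial_sill = v$psill,
      sill_effect = sill_effect(v))
  }
  vario <- do.call(rbind, vario_rows)
  utils::write.csv(vario, file.path(out_dir, "variogram.csv"),
                   row.names = FALSE, quote = FALSE)

  cv_tab <- if (screen_in_fold) tab else sc$table
  cv <- loo_cv(cv_tab, loc_km, learners = learners, hybrids = TRUE,
               screen = screen_in_fold, threshold = threshold,
               alpha = alpha, seed = config$seed)
  files <- write_cv_report(cv, out_dir, rf_model = rf_full)
  utils::write.csv(feat, file.path(out_dir, "features.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, n_plots = config$n_plots,
         n_predictors = length(candidate_predictor_names()),
         n_selected = sum(sc$result$selected),
         package_version = as.character(utils::packageVersion("volkrig"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  structure(list(features = feat, screening = sc$result, variogram = vario,
                 cv = cv, files = files, out_dir = out_dir),
            class = "vk_run")
}
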