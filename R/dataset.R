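#' Write a synthetic dataset to disk
#'
#' Persists a generated landscape as an on-disk dataset: the DEM as a
#' binary grid + JSON sidecar, plot and tree tables as CSV, per-plot
#' point clouds as both LAS 1.2 and CSV, per-plot RGB tiles as one binary
#' grid per band, and a JSON manifest recording the seed, the generator
#' configuration, and the truth parameters. The truth block is protected
#' by an FNV-1a checksum so silent tampering is detected on read.
#'
#' @param landscape a [generate_landscape()] result.
#' @param path output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
write_dataset <- function(landscape, path) {
  stopifnot(inherits(landscape, "vk_landscape"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "clouds"), showWarnings = FALSE)
  dir.create(file.path(path, "tiles"), showWarnings = FALSE)
  write_grid(landscape$dem, file.path(path, "dem"))
  plots <- landscape$stand$plots
  utils::write.csv(plots, file.path(path, "plots.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(landscape$stand$trees, file.path(path, "trees.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in plots$plot_id) {
    if (!is.null(landscape$clouds)) {
      write_cloud_csv(landscape$clouds[[id]],
                      file.path(path, "clouds", paste0(id, ".csv")))
      write_las(landscape$clouds[[id]],
                file.path(path, "clouds", paste0(id, ".las")))
    }
    if (!is.null(landscape$tiles)) {
      tile <- landscape$tiles[[id]]
      for (bn in c("R", "G", "B")) {
        g <- vk_grid(tile[[bn]], origin = tile$origin, pixel = tile$pixel)
        write_grid(g, file.path(path, "tiles", paste0(id, "_", bn)))
      }
    }
  }
  cfg <- landscape$config
  truth <- list(
    residual_variogram = cfg$residual_variogram[
      c("family", "nugget", "psill", "range")],
    plots = plots[, c("plot_id", "true_volume_m3ha", "residual_truth_m3ha",
                      "observed_m3ha")])
  truth_json <- as.character(jsonlite::toJSON(truth, auto_unbox = TRUE,
                                              digits = NA))
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "residual_variogram")],
    truth = truth,
    truth_checksum = fnv1a32(truth_json))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' Restores the DEM, plot/tree tables, point clouds (CSV dialect) and RGB
#' tiles, and verifies the manifest's truth checksum.
#'
#' @param path dataset directory.
#' @return list of class `vk_dataset` with `dem`, `plots`, `trees`,
#'   `clouds`, `tiles`, `manifest`.
#' @export
read_dataset <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  truth_json <- as.character(jsonlite::toJSON(
    list(residual_variogram = as.list(manifest$truth$residual_variogram),
         plots = as.data.frame(manifest$truth$plots)),
    auto_unbox = TRUE, digits = NA))
  if (!identical(fnv1a32(truth_json), manifest$truth_checksum))
    stop("read_dataset: truth block checksum mismatch in ",
         file.path(path, "manifest.json"))
  plots <- utils::read.csv(file.path(path, "plots.csv"))
  trees <- utils::read.csv(file.path(path, "trees.csv"))
  clouds <- tiles <- list()
  for (id in plots$plot_id) {
    cp <- file.path(path, "clouds", paste0(id, ".csv"))
    if (file.exists(cp)) clouds[[id]] <- read_cloud_csv(cp)
    tp <- file.path(path, "tiles", paste0(id, "_R"))
    if (file.exists(paste0(tp, ".json"))) {
      bands <- lapply(c("R", "G", "B"), function(bn)
        read_grid(file.path(path, "tiles", paste0(id, "_", bn))))
      tiles[[id]] <- vk_tile(bands[[1]]$values, bands[[2]]$values,
                             bands[[3]]$values, origin = bands[[1]]$origin,
                             pixel = bands[[1]]$pixel)
    }
  }
  structure(list(dem = read_grid(file.path(path, "dem")), plots = plots,
                 trees = trees, clouds = clouds, tiles = tiles,
                 manifest = manifest), class = "vk_dataset")
}
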