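#' Binary volume equation parameters for Northeast-China conifers
#'
#' Species-specific parameters of the two-way (binary) stem volume equation
#' V = a * D^b * H^c, with V in cubic metres, D the diameter at breast
#' height in centimetres and H the total height in metres. The three
#' built-in rows cover the plantation conifers handled by the package.
#'
#' @return data.frame with columns `species`, `a`, `b`, `c`.
#' @export
volume_params <- function() {
  data.frame(
    species = c("larix", "koraiensis", "sylvestris"),
    a = c(0.00005017, 0.00006353, 0.00006938),
    b = c(1.7583, 1.9436, 1.7631),
    c = c(1.14967, 0.89689, 1.03701),
    stringsAsFactors = FALSE
  )
}

#' Individual-tree stem volume
#'
#' Evaluates the binary volume equation V = a * D^b * H^c for each tree.
#' All three arguments are recycled to a common length.
#'
#' @param species character vector; one of `"larix"`, `"koraiensis"`,
#'   `"sylvestris"`.
#' @param dbh_cm diameter at breast height, cm, strictly positive.
#' @param height_m total tree height, m, strictly positive.
#' @return stem volume in cubic metres.
#' @examples
#' tree_volume("larix", 20, 15)
#' @export
tree_volume <- function(species, dbh_cm, height_m) {
  n <- max(length(species), length(dbh_cm), length(height_m))
  species <- rep_len(as.character(species), n)
  dbh_cm <- rep_len(dbh_cm, n)
  height_m <- rep_len(height_m, n)
  pars <- volume_params()
  idx <- match(species, pars$species)
  if (anyNA(idx))
    stop("tree_volume: unknown species: ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  if (any(dbh_cm <= 0) || any(height_m <= 0))
    stop("tree_volume: dbh_cm and height_m must be > 0")
  pars$a[idx] * dbh_cm^pars$b[idx] * height_m^pars$c[idx]
}

#' Per-hectare plot volume
#'
#' Sums individual-tree volumes over a plot's tree list and divides by the
#' plot area in hectares, giving the stand volume M in m3/ha. The plot area
#' is expressed in hectares so that the summed per-tree volumes (m3) yield
#' m3/ha directly.
#'
#' @param trees data.frame with columns `species`, `dbh_cm`, `height_m`
#'   (extra columns ignored). An empty tree list gives 0 with a message.
#' @param area_ha plot area in hectares, > 0.
#' @return stand volume in m3/ha.
#' @export
plot_volume_per_ha <- function(trees, area_ha) {
  stopifnot(is.numeric(area_ha), length(area_ha) == 1, area_ha > 0)
  if (nrow(trees) == 0) {
    message("plot_volume_per_ha: empty tree list, volume 0")
    return(0)
  }
  sum(tree_volume(trees$species, trees$dbh_cm, trees$height_m)) / area_ha
}
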