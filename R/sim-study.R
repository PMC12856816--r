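#' Generate a complete synthetic study data set
#'
#' Runs every generator with seeds derived from `config$seed`: phylogenies,
#' life-history traits, environmental layers, species ranges, tenure and
#' protected-area mask, spatial predictor summaries, standardized
#' predictors, and ground-truth ordinal threat statuses (with designated
#' suppressed species). The result feeds every downstream stage of the
#' pipeline.
#'
#' @param config a [sim_config].
#' @param true_model a [true_risk_model] (defaults used if `NULL`).
#' @return list with `config`, `true_model`, `trees`, `traits`, `landscape`,
#'   `ranges`, `tenure`, `pa_mask`, `boundary`, `predictors_raw`,
#'   `predictors` (standardized, with `body_mass2`), `centroids`, `status`,
#'   and `data` (analysis data.frame: species, ordinal, predictors).
#' @export
simulate_study <- function(config = sim_config(), true_model = NULL) {
  validate_sim_config(config)
  if (is.null(true_model)) true_model <- true_risk_model()
  seed <- config$seed
  trees <- simulate_phylogenies(config$n_species, config$n_trees,
                                seed = seed)
  traits <- simulate_traits(trees[[1]], seed = seed + 1L)
  land <- simulate_landscape(config, seed = seed + 2L)
  ranges <- simulate_ranges(config, seed = seed + 3L)
  ten <- simulate_tenure(config, seed = seed + 4L)
  sp <- summarize_predictors(ranges, land, traits)
  pred_raw <- sp$predictors
  global_area <- attr(ranges, "global_cells") * config$cell_size^2
  # analysis predictor set: rename traits to model terms; range size is the
  # species' global range (region + margin)
  pr <- data.frame(
    species = pred_raw$species,
    body_mass = pred_raw$body_mass_g,
    age_first_repro = pred_raw$age_first_repro,
    litters_per_year = pred_raw$litters_per_year,
    litter_size = pred_raw$litter_size,
    range_size = unname(global_area[pred_raw$species]),
    fox_overlap = pred_raw$fox_overlap,
    toad_overlap = pred_raw$toad_overlap,
    temp_wet_q = pred_raw$temp_wet_q,
    hii = pred_raw$hii,
    fire_total = pred_raw$fire_total,
    fire_lds = pred_raw$fire_lds,
    stringsAsFactors = FALSE)
  std <- transform_standardize(pr[-1])
  # quadratic mass on the transformed scale, itself standardized
  bm2 <- std$body_mass^2
  std$body_mass2 <- (bm2 - mean(bm2)) / stats::sd(bm2)
  rownames(std) <- pr$species
  status <- assign_threat_status(true_model, as.matrix(std), trees[[1]],
                                 sp$centroids,
                                 suppressed_fraction = config$suppressed_fraction,
                                 seed = seed + 5L)
  dat <- cbind(data.frame(species = pr$species,
                          ordinal = status$ordinal,
                          stringsAsFactors = FALSE), std)
  rownames(dat) <- pr$species
  boundary <- region_boundary(config)
  list(config = config, true_model = true_model, trees = trees,
       traits = traits, landscape = land, ranges = ranges,
       A = attr(ranges, "A"),
       tenure = ten$tenure, pa_mask = ten$pa_mask, boundary = boundary,
       predictors_raw = pred_raw, predictors = std,
       centroids = sp$centroids, status = status, data = dat)
}

#' Region boundary polygon of a simulated study
#'
#' The synthetic region is the rectangle spanned by the grid (planar km, a
#' synthetic CRS).
#'
#' @param config a [sim_config].
#' @return two-column matrix of polygon vertices.
#' @export
region_boundary <- function(config) {
  w <- config$grid_ncols * config$cell_size
  h <- config$grid_nrows * config$cell_size
  cbind(x = c(0, w, w, 0), y = c(0, 0, h, h))
}

#' Write a polygon (or planning units) as GeoJSON
#'
#' @param coords two-column matrix of exterior-ring vertices.
#' @param path output path.
#' @param properties optional named list of feature properties.
#' @return `path` invisibly.
#' @export
write_geojson_polygon <- function(coords, path, properties = NULL) {
  ring <- rbind(coords, coords[1, , drop = FALSE])
  feat <- list(type = "Feature",
               properties = if (is.null(properties)) structure(list(), names = character(0)) else properties,
               geometry = list(type = "Polygon",
                               coordinates = list(unname(
                                 lapply(seq_len(nrow(ring)),
                                        function(i) as.numeric(ring[i, ]))))))
  gj <- list(type = "FeatureCollection", features = list(feat))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a planning-unit lattice as GeoJSON
#'
#' One polygon feature per planning unit with its attribute columns as
#' properties, plus any extra per-unit vectors supplied via `extra`.
#'
#' @param pus a [tessellate_hexagons()] lattice (possibly with added
#'   columns).
#' @param path output path.
#' @param extra named list of per-PU vectors to add as properties.
#' @return `path` invisibly.
#' @export
write_geojson_pus <- function(pus, path, extra = NULL) {
  verts <- attr(pus, "vertices")
  if (is.null(verts)) {
    side <- attr(pus, "side_km")
    verts <- lapply(seq_len(nrow(pus)),
                    function(i) hex_vertices(pus$x[i], pus$y[i], side))
  }
  feats <- lapply(seq_len(nrow(pus)), function(i) {
    props <- as.list(as.data.frame(pus)[i, , drop = FALSE])
    for (nm in names(extra)) props[[nm]] <- extra[[nm]][i]
    ring <- verts[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(r) as.numeric(ring[r, ]))))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
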