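#' Run the 2 x 2 scenario grid
#'
#' Solves the reserve-selection problem for every combination of protection
#' criterion (current risk vs. positive latent risk) and conservation
#' objective (any tenure vs. Indigenous tenure only), on a shared
#' planning-unit table and feature matrix, and computes per-unit selection
#' frequency over the four scenarios. Selection frequency counts newly
#' selected units only (locked-in units would trivially score 4);
#' `include_locked` switches that off.
#'
#' @param pu a [build_pu_table()] result.
#' @param risk_current named ordinal statuses.
#' @param risk_latent named mean latent risks.
#' @param A named in-region distribution proportions (scalar 1 if absent).
#' @param latent_threshold latent-risk target cutoff.
#' @param cap target-proportion cap.
#' @param gap,node_limit passed to [solve_prioritization()].
#' @param include_locked count locked-in units in selection frequency.
#' @return an object of class `scenario_set`: `solutions` and `metrics`
#'   (lists keyed `current_obj1`, ..., `latent_obj2`), `targets` (per
#'   criterion), `freq` (per-PU selection frequency 0..4), `high_priority`
#'   (ids with frequency 4), `table` (metrics data.frame, 4 rows).
#' @export
run_scenarios <- function(pu, risk_current, risk_latent, A = 1,
                          latent_threshold = 1.5, cap = 0.75,
                          gap = 0, node_limit = 500000L,
                          include_locked = FALSE) {
  totals <- attr(pu$features, "totals")
  tg <- list(
    current = build_targets(risk_current, totals, "current", cap = cap,
                            A = A),
    latent = build_targets(risk_latent, totals, "latent",
                           latent_threshold = latent_threshold, cap = cap,
                           A = A))
  solutions <- list(); metrics <- list()
  rows <- list()
  for (crit in c("current", "latent")) {
    for (obj in 1:2) {
      key <- sprintf("%s_obj%d", crit, obj)
      prob <- tryCatch(build_problem(pu, tg[[crit]], objective = obj),
                       error = function(e)
                         stopf("scenario %s: %s", key, conditionMessage(e)))
      sol <- solve_prioritization(prob, "exact", gap = gap,
                                  node_limit = node_limit)
      audit_solution(prob, sol)
      met <- solution_metrics(sol, pu)
      solutions[[key]] <- sol
      metrics[[key]] <- met
      rows[[key]] <- data.frame(
        criterion = crit, objective = obj,
        n_pu = met$n_new, proxy_cost = met$cost_new,
        area_km2 = met$area_total_km2, boundary_km = met$boundary_km,
        mean_coverage_pct = met$mean_coverage_pct,
        status = sol$status, stringsAsFactors = FALSE)
    }
  }
  ids <- pu$pus$id
  freq <- stats::setNames(integer(length(ids)), ids)
  for (key in names(solutions)) {
    inset <- if (include_locked) solutions[[key]]$selected
    else solutions[[key]]$new
    freq[as.character(inset)] <- freq[as.character(inset)] + 1L
  }
  structure(list(solutions = solutions, metrics = metrics, targets = tg,
                 freq = freq, high_priority = ids[freq == 4L],
                 table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 include_locked = include_locked),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("<scenario_set> 4 scenarios (criterion x objective)\n")
  print(x$table)
  cat(sprintf("High-priority PUs (selected in all 4): %d\n",
              length(x$high_priority)))
  invisible(x)
}

#' Tenure breakdown of scenario selections
#'
#' Cross-tabulates newly selected planning units by land tenure against
#' selection frequency, and reports tenure proportions of each scenario's
#' newly selected units (each scenario's proportions sum to 1).
#'
#' @param scenarios a [run_scenarios()] result.
#' @param pu the shared [build_pu_table()].
#' @return list with `by_frequency` (tenure x frequency count matrix) and
#'   `by_scenario` (tenure x scenario proportion matrix).
#' @export
tenure_breakdown <- function(scenarios, pu) {
  pus <- pu$pus
  lev <- tenure_classes()
  fr <- scenarios$freq[as.character(pus$id)]
  sel_any <- fr > 0
  by_freq <- table(factor(pus$tenure[sel_any], levels = lev),
                   factor(fr[sel_any], levels = 1:4))
  by_scen <- sapply(scenarios$solutions, function(sol) {
    new <- sol$new
    if (!length(new)) return(stats::setNames(rep(0, length(lev)), lev))
    p <- table(factor(pus$tenure[match(new, pus$id)], levels = lev))
    as.numeric(p) / length(new)
  })
  rownames(by_scen) <- lev
  list(by_frequency = unclass(by_freq), by_scenario = by_scen)
}

#' Write the scenario report bundle
#'
#' Emits the metrics table (one CSV row per scenario), the per-unit
#' selection-frequency map as GeoJSON, tenure breakdown tables, and a run
#' manifest (config hash, seed, package version).
#'
#' @param scenarios a [run_scenarios()] result.
#' @param pu the shared [build_pu_table()].
#' @param dir output directory (created if missing).
#' @param config the configuration list to fingerprint in the manifest.
#' @return named character vector of written paths, invisibly.
#' @export
scenario_report <- function(scenarios, pu, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(metrics = file.path(dir, "scenario_metrics.csv"),
             freq = file.path(dir, "selection_frequency.geojson"),
             tenure_freq = file.path(dir, "tenure_by_frequency.csv"),
             tenure_scen = file.path(dir, "tenure_by_scenario.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(scenarios$table, paths[["metrics"]], row.names = FALSE)
  bd <- tenure_breakdown(scenarios, pu)
  utils::write.csv(as.data.frame.matrix(bd$by_frequency),
                   paths[["tenure_freq"]])
  utils::write.csv(as.data.frame(bd$by_scenario), paths[["tenure_scen"]])
  write_geojson_pus(pu$pus, paths[["freq"]],
                    extra = list(selection_frequency =
                                   as.integer(scenarios$freq)))
  manifest <- list(
    package = "tenureplan",
    version = as.character(utils::packageVersion("tenureplan")),
    seed = if (!is.null(config$sim$seed)) config$sim$seed else NA,
    config_hash = config_hash(config),
    n_pu = nrow(pu$pus),
    high_priority = length(scenarios$high_priority))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# MD5 fingerprint of a configuration list via its canonical YAML rendering.
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

default_config <- function() {
  list(
    sim = list(grid_nrows = 100L, grid_ncols = 100L, cell_size = 1,
               n_species = 60L, n_trees = 20L, pa_fraction = 0.18,
               suppressed_fraction = 0.1, smooth_sigma = 8,
               margin_cells = 30L, seed = 1L),
    model = list(vif_threshold = 5, skew_threshold = 1, delta_aicc = 2,
                 estimate_cov = TRUE),
    targets = list(latent_threshold = 1.5, cap = 0.75),
    plan = list(side_km = 7.5, w_floor = 0.01, gap = 0.1,
                node_limit = 150000L))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Run the full pipeline from a configuration
#'
#' Drives every stage end to end: synthetic study generation, predictor
#' screening, full GLS fit with estimated covariance weights, stepwise
#' minimum-adequate-model search, latent risk over the tree sample, risk
#' maps, planning-unit construction, the four prioritization scenarios, and
#' the report bundle. Fully deterministic given the configuration (seed
#' included).
#'
#' @param config `NULL` (package defaults), a configuration list, or the
#'   path of a YAML file with sections `sim`, `model`, `targets`, `plan`.
#' @param out_dir output directory; `NULL` skips all file output.
#' @return list (invisibly when writing): `study`, `vif`, `fit_full`,
#'   `mam`, `latent`, `maps`, `pu`, `scenarios`, `paths`.
#' @export
run_all <- function(config = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), if (is.null(config)) list() else config)
  sim_args <- cfg$sim
  study <- simulate_study(do.call(sim_config, sim_args))

  # collinearity screen on the linear predictors (quadratic term exempt)
  linear <- setdiff(names(study$predictors), "body_mass2")
  vif <- vif_screen(study$predictors[linear],
                    threshold = cfg$model$vif_threshold)
  terms <- vif$retained
  if ("body_mass" %in% terms) terms <- c(terms, "body_mass2")
  f <- stats::reformulate(terms, response = "ordinal")

  fit_full <- risk_gls(f, study$data, tree = study$trees[[1]],
                       centroids = study$centroids,
                       estimate_cov = cfg$model$estimate_cov)
  mam <- step_mam(fit_full, delta = cfg$model$delta_aicc,
                  hierarchy = c(body_mass2 = "body_mass"))
  lat <- latent_risk(mam, study$trees)

  status <- stats::setNames(study$status$ordinal, study$status$species)
  latent <- stats::setNames(lat$latent, lat$species)
  maps <- risk_maps(study$ranges, status, latent)

  pu <- build_pu_table(study$boundary, cfg$plan$side_km, study$tenure,
                       study$landscape$mei, study$landscape$hii,
                       study$ranges, w_floor = cfg$plan$w_floor)
  scen <- run_scenarios(pu, status, latent, A = study$A,
                        latent_threshold = cfg$targets$latent_threshold,
                        cap = cfg$targets$cap, gap = cfg$plan$gap,
                        node_limit = cfg$plan$node_limit)

  paths <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- scenario_report(scen, pu, out_dir, config = cfg)
    # model outputs
    coefs <- summary(mam$fit)$coefficients
    utils::write.csv(data.frame(predictor = rownames(coefs), coefs,
                                row.names = NULL),
                     file.path(out_dir, "mam_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(lat),
                     file.path(out_dir, "latent_risk.csv"),
                     row.names = FALSE)
    jsonlite::write_json(mam$trace, file.path(out_dir, "stepwise_trace.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(study$status, file.path(out_dir, "status.csv"),
                     row.names = FALSE)
    ape::write.tree(study$trees, file.path(out_dir, "trees.nwk"))
    for (nm in names(maps))
      write_asc(maps[[nm]], file.path(out_dir, paste0("map_", nm, ".asc")))
    write_geojson_polygon(study$boundary,
                          file.path(out_dir, "boundary.geojson"))
    paths <- c(paths, out_dir = out_dir)
  }
  out <- list(study = study, vif = vif, fit_full = fit_full, mam = mam,
              latent = lat, maps = maps, pu = pu, scenarios = scen,
              paths = paths)
  if (is.null(out_dir)) out else invisible(out)
}
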