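#' Pipeline configuration
#'
#' Builds the configuration driving [run_pipeline()]: either synthesise a
#' city (scenario settings) or read one from CSV tables, then compute travel
#' times, 2SFCA accessibility, and the deprivation analysis. Accepts a YAML
#' file path or a named list; values override the defaults shown below.
#'
#' @param config `NULL`, a named list, or a path to a YAML file with any of:
#'   `seed`, `scenario` (list of [scenario_config()] arguments),
#'   `input_dir` (read city tables instead of simulating),
#'   `thresholds` (named minutes per mode), `estimate_thresholds` (logical:
#'   re-derive thresholds from the simulated trip survey), `trips`
#'   (list: `n_per_mode`, `slope_ratio`), `covariates` (KRLS covariate
#'   names), `standard_m2` (per-capita flag threshold).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    seed = 1,
    scenario = list(),
    input_dir = NULL,
    thresholds = as.list(access_config()),
    estimate_thresholds = FALSE,
    trips = list(n_per_mode = 1000, slope_ratio = 0.3),
    covariates = NULL,
    standard_m2 = 12
  )
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config)
  thr <- unlist(cfg$thresholds)
  if (any(thr <= 0)) abort("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Demo pipeline configuration
#'
#' A small synthetic scenario (8 x 8 grid, 40 communities, 10 green spaces)
#' that runs the full pipeline in seconds; used in examples and tests.
#'
#' @param seed RNG seed.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 42) {
  pipeline_config(list(
    seed = seed,
    scenario = list(
      grid = c(8, 8), n_communities = 40,
      ugs_levels = tibble(level = 1:3, n = c(1, 3, 6),
                          area_min = c(2e5, 2e4, 2e3),
                          area_max = c(8e5, 2e5, 2e4)),
      coupling = c(less_educated = -1)
    ),
    trips = list(n_per_mode = 400, slope_ratio = 0.3),
    estimate_thresholds = TRUE
  ))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full accessibility and deprivation pipeline
#'
#' Chains every stage: obtain a city (simulated from the scenario, or read
#' from `input_dir`), simulate a trip survey and optionally re-estimate the
#' catchment thresholds from it, compute mode-specific travel-time matrices,
#' the two-step supply-demand ratios and accessibility scores (with
#' level-stratified breakdown and below-standard flags), fit the KRLS
#' deprivation tables, and write every table plus a run manifest to
#' `out_dir`. Outputs are deterministic: rerunning with the same
#' configuration reproduces byte-identical files.
#'
#' @param config A [pipeline_config()], a list or YAML path accepted by it.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results: `city`, `trips`,
#'   `thresholds`, `ttms`, `ratios`, `access`, `stratified`, `deprivation`,
#'   `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(demo_pipeline_config(), tempfile("demo"))
#' res$thresholds
#' }
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  city <- run_stage("city", {
    if (!is.null(config$input_dir)) {
      read_city(config$input_dir)
    } else {
      sc <- config$scenario
      sc$seed <- config$seed
      if (!is.null(sc$ugs_levels)) sc$ugs_levels <- as_tibble(sc$ugs_levels)
      if (!is.null(sc$ses_params)) sc$ses_params <- as_tibble(sc$ses_params)
      generate_city(do.call(scenario_config, sc))
    }
  })

  trips <- run_stage("trips", {
    generate_trip_survey(seed = config$seed + 1,
                         n_per_mode = config$trips$n_per_mode,
                         slope_ratio = config$trips$slope_ratio)
  })

  thresholds <- run_stage("thresholds", {
    if (isTRUE(config$estimate_thresholds)) {
      est <- estimate_threshold(trips)
      do.call(access_config, as.list(setNames(est$threshold_min, est$mode)))
    } else {
      do.call(access_config, config$thresholds)
    }
  })

  ttms <- run_stage("travel_times", city_travel_times(city))
  ratios <- run_stage("supply_demand", {
    supply_demand_ratios(city$ugs, city$communities, ttms, thresholds)
  })
  access <- run_stage("accessibility", {
    accessibility_scores(city$communities, city$ugs, ratios, ttms, thresholds) |>
      flag_below_standard(config$standard_m2)
  })
  stratified <- run_stage("stratified", {
    stratified_accessibility(city$communities, city$ugs, ttms, thresholds)
  })
  deprivation <- run_stage("deprivation", {
    ses_cols <- config$covariates %||% city$config$ses_params$covariate
    ses <- city$communities[c("id", ses_cols)]
    names(ses)[1] <- "community_id"
    cross_sectional_analysis(access, ses, ses_cols)
  })

  run_stage("write", {
    write_city(city, out_dir)
    write_table_csv(trips, file.path(out_dir, "trips.csv"))
    write_table_csv(
      tibble(mode = names(thresholds), threshold_min = unname(thresholds)),
      file.path(out_dir, "thresholds.csv")
    )
    for (m in MODES) {
      write_ttm(ttms[[m]], file.path(out_dir, paste0("ttm_", m, ".csv")))
    }
    write_table_csv(ratios, file.path(out_dir, "ratios.csv"))
    write_table_csv(access, file.path(out_dir, "access.csv"))
    write_table_csv(stratified, file.path(out_dir, "stratified.csv"))
    render_tables(deprivation, out_dir)
  })

  manifest <- list(
    package = "greenaccess",
    version = as.character(utils::packageVersion("greenaccess")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    thresholds = as.list(thresholds),
    n_communities = nrow(city$communities),
    n_green_spaces = length(unique(city$ugs$id)),
    outputs = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(city = city, trips = trips, thresholds = thresholds,
                 ttms = ttms, ratios = ratios, access = access,
                 stratified = stratified, deprivation = deprivation,
                 manifest = manifest))
}
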