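#' Road classes of the multi-modal network
#'
#' The nine road classes the travel-cost model distinguishes, from highways
#' down to internal roads, plus subway track. Every edge of a road network
#' must carry one of these labels.
#'
#' @return Character vector of the nine class names.
#' @export
#' @examples
#' road_classes()
road_classes <- function() {
  c("highway", "city_circle", "auxiliary_road", "main_street",
    "minor_street", "ramp", "feeder", "internal_road", "subway")
}

#' Default mode-by-road-class travel speeds
#'
#' Travel speeds (km/h) for walking, cycling and public transport on each
#' road class. `NA` means the class is inaccessible to that mode: pedestrians
#' and cyclists are restricted to main streets, minor streets, feeders and
#' internal roads (5 and 15 km/h respectively), while public transport runs
#' on every class, fastest on highways and subway track (50 km/h).
#'
#' @return A tibble with columns `mode`, `road_class` and `speed_kmh`
#'   (`NA` = inaccessible), one row per mode-class pair.
#' @export
#' @examples
#' default_speed_table()
default_speed_table <- function() {
  rc <- road_classes()
  speeds <- list(
    public_transport = c(50, 40, 30, 30, 30, 20, 20, 20, 50),
    cycling          = c(NA, NA, NA, 15, 15, NA, 15, 15, NA),
    walking          = c(NA, NA, NA,  5,  5, NA,  5,  5, NA)
  )
  purrr::map_dfr(MODES, function(m) {
    tibble(mode = m, road_class = rc, speed_kmh = speeds[[m]])
  })
}

## Validate a user speed table; returns it with columns in canonical order.
validate_speed_table <- function(speeds) {
  needed <- c("mode", "road_class", "speed_kmh")
  if (!all(needed %in% names(speeds))) {
    abort("speed table needs columns mode, road_class, speed_kmh")
  }
  bad_mode <- setdiff(unique(speeds$mode), MODES)
  if (length(bad_mode)) {
    abort(paste0("unknown mode(s) in speed table: ",
                 paste(bad_mode, collapse = ", ")))
  }
  bad_rc <- setdiff(unique(speeds$road_class), road_classes())
  if (length(bad_rc)) {
    abort(paste0("unknown road class(es) in speed table: ",
                 paste(bad_rc, collapse = ", ")))
  }
  if (any(!is.na(speeds$speed_kmh) & speeds$speed_kmh <= 0)) {
    abort("speeds must be positive where not NA (inaccessible)")
  }
  as_tibble(speeds)[needed]
}

## Named speed lookup (road_class -> km/h, NA = inaccessible) for one mode.
mode_speed_lookup <- function(mode, speeds = default_speed_table()) {
  mode <- match.arg(mode, MODES)
  speeds <- validate_speed_table(speeds)
  s <- speeds[speeds$mode == mode, ]
  if (nrow(s) == 0) abort(paste0("no speeds defined for mode '", mode, "'"))
  setNames(s$speed_kmh, s$road_class)
}
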