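## CSV writer with a stable, diff-friendly numeric format: doubles printed
## with 10 significant digits so reruns are byte-comparable.
write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(v) {
        if (is.na(v)) "" else sprintf("%.10g", v)
      }, character(1))
    }
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Read point or line geometry from CSV or GeoJSON
#'
#' Accepts either a CSV with planar `x`, `y` columns (plus attributes) or a
#' GeoJSON FeatureCollection of `Point` or `LineString` features. Points
#' return one row per feature with coordinates and properties. LineStrings
#' (road links) return one row per feature with endpoint coordinates
#' `x1, y1, x2, y2`, a `length_m` computed from the full geometry when the
#' properties do not supply one, and the feature properties. Coordinates are
#' taken as planar metres (projected CRS); no geodesy is performed.
#'
#' @param path Path to a `.csv`, `.json` or `.geojson` file.
#' @return A tibble; LineString input additionally carries
#'   `attr(, "geometry") == "linestring"`.
#' @export
read_geo <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("x", "y") %in% names(d))) {
      abort(paste0("CSV ", path, " lacks x,y coordinate columns"))
    }
    return(as_tibble(d))
  }
  gj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("malformed JSON in ", path, ": ", conditionMessage(e)))
    }
  )
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else abort(paste0(path, " is not a GeoJSON FeatureCollection"))
  types <- vapply(feats, function(f) f$geometry$type %||% "", character(1))
  if (length(unique(types)) != 1 || !unique(types) %in% c("Point", "LineString")) {
    abort(paste0("unsupported or mixed geometry types in ", path, ": ",
                 paste(unique(types), collapse = ", ")))
  }
  props <- purrr::map_dfr(feats, function(f) {
    p <- f$properties %||% list()
    if (length(p) == 0) tibble(.rows = 1) else as_tibble(p)
  })
  if (unique(types) == "Point") {
    xy <- t(vapply(feats, function(f) unlist(f$geometry$coordinates)[1:2],
                   numeric(2)))
    return(bind_cols(tibble(x = xy[, 1], y = xy[, 2]), props))
  }
  ends <- purrr::map_dfr(feats, function(f) {
    cc <- f$geometry$coordinates
    pts <- do.call(rbind, lapply(cc, function(p) unlist(p)[1:2]))
    seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    tibble(x1 = pts[1, 1], y1 = pts[1, 2],
           x2 = pts[nrow(pts), 1], y2 = pts[nrow(pts), 2],
           geom_length_m = sum(seg))
  })
  out <- bind_cols(ends, props)
  if (!"length_m" %in% names(out)) {
    out$length_m <- out$geom_length_m
  } else {
    out$length_m <- ifelse(is.na(out$length_m), out$geom_length_m, out$length_m)
  }
  attr(out, "geometry") <- "linestring"
  out
}

#' Build a road network from GeoJSON LineStrings
#'
#' Converts a LineString FeatureCollection (properties: `road_class`,
#' optional `length_m` and `oneway`) into a [load_network()] object by
#' uniquing segment endpoints into nodes.
#'
#' @param path GeoJSON path.
#' @return A `road_network`.
#' @export
network_from_geojson <- function(path) {
  seg <- read_geo(path)
  if (!identical(attr(seg, "geometry"), "linestring")) {
    abort(paste0(path, " does not contain LineString features"))
  }
  if (!"road_class" %in% names(seg)) {
    abort("LineString features need a road_class property")
  }
  pts <- unique(rbind(cbind(seg$x1, seg$y1), cbind(seg$x2, seg$y2)))
  nodes <- tibble(id = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2])
  find <- function(x, y) {
    nodes$id[match(paste(x, y), paste(nodes$x, nodes$y))]
  }
  edges <- tibble(
    u = find(seg$x1, seg$y1), v = find(seg$x2, seg$y2),
    length_m = seg$length_m, road_class = seg$road_class,
    oneway = if ("oneway" %in% names(seg)) as.integer(seg$oneway) else 0L
  )
  load_network(nodes, edges)
}

#' Write the tables of a synthetic city to CSV
#'
#' Emits `nodes.csv`, `edges.csv`, `communities.csv` and `ugs.csv` under
#' `dir` in the package's documented column orders.
#'
#' @param city A `city` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_city <- function(city, dir) {
  stopifnot(inherits(city, "city"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_table_csv(city$network$nodes, file.path(dir, "nodes.csv")),
    write_table_csv(city$network$edges, file.path(dir, "edges.csv")),
    write_table_csv(city$communities, file.path(dir, "communities.csv")),
    write_table_csv(city$ugs, file.path(dir, "ugs.csv"))
  )
  invisible(paths)
}

#' Read city tables written by [write_city()]
#'
#' @param dir Directory holding `nodes.csv`, `edges.csv`, `communities.csv`,
#'   `ugs.csv`.
#' @return A `city` object (without a scenario config).
#' @export
read_city <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort(paste0("file not found: ", p))
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  net <- load_network(rd("nodes.csv"), rd("edges.csv"))
  structure(list(network = net, communities = rd("communities.csv"),
                 ugs = rd("ugs.csv"), config = NULL),
            class = "city")
}

#' Write a travel-time matrix to CSV (long form)
#'
#' @param ttm A [travel_time_matrix()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ttm <- function(ttm, path) {
  write_table_csv(tidy(ttm), path)
}
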