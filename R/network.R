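#' Build a validated multi-modal road network
#'
#' Assembles node and edge tables into a road network object. Coordinates are
#' planar metres (a projected CRS); the package never does geodesy. Edges are
#' bidirectional unless flagged one-way, and each undirected edge is expanded
#' into two directed arcs.
#'
#' @param nodes Data frame with columns `id`, `x`, `y` (metres).
#' @param edges Data frame with columns `u`, `v`, `length_m`, `road_class`
#'   and optionally `oneway` (0/1, default 0). `road_class` must be one of
#'   [road_classes()].
#' @return An object of class `road_network`: a list with tibbles `nodes`,
#'   `edges` (as given) and `arcs` (directed expansion).
#' @export
#' @examples
#' nodes <- data.frame(id = 1:2, x = c(0, 1000), y = 0)
#' edges <- data.frame(u = 1, v = 2, length_m = 1000, road_class = "main_street")
#' net <- load_network(nodes, edges)
#' net
load_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  for (col in c("id", "x", "y")) {
    if (!col %in% names(nodes)) abort(paste0("nodes table lacks column '", col, "'"))
  }
  if (anyDuplicated(nodes$id)) {
    abort(paste0("duplicate node ids: ",
                 paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")))
  }
  if (nrow(edges) > 0) {
    for (col in c("u", "v", "length_m", "road_class")) {
      if (!col %in% names(edges)) abort(paste0("edges table lacks column '", col, "'"))
    }
    if (!"oneway" %in% names(edges)) edges$oneway <- 0L
    edges$oneway <- as.integer(edges$oneway)
    bad_rc <- which(!edges$road_class %in% road_classes())
    if (length(bad_rc)) {
      abort(paste0(
        "unknown road class '", edges$road_class[bad_rc[1]], "' in edge row ",
        bad_rc[1], "; valid classes: ", paste(road_classes(), collapse = ", ")
      ))
    }
    dangling <- which(!(edges$u %in% nodes$id) | !(edges$v %in% nodes$id))
    if (length(dangling)) {
      abort(paste0("edge row(s) ", paste(head(dangling, 5), collapse = ", "),
                   " reference node ids absent from the node table"))
    }
    if (any(edges$length_m <= 0)) abort("edge lengths must be > 0 m")
    fwd <- edges[c("u", "v", "length_m", "road_class")]
    names(fwd)[1:2] <- c("from", "to")
    rev <- edges[edges$oneway == 0L, c("v", "u", "length_m", "road_class")]
    names(rev)[1:2] <- c("from", "to")
    arcs <- bind_rows(fwd, rev)
  } else {
    edges <- tibble(u = numeric(), v = numeric(), length_m = numeric(),
                    road_class = character(), oneway = integer())
    arcs <- tibble(from = numeric(), to = numeric(), length_m = numeric(),
                   road_class = character())
  }
  structure(list(nodes = nodes, edges = edges, arcs = arcs),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat("<road_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", nrow(x$arcs), " directed arcs)\n", sep = "")
  invisible(x)
}

#' Mode-specific weighted subgraph
#'
#' Drops arcs whose road class is inaccessible to the mode and weights the
#' rest with traversal time in minutes (`length_m / 1000 / speed_kmh * 60`).
#' All nodes are kept, so isolated nodes remain (unreachable).
#'
#' @param net A [load_network()] result.
#' @param mode One of [travel_modes()].
#' @param speeds Speed table as in [default_speed_table()].
#' @return A directed `igraph` with edge attribute `minutes`; vertex names are
#'   the node ids as character.
#' @export
mode_subgraph <- function(net, mode, speeds = default_speed_table()) {
  stopifnot(inherits(net, "road_network"))
  lookup <- mode_speed_lookup(mode, speeds)
  arcs <- net$arcs
  spd <- unname(lookup[arcs$road_class])
  keep <- !is.na(spd)
  arcs <- arcs[keep, , drop = FALSE]
  minutes <- arcs$length_m / 1000 / spd[keep] * 60
  el <- data.frame(from = as.character(arcs$from), to = as.character(arcs$to),
                   minutes = minutes, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = data.frame(name = as.character(net$nodes$id))
  )
}

#' Snap points to their nearest network node
#'
#' Assigns each point to the nearest node by planar distance. The access leg
#' is assumed free: travel times are measured node-to-node. Ties are broken
#' by the smallest node id (by table order after sorting) so results are
#' deterministic. Points farther than `tolerance_m` from every node are
#' flagged unreachable with a warning.
#'
#' @param points Data frame with columns `id`, `x`, `y`.
#' @param net A [load_network()] result.
#' @param tolerance_m Maximum snap distance in metres (default 500).
#' @return Tibble `id`, `node`, `snap_dist_m`, `reachable`.
#' @export
snap_points <- function(points, net, tolerance_m = 500) {
  stopifnot(inherits(net, "road_network"), tolerance_m > 0)
  points <- as_tibble(points)
  nd <- net$nodes[order(net$nodes$id), ]
  if (nrow(nd) == 0) abort("network has no nodes to snap to")
  res <- purrr::map_dfr(seq_len(nrow(points)), function(i) {
    d <- sqrt((nd$x - points$x[i])^2 + (nd$y - points$y[i])^2)
    j <- which.min(d)  # first minimum = smallest id after sort
    tibble(id = points$id[i], node = nd$id[j], snap_dist_m = d[j],
           reachable = d[j] <= tolerance_m)
  })
  if (any(!res$reachable)) {
    warn(paste0(sum(!res$reachable), " point(s) farther than ", tolerance_m,
                " m from any node; flagged unreachable"))
  }
  res
}

#' Mode-specific shortest travel-time matrix
#'
#' Shortest-path minutes (Dijkstra over the mode subgraph) from each origin
#' node to each destination node. Unreachable pairs are `Inf`; the diagonal
#' for identical nodes is 0.
#'
#' @param net A [load_network()] result.
#' @param origins,destinations Node ids present in `net`.
#' @param boarding_min Constant boarding/waiting penalty in minutes added to
#'   every trip between distinct nodes (default 0; mainly for public
#'   transport, whose cost model otherwise has no headways or transfers).
#' @inheritParams mode_subgraph
#' @return An object of class `travel_time_matrix`: list with `mode`,
#'   `origins`, `destinations` and the numeric matrix `minutes`
#'   (origins x destinations, dimnames are ids as character).
#' @export
travel_time_matrix <- function(net, origins, destinations, mode,
                               speeds = default_speed_table(),
                               boarding_min = 0) {
  stopifnot(inherits(net, "road_network"), boarding_min >= 0)
  miss <- setdiff(c(origins, destinations), net$nodes$id)
  if (length(miss)) {
    abort(paste0("node id(s) not in network: ", paste(head(miss, 5), collapse = ", ")))
  }
  g <- mode_subgraph(net, mode, speeds)
  m <- igraph::distances(
    g, v = as.character(origins), to = as.character(destinations),
    mode = "out", weights = igraph::E(g)$minutes, algorithm = "dijkstra"
  )
  dimnames(m) <- list(as.character(origins), as.character(destinations))
  if (boarding_min > 0) {
    m[is.finite(m) & m > 0] <- m[is.finite(m) & m > 0] + boarding_min
  }
  structure(list(mode = mode, origins = origins, destinations = destinations,
                 minutes = m),
            class = "travel_time_matrix")
}

#' @export
print.travel_time_matrix <- function(x, ...) {
  cat("<travel_time_matrix> mode ", x$mode, ": ", length(x$origins), " x ",
      length(x$destinations), " (minutes)\n", sep = "")
  invisible(x)
}

#' Tidy a travel-time matrix into long form
#'
#' @param x A [travel_time_matrix()] result.
#' @param ... Unused.
#' @return Tibble `origin`, `destination`, `mode`, `minutes`.
#' @method tidy travel_time_matrix
#' @export
tidy.travel_time_matrix <- function(x, ...) {
  m <- x$minutes
  tibble(
    origin = rep(x$origins, times = ncol(m)),
    destination = rep(x$destinations, each = nrow(m)),
    mode = x$mode,
    minutes = as.vector(m)
  )
}
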