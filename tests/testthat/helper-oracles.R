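## Independent oracles and fixture builders. Everything here is deliberately
## written the slow, obvious way (loops, Floyd-Warshall, refits) so the fast
## implementation is checked against a different route.

# All-pairs shortest travel times by Floyd-Warshall over the mode-filtered
# arc list; independent of the igraph/Dijkstra path used by the package.
fw_oracle <- function(net, mode, speeds = default_speed_table()) {
  ids <- as.character(net$nodes$id)
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  sp <- speeds[speeds$mode == mode, ]
  kmh <- stats::setNames(sp$speed_kmh, sp$road_class)
  arcs <- net$arcs
  w <- arcs$length_m / 1000 / unname(kmh[arcs$road_class]) * 60
  for (k in which(!is.na(w))) {
    i <- as.character(arcs$from[k]); j <- as.character(arcs$to[k])
    D[i, j] <- min(D[i, j], w[k])
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Random road network with all nine classes and optional one-way edges.
random_network <- function(seed, max_nodes = 60, oneway_prob = 0.2) {
  withr::with_seed(seed, {
    n <- sample(5:max_nodes, 1)
    nodes <- tibble::tibble(id = seq_len(n),
                            x = stats::runif(n, 0, 10000),
                            y = stats::runif(n, 0, 10000))
    m <- sample(n:(3 * n), 1)
    edges <- tibble::tibble(
      u = sample(n, m, replace = TRUE),
      v = sample(n, m, replace = TRUE),
      length_m = stats::runif(m, 100, 3000),
      road_class = sample(road_classes(), m, replace = TRUE),
      oneway = stats::rbinom(m, 1, oneway_prob)
    )
    edges <- edges[edges$u != edges$v, ]
    load_network(nodes, edges)
  })
}

# Plain-loop multi-mode 2SFCA: travel-time matrices (community x space,
# already minimised over entrances), per-mode population vectors, areas,
# thresholds. Returns supply-demand ratios and accessibility.
brute_2sfca <- function(tts, pops, areas, thr) {
  n_c <- nrow(tts[[1]]); n_u <- ncol(tts[[1]])
  V <- numeric(n_u)
  for (j in seq_len(n_u)) {
    dem <- 0
    for (m in seq_along(tts)) {
      for (i in seq_len(n_c)) {
        if (tts[[m]][i, j] <= thr[[m]]) dem <- dem + pops[[m]][i]
      }
    }
    V[j] <- if (dem > 0) areas[j] / dem else 0
  }
  A <- numeric(n_c)
  for (i in seq_len(n_c)) {
    tot <- 0
    for (m in seq_along(tts)) tot <- tot + pops[[m]][i]
    acc <- 0
    for (m in seq_along(tts)) {
      vsum <- 0
      for (j in seq_len(n_u)) if (tts[[m]][i, j] <= thr[[m]]) vsum <- vsum + V[j]
      acc <- acc + pops[[m]][i] * vsum
    }
    A[i] <- if (tot > 0) acc / tot else NA_real_
  }
  list(V = V, A = A)
}

# Hand-built travel-time matrix object (abstract instances without a network).
make_ttm <- function(mode, origins, destinations, minutes) {
  dimnames(minutes) <- list(as.character(origins), as.character(destinations))
  structure(list(mode = mode, origins = origins, destinations = destinations,
                 minutes = minutes),
            class = c("travel_time_matrix"))
}

# Random abstract 2SFCA instance: communities, single-entrance spaces, and
# consistent travel-time matrices for all three modes.
random_instance <- function(seed, max_comm = 20, max_ugs = 8,
                            single_mode = FALSE) {
  withr::with_seed(seed, {
    n_c <- sample(2:max_comm, 1)
    n_u <- sample(1:max_ugs, 1)
    comm_nodes <- seq_len(n_c)
    ugs_nodes <- 1000 + seq_len(n_u)
    communities <- tibble::tibble(
      id = paste0("C", seq_len(n_c)), node = comm_nodes,
      pop_walking = sample(0:500, n_c, replace = TRUE),
      pop_cycling = if (single_mode) 0 else sample(0:500, n_c, replace = TRUE),
      pop_transit = if (single_mode) 0 else sample(0:500, n_c, replace = TRUE)
    )
    communities <- communities[rowSums(communities[c("pop_walking",
                                                     "pop_cycling",
                                                     "pop_transit")]) > 0, ]
    ugs <- tibble::tibble(
      id = paste0("G", seq_len(n_u)), node = ugs_nodes,
      area_m2 = stats::runif(n_u, 1e3, 1e5),
      level = sample(1:3, n_u, replace = TRUE)
    )
    ttms <- lapply(stats::setNames(travel_modes(), travel_modes()), function(m) {
      make_ttm(m, communities$node, ugs_nodes,
               matrix(stats::runif(nrow(communities) * n_u, 0, 60),
                      nrow(communities), n_u))
    })
    list(communities = communities, ugs = ugs, ttms = ttms)
  })
}

# Brute-force leave-one-out for kernel ridge: refit without observation i at
# the same sigma2/lambda and predict x_i.
brute_loo_errors <- function(X, y, sigma2, lambda) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    Ki <- gaussian_kernel(X[-i, , drop = FALSE], sigma2)
    ci <- solve(Ki + lambda * diag(n - 1), y[-i])
    k_new <- exp(-colSums((t(X[-i, , drop = FALSE]) - X[i, ])^2) / sigma2)
    y[i] - sum(k_new * ci)
  }, numeric(1))
}

# Small synthetic city for fast tests (8 x 8 grid, 30 communities, 10 spaces).
test_city <- function(seed, ...) {
  generate_city(scenario_config(
    seed = seed, grid = c(8, 8), n_communities = 30,
    ugs_levels = tibble::tibble(level = 1:3, n = c(1, 3, 6),
                                area_min = c(3e5, 6e4, 1.5e4),
                                area_max = c(6e5, 1.5e5, 3e4)),
    ...
  ))
}

# Conservation check: population-weighted total accessibility must equal the
# area of all green spaces with nonzero demand.
conservation_rel_err <- function(city, res) {
  pops <- rowSums(as.matrix(
    city$communities[c("pop_walking", "pop_cycling", "pop_transit")]
  ))
  acc <- res$access$access_integrated[match(city$communities$id,
                                            res$access$community_id)]
  supplied <- sum(res$ratios$area_m2[!res$ratios$zero_demand])
  abs(sum(pops * acc) - supplied) / supplied
}

# SES table of a city keyed the way the deprivation analysis expects.
city_ses <- function(city) {
  ses <- city$communities[c("id", city$config$ses_params$covariate)]
  names(ses)[1] <- "community_id"
  ses
}
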