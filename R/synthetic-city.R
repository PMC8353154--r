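#' Default socioeconomic covariate targets
#'
#' Target moments of the Beta-distributed community-level proportions the
#' generator draws: share of residents over 65, unemployed, illiterate, with
#' less than junior-middle-school education, and floating (migrant)
#' population. Defaults follow published community-level descriptive
#' statistics for a mid-sized Chinese provincial capital.
#'
#' @return Tibble `covariate`, `mean`, `sd`.
#' @export
default_ses_params <- function() {
  tibble(
    covariate = c("older", "unemployed", "illiterate", "less_educated",
                  "migrants"),
    mean = c(0.24, 0.19, 0.15, 0.46, 0.24),
    sd   = c(0.07, 0.15, 0.06, 0.15, 0.20)
  )
}

## Default road-class mix of the gridded synthetic city: street-dominated,
## with a thin share of limited-access classes and subway track.
default_class_mix <- function() {
  c(main_street = 0.22, minor_street = 0.28, feeder = 0.20,
    internal_road = 0.15, auxiliary_road = 0.05, city_circle = 0.03,
    highway = 0.02, ramp = 0.03, subway = 0.02)
}

#' Scenario configuration for the synthetic city
#'
#' Collects every knob of the generator: grid geometry, road-class mix,
#' community count and population range, Dirichlet mode-share concentration,
#' Beta moment targets for the SES proportions, the supply-side coupling that
#' plants deprivation (green-space placement weights proportional to
#' `exp(sum_c coupling_c * z(ses_c))`, so negative coupling steers supply
#' away from disadvantaged communities), green-space counts and area ranges
#' per level, and the belt-park fraction. Output is fully determined by
#' `seed`.
#'
#' @param seed Integer RNG seed.
#' @param grid Nodes per side, `c(nx, ny)`.
#' @param spacing_m Grid spacing in metres.
#' @param diagonal_prob Probability a grid cell gets a diagonal street.
#' @param class_mix Named probabilities over [road_classes()], summing to 1.
#' @param n_communities Number of communities.
#' @param pop_range Total population range per community.
#' @param mode_dirichlet Dirichlet concentration for the
#'   walking/cycling/public-transport population split (walking-heavy by
#'   default).
#' @param ses_params Tibble as [default_ses_params()].
#' @param ses_range_frac Correlation range of the latent SES field as a
#'   fraction of the city extent (only relevant when `ses_nugget < 1`).
#' @param ses_nugget Idiosyncratic share of the latent SES field, in
#'   `(0, 1]`. The default 1 draws SES independently across communities,
#'   matching the exchangeability assumption behind the KRLS inference;
#'   values below 1 add district-scale spatial autocorrelation (more
#'   realistic, but chance spatial confounding then inflates the nominal
#'   significance of effects — see the vignette).
#' @param coupling Named vector, covariate -> placement effect (0 = equitable
#'   supply).
#' @param ugs_levels Tibble `level`, `n`, `area_min`, `area_max` (m2):
#'   level 1 = a few large city parks, 3 = many small community gardens.
#' @param belt_fraction Fraction of green spaces emitted as belt parks split
#'   into multiple parts with partitioned area.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            grid = c(20, 20),
                            spacing_m = 1600,
                            diagonal_prob = 0.25,
                            class_mix = default_class_mix(),
                            n_communities = 200,
                            pop_range = c(300, 1500),
                            mode_dirichlet = c(walking = 4, cycling = 3,
                                               public_transport = 3),
                            ses_params = default_ses_params(),
                            ses_range_frac = 0.25,
                            ses_nugget = 1,
                            coupling = c(less_educated = 0),
                            ugs_levels = tibble(
                              level = 1:3, n = c(2, 8, 20),
                              area_min = c(3e5, 6e4, 1.5e4),
                              area_max = c(6e5, 1.5e5, 3e4)
                            ),
                            belt_fraction = 0.15) {
  if (abs(sum(class_mix) - 1) > 1e-8) abort("class_mix must sum to 1")
  bad <- setdiff(names(class_mix), road_classes())
  if (length(bad)) abort(paste0("unknown road class in mix: ", paste(bad, collapse = ", ")))
  if (any(grid < 2) || n_communities < 1 || any(ugs_levels$n < 1)) {
    abort("grid dims, community and green-space counts must be positive")
  }
  ## Beta feasibility of the SES moment targets: sd^2 < mean (1 - mean).
  infeasible <- ses_params$sd^2 >= ses_params$mean * (1 - ses_params$mean)
  if (any(infeasible)) {
    abort(paste0("SES moment target(s) outside the Beta-feasible region: ",
                 paste(ses_params$covariate[infeasible], collapse = ", ")))
  }
  miss <- setdiff(names(coupling), ses_params$covariate)
  if (length(miss)) {
    abort(paste0("coupling names not among SES covariates: ",
                 paste(miss, collapse = ", ")))
  }
  structure(
    list(seed = seed, grid = grid, spacing_m = spacing_m,
         diagonal_prob = diagonal_prob, class_mix = class_mix,
         n_communities = n_communities, pop_range = pop_range,
         mode_dirichlet = mode_dirichlet, ses_params = ses_params,
         ses_range_frac = ses_range_frac, ses_nugget = ses_nugget,
         coupling = coupling, ugs_levels = ugs_levels,
         belt_fraction = belt_fraction),
    class = "scenario_config"
  )
}

beta_shapes <- function(m, s) {
  nu <- m * (1 - m) / s^2 - 1
  list(shape1 = m * nu, shape2 = (1 - m) * nu)
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

## Other endpoints of edges incident to `node` (candidate entrance sites).
node_neighbours <- function(edges, node) {
  unique(c(edges$v[edges$u == node], edges$u[edges$v == node]))
}

## sample() without the scalar-x surprise.
resample <- function(x, k) x[sample.int(length(x), k)]

## Standardized latent field: sum of random radial bumps (district structure)
## plus an independent nugget; standardized to mean 0, sd 1.
latent_spatial_field <- function(x, y, n_centres = 6, range_frac = 0.25,
                                 nugget = 0.3) {
  extent <- max(max(x) - min(x), max(y) - min(y), 1)
  r <- range_frac * extent
  cx <- runif(n_centres, min(x), max(x))
  cy <- runif(n_centres, min(y), max(y))
  a <- stats::rnorm(n_centres)
  f <- rowSums(vapply(seq_len(n_centres), function(k) {
    a[k] * exp(-((x - cx[k])^2 + (y - cy[k])^2) / (2 * r^2))
  }, numeric(length(x))))
  f <- if (sd(f) > 0) (f - mean(f)) / sd(f) else rep(0, length(x))
  z <- sqrt(1 - nugget^2) * f + nugget * stats::rnorm(length(x))
  (z - mean(z)) / sd(z)
}

#' Generate a synthetic city
#'
#' Builds a gridded road network with diagonals and a sampled road-class mix,
#' places communities at nodes with Dirichlet mode shares and Beta SES
#' proportions, and places leveled green spaces with probability coupled to
#' local socioeconomic composition (planting a known, supply-side pattern of
#' deprivation). A configurable fraction of spaces are belt parks emitted as
#' multiple part-records whose areas partition the original area; other
#' spaces may carry several entrances. The same seed reproduces the city
#' exactly.
#'
#' @param cfg A [scenario_config()].
#' @return List of class `city`: `network` ([load_network()] object),
#'   `communities` (tibble: id, node, x, y, mode populations, SES
#'   proportions), `ugs` (tibble: id, node, area_m2, level, one row per
#'   entrance/part), and `config`.
#' @export
#' @examples
#' city <- generate_city(scenario_config(seed = 7, grid = c(6, 6),
#'                                       n_communities = 20))
#' city$network
generate_city <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$seed, {
    nx <- cfg$grid[1]; ny <- cfg$grid[2]; sp <- cfg$spacing_m
    nodes <- tibble(
      id = seq_len(nx * ny),
      x = rep(seq_len(nx) - 1, times = ny) * sp,
      y = rep(seq_len(ny) - 1, each = nx) * sp
    )
    nid <- function(ix, iy) (iy - 1) * nx + ix
    h <- tidyr::expand_grid(ix = seq_len(nx - 1), iy = seq_len(ny)) |>
      mutate(u = nid(.data$ix, .data$iy), v = nid(.data$ix + 1, .data$iy),
             length_m = sp)
    v <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny - 1)) |>
      mutate(u = nid(.data$ix, .data$iy), v = nid(.data$ix, .data$iy + 1),
             length_m = sp)
    dg <- tidyr::expand_grid(ix = seq_len(nx - 1), iy = seq_len(ny - 1)) |>
      mutate(u = nid(.data$ix, .data$iy), v = nid(.data$ix + 1, .data$iy + 1),
             length_m = sp * sqrt(2))
    dg <- dg[runif(nrow(dg)) < cfg$diagonal_prob, ]
    edges <- bind_rows(h, v, dg)[c("u", "v", "length_m")]
    edges$road_class <- sample(names(cfg$class_mix), nrow(edges),
                               replace = TRUE, prob = cfg$class_mix)
    edges$oneway <- 0L
    net <- load_network(nodes, edges)

    n <- cfg$n_communities
    comm_nodes <- if (n <= nrow(nodes)) {
      sample(nodes$id, n)
    } else {
      sample(nodes$id, n, replace = TRUE)
    }
    total_pop <- round(runif(n, cfg$pop_range[1], cfg$pop_range[2]))
    shares <- rdirichlet1(n, cfg$mode_dirichlet)
    communities <- tibble(
      id = paste0("C", seq_len(n)),
      node = comm_nodes,
      x = nodes$x[match(comm_nodes, nodes$id)],
      y = nodes$y[match(comm_nodes, nodes$id)],
      pop_walking = round(total_pop * shares[, 1]),
      pop_cycling = round(total_pop * shares[, 2]),
      pop_transit = round(total_pop * shares[, 3])
    )
    ## SES proportions with Beta marginals and district-scale spatial
    ## autocorrelation: a smooth latent field (Gaussian-copula transform)
    ## so that disadvantage clusters into neighbourhoods, as in real cities.
    for (i in seq_len(nrow(cfg$ses_params))) {
      sh <- beta_shapes(cfg$ses_params$mean[i], cfg$ses_params$sd[i])
      z <- latent_spatial_field(communities$x, communities$y,
                                range_frac = cfg$ses_range_frac,
                                nugget = cfg$ses_nugget)
      communities[[cfg$ses_params$covariate[i]]] <-
        stats::qbeta(pnorm(z), sh$shape1, sh$shape2)
    }

    ugs <- place_green_spaces(cfg, net, communities)
    structure(list(network = net, communities = communities, ugs = ugs,
                   config = cfg),
              class = "city")
  })
}

## Supply-side placement: anchor green spaces at community nodes sampled with
## weight exp(sum_c coupling_c * z(ses_c)); negative coupling starves
## disadvantaged neighbourhoods of supply.
place_green_spaces <- function(cfg, net, communities, id_offset = 0) {
  w <- rep(1, nrow(communities))
  for (cv in names(cfg$coupling)) {
    z <- as.numeric(scale(communities[[cv]]))
    w <- w * exp(cfg$coupling[[cv]] * z)
  }
  w <- w / sum(w)
  rows <- list()
  k <- id_offset
  for (li in seq_len(nrow(cfg$ugs_levels))) {
    lev <- cfg$ugs_levels$level[li]
    for (s in seq_len(cfg$ugs_levels$n[li])) {
      k <- k + 1
      anchor <- communities$node[sample.int(nrow(communities), 1, prob = w)]
      area <- runif(1, cfg$ugs_levels$area_min[li], cfg$ugs_levels$area_max[li])
      nbr <- node_neighbours(net$edges, anchor)
      if (runif(1) < cfg$belt_fraction && length(nbr) >= 1) {
        ## Belt park: parts with partitioned area, one entrance each.
        n_parts <- min(1 + sample(1:2, 1), 1 + length(nbr))
        part_nodes <- c(anchor, resample(nbr, n_parts - 1))
        cuts <- rdirichlet1(1, rep(2, n_parts))[1, ]
        rows[[length(rows) + 1]] <- tibble(
          id = paste0("G", k, "_part", seq_len(n_parts)),
          node = part_nodes, area_m2 = area * cuts, level = lev
        )
      } else {
        ## Single space, possibly with a second entrance.
        ent <- anchor
        if (length(nbr) >= 1 && runif(1) < 0.4) ent <- c(anchor, resample(nbr, 1))
        rows[[length(rows) + 1]] <- tibble(
          id = paste0("G", k), node = ent, area_m2 = area, level = lev
        )
      }
    }
  }
  bind_rows(rows)
}

#' @export
print.city <- function(x, ...) {
  cat("<city> ", nrow(x$network$nodes), " nodes, ", nrow(x$network$edges),
      " edges, ", nrow(x$communities), " communities, ",
      length(unique(x$ugs$id)), " green spaces\n", sep = "")
  invisible(x)
}

#' Generate a synthetic trip survey
#'
#' Draws trip durations per mode from a two-slope cumulative model: the
#' cumulative share of trips rises linearly up to the mode's breakpoint and
#' continues with a flatter slope (ratio `slope_ratio`) out to
#' `breakpoint + tail_min` minutes. With `sampling = "deterministic"` the
#' durations are the exact quantiles of that model (a noise-free survey), so
#' [estimate_threshold()] recovers the planted breakpoints exactly.
#'
#' @param seed RNG seed (ignored for deterministic sampling).
#' @param breakpoints Named planted breakpoints in minutes.
#' @param n_per_mode Trips per mode (at least 100).
#' @param slope_ratio Post-breakpoint over pre-breakpoint cumulative slope,
#'   in (0, 1).
#' @param tail_min Minutes of flat-slope tail beyond the breakpoint.
#' @param sampling `"random"` (default) or `"deterministic"`.
#' @return Tibble `mode`, `minutes`.
#' @export
generate_trip_survey <- function(seed = 1,
                                 breakpoints = c(walking = 18, cycling = 23,
                                                 public_transport = 33),
                                 n_per_mode = 1000,
                                 slope_ratio = 0.3,
                                 tail_min = 27,
                                 sampling = c("random", "deterministic")) {
  sampling <- match.arg(sampling)
  if (n_per_mode < 100) {
    abort("at least 100 trips per mode are required for a stable curve")
  }
  if (slope_ratio <= 0 || slope_ratio >= 1) abort("slope_ratio must be in (0, 1)")
  draw <- function(mode) {
    b <- breakpoints[[mode]]
    tmax <- b + tail_min
    p1 <- b / (b + slope_ratio * (tmax - b))  # mass before the breakpoint
    u <- if (sampling == "deterministic") {
      (seq_len(n_per_mode) - 0.5) / n_per_mode
    } else {
      runif(n_per_mode)
    }
    minutes <- ifelse(u < p1,
                      u / p1 * b,
                      b + (u - p1) / (1 - p1) * (tmax - b))
    tibble(mode = mode, minutes = minutes)
  }
  if (sampling == "random") {
    withr::with_seed(seed, purrr::map_dfr(names(breakpoints), draw))
  } else {
    purrr::map_dfr(names(breakpoints), draw)
  }
}

#' Evolve a city to the next timepoint
#'
#' Applies urban growth: densifies the road network toward
#' `edge_multiplier` times the current edge count (new short links between
#' nearby, not-yet-connected node pairs, classes drawn from the scenario
#' mix), scales mode populations by `population_multiplier`, and places
#' `n_new_ugs` additional green spaces with the scenario's coupling.
#' Community ids are preserved, so [change_analysis()] applies across
#' timepoints. Identity growth returns the city unchanged.
#'
#' @param city A [generate_city()] result.
#' @param edge_multiplier Target edge-count multiplier (>= 1).
#' @param population_multiplier Population multiplier (> 0).
#' @param n_new_ugs Number of green spaces to add (level 3 area range).
#' @param seed Seed for the growth draws; defaults to the city's seed + 1.
#' @return A new `city` object.
#' @export
evolve_scenario <- function(city, edge_multiplier = 1.5,
                            population_multiplier = 1.2, n_new_ugs = 5,
                            seed = NULL) {
  stopifnot(inherits(city, "city"), edge_multiplier >= 1,
            population_multiplier > 0)
  if (edge_multiplier == 1 && population_multiplier == 1 && n_new_ugs == 0) {
    return(city)
  }
  cfg <- city$config
  seed <- seed %||% (cfg$seed + 1)
  withr::with_seed(seed, {
    net <- city$network
    nodes <- net$nodes
    edges <- net$edges
    target <- round(edge_multiplier * nrow(edges))
    n_add <- target - nrow(edges)
    if (n_add > 0) {
      ## Candidate links: node pairs within 2.2 grid steps, not yet connected.
      lim <- 2.2 * cfg$spacing_m
      cand <- tidyr::expand_grid(u = nodes$id, v = nodes$id) |>
        filter(.data$u < .data$v)
      du <- nodes$x[match(cand$u, nodes$id)] - nodes$x[match(cand$v, nodes$id)]
      dv <- nodes$y[match(cand$u, nodes$id)] - nodes$y[match(cand$v, nodes$id)]
      cand$length_m <- sqrt(du^2 + dv^2)
      cand <- cand[cand$length_m <= lim & cand$length_m > 0, ]
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      cand <- cand[!key(cand$u, cand$v) %in% key(edges$u, edges$v), ]
      n_add <- min(n_add, nrow(cand))
      pick <- cand[sample.int(nrow(cand), n_add), ]
      pick$road_class <- sample(names(cfg$class_mix), n_add, replace = TRUE,
                                prob = cfg$class_mix)
      pick$oneway <- 0L
      edges <- bind_rows(edges, pick[names(edges)])
    }
    net2 <- load_network(nodes, edges)

    communities <- city$communities
    for (col in unname(POP_COLS)) {
      communities[[col]] <- round(communities[[col]] * population_multiplier)
    }

    ugs <- city$ugs
    if (n_new_ugs > 0) {
      last <- max(as.integer(sub("^G(\\d+).*$", "\\1", unique(city$ugs$id))))
      grow_cfg <- cfg
      grow_cfg$ugs_levels <- tibble(
        level = 3, n = n_new_ugs,
        area_min = cfg$ugs_levels$area_min[cfg$ugs_levels$level == 3],
        area_max = cfg$ugs_levels$area_max[cfg$ugs_levels$level == 3]
      )
      new_ugs <- place_green_spaces(grow_cfg, net2, communities,
                                    id_offset = last)
      ugs <- bind_rows(ugs, new_ugs)
    }
    structure(list(network = net2, communities = communities, ugs = ugs,
                   config = cfg),
              class = "city")
  })
}

#' Travel-time matrices of a city
#'
#' Computes, per mode, shortest travel times from community anchor nodes to
#' green-space entrance nodes.
#'
#' @param city A `city` object.
#' @param speeds Speed table (default [default_speed_table()]).
#' @return Named list of [travel_time_matrix()] over [travel_modes()].
#' @export
city_travel_times <- function(city, speeds = default_speed_table()) {
  stopifnot(inherits(city, "city"))
  origins <- sort(unique(city$communities$node))
  dests <- sort(unique(city$ugs$node))
  lapply(setNames(MODES, MODES), function(m) {
    travel_time_matrix(city$network, origins, dests, m, speeds)
  })
}

#' One-call accessibility of a synthetic city
#'
#' Chains [city_travel_times()], [supply_demand_ratios()] and
#' [accessibility_scores()].
#'
#' @param city A `city` object.
#' @param thresholds [access_config()] thresholds.
#' @param speeds Speed table.
#' @return List: `ttms`, `ratios`, `access`.
#' @export
city_access <- function(city, thresholds = access_config(),
                        speeds = default_speed_table()) {
  ttms <- city_travel_times(city, speeds)
  ratios <- supply_demand_ratios(city$ugs, city$communities, ttms, thresholds)
  access <- accessibility_scores(city$communities, city$ugs, ratios, ttms,
                                 thresholds)
  list(ttms = ttms, ratios = ratios, access = access)
}
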