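#' Catchment configuration for the multi-mode 2SFCA
#'
#' Threshold travel times (minutes) per mode, defining the catchment of every
#' green space and community. Defaults are the survey-derived inflection
#' points of the cumulative trip-frequency curves: 18 min walking, 23 min
#' cycling, 33 min public transport.
#'
#' @param walking,cycling,public_transport Threshold minutes, all > 0.
#' @return Named numeric vector over [travel_modes()].
#' @export
#' @examples
#' access_config()
access_config <- function(walking = 18, cycling = 23, public_transport = 33) {
  thr <- c(walking = walking, cycling = cycling,
           public_transport = public_transport)
  if (any(!is.finite(thr)) || any(thr <= 0)) abort("thresholds must be positive")
  thr
}

validate_communities <- function(communities) {
  communities <- as_tibble(communities)
  needed <- c("id", "node", unname(POP_COLS))
  miss <- setdiff(needed, names(communities))
  if (length(miss)) {
    abort(paste0("communities table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(communities$id)) abort("duplicate community ids")
  pops <- as.matrix(communities[unname(POP_COLS)])
  if (any(pops < 0)) abort("mode populations must be nonnegative")
  communities
}

validate_ugs <- function(ugs) {
  ugs <- as_tibble(ugs)
  needed <- c("id", "node", "area_m2")
  miss <- setdiff(needed, names(ugs))
  if (length(miss)) {
    abort(paste0("green-space table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(ugs$area_m2 <= 0)) abort("green-space areas must be > 0 m^2")
  area_chk <- ugs |>
    summarise(ok = dplyr::n_distinct(.data$area_m2) == 1, .by = "id")
  if (any(!area_chk$ok)) {
    abort("all entrance rows of a green space must repeat the same area_m2")
  }
  ugs
}

#' Travel time to each green space: minimum over its entrances
#'
#' A green space with several entrances (for example a belt park split into
#' parts) is reached through whichever entrance is closest in time; its travel
#' time from an origin is the minimum over entrance nodes. A space with all
#' entrances unreachable gets `Inf`.
#'
#' @param ttm A [travel_time_matrix()] whose destinations include every
#'   entrance node.
#' @param ugs Green-space table, one row per entrance: columns `id`, `node`,
#'   `area_m2` and optionally `level`.
#' @return Numeric matrix, origins x green-space ids (minutes).
#' @export
ugs_travel_time <- function(ttm, ugs) {
  stopifnot(inherits(ttm, "travel_time_matrix"))
  ugs <- validate_ugs(ugs)
  M <- ttm$minutes
  miss <- setdiff(as.character(ugs$node), colnames(M))
  if (length(miss)) {
    abort(paste0("entrance node(s) absent from travel-time destinations: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  ids <- unique(ugs$id)
  out <- matrix(Inf, nrow = nrow(M), ncol = length(ids),
                dimnames = list(rownames(M), as.character(ids)))
  for (j in seq_along(ids)) {
    ent <- as.character(ugs$node[ugs$id == ids[j]])
    out[, j] <- do.call(pmin, as.data.frame(M[, ent, drop = FALSE]))
  }
  out
}

## Per-mode minutes from community anchors to green spaces (community x ugs).
community_ugs_minutes <- function(communities, ugs, ttms) {
  miss_modes <- setdiff(MODES, names(ttms))
  if (length(miss_modes)) {
    abort(paste0("travel-time matrices missing for mode(s): ",
                 paste(miss_modes, collapse = ", ")))
  }
  lapply(setNames(MODES, MODES), function(m) {
    tt <- ugs_travel_time(ttms[[m]], ugs)
    rows <- as.character(communities$node)
    miss <- setdiff(rows, rownames(tt))
    if (length(miss)) {
      abort(paste0("community node(s) absent from travel-time origins: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
    tt[rows, , drop = FALSE]
  })
}

#' Step 1 of the multi-mode 2SFCA: supply-demand ratios
#'
#' For each green space *j*, sums the mode-specific populations of every
#' community inside the mode's catchment (travel time at or below the mode
#' threshold, inclusive) and divides the area into that demand:
#' `V_j = S_j / (sum_modes sum_{k in catchment(mode)} P_k,mode)`,
#' in square metres per person. Spaces whose catchments contain no population
#' get `V_j = 0` and are flagged `zero_demand` (they are excluded from the
#' supply-conservation identity).
#'
#' @param ugs Green-space table (one row per entrance; see [ugs_travel_time()]).
#' @param communities Community table: `id`, `node`, `pop_walking`,
#'   `pop_cycling`, `pop_transit`.
#' @param ttms Named list of [travel_time_matrix()] per mode, origins =
#'   community anchor nodes, destinations = entrance nodes.
#' @param thresholds Named thresholds as from [access_config()].
#' @return Tibble `ugs_id`, `area_m2`, `demand`, `ratio`, `zero_demand`.
#' @export
supply_demand_ratios <- function(ugs, communities, ttms,
                                 thresholds = access_config()) {
  communities <- validate_communities(communities)
  ugs <- validate_ugs(ugs)
  tts <- community_ugs_minutes(communities, ugs, ttms)
  ids <- unique(ugs$id)
  demand <- numeric(length(ids))
  for (m in MODES) {
    pop <- communities[[POP_COLS[[m]]]]
    inside <- tts[[m]] <= thresholds[[m]]
    demand <- demand + as.vector(crossprod(inside, pop))
  }
  area <- ugs$area_m2[match(ids, ugs$id)]
  zero <- demand == 0
  ratio <- ifelse(zero, 0, area / demand)
  tibble(ugs_id = ids, area_m2 = area, demand = demand,
         ratio = ratio, zero_demand = zero)
}

#' Step 2 of the multi-mode 2SFCA: community accessibility scores
#'
#' For each community *i*, sums the supply-demand ratios of the green spaces
#' inside each mode's catchment, weights each mode's sum by the community's
#' mode population, and divides by total population:
#' `A_i = (sum_modes P_i,mode * sum_{j in catchment(mode)} V_j) / sum_modes P_i,mode`
#' (square metres of green space per person). Mode-specific columns report the
#' accessibility the community would have with its whole population on that
#' single mode, i.e. the plain catchment sum of ratios.
#'
#' @inheritParams supply_demand_ratios
#' @param ratios Result of [supply_demand_ratios()] computed with the same
#'   thresholds.
#' @return A tibble of class `ugs_access`: `community_id`, `access_walking`,
#'   `access_cycling`, `access_transit`, `access_integrated`. Communities with
#'   zero total population are excluded with a warning.
#' @export
accessibility_scores <- function(communities, ugs, ratios, ttms,
                                 thresholds = access_config()) {
  communities <- validate_communities(communities)
  ugs <- validate_ugs(ugs)
  ptot <- rowSums(as.matrix(communities[unname(POP_COLS)]))
  if (any(ptot == 0)) {
    warn(paste0("excluding ", sum(ptot == 0),
                " community(ies) with zero total population"))
    communities <- communities[ptot > 0, , drop = FALSE]
    ptot <- ptot[ptot > 0]
  }
  tts <- community_ugs_minutes(communities, ugs, ttms)
  ids <- unique(ugs$id)
  V <- ratios$ratio[match(ids, ratios$ugs_id)]
  if (anyNA(V)) abort("ratios table does not cover every green space")
  per_mode <- lapply(setNames(MODES, MODES), function(m) {
    inside <- tts[[m]] <= thresholds[[m]]
    as.vector(inside %*% V)
  })
  num <- Reduce(`+`, lapply(MODES, function(m) {
    communities[[POP_COLS[[m]]]] * per_mode[[m]]
  }))
  out <- tibble(
    community_id = communities$id,
    access_walking = per_mode$walking,
    access_cycling = per_mode$cycling,
    access_transit = per_mode$public_transport,
    access_integrated = num / ptot
  )
  class(out) <- c("ugs_access", class(out))
  out
}

#' Level-stratified accessibility
#'
#' Recomputes the full two-step calculation restricted to each green-space
#' level (1 = city, 2 = district, 3 = community scale) and to the full set.
#' Because a space's ratio depends only on its own catchment, the level
#' results add up exactly to the total.
#'
#' @inheritParams supply_demand_ratios
#' @return Long tibble `community_id`, `mode` (including `"integrated"`),
#'   `access_total`, `access_level1`, `access_level2`, `access_level3`.
#' @export
stratified_accessibility <- function(communities, ugs, ttms,
                                     thresholds = access_config()) {
  ugs <- validate_ugs(ugs)
  if (!"level" %in% names(ugs) || anyNA(ugs$level)) {
    abort("every green space needs a level in {1,2,3}")
  }
  one <- function(sub) {
    if (nrow(sub) == 0) return(NULL)
    r <- supply_demand_ratios(sub, communities, ttms, thresholds)
    accessibility_scores(communities, sub, r, ttms, thresholds)
  }
  total <- one(ugs)
  long_total <- tidyr::pivot_longer(
    total, cols = dplyr::all_of(unname(ACCESS_COLS)),
    names_to = "mode", values_to = "access_total"
  ) |>
    mutate(mode = names(ACCESS_COLS)[match(.data$mode, ACCESS_COLS)])
  out <- long_total
  for (lev in 1:3) {
    res <- one(ugs[ugs$level == lev, , drop = FALSE])
    col <- paste0("access_level", lev)
    if (is.null(res)) {
      out[[col]] <- 0
    } else {
      long <- tidyr::pivot_longer(
        res, cols = dplyr::all_of(unname(ACCESS_COLS)),
        names_to = "mode", values_to = col
      ) |>
        mutate(mode = names(ACCESS_COLS)[match(.data$mode, ACCESS_COLS)])
      out <- left_join(out, long, by = c("community_id", "mode"))
      out[[col]][is.na(out[[col]])] <- 0
    }
  }
  out
}

#' Mean accessibility by mode and green-space level
#'
#' Averages [stratified_accessibility()] across communities into a compact
#' mode-by-level table (the format used to track how total, city-, district-
#' and community-level accessibility evolve).
#'
#' @param stratified Result of [stratified_accessibility()].
#' @return Tibble: `mode`, `total`, `level1`, `level2`, `level3` (m2/person).
#' @export
summarize_access <- function(stratified) {
  stratified |>
    summarise(
      total = mean(.data$access_total),
      level1 = mean(.data$access_level1),
      level2 = mean(.data$access_level2),
      level3 = mean(.data$access_level3),
      .by = "mode"
    )
}

#' Fraction of green spaces reachable within a threshold
#'
#' Share of (optionally level-filtered) green spaces that at least one
#' community can reach within the threshold by the matrix's mode.
#'
#' @param ugs Green-space table.
#' @param ttm [travel_time_matrix()] from community anchors to entrances.
#' @param threshold Minutes.
#' @param level Optional level filter (1, 2 or 3).
#' @return A fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(ugs, ttm, threshold, level = NULL) {
  ugs <- validate_ugs(ugs)
  if (!is.null(level)) {
    if (!"level" %in% names(ugs)) abort("green-space table has no level column")
    ugs <- ugs[ugs$level %in% level, , drop = FALSE]
  }
  if (nrow(ugs) == 0) abort("no green spaces left after level filtering")
  tt <- ugs_travel_time(ttm, ugs)
  mean(apply(tt <= threshold, 2, any))
}

#' Flag communities below a per-capita green-space standard
#'
#' Marks communities whose integrated accessibility falls strictly below the
#' standard; the default 12 m2/person is the National Ecological Garden City
#' requirement.
#'
#' @param access An [accessibility_scores()] result.
#' @param standard_m2 Per-capita standard in m2/person (default 12).
#' @return `access` with a logical `below_standard` column appended.
#' @export
flag_below_standard <- function(access, standard_m2 = 12) {
  access$below_standard <- access$access_integrated < standard_m2
  access
}
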