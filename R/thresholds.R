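#' Estimate catchment thresholds from a trip survey
#'
#' The threshold travel time of a mode is operationalised as the inflection
#' point of the cumulative trip-frequency curve: the curve of the proportion
#' of trips no longer than *t* minutes rises steeply up to a typical travel
#' time and flattens beyond it. The estimator evaluates the empirical curve
#' at integer minutes, fits a continuous two-segment piecewise-linear
#' function by least squares for every interior integer breakpoint, and
#' returns the breakpoint minimising the residual sum of squares (smallest
#' minute wins ties). If no breakpoint improves on a single straight line
#' the curve is effectively linear: the boundary candidate is returned with
#' a warning and the row is flagged `degenerate`.
#'
#' @param trips Data frame with columns `mode` and `minutes` (> 0).
#' @param min_trips Minimum trips required per mode (default 30).
#' @return Tibble `mode`, `threshold_min`, `sse`, `degenerate`, one row per
#'   mode present in `trips`.
#' @export
#' @examples
#' trips <- generate_trip_survey(seed = 1, n_per_mode = 500)
#' estimate_threshold(trips)
estimate_threshold <- function(trips, min_trips = 30) {
  trips <- as_tibble(trips)
  if (!all(c("mode", "minutes") %in% names(trips))) {
    abort("trips table needs columns mode and minutes")
  }
  modes <- intersect(MODES, unique(trips$mode))
  purrr::map_dfr(modes, function(m) {
    mins <- trips$minutes[trips$mode == m]
    if (length(mins) < min_trips) {
      abort(paste0("mode '", m, "' has ", length(mins), " trips; at least ",
                   min_trips, " are required"))
    }
    fit <- fit_breakpoint(mins)
    tibble(mode = m, threshold_min = fit$breakpoint, sse = fit$sse,
           degenerate = fit$degenerate)
  })
}

## Two-segment continuous piecewise-linear least squares on the empirical
## cumulative curve, breakpoint on the integer-minute grid.
fit_breakpoint <- function(minutes) {
  tmax <- ceiling(max(minutes))
  t <- seq(0, tmax)
  y <- vapply(t, function(ti) mean(minutes <= ti), numeric(1))
  cands <- t[t > min(t) & t < max(t)]
  if (length(cands) == 0) abort("travel-time range too narrow for a breakpoint")
  sse <- vapply(cands, function(b) {
    hinge <- pmax(t - b, 0)
    sum(lm(y ~ t + hinge)$residuals^2)
  }, numeric(1))
  best <- which.min(sse)  # first minimum: smallest breakpoint wins ties
  sse_line <- sum(lm(y ~ t)$residuals^2)
  ## degenerate when no breakpoint improves on a straight line (relative
  ## check, with an absolute floor for exactly linear curves)
  degenerate <- (sse_line - sse[best]) <= max(1e-10 * sse_line, 1e-12)
  if (degenerate) {
    warn("cumulative trip curve has no clear breakpoint; returning the search-range boundary")
    best <- 1L
  }
  list(breakpoint = cands[best], sse = sse[best], degenerate = degenerate)
}
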