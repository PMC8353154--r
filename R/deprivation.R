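DEPRIVATION_MODES <- c(MODES, "integrated")

new_deprivation_table <- function(rows, modes, covariates, n, timepoint = NA) {
  structure(as_tibble(rows), class = c("deprivation_table", class(as_tibble(rows))),
            modes = modes, covariates = covariates, n_communities = n,
            timepoint = timepoint)
}

#' Community deprivation of green-space access at one timepoint
#'
#' For every travel mode (and the integrated score), regresses community
#' accessibility on the socioeconomic composition of the community with
#' [krls()], and reports the average marginal effect, its P25/P50/P75
#' heterogeneity summary, and significance stars. A negative, significant
#' effect of a disadvantage indicator (e.g. the proportion of less-educated
#' residents) is the signature of deprivation: disadvantaged communities
#' systematically see less green space per capita.
#'
#' Effects are in response units (m2/person) per unit covariate (a
#' proportion moving from 0 to 1); covariates enter jointly.
#'
#' @param access An [accessibility_scores()] result (columns
#'   `community_id`, `access_walking`, `access_cycling`, `access_transit`,
#'   `access_integrated`).
#' @param ses Data frame: `community_id` plus covariate proportion columns.
#' @param covariates Covariate columns to use (default: all numeric columns
#'   of `ses` except the id).
#' @param modes Modes to analyse; default all three plus `"integrated"`.
#' @return A tibble of class `deprivation_table`, one row per
#'   (covariate, mode): `covariate`, `mode`, `avg`, `p25`, `p50`, `p75`,
#'   `se`, `p_value`, `stars`.
#' @export
cross_sectional_analysis <- function(access, ses, covariates = NULL,
                                     modes = DEPRIVATION_MODES) {
  access <- as_tibble(access)
  ses <- as_tibble(ses)
  modes <- match.arg(modes, DEPRIVATION_MODES, several.ok = TRUE)
  if (!"community_id" %in% names(ses)) abort("ses table needs community_id")
  only_a <- setdiff(access$community_id, ses$community_id)
  only_s <- setdiff(ses$community_id, access$community_id)
  if (length(only_a) || length(only_s)) {
    abort(paste0(
      "community ids do not align; only in access: {",
      paste(head(only_a, 5), collapse = ", "), "}, only in ses: {",
      paste(head(only_s, 5), collapse = ", "), "}"
    ))
  }
  if (is.null(covariates)) {
    num <- names(ses)[vapply(ses, is.numeric, logical(1))]
    covariates <- setdiff(num, "community_id")
  }
  if (length(covariates) == 0) abort("no covariates supplied")
  d <- left_join(access, ses, by = "community_id")
  rows <- purrr::map_dfr(modes, function(m) {
    col <- ACCESS_COLS[[m]]
    fit <- tryCatch(
      krls(d, response = col, covariates = covariates),
      error = function(e) {
        abort(paste0("KRLS fit failed for mode '", m, "': ",
                     conditionMessage(e)))
      }
    )
    summarize_effects(fit) |> mutate(mode = m, .after = "covariate")
  })
  new_deprivation_table(rows, modes, covariates, nrow(d))
}

#' Deprivation dynamics between two timepoints
#'
#' Regresses the change in accessibility between two timepoints on the change
#' in community socioeconomic composition: responses are
#' `A_i(t2) - A_i(t1)` per mode and covariates are `SES(t2) - SES(t1)`,
#' then the analysis proceeds as in [cross_sectional_analysis()]. Communities
#' present at only one timepoint are dropped with a warning; fully disjoint
#' community sets are an error.
#'
#' @param access_t1,access_t2 [accessibility_scores()] results at the two
#'   timepoints.
#' @param ses_t1,ses_t2 SES tables at the two timepoints.
#' @inheritParams cross_sectional_analysis
#' @return A `deprivation_table` of change-on-change effects.
#' @export
change_analysis <- function(access_t1, access_t2, ses_t1, ses_t2,
                            covariates = NULL, modes = DEPRIVATION_MODES) {
  a1 <- as_tibble(access_t1); a2 <- as_tibble(access_t2)
  s1 <- as_tibble(ses_t1); s2 <- as_tibble(ses_t2)
  common <- intersect(a1$community_id, a2$community_id)
  common <- intersect(common, intersect(s1$community_id, s2$community_id))
  if (length(common) == 0) {
    abort("no community is present at both timepoints")
  }
  dropped <- length(union(a1$community_id, a2$community_id)) - length(common)
  if (dropped > 0) {
    warn(paste0(dropped, " community(ies) present at only one timepoint; excluded"))
  }
  if (is.null(covariates)) {
    num <- names(s1)[vapply(s1, is.numeric, logical(1))]
    covariates <- setdiff(num, "community_id")
  }
  acc_cols <- unname(ACCESS_COLS)
  a1 <- a1[match(common, a1$community_id), ]
  a2 <- a2[match(common, a2$community_id), ]
  s1 <- s1[match(common, s1$community_id), ]
  s2 <- s2[match(common, s2$community_id), ]
  d_access <- tibble(community_id = common)
  for (col in acc_cols) d_access[[col]] <- a2[[col]] - a1[[col]]
  d_ses <- tibble(community_id = common)
  for (col in covariates) d_ses[[col]] <- s2[[col]] - s1[[col]]
  cross_sectional_analysis(d_access, d_ses, covariates, modes)
}

#' Write a deprivation table to CSV and aligned text
#'
#' Writes `deprivation.csv` (machine-readable, stable column order) and
#' `deprivation.txt` (aligned columns with the significance-star legend)
#' under `dir`.
#'
#' @param table A `deprivation_table`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "txt")`.
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(table, dir, formats = c("csv", "txt")) {
  stopifnot(inherits(table, "deprivation_table"))
  if (nrow(table) == 0) abort("deprivation table is empty")
  formats <- match.arg(formats, c("csv", "txt"), several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("csv" %in% formats) {
    p <- file.path(dir, "deprivation.csv")
    write_table_csv(as_tibble(table), p)
    paths <- c(paths, p)
  }
  if ("txt" %in% formats) {
    p <- file.path(dir, "deprivation.txt")
    df <- as.data.frame(table)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
    lines <- c(
      utils::capture.output(print(df, row.names = FALSE)),
      "",
      "* p < 0.05, ** p < 0.01, *** p < 0.001"
    )
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a rendered deprivation table
#'
#' Inverse of the CSV rendering of [render_tables()].
#'
#' @param path Path to `deprivation.csv`.
#' @return A `deprivation_table`.
#' @export
read_deprivation_table <- function(path) {
  rows <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(stars = readr::col_character()))
  rows$stars[is.na(rows$stars)] <- ""
  new_deprivation_table(rows, unique(rows$mode), unique(rows$covariate),
                        NA_integer_)
}
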