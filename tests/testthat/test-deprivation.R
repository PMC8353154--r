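## Shared fixture: one modest synthetic city with strongly inequitable
## supply, its accessibility, and its SES table.
deprived_fixture <- function(seed = 101) {
  city <- generate_city(scenario_config(
    seed = seed, coupling = c(less_educated = -3)
  ))
  res <- city_access(city)
  list(city = city, access = res$access, ses = city_ses(city))
}

test_that("cross-sectional analysis recovers planted supply-side deprivation", {
  fx <- deprived_fixture()
  dt <- cross_sectional_analysis(fx$access, fx$ses, modes = "walking")
  expect_s3_class(dt, "deprivation_table")
  expect_equal(nrow(dt), 5)  # one row per covariate for the single mode
  row <- dt[dt$covariate == "less_educated", ]
  expect_lt(row$avg, 0)
  expect_lt(row$p_value, 0.05)
  expect_true(row$stars != "")
  expect_true(all(dt$p25 <= dt$p50 & dt$p50 <= dt$p75))
})

test_that("deprivation tables cover every requested covariate-mode pair", {
  fx <- deprived_fixture(102)
  dt <- cross_sectional_analysis(fx$access, fx$ses,
                                 covariates = c("older", "less_educated"),
                                 modes = c("walking", "integrated"))
  expect_equal(nrow(dt), 4)
  expect_setequal(unique(dt$mode), c("walking", "integrated"))
})

test_that("misaligned or degenerate inputs fail with context", {
  fx <- deprived_fixture(103)
  bad <- fx$ses
  bad$community_id[1] <- "NOPE"
  expect_error(cross_sectional_analysis(fx$access, bad), "NOPE")

  const <- fx$ses
  const$older <- 0.2
  expect_error(
    cross_sectional_analysis(fx$access, const, modes = "walking"),
    "mode 'walking'.*older"
  )
  expect_error(cross_sectional_analysis(fx$access, fx$ses,
                                        covariates = character(0)),
               "no covariates")
})

test_that("identical timepoints yield zero change effects", {
  fx <- deprived_fixture(104)
  dt <- change_analysis(fx$access, fx$access, fx$ses, fx$ses,
                        modes = "walking")
  expect_true(all(dt$avg == 0))
  expect_true(all(dt$p_value == 1))
  expect_true(all(dt$stars == ""))
})

test_that("change analysis couples SES shifts to accessibility shifts", {
  fx <- deprived_fixture(105)
  # plant: communities whose less-educated share grows lose accessibility
  shift <- withr::with_seed(106, rnorm(nrow(fx$ses), sd = 0.05))
  ses2 <- fx$ses
  ses2$less_educated <- pmin(pmax(ses2$less_educated + shift, 0), 1)
  acc2 <- fx$access
  acc2$access_walking <- acc2$access_walking - 8 * shift +
    withr::with_seed(107, rnorm(nrow(acc2), sd = 0.1))
  dt <- change_analysis(fx$access, acc2, fx$ses, ses2,
                        covariates = "less_educated", modes = "walking")
  row <- dt[dt$covariate == "less_educated", ]
  expect_lt(row$avg, 0)
  expect_lt(row$p_value, 0.05)

  # disjoint community sets cannot be compared
  renamed <- dplyr::mutate(acc2, community_id = paste0("X", community_id))
  ses_renamed <- dplyr::mutate(ses2, community_id = paste0("X", community_id))
  expect_error(change_analysis(fx$access, renamed, fx$ses, ses_renamed),
               "both timepoints")

  # partial overlap drops the unmatched community with a warning
  expect_warning(
    change_analysis(fx$access[-1, ], acc2, fx$ses, ses2,
                    covariates = "less_educated", modes = "walking"),
    "excluded"
  )
})

test_that("consistently relabelling communities leaves effects unchanged", {
  fx <- deprived_fixture(108)
  dt1 <- cross_sectional_analysis(fx$access, fx$ses, modes = "walking")
  relab <- function(d) dplyr::mutate(d, community_id = paste0("Z", community_id))
  dt2 <- cross_sectional_analysis(relab(fx$access), relab(fx$ses),
                                  modes = "walking")
  expect_equal(dt1$avg, dt2$avg, tolerance = 1e-12)
  expect_equal(dt1$p_value, dt2$p_value, tolerance = 1e-12)
})

test_that("rendered tables round-trip through their reader", {
  fx <- deprived_fixture(109)
  dt <- cross_sectional_analysis(fx$access, fx$ses,
                                 modes = c("walking", "integrated"))
  dir <- withr::local_tempdir()
  paths <- render_tables(dt, dir)
  expect_true(all(file.exists(file.path(dir, c("deprivation.csv",
                                               "deprivation.txt")))))
  txt <- readLines(file.path(dir, "deprivation.txt"))
  expect_true(any(grepl("p < 0.001", txt)))

  back <- read_deprivation_table(file.path(dir, "deprivation.csv"))
  expect_equal(as.data.frame(back)[c("covariate", "mode", "stars")],
               as.data.frame(dt)[c("covariate", "mode", "stars")])
  expect_equal(back$avg, dt$avg, tolerance = 1e-9)

  expect_error(render_tables(dt[0, ], dir), "empty")
})
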