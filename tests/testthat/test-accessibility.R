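## Toy fixture: a path network 1 -- 2 -- 3 of main streets, one green space
## at node 2 reachable through travel-time matrices built per mode.
path_city <- function(len12 = 1000, len23 = 5000) {
  nodes <- tibble::tibble(id = 1:3, x = c(0, len12, len12 + len23), y = 0)
  edges <- tibble::tibble(u = c(1, 2), v = c(2, 3),
                          length_m = c(len12, len23),
                          road_class = "main_street")
  load_network(nodes, edges)
}

mode_ttms <- function(net, origins, destinations) {
  lapply(stats::setNames(travel_modes(), travel_modes()), function(m) {
    travel_time_matrix(net, origins, destinations, m)
  })
}

test_that("green-space travel time is the minimum over entrances", {
  ttm <- make_ttm("walking", 1, c(101, 102),
                  matrix(c(10, 7), 1, 2))
  ugs <- tibble::tibble(id = "G1", node = c(101, 102), area_m2 = 1000)
  expect_equal(unname(ugs_travel_time(ttm, ugs)[1, 1]), 7)

  single <- make_ttm("walking", 1, 101, matrix(12, 1, 1))
  expect_equal(unname(ugs_travel_time(single,
    tibble::tibble(id = "G1", node = 101, area_m2 = 1))[1, 1]), 12)

  dead <- make_ttm("walking", 1, c(101, 102), matrix(Inf, 1, 2))
  expect_equal(unname(ugs_travel_time(dead, ugs)[1, 1]), Inf)
})

test_that("supply-demand ratios implement the mode-specific catchment sums", {
  net <- path_city()
  comm <- tibble::tibble(id = "C1", node = 1,
                         pop_walking = 500, pop_cycling = 0, pop_transit = 0)
  ugs <- tibble::tibble(id = "U1", node = 2, area_m2 = 10000, level = 3)
  ttms <- mode_ttms(net, 1, 2)
  r <- supply_demand_ratios(ugs, comm, ttms)
  expect_equal(r$ratio, 20)  # 10000 m2 over 500 walkers at 12 min

  # walkers near, cyclists far: both mode catchments contribute demand
  comm2 <- tibble::tibble(
    id = c("C1", "C2"), node = c(1, 3),
    pop_walking = c(100, 0), pop_cycling = c(0, 200), pop_transit = 0
  )
  ugs2 <- tibble::tibble(id = "U1", node = 2, area_m2 = 9000, level = 3)
  ttms2 <- mode_ttms(net, c(1, 3), 2)
  r2 <- supply_demand_ratios(ugs2, comm2, ttms2)
  # C2 walking 60 min excluded; C2 cycling 20 min within 23 min included
  expect_equal(r2$ratio, 30)

  # no demand in any catchment: ratio 0 and flagged
  lonely <- tibble::tibble(id = "C1", node = 1, pop_walking = 500,
                           pop_cycling = 0, pop_transit = 0)
  far <- tibble::tibble(id = "U1", node = 3, area_m2 = 1000, level = 3)
  rfar <- supply_demand_ratios(
    far, lonely, mode_ttms(net, 1, 3),
    thresholds = access_config(walking = 1, cycling = 1, public_transport = 1)
  )
  expect_equal(rfar$ratio, 0)
  expect_true(rfar$zero_demand)
})

test_that("accessibility scores weight catchment ratio sums by mode populations", {
  net <- path_city()
  comm <- tibble::tibble(id = "C1", node = 1,
                         pop_walking = 500, pop_cycling = 0, pop_transit = 0)
  ugs <- tibble::tibble(id = "U1", node = 2, area_m2 = 10000, level = 3)
  ttms <- mode_ttms(net, 1, 2)
  r <- supply_demand_ratios(ugs, comm, ttms)
  a <- accessibility_scores(comm, ugs, r, ttms)
  expect_equal(a$access_integrated, 20)
  expect_equal(a$access_walking, 20)

  # a community out of every catchment scores zero
  comm0 <- tibble::tibble(id = "C9", node = 3, pop_walking = 50,
                          pop_cycling = 0, pop_transit = 0)
  both <- dplyr::bind_rows(comm, comm0)
  ttms2 <- mode_ttms(net, c(1, 3), 2)
  thr <- access_config(walking = 18, cycling = 1, public_transport = 1)
  r2 <- supply_demand_ratios(ugs, both, ttms2, thr)
  a2 <- accessibility_scores(both, ugs, r2, ttms2, thr)
  expect_equal(a2$access_integrated[a2$community_id == "C9"], 0)

  # zero-population community is excluded with a warning
  zero <- dplyr::bind_rows(comm, tibble::tibble(
    id = "Z", node = 3, pop_walking = 0, pop_cycling = 0, pop_transit = 0))
  expect_warning(
    az <- accessibility_scores(zero, ugs, r, ttms2),
    "zero total population"
  )
  expect_false("Z" %in% az$community_id)
})

test_that("engine matches the plain-loop multi-mode oracle on random instances", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    r <- supply_demand_ratios(inst$ugs, inst$communities, inst$ttms)
    a <- accessibility_scores(inst$communities, inst$ugs, r, inst$ttms)
    oracle <- brute_2sfca(
      lapply(inst$ttms, function(t) t$minutes),
      list(inst$communities$pop_walking, inst$communities$pop_cycling,
           inst$communities$pop_transit),
      inst$ugs$area_m2, access_config()
    )
    expect_equal(r$ratio, oracle$V, tolerance = 1e-12)
    expect_equal(a$access_integrated, oracle$A, tolerance = 1e-12)
  }
})

test_that("level-stratified accessibility is additive and handles empty levels", {
  city <- test_city(21)
  ttms <- city_travel_times(city)
  strat <- stratified_accessibility(city$communities, city$ugs, ttms)
  expect_equal(strat$access_total,
               strat$access_level1 + strat$access_level2 + strat$access_level3,
               tolerance = 1e-12)

  all3 <- dplyr::mutate(city$ugs, level = 3)
  s3 <- stratified_accessibility(city$communities, all3, ttms)
  expect_equal(s3$access_level3, s3$access_total)
  expect_true(all(s3$access_level1 == 0))
  expect_true(all(s3$access_level2 == 0))

  summary <- summarize_access(strat)
  expect_setequal(summary$mode,
                  c("walking", "cycling", "public_transport", "integrated"))
})

test_that("supply is conserved and responds linearly, demand monotonically", {
  for (seed in 31:33) {
    city <- test_city(seed)
    res <- city_access(city)
    expect_lt(conservation_rel_err(city, res), 1e-9)
    expect_true(all(res$ratios$ratio >= 0))
    expect_true(all(res$access$access_integrated >= 0))

    # linearity in supply: scaling every area scales ratios and scores
    scaled <- dplyr::mutate(city$ugs, area_m2 = area_m2 * 3.7)
    res2 <- supply_demand_ratios(scaled, city$communities, res$ttms)
    expect_equal(res2$ratio, res$ratios$ratio * 3.7, tolerance = 1e-12)
    a2 <- accessibility_scores(city$communities, scaled, res2, res$ttms)
    expect_equal(a2$access_integrated, res$access$access_integrated * 3.7,
                 tolerance = 1e-12)

    # extra population can only dilute ratios
    crowded <- city$communities
    crowded$pop_walking[1] <- crowded$pop_walking[1] + 5000
    r3 <- supply_demand_ratios(city$ugs, crowded, res$ttms)
    expect_true(all(r3$ratio <= res$ratios$ratio + 1e-12))

    # wider thresholds can only grow catchment demand
    wide <- access_config(30, 40, 50)
    r4 <- supply_demand_ratios(city$ugs, city$communities, res$ttms, wide)
    expect_true(all(r4$demand >= res$ratios$demand))
  }
})

test_that("single-mode reduction equals the classic 2SFCA oracle", {
  for (seed in 41:60) {
    inst <- random_instance(seed, single_mode = TRUE)
    r <- supply_demand_ratios(inst$ugs, inst$communities, inst$ttms)
    a <- accessibility_scores(inst$communities, inst$ugs, r, inst$ttms)
    oracle <- brute_2sfca(
      list(inst$ttms$walking$minutes),
      list(inst$communities$pop_walking),
      inst$ugs$area_m2, access_config()["walking"]
    )
    expect_equal(r$ratio, oracle$V, tolerance = 1e-12)
    expect_equal(a$access_integrated, oracle$A, tolerance = 1e-12)
  }
})

test_that("coverage fractions count reachable spaces", {
  ttm <- make_ttm("walking", 1:2, c(101, 102, 103),
                  matrix(c(5, 50, 50, 50, 10, 40), 2, 3))
  ugs <- tibble::tibble(id = c("A", "B", "C"), node = c(101, 102, 103),
                        area_m2 = 1, level = c(1, 1, 2))
  expect_equal(coverage_fraction(ugs, ttm, 18), 2 / 3)
  expect_equal(coverage_fraction(ugs, ttm, 60), 1)
  expect_equal(coverage_fraction(ugs, ttm, 1), 0)
  expect_equal(coverage_fraction(ugs, ttm, 18, level = 1), 1 / 2)
  expect_error(coverage_fraction(ugs[0, ], ttm, 18), "no green spaces")
})

test_that("below-standard flags use a strict cutoff", {
  acc <- tibble::tibble(community_id = c("a", "b", "c"),
                        access_integrated = c(11.9, 12, 0))
  fl <- flag_below_standard(acc)
  expect_equal(fl$below_standard, c(TRUE, FALSE, TRUE))
})
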