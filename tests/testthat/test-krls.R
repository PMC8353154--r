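linear_data <- function(seed, n = 200, sd = 0.1) {
  withr::with_seed(seed, {
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 2 * d$x1 - d$x2 + rnorm(n, sd = sd)
    d
  })
}

test_that("standardization round-trips and rejects constant columns", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(0, 5, 1, 9))
  y <- c(2, 4, 6, 9)
  des <- standardize_design(X, y)
  expect_equal(unname(colMeans(des$X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(des$X, 2, sd)), c(1, 1), tolerance = 1e-12)
  back <- sweep(sweep(des$X, 2, des$x_sd, "*"), 2, des$x_mean, "+")
  expect_equal(back, X, tolerance = 1e-12)
  expect_equal(des$y * des$y_sd + des$y_mean, y, tolerance = 1e-12)
  expect_error(standardize_design(cbind(a = c(1, 1, 1), b = 1:3), 1:3), "a")
})

test_that("the Gaussian kernel matches direct scalar evaluation", {
  X <- rbind(c(0, 0), c(1, 2), c(-1, 0.5))
  K <- gaussian_kernel(X, 2)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(K[i, j], exp(-sum((X[i, ] - X[j, ])^2) / 2), tolerance = 1e-15)
  }
  same <- gaussian_kernel(rbind(c(1, 1), c(1, 1)), 3)
  expect_equal(same, matrix(1, 2, 2))
  far <- gaussian_kernel(rbind(0, 1e6), 1)
  expect_equal(far[1, 2], 0)
})

test_that("degenerate and limiting fits behave as ridge theory predicts", {
  # constant response: exact mean fit, zero effects
  d0 <- data.frame(x = rnorm(20), y = 0)
  f0 <- krls(d0, "y")
  expect_equal(unname(f0$coefficients), rep(0, 20))
  expect_equal(f0$fitted, rep(0, 20))
  expect_equal(unname(f0$avg), 0)

  # infinite-penalty limit: fit collapses to the mean, derivatives vanish
  d <- linear_data(1, n = 60)
  f_inf <- krls(d, "y", lambda = 1e8)
  expect_lt(max(abs(f_inf$fitted - mean(d$y))), 1e-4)
  expect_lt(max(abs(f_inf$derivatives)), 1e-4)

  # vanishing penalty: the surface interpolates the training data (up to the
  # floating-point rank of the kernel, hence the small n here)
  d_small <- linear_data(2, n = 25)
  f_mid <- krls(d_small, "y", lambda = 1e-4)
  f_0 <- krls(d_small, "y", lambda = 1e-9)
  expect_lt(max(abs(f_0$fitted - d_small$y)), 1e-3)
  expect_lt(max(abs(f_0$fitted - d_small$y)),
            max(abs(f_mid$fitted - d_small$y)))
})

test_that("hat-matrix leave-one-out errors equal brute-force refits", {
  d <- linear_data(7, n = 25, sd = 0.3)
  des <- standardize_design(as.matrix(d[c("x1", "x2")]), d$y)
  lambda <- 0.37
  fit <- krls(data.frame(des$X, y = des$y), "y",
              covariates = c("x1", "x2"),
              sigma2 = 2, lambda = lambda, standardize = FALSE)
  oracle <- brute_loo_errors(des$X, des$y, sigma2 = 2, lambda = lambda)
  expect_equal(unname(fit$loo_errors), oracle, tolerance = 1e-8)
})

test_that("closed-form derivatives match numerical differentiation of the surface", {
  d <- linear_data(3, n = 80, sd = 0.2)
  d$y <- d$y + 0.5 * d$x1 * d$x2  # mild interaction: a curved surface
  fit <- krls(d, "y")
  h <- 1e-5
  for (cv in c("x1", "x2")) {
    up <- d; up[[cv]] <- up[[cv]] + h
    dn <- d; dn[[cv]] <- dn[[cv]] - h
    fd <- (predict(fit, up) - predict(fit, dn)) / (2 * h)
    expect_lt(max(abs(fd - fit$derivatives[, cv])), 1e-5)
  }
})

test_that("average marginal effects recover linear truth and kill null covariates", {
  d <- linear_data(11)
  d$noise <- withr::with_seed(12, rnorm(nrow(d)))
  fit <- krls(d, "y", covariates = c("x1", "x2", "noise"))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "x1"], 2, tolerance = 0.05)
  expect_equal(td$estimate[td$term == "x2"], -1, tolerance = 0.05)
  expect_lt(abs(td$estimate[td$term == "noise"]), 0.05)
  expect_gt(td$p.value[td$term == "noise"], 0.05)

  # near-linear 1-D fit reproduces the OLS slope
  d1 <- withr::with_seed(5, data.frame(x = rnorm(150)))
  d1$y <- d1$x + withr::with_seed(6, rnorm(150, sd = 0.05))
  f1 <- krls(d1, "y")
  expect_equal(unname(f1$avg), unname(coef(lm(y ~ x, d1))[2]), tolerance = 0.05)
})

test_that("effect summaries are permutation-invariant with ordered quantiles", {
  d <- linear_data(21, n = 90)
  fit <- krls(d, "y")
  perm <- withr::with_seed(22, sample(nrow(d)))
  fit_p <- krls(d[perm, ], "y")
  expect_equal(tidy(fit)$estimate, tidy(fit_p)$estimate, tolerance = 1e-10)
  expect_equal(tidy(fit)$p25, tidy(fit_p)$p25, tolerance = 1e-10)

  td <- tidy(fit)
  expect_true(all(td$p25 <= td$p50 & td$p50 <= td$p75))

  # quantiles use linear interpolation between closest ranks
  eff <- summarize_effects(fit)
  for (k in seq_len(nrow(eff))) {
    v <- sort(fit$derivatives[, eff$covariate[k]])
    n <- length(v)
    hpos <- function(p) {
      h <- (n - 1) * p + 1
      v[floor(h)] + (h - floor(h)) * (v[ceiling(h)] - v[floor(h)])
    }
    expect_equal(eff$p25[k], hpos(0.25), tolerance = 1e-12)
    expect_equal(eff$p50[k], hpos(0.50), tolerance = 1e-12)
    expect_equal(eff$p75[k], hpos(0.75), tolerance = 1e-12)
  }

  # significance stars follow the conventional thresholds
  expect_equal(greenaccess:::significance_stars(c(0.2, 0.04, 0.004, 4e-4)),
               c("", "*", "**", "***"))
})

test_that("exhaustive subset selection finds planted sparse truth", {
  hits <- 0
  for (seed in 1:10) {
    d <- withr::with_seed(seed, {
      d <- data.frame(x1 = rnorm(150), x2 = rnorm(150), x3 = rnorm(150))
      d$y <- 2 * d$x1 + rnorm(150, sd = 0.3)
      d
    })
    sel <- best_subset(d, "y", c("x1", "x2", "x3"))
    hits <- hits + identical(sel$selected, "x1")
    expect_equal(nrow(sel$results), 7)
  }
  expect_gte(hits, 9)

  single <- best_subset(linear_data(30, 60), "y", "x1")
  expect_equal(single$selected, "x1")

  wide <- as.data.frame(matrix(rnorm(17 * 30), 30))
  names(wide) <- c("y", paste0("v", 1:16))
  expect_error(best_subset(wide, "y", paste0("v", 1:16)), "15")
})

test_that("glance and predict expose the fit consistently", {
  d <- linear_data(41, n = 70)
  fit <- krls(d, "y")
  g <- glance(fit)
  expect_equal(g$n, 70)
  expect_gt(g$r.squared, 0.95)
  expect_equal(predict(fit, d), fit$fitted, tolerance = 1e-10)
})
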