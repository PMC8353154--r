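#' Standardize a design matrix and response
#'
#' Centres and scales every covariate column and the response to mean 0,
#' sd 1, keeping the moments so estimates can be returned in original units.
#'
#' @param X Numeric matrix or data frame of covariates (n x D, n > D).
#' @param y Numeric response vector, length n.
#' @return List with standardized `X`, `y` and the moments `x_mean`, `x_sd`,
#'   `y_mean`, `y_sd`.
#' @export
standardize_design <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("X and y sizes disagree")
  if (nrow(X) <= ncol(X)) abort("need more observations than covariates")
  x_sd <- apply(X, 2, sd)
  const <- which(x_sd == 0 | !is.finite(x_sd))
  if (length(const)) {
    nm <- colnames(X)[const] %||% as.character(const)
    abort(paste0("constant covariate column(s): ", paste(nm, collapse = ", ")))
  }
  y_sd <- sd(y)
  if (y_sd == 0) abort("response is constant")
  x_mean <- colMeans(X)
  list(
    X = sweep(sweep(X, 2, x_mean), 2, x_sd, "/"),
    y = (y - mean(y)) / y_sd,
    x_mean = x_mean, x_sd = x_sd, y_mean = mean(y), y_sd = y_sd
  )
}

## Pairwise squared Euclidean distances between rows of A and B.
sq_dists <- function(A, B = A) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

#' Gaussian kernel matrix
#'
#' `K[i, j] = exp(-||x_i - x_j||^2 / sigma2)`: symmetric with unit diagonal.
#'
#' @param X Numeric matrix (rows = observations).
#' @param sigma2 Bandwidth (> 0); the conventional default elsewhere in the
#'   package is the number of covariates on standardized data.
#' @return n x n numeric matrix.
#' @export
gaussian_kernel <- function(X, sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 <= 0) {
    abort("sigma2 must be a positive scalar")
  }
  X <- as.matrix(X)
  K <- exp(-sq_dists(X) / sigma2)
  diag(K) <- 1
  (K + t(K)) / 2
}

## Leave-one-out SSE at a given lambda from the eigendecomposition of K.
## Uses the exact ridge identity e_i = (y_i - yhat_i) / (1 - H_ii).
loo_sse_at <- function(lambda, vals, Q, qty, y) {
  s <- vals / (vals + lambda)
  yhat <- Q %*% (s * qty)
  hii <- rowSums(sweep(Q^2, 2, s, "*"))
  sum(((y - yhat) / (1 - hii))^2)
}

## Deterministic golden-section minimisation of f over [lo, hi].
golden_section <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  (a + b) / 2
}

#' Kernel regularized least squares with pointwise marginal effects
#'
#' Fits Gaussian-kernel ridge regression `c = (K + lambda I)^-1 y` on
#' standardized data and derives, in closed form, the pointwise partial
#' derivative of the fitted surface with respect to every covariate at every
#' observation — the heterogeneous marginal effects. The ridge penalty is
#' chosen by minimising the exact leave-one-out sum of squared errors
#' (hat-matrix identity) with a golden-section search on `log(lambda)`;
#' fitting is fully deterministic.
#'
#' Marginal effects are reported in original units (response units per unit
#' covariate). The average effect of covariate *d* is linear in the kernel
#' coefficients, so its standard error follows from the delta method with
#' `cov(c) = sigma_hat^2 (K + lambda I)^-2`; p-values are two-sided normal.
#'
#' @param data Data frame holding the response and covariates.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate columns (default: all
#'   numeric columns except the response).
#' @param sigma2 Kernel bandwidth; default `NULL` means the number of
#'   covariates (the standard choice on standardized designs).
#' @param lambda Ridge penalty: `"loo"` (default) for the leave-one-out
#'   search over `[1e-6, 1e3]`, or a positive number.
#' @param standardize Standardize covariates and response internally
#'   (default `TRUE`; effects are always reported in original units).
#' @return Object of class `krls`; see [tidy.krls()], [glance.krls()],
#'   [predict.krls()], [summarize_effects()].
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
#' d$y <- 2 * d$x1 - d$x2 + rnorm(80, sd = 0.1)
#' fit <- krls(d, "y")
#' tidy(fit)
krls <- function(data, response, covariates = NULL, sigma2 = NULL,
                 lambda = "loo", standardize = TRUE) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) {
    abort(paste0("response column '", response, "' not found"))
  }
  if (is.null(covariates)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    covariates <- setdiff(num, response)
  }
  miss <- setdiff(covariates, names(data))
  if (length(miss)) {
    abort(paste0("covariate column(s) not found: ", paste(miss, collapse = ", ")))
  }
  if (length(covariates) == 0) abort("no covariates to fit")
  X_raw <- as.matrix(data[covariates])
  y_raw <- as.numeric(data[[response]])
  n <- nrow(X_raw); D <- ncol(X_raw)

  ## A constant response (e.g. change-on-change between identical timepoints)
  ## is fit exactly by its mean: zero coefficients, zero effects everywhere.
  if (sd(y_raw) == 0) {
    qs <- matrix(0, D, 3, dimnames = list(covariates, c("p25", "p50", "p75")))
    return(structure(list(
      covariates = covariates, response = response,
      n = n, d = D, sigma2 = sigma2 %||% D, lambda = Inf,
      scales = list(x_mean = rep(0, D), x_sd = rep(1, D),
                    y_mean = y_raw[1], y_sd = 0),
      X_std = X_raw, y_std = rep(0, n),
      coefficients = rep(0, n), fitted = y_raw, fitted_std = rep(0, n),
      loo_errors = rep(0, n), loo_sse = 0,
      sigma_hat2 = 0, edf = 0,
      derivatives = matrix(0, n, D, dimnames = list(NULL, covariates)),
      avg = setNames(rep(0, D), covariates),
      se_avg = setNames(rep(0, D), covariates),
      p_avg = setNames(rep(1, D), covariates),
      quantiles = qs
    ), class = "krls"))
  }

  if (standardize) {
    des <- standardize_design(X_raw, y_raw)
  } else {
    des <- list(X = X_raw, y = y_raw,
                x_mean = rep(0, D), x_sd = rep(1, D), y_mean = 0, y_sd = 1)
  }
  sigma2 <- sigma2 %||% D
  K <- gaussian_kernel(des$X, sigma2)
  eig <- eigen(K, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  Q <- eig$vectors
  qty <- as.vector(crossprod(Q, des$y))

  if (identical(lambda, "loo")) {
    loglam <- golden_section(
      function(l) loo_sse_at(exp(l), vals, Q, qty, des$y),
      log(1e-6), log(1e3), tol = 1e-4
    )
    lambda <- exp(loglam)
  }
  if (!is.numeric(lambda) || lambda <= 0) abort("lambda must be positive")
  if (min(vals) + lambda <= 1e-12) {
    abort("K + lambda*I is numerically singular; raise the lambda floor")
  }

  cvec <- as.vector(Q %*% (qty / (vals + lambda)))
  s <- vals / (vals + lambda)
  fitted_std <- as.vector(K %*% cvec)
  hii <- rowSums(sweep(Q^2, 2, s, "*"))
  resid_std <- des$y - fitted_std
  loo_errors <- resid_std / (1 - hii)
  edf <- sum(s)
  sigma_hat2 <- sum(resid_std^2) / max(n - edf, 1)

  ## Closed-form pointwise derivatives in standardized space:
  ## d yhat_i / d x_d = -(2/sigma2) * sum_j c_j K_ij (x_id - x_jd)
  Kc <- K * rep(cvec, each = n)              # K_ij * c_j
  rs <- rowSums(Kc)                          # sum_j c_j K_ij
  deriv_std <- matrix(0, n, D, dimnames = list(NULL, covariates))
  for (d in seq_len(D)) {
    xd <- des$X[, d]
    deriv_std[, d] <- -(2 / sigma2) * (xd * rs - Kc %*% xd)
  }
  scale_d <- des$y_sd / des$x_sd
  deriv <- sweep(deriv_std, 2, scale_d, "*")

  ## Average effect is g_d' c; delta-method variance with
  ## cov(c) = sigma_hat2 * (K + lambda I)^-2.
  avg_std <- colMeans(deriv_std)
  se_std <- numeric(D)
  for (d in seq_len(D)) {
    xd <- des$X[, d]
    ## g_j = -(2/sigma2)(1/n) sum_i K_ij (x_id - x_jd); K symmetric
    g <- -(2 / sigma2) / n * (as.vector(crossprod(K, xd)) - xd * colSums(K))
    qg <- as.vector(crossprod(Q, g))
    se_std[d] <- sqrt(sigma_hat2 * sum(qg^2 / (vals + lambda)^2))
  }
  avg <- avg_std * scale_d
  se_avg <- se_std * scale_d
  z <- ifelse(se_avg > 0, avg / se_avg, 0)
  p_avg <- 2 * pnorm(-abs(z))
  qs <- t(apply(deriv, 2, quantile, probs = c(0.25, 0.5, 0.75), names = FALSE))
  colnames(qs) <- c("p25", "p50", "p75")

  structure(list(
    covariates = covariates, response = response,
    n = n, d = D, sigma2 = sigma2, lambda = lambda,
    scales = des[c("x_mean", "x_sd", "y_mean", "y_sd")],
    X_std = des$X, y_std = des$y,
    coefficients = cvec, fitted = des$y_mean + des$y_sd * fitted_std,
    fitted_std = fitted_std,
    loo_errors = loo_errors, loo_sse = sum(loo_errors^2),
    sigma_hat2 = sigma_hat2, edf = edf,
    derivatives = deriv, avg = avg, se_avg = se_avg, p_avg = p_avg,
    quantiles = qs
  ), class = "krls")
}

#' @export
print.krls <- function(x, ...) {
  cat("<krls> n = ", x$n, ", D = ", x$d,
      ", sigma2 = ", signif(x$sigma2, 4),
      ", lambda = ", signif(x$lambda, 4),
      ", LOO SSE = ", signif(x$loo_sse, 6), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Predict from a KRLS fit
#'
#' Evaluates the fitted kernel surface at new covariate values, in original
#' response units.
#'
#' @param object A [krls()] fit.
#' @param newdata Data frame containing the fit's covariate columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.krls <- function(object, newdata, ...) {
  Xn <- as.matrix(as.data.frame(newdata)[object$covariates])
  Xn <- sweep(sweep(Xn, 2, object$scales$x_mean), 2, object$scales$x_sd, "/")
  Kn <- exp(-sq_dists(Xn, object$X_std) / object$sigma2)
  object$scales$y_mean +
    object$scales$y_sd * as.vector(Kn %*% object$coefficients)
}

#' Tidy the marginal effects of a KRLS fit
#'
#' @param x A [krls()] fit.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (average marginal effect), `std.error`,
#'   `p.value`, `p25`, `p50`, `p75`, `stars`.
#' @method tidy krls
#' @export
tidy.krls <- function(x, ...) {
  tibble(
    term = x$covariates,
    estimate = unname(x$avg),
    std.error = unname(x$se_avg),
    p.value = unname(x$p_avg),
    p25 = unname(x$quantiles[, "p25"]),
    p50 = unname(x$quantiles[, "p50"]),
    p75 = unname(x$quantiles[, "p75"]),
    stars = significance_stars(x$p_avg)
  )
}

#' One-row summary of a KRLS fit
#'
#' @param x A [krls()] fit.
#' @param ... Unused.
#' @return Tibble `n`, `d`, `sigma2`, `lambda`, `loo_sse`, `edf`,
#'   `sigma_hat2`, `r.squared` (on the standardized scale).
#' @method glance krls
#' @export
glance.krls <- function(x, ...) {
  tibble(
    n = x$n, d = x$d, sigma2 = x$sigma2, lambda = x$lambda,
    loo_sse = x$loo_sse, edf = x$edf, sigma_hat2 = x$sigma_hat2,
    r.squared = 1 - sum((x$y_std - x$fitted_std)^2) / sum(x$y_std^2)
  )
}

## p-value significance stars: *** < 0.001, ** < 0.01, * < 0.05.
significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

#' Marginal-effect summary table
#'
#' One row per covariate with the average pointwise derivative, its
#' interquartile summary (P25/P50/P75, linear interpolation between closest
#' ranks), the delta-method standard error, p-value and significance stars.
#'
#' @param fit A [krls()] fit.
#' @return Tibble `covariate`, `avg`, `p25`, `p50`, `p75`, `se`, `p_value`,
#'   `stars`.
#' @export
summarize_effects <- function(fit) {
  stopifnot(inherits(fit, "krls"))
  td <- tidy(fit)
  tibble(covariate = td$term, avg = td$estimate, p25 = td$p25, p50 = td$p50,
         p75 = td$p75, se = td$std.error, p_value = td$p.value,
         stars = td$stars)
}

#' Exhaustive best-subset covariate selection for KRLS
#'
#' Enumerates every non-empty covariate subset up to `max_size`, fits each by
#' [krls()] and returns the subset minimising the leave-one-out SSE. Ties go
#' to the smaller subset, then to lexicographic (enumeration) order. The
#' exhaustive search is capped at 15 candidates; pre-screen beyond that.
#'
#' @param data Data frame with response and candidate columns.
#' @param response Response column name.
#' @param candidates Character vector of candidate covariates (default: all
#'   numeric columns except the response).
#' @param max_size Largest subset size considered (default: all candidates).
#' @param ... Passed to [krls()].
#' @return List of class `krls_subsets`: `selected` (character vector),
#'   `fit` (the winning [krls()] fit) and `results` (tibble of every subset
#'   with size and LOO SSE).
#' @export
best_subset <- function(data, response, candidates = NULL, max_size = NULL,
                        ...) {
  data <- as.data.frame(data)
  if (is.null(candidates)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    candidates <- setdiff(num, response)
  }
  if (length(candidates) > 15) {
    abort(paste0(length(candidates), " candidate covariates exceed the ",
                 "exhaustive-search cap of 15; pre-screen the candidate set"))
  }
  max_size <- max_size %||% length(candidates)
  subsets <- unlist(
    lapply(seq_len(min(max_size, length(candidates))), function(k) {
      combn(candidates, k, simplify = FALSE)
    }),
    recursive = FALSE
  )
  rows <- purrr::map_dfr(subsets, function(s) {
    f <- krls(data, response, covariates = s, ...)
    tibble(subset = paste(s, collapse = "+"), size = length(s),
           loo_sse = f$loo_sse)
  })
  best <- which.min(rows$loo_sse)  # first minimum: smaller, then lexicographic
  sel <- subsets[[best]]
  structure(list(selected = sel,
                 fit = krls(data, response, covariates = sel, ...),
                 results = rows),
            class = "krls_subsets")
}

#' @export
print.krls_subsets <- function(x, ...) {
  cat("<krls_subsets> selected: {", paste(x$selected, collapse = ", "),
      "} out of ", nrow(x$results), " subsets\n", sep = "")
  invisible(x)
}
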