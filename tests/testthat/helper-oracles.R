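# Independent brute-force oracles and small fixture builders.

# Weighted-mean PI computed the long way: explicit proportions.
brute_pi <- function(counts) {
  total <- sum(counts)
  stopifnot(total > 0)
  p <- counts / total
  sum(p * 1:4)
}

# Simple-regression OLS via the explicit sum formulas.
brute_ols_simple <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sigma2 <- sum(resid^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(sigma2 / sxx),
       r2 = 1 - sum(resid^2) / (sum(y^2) - sum(y)^2 / n))
}

# Multiple-regression OLS by explicit normal equations.
brute_ols_multi <- function(X, y) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  resid <- y - X1 %*% beta
  df <- nrow(X1) - ncol(X1)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(sigma2 * solve(t(X1) %*% X1)))
  list(beta = drop(beta), se = se, sse = sum(resid^2), df = df)
}

# Partial R^2 by explicitly refitting without the focal term:
# (SSE_reduced - SSE_full) / SSE_reduced.
brute_partial_r2 <- function(data, response, terms, focal) {
  full <- stats::lm(stats::reformulate(terms, response), data = data)
  red <- stats::lm(stats::reformulate(setdiff(terms, focal), response),
                   data = data)
  sse_full <- sum(stats::residuals(full)^2)
  sse_red <- sum(stats::residuals(red)^2)
  (sse_red - sse_full) / sse_red
}

# Minimal specimen table from count matrices and optional metadata.
make_specimens <- function(manual, predicted = NULL, year = NULL,
                           doy = NULL, ...) {
  manual <- matrix(manual, ncol = 4)
  n <- nrow(manual)
  extra <- list(...)
  x <- data.frame(id = sprintf("S%03d", seq_len(n)),
                  year = year %||% rep(1980L, n),
                  doy = doy %||% rep(180L, n),
                  latitude = extra$latitude %||% rep(38, n),
                  longitude = extra$longitude %||% rep(-120, n),
                  elevation = extra$elevation %||% rep(1000, n),
                  spring_tmax = extra$spring_tmax %||% rep(15, n),
                  winter_ppt = extra$winter_ppt %||% rep(600, n),
                  stringsAsFactors = FALSE)
  x[paste0("manual_", c("buds", "flowers", "immature", "mature"))] <-
    as.data.frame(manual)
  if (!is.null(predicted)) {
    predicted <- matrix(predicted, ncol = 4)
    x[paste0("pred_", c("buds", "flowers", "immature", "mature"))] <-
      as.data.frame(predicted)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Specimen table whose DOY follows a known linear law exactly.
noiseless_specimens <- function(n = 40, seed = 61,
                                fun = function(d) 200 - 0.1 * (d$year - 1950) +
                                  17 * d$pi) {
  set.seed(seed)
  manual <- t(rmultinom(n, 30, c(1, 1, 1, 1)))
  x <- make_specimens(manual, predicted = manual,
                      year = sample(1900:2013, n, replace = TRUE),
                      latitude = runif(n, 36, 41),
                      longitude = runif(n, -122, -118),
                      elevation = runif(n, 200, 3000),
                      spring_tmax = runif(n, 2, 25),
                      winter_ppt = runif(n, 100, 2000))
  x$pi <- pi_table(x, "manual")$pi
  doy <- fun(cbind(x, pi = x$pi))
  x$doy <- round(doy * 1e6) / 1e6
  x$doy_exact <- doy
  x
}

# All non-negative integer 4-vectors with a given total.
compositions4 <- function(total) {
  out <- list()
  for (a in 0:total) for (b in 0:(total - a)) for (c in 0:(total - a - b)) {
    out[[length(out) + 1L]] <- c(a, b, c, total - a - b - c)
  }
  do.call(rbind, out)
}
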