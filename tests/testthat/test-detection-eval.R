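test_that("counting errors follow the predicted-minus-manual convention", {
  x <- make_specimens(rbind(c(10, 0, 2, 5), c(3, 3, 3, 3), c(0, 0, 1, 1)),
                      predicted = rbind(c(7, 2, 2, 5), c(3, 3, 3, 3),
                                        c(0, 1, 0, 1)))
  e <- counting_errors(x)
  expect_equal(e$e_buds, c(-3, 0, 0))     # underestimate is negative
  expect_equal(e$e_flowers, c(2, 0, 1))   # overestimate is positive
  expect_equal(unlist(e[2, -1], use.names = FALSE), rep(0, 4))
  expect_error(counting_errors(make_specimens(diag(4))), "no predicted")
})

test_that("per-class MAE is the mean absolute error and matches raw counts", {
  e <- data.frame(id = c("a", "b", "c"),
                  e_buds = c(-3, 1, 0), e_flowers = c(0, 0, 0),
                  e_immature = c(-2, -2, -2), e_mature = c(2, -2, 2))
  mae <- mae_per_class(e)
  expect_equal(unname(mae), c(4 / 3, 0, 2, 2))
  expect_error(mae_per_class(e[0, ]), "at least one sheet")

  # Consistency: MAE from the error table equals MAE from raw columns.
  set.seed(11)
  manual <- matrix(rpois(40, 10), ncol = 4)
  pred <- matrix(rpois(40, 7), ncol = 4)
  x <- make_specimens(manual, predicted = pred)
  expect_equal(unname(mae_per_class(counting_errors(x))),
               unname(colMeans(abs(pred - manual))))
  expect_equal(mae_per_class(x), mae_per_class(counting_errors(x)))
})

test_that("concordance recovers exact linear relationships", {
  set.seed(21)
  manual <- matrix(rpois(60, 12), ncol = 4)
  x <- make_specimens(manual, predicted = manual)
  cc <- suppressWarnings(concordance(x, "buds"))
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$slope, 1)
  expect_equal(cc$intercept, 0)
  expect_equal(cc$mae, 0)

  # exactly proportional values: r = 1, slope = the proportion
  x2 <- make_specimens(manual, predicted = manual)
  x2$pred_flowers <- 0.3 * manual[, 2]
  cc2 <- suppressWarnings(concordance(x2, "flowers"))
  expect_equal(cc2$pearson_r, 1)
  expect_equal(cc2$slope, 0.3, tolerance = 1e-12)

  same <- make_specimens(matrix(5, 3, 4), predicted = matrix(2, 3, 4))
  expect_error(concordance(same, "buds"), "degenerate regressor")
  expect_error(concordance(x[1:2, ], "buds"), "at least 3 sheets")
})

test_that("concordance agrees with the closed-form OLS oracle", {
  # five-point toy set
  manual <- cbind(c(2, 5, 9, 14, 20), 1, 1, 1)
  pred <- cbind(c(1, 2, 2, 5, 6), 1, 1, 1)
  x <- make_specimens(manual, predicted = pred)
  cc <- concordance(x, "buds")
  o <- brute_ols_simple(manual[, 1], pred[, 1])
  expect_equal(cc$slope, o$slope, tolerance = 1e-10)
  expect_equal(cc$slope_se, o$slope_se, tolerance = 1e-10)
  expect_equal(cc$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(cc$r2, o$r2, tolerance = 1e-10)

  # property: random instances of n <= 20
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    mm <- cbind(rpois(n, 15), rpois(n, 5), rpois(n, 5), rpois(n, 5))
    pp <- cbind(rbinom(n, mm[, 1], 0.4) + rpois(n, 1),
                mm[, -1, drop = FALSE])
    if (var(mm[, 1]) == 0) next
    xx <- make_specimens(mm, predicted = pp)
    cc <- concordance(xx, "buds")
    oo <- brute_ols_simple(mm[, 1], pp[, 1])
    expect_equal(cc$slope, oo$slope, tolerance = 1e-10)
    expect_equal(cc$slope_se, oo$slope_se, tolerance = 1e-10)
    expect_equal(cc$pearson_r, cor(mm[, 1], pp[, 1]), tolerance = 1e-12)
  }
})

test_that("detection ratio is the reciprocal slope", {
  expect_equal(detection_ratio(1), 1)
  expect_equal(detection_ratio(0.16), 6.25)
  expect_equal(round(detection_ratio(0.16), 1), 6.2)
  expect_equal(round(detection_ratio(0.28), 1), 3.6)
  expect_error(detection_ratio(0), "positive slope")
  expect_error(detection_ratio(-2), "positive slope")
})

test_that("abundance bins partition sheets at width 10 with an open top", {
  manual <- cbind(c(5, 15, 45), 0, 0, 0)
  x <- make_specimens(manual, predicted = manual)
  suppressWarnings(b <- bin_errors_by_abundance(x, "buds"))
  expect_equal(b$lower, c(0, 10, 20, 30, 40))
  expect_equal(b$upper, c(10, 20, 30, 40, Inf))
  expect_equal(b$n, c(1L, 1L, 0L, 0L, 1L))
  expect_true(all(b$median[b$n > 0] == 0))  # perfect detector
  expect_true(all(is.na(b$median[b$n == 0])))
})

test_that("binned mean errors match the binomial-thinning expectation", {
  # detector keeping each organ with p = 0.3 loses 0.7 per manual organ
  set.seed(41)
  n <- 1e4
  manual <- cbind(sample(0:60, n, replace = TRUE), 0, 0, 0)
  pred <- cbind(rbinom(n, manual[, 1], 0.3), 0, 0, 0)
  x <- make_specimens(manual, predicted = pred)
  b <- bin_errors_by_abundance(x, "buds")
  e <- pred[, 1] - manual[, 1]
  bin <- pmin(manual[, 1] %/% 10, 4) + 1
  for (i in 1:5) {
    mean_manual <- mean(manual[bin == i, 1])
    se <- sd(e[bin == i]) / sqrt(sum(bin == i))
    expect_equal(mean(e[bin == i]), -0.7 * mean_manual,
                 tolerance = max(4 * se / abs(0.7 * mean_manual), 1e-6))
  }
})

test_that("PI is exactly invariant under uniform expected thinning", {
  set.seed(51)
  for (rep in 1:20) {
    counts <- rpois(4, 20) + 1
    p <- runif(1, 0.1, 0.9)
    expect_equal(phenological_index(counts),
                 brute_pi(p * counts), tolerance = 1e-12)
  }
})

test_that("uniform thinning leaves the PI nearly unchanged on busy sheets", {
  # sheets with >= 40 organs from the generator's composition model;
  # a detector keeping each organ with the same per-sheet probability
  set.seed(99)
  n <- 1e4
  u <- runif(n, 0, 3)
  intensity <- phenindex:::.stage_class_intensity(
    1 + u, 0.6, c(27.4, 28.5, 11, 12.5))
  mu <- rowSums(intensity)
  tot <- rnbinom(n, size = 3, mu = mu)
  idx <- which(tot < 40)
  while (length(idx)) {
    tot[idx] <- rnbinom(length(idx), size = 3, mu = mu[idx])
    idx <- idx[tot[idx] < 40]
  }
  manual <- t(vapply(seq_len(n),
                     function(i) rmultinom(1, tot[i], intensity[i, ])[, 1],
                     integer(4)))
  dpi_at <- function(pmin, pmax) {
    p <- runif(n, pmin, pmax)
    pred <- sapply(1:4, function(k) rbinom(n, manual[, k], p))
    keep <- rowSums(pred) > 0
    mean(abs(phenological_index(pred[keep, , drop = FALSE]) -
               phenological_index(manual[keep, , drop = FALSE])))
  }
  mid <- dpi_at(0.4, 0.8)
  expect_lt(mid, 0.05)
  # heavier thinning hurts, but degrades gracefully
  low <- dpi_at(0.2, 0.4)
  expect_gt(low, mid)
  expect_lt(low, 0.10)
})

test_that("age effect is null for constant errors and exact for geometric growth", {
  manual <- matrix(rep(c(10, 5, 3, 2), each = 11), ncol = 4)
  pred <- manual - cbind(rep(2L, 11), 0L, 0L, 0L)
  year <- seq(1900, 2000, by = 10)
  x <- make_specimens(manual, predicted = pred, year = year)
  a <- suppressWarnings(age_effect(x, "buds"))
  expect_equal(a$slope, 0, tolerance = 1e-12)
  expect_equal(a$transform, "log10(|e|+1)")

  # |e| + 1 = 10^(0.002 (2000 - year)), noiseless -> slope is -0.002
  e <- 10^(0.002 * (2000 - year)) - 1
  x2 <- x
  x2$pred_buds <- x2$manual_buds + e   # fractional counts: pure math check
  a2 <- age_effect(x2, "buds")
  expect_equal(a2$slope, -0.002, tolerance = 1e-10)
  expect_lt(a2$p_value, 1e-6)

  xc <- make_specimens(manual, predicted = pred, year = rep(1950, 11))
  expect_error(age_effect(xc, "buds"), "year is constant")
})

test_that("age effect stays null when errors are independent of year", {
  # calibration: with no true age effect, p > 0.05 in most replicates
  pvals <- vapply(1:20, function(s) {
    set.seed(600 + s)
    n <- 500
    manual <- matrix(rpois(4 * n, 12), ncol = 4)
    pred <- matrix(rbinom(4 * n, as.vector(manual), 0.5), ncol = 4)
    x <- make_specimens(manual, predicted = pred,
                        year = sample(1900:2013, n, replace = TRUE))
    age_effect(x, "buds")$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("the evaluation report covers the four classes plus the PI", {
  x <- suppressWarnings(
    simulate_collection(simulation_config(n_specimens = 150, seed = 5)))
  rep_tab <- suppressWarnings(evaluation_report(x))
  expect_equal(rep_tab$target,
               c("buds", "flowers", "immature_fruits", "mature_fruits",
                 "pi"))
  expect_true(all(rep_tab$mae >= 0))
  expect_true(all(rep_tab$pearson_r >= -1 & rep_tab$pearson_r <= 1))
  expect_true(all(rep_tab$r2 >= 0 & rep_tab$r2 <= 1))
})
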