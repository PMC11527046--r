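test_that("Kaplan-Meier estimate matches hand products and edge cases", {
  expect_error(km_estimate(numeric(), numeric()), "empty")

  none <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(none$surv == 1))

  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_at(km, 1), 2 / 3)
  expect_equal(km_at(km, 2.5), 2 / 3)  # right-continuous between events
  expect_equal(km_at(km, 3), 0)
  expect_equal(km_at(km, 0.5), 1)
})

test_that("KM equals the empirical survival function without censoring", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- rexp(40, 0.1) + 0.01
    km <- km_estimate(t, rep(1, 40))
    grid <- quantile(t, c(0.1, 0.35, 0.6, 0.9))
    expect_equal(km_at(km, grid), sapply(grid, function(g) mean(t > g)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("log-rank test behaves under null and multi-group inputs", {
  g <- list(times = c(1, 3, 5, 7, 9), events = c(1, 0, 1, 1, 0))
  r <- logrank_test(list(g, g))
  expect_lt(r$chi2, 1e-10)
  expect_equal(r$p, 1, tolerance = 1e-6)

  r3 <- logrank_test(list(g, g, list(times = c(2, 4, 6),
                                     events = c(1, 1, 0))))
  expect_equal(r3$df, 2)
  expect_error(logrank_test(list(g, list(times = numeric(),
                                         events = numeric()))), "zero")
})

test_that("log-rank p agrees with its permutation distribution", {
  set.seed(8)
  n <- 30
  times <- rexp(2 * n, 0.05)
  events <- rbinom(2 * n, 1, 0.8)
  grp <- rep(1:2, each = n)
  split_groups <- function(g) {
    lapply(1:2, function(k) list(times = times[g == k],
                                 events = events[g == k]))
  }
  obs <- logrank_test(split_groups(grp))
  perm <- replicate(400, {
    logrank_test(split_groups(sample(grp)))$chi2
  })
  p_perm <- mean(perm >= obs$chi2)
  expect_lt(abs(p_perm - obs$p), 0.1)
})

test_that("Harrell's C has the expected fixed points", {
  set.seed(2)
  t <- rexp(100, 0.05); e <- rbinom(100, 1, 0.7)
  expect_equal(harrell_c(rep(1, 100), t, e)$c, 0.5)
  expect_equal(harrell_c(-t, t, rep(1, 100))$c, 1)
  # monotone transform invariance
  r <- runif(100)
  expect_equal(harrell_c(r, t, e)$c, harrell_c(exp(3 * r), t, e)$c)

  set.seed(3)
  big <- harrell_c(runif(2000), rexp(2000, 0.02), rbinom(2000, 1, 0.5))
  expect_lt(abs(big$c - 0.5), 0.02)
})

test_that("paired C-index comparison is null for a model vs itself", {
  set.seed(4)
  t <- rexp(300, 0.02); e <- rbinom(300, 1, 0.5); r <- runif(300)
  res <- cindex_difference(r, r, t, e, n_boot = 150, seed = 1)
  expect_equal(res$delta, 0)
  expect_equal(res$p, 1)
  res2 <- cindex_difference(r, r, t, e, n_boot = 150, seed = 1)
  expect_identical(res, res2)  # seeded reproducibility
  expect_warning(cindex_difference(r, r, t, e, n_boot = 50), "n_boot")
})

test_that("adding a null covariate leaves the C-difference near zero", {
  set.seed(5)
  n <- 1500
  x <- rnorm(n)
  noise <- rnorm(n)
  t <- rexp(n, 0.01 * exp(0.5 * x))
  e <- as.integer(t < 80); t <- pmin(t, 80)
  f1 <- fit_cox(data.frame(x = x), t, e)
  f2 <- fit_cox(data.frame(x = x, noise = noise), t, e)
  r1 <- predict(f1$fit, type = "lp")
  r2 <- predict(f2$fit, type = "lp")
  res <- cindex_difference(r1, r2, t, e, n_boot = 150, seed = 2)
  expect_lt(abs(res$delta), 0.01)
})

test_that("Cox fit recovers generating effects and the null", {
  set.seed(6)
  n <- 2500
  x <- rbinom(n, 1, 0.4)
  t <- rexp(n, 2e-3 * exp(log(1.42) * x))
  e <- as.integer(t < 80); t <- pmin(t, 80)
  f <- fit_cox(data.frame(x = x), t, e)
  expect_lt(abs(f$log_hr[["x"]] - log(1.42)), 3 * f$se[["x"]])

  z <- rnorm(n)
  f0 <- fit_cox(data.frame(z = z), t, e)
  expect_lt(abs(f0$log_hr[["z"]]), 3 * f0$se[["z"]])
})

test_that("Cox estimate matches the exponential rate-ratio oracle", {
  set.seed(7)
  n <- 6000
  x <- rep(0:1, each = n / 2)
  r0 <- 0.01; r1 <- 0.025
  t <- rexp(n, ifelse(x == 1, r1, r0))
  e <- rep(1L, n)  # fully observed
  f <- fit_cox(data.frame(x = x), t, e)
  # closed-form MLE for exponential data: log of the event/person-time ratio
  oracle <- log((sum(x) / sum(t[x == 1])) / (sum(1 - x) / sum(t[x == 0])))
  expect_equal(f$log_hr[["x"]], oracle, tolerance = 0.05)
})

test_that("likelihood-ratio comparison of nested Cox fits is sound", {
  set.seed(9)
  n <- 800
  x <- rnorm(n)
  t <- rexp(n, 0.01 * exp(0.4 * x)); e <- as.integer(t < 100)
  t <- pmin(t, 100)
  f0 <- fit_cox(data.frame(noise = rnorm(n)), t, e)
  f1 <- fit_cox(data.frame(noise = rnorm(n), x = x), t, e)
  lrt <- cox_lrt(f0, f1)
  expect_equal(lrt$df, 1)
  expect_gt(lrt$chi2, 0)
  expect_lt(lrt$p, 0.01)
})
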