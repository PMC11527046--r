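sim_instruments <- function(k, beta = 0.3, pleiotropy = 0,
                            n_invalid = 0, invalid_shift = 0, seed = 1) {
  set.seed(seed)
  bx <- runif(k, 0.1, 0.4)
  se_x <- runif(k, 0.005, 0.02)
  se_y <- runif(k, 0.01, 0.04)
  by <- beta * bx + pleiotropy + rnorm(k, 0, se_y)
  if (n_invalid > 0) {
    by[seq_len(n_invalid)] <- by[seq_len(n_invalid)] + invalid_shift
  }
  instrument_set(paste0("rs", seq_len(k)), bx, se_x, by, se_y)
}

test_that("IVW fixed points: single instrument and zero outcome betas", {
  one <- instrument_set("rs1", 0.2, 0.01, 0.06, 0.02)
  expect_equal(ivw(one)$beta, 0.06 / 0.2)
  expect_equal(ivw(one)$se, 0.02 / 0.2)

  zero <- sim_instruments(20, beta = 0)
  zero$beta_outcome <- 0
  expect_equal(ivw(zero)$beta, 0)
  expect_error(ivw(zero[0, ]), "no instruments")
})

test_that("fixed-effect IVW equals weighted least squares through the origin", {
  inst <- sim_instruments(40, beta = 0.3, seed = 2)
  got <- ivw(inst, random_effects = FALSE)
  wls <- lm(beta_outcome ~ 0 + beta_exposure, data = inst,
            weights = 1 / inst$se_outcome^2)
  expect_equal(got$beta, unname(coef(wls)[1]), tolerance = 1e-12)
})

test_that("IVW recovers a simulated causal effect; random effects never shrink the SE", {
  inst <- sim_instruments(50, beta = 0.3, seed = 3)
  fe <- ivw(inst, random_effects = FALSE)
  re <- ivw(inst, random_effects = TRUE)
  expect_lt(abs(re$beta - 0.3), 3 * re$se)
  expect_gte(re$se, fe$se)
  expect_equal(re$or, exp(re$beta))
})

test_that("MR-Egger separates slope from directional pleiotropy", {
  # exact construction: outcome = 0.3 * exposure + 0.05, no noise
  bx <- seq(0.1, 0.5, length.out = 10)
  inst <- instrument_set(paste0("rs", 1:10), bx, rep(0.01, 10),
                         0.3 * bx + 0.05, rep(0.02, 10))
  eg <- mr_egger(inst)
  expect_equal(eg$slope, 0.3, tolerance = 1e-9)
  expect_equal(eg$intercept, 0.05, tolerance = 1e-9)

  bal <- sim_instruments(60, beta = 0.25, seed = 4)
  egb <- mr_egger(bal)
  expect_lt(abs(egb$slope - 0.25), 4 * egb$slope_se)
  expect_gt(egb$intercept_p, 0.01)

  expect_error(mr_egger(bal[1:2, ]), "at least 3")
})

test_that("weighted median resists up to half invalid instruments", {
  clean <- sim_instruments(20, beta = 0.3, seed = 5)
  equal_ratio <- instrument_set(paste0("rs", 1:5), rep(0.2, 5),
                                rep(0.01, 5), rep(0.08, 5), rep(0.02, 5))
  expect_equal(weighted_median(equal_ratio, n_boot = 50)$beta, 0.4)

  corrupt <- sim_instruments(40, beta = 0.3, n_invalid = 12,
                             invalid_shift = 0.3, seed = 6)
  wm <- weighted_median(corrupt, n_boot = 200, seed = 1)
  iv <- ivw(corrupt)
  expect_lt(abs(wm$beta - 0.3), 0.1)
  expect_gt(abs(iv$beta - 0.3), abs(wm$beta - 0.3))

  a <- weighted_median(clean, n_boot = 100, seed = 3)
  b <- weighted_median(clean, n_boot = 100, seed = 3)
  expect_identical(a, b)
})

test_that("Cochran's Q flags outliers and is undefined for one instrument", {
  inst <- sim_instruments(30, beta = 0.2, seed = 7)
  q0 <- cochran_q(inst)
  expect_equal(q0$df, 29)
  out <- inst
  out$beta_outcome[1] <- out$beta_outcome[1] + 1
  expect_gt(cochran_q(out)$Q, q0$Q)
  expect_error(cochran_q(inst[1, ]), "single instrument")

  # homogeneous simulation: rejection near nominal
  set.seed(8)
  rej <- mean(replicate(200, {
    cochran_q(sim_instruments(15, beta = 0.1, seed = sample.int(1e6, 1)))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.06)
})

test_that("estimators are invariant to per-variant sign flips", {
  inst <- sim_instruments(25, beta = 0.3, seed = 9)
  flipped <- inst
  i <- seq(1, 25, by = 2)
  flipped$beta_exposure[i] <- -flipped$beta_exposure[i]
  flipped$beta_outcome[i] <- -flipped$beta_outcome[i]
  expect_equal(ivw(flipped)$beta, ivw(inst)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(flipped)$slope, mr_egger(inst)$slope,
               tolerance = 1e-12)
  expect_equal(weighted_median(flipped, n_boot = 0 + 100, seed = 2)$beta,
               weighted_median(inst, n_boot = 100, seed = 2)$beta,
               tolerance = 1e-12)
})

test_that("binary-exposure scaling multiplies by log 2", {
  sc <- binary_exposure_scale(1, c(0.5, 1.5))
  expect_equal(sc$beta, log(2))
  expect_equal(sc$ci, log(2) * c(0.5, 1.5))
  expect_equal(binary_exposure_scale(0, c(-0.1, 0.1))$beta, 0)
  expect_true(sc$ci[1] < sc$ci[2])
  expect_equal(sc$or, exp(log(2)))
})

test_that("instrument TSV reader matches the constructor", {
  inst <- sim_instruments(10, seed = 10)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(snp = inst$snp, beta_exp = inst$beta_exposure,
                         se_exp = inst$se_exposure,
                         beta_out = inst$beta_outcome,
                         se_out = inst$se_outcome),
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(as.data.frame(read_instruments(tf)), as.data.frame(inst),
               tolerance = 1e-12)
})
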