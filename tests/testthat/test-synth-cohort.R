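test_that("parameter validation rejects bad inputs with named fields", {
  expect_error(cohort_params(covariate_sds = c(age = -1)), "SDs")
  expect_error(cohort_params(fractions = c(female = 1.2)), "fractions")
  expect_error(cohort_params(covariate_means = c(age = NA)),
               "covariate_means")
  expect_error(cohort_params(plaque_model = list(intercept = Inf)),
               "plaque_model")
  expect_error(cohort_params(count_levels = c(p_one = 0.5, p_two = 0.3,
                                              p_three = 0.3)), "sum to 1")
  expect_error(cohort_params(admin_censor_months = 0), "admin_censor")
})

test_that("default cohort matches the emulated study conditions", {
  d <- generate_cohort(cohort_params(seed = 3))
  expect_equal(nrow(d), 19499)
  expect_true(abs(mean(d$plaque_present) - 0.45) < 0.02)
  expect_true(abs(mean(d$plaque_count >= 2) - 0.14) < 0.02)
  expect_true(validate_cohort(d))
  # follow-up structure: in (0, 80], median near 55 months
  expect_true(all(d$time_months > 0 & d$time_months <= 80))
  expect_true(abs(median(d$time_months) - 55) < 3)
  # event mix covers all MACE components
  expect_setequal(unique(d$event_type[d$event == 1]),
                  c("mi", "stroke", "cvd_death"))
})

test_that("generation is deterministic given params and seed", {
  p <- cohort_params(n_participants = 500, seed = 42)
  expect_identical(generate_cohort(p), generate_cohort(p))
  fx1 <- generate_detection_fixtures(n_images = 20, seed = 9)
  fx2 <- generate_detection_fixtures(n_images = 20, seed = 9)
  expect_identical(fx1, fx2)
})

test_that("degenerate hazard gives no events and full follow-up", {
  p <- cohort_params(n_participants = 300,
                     hazard_model = list(base_rate = 0),
                     followup_spread_months = 0, seed = 5)
  d <- generate_cohort(p)
  expect_equal(sum(d$event), 0)
  expect_true(all(d$time_months == 80))
  expect_true(all(d$event_type == "none"))
})

test_that("raising the baseline rate increases the event count", {
  mk <- function(rate) {
    sum(generate_cohort(cohort_params(
      n_participants = 4000, hazard_model = list(base_rate = rate),
      seed = 7))$event)
  }
  e1 <- mk(1e-4); e2 <- mk(5e-4); e3 <- mk(2e-3)
  expect_lt(e1, e2)
  expect_lt(e2, e3)
})

test_that("logistic plaque model is recovered from a large cohort", {
  p <- cohort_params(n_participants = 200000, seed = 21)
  d <- generate_cohort(p)
  cf <- p$plaque_model$coef
  fit <- fit_logistic(d[names(cf)], d$plaque_present)
  z <- (fit$log_or[names(cf)] - cf) / fit$se[names(cf)]
  expect_true(all(abs(z) < 3))
})

test_that("detection fixtures degenerate correctly at the rate extremes", {
  fx <- generate_detection_fixtures(n_images = 30, jitter = 0, fp_rate = 0,
                                    fn_rate = 0, seed = 2)
  ann <- fx$annotations[order(fx$annotations$image_id, fx$annotations$x_min), ]
  prd <- fx$predictions[order(fx$predictions$image_id, fx$predictions$x_min), ]
  expect_equal(nrow(ann), nrow(prd))
  for (cc in c("image_id", "x_min", "y_min", "x_max", "y_max")) {
    expect_equal(unname(unlist(ann[[cc]])), unname(unlist(prd[[cc]])))
  }
  expect_true(all(prd$confidence > 0 & prd$confidence <= 1))

  fx0 <- generate_detection_fixtures(n_images = 30, fp_rate = 0, fn_rate = 1,
                                     seed = 2)
  expect_equal(nrow(fx0$predictions), 0)
})

test_that("cohort TSV and params YAML round-trip", {
  p <- cohort_params(n_participants = 120, seed = 4)
  d <- generate_cohort(p)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(d, tf)
  d2 <- read_cohort_tsv(tf)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)

  yf <- withr::local_tempfile(fileext = ".yaml")
  write_params_yaml(p, yf)
  p2 <- read_params_yaml(yf)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
})

test_that("box JSON and YOLO formats round-trip", {
  fx <- generate_detection_fixtures(n_images = 12, seed = 6)
  jf <- withr::local_tempfile(fileext = ".json")
  write_boxes_json(fx$predictions, jf, image_ids = fx$image_ids)
  back <- read_boxes_json(jf)
  expect_equal(back$image_ids, fx$image_ids)
  ord <- function(b) b[order(b$image_id, b$x_min), ]
  expect_equal(ord(back$boxes)$x_max, ord(fx$predictions)$x_max,
               tolerance = 1e-9)

  yd <- withr::local_tempdir()
  write_boxes_yolo(fx$predictions, yd, image_ids = fx$image_ids)
  back2 <- read_boxes_yolo(yd)
  expect_equal(back2$image_ids, fx$image_ids)
  b1 <- ord(back2$boxes); b2 <- ord(fx$predictions)
  for (cc in c("x_min", "y_min", "x_max", "y_max", "confidence")) {
    expect_equal(b1[[cc]], b2[[cc]], tolerance = 1e-4)
  }
})
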