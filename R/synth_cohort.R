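#' Parameters for the synthetic carotid-plaque cohort generator
#'
#' Bundles everything the generator needs: marginal covariate distributions,
#' a logistic model linking covariates to plaque presence, the conditional
#' distribution of plaque count among plaque-positive participants, a
#' proportional-hazards model for time to a major adverse cardiovascular
#' event (MACE), and the administrative censoring scheme.
#'
#' Defaults emulate a population-based imaging cohort of ~19,500
#' participants in their mid-60s: age mean 64.6 (SD 7.6) years, SBP 138.6
#' (17.94) mmHg, total cholesterol 5.72 (1.09) mmol/L, HDL 1.48 (0.37)
#' mmol/L, LDL 3.58 (0.83) mmol/L, 50.8% female, 3.6% current smokers, 5.5%
#' diabetes, 23.7% statin use, 24.7% antihypertensive use, 7.1% prior CVD.
#' The plaque model intercept is calibrated so that default covariates give
#' ~45% plaque prevalence; among positives the count distribution gives
#' cumulative prevalences of ~45% (>=1), ~14% (>=2) and ~3.1% (>=3) plaques.
#' The hazard model defaults to count-level plaque log hazard ratios
#' log(1.30) (one plaque) and log(1.62) (two or more), with the baseline
#' rate calibrated to ~2% observed MACE over the follow-up window.
#' Follow-up is administratively censored per person, uniformly over
#' (admin_censor_months - followup_spread_months, admin_censor_months];
#' the defaults give a median follow-up of 55 months on a 1-80 month range.
#'
#' @param n_participants cohort size.
#' @param covariate_means,covariate_sds named numerics for the continuous
#'   covariates (age, sbp, total_chol, hdl, ldl).
#' @param fractions named numerics in \[0,1\] for the binary covariates and
#'   race-group fractions.
#' @param plaque_model list with `intercept` and named `coef` (log odds per
#'   unit) for the plaque-presence logistic model.
#' @param count_levels named numerics `p_one`, `p_two`, `p_three`: the
#'   distribution of plaque count among plaque-positive participants
#'   (must sum to 1).
#' @param hazard_model list with `base_rate` (events per person-month for a
#'   participant at the model's covariate centers), named `log_hr` (may
#'   include either `plaque_present` or the pair `plaque1`/`plaque2plus`),
#'   and named `centers` used to center covariates in the linear predictor.
#' @param admin_censor_months maximum follow-up (administrative censoring).
#' @param followup_spread_months width of the per-person uniform censoring
#'   window below `admin_censor_months`; 0 censors everyone at the maximum.
#' @param event_type_probs probabilities of (mi, stroke, cvd_death) for
#'   participants with an event.
#' @param seed integer seed; generation is fully reproducible given the
#'   parameter set.
#' @return an object of class `cohort_params`.
#' @seealso [generate_cohort()]
#' @export
cohort_params <- function(n_participants = 19499,
                          covariate_means = NULL,
                          covariate_sds = NULL,
                          fractions = NULL,
                          plaque_model = NULL,
                          count_levels = NULL,
                          hazard_model = NULL,
                          admin_censor_months = 80,
                          followup_spread_months = 50,
                          event_type_probs = c(mi = 0.453, stroke = 0.400,
                                               cvd_death = 0.147),
                          seed = 1) {
  def_means <- c(age = 64.6, sbp = 138.6, total_chol = 5.72,
                 hdl = 1.48, ldl = 3.58)
  def_sds <- c(age = 7.6, sbp = 17.94, total_chol = 1.09,
               hdl = 0.37, ldl = 0.83)
  def_frac <- c(female = 0.508, smoker_current = 0.036, diabetes = 0.055,
                statin = 0.237, antihtn = 0.247, prior_cvd = 0.071,
                race_black = 0.006, race_other = 0.023)
  def_plaque <- list(
    intercept = -5.346,
    coef = c(age = 0.055, female = -0.20, smoker_current = 0.45,
             sbp = 0.008, statin = 0.45, antihtn = 0.20, prior_cvd = 0.50,
             ldl = 0.10, diabetes = 0.20))
  def_counts <- c(p_one = 0.689, p_two = 0.242, p_three = 0.069)
  def_hazard <- list(
    base_rate = 2.9e-4,
    log_hr = c(age = 0.07, female = -0.45, sbp = 0.012,
               smoker_current = 0.65, diabetes = 0.55, antihtn = 0.25,
               statin = 0.10, prior_cvd = 1.10, total_chol = 0.12,
               hdl = -0.50, plaque1 = log(1.30), plaque2plus = log(1.62)),
    centers = c(age = 64.6, sbp = 138.6, total_chol = 5.72, hdl = 1.48,
                female = 0.508, smoker_current = 0.036, diabetes = 0.055,
                statin = 0.237, antihtn = 0.247, prior_cvd = 0.071,
                plaque_present = 0.45, plaque1 = 0.31, plaque2plus = 0.14))

  merge_named <- function(def, user) {
    if (is.null(user)) return(def)
    def[names(user)] <- user
    def
  }
  p <- list(
    n_participants = n_participants,
    covariate_means = merge_named(def_means, covariate_means),
    covariate_sds = merge_named(def_sds, covariate_sds),
    fractions = merge_named(def_frac, fractions),
    plaque_model = if (is.null(plaque_model)) def_plaque else
      list(intercept = plaque_model$intercept %||% def_plaque$intercept,
           coef = merge_named(def_plaque$coef, plaque_model$coef)),
    count_levels = merge_named(def_counts, count_levels),
    hazard_model = if (is.null(hazard_model)) def_hazard else
      list(base_rate = hazard_model$base_rate %||% def_hazard$base_rate,
           log_hr = hazard_model$log_hr %||% def_hazard$log_hr,
           centers = merge_named(def_hazard$centers, hazard_model$centers)),
    admin_censor_months = admin_censor_months,
    followup_spread_months = followup_spread_months,
    event_type_probs = event_type_probs,
    seed = seed)
  class(p) <- "cohort_params"
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  check_finite(p$n_participants, "n_participants")
  if (p$n_participants < 1) stop("n_participants must be positive")
  for (f in c("covariate_means", "covariate_sds", "fractions",
              "count_levels", "admin_censor_months",
              "followup_spread_months", "event_type_probs")) {
    check_finite(p[[f]], f)
  }
  check_finite(p$plaque_model$intercept, "plaque_model$intercept")
  check_finite(p$plaque_model$coef, "plaque_model$coef")
  check_finite(p$hazard_model$base_rate, "hazard_model$base_rate")
  check_finite(p$hazard_model$log_hr, "hazard_model$log_hr")
  check_finite(p$hazard_model$centers, "hazard_model$centers")
  if (any(p$covariate_sds <= 0)) stop("all covariate SDs must be > 0")
  if (any(p$fractions < 0 | p$fractions > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (p$admin_censor_months <= 0) stop("admin_censor_months must be > 0")
  if (p$followup_spread_months < 0 ||
      p$followup_spread_months >= p$admin_censor_months) {
    stop("followup_spread_months must be in [0, admin_censor_months)")
  }
  if (abs(sum(p$count_levels) - 1) > 1e-9) {
    stop("count_levels must sum to 1")
  }
  if (p$hazard_model$base_rate < 0) stop("hazard_model$base_rate must be >= 0")
  invisible(TRUE)
}

#' Generate a synthetic cohort table
#'
#' Draws covariates from independent marginals, assigns plaque presence from
#' the logistic plaque model and plaque count from the conditional count
#' distribution, then draws a MACE time from an exponential (constant
#' baseline hazard) proportional-hazards model and censors it at a
#' per-person administrative date.
#'
#' @param params a [cohort_params()] object.
#' @return a `data.frame` (class `cohort_table`) with one row per
#'   participant: `id`, `female`, `age`, `sbp`, `total_chol`, `hdl`, `ldl`
#'   (lipids in mmol/L), `smoker_current`, `diabetes`, `statin`, `antihtn`,
#'   `prior_cvd` (0/1 flags), `race` ("white"/"black"/"other"),
#'   `plaque_present`, `plaque_count`, `time_months`, `event`, `event_type`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  validate_cohort_params(params)
  set.seed(params$seed)
  n <- params$n_participants
  m <- params$covariate_means
  s <- params$covariate_sds
  fr <- params$fractions

  d <- data.frame(
    id = seq_len(n),
    female = rbinom(n, 1, fr[["female"]]),
    age = rnorm(n, m[["age"]], s[["age"]]),
    sbp = rnorm(n, m[["sbp"]], s[["sbp"]]),
    total_chol = rnorm(n, m[["total_chol"]], s[["total_chol"]]),
    hdl = pmax(rnorm(n, m[["hdl"]], s[["hdl"]]), 0.2),
    ldl = pmax(rnorm(n, m[["ldl"]], s[["ldl"]]), 0.3),
    smoker_current = rbinom(n, 1, fr[["smoker_current"]]),
    diabetes = rbinom(n, 1, fr[["diabetes"]]),
    statin = rbinom(n, 1, fr[["statin"]]),
    antihtn = rbinom(n, 1, fr[["antihtn"]]),
    prior_cvd = rbinom(n, 1, fr[["prior_cvd"]]))
  d$race <- sample(c("white", "black", "other"), n, replace = TRUE,
                   prob = c(1 - fr[["race_black"]] - fr[["race_other"]],
                            fr[["race_black"]], fr[["race_other"]]))

  pm <- params$plaque_model
  lp_plaque <- pm$intercept +
    as.matrix(d[names(pm$coef)]) %*% pm$coef
  d$plaque_present <- rbinom(n, 1, stats::plogis(lp_plaque))

  cl <- params$count_levels
  d$plaque_count <- 0L
  npos <- sum(d$plaque_present)
  if (npos > 0) {
    d$plaque_count[d$plaque_present == 1] <-
      sample(c(1L, 2L, 3L), npos, replace = TRUE,
             prob = cl[c("p_one", "p_two", "p_three")])
  }

  hz <- params$hazard_model
  d$plaque1 <- as.integer(d$plaque_count == 1)
  d$plaque2plus <- as.integer(d$plaque_count >= 2)
  x <- as.matrix(d[names(hz$log_hr)])
  x <- sweep(x, 2, hz$centers[names(hz$log_hr)])
  lp_haz <- drop(x %*% hz$log_hr)

  rate <- hz$base_rate * exp(lp_haz)
  t_event <- ifelse(rate > 0, rexp(n) / pmax(rate, .Machine$double.xmin), Inf)
  censor <- params$admin_censor_months -
    runif(n, 0, params$followup_spread_months)
  d$time_months <- pmin(t_event, censor)
  d$event <- as.integer(t_event <= censor)
  d$event_type <- "none"
  nev <- sum(d$event)
  if (nev > 0) {
    d$event_type[d$event == 1] <-
      sample(names(params$event_type_probs), nev, replace = TRUE,
             prob = params$event_type_probs)
  }
  d$plaque1 <- NULL
  d$plaque2plus <- NULL
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Check the internal consistency of a cohort table
#'
#' Verifies the structural invariants the downstream analysis relies on:
#' plaque presence agrees with count >= 1, event types are present exactly
#' for events, and follow-up lies in (0, admin_censor_months].
#'
#' @param cohort a cohort table.
#' @param admin_censor_months the maximum follow-up used at generation.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_cohort <- function(cohort, admin_censor_months = 80) {
  stopifnot(is.data.frame(cohort))
  if (!all(cohort$plaque_present == (cohort$plaque_count >= 1))) {
    stop("plaque_present must equal (plaque_count >= 1)")
  }
  if (!all((cohort$event_type == "none") == (cohort$event == 0))) {
    stop("event_type must be 'none' exactly for non-events")
  }
  if (any(cohort$time_months <= 0) ||
      any(cohort$time_months > admin_censor_months + 1e-9)) {
    stop("time_months must lie in (0, admin_censor_months]")
  }
  invisible(TRUE)
}

#' Generate paired ground-truth and predicted detection fixtures
#'
#' Emulates an evaluation image set for a single-class plaque detector on a
#' fixed ultrasound crop canvas (default 480 x 448 pixels). Ground truth
#' boxes are placed uniformly on positive images; predictions are jittered
#' copies of the true boxes with per-box misses at `fn_rate`, plus spurious
#' Poisson(`fp_rate`) boxes per image, each carrying a confidence in (0, 1].
#'
#' @param n_images number of images.
#' @param pos_fraction fraction of images containing at least one plaque.
#' @param boxes_per_positive probabilities of 1, 2 and 3 boxes on a positive
#'   image.
#' @param jitter half-width (pixels) of the uniform corner perturbation
#'   applied to predicted boxes; jittered boxes that collapse to zero area
#'   are dropped with a message.
#' @param fp_rate expected number of spurious predicted boxes per image.
#' @param fn_rate per-box probability that a true box is missed.
#' @param canvas named vector `c(width=, height=)` in pixels.
#' @param seed integer seed.
#' @return a list with `annotations` and `predictions`, each a data.frame
#'   with columns `image_id`, `x_min`, `y_min`, `x_max`, `y_max` (pixels,
#'   origin top-left, half-open intervals) and, for predictions,
#'   `confidence`; plus `image_ids`, the full image universe (needed because
#'   negative images have no rows).
#' @export
generate_detection_fixtures <- function(n_images = 103,
                                        pos_fraction = 38 / 103,
                                        boxes_per_positive = c(0.68, 0.25, 0.07),
                                        jitter = 6,
                                        fp_rate = 0.155,
                                        fn_rate = 0.28,
                                        canvas = c(width = 480, height = 448),
                                        seed = 1) {
  stopifnot(n_images >= 1, pos_fraction >= 0, pos_fraction <= 1,
            jitter >= 0, fp_rate >= 0, fn_rate >= 0, fn_rate <= 1,
            all(canvas > 0))
  set.seed(seed)
  ids <- sprintf("img_%04d", seq_len(n_images))
  n_pos <- round(n_images * pos_fraction)
  pos <- sample(ids, n_pos)
  w <- canvas[["width"]]; h <- canvas[["height"]]

  rand_box <- function(k) {
    bw <- runif(k, 40, 140)
    bh <- runif(k, 16, 60)
    x0 <- runif(k, 0, w - bw)
    y0 <- runif(k, 0, h - bh)
    data.frame(x_min = x0, y_min = y0, x_max = x0 + bw, y_max = y0 + bh)
  }

  ann <- list()
  for (id in pos) {
    k <- sample(1:3, 1, prob = boxes_per_positive)
    b <- rand_box(k)
    b$image_id <- id
    ann[[id]] <- b
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(image_id = character(), x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric())
  rownames(annotations) <- NULL
  annotations <- annotations[c("image_id", "x_min", "y_min", "x_max", "y_max")]

  preds <- list()
  n_dropped <- 0L
  if (nrow(annotations)) {
    keep <- runif(nrow(annotations)) >= fn_rate
    tp <- annotations[keep, , drop = FALSE]
    if (nrow(tp)) {
      for (cc in c("x_min", "y_min", "x_max", "y_max")) {
        tp[[cc]] <- tp[[cc]] + runif(nrow(tp), -jitter, jitter)
      }
      tp$x_min <- pmax(tp$x_min, 0); tp$y_min <- pmax(tp$y_min, 0)
      tp$x_max <- pmin(tp$x_max, w); tp$y_max <- pmin(tp$y_max, h)
      ok <- tp$x_max > tp$x_min & tp$y_max > tp$y_min
      n_dropped <- sum(!ok)
      tp <- tp[ok, , drop = FALSE]
      tp$confidence <- runif(nrow(tp), 0.15, 1)
      preds[["tp"]] <- tp
    }
  }
  n_fp <- rpois(n_images, fp_rate)
  if (sum(n_fp) > 0) {
    fp <- rand_box(sum(n_fp))
    fp$image_id <- rep(ids, n_fp)
    fp$confidence <- runif(nrow(fp), 0.13, 0.6)
    preds[["fp"]] <- fp[c("image_id", "x_min", "y_min", "x_max", "y_max",
                          "confidence")]
  }
  predictions <- if (length(preds)) {
    do.call(rbind, lapply(preds, function(x)
      x[c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")]))
  } else {
    data.frame(image_id = character(), x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric(), confidence = numeric())
  }
  rownames(predictions) <- NULL
  if (n_dropped > 0) {
    message(n_dropped, " jittered box(es) collapsed to zero area and were dropped")
  }
  list(annotations = annotations, predictions = predictions, image_ids = ids)
}
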