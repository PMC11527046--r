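#' Recalibrate an external risk score to a cohort
#'
#' Fits a sex-stratified Cox model with the external linear predictor as the
#' single covariate, takes the Breslow baseline cumulative hazard per
#' stratum, and returns absolute risks at the horizon:
#' `risk(t0) = 1 - exp(-H0(t0) * exp(beta * lp))`. The calibration slope
#' `beta` is reported, so shrinkage or expansion of the external score is
#' visible. A zero-variance linear predictor (within every stratum) is
#' handled by fixing `beta = 0`, in which case the recalibrated risk is the
#' stratum Nelson-Aalen risk at the horizon.
#'
#' @param lp external linear predictors (e.g. PCE log hazards).
#' @param times,events follow-up (months) and event indicator.
#' @param sex stratification factor (e.g. "male"/"female").
#' @param t0 horizon in months (default 80; must not exceed max follow-up).
#' @return list with `risk` (per-individual recalibrated risk at `t0`),
#'   `slope`, `slope_se`, `baseline` (data.frame stratum, `H0_t0`), `t0`.
#' @export
recalibrate <- function(lp, times, events, sex, t0 = 80) {
  stopifnot(length(lp) == length(times), length(times) == length(events),
            length(sex) == length(times))
  if (t0 > max(times)) stop("t0 exceeds maximum follow-up")
  sex <- as.factor(sex)
  for (s in levels(sex)) {
    if (sum(events[sex == s]) == 0) {
      stop("stratum with no events: ", s)
    }
  }
  degenerate <- all(tapply(lp, sex, function(x) var(x) == 0 || is.na(var(x))))
  if (!degenerate) {
    d <- data.frame(lp = lp, times = times, events = events, sex = sex)
    fit <- survival::coxph(
      survival::Surv(times, events) ~ lp + survival::strata(sex),
      data = d, ties = "breslow")
    beta <- unname(coef(fit)[1])
    beta_se <- sqrt(fit$var[1, 1])
    bh <- survival::basehaz(fit, centered = FALSE)
    strat_col <- if ("strata" %in% names(bh)) bh$strata else
      factor(rep(levels(sex)[1], nrow(bh)))
    h0 <- vapply(levels(sex), function(s) {
      rows <- bh[strat_col == paste0("sex=", s) | strat_col == s, ,
                 drop = FALSE]
      i <- which(rows$time <= t0)
      if (!length(i)) 0 else rows$hazard[max(i)]
    }, numeric(1))
  } else {
    beta <- 0
    beta_se <- NA_real_
    h0 <- vapply(levels(sex), function(s) {
      i <- sex == s
      fit <- survival::survfit(survival::Surv(times[i], events[i]) ~ 1)
      j <- which(fit$time <= t0)
      if (!length(j)) 0 else fit$cumhaz[max(j)]
    }, numeric(1))
  }
  risk <- 1 - exp(-h0[as.character(sex)] * exp(beta * lp))
  list(risk = unname(risk), slope = beta, slope_se = beta_se,
       baseline = data.frame(stratum = levels(sex), H0_t0 = unname(h0)),
       t0 = t0)
}

# Kaplan-Meier risk (1 - S(t0)) and its Greenwood variance for one group
km_risk_var <- function(times, events, t0) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  i <- which(fit$time <= t0)
  if (!length(i)) return(c(risk = 0, var = 0, n_events = 0))
  i <- max(i)
  s <- fit$surv[i]
  gw <- (s * fit$std.err[i])^2  # std.err is on the cumulative-hazard scale
  c(risk = 1 - s, var = gw, n_events = sum(fit$n.event[fit$time <= t0]))
}

#' Greenwood-Nam-D'Agostino calibration test
#'
#' Splits the cohort into groups by predicted risk (deciles by default),
#' estimates observed risk per group as 1 - KM(t0) with Greenwood variance,
#' and sums `(observed - mean predicted)^2 / var` over groups. Groups with
#' fewer than 5 events by the horizon are merged with the neighboring group
#' above (the last group merges downward). Because the predictions are
#' externally specified (no parameter is estimated from the grouped data),
#' the statistic is compared with a chi-square on one degree of freedom per
#' group, which simulation under the true model confirms.
#'
#' @param pred_risk predicted risks at `t0`.
#' @param times,events follow-up and event indicator.
#' @param t0 horizon in months.
#' @param n_groups number of risk groups before merging (default 10).
#' @return list with `chi2`, `df`, `p`, and a per-group `table`
#'   (n, n_events, mean predicted, observed, variance).
#' @export
gnd_test <- function(pred_risk, times, events, t0, n_groups = 10) {
  stopifnot(length(pred_risk) == length(times))
  br <- unique(quantile(pred_risk, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(br) >= 3) {
    grp <- cut(pred_risk, breaks = br, include.lowest = TRUE, labels = FALSE)
  } else {
    # heavily tied predictions: fall back to equal-size groups in rank
    # order (ties broken arbitrarily), which keeps the statistic defined
    # for a constant predictor
    grp <- ceiling(rank(pred_risk, ties.method = "first") *
                     n_groups / length(pred_risk))
  }

  # merge sparse groups (fewer than 5 horizon events) into their neighbor
  repeat {
    gs <- sort(unique(grp))
    ev <- vapply(gs, function(g)
      sum(events[grp == g & times <= t0]), numeric(1))
    if (length(gs) < 2) stop("fewer than 2 usable risk groups")
    small <- which(ev < 5)
    if (!length(small)) break
    g <- gs[small[1]]
    target <- if (small[1] < length(gs)) gs[small[1] + 1] else gs[small[1] - 1]
    grp[grp == g] <- target
  }

  gs <- sort(unique(grp))
  tab <- do.call(rbind, lapply(gs, function(g) {
    i <- grp == g
    kv <- km_risk_var(times[i], events[i], t0)
    data.frame(group = g, n = sum(i), n_events = kv[["n_events"]],
               pred = mean(pred_risk[i]), obs = kv[["risk"]],
               var = kv[["var"]])
  }))
  if (any(tab$var <= 0)) stop("degenerate Greenwood variance in a group")
  chi2 <- sum((tab$obs - tab$pred)^2 / tab$var)
  df <- nrow(tab)
  list(chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE), table = tab)
}

#' Jackknife pseudo-observations of the event probability at a horizon
#'
#' For subject i the pseudo-observation is
#' `n * F(t0) - (n - 1) * F_(-i)(t0)` with `F = 1 - KM`; it behaves like an
#' unbiased per-subject event indicator at `t0` even under right censoring.
#' The leave-one-out curves are obtained analytically from the risk-set
#' counts rather than by refitting n times.
#'
#' @param times,events follow-up and event indicator.
#' @param t0 horizon.
#' @return numeric vector of pseudo event probabilities (one per subject).
#' @export
km_pseudo <- function(times, events, t0) {
  n <- length(times)
  stopifnot(n >= 2, length(events) == n)
  evt <- sort(unique(times[events == 1 & times <= t0]))
  k <- length(evt)
  s_full <- 1 - km_at(km_estimate(times, events), t0)
  if (k == 0) return(rep(n * s_full, n))  # zero; keeps the formula explicit
  n_at <- vapply(evt, function(tt) sum(times >= tt), numeric(1))
  d <- vapply(evt, function(tt) sum(times == tt & events == 1), numeric(1))
  logA <- log1p(-d / n_at)
  logB <- ifelse(n_at > 1, log1p(-d / (n_at - 1)), 0)
  logC <- ifelse(n_at > 1, log1p(-(d - 1) / (n_at - 1)), 0)
  cumA <- c(0, cumsum(logA))
  cumB <- c(0, cumsum(logB))
  # terms with event time below the subject's own time use the reduced risk
  # set (B); the subject's own tied event time swaps one event out (C); a
  # subject censored at an event time stays in that risk set (B); later
  # event times are unaffected (A)
  a_idx <- findInterval(times, evt, left.open = TRUE)  # evt_j < t_i
  tie <- match(times, evt)
  has_tie <- !is.na(tie) & times <= t0
  tie_term <- numeric(n)
  tie_term[has_tie & events == 1] <- logC[tie[has_tie & events == 1]]
  tie_term[has_tie & events == 0] <- logB[tie[has_tie & events == 0]]
  upto <- a_idx + as.integer(has_tie)
  log_s_loo <- cumB[a_idx + 1] + tie_term + (cumA[k + 1] - cumA[upto + 1])
  f_loo <- 1 - exp(log_s_loo)
  n * s_full - (n - 1) * f_loo
}

#' Integrated calibration index at a horizon
#'
#' Mean absolute difference between predicted risk and a smoothed observed
#' risk curve. Observed risk is estimated from [km_pseudo()] pseudo-observations
#' of the event probability at `t0` (so censored individuals contribute),
#' smoothed against predicted risk by local-linear (degree-1 loess)
#' regression. With a constant predictor the smoothed observed risk is the
#' mean pseudo-observation.
#'
#' @param pred_risk predicted risks at `t0`.
#' @param times,events follow-up and event indicator.
#' @param t0 horizon in months.
#' @param span loess span (default 0.75).
#' @return list with `ici`, `smoothed` (per-individual smoothed observed
#'   risk), `pseudo` (the pseudo-observations).
#' @export
ici <- function(pred_risk, times, events, t0, span = 0.75) {
  stopifnot(length(pred_risk) == length(times))
  if (span <= 0) stop("degenerate bandwidth")
  ps <- km_pseudo(times, events, t0)
  if (sd(pred_risk) == 0) {
    sm <- rep(mean(ps), length(ps))
  } else {
    lo <- loess(ps ~ pred_risk, degree = 1, span = span,
                control = loess.control(surface = "direct"))
    sm <- predict(lo, newdata = data.frame(pred_risk = pred_risk))
  }
  list(ici = mean(abs(pred_risk - sm)), smoothed = sm, pseudo = ps)
}
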