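# Censoring-aware primitives. Kaplan-Meier curves, log-rank tests, Cox fits
# and concordance are delegated to the survival package; the wrappers fix
# the contracts the rest of the pipeline relies on (months as the time unit,
# Efron ties, right-continuous step lookup).

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (> 0), in months.
#' @param events 0/1 event indicators.
#' @return a `km_curve`: data.frame with `time` (ascending), `n_risk`,
#'   `n_event`, `surv`, `std_err` (Greenwood standard error of the survival
#'   estimate).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(times > 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           se.fit = TRUE, conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    std_err = fit$std.err * fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Right-continuous lookup of a Kaplan-Meier curve
#'
#' @param curve a [km_estimate()] result.
#' @param t time(s) at which to evaluate survival; S(t) = 1 before the
#'   first observed time.
#' @return survival probability at `t`.
#' @export
km_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test over two or more groups
#'
#' Standard observed-minus-expected statistic over pooled event times.
#'
#' @param groups list of per-group lists/data.frames with `times` and
#'   `events`.
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(groups) {
  stopifnot(length(groups) >= 2)
  sizes <- vapply(groups, function(g) length(g$times), integer(1))
  if (any(sizes == 0)) stop("a group with zero subjects")
  d <- data.frame(
    times = unlist(lapply(groups, `[[`, "times")),
    events = unlist(lapply(groups, `[[`, "events")),
    group = rep(seq_along(groups), sizes))
  fit <- survival::survdiff(survival::Surv(times, events) ~ group, data = d)
  df <- length(groups) - 1
  list(chi2 = unname(fit$chisq), df = df,
       p = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' All pairwise log-rank comparisons
#'
#' @inheritParams logrank_test
#' @return data.frame with one row per group pair (`i`, `j`, `chi2`, `p`).
#' @export
pairwise_logrank <- function(groups) {
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    r <- logrank_test(groups[ij])
    c(i = ij[1], j = ij[2], chi2 = r$chi2, p = r$p)
  })
  as.data.frame(t(out))
}

#' Harrell's concordance index
#'
#' Concordant comparable pairs over comparable pairs under right censoring;
#' ties in the risk score count 1/2.
#'
#' @param risk_scores higher = riskier.
#' @param times,events follow-up and event indicator.
#' @return list with `c`, `se`, `ci` (95%).
#' @export
harrell_c <- function(risk_scores, times, events) {
  if (sum(events) == 0) return(list(c = NA_real_, se = NA_real_,
                                    ci = c(NA_real_, NA_real_)))
  fit <- survival::concordance(survival::Surv(times, events) ~ risk_scores,
                               reverse = TRUE)
  se <- sqrt(fit$var)
  list(c = unname(fit$concordance), se = se,
       ci = unname(fit$concordance) + c(-1, 1) * qnorm(0.975) * se)
}

#' Paired bootstrap comparison of two C-indices
#'
#' Resamples individuals with replacement, recomputing both models'
#' concordance on each resample; the difference is new minus old.
#'
#' @param risk_a baseline-model risk scores.
#' @param risk_b new-model risk scores (same individuals).
#' @param times,events follow-up and event indicator.
#' @param n_boot bootstrap resamples (a warning below 100).
#' @param seed integer seed.
#' @return list with `delta` (C_b - C_a), `ci` (percentile 95%), `p`
#'   (two-sided normal from the bootstrap SE), `c_a`, `c_b`.
#' @export
cindex_difference <- function(risk_a, risk_b, times, events,
                              n_boot = 1000, seed = 1) {
  if (n_boot > 0 && n_boot < 100) warning("n_boot < 100 gives unstable CIs")
  n <- length(times)
  cc <- function(r, t, e) {
    unname(survival::concordance(survival::Surv(t, e) ~ r,
                                 reverse = TRUE)$concordance)
  }
  delta <- cc(risk_b, times, events) - cc(risk_a, times, events)
  if (n_boot > 0) {
    set.seed(seed)
    boots <- replicate(n_boot, {
      i <- sample.int(n, n, replace = TRUE)
      cc(risk_b[i], times[i], events[i]) - cc(risk_a[i], times[i], events[i])
    })
    se <- sd(boots)
    ci <- unname(quantile(boots, c(0.025, 0.975)))
    p <- if (se > 0) 2 * pnorm(-abs(delta) / se) else 1
  } else {
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
    p <- NA_real_
  }
  list(delta = delta,
       ci = ci,
       p = p,
       c_a = cc(risk_a, times, events),
       c_b = cc(risk_b, times, events))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling, delegated to
#' `survival::coxph`.
#'
#' @param design data.frame or matrix of covariates.
#' @param times,events follow-up and event indicator.
#' @return list with `log_hr`, `se`, `loglik` (null, fitted), `fit` (the
#'   underlying coxph object).
#' @export
fit_cox <- function(design, times, events) {
  d <- as.data.frame(design)
  d$.time <- times
  d$.event <- events
  covars <- setdiff(names(d), c(".time", ".event"))
  f <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                               paste(sprintf("`%s`", covars), collapse = " + ")))
  fit <- survival::coxph(f, data = d, ties = "efron")
  if (any(is.na(coef(fit)))) {
    stop("Cox fit failed to converge (NA coefficients); iterations: ",
         fit$iter)
  }
  # coxph backtick-quotes non-syntactic covariate names; report them as given
  names(fit$coefficients) <- gsub("`", "", names(fit$coefficients))
  list(log_hr = coef(fit),
       se = setNames(sqrt(diag(fit$var)), names(coef(fit))),
       loglik = fit$loglik,
       fit = fit)
}

#' Likelihood-ratio comparison of nested Cox fits
#'
#' @param fit_null,fit_alt results of [fit_cox()] on nested designs.
#' @return list with `chi2`, `df`, `p`.
#' @export
cox_lrt <- function(fit_null, fit_alt) {
  chi2 <- 2 * (fit_alt$loglik[2] - fit_null$loglik[2])
  df <- length(fit_alt$log_hr) - length(fit_null$log_hr)
  stopifnot(df >= 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}
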