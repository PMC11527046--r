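#' Cross-classified reclassification table under censoring
#'
#' Cases are individuals with an event by the horizon. With
#' `censored = "exclude"` (the default), controls are those still event-free
#' at the horizon, and individuals censored earlier without an event carry
#' no case/control status and are excluded (their count is retained). With
#' `censored = "as_control"` every non-case is a control — the
#' binary-outcome convention of the classical reclassification-table tools,
#' which published tables whose case/control totals exhaust the cohort
#' follow. Risk categories are formed from the threshold(s) (default the
#' 7.5% treatment-decision threshold).
#'
#' @param risk_old,risk_new absolute risks in \[0, 1\] under the old and new
#'   model.
#' @param times,events follow-up (months) and event indicator.
#' @param t0 horizon in months.
#' @param thresholds category cutpoints (k thresholds give k+1 categories).
#' @param censored how to treat individuals censored event-free before the
#'   horizon: `"exclude"` or `"as_control"`.
#' @return a `reclass_table`: list with `cases` and `controls` (old x new
#'   count matrices), `thresholds`, `n_excluded`.
#' @export
build_reclass_table <- function(risk_old, risk_new, times, events, t0,
                                thresholds = 0.075,
                                censored = c("exclude", "as_control")) {
  censored <- match.arg(censored)
  stopifnot(all(risk_old >= 0 & risk_old <= 1),
            all(risk_new >= 0 & risk_new <= 1),
            length(risk_old) == length(risk_new))
  case <- events == 1 & times <= t0
  control <- if (censored == "as_control") !case else
    times >= t0 | (events == 1 & times > t0)
  excluded <- !case & !control
  if (!any(case)) stop("no cases by the horizon")
  if (!any(control)) stop("no controls at the horizon")
  br <- c(-Inf, sort(thresholds), Inf)
  labs <- category_labels(thresholds)
  cat_old <- cut(risk_old, breaks = br, labels = labs, right = FALSE)
  cat_new <- cut(risk_new, breaks = br, labels = labs, right = FALSE)
  out <- list(
    cases = table(old = cat_old[case], new = cat_new[case]),
    controls = table(old = cat_old[control], new = cat_new[control]),
    thresholds = sort(thresholds),
    n_excluded = sum(excluded))
  class(out) <- "reclass_table"
  out
}

category_labels <- function(thresholds) {
  thr <- sort(thresholds)
  pct <- paste0(format(100 * thr, trim = TRUE, drop0trailing = TRUE), "%")
  c(paste0("<", pct[1]),
    if (length(thr) > 1) paste0(pct[-length(pct)], "-", pct[-1]),
    paste0(">=", pct[length(pct)]))
}

#' Build a reclassification table directly from count matrices
#'
#' For working from published tables: supply the case and control old x new
#' count matrices.
#'
#' @param cases,controls square count matrices (old categories in rows).
#' @param thresholds the thresholds the categories correspond to.
#' @return a `reclass_table`.
#' @export
reclass_table_from_counts <- function(cases, controls, thresholds = 0.075) {
  stopifnot(nrow(cases) == ncol(cases), nrow(controls) == ncol(controls),
            all(cases >= 0), all(controls >= 0))
  out <- list(cases = as.table(cases), controls = as.table(controls),
              thresholds = sort(thresholds), n_excluded = 0L)
  class(out) <- "reclass_table"
  out
}

# net up-minus-down movement fraction for one count matrix
net_up_fraction <- function(mat) {
  idx <- row(mat) - col(mat)
  up <- sum(mat[idx < 0])
  down <- sum(mat[idx > 0])
  n <- sum(mat)
  if (n == 0) stop("zero denominator in reclassification table")
  (up - down) / n
}

#' Categorical net reclassification improvement
#'
#' `NRI = (up_cases - down_cases)/n_cases + (down_controls -
#' up_controls)/n_controls`, with a bootstrap percentile confidence interval
#' obtained by resampling individuals reconstructed from the table counts.
#'
#' @param table a `reclass_table`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with `nri`, `event_component`, `nonevent_component`, `ci`.
#' @export
categorical_nri <- function(table, n_boot = 1000, seed = 1) {
  stopifnot(inherits(table, "reclass_table"))
  ev <- net_up_fraction(table$cases)
  ne <- -net_up_fraction(table$controls)
  nri <- ev + ne
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    cell_stat <- function(mat) {
      n <- sum(mat)
      cells <- as.vector(mat)
      function() {
        resampled <- stats::rmultinom(1, n, cells / n)
        matrix(resampled, nrow(mat))
      }
    }
    draw_cases <- cell_stat(table$cases)
    draw_controls <- cell_stat(table$controls)
    boots <- replicate(n_boot,
      net_up_fraction(draw_cases()) - net_up_fraction(draw_controls()))
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  list(nri = nri, event_component = ev, nonevent_component = ne, ci = ci)
}

# KM-based event probability by t0 within a subgroup; empirical fraction
# when the subgroup is fully observed to t0
group_event_prob <- function(times, events, t0) {
  if (!length(times)) return(NA_real_)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  i <- which(fit$time <= t0)
  if (!length(i)) 0 else 1 - fit$surv[max(i)]
}

cfnri_point <- function(risk_old, risk_new, times, events, t0) {
  move <- sign(risk_new - risk_old)  # 1 up, -1 down, 0 unchanged
  p_g <- c(up = mean(move == 1), down = mean(move == -1),
           same = mean(move == 0))
  pe_g <- c(
    up = if (p_g[["up"]] > 0)
      group_event_prob(times[move == 1], events[move == 1], t0) else 0,
    down = if (p_g[["down"]] > 0)
      group_event_prob(times[move == -1], events[move == -1], t0) else 0,
    same = if (p_g[["same"]] > 0)
      group_event_prob(times[move == 0], events[move == 0], t0) else 0)
  p_event <- sum(p_g * pe_g)
  if (p_event <= 0 || p_event >= 1) return(NA_real_)
  p_up_e <- p_g[["up"]] * pe_g[["up"]] / p_event
  p_down_e <- p_g[["down"]] * pe_g[["down"]] / p_event
  p_up_ne <- p_g[["up"]] * (1 - pe_g[["up"]]) / (1 - p_event)
  p_down_ne <- p_g[["down"]] * (1 - pe_g[["down"]]) / (1 - p_event)
  (p_up_e - p_down_e) + (p_down_ne - p_up_ne)
}

#' Category-free net reclassification improvement under censoring
#'
#' Movement up/down is any increase/decrease in predicted risk. Event
#' probabilities by the horizon within each movement group are estimated by
#' 1 - KM(t0); the group probabilities are combined by Bayes' rule, giving
#' `cfNRI = [P(up|event) - P(down|event)] + [P(down|nonevent) -
#' P(up|nonevent)]` in \[-2, 2\]. Without censoring this reduces exactly to
#' the classical binary-outcome formula. The confidence interval uses the
#' bootstrap standard error with a normal approximation.
#'
#' @inheritParams build_reclass_table
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with `cfnri`, `se`, `ci`, `p`.
#' @export
cf_nri <- function(risk_old, risk_new, times, events, t0,
                   n_boot = 1000, seed = 1) {
  if (all(risk_new == risk_old)) stop("all risks tied; no movement")
  est <- cfnri_point(risk_old, risk_new, times, events, t0)
  se <- NA_real_; ci <- c(NA_real_, NA_real_); p <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(times)
    boots <- replicate(n_boot, {
      i <- sample.int(n, n, replace = TRUE)
      cfnri_point(risk_old[i], risk_new[i], times[i], events[i], t0)
    })
    se <- sd(boots, na.rm = TRUE)
    ci <- est + c(-1, 1) * qnorm(0.975) * se
    p <- 2 * pnorm(-abs(est) / se)
  }
  list(cfnri = est, se = se, ci = ci, p = p)
}

# per-individual probability of being a case by t0 given the observed data:
# 1 for observed events, 0 for those followed past t0, and the conditional
# KM estimate 1 - S(t0)/S(c_i) for those censored earlier
case_weights <- function(times, events, t0) {
  w <- numeric(length(times))
  w[events == 1 & times <= t0] <- 1
  cens <- events == 0 & times < t0
  if (any(cens)) {
    fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                             conf.type = "none")
    surv_at <- function(t) {
      i <- which(fit$time <= t)
      if (!length(i)) 1 else fit$surv[max(i)]
    }
    s0 <- surv_at(t0)
    w[cens] <- vapply(times[cens],
                      function(ci) 1 - s0 / surv_at(ci), numeric(1))
  }
  pmin(pmax(w, 0), 1)
}

idi_point <- function(risk_old, risk_new, times, events, t0) {
  w <- case_weights(times, events, t0)
  slope <- function(risk) {
    sum(w * risk) / sum(w) - sum((1 - w) * risk) / sum(1 - w)
  }
  slope(risk_new) - slope(risk_old)
}

#' Integrated discrimination improvement under censoring
#'
#' Difference in discrimination slopes (mean risk among cases minus mean
#' risk among controls) between the new and old model. Case status at the
#' horizon is known for individuals observed to the event or past `t0`;
#' individuals censored earlier contribute fractionally with their
#' conditional KM probability of an event by `t0`. Without censoring this
#' equals the classical uncensored IDI exactly.
#'
#' @inheritParams cf_nri
#' @return list with `idi`, `ci` (bootstrap percentile), `se`.
#' @export
idi <- function(risk_old, risk_new, times, events, t0,
                n_boot = 1000, seed = 1) {
  est <- idi_point(risk_old, risk_new, times, events, t0)
  se <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(times)
    boots <- replicate(n_boot, {
      i <- sample.int(n, n, replace = TRUE)
      idi_point(risk_old[i], risk_new[i], times[i], events[i], t0)
    })
    se <- sd(boots, na.rm = TRUE)
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  list(idi = est, se = se, ci = ci)
}
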