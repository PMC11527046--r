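#' Plaque prevalence table with Wilson confidence intervals
#'
#' @param cohort cohort table with `plaque_present`, `female`, `age`.
#' @param group_by any of "sex", "age_band"; empty gives the overall row.
#' @param age_breaks age band edges; defaults to bands <45, 45-54, 55-64,
#'   65-74, >=75.
#' @param conf_level confidence level for the Wilson interval.
#' @return data.frame with group columns, `n`, `n_plaque`, `prevalence`,
#'   `ci_lower`, `ci_upper`. Empty groups give `NA` with a warning.
#' @export
prevalence_table <- function(cohort, group_by = c("sex", "age_band"),
                             age_breaks = c(-Inf, 45, 55, 65, 75, Inf),
                             conf_level = 0.95) {
  d <- as.data.frame(cohort)
  keys <- list()
  if ("sex" %in% group_by) {
    keys$sex <- ifelse(d$female == 1, "female", "male")
  }
  if ("age_band" %in% group_by) {
    labs <- age_band_labels(age_breaks)
    keys$age_band <- cut(d$age, breaks = age_breaks, right = FALSE,
                         labels = labs)
  }
  if (!length(keys)) keys$group <- rep("all", nrow(d))
  grp <- interaction(keys, drop = FALSE, sep = "|")
  empty <- character()
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    i <- grp == g
    n <- sum(i)
    x <- sum(d$plaque_present[i])
    ci <- if (n > 0) wilson_ci(x, n, conf_level) else c(NA_real_, NA_real_)
    if (n == 0) empty <<- c(empty, g)
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    cbind(as.data.frame(setNames(as.list(parts), names(keys))),
          data.frame(n = n, n_plaque = x,
                     prevalence = if (n > 0) x / n else NA_real_,
                     ci_lower = ci[1], ci_upper = ci[2]))
  }))
  if (length(empty)) {
    warning("empty group(s): ", paste(empty, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

age_band_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  ifelse(is.infinite(lo), paste0("<", hi),
         ifelse(is.infinite(hi), paste0(">=", lo),
                paste0(lo, "-", hi - 1)))
}

#' Wilson score interval for a proportion
#'
#' @param x successes, @param n trials, @param conf_level level.
#' @return c(lower, upper).
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Pooled two-proportion z-test
#'
#' z with pooled variance and a two-sided normal p-value.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `z`, `p`, `p1`, `p2`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) stop("group with zero trials")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Cochran-Armitage trend test
#'
#' Trend in proportions over ordered categories with (by default equally
#' spaced) scores; signed z with a two-sided normal p. With two categories
#' the squared statistic equals the pooled two-proportion z squared.
#'
#' @param cases per-category case counts.
#' @param totals per-category totals.
#' @param scores category scores (default equally spaced).
#' @return list with `z`, `p`.
#' @export
cochran_armitage <- function(cases, totals, scores = seq_along(cases)) {
  stopifnot(length(cases) == length(totals), all(totals > 0),
            all(cases >= 0), all(cases <= totals))
  n <- sum(totals)
  pbar <- sum(cases) / n
  num <- sum(scores * (cases - totals * pbar))
  v <- pbar * (1 - pbar) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / n)
  z <- if (v <= 0) 0 else num / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Normal approximation with tie correction, delegated to
#' `stats::wilcox.test`; the U statistic is returned.
#'
#' @param x,y the two samples.
#' @return list with `statistic` (U for `x`), `p`.
#' @export
rank_sum_test <- function(x, y) {
  fit <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(statistic = unname(fit$statistic), p = fit$p.value)
}

#' Multivariable logistic model for plaque presence
#'
#' Maximum-likelihood logistic regression delegated to `stats::glm`.
#' Continuous covariates can be standardized so that their odds ratios are
#' per SD (the forest-plot convention).
#'
#' @param design data.frame of covariates.
#' @param outcome 0/1 outcome.
#' @param standardize standardize continuous (non 0/1) columns to unit SD.
#' @return list with `log_or`, `se`, `or`, `fit`.
#' @export
fit_logistic <- function(design, outcome, standardize = FALSE) {
  d <- as.data.frame(design)
  if (standardize) {
    for (cc in names(d)) {
      v <- d[[cc]]
      if (is.numeric(v) && length(unique(v)) > 2) d[[cc]] <- v / sd(v)
    }
  }
  d$.y <- outcome
  fit <- glm(.y ~ ., data = d, family = binomial())
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) {
    stop("logistic fit did not converge (possible separation)")
  }
  est <- coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  list(log_or = est, se = se, or = exp(est), fit = fit)
}
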