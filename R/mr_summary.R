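# Two-sample summary-statistics Mendelian randomization estimators.
# Instruments are assumed independent (clumped upstream); Wald-ratio
# standard errors use the first-order delta method se_out/|beta_exp|,
# ignoring exposure-side uncertainty in the weights (the conventional
# default).

#' Build an instrument set from per-variant summary statistics
#'
#' @param snp variant identifiers.
#' @param beta_exposure,se_exposure per-variant association with the
#'   exposure and its standard error.
#' @param beta_outcome,se_outcome per-variant association with the outcome
#'   and its standard error.
#' @return an `instrument_set` data.frame.
#' @export
instrument_set <- function(snp, beta_exposure, se_exposure,
                           beta_outcome, se_outcome) {
  stopifnot(length(snp) >= 1, all(se_exposure > 0), all(se_outcome > 0),
            all(beta_exposure != 0))
  d <- data.frame(snp = as.character(snp),
                  beta_exposure = beta_exposure,
                  se_exposure = se_exposure,
                  beta_outcome = beta_outcome,
                  se_outcome = se_outcome)
  class(d) <- c("instrument_set", "data.frame")
  d
}

#' Read instruments from a TSV file
#'
#' Expected columns: `snp`, `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#'
#' @param path file path.
#' @return an [instrument_set()].
#' @export
read_instruments <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  instrument_set(d$snp, d$beta_exp, d$se_exp, d$beta_out, d$se_out)
}

wald_ratios <- function(inst) {
  list(ratio = inst$beta_outcome / inst$beta_exposure,
       se = inst$se_outcome / abs(inst$beta_exposure))
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted mean of per-variant Wald ratios with weights 1/se^2. Under
#' random effects the standard error is inflated by
#' `max(1, sqrt(Q/(k-1)))` (multiplicative overdispersion, never shrunk
#' below the fixed-effect value).
#'
#' @param instruments an [instrument_set()].
#' @param random_effects logical (default TRUE).
#' @return list with `beta`, `se`, `ci`, `or`, `or_ci`, `k`.
#' @export
ivw <- function(instruments, random_effects = TRUE) {
  k <- nrow(instruments)
  if (k == 0) stop("no instruments")
  wr <- wald_ratios(instruments)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  if (random_effects && k > 1) {
    q <- sum(w * (wr$ratio - beta)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  ci <- beta + c(-1, 1) * qnorm(0.975) * se
  list(beta = beta, se = se, ci = ci, or = exp(beta), or_ci = exp(ci), k = k)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights 1/se_outcome^2), after orienting every variant so the
#' exposure beta is positive. A non-zero intercept indicates directional
#' pleiotropy. Standard errors use multiplicative random effects (residual
#' SD never shrunk below 1).
#'
#' @param instruments an [instrument_set()] with at least 3 variants.
#' @return list with `slope`, `slope_se`, `slope_ci`, `intercept`,
#'   `intercept_se`, `intercept_p`, `k`.
#' @export
mr_egger <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(instruments$beta_exposure)
  bx <- instruments$beta_exposure * flip
  by <- instruments$beta_outcome * flip
  w <- 1 / instruments$se_outcome^2
  fit <- summary(lm(by ~ bx, weights = w))
  disp <- max(1, fit$sigma)  # no underdispersion
  slope <- fit$coefficients["bx", "Estimate"]
  slope_se <- fit$coefficients["bx", "Std. Error"] / fit$sigma * disp
  intercept <- fit$coefficients["(Intercept)", "Estimate"]
  intercept_se <- fit$coefficients["(Intercept)", "Std. Error"] /
    fit$sigma * disp
  tval <- intercept / intercept_se
  list(slope = slope, slope_se = slope_se,
       slope_ci = slope + c(-1, 1) * qnorm(0.975) * slope_se,
       intercept = intercept, intercept_se = intercept_se,
       intercept_p = 2 * pt(-abs(tval), df = k - 2), k = k)
}

#' Weighted median MR estimate
#'
#' Interpolated median of the Wald ratios weighted by inverse variance;
#' consistent when at least half the weight comes from valid instruments.
#' The standard error comes from a parametric bootstrap of the per-variant
#' ratios.
#'
#' @param instruments an [instrument_set()] with at least 3 variants.
#' @param n_boot parametric bootstrap draws for the SE.
#' @param seed integer seed.
#' @return list with `beta`, `se`, `ci`.
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed = 1) {
  k <- nrow(instruments)
  if (k < 3) stop("weighted median needs at least 3 instruments")
  wr <- wald_ratios(instruments)
  w <- 1 / wr$se^2
  beta <- weighted_median_point(wr$ratio, w)
  set.seed(seed)
  boots <- replicate(n_boot, {
    r <- rnorm(k, wr$ratio, wr$se)
    weighted_median_point(r, w)
  })
  se <- sd(boots)
  list(beta = beta, se = se, ci = beta + c(-1, 1) * qnorm(0.975) * se)
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; ww <- w[ord]
  p <- (cumsum(ww) - ww / 2) / sum(ww)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5)$y
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_i (ratio_i - beta)^2` on k-1 degrees of freedom.
#'
#' @param instruments an [instrument_set()] with at least 2 variants.
#' @param beta the pooled estimate to measure dispersion around (defaults
#'   to the fixed-effect IVW estimate).
#' @return list with `Q`, `df`, `p`.
#' @export
cochran_q <- function(instruments, beta = NULL) {
  k <- nrow(instruments)
  if (k < 2) stop("heterogeneity is undefined for a single instrument")
  wr <- wald_ratios(instruments)
  w <- 1 / wr$se^2
  if (is.null(beta)) beta <- sum(w * wr$ratio) / sum(w)
  q <- sum(w * (wr$ratio - beta)^2)
  list(Q = q, df = k - 1, p = pchisq(q, k - 1, lower.tail = FALSE))
}

#' Rescale an MR estimate for a binary exposure
#'
#' Multiplies the log-odds estimate and its confidence bounds by
#' log(2) = 0.693, expressing the effect per two-fold increase in exposure
#' prevalence; the exponentiated values give the corresponding OR.
#'
#' @param beta log-odds estimate.
#' @param ci length-2 confidence bounds.
#' @return list with `beta`, `ci`, `or`, `or_ci`.
#' @export
binary_exposure_scale <- function(beta, ci) {
  stopifnot(length(ci) == 2)
  b <- beta * log(2)
  cc <- sort(ci * log(2))
  list(beta = b, ci = cc, or = exp(b), or_ci = exp(cc))
}
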