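#' Specification for folding a marker into an absolute risk score
#'
#' The multiplication-factor method updates a baseline absolute risk `Rbl`
#' for an individual at marker level k as `R(k) = Rbl * HR_k / [r]`, where
#' `[r] = sum_k p_k * HR_k` is the prevalence-weighted mean hazard ratio.
#' In the binary case `[r] = p * HR + (1 - p)`. The construction preserves
#' the population mean risk: `sum_k p_k * R(k) = Rbl`.
#'
#' @param levels ordered marker levels, reference first (e.g. `c("0", "1",
#'   "2+")`).
#' @param prevalence named list: one numeric vector of level prevalences per
#'   stratum (e.g. `list(male = ..., female = ...)`); each must sum to 1
#'   (tolerance 1e-9).
#' @param hazard_ratio hazard ratio per level; the reference level must be
#'   1 and all must be positive.
#' @return a `marker_spec`.
#' @export
marker_spec <- function(levels, prevalence, hazard_ratio) {
  stopifnot(length(levels) >= 2, length(hazard_ratio) == length(levels))
  if (abs(hazard_ratio[1] - 1) > 1e-12) {
    stop("reference-level hazard ratio must be 1")
  }
  if (any(hazard_ratio <= 0)) stop("hazard ratios must be > 0")
  stopifnot(is.list(prevalence), length(prevalence) >= 1)
  for (s in names(prevalence)) {
    p <- prevalence[[s]]
    if (length(p) != length(levels)) {
      stop("prevalence for stratum '", s, "' must have one entry per level")
    }
    if (any(p < 0)) stop("prevalences must be non-negative")
    if (abs(sum(p) - 1) > 1e-9) {
      stop("prevalences for stratum '", s, "' do not sum to 1")
    }
    names(prevalence[[s]]) <- levels
  }
  spec <- list(levels = as.character(levels),
               prevalence = prevalence,
               hazard_ratio = setNames(hazard_ratio, levels))
  class(spec) <- "marker_spec"
  spec
}

#' Prevalence-weighted mean hazard ratio
#'
#' `[r] = sum_k p_k HR_k` for one stratum; the normalizer of the
#' multiplication-factor update.
#'
#' @param spec a [marker_spec()].
#' @param stratum stratum name.
#' @return the weighted mean relative risk (1 when all HRs are 1).
#' @export
weighted_mean_risk <- function(spec, stratum) {
  stopifnot(inherits(spec, "marker_spec"))
  p <- spec$prevalence[[stratum]]
  if (is.null(p)) stop("unknown stratum: ", stratum)
  sum(p * spec$hazard_ratio)
}

#' Update a baseline absolute risk for an observed marker level
#'
#' `R(k) = Rbl * HR_k / [r]`; values exceeding 1 are capped with a warning.
#'
#' @param baseline_risk baseline absolute risk(s), strictly in (0, 1).
#' @param level observed marker level (recycled against `baseline_risk`).
#' @param spec a [marker_spec()].
#' @param stratum stratum name.
#' @return updated absolute risk(s).
#' @export
update_risk <- function(baseline_risk, level, spec, stratum) {
  stopifnot(inherits(spec, "marker_spec"))
  if (any(baseline_risk <= 0 | baseline_risk >= 1)) {
    stop("baseline_risk must lie strictly in (0, 1)")
  }
  level <- as.character(level)
  if (!all(level %in% spec$levels)) {
    stop("marker level absent from spec: ",
         paste(setdiff(unique(level), spec$levels), collapse = ", "))
  }
  r_bar <- weighted_mean_risk(spec, stratum)
  out <- baseline_risk * unname(spec$hazard_ratio[level]) / r_bar
  if (any(out > 1)) {
    warning(sum(out > 1), " updated risk(s) exceeded 1 and were capped")
    out <- pmin(out, 1)
  }
  out
}

#' Apply a marker update across a cohort
#'
#' Row-wise multiplication-factor update using each row's sex-stratum
#' prevalences and the marker level's hazard ratio.
#'
#' @param risks baseline absolute risks in (0, 1).
#' @param marker per-row marker levels (must all appear in the spec).
#' @param sex per-row stratum labels matching `names(spec$prevalence)`.
#' @param spec a [marker_spec()].
#' @return updated risk vector.
#' @export
apply_to_cohort <- function(risks, marker, sex, spec) {
  stopifnot(length(risks) == length(marker), length(marker) == length(sex))
  out <- numeric(length(risks))
  for (s in unique(sex)) {
    i <- sex == s
    out[i] <- update_risk(risks[i], marker[i], spec, s)
  }
  out
}

#' Estimate a marker specification from a cohort
#'
#' Level prevalences are computed per sex from the (by default
#' PCE-eligible) sub-cohort; level hazard ratios come from a Cox model on
#' that sub-cohort adjusted for the conventional risk-factor set (sex, age,
#' HDL and total cholesterol, antihypertensive use, current smoking, SBP,
#' statin use).
#'
#' @param cohort a cohort table (see [generate_cohort()]), already scored or
#'   not; needs the covariate columns plus `time_months`, `event`.
#' @param marker `"plaque_present"` (levels 0/1) or `"plaque_count"`
#'   (levels 0, 1, 2+).
#' @param eligible_only restrict estimation to rows where `pce_eligible`
#'   is `TRUE` (requires a scored cohort); default `TRUE`.
#' @return a [marker_spec()] with strata `male` and `female`, plus
#'   attributes `log_hr` and `se` from the adjusted fit.
#' @export
estimate_marker_spec <- function(cohort,
                                 marker = c("plaque_present", "plaque_count"),
                                 eligible_only = TRUE) {
  marker <- match.arg(marker)
  d <- cohort
  if (eligible_only) {
    if (is.null(d$pce_eligible)) stop("cohort must be scored (pce_eligible)")
    d <- d[d$pce_eligible, , drop = FALSE]
  }
  lev <- if (marker == "plaque_present") c("0", "1") else c("0", "1", "2+")
  mk <- marker_levels(d, marker)
  adj <- d[c("female", "age", "hdl", "total_chol", "antihtn",
             "smoker_current", "sbp", "statin")]
  design <- cbind(adj, marker_design(mk, lev))
  fit <- fit_cox(design, d$time_months, d$event)
  hr_terms <- paste0("level_", lev[-1])
  hr <- c(1, unname(exp(fit$log_hr[hr_terms])))
  prev <- lapply(c(male = 0, female = 1), function(f) {
    tab <- table(factor(mk[d$female == f], levels = lev))
    as.numeric(tab / sum(tab))
  })
  spec <- marker_spec(lev, prev, hr)
  attr(spec, "log_hr") <- fit$log_hr[hr_terms]
  attr(spec, "se") <- fit$se[hr_terms]
  spec
}

# collapse plaque_count to the ordinal levels used downstream
marker_levels <- function(cohort, marker) {
  if (marker == "plaque_present") {
    as.character(as.integer(cohort$plaque_present))
  } else {
    ifelse(cohort$plaque_count >= 2, "2+", as.character(cohort$plaque_count))
  }
}

marker_design <- function(levels_obs, lev) {
  out <- sapply(lev[-1], function(l) as.integer(levels_obs == l))
  colnames(out) <- paste0("level_", lev[-1])
  as.data.frame(out)
}
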