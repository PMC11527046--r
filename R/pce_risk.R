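# Pooled Cohort Equations: sex x race-group Cox-type absolute 10-year risk.
# The coefficient table ships as a human-readable CSV (inst/extdata) with a
# checksum verified at load, so the guideline-derived numbers stay auditable.

PCE_CSV_MD5 <- "eeeecc92b4c4f700b669cd9963beecad"

MGDL_PER_MMOL <- 38.67

#' Convert cholesterol between SI and conventional units
#'
#' @param x cholesterol values.
#' @return converted values (mg/dL = mmol/L x 38.67).
#' @export
mmol_to_mgdl <- function(x) x * MGDL_PER_MMOL

#' @rdname mmol_to_mgdl
#' @export
mgdl_to_mmol <- function(x) x / MGDL_PER_MMOL

#' Load the Pooled Cohort Equations risk model
#'
#' Reads the shipped coefficient table (terms on the natural-log scale,
#' lipids in mg/dL, SBP in mmHg), verifies its checksum, and returns the
#' four sex-by-race-group strata, each with its coefficient set, group mean
#' linear predictor, and 10-year baseline survival.
#'
#' @param path optional alternative coefficient CSV; the checksum is only
#'   enforced for the shipped file.
#' @return a `pce_model`: named list of strata (`female_white`,
#'   `female_black`, `male_white`, `male_black`), each with `coef`,
#'   `mean_lp`, `baseline_survival`.
#' @export
pce_load_model <- function(path = NULL) {
  shipped <- is.null(path)
  if (shipped) {
    path <- system.file("extdata", "pce_coefficients.csv",
                        package = "cardioreclass")
  }
  if (shipped && !identical(unname(tools::md5sum(path)), PCE_CSV_MD5)) {
    stop("checksum mismatch for shipped PCE coefficient table")
  }
  tab <- read.delim(path, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE)
  model <- lapply(split(tab, tab$stratum), function(d) {
    v <- setNames(d$value, d$term)
    list(coef = v[setdiff(names(v), c("mean_lp", "baseline_survival"))],
         mean_lp = unname(v[["mean_lp"]]),
         baseline_survival = unname(v[["baseline_survival"]]))
  })
  for (st in model) {
    stopifnot(st$baseline_survival > 0, st$baseline_survival < 1)
  }
  class(model) <- "pce_model"
  model
}

# map sex/race to the model stratum; unknown ethnicity falls into the
# white/other equations
pce_stratum <- function(female, race = "white") {
  grp <- ifelse(race == "black", "black", "white")
  paste0(ifelse(as.logical(female), "female_", "male_"), grp)
}

pce_term_matrix <- function(age, tc, hdl, sbp, treated, smoker, diabetes) {
  la <- log(age); lt <- log(tc); lh <- log(hdl); ls <- log(sbp)
  cbind(ln_age = la,
        ln_age_sq = la^2,
        ln_tc = lt,
        ln_age_ln_tc = la * lt,
        ln_hdl = lh,
        ln_age_ln_hdl = la * lh,
        ln_sbp_treated = ls * treated,
        ln_age_ln_sbp_treated = la * ls * treated,
        ln_sbp_untreated = ls * (1 - treated),
        ln_age_ln_sbp_untreated = la * ls * (1 - treated),
        smoker = smoker,
        ln_age_smoker = la * smoker,
        diabetes = diabetes)
}

#' Pooled Cohort Equations linear predictor
#'
#' Computes the stratum-specific sum of coefficient x transformed covariate.
#' Input columns: `age` (years), `total_chol`, `hdl` (mmol/L for
#' `units = "si"`, mg/dL for `"conventional"`), `sbp` (mmHg), `antihtn`,
#' `smoker_current`, `diabetes`, `female` (0/1), and optionally `race`.
#' Covariates outside the equations' supported ranges raise a warning but
#' are still scored.
#'
#' @param data data.frame of participants.
#' @param model a [pce_load_model()] object.
#' @param units `"si"` (mmol/L lipids, converted internally) or
#'   `"conventional"` (mg/dL).
#' @return numeric vector of linear predictors.
#' @export
pce_linear_predictor <- function(data, model = pce_load_model(),
                                 units = c("si", "conventional")) {
  units <- match.arg(units)
  tc <- data$total_chol
  hdl <- data$hdl
  if (units == "si") {
    tc <- mmol_to_mgdl(tc)
    hdl <- mmol_to_mgdl(hdl)
  }
  race <- data$race %||% rep("white", nrow(data))
  stratum <- pce_stratum(data$female, race)
  unknown <- setdiff(unique(stratum), names(model))
  if (length(unknown)) stop("unknown stratum: ", paste(unknown, collapse = ", "))
  n_out <- sum(data$age < 40 | data$age > 79 | tc < 130 | tc > 320 |
                 hdl < 20 | hdl > 100 | data$sbp < 90 | data$sbp > 200)
  if (n_out > 0) {
    warning(n_out, " row(s) have covariates outside the supported PCE ",
            "ranges; scored anyway")
  }
  tm <- pce_term_matrix(data$age, tc, hdl, data$sbp, data$antihtn,
                        data$smoker_current, data$diabetes)
  lp <- numeric(nrow(data))
  for (st in unique(stratum)) {
    i <- stratum == st
    cf <- model[[st]]$coef
    lp[i] <- drop(tm[i, names(cf), drop = FALSE] %*% cf)
  }
  lp
}

#' Absolute risk from a PCE linear predictor
#'
#' `1 - baseline_survival ^ exp(lp - mean_lp)` for the participant's
#' stratum; strictly increasing in `lp` and bounded in (0, 1).
#'
#' @param lp linear predictor(s).
#' @param model a [pce_load_model()] object.
#' @param stratum stratum name(s), recycled against `lp`.
#' @return absolute event risk(s) at the model horizon.
#' @export
pce_risk <- function(lp, model = pce_load_model(), stratum) {
  stratum <- rep_len(stratum, length(lp))
  s0 <- vapply(stratum, function(s) model[[s]]$baseline_survival,
               numeric(1), USE.NAMES = FALSE)
  mlp <- vapply(stratum, function(s) model[[s]]$mean_lp,
                numeric(1), USE.NAMES = FALSE)
  1 - s0^exp(lp - mlp)
}

#' PCE eligibility filter
#'
#' Closed-interval criteria, bounds inclusive: age 40-79 years, total
#' cholesterol 130-320 mg/dL, HDL 20-100 mg/dL, SBP 90-200 mmHg.
#'
#' @inheritParams pce_linear_predictor
#' @return logical vector.
#' @export
pce_eligible <- function(data, units = c("si", "conventional")) {
  units <- match.arg(units)
  tc <- data$total_chol
  hdl <- data$hdl
  if (units == "si") {
    tc <- mmol_to_mgdl(tc)
    hdl <- mmol_to_mgdl(hdl)
  }
  data$age >= 40 & data$age <= 79 &
    tc >= 130 & tc <= 320 &
    hdl >= 20 & hdl <= 100 &
    data$sbp >= 90 & data$sbp <= 200
}

#' Score a cohort with the Pooled Cohort Equations
#'
#' @inheritParams pce_linear_predictor
#' @return the input data with added columns `pce_stratum`, `pce_lp`,
#'   `pce_lp_centered` (lp minus the stratum mean linear predictor — the
#'   log relative hazard that enters the risk formula, comparable across
#'   strata), `pce_risk`, `pce_eligible`.
#' @export
pce_score <- function(data, model = pce_load_model(),
                      units = c("si", "conventional")) {
  units <- match.arg(units)
  race <- data$race %||% rep("white", nrow(data))
  data$pce_stratum <- pce_stratum(data$female, race)
  data$pce_lp <- suppressWarnings(pce_linear_predictor(data, model, units))
  mlp <- vapply(data$pce_stratum, function(s) model[[s]]$mean_lp,
                numeric(1), USE.NAMES = FALSE)
  data$pce_lp_centered <- data$pce_lp - mlp
  data$pce_risk <- pce_risk(data$pce_lp, model, data$pce_stratum)
  data$pce_eligible <- pce_eligible(data, units)
  data
}
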