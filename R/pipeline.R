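#' Default pipeline configuration
#'
#' @param seed global seed fanned out to per-stage child seeds via
#'   [child_seed()].
#' @param n_participants synthetic cohort size.
#' @param horizon_months risk/reclassification horizon.
#' @param threshold risk-category threshold for the reclassification table.
#' @param n_boot bootstrap resamples for NRI/IDI/C-index comparisons.
#' @param output_dir directory for the report bundle (created if needed).
#' @param mr_instruments optional path to an instrument TSV; when supplied
#'   the MR estimators run too.
#' @return a named list usable as [run_pipeline()] config.
#' @export
default_pipeline_config <- function(seed = 1, n_participants = 19499,
                                    horizon_months = 80, threshold = 0.075,
                                    n_boot = 1000, output_dir = "results",
                                    mr_instruments = NULL) {
  list(seed = seed, n_participants = n_participants,
       horizon_months = horizon_months, threshold = threshold,
       n_boot = n_boot, output_dir = output_dir,
       mr_instruments = mr_instruments)
}

#' Run the full reclassification analysis end to end
#'
#' Synthesize a cohort, score it with the Pooled Cohort Equations, filter
#' to the eligible sub-cohort, recalibrate the score, estimate marker
#' hazard ratios and prevalences, fold plaque presence and count into the
#' recalibrated risk, and compute calibration (GND, ICI), reclassification
#' (categorical NRI, cfNRI, IDI) and discrimination (C-index difference)
#' metrics. Artifacts (cohort TSV, risk columns, metrics JSON,
#' reclassification TSVs, calibration TSV, run log) are written to the
#' configured output directory.
#'
#' @param config a config list (see [default_pipeline_config()]) or the
#'   path to a YAML file with the same fields.
#' @return invisibly, a list with the cohort, risks, specs and metrics.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_pipeline_config(), config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- cfg$horizon_months
  log <- list(r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("cardioreclass")),
              seed = cfg$seed, config = cfg, stages = list())

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log$stages[[name]] <<- list(seed = child_seed(cfg$seed, name))
    res
  }

  # 1. synthesize
  cohort <- run_stage("cohort", {
    hz <- if (is.null(cfg$hazard_log_hr)) NULL else
      list(log_hr = unlist(cfg$hazard_log_hr))
    params <- cohort_params(n_participants = cfg$n_participants,
                            hazard_model = hz,
                            seed = child_seed(cfg$seed, "cohort"))
    generate_cohort(params)
  })

  # 2. PCE scoring + eligibility
  model <- pce_load_model()
  scored <- run_stage("pce", pce_score(cohort, model))
  elig <- scored[scored$pce_eligible, , drop = FALSE]

  # 3. recalibration to the cohort; the evaluation horizon cannot exceed
  # the longest observed follow-up in the eligible sub-cohort
  t0 <- min(t0, max(elig$time_months))
  recal <- run_stage("recalibrate", {
    recalibrate(elig$pce_lp_centered, elig$time_months, elig$event,
                ifelse(elig$female == 1, "female", "male"), t0 = t0)
  })
  elig$risk_recal <- recal$risk

  # 4. marker specs (prevalence per sex, adjusted HRs) and risk update
  sexlab <- ifelse(elig$female == 1, "female", "male")
  spec_presence <- run_stage("marker",
    estimate_marker_spec(elig, "plaque_present"))
  spec_count <- estimate_marker_spec(elig, "plaque_count")
  rb <- pmin(pmax(elig$risk_recal, 1e-12), 1 - 1e-12)
  elig$risk_presence <- suppressWarnings(apply_to_cohort(
    rb, marker_levels(elig, "plaque_present"), sexlab, spec_presence))
  elig$risk_count <- suppressWarnings(apply_to_cohort(
    rb, marker_levels(elig, "plaque_count"), sexlab, spec_count))

  # 5. calibration of the recalibrated score
  calib <- run_stage("calibration", {
    g <- gnd_test(elig$risk_recal, elig$time_months, elig$event, t0)
    ic <- ici(elig$risk_recal, elig$time_months, elig$event, t0)
    list(gnd = g[c("chi2", "df", "p")], ici = ic$ici, table = g$table)
  })

  # 6. reclassification and discrimination
  bseed <- child_seed(cfg$seed, "boot")
  metrics <- run_stage("reclass", {
    out <- list()
    for (mk in c("presence", "count")) {
      new_risk <- elig[[paste0("risk_", mk)]]
      # published reclassification tables exhaust the cohort: event-free
      # participants count as controls whatever their follow-up
      tab <- build_reclass_table(elig$risk_recal, new_risk, elig$time_months,
                                 elig$event, t0, cfg$threshold,
                                 censored = "as_control")
      out[[mk]] <- list(
        table = tab,
        nri = categorical_nri(tab, n_boot = cfg$n_boot, seed = bseed),
        cfnri = cf_nri(elig$risk_recal, new_risk, elig$time_months,
                       elig$event, t0, n_boot = cfg$n_boot, seed = bseed),
        idi = idi(elig$risk_recal, new_risk, elig$time_months, elig$event,
                  t0, n_boot = cfg$n_boot, seed = bseed),
        cindex = cindex_difference(elig$risk_recal, new_risk,
                                   elig$time_months, elig$event,
                                   n_boot = min(cfg$n_boot, 200),
                                   seed = bseed))
    }
    out
  })

  # 7. optional MR on supplied summary statistics
  mr <- NULL
  if (!is.null(cfg$mr_instruments)) {
    mr <- run_stage("mr", {
      inst <- read_instruments(cfg$mr_instruments)
      list(ivw = ivw(inst),
           egger = mr_egger(inst),
           wmedian = weighted_median(inst, seed = child_seed(cfg$seed, "mr")),
           q = cochran_q(inst))
    })
  }

  # write the report bundle
  odir <- cfg$output_dir
  write_cohort_tsv(scored, file.path(odir, "cohort.tsv"))
  risk_cols <- elig[c("id", "pce_risk", "risk_recal", "risk_presence",
                      "risk_count")]
  write.table(risk_cols, file.path(odir, "risks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (mk in c("presence", "count")) {
    tab <- metrics[[mk]]$table
    flat <- rbind(cbind(status = "control", as.data.frame(tab$controls)),
                  cbind(status = "case", as.data.frame(tab$cases)))
    write.table(flat, file.path(odir, sprintf("reclassification_%s.tsv", mk)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(calib$table, file.path(odir, "calibration.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summarize <- function(mk) {
    m <- metrics[[mk]]
    list(nri = m$nri$nri, nri_ci = m$nri$ci,
         cfnri = m$cfnri$cfnri, cfnri_ci = m$cfnri$ci, cfnri_p = m$cfnri$p,
         idi = m$idi$idi, idi_ci = m$idi$ci,
         c_old = m$cindex$c_a, c_new = m$cindex$c_b,
         c_delta = m$cindex$delta, c_p = m$cindex$p,
         n_excluded = m$table$n_excluded)
  }
  report <- list(
    n_total = nrow(scored), n_eligible = nrow(elig),
    plaque_prevalence = mean(scored$plaque_present),
    event_fraction = mean(scored$event),
    recalibration_slope = recal$slope,
    calibration = list(gnd = calib$gnd, ici = calib$ici),
    presence = summarize("presence"), count = summarize("count"),
    mr = mr)
  jsonlite::write_json(report, file.path(odir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log$checksums <- as.list(tools::md5sum(list.files(odir, full.names = TRUE,
                                                    pattern = "\\.tsv$")))
  jsonlite::write_json(log, file.path(odir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(cohort = scored, eligible = elig, recalibration = recal,
                 specs = list(presence = spec_presence, count = spec_count),
                 calibration = calib, metrics = metrics, mr = mr,
                 report = report))
}
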