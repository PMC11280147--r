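#' Default run configuration
#'
#' All knobs of the pipeline in one list: input table, circuit defaults,
#' optimizer settings, synthetic-waveform settings and the output directory.
#' A configuration file (YAML, with JSON fallback) overrides any subset of
#' these keys.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    table = "bundled",           # patient CSV path or "bundled"
    waveform_dir = NULL,         # per-patient flow CSVs; synthetic if NULL
    out_dir = "glennpvr-output",
    circuit = list(r_svc = 0, r_lpa_vessel = 0, r_rpa_vessel = 0,
                   distal_pressure_column = "p_la"),
    optimizer = list(tolerance = 1e-4, max_evals = 2000, penalty = 1e6,
                     init = NULL),  # NULL: cohort initial guess
    synthetic = list(cycle_length = 0.8, dt = 0.001, pulsatility = 0.3,
                     noise = 0, seed = 1L)
  )
}

#' Load a run configuration file
#'
#' Reads YAML (or JSON as a fallback) and merges it over [default_config()].
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) jsonlite::read_json(path,
                                                             simplifyVector = TRUE))
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.numeric(cfg$optimizer$tolerance) || cfg$optimizer$tolerance <= 0) {
    stop("optimizer tolerance must be > 0", call. = FALSE)
  }
  if (!is.null(cfg$waveform_dir) && !dir.exists(cfg$waveform_dir)) {
    stop("waveform_dir does not exist: ", cfg$waveform_dir, call. = FALSE)
  }
  cfg
}

ensure_out_dir <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  cfg$out_dir
}

#' Compute per-patient direct PVR and the cohort summary
#'
#' Orchestrates [computed_pvr()] over a patient table: writes
#' `computed_pvr.csv` (pid, per-lung PVR, total, CATH PVR) and
#' `cohort_summary.csv` under the configured output directory. Patients with
#' zero branch flow are flagged in the output and skipped rather than
#' aborting the cohort.
#'
#' @param config Configuration list (see [load_run_config()]).
#' @return Invisibly, `list(pvr = <per-patient tibble>, summary = <tibble>)`.
#' @export
#' @examples
#' \donttest{
#' cfg <- default_config()
#' cfg$out_dir <- tempfile()
#' res <- cmd_compute_pvr(cfg)
#' res$pvr
#' }
cmd_compute_pvr <- function(config = default_config()) {
  records <- load_patient_table(config$table)
  usable <- records$q_lpa > 0 & records$q_rpa > 0
  pvr <- computed_pvr(records[usable, , drop = FALSE])
  if (any(!usable)) {
    warning("patient(s) with zero branch flow skipped: ",
            paste(records$pid[!usable], collapse = ", "), call. = FALSE)
    flagged <- tibble::tibble(pid = records$pid[!usable],
                              pvr_lpa = NA_real_, pvr_rpa = NA_real_,
                              pvr_total = NA_real_,
                              pvr_cath = records$pvr_cath[!usable])
    pvr <- dplyr::bind_rows(pvr, flagged)
    pvr <- pvr[match(records$pid, pvr$pid), , drop = FALSE]
  }
  summ <- summarize_cohort(dplyr::select(pvr[stats::complete.cases(pvr), ],
                                         -"pid"))
  out <- ensure_out_dir(config)
  utils::write.csv(pvr, file.path(out, "computed_pvr.csv"), row.names = FALSE)
  utils::write.csv(summ, file.path(out, "cohort_summary.csv"),
                   row.names = FALSE)
  invisible(list(pvr = pvr, summary = summ))
}

# Self-consistent synthetic targets for one bundled-table patient: both
# branch waveforms share the sinusoid shape, the inlet is their pointwise sum
# (mass-consistent), and the pressure target is the recorded mean SVC
# pressure. With this construction the cost has an exact zero at the
# directly computed per-lung PVR values.
synthetic_targets_for_record <- function(record, synth_cfg) {
  q_l <- synth_inlet_waveform(record$q_lpa, synth_cfg$pulsatility,
                              synth_cfg$cycle_length, synth_cfg$dt)
  q_r <- synth_inlet_waveform(record$q_rpa, synth_cfg$pulsatility,
                              synth_cfg$cycle_length, synth_cfg$dt)
  inlet <- flow_waveform(q_l$flow + q_r$flow, synth_cfg$cycle_length)
  list(inlet = inlet,
       target = clinical_target(q_l, q_r, record$p_svc))
}

load_waveform_targets <- function(record, dir) {
  read1 <- function(stem) {
    p <- file.path(dir, sprintf("%s_%s.csv", record$pid, stem))
    if (!file.exists(p)) stop("waveform file not found: ", p, call. = FALSE)
    read_waveform_csv(p)
  }
  inlet <- read1("svc")
  q_l <- resample_linear(read1("lpa"), attr(inlet, "dt"))
  q_r <- resample_linear(read1("rpa"), attr(inlet, "dt"))
  list(inlet = inlet, target = clinical_target(q_l, q_r, record$p_svc))
}

#' Calibrate outlet resistances for every patient of a table
#'
#' For each patient, builds a circuit from the configured proximal
#' resistances and the patient's distal pressure, assembles the clinical
#' target (from per-patient waveform CSVs under `waveform_dir` named
#' `<pid>_svc.csv`, `<pid>_lpa.csv`, `<pid>_rpa.csv`, or from self-consistent
#' synthetic stand-ins whose cycle averages match the table), and runs
#' [optimize_pvr()] from the cohort initial guess. Per-patient failures are
#' logged as warnings and do not abort the cohort run. Results are written as
#' `optimized_pvr.csv` and `optimization_results.json`.
#'
#' @inheritParams cmd_compute_pvr
#' @return Invisibly, a tibble with one row per patient: outlet resistances,
#'   per-lung PVR, computed PVR for comparison, cost, evaluations, converged.
#' @export
cmd_optimize <- function(config = default_config()) {
  records <- load_patient_table(config$table)
  cc <- config$circuit
  p_col <- cc$distal_pressure_column
  init <- config$optimizer$init
  if (is.null(init)) {
    init <- initial_guess(records,
                          r_proximal = cc$r_svc +
                            mean(c(cc$r_lpa_vessel, cc$r_rpa_vessel)))
  }

  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    tryCatch({
      tg <- if (is.null(config$waveform_dir)) {
        synthetic_targets_for_record(rec, config$synthetic)
      } else {
        load_waveform_targets(rec, config$waveform_dir)
      }
      template <- glenn_circuit(
        r_svc = cc$r_svc,
        r_lpa_vessel = cc$r_lpa_vessel, r_rpa_vessel = cc$r_rpa_vessel,
        r_lpa_outlet = init[[1]], r_rpa_outlet = init[[2]],
        p_dist_l = rec[[p_col]], p_dist_r = rec[[p_col]])
      fit <- optimize_pvr(template, tg$inlet, tg$target, init = init,
                          tol = config$optimizer$tolerance,
                          max_evals = config$optimizer$max_evals,
                          penalty = config$optimizer$penalty)
      if (!fit$converged) {
        warning("patient ", rec$pid, ": evaluation budget exhausted before ",
                "convergence", call. = FALSE)
      }
      cmp <- computed_pvr(rec)
      tibble::tibble(pid = rec$pid,
                     r_lpa_outlet = fit$r_lpa_outlet,
                     r_rpa_outlet = fit$r_rpa_outlet,
                     pvr_lpa = fit$pvr$pvr[1], pvr_rpa = fit$pvr$pvr[2],
                     pvr_total = total_pvr(fit$pvr$pvr[1], fit$pvr$pvr[2]),
                     computed_lpa = cmp$pvr_lpa, computed_rpa = cmp$pvr_rpa,
                     pvr_cath = rec$pvr_cath,
                     cost = fit$cost, evals = fit$evals,
                     converged = fit$converged)
    }, error = function(e) {
      warning("patient ", rec$pid, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) stop("optimization failed for every patient",
                            call. = FALSE)
  out <- ensure_out_dir(config)
  utils::write.csv(res, file.path(out, "optimized_pvr.csv"), row.names = FALSE)
  jsonlite::write_json(res, file.path(out, "optimization_results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Method-agreement report across computed, optimized and CATH PVR
#'
#' Joins the direct computed-PVR baseline with the optimization results and
#' emits agreement rows (mean differences, percent differences, ICC with CI,
#' Bland-Altman limits, gated paired-test p-values) plus a per-patient
#' flow-ratio table relating `Q_L/Q_R` to `PVR_R/PVR_L` (their product is 1
#' under a shared distal pressure, by Ohm's law).
#'
#' @inheritParams cmd_compute_pvr
#' @param optimized Optional tibble from [cmd_optimize()]; computed if absent.
#' @return Invisibly, `list(agreement = <tibble>, ratios = <tibble>)`.
#' @export
cmd_report <- function(config = default_config(), optimized = NULL) {
  records <- load_patient_table(config$table)
  if (is.null(optimized)) optimized <- cmd_optimize(config)
  if (!setequal(records$pid, optimized$pid)) {
    stop("join error: patient sets of the table and the optimization ",
         "results differ", call. = FALSE)
  }
  d <- dplyr::inner_join(computed_pvr(records),
                         dplyr::select(optimized, -"pvr_cath"),
                         by = "pid", suffix = c("_comp", "_opt"))
  d <- dplyr::inner_join(d, dplyr::select(records, "pid", "q_lpa", "q_rpa"),
                         by = "pid")

  agreement <- dplyr::bind_rows(
    agreement_report(d, pvr_lpa_comp, pvr_lpa_opt,
                     label = "LPA PVR: computed vs optimized"),
    agreement_report(d, pvr_rpa_comp, pvr_rpa_opt,
                     label = "RPA PVR: computed vs optimized"),
    agreement_report(d, pvr_cath, pvr_total_opt,
                     label = "total PVR: CATH vs optimized"),
    agreement_report(records, q_svc, qp_cath,
                     label = "Qp: CMR vs CATH")
  )
  ratios <- tibble::tibble(
    pid = d$pid,
    flow_ratio_lr = d$q_lpa / d$q_rpa,
    pvr_ratio_rl = d$pvr_rpa_opt / d$pvr_lpa_opt,
    product = (d$q_lpa / d$q_rpa) * (d$pvr_lpa_opt / d$pvr_rpa_opt)
  )
  out <- ensure_out_dir(config)
  utils::write.csv(agreement, file.path(out, "agreement_report.csv"),
                   row.names = FALSE)
  utils::write.csv(ratios, file.path(out, "flow_ratio_table.csv"),
                   row.names = FALSE)
  invisible(list(agreement = agreement, ratios = ratios))
}
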