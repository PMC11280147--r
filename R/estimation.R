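#' Clinical calibration target
#'
#' The data an outlet-resistance calibration is matched against: the measured
#' branch flow waveforms (from CMR phase contrast, or synthetic stand-ins)
#' and the mean SVC pressure from catheterization.
#'
#' @param q_lpa_obs,q_rpa_obs Observed branch flow [flow_waveform()]s, on a
#'   common grid.
#' @param p_svc_mean Mean SVC pressure, mmHg (> 0).
#' @return A `clinical_target` object holding the waveforms and their cycle
#'   averages (which act as cost-function denominators and must be > 0).
#' @export
clinical_target <- function(q_lpa_obs, q_rpa_obs, p_svc_mean) {
  if (nrow(q_lpa_obs) != nrow(q_rpa_obs) ||
      abs(cycle_length(q_lpa_obs) - cycle_length(q_rpa_obs)) > 1e-12) {
    stop("branch waveforms must share one grid (same n and cycle length)",
         call. = FALSE)
  }
  qbar_l <- time_average(q_lpa_obs)
  qbar_r <- time_average(q_rpa_obs)
  if (qbar_l <= 0 || qbar_r <= 0) {
    stop("mean observed branch flows must be > 0 (cost denominators)",
         call. = FALSE)
  }
  if (!is.finite(p_svc_mean) || p_svc_mean <= 0) {
    stop("mean SVC pressure must be > 0 (cost denominator)", call. = FALSE)
  }
  structure(list(q_lpa_obs = q_lpa_obs, q_rpa_obs = q_rpa_obs,
                 p_svc_mean = p_svc_mean,
                 qbar_l = qbar_l, qbar_r = qbar_r),
            class = "clinical_target")
}

#' Calibration cost between clinical and simulated hemodynamics
#'
#' Mean squared branch-flow error over the cardiac cycle, each branch
#' normalized by its mean observed flow, plus the squared mean-SVC-pressure
#' error normalized by the observed mean pressure:
#' \deqn{f = \frac{1}{n}\sum_t \left[
#'   \frac{(Q^c_{LPA}(t)-Q^s_{LPA}(t))^2}{\bar Q^c_{LPA}} +
#'   \frac{(Q^c_{RPA}(t)-Q^s_{RPA}(t))^2}{\bar Q^c_{RPA}} \right] +
#'   \frac{(\bar P^c_{SVC}-\bar P^s_{SVC})^2}{\bar P^c_{SVC}}}
#' The pressure term is constant in t, so adding it once equals carrying it
#' under the (1/n) sum. The cost is zero exactly when simulated and clinical
#' data coincide.
#'
#' @param clinical A [clinical_target()].
#' @param sim A `glenn_sim` from [simulate_circuit()], on the same n-point
#'   grid as the clinical waveforms (resample first if needed).
#' @return Non-negative scalar.
#' @export
waveform_cost <- function(clinical, sim) {
  n <- nrow(sim)
  if (nrow(clinical$q_lpa_obs) != n ||
      abs(cycle_length(clinical$q_lpa_obs) - attr(sim, "cycle_length")) > 1e-9) {
    stop("grid mismatch: clinical and simulated waveforms must share the ",
         "same n-point cycle grid", call. = FALSE)
  }
  flow_term <- mean((clinical$q_lpa_obs$flow - sim$q_l)^2) / clinical$qbar_l +
    mean((clinical$q_rpa_obs$flow - sim$q_r)^2) / clinical$qbar_r
  p_term <- (clinical$p_svc_mean - mean(sim$p_svc))^2 / clinical$p_svc_mean
  flow_term + p_term
}

#' Cohort-wide initial guess for the outlet resistances
#'
#' Every patient's calibration starts from the same point: the cohort mean of
#' the directly computed per-lung PVR ([computed_pvr()]), less any proximal
#' series resistance already present in the circuit template, floored at
#' 0.1 WU.m^2.
#'
#' @param records Patient table.
#' @param r_proximal Proximal series resistance (r_svc plus branch vessel
#'   resistor) to subtract, WU.m^2. Default 0.
#' @return Named numeric vector `c(r_lpa = ..., r_rpa = ...)`.
#' @export
#' @examples
#' initial_guess(load_patient_table("bundled"))
initial_guess <- function(records, r_proximal = 0) {
  usable <- records$q_lpa > 0 & records$q_rpa > 0
  if (any(!usable)) {
    warning("excluding ", sum(!usable),
            " record(s) with zero branch flow from the initial guess",
            call. = FALSE)
    records <- records[usable, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("no usable records for the initial guess", call. = FALSE)
  }
  pvr <- computed_pvr(records)
  c(r_lpa = max(mean(pvr$pvr_lpa) - r_proximal, 0.1),
    r_rpa = max(mean(pvr$pvr_rpa) - r_proximal, 0.1))
}

# Nelder-Mead simplex minimizer (Lagarias et al. coefficients: reflection 1,
# expansion 2, contraction 0.5, shrink 0.5). Initial simplex perturbs each
# coordinate by 5% (0.00025 if zero). Converged when the maximum absolute
# vertex spread AND the function-value spread both fall below `tol`.
nelder_mead <- function(fn, x0, tol = 1e-4, max_evals = 2000) {
  d <- length(x0)
  simplex <- matrix(rep(x0, d + 1), nrow = d + 1, byrow = TRUE)
  for (i in seq_len(d)) {
    simplex[i + 1, i] <- if (x0[i] != 0) x0[i] * 1.05 else 0.00025
  }
  evals <- 0L
  eval_fn <- function(x) {
    evals <<- evals + 1L
    fn(x)
  }
  fv <- apply(simplex, 1, eval_fn)

  converged <- FALSE
  while (evals < max_evals) {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]
    fv <- fv[ord]
    spread_x <- max(abs(sweep(simplex[-1, , drop = FALSE], 2, simplex[1, ])))
    spread_f <- max(abs(fv[-1] - fv[1]))
    if (spread_x <= tol && spread_f <= tol) {
      converged <- TRUE
      break
    }
    centroid <- colMeans(simplex[-(d + 1), , drop = FALSE])
    worst <- simplex[d + 1, ]
    xr <- centroid + (centroid - worst)
    fr <- eval_fn(xr)
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - worst)
      fe <- eval_fn(xe)
      if (fe < fr) {
        simplex[d + 1, ] <- xe; fv[d + 1] <- fe
      } else {
        simplex[d + 1, ] <- xr; fv[d + 1] <- fr
      }
    } else if (fr < fv[d]) {
      simplex[d + 1, ] <- xr; fv[d + 1] <- fr
    } else {
      if (fr < fv[d + 1]) { # outside contraction
        xc <- centroid + 0.5 * (xr - centroid)
        fc <- eval_fn(xc)
        accept <- fc <= fr
      } else {              # inside contraction
        xc <- centroid - 0.5 * (centroid - worst)
        fc <- eval_fn(xc)
        accept <- fc < fv[d + 1]
      }
      if (accept) {
        simplex[d + 1, ] <- xc; fv[d + 1] <- fc
      } else {              # shrink toward the best vertex
        for (i in 2:(d + 1)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          fv[i] <- eval_fn(simplex[i, ])
        }
      }
    }
  }
  ord <- order(fv)
  list(par = simplex[ord[1], ], value = fv[ord[1]],
       evals = evals, converged = converged)
}

#' Calibrate the two outlet resistances against clinical data
#'
#' Nelder-Mead minimization of [waveform_cost()] over
#' `(r_lpa_outlet, r_rpa_outlet)`, every other circuit parameter held fixed.
#' Candidate points with a non-positive resistance receive a large finite
#' penalty instead of being simulated, keeping the optimizer the plain
#' unconstrained simplex method.
#'
#' @param circuit_template A [glenn_circuit()] providing the fixed proximal
#'   resistances and distal pressures (its outlet values are overwritten).
#' @param inlet Inlet flow [flow_waveform()]; its grid defines the comparison
#'   grid, and the clinical waveforms are linearly resampled onto it.
#' @param clinical A [clinical_target()].
#' @param init Length-2 starting point (see [initial_guess()]).
#' @param backend `"closed_form"` (default), `"nodal"` (the independent
#'   linear-solve path, slow), or a function `(r_lpa_outlet, r_rpa_outlet) ->
#'   glenn_sim` implementing the simulator contract — e.g. a wrapper around an
#'   external 3D CFD solver.
#' @param tol Absolute Nelder-Mead tolerance applied to both the simplex
#'   parameter spread and the function-value spread. Default 1e-4.
#' @param max_evals Evaluation budget; if exhausted the best point is
#'   returned with `converged = FALSE`. Default 2000.
#' @param penalty Cost assigned to non-positive candidate resistances.
#'   Default 1e6.
#' @return A `pvr_fit` object; see [tidy.pvr_fit()] and [glance.pvr_fit()].
#' @export
#' @examples
#' truth <- glenn_circuit(r_lpa_outlet = 9, r_rpa_outlet = 5, p_dist_l = 5)
#' inlet <- synth_inlet_waveform(1.8, dt = 0.01)
#' obs <- simulate_circuit(truth, inlet)
#' target <- clinical_target(flow_waveform(obs$q_l, 0.8),
#'                           flow_waveform(obs$q_r, 0.8),
#'                           p_svc_mean = mean(obs$p_svc))
#' fit <- optimize_pvr(truth, inlet, target, init = c(6, 6))
#' glance(fit)
optimize_pvr <- function(circuit_template, inlet, clinical, init,
                         backend = "closed_form", tol = 1e-4,
                         max_evals = 2000, penalty = 1e6) {
  stopifnot(length(init) == 2L, all(is.finite(init)))
  clinical <- align_target(clinical, inlet)

  simulate_pair <- make_backend(backend, circuit_template, inlet)
  objective <- function(x) {
    if (any(x <= 0)) return(penalty)
    waveform_cost(clinical, simulate_pair(x[1], x[2]))
  }

  opt <- nelder_mead(objective, as.numeric(init), tol = tol,
                     max_evals = max_evals)
  best_sim <- simulate_pair(opt$par[1], opt$par[2])
  best_circuit <- set_outlets(circuit_template, opt$par[1], opt$par[2])
  pvr <- report_pvr(best_sim, best_circuit)

  structure(
    list(r_lpa_outlet = opt$par[1], r_rpa_outlet = opt$par[2],
         pvr = pvr, cost = opt$value, evals = opt$evals,
         converged = opt$converged, sim = best_sim,
         circuit = best_circuit, clinical = clinical),
    class = "pvr_fit")
}

align_target <- function(clinical, inlet) {
  n <- nrow(inlet)
  if (nrow(clinical$q_lpa_obs) == n &&
      abs(cycle_length(clinical$q_lpa_obs) - cycle_length(inlet)) < 1e-12) {
    return(clinical)
  }
  dt <- attr(inlet, "dt")
  clinical_target(resample_linear(clinical$q_lpa_obs, dt),
                  resample_linear(clinical$q_rpa_obs, dt),
                  clinical$p_svc_mean)
}

set_outlets <- function(circuit, r_l, r_r) {
  glenn_circuit(r_svc = circuit$r_svc,
                r_lpa_vessel = circuit$r_lpa_vessel,
                r_rpa_vessel = circuit$r_rpa_vessel,
                r_lpa_outlet = r_l, r_rpa_outlet = r_r,
                p_dist_l = circuit$p_dist_l, p_dist_r = circuit$p_dist_r)
}

make_backend <- function(backend, circuit_template, inlet) {
  if (is.function(backend)) return(backend)
  backend <- match.arg(backend, c("closed_form", "nodal"))
  if (backend == "closed_form") {
    function(r_l, r_r) {
      simulate_circuit(set_outlets(circuit_template, r_l, r_r), inlet)
    }
  } else {
    function(r_l, r_r) {
      circ <- set_outlets(circuit_template, r_l, r_r)
      sol <- purrr::map_dfr(inlet$flow, function(q) nodal_oracle(circ, q))
      out <- tibble::tibble(time = inlet$time, q_in = inlet$flow,
                            q_l = sol$q_l, q_r = sol$q_r,
                            p_junction = sol$p_junction, p_svc = sol$p_svc)
      structure(out, means = vapply(out[-1L], mean, numeric(1)),
                cycle_length = cycle_length(inlet), dt = attr(inlet, "dt"),
                class = c("glenn_sim", class(out)))
    }
  }
}

#' Per-lung PVR and its decomposition from a simulation
#'
#' The reported per-lung PVR is the cycle-averaged SVC-to-distal gradient over
#' the cycle-averaged branch flow, `(mean(P_SVC) - p_dist) / mean(Q_branch)` —
#' the same definition as the directly computed PVR, so the report does not
#' depend on how resistance is split along the pathway. The decomposition
#' attributes the gradient to the series SVC/junction resistor, the branch
#' vessel resistor and the outlet resistor via their Ohmic drops at mean flow;
#' in this purely resistive (linear) circuit the three drops sum to the
#' gradient up to floating-point residual, which is reported.
#'
#' @param sim A `glenn_sim`.
#' @param circuit The [glenn_circuit()] that produced it.
#' @return A tibble with one row per lung: `lung`, `pvr`, `drop_svc`,
#'   `drop_vessel`, `drop_outlet`, `residual` (mmHg).
#' @export
report_pvr <- function(sim, circuit) {
  m <- sim_means(sim)
  if (m[["q_l"]] <= 0 || m[["q_r"]] <= 0) {
    stop("zero or negative mean branch flow: per-lung PVR undefined",
         call. = FALSE)
  }
  dp_l <- m[["p_svc"]] - circuit$p_dist_l
  dp_r <- m[["p_svc"]] - circuit$p_dist_r
  drop_svc <- circuit$r_svc * m[["q_in"]]
  tibble::tibble(
    lung = c("lpa", "rpa"),
    pvr = c(dp_l / m[["q_l"]], dp_r / m[["q_r"]]),
    drop_svc = drop_svc,
    drop_vessel = c(circuit$r_lpa_vessel * m[["q_l"]],
                    circuit$r_rpa_vessel * m[["q_r"]]),
    drop_outlet = c(circuit$r_lpa_outlet * m[["q_l"]],
                    circuit$r_rpa_outlet * m[["q_r"]]),
    residual = c(dp_l, dp_r) - drop_svc -
      c(circuit$r_lpa_vessel * m[["q_l"]] + circuit$r_lpa_outlet * m[["q_l"]],
        circuit$r_rpa_vessel * m[["q_r"]] + circuit$r_rpa_outlet * m[["q_r"]])
  )
}

#' @export
print.pvr_fit <- function(x, ...) {
  cat("<pvr_fit>\n")
  cat(sprintf("  outlet resistances: r_lpa = %.4f, r_rpa = %.4f WU·m²\n",
              x$r_lpa_outlet, x$r_rpa_outlet))
  cat(sprintf("  per-lung PVR: lpa = %.4f, rpa = %.4f WU·m²\n",
              x$pvr$pvr[1], x$pvr$pvr[2]))
  cat(sprintf("  cost = %.3g after %d evaluations (%s)\n",
              x$cost, x$evals,
              if (x$converged) "converged" else "budget exhausted"))
  invisible(x)
}

#' Tidy / summarize a fitted outlet-resistance calibration
#'
#' `tidy()` returns one row per lung (outlet resistance, reported PVR, and
#' the pressure-drop decomposition); `glance()` returns a one-row fit summary.
#'
#' @param x A `pvr_fit` from [optimize_pvr()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pvr_fit <- function(x, ...) {
  dplyr::mutate(x$pvr,
                r_outlet = c(x$r_lpa_outlet, x$r_rpa_outlet),
                .after = "lung")
}

#' @rdname tidy.pvr_fit
#' @export
glance.pvr_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, evals = x$evals, converged = x$converged,
                 pvr_lpa = x$pvr$pvr[1], pvr_rpa = x$pvr$pvr[2],
                 pvr_total = total_pvr(x$pvr$pvr[1], x$pvr$pvr[2]))
}

#' @export
autoplot.pvr_fit <- function(object, ...) {
  obs <- tibble::tibble(
    time = object$clinical$q_lpa_obs$time,
    lpa = object$clinical$q_lpa_obs$flow,
    rpa = object$clinical$q_rpa_obs$flow,
    source = "clinical")
  fit <- tibble::tibble(time = object$sim$time, lpa = object$sim$q_l,
                        rpa = object$sim$q_r, source = "simulated")
  long <- tidyr::pivot_longer(dplyr::bind_rows(obs, fit), c("lpa", "rpa"),
                              names_to = "branch", values_to = "flow")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$flow,
                                     colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~branch) +
    ggplot2::labs(x = "time (s)", y = "flow (L/min/m²)", colour = NULL)
}
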