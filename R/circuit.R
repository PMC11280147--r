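#' The 0D resistive Glenn circuit
#'
#' Lumped-parameter analogue of the superior cavopulmonary connection: the SVC
#' inlet flow passes a series resistor `r_svc` (which also absorbs the
#' pulmonary-artery junction resistance) to the junction node, then splits
#' into left and right branches. Each branch is a proximal vessel resistor in
#' series with an outlet resistor terminated by a constant distal pressure
#' (the left-atrial pressure in normal use). Pressure, flow and resistance
#' play the roles of voltage, current and resistance, so every element obeys
#' delta-P = R * Q; the model has no compliance, so it is memoryless and each
#' timestep solves independently.
#'
#' @param r_svc Series inlet (SVC + junction) resistance, WU.m^2.
#' @param r_lpa_vessel,r_rpa_vessel Proximal branch vessel resistances, WU.m^2.
#' @param r_lpa_outlet,r_rpa_outlet Outlet (distal pulmonary bed) resistances,
#'   WU.m^2 — the two parameters calibrated by [optimize_pvr()].
#' @param p_dist_l,p_dist_r Constant distal pressures behind each outlet, mmHg.
#' @return An object of class `glenn_circuit`.
#' @details All resistances must be non-negative and at least one branch
#'   total `r_*_vessel + r_*_outlet` must be positive. A circuit with exactly
#'   one zero-total branch is degenerate (that branch pins the junction to its
#'   distal pressure) and is flagged when solved.
#' @export
#' @examples
#' circ <- glenn_circuit(r_lpa_outlet = 6, r_rpa_outlet = 6,
#'                       p_dist_l = 4, p_dist_r = 4)
#' solve_timestep(circ, q_in = 2)
glenn_circuit <- function(r_svc = 0, r_lpa_vessel = 0, r_rpa_vessel = 0,
                          r_lpa_outlet, r_rpa_outlet,
                          p_dist_l, p_dist_r = p_dist_l) {
  r <- c(r_svc = r_svc, r_lpa_vessel = r_lpa_vessel,
         r_rpa_vessel = r_rpa_vessel,
         r_lpa_outlet = r_lpa_outlet, r_rpa_outlet = r_rpa_outlet)
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("all resistances must be finite and >= 0", call. = FALSE)
  }
  if (!all(is.finite(c(p_dist_l, p_dist_r)))) {
    stop("distal pressures must be finite", call. = FALSE)
  }
  if ((r_lpa_vessel + r_lpa_outlet) <= 0 && (r_rpa_vessel + r_rpa_outlet) <= 0) {
    stop("singular circuit: both branch total resistances are zero",
         call. = FALSE)
  }
  structure(
    list(r_svc = r_svc,
         r_lpa_vessel = r_lpa_vessel, r_rpa_vessel = r_rpa_vessel,
         r_lpa_outlet = r_lpa_outlet, r_rpa_outlet = r_rpa_outlet,
         p_dist_l = p_dist_l, p_dist_r = p_dist_r),
    class = "glenn_circuit")
}

#' @export
print.glenn_circuit <- function(x, ...) {
  cat("<glenn_circuit> (resistances WU·m², pressures mmHg)\n")
  cat(sprintf("  inlet:  r_svc = %.4g\n", x$r_svc))
  cat(sprintf("  left:   r_vessel = %.4g, r_outlet = %.4g, p_dist = %.4g\n",
              x$r_lpa_vessel, x$r_lpa_outlet, x$p_dist_l))
  cat(sprintf("  right:  r_vessel = %.4g, r_outlet = %.4g, p_dist = %.4g\n",
              x$r_rpa_vessel, x$r_rpa_outlet, x$p_dist_r))
  invisible(x)
}

branch_totals <- function(circuit) {
  c(l = circuit$r_lpa_vessel + circuit$r_lpa_outlet,
    r = circuit$r_rpa_vessel + circuit$r_rpa_outlet)
}

#' Solve the circuit at one (or many) timesteps in closed form
#'
#' Because the network is purely resistive, Kirchhoff's current law at the
#' junction gives the junction pressure directly:
#' `p_j = (q_in + p_dist_l/R_L + p_dist_r/R_R) / (1/R_L + 1/R_R)` with branch
#' totals `R_L`, `R_R`; branch flows and the SVC pressure follow by Ohm's law.
#' Vectorized over `q_in`, so a whole cycle solves in one call.
#'
#' @param circuit A [glenn_circuit()].
#' @param q_in Inlet (SVC) flow, L/min/m^2; scalar or vector.
#' @return A tibble with columns `q_l`, `q_r`, `p_junction`, `p_svc`, one row
#'   per element of `q_in`. If exactly one branch total resistance is zero the
#'   result carries attribute `degenerate = TRUE` and the junction is pinned
#'   to that branch's distal pressure.
#' @export
solve_timestep <- function(circuit, q_in) {
  rt <- branch_totals(circuit)
  degenerate <- any(rt == 0)
  if (all(rt == 0)) {
    stop("singular circuit: both branch total resistances are zero",
         call. = FALSE)
  }
  if (rt[["l"]] == 0) {
    p_j <- rep(circuit$p_dist_l, length(q_in))
    q_r <- (p_j - circuit$p_dist_r) / rt[["r"]]
    q_l <- q_in - q_r
  } else if (rt[["r"]] == 0) {
    p_j <- rep(circuit$p_dist_r, length(q_in))
    q_l <- (p_j - circuit$p_dist_l) / rt[["l"]]
    q_r <- q_in - q_l
  } else {
    g_l <- 1 / rt[["l"]]
    g_r <- 1 / rt[["r"]]
    p_j <- (q_in + circuit$p_dist_l * g_l + circuit$p_dist_r * g_r) / (g_l + g_r)
    q_l <- (p_j - circuit$p_dist_l) * g_l
    q_r <- (p_j - circuit$p_dist_r) * g_r
  }
  out <- tibble::tibble(q_l = q_l, q_r = q_r, p_junction = p_j,
                        p_svc = p_j + q_in * circuit$r_svc)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Simulate one cardiac cycle of the Glenn circuit
#'
#' Applies [solve_timestep()] across an inlet flow waveform. The circuit has
#' no storage elements, so the periodic steady state is reached within the
#' single simulated cycle and the output at each instant depends only on the
#' inlet flow at that instant.
#'
#' @param circuit A [glenn_circuit()].
#' @param inlet Inlet flow [flow_waveform()].
#' @return A `glenn_sim` object: tibble with columns `time`, `q_in`, `q_l`,
#'   `q_r`, `p_junction`, `p_svc` plus a `means` attribute holding the cycle
#'   averages of each signal.
#' @export
#' @examples
#' circ <- glenn_circuit(r_lpa_outlet = 9, r_rpa_outlet = 5, p_dist_l = 5)
#' sim <- simulate_circuit(circ, synth_inlet_waveform(1.78))
#' sim_means(sim)
simulate_circuit <- function(circuit, inlet) {
  sol <- solve_timestep(circuit, inlet$flow)
  out <- tibble::tibble(time = inlet$time, q_in = inlet$flow,
                        q_l = sol$q_l, q_r = sol$q_r,
                        p_junction = sol$p_junction, p_svc = sol$p_svc)
  means <- vapply(out[-1L], mean, numeric(1))
  structure(out,
            means = means,
            cycle_length = cycle_length(inlet), dt = attr(inlet, "dt"),
            degenerate = isTRUE(attr(sol, "degenerate")),
            class = c("glenn_sim", class(out)))
}

#' @rdname simulate_circuit
#' @param sim A `glenn_sim`.
#' @export
sim_means <- function(sim) attr(sim, "means")

#' @export
autoplot.glenn_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("q_in", "q_l", "q_r"),
                              names_to = "signal", values_to = "flow")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$flow,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "flow (L/min/m²)", colour = NULL)
}

#' Nodal-analysis reference solver
#'
#' Independent verification path for [solve_timestep()]: assembles the full
#' linear system of the circuit — unknown node pressures and branch flows,
#' with Ohm's law per resistor and Kirchhoff's current law at the junction —
#' and solves it with a generic dense linear solve. No closed-form expression
#' is used.
#'
#' @param circuit A [glenn_circuit()].
#' @param q_in Scalar inlet flow.
#' @return A one-row tibble with `q_l`, `q_r`, `p_junction`, `p_svc`.
#' @export
nodal_oracle <- function(circuit, q_in) {
  stopifnot(length(q_in) == 1L, is.finite(q_in))
  # unknowns x = (p_svc, p_j, p_mid_l, p_mid_r, q_l, q_r)
  # rows: Ohm across r_svc; Ohm across each vessel and outlet resistor;
  #       KCL at the junction.
  A <- matrix(0, 6, 6)
  b <- numeric(6)
  A[1, ] <- c(1, -1, 0, 0, 0, 0);                b[1] <- circuit$r_svc * q_in
  A[2, ] <- c(0, 1, -1, 0, -circuit$r_lpa_vessel, 0)
  A[3, ] <- c(0, 0, 1, 0, -circuit$r_lpa_outlet, 0); b[3] <- circuit$p_dist_l
  A[4, ] <- c(0, 1, 0, -1, 0, -circuit$r_rpa_vessel)
  A[5, ] <- c(0, 0, 0, 1, 0, -circuit$r_rpa_outlet); b[5] <- circuit$p_dist_r
  A[6, ] <- c(0, 0, 0, 0, 1, 1);                 b[6] <- q_in
  x <- tryCatch(solve(A, b),
                error = function(e) stop("singular circuit: ",
                                         conditionMessage(e), call. = FALSE))
  tibble::tibble(q_l = x[5], q_r = x[6], p_junction = x[2], p_svc = x[1])
}

#' Poiseuille resistance of a cylindrical vessel
#'
#' Fully developed laminar flow resistance `8 * mu * L / (pi * r^4)` in
#' dyn.s/cm^5, converted to Wood units (mmHg.min/L) via
#' `R_WU = R_cgs * (1000/60) / 1333.22`. With a body surface area the
#' BSA-indexed value (WU.m^2) is returned instead, consistent with indexed
#' resistance times indexed flow giving mmHg.
#'
#' @param mu Dynamic viscosity, poise. Default 0.04 poise (blood).
#' @param length Vessel length, cm.
#' @param radius Vessel radius, cm.
#' @param bsa Optional body surface area, m^2; if given, the result is the
#'   indexed resistance `R_WU * bsa` in WU.m^2.
#' @return Resistance in WU (or WU.m^2 when `bsa` is supplied).
#' @export
#' @examples
#' poiseuille_resistance(mu = 0.04, length = 1, radius = 0.5)
poiseuille_resistance <- function(mu = 0.04, length, radius, bsa = NULL) {
  vals <- c(mu, length, radius)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("mu, length and radius must all be > 0", call. = FALSE)
  }
  r_cgs <- 8 * mu * length / (pi * radius^4)
  r_wu <- r_cgs * (1000 / 60) / 1333.22
  if (is.null(bsa)) return(r_wu)
  check_bsa(bsa)
  r_wu * bsa
}
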