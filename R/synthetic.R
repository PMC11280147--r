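#' Describe a synthetic Glenn patient
#'
#' A synthetic patient pairs a ground-truth circuit with an inlet-waveform
#' prescription and an observation-noise level, standing in for a patient's
#' CMR flow measurements in parameter-recovery studies. Defaults mirror the
#' bundled reference cohort: mean inlet flow 1.97 L/min/m^2 (cohort mean SVC
#' flow), distal pressure 4.4 mmHg (cohort mean left-atrial pressure), outlet
#' resistances near the cohort-mean computed per-lung PVR, cycle length
#' 0.8 s, timestep 0.001 s, pulsatility 0.3 (venous flow in the superior
#' cavopulmonary pathway is modestly pulsatile).
#'
#' @param r_lpa_outlet,r_rpa_outlet Ground-truth outlet resistances, WU.m^2.
#' @param r_svc,r_lpa_vessel,r_rpa_vessel Proximal resistances, WU.m^2.
#' @param p_dist Distal pressure (both lungs), mmHg.
#' @param q_mean Cycle-averaged inlet flow, L/min/m^2.
#' @param pulsatility,cycle_length,dt,phase Inlet waveform shape; see
#'   [synth_inlet_waveform()].
#' @param noise Observation noise on the branch flows, as a fraction of each
#'   branch's mean flow (Gaussian, zero-mean, added pointwise). `0` gives
#'   noise-free observations that satisfy the circuit equations exactly.
#' @param seed Integer seed for the observation noise; the generator is
#'   deterministic given the seed and leaves the caller's RNG state intact.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(r_lpa_outlet = 6.2, r_rpa_outlet = 5.3,
                               r_svc = 0, r_lpa_vessel = 0, r_rpa_vessel = 0,
                               p_dist = 4.4, q_mean = 1.97,
                               pulsatility = 0.3, cycle_length = 0.8,
                               dt = 0.001, phase = 0,
                               noise = 0, seed = 1L) {
  if (!is.finite(q_mean) || q_mean <= 0) stop("q_mean must be > 0", call. = FALSE)
  if (!is.finite(noise) || noise < 0) stop("noise must be >= 0", call. = FALSE)
  if (pulsatility < 0 || pulsatility >= 1) {
    stop("pulsatility must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(circuit = glenn_circuit(r_svc = r_svc,
                                 r_lpa_vessel = r_lpa_vessel,
                                 r_rpa_vessel = r_rpa_vessel,
                                 r_lpa_outlet = r_lpa_outlet,
                                 r_rpa_outlet = r_rpa_outlet,
                                 p_dist_l = p_dist, p_dist_r = p_dist),
         q_mean = q_mean, pulsatility = pulsatility,
         cycle_length = cycle_length, dt = dt, phase = phase,
         noise = noise, seed = as.integer(seed)),
    class = "synthetic_scenario")
}

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic patient: record, inlet, observed branch flows
#'
#' Simulates the scenario's ground-truth circuit on its raised-sinusoid inlet
#' waveform, then adds seeded zero-mean Gaussian noise (sd = `noise` times
#' the branch mean flow) to the branch flow waveforms to produce the
#' "observed" data. The returned patient record carries the noise-free
#' simulation's cycle averages, so with `noise = 0` the observations satisfy
#' the circuit equations exactly and the ground-truth parameters have zero
#' calibration cost.
#'
#' @param scenario A [synthetic_scenario()].
#' @param pid Patient identifier for the generated record.
#' @return A list with elements `record` (one-row patient tibble), `inlet`,
#'   `q_lpa_obs`, `q_rpa_obs` (flow waveforms), `target` (a ready
#'   [clinical_target()]), and `truth` (the ground-truth circuit).
#' @export
#' @examples
#' sp <- make_synthetic_patient(synthetic_scenario(seed = 7))
#' sp$record
make_synthetic_patient <- function(scenario, pid = "synthetic") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  inlet <- synth_inlet_waveform(scenario$q_mean, scenario$pulsatility,
                                scenario$cycle_length, scenario$dt,
                                scenario$phase)
  sim <- simulate_circuit(scenario$circuit, inlet)
  m <- sim_means(sim)
  l <- scenario$cycle_length

  noise_l <- noise_r <- 0
  if (scenario$noise > 0) {
    noise_l <- with_seed(scenario$seed,
                         stats::rnorm(nrow(sim), 0, scenario$noise * m[["q_l"]]))
    noise_r <- with_seed(scenario$seed + 1L,
                         stats::rnorm(nrow(sim), 0, scenario$noise * m[["q_r"]]))
  }
  q_lpa_obs <- flow_waveform(sim$q_l + noise_l, l)
  q_rpa_obs <- flow_waveform(sim$q_r + noise_r, l)

  record <- tibble::tibble(
    pid = pid, sex = NA_character_, bsa = 1, age = NA_real_,
    q_svc = m[["q_in"]], q_lpa = m[["q_l"]], q_rpa = m[["q_r"]],
    pvr_cath = NA_real_, qp_cath = m[["q_in"]],
    p_svc = m[["p_svc"]], p_lpa = m[["p_junction"]],
    p_rpa = m[["p_junction"]],
    p_la = scenario$circuit$p_dist_l, p_ra = scenario$circuit$p_dist_r)

  list(record = record, inlet = inlet,
       q_lpa_obs = q_lpa_obs, q_rpa_obs = q_rpa_obs,
       target = clinical_target(q_lpa_obs, q_rpa_obs, m[["p_svc"]]),
       truth = scenario$circuit)
}

#' Draw a cohort of synthetic patients
#'
#' Ground-truth parameters are drawn per patient from normal distributions
#' matched to the reference cohort (outlet resistances ~ N(6.2, 3.2) and
#' N(5.3, 2.1) WU.m^2, inlet flow ~ N(1.97, 0.56) L/min/m^2, distal pressure
#' ~ N(4.4, 0.96) mmHg), truncated away from non-physiologic values.
#'
#' @param n Number of patients.
#' @param seed Integer seed; patient i uses noise seed `seed + i`.
#' @param noise Branch-flow observation noise fraction (see
#'   [synthetic_scenario()]).
#' @param dt,cycle_length Waveform discretization.
#' @return A list of `n` synthetic patients (see [make_synthetic_patient()]).
#' @export
make_synthetic_cohort <- function(n, seed = 1L, noise = 0,
                                  dt = 0.001, cycle_length = 0.8) {
  draws <- with_seed(seed, tibble::tibble(
    r_l = pmax(stats::rnorm(n, 6.2, 3.2), 1),
    r_r = pmax(stats::rnorm(n, 5.3, 2.1), 1),
    q = pmax(stats::rnorm(n, 1.97, 0.56), 0.8),
    p_dist = pmax(stats::rnorm(n, 4.4, 0.96), 2),
    phase = stats::runif(n, 0, 2 * pi)
  ))
  purrr::map(seq_len(n), function(i) {
    sc <- synthetic_scenario(
      r_lpa_outlet = draws$r_l[i], r_rpa_outlet = draws$r_r[i],
      p_dist = draws$p_dist[i], q_mean = draws$q[i], phase = draws$phase[i],
      cycle_length = cycle_length, dt = dt,
      noise = noise, seed = seed + i)
    make_synthetic_patient(sc, pid = paste0("synth", i))
  })
}
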