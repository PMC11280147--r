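# Shared fixtures and independent reference implementations used across tests.

bundled <- load_patient_table("bundled")

random_circuit <- function() {
  glenn_circuit(
    r_svc = runif(1, 0, 2),
    r_lpa_vessel = runif(1, 0, 3), r_rpa_vessel = runif(1, 0, 3),
    r_lpa_outlet = runif(1, 0.5, 12), r_rpa_outlet = runif(1, 0.5, 12),
    p_dist_l = runif(1, 0, 10), p_dist_r = runif(1, 0, 10))
}

# Direct pointwise evaluation of the periodic piecewise-linear interpolant,
# written as an explicit loop so it shares nothing with resample_linear().
pwl_reference <- function(flow, l, t) {
  n <- length(flow)
  dt <- l / n
  vapply(t, function(ti) {
    ti <- ti %% l
    i <- floor(ti / dt)
    w <- (ti - i * dt) / dt
    f0 <- flow[i + 1]
    f1 <- flow[if (i + 1 < n) i + 2 else 1]
    (1 - w) * f0 + w * f1
  }, numeric(1))
}

# Term-by-term accumulation of the calibration cost, independent of
# waveform_cost()'s vectorized form.
cost_reference <- function(qc_l, qs_l, qc_r, qs_r, pbar_c, pbar_s) {
  n <- length(qc_l)
  acc <- 0
  for (t in seq_len(n)) {
    acc <- acc + (qc_l[t] - qs_l[t])^2 / mean(qc_l) +
      (qc_r[t] - qs_r[t])^2 / mean(qc_r) +
      (pbar_c - pbar_s)^2 / pbar_c
  }
  acc / n
}

# Minimal glenn_sim stand-in for cost-function unit tests.
fake_sim <- function(q_l, q_r, p_svc, l = 0.8) {
  n <- length(q_l)
  out <- tibble::tibble(time = (seq_len(n) - 1) * l / n,
                        q_in = q_l + q_r, q_l = q_l, q_r = q_r,
                        p_junction = p_svc, p_svc = p_svc)
  structure(out, means = vapply(out[-1], mean, numeric(1)),
            cycle_length = l, dt = l / n,
            class = c("glenn_sim", class(out)))
}
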