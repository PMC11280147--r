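test_that("the calibration cost matches hand arithmetic and is zero at a perfect fit", {
  l <- 0.8
  clin <- clinical_target(flow_waveform(c(1, 1), l), flow_waveform(c(2, 2), l),
                          p_svc_mean = 10)
  perfect <- fake_sim(c(1, 1), c(2, 2), c(10, 10), l)
  expect_equal(waveform_cost(clin, perfect), 0)

  off <- fake_sim(c(1.1, 0.9), c(2, 2), c(10, 10), l)
  expect_equal(waveform_cost(clin, off), 0.01) # (1/2)(0.01 + 0.01)/1
})

test_that("cost equals an independent term-by-term accumulation", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(4:60, 1)
    qc_l <- runif(n, 0.5, 2); qs_l <- qc_l + rnorm(n, 0, 0.2)
    qc_r <- runif(n, 0.5, 2); qs_r <- qc_r + rnorm(n, 0, 0.2)
    p_c <- runif(1, 6, 12); p_s <- p_c + rnorm(1)
    clin <- clinical_target(flow_waveform(qc_l, 0.8),
                            flow_waveform(qc_r, 0.8), p_c)
    sim <- fake_sim(qs_l, qs_r, rep(p_s, n), 0.8)
    expect_equal(waveform_cost(clin, sim),
                 cost_reference(qc_l, qs_l, qc_r, qs_r, p_c, p_s),
                 tolerance = 1e-12)
  }
})

test_that("adding the constant pressure term once equals carrying it in the sum", {
  # carrying (Pbar_c - Pbar_s)^2 / Pbar_c under (1/n) * sum over n terms is
  # identical to adding it once; cost_reference does the former.
  clin <- clinical_target(flow_waveform(c(1, 2, 1.5), 0.8),
                          flow_waveform(c(0.8, 1.1, 0.9), 0.8), 9)
  sim <- fake_sim(c(1.2, 1.9, 1.4), c(0.7, 1.2, 1.0), rep(8.4, 3), 0.8)
  in_sum <- cost_reference(c(1, 2, 1.5), c(1.2, 1.9, 1.4),
                           c(0.8, 1.1, 0.9), c(0.7, 1.2, 1.0), 9, 8.4)
  expect_equal(waveform_cost(clin, sim), in_sum)
})

test_that("cost guards degenerate inputs", {
  clin <- clinical_target(flow_waveform(c(1, 1), 0.8),
                          flow_waveform(c(2, 2), 0.8), 10)
  expect_error(waveform_cost(clin, fake_sim(1:3, 1:3, rep(10, 3), 0.8)),
               "grid mismatch")
  expect_error(clinical_target(flow_waveform(c(0, 0), 0.8),
                               flow_waveform(c(2, 2), 0.8), 10),
               "denominator")
  expect_error(clinical_target(flow_waveform(c(1, 1), 0.8),
                               flow_waveform(c(2, 2), 0.8), -1),
               "SVC pressure")
})

test_that("the cohort initial guess is the mean computed PVR less proximal resistance", {
  g <- initial_guess(bundled)
  pvr <- computed_pvr(bundled)
  expect_equal(unname(g), c(mean(pvr$pvr_lpa), mean(pvr$pvr_rpa)))
  expect_equal(unname(g), c(6.183, 5.290), tolerance = 0.01)

  g1 <- initial_guess(bundled, r_proximal = 1)
  expect_equal(unname(g1), unname(g) - 1)

  single <- initial_guess(bundled[1, ])
  expect_equal(unname(single), c(pvr$pvr_lpa[1], pvr$pvr_rpa[1]))

  floored <- initial_guess(bundled, r_proximal = 100)
  expect_equal(unname(floored), c(0.1, 0.1))

  zeroed <- bundled
  zeroed$q_lpa[2] <- 0
  expect_warning(gz <- initial_guess(zeroed), "zero branch flow")
  expect_equal(unname(gz),
               unname(initial_guess(bundled[-2, ])))
  expect_error(suppressWarnings(initial_guess(zeroed[2, ])), "no usable")
})

test_that("starting at the optimum stays there", {
  sp <- make_synthetic_patient(synthetic_scenario(r_lpa_outlet = 7.7,
                                                  r_rpa_outlet = 4.9,
                                                  dt = 0.01))
  fit <- optimize_pvr(sp$truth, sp$inlet, sp$target,
                      init = c(7.7, 4.9))
  expect_lte(fit$cost, 1e-8)
  expect_equal(c(fit$r_lpa_outlet, fit$r_rpa_outlet), c(7.7, 4.9),
               tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("noise-free ground truth is recovered from the cohort start", {
  init <- initial_guess(bundled)
  set.seed(17)
  for (i in 1:4) {
    truth_l <- runif(1, 2, 11)
    truth_r <- runif(1, 2, 9)
    sp <- make_synthetic_patient(synthetic_scenario(
      r_lpa_outlet = truth_l, r_rpa_outlet = truth_r,
      p_dist = runif(1, 3, 6), q_mean = runif(1, 1.2, 3), dt = 0.005))
    fit <- optimize_pvr(sp$truth, sp$inlet, sp$target, init = init)
    expect_equal(fit$r_lpa_outlet, truth_l, tolerance = 0.01)
    expect_equal(fit$r_rpa_outlet, truth_r, tolerance = 0.01)
    # reported per-lung PVR coincides with the record's computed PVR
    cmp <- computed_pvr(sp$record)
    expect_equal(fit$pvr$pvr, c(cmp$pvr_lpa, cmp$pvr_rpa), tolerance = 0.005)
  }
})

test_that("the closed-form and nodal backends give the same fit", {
  sp <- make_synthetic_patient(synthetic_scenario(r_lpa_outlet = 6.5,
                                                  r_rpa_outlet = 4.2,
                                                  dt = 0.02))
  f1 <- optimize_pvr(sp$truth, sp$inlet, sp$target, init = c(6.18, 5.29),
                     backend = "closed_form")
  f2 <- optimize_pvr(sp$truth, sp$inlet, sp$target, init = c(6.18, 5.29),
                     backend = "nodal")
  expect_equal(c(f1$r_lpa_outlet, f1$r_rpa_outlet),
               c(f2$r_lpa_outlet, f2$r_rpa_outlet), tolerance = 1e-8)
})

test_that("an independent optimizer lands on the same minimum", {
  sp <- make_synthetic_patient(synthetic_scenario(r_lpa_outlet = 8.2,
                                                  r_rpa_outlet = 3.9,
                                                  dt = 0.01))
  fit <- optimize_pvr(sp$truth, sp$inlet, sp$target, init = c(6.18, 5.29))
  obj <- function(x) {
    if (any(x <= 0)) return(1e6)
    circ <- glenn_circuit(r_lpa_outlet = x[1], r_rpa_outlet = x[2],
                          p_dist_l = sp$truth$p_dist_l)
    waveform_cost(sp$target, simulate_circuit(circ, sp$inlet))
  }
  ref <- optim(c(6.18, 5.29), obj, control = list(reltol = 1e-12))
  expect_equal(c(fit$r_lpa_outlet, fit$r_rpa_outlet), ref$par,
               tolerance = 1e-3)
})

test_that("non-positive candidates are penalized, not simulated", {
  sp <- make_synthetic_patient(synthetic_scenario(r_lpa_outlet = 2.2,
                                                  r_rpa_outlet = 2.8,
                                                  dt = 0.02))
  # a start hugging the constraint boundary still converges to the truth
  fit <- optimize_pvr(sp$truth, sp$inlet, sp$target, init = c(0.05, 0.05))
  expect_true(fit$converged)
  expect_equal(c(fit$r_lpa_outlet, fit$r_rpa_outlet), c(2.2, 2.8),
               tolerance = 0.02)
})

test_that("an exhausted budget is reported, not hidden", {
  sp <- make_synthetic_patient(synthetic_scenario(dt = 0.02))
  fit <- optimize_pvr(sp$truth, sp$inlet, sp$target, init = c(1, 1),
                      max_evals = 4)
  expect_false(fit$converged)
  expect_lte(fit$evals, 4 + 4) # the in-flight iteration may finish
})

test_that("reported PVR follows the computed definition and decomposes exactly", {
  # single-resistor branch, constant inlet: PVR is the outlet resistor
  circ <- glenn_circuit(r_lpa_outlet = 7, r_rpa_outlet = 7, p_dist_l = 4)
  sim <- simulate_circuit(circ, flow_waveform(rep(2, 10), 0.8))
  rep1 <- report_pvr(sim, circ)
  expect_equal(rep1$pvr, c(7, 7))
  expect_equal(rep1$residual, c(0, 0), tolerance = 1e-8)

  # patient-1-like arithmetic: (11 - 5) / 0.65
  p1 <- glenn_circuit(r_lpa_outlet = 6 / 0.65, r_rpa_outlet = 6 / 1.13,
                      p_dist_l = 5)
  sim1 <- simulate_circuit(p1, synth_inlet_waveform(1.78, dt = 0.01))
  rep2 <- report_pvr(sim1, p1)
  expect_equal(rep2$pvr[1], 9.231, tolerance = 1e-3)

  # split across svc/vessel/outlet resistors: drops sum to the gradient and
  # the reported PVR is invariant to the split
  mixed <- glenn_circuit(r_svc = 0.5, r_lpa_vessel = 1.2, r_rpa_vessel = 0.3,
                         r_lpa_outlet = 5, r_rpa_outlet = 6, p_dist_l = 4)
  simm <- simulate_circuit(mixed, synth_inlet_waveform(2.1, dt = 0.01))
  repm <- report_pvr(simm, mixed)
  m <- sim_means(simm)
  expect_equal(repm$drop_svc + repm$drop_vessel + repm$drop_outlet,
               m[["p_svc"]] - c(mixed$p_dist_l, mixed$p_dist_r),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(repm$pvr,
               (m[["p_svc"]] - 4) / c(m[["q_l"]], m[["q_r"]]),
               ignore_attr = TRUE)
})

test_that("tidy and glance expose the fit in broom shape", {
  sp <- make_synthetic_patient(synthetic_scenario(dt = 0.02))
  fit <- optimize_pvr(sp$truth, sp$inlet, sp$target, init = c(6, 5))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$lung, c("lpa", "rpa"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("cost", "evals", "converged", "pvr_total") %in% names(gl)))
  expect_equal(gl$pvr_total, total_pvr(gl$pvr_lpa, gl$pvr_rpa))
})
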