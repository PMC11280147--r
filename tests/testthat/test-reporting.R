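cfg_for <- function(dir, ...) {
  cfg <- default_config()
  cfg$out_dir <- dir
  utils::modifyList(cfg, list(...))
}

test_that("run configs load, merge and validate", {
  cfg <- load_run_config(NULL)
  expect_equal(cfg$table, "bundled")
  expect_equal(cfg$optimizer$tolerance, 1e-4)

  ym <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("table: bundled", "optimizer:", "  max_evals: 50"), ym)
  cfg2 <- load_run_config(ym)
  expect_equal(cfg2$optimizer$max_evals, 50)
  expect_equal(cfg2$optimizer$tolerance, 1e-4) # untouched default

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"optimizer": {"tolerance": 0.01}}', js)
  expect_equal(load_run_config(js)$optimizer$tolerance, 0.01)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("optimizer:\n  tolerance: -1", bad)
  expect_error(load_run_config(bad), "tolerance")
  expect_error(load_run_config("missing.yaml"), "not found")
})

test_that("compute-pvr writes the per-patient table and cohort summary", {
  out <- withr::local_tempdir()
  res <- cmd_compute_pvr(cfg_for(out))
  expect_equal(nrow(res$pvr), 16L)
  expect_equal(mean(res$pvr$pvr_lpa), 6.18, tolerance = 0.001)
  expect_true(file.exists(file.path(out, "computed_pvr.csv")))
  expect_true(file.exists(file.path(out, "cohort_summary.csv")))
  disk <- read.csv(file.path(out, "computed_pvr.csv"))
  expect_equal(disk$pvr_lpa, res$pvr$pvr_lpa, tolerance = 1e-12)
})

test_that("a zero-flow patient is flagged while the rest are computed", {
  out <- withr::local_tempdir()
  tbl <- withr::local_tempfile(fileext = ".csv")
  broken <- bundled
  broken$q_lpa[5] <- 0
  write_patient_table(broken, tbl)
  expect_warning(res <- cmd_compute_pvr(cfg_for(out, table = tbl)),
                 "skipped")
  expect_equal(nrow(res$pvr), 16L)
  expect_true(is.na(res$pvr$pvr_lpa[5]))
  expect_equal(sum(is.na(res$pvr$pvr_lpa)), 1L)
  expect_error(cmd_compute_pvr(cfg_for(out, table = "gone.csv")), "not found")
})

test_that("optimizing a seeded synthetic cohort recovers every ground truth", {
  out <- withr::local_tempdir()
  wdir <- withr::local_tempdir()
  cohort <- make_synthetic_cohort(5, seed = 13, dt = 0.005)
  tbl_path <- file.path(wdir, "table.csv")
  write_patient_table(dplyr::bind_rows(purrr::map(cohort, "record")), tbl_path)
  for (p in cohort) {
    write_waveform_csv(p$inlet, file.path(wdir, paste0(p$record$pid, "_svc.csv")))
    write_waveform_csv(p$q_lpa_obs, file.path(wdir, paste0(p$record$pid, "_lpa.csv")))
    write_waveform_csv(p$q_rpa_obs, file.path(wdir, paste0(p$record$pid, "_rpa.csv")))
  }
  cfg <- cfg_for(out, table = tbl_path, waveform_dir = wdir)
  res <- cmd_optimize(cfg)
  expect_equal(nrow(res), 5L)
  expect_true(all(res$converged))
  truth_l <- purrr::map_dbl(cohort, ~.x$truth$r_lpa_outlet)
  truth_r <- purrr::map_dbl(cohort, ~.x$truth$r_rpa_outlet)
  expect_lt(max(abs(res$r_lpa_outlet / truth_l - 1)), 0.01)
  expect_lt(max(abs(res$r_rpa_outlet / truth_r - 1)), 0.01)
  expect_true(file.exists(file.path(out, "optimization_results.json")))
})

test_that("bundled table with synthetic targets matches the computed PVR", {
  out <- withr::local_tempdir()
  cfg <- cfg_for(out)
  cfg$synthetic$dt <- 0.005
  res <- cmd_optimize(cfg)
  expect_equal(nrow(res), 16L)
  expect_lt(max(abs(res$pvr_lpa / res$computed_lpa - 1)), 0.02)
  expect_lt(max(abs(res$pvr_rpa / res$computed_rpa - 1)), 0.02)
})

test_that("budget exhaustion warns but completes the cohort", {
  out <- withr::local_tempdir()
  cfg <- cfg_for(out)
  cfg$synthetic$dt <- 0.02
  cfg$optimizer$max_evals <- 4
  w <- capture_warnings(res <- cmd_optimize(cfg))
  expect_true(any(grepl("budget", w)))
  expect_equal(nrow(res), 16L)
  expect_true(all(!res$converged))
})

test_that("the agreement report closes the loop on self-consistent data", {
  out <- withr::local_tempdir()
  cfg <- cfg_for(out)
  cfg$synthetic$dt <- 0.005
  opt <- cmd_optimize(cfg)
  rep <- cmd_report(cfg, optimized = opt)
  lpa_row <- rep$agreement[rep$agreement$comparison ==
                            "LPA PVR: computed vs optimized", ]
  expect_gt(lpa_row$icc, 0.99)
  # Ohm's law with a shared distal pressure: flow ratio times PVR ratio is 1
  expect_lt(max(abs(rep$ratios$product - 1)), 1e-3)
  cath_row <- rep$agreement[rep$agreement$comparison ==
                              "total PVR: CATH vs optimized", ]
  expect_equal(cath_row$mean_x, 1.80, tolerance = 0.005)

  mismatched <- opt[-1, ]
  expect_error(cmd_report(cfg, optimized = mismatched), "join")
})

test_that("identical config and seed give byte-identical outputs", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg1 <- cfg_for(out1)
  cfg1$synthetic$dt <- 0.02
  cfg2 <- cfg_for(out2)
  cfg2$synthetic$dt <- 0.02
  cmd_optimize(cfg1)
  cmd_optimize(cfg2)
  expect_identical(readLines(file.path(out1, "optimized_pvr.csv")),
                   readLines(file.path(out2, "optimized_pvr.csv")))
})
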