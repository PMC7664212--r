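fake_cal <- function(completeness_n, carbons = 5:24) {
  run <- ladder_run(carbons = carbons)
  detect_ladder(run[seq_len(completeness_n), ], carbons = carbons)
}

test_that("samples with partially detected ladders are excluded", {
  cals <- list(S1 = fake_cal(20), S2 = fake_cal(18), S3 = fake_cal(20))
  qc <- qc_samples(cals)
  expect_equal(qc$kept, c("S1", "S3"))
  expect_equal(qc$excluded, "S2")
  expect_match(qc$report$missing[qc$report$sample_id == "S2"], "23,24")
  # a relaxed threshold keeps the 18/20 sample
  expect_equal(length(qc_samples(cals, required_fraction = 0.9)$kept), 3)
  expect_error(qc_samples(list(S1 = fake_cal(1))), "all samples excluded")
})

test_that("planted ladder dropout drives exactly the intended exclusions", {
  cfg <- simulation_config(seed = 31, decoys_per_run = 0,
                           samples_per_region = 3,
                           dropout = list(HP_02 = c(5, 6), CE_01 = 12,
                                          CE_03 = c(20, 21)))
  sim <- simulate_quantitative_study(cfg)
  runs <- split(as.data.frame(sim$features), sim$features$sample_id)
  cals <- lapply(runs, detect_ladder)
  qc <- qc_samples(cals)
  expect_setequal(qc$excluded, sim$manifest$expected_excluded)
  expect_equal(length(qc$kept), 9)
})

test_that("normalization divides by the nearest-RI standard with lower-carbon ties", {
  cal <- fake_cal(20)
  cal$anchors$intensity <- seq(1e6, 2e6, length.out = 20)
  # analyte at RI 805: nearest standard C8:0 (RI 800)
  v <- normalize_by_ladder(2e6, 805, cal)
  expect_equal(v, 2e6 / cal$anchors$intensity[cal$anchors$carbon == 8])
  # RI 850 equidistant from C8:0 and C9:0 -> C8:0 (lower carbon)
  v2 <- normalize_by_ladder(1e6, 850, cal)
  expect_equal(v2, 1e6 / cal$anchors$intensity[cal$anchors$carbon == 8])
})

test_that("per-run global intensity scaling cancels exactly", {
  cfg <- simulation_config(seed = 33, regions = c("OB", "CE"),
                           samples_per_region = 2, decoys_per_run = 0)
  sim <- simulate_quantitative_study(cfg)
  runs <- split(as.data.frame(sim$features), sim$features$sample_id)
  r <- runs[[1]]
  cal <- detect_ladder(r)
  p <- drop_ladder_peaks(calibrate_peaks(r, cal))
  v1 <- normalize_by_ladder(p$intensity, p$ri, cal)
  r2 <- r; r2$intensity <- r2$intensity * 7.3
  cal2 <- detect_ladder(r2)
  p2 <- drop_ladder_peaks(calibrate_peaks(r2, cal2))
  v2 <- normalize_by_ladder(p2$intensity, p2$ri, cal2)
  expect_equal(v2, v1)
})

test_that("region fold changes are recovered from normalized abundances", {
  effects <- list("myristic acid" = c(OB = 2.5))
  cfg <- simulation_config(seed = 35, effects = effects, decoys_per_run = 0)
  sim <- simulate_quantitative_study(cfg)
  runs <- split(as.data.frame(sim$features), sim$features$sample_id)
  cals <- lapply(runs, detect_ladder)
  regions <- vapply(runs, function(r) r$region[1], character(1))
  analyte <- lapply(names(runs), function(id)
    drop_ladder_peaks(calibrate_peaks(runs[[id]], cals[[id]])))
  names(analyte) <- names(runs)
  ab <- build_abundance_table(analyte, cals, regions)
  pan <- sim$manifest$panel
  j <- which.min(abs(ab$features$mz -
                       pan$mz_light[pan$ffa_id == "myristic acid"]))
  v <- ab$values[, j]
  rg <- ab$samples$region
  fold_hat <- mean(v[rg == "OB"]) / mean(v[rg != "OB"])
  expect_lt(abs(fold_hat - 2.5) / 2.5, 0.10)
  # undetected analytes are explicit NAs, never zeros
  expect_true(all(is.na(ab$values) | ab$values > 0))
})
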