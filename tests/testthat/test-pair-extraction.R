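test_that("the caprylic-acid light/heavy duo is extracted as one pair", {
  peaks <- peaks_df(c(215.2118, 219.2369), c(800, 800), c(1.0e6, 1.1e6))
  pr <- extract_pairs(peaks)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$light_mz, 215.2118)
  expect_equal(pr$heavy_mz, 219.2369)
  expect_lt(abs(pr$mass_error_mda), 0.1)
})

test_that("intensity-fold and RI filters suppress non-pairs", {
  # fold 20 at default max fold 5
  p1 <- peaks_df(c(215.2118, 219.2369), c(800, 800), c(1.0e6, 2.0e7))
  expect_equal(nrow(extract_pairs(p1)), 0)
  # RI gap 100 at default tolerance 5
  p2 <- peaks_df(c(215.2118, 219.2369), c(800, 900), c(1.0e6, 1.1e6))
  expect_equal(nrow(extract_pairs(p2)), 0)
  # both pass at the boundary fold
  p3 <- peaks_df(c(215.2118, 219.2369), c(800, 800), c(1.0e6, 5.0e6))
  expect_equal(nrow(extract_pairs(p3)), 1)
})

test_that("ambiguous heavy candidates resolve to the smaller mass error", {
  peaks <- peaks_df(c(215.2118, 215.2118 + 4.0251, 215.2118 + 4.0290),
                    c(800, 800, 800), c(1e6, 1e6, 1e6))
  pr <- extract_pairs(peaks)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$heavy_mz, 215.2118 + 4.0251)
})

test_that("uncalibrated peaks are refused", {
  p <- peaks_df(c(215.2118, 219.2369), c(800, 800), c(1e6, 1e6))
  p$ri <- NULL
  expect_error(extract_pairs(p), "calibrat")
})

test_that("no peak is used twice and output ignores input row order", {
  set.seed(8)
  panel <- random_ffa_panel(100)
  cfg <- simulation_config(seed = 8, regions = "OB", panel = panel,
                           presence_prob = 1, decoys_per_run = 300)
  sim <- simulate_qualitative_run(cfg)
  run <- as.data.frame(sim$features)
  run <- calibrate_peaks(run, detect_ladder(run))
  pr <- extract_pairs(run)
  keys <- c(paste(pr$light_mz, pr$light_ri), paste(pr$heavy_mz, pr$heavy_ri))
  expect_equal(anyDuplicated(keys), 0)
  shuffled <- run[sample(nrow(run)), ]
  expect_equal(extract_pairs(shuffled), pr)
})

test_that("planted pairs are recovered with no decoy false pairs", {
  set.seed(9)
  panel <- random_ffa_panel(200)
  cfg <- simulation_config(seed = 9, regions = "OB", panel = panel,
                           presence_prob = 1, decoys_per_run = 400)
  sim <- simulate_qualitative_run(cfg)
  run <- as.data.frame(sim$features)
  run <- calibrate_peaks(run, detect_ladder(run))
  pr <- extract_pairs(run)
  truth <- sim$manifest$pairs
  recall <- mean(vapply(seq_len(nrow(truth)), function(i)
    any(abs(pr$light_mz - truth$mz_light[i]) <= 0.005 &
          abs(pr$light_ri - truth$ri[i]) <= 6), logical(1)))
  expect_gte(recall, 0.99)
  false_pairs <- sum(vapply(seq_len(nrow(pr)), function(k)
    !any(abs(truth$mz_light - pr$light_mz[k]) <= 0.005), logical(1)))
  expect_equal(false_pairs, 0)
})

test_that("cross-sample merging gives one potential FFA per planted compound", {
  # same FFA in 3 runs -> 1 potential FFA present in 3 samples
  mk <- function(sid, rg) {
    p <- peaks_df(c(215.2118, 219.2369), c(800, 800), c(1e6, 1.1e6),
                  sample_id = sid, region = rg)
    extract_pairs(p)
  }
  merged <- merge_pairs(list(mk("S1", "OB"), mk("S2", "OB"), mk("S3", "CE")))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_samples, 3L)
  expect_true(merged$in_OB && merged$in_CE)

  # two FFAs 0.5 Da apart stay distinct
  p2 <- peaks_df(c(215.2118, 219.2369, 215.7118, 219.7369),
                 c(800, 800, 820, 820), rep(1e6, 4))
  merged2 <- merge_pairs(extract_pairs(p2))
  expect_equal(nrow(merged2), 2)
})

test_that("noiseless runs with decoys merge to exactly the planted FFAs", {
  set.seed(10)
  panel <- random_ffa_panel(10)
  cfg <- simulation_config(seed = 10, regions = c("OB", "CE"), panel = panel,
                           presence_prob = 1, decoys_per_run = 100,
                           mz_noise_mda = 0, ri_jitter = 0)
  sim <- simulate_qualitative_run(cfg)
  runs <- split(as.data.frame(sim$features), sim$features$sample_id)
  prs <- lapply(runs, function(r) extract_pairs(calibrate_peaks(r, detect_ladder(r))))
  merged <- merge_pairs(prs)
  expect_equal(nrow(merged), 10)
  expect_true(all(merged$n_samples == 2))
})
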