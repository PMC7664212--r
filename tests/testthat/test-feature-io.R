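test_that("feature tables read back with validation and rejection logging", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(mz = c(215.2118, 219.2369, 300.1),
                   rt = c(3.5, 3.5, 7.1),
                   intensity = c(1e6, 1.1e6, 2e5),
                   sample_id = "S1", region = "OB")
  write.csv(df, tmp, row.names = FALSE)
  pl <- read_feature_table(tmp)
  expect_s3_class(pl, "peak_list")
  expect_equal(nrow(pl), 3)
  expect_equal(attr(pl, "n_rejected"), 0)

  # zero-intensity row is rejected and counted, not silently dropped
  df$intensity[2] <- 0
  write.csv(df, tmp, row.names = FALSE)
  expect_message(pl2 <- read_feature_table(tmp), "rejected")
  expect_equal(nrow(pl2), 2)
  expect_equal(attr(pl2, "n_rejected"), 1)
})

test_that("missing columns and non-numeric fields are named in errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(rt = 1, intensity = 1, sample_id = "a"), tmp,
            row.names = FALSE)
  expect_error(read_feature_table(tmp), "mz")
  write.csv(data.frame(mz = c("1.0", "oops"), rt = c(1, 2),
                       intensity = c(1, 1), sample_id = "a"),
            tmp, row.names = FALSE)
  expect_error(read_feature_table(tmp), "non-numeric mz")
  expect_error(read_feature_table(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("the packaged synthetic library loads with the expected structure", {
  lib <- read_library()
  expect_s3_class(lib, "ffa_library")
  expect_gte(nrow(lib), 56)
  # the full straight-chain ladder C5:0..C24:0 is present at RI = 100*n
  sat <- lib[grepl("^C\\d+H\\d+O2$", lib$formula) &
               lib$class == "saturated FA", ]
  carbons <- as.integer(sub("^C(\\d+)H.*", "\\1", sat$formula))
  expect_true(all(5:24 %in% carbons))
  ladder <- sat[match(5:24, carbons), ]
  expect_equal(ladder$reference_ri, 100 * (5:24))
  # caprylic acid entry carries the oracle mass
  cap <- lib[lib$name == "caprylic acid", ]
  expect_equal(round(cap$mass, 4), 144.1150)
  expect_equal(round(cap$mz_light, 4), 215.2118)
})

test_that("duplicate names and malformed formulas are library errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(name = c("myristic acid", "myristic acid"),
                       formula = c("C14H28O2", "C14H28O2"),
                       reference_ri = c(1400, 1400),
                       class = "saturated FA"), tmp, row.names = FALSE)
  expect_error(read_library(tmp), "duplicate")
  write.csv(data.frame(name = "bad", formula = "C2X4",
                       reference_ri = 100, class = "other"),
            tmp, row.names = FALSE)
  expect_error(read_library(tmp), "bad formula")
})

test_that("pair tables and matrices round-trip to 6 significant figures", {
  set.seed(3)
  run <- ladder_run()
  extra <- peaks_df(c(215.21181, 219.23691), c(800, 800), c(1e6, 1.05e6),
                    rt = c(3.5, 3.5))
  peaks <- rbind(run, extra)
  cal <- detect_ladder(peaks)
  pairs <- extract_pairs(calibrate_peaks(peaks, cal))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_pair_table(pairs, tmp, header = "config_hash=deadbeef seed=1")
  back <- read_pair_table(tmp)
  expect_equal(nrow(back), nrow(pairs))
  for (col in c("light_mz", "heavy_mz", "light_ri", "intensity_ratio")) {
    expect_equal(signif(back[[col]], 6), signif(pairs[[col]], 6))
  }
  # header comment is preserved at the top of the file
  expect_match(readLines(tmp, n = 1), "config_hash")

  m <- matrix(c(31, 12, 12, 26), 2, 2,
              dimnames = list(c("OB", "CE"), c("OB", "CE")))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, tmp2)
  expect_equal(read_matrix(tmp2), m)

  # empty pair list -> header-only file
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write_pair_table(extract_pairs(calibrate_peaks(run, cal)), tmp3)
  expect_equal(nrow(read_pair_table(tmp3)), 0)
})
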