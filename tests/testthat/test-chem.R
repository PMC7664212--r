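test_that("monoisotopic masses match independent atomic-mass sums", {
  expect_equal(monoisotopic_mass("C8H16O2"), oracle_mass(C = 8, H = 16, O = 2))
  expect_equal(round(monoisotopic_mass("C8H16O2"), 4), 144.1150)
  expect_equal(round(monoisotopic_mass("H2O"), 4), 18.0106)
  expect_equal(monoisotopic_mass(""), 0)
  expect_equal(monoisotopic_mass("C12H26N2O"),
               oracle_mass(C = 12, H = 26, N = 2, O = 1))
})

test_that("formula parser handles Hill strings, implicit 1s, and bad input", {
  f <- parse_formula("C12H26N2O")
  expect_equal(unclass(f)[c("C", "H", "N", "O")],
               c(C = 12L, H = 26L, N = 2L, O = 1L))
  expect_equal(format_formula(f), "C12H26N2O")
  expect_error(parse_formula("C2H5Cl"), "Cl")
  expect_error(parse_formula("c8h16"), "parse")
  # deuterium is a distinct symbol with its own mass
  expect_equal(monoisotopic_mass("C4H8D4N2") - monoisotopic_mass("C4H12N2"),
               4 * (2.01410177785 - 1.00782503207))
})

test_that("derivative m/z reproduces the caprylic-acid light/heavy ions", {
  expect_equal(round(derivative_mz("C8H16O2", "light"), 4), 215.2118)
  expect_equal(round(derivative_mz("C8H16O2", "heavy"), 4), 219.2369)
  expect_equal(round(derivative_mz("C16H32O2", "light"), 4), 327.3370)
  expect_equal(round(label_delta("light"), 4), 70.0895)
})

test_that("pair mass delta is the exact 4xD-H difference", {
  expect_equal(round(pair_mass_delta(), 4), 4.0251)
  expect_equal(round(pair_mass_delta(), 3), 4.025)
  # algebraic identity heavy - light = delta, and heavy > light, for any F
  for (f in c("C5H10O2", "C18H32O2", "C24H40O5", "C6H10O3")) {
    expect_equal(derivative_mz(f, "heavy") - derivative_mz(f, "light"),
                 pair_mass_delta())
    expect_gt(derivative_mz(f, "heavy"), derivative_mz(f, "light"))
  }
})

test_that("formula generation finds known compositions and rejects bad input", {
  g <- generate_formulas(214.2045)
  expect_true("C12H26N2O" %in% g$formula)
  g2 <- generate_formulas(18.0106)
  expect_true("H2O" %in% g2$formula)
  expect_error(generate_formulas(-1), "positive")
  expect_error(generate_formulas(0), "positive")
  # empty bounds give an empty result
  empty <- generate_formulas(100, bounds = list(C = c(0, 0), H = c(0, 0),
                                                N = c(0, 0), O = c(0, 0)))
  expect_equal(nrow(empty), 0)
})

test_that("formula generation is ordered by |mass error| with stable ties", {
  g <- generate_formulas(250.1, tolerance_mda = 50)
  expect_true(nrow(g) > 1)
  expect_true(!is.unsorted(abs(g$error_mda)))
})

test_that("formula generation agrees exactly with brute-force enumeration", {
  set.seed(42)
  masses <- runif(25, 100, 500)
  for (m in masses) {
    expect_identical(formula_key(generate_formulas(m)), oracle_generate(m))
  }
  # and with the plausibility filter off
  for (m in masses[1:5]) {
    expect_identical(formula_key(generate_formulas(m, rdbe_filter = FALSE)),
                     oracle_generate(m, rdbe_filter = FALSE))
  }
})

test_that("library FFAs round-trip through derivative-mass formula generation", {
  lib <- read_library()
  for (i in seq_len(nrow(lib))) {
    g <- generate_formulas(lib$mass[i] + label_delta("light"))
    f <- parse_formula(lib$formula[i])
    deriv <- format_formula(parse_formula(paste0(
      "C", f[["C"]] + 4, "H", f[["H"]] + 10, "N", f[["N"]] + 2,
      if (f[["O"]] - 1 > 0) paste0("O", f[["O"]] - 1) else "")))
    expect_true(deriv %in% g$formula, label = lib$name[i])
    # amidation swaps the acid C=O for an amide C=O: RDBE is conserved
    expect_equal(rdbe(deriv), rdbe(f))
  }
})
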