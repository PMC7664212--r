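# Independent oracles used across tests. Atomic masses are written out
# here on purpose (NIST values) so the oracle does not share constants
# with the package.
oracle_mass <- function(C = 0, H = 0, N = 0, O = 0, D = 0) {
  C * 12 + H * 1.00782503207 + N * 14.0030740048 + O * 15.9949146196 +
    D * 2.01410177785
}

# Exhaustive CHNO enumeration over bounds; returns formula strings of all
# compositions within tol_mda of the target (with the plausibility filter
# applied when requested). Grid is built once per bounds and cached.
oracle_formula_grid <- local({
  cache <- list()
  function(bounds) {
    key <- paste(unlist(bounds), collapse = ",")
    if (is.null(cache[[key]])) {
      g <- expand.grid(C = bounds$C[1]:bounds$C[2],
                       H = bounds$H[1]:bounds$H[2],
                       N = bounds$N[1]:bounds$N[2],
                       O = bounds$O[1]:bounds$O[2])
      g$mass <- oracle_mass(g$C, g$H, g$N, g$O)
      g$rdbe <- g$C - g$H / 2 + g$N / 2 + 1
      cache[[key]] <<- g
    }
    cache[[key]]
  }
})

oracle_generate <- function(mass, tol_mda = 5, bounds = default_element_bounds(),
                            rdbe_filter = TRUE) {
  g <- oracle_formula_grid(bounds)
  keep <- abs(g$mass - mass) <= tol_mda / 1000 & (g$C + g$H + g$N + g$O) > 0
  if (rdbe_filter) keep <- keep & g$rdbe >= 0 & g$rdbe == floor(g$rdbe)
  hit <- g[keep, , drop = FALSE]
  sort(sprintf("C%d|H%d|N%d|O%d", hit$C, hit$H, hit$N, hit$O))
}

formula_key <- function(df) sort(sprintf("C%d|H%d|N%d|O%d",
                                         df$C, df$H, df$N, df$O))

# Peak table builder for hand-constructed pairing scenarios.
peaks_df <- function(mz, ri, intensity, rt = seq_along(mz),
                     sample_id = "S1", region = "OB") {
  data.frame(mz = mz, rt = rt, ri = ri, intensity = intensity,
             sample_id = sample_id, region = region,
             stringsAsFactors = FALSE)
}

# A clean synthetic ladder run: all 20 standards at their model RTs.
ladder_run <- function(intensity = 5e6, carbons = 5:24) {
  lad <- ladder_mz(carbons)
  data.frame(mz = lad$mz, rt = 2 + 0.28 * lad$carbon + 0.004 * lad$carbon^2,
             ri = NA_real_, intensity = intensity, sample_id = "S1",
             region = "OB", stringsAsFactors = FALSE)
}
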