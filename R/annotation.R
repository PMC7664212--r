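#' Match potential FFAs against a standards library
#'
#' A potential FFA matches the library entry whose light derivative m/z is
#' within `mz_tolerance_mda` and whose reference RI is within
#' `ri_tolerance`. If several entries qualify, the closest m/z wins; m/z
#' ties are broken by closest RI. Unmatched FFAs are flagged for de novo
#' formula generation.
#'
#' @param ffas A `ffa_table` from [merge_pairs()] (needs `ffa_id`, `mz`,
#'   `ri`).
#' @param library A `ffa_library` from [read_library()].
#' @param mz_tolerance_mda m/z window in mDa (default 5.0).
#' @param ri_tolerance RI window (default 10).
#' @return Data.frame: `ffa_id`, `mz`, `ri`, `status` ("library" or
#'   "unmatched"), `name`, `formula`, `class`, `mass_error_mda`,
#'   `ri_error`.
#' @export
match_library <- function(ffas, library, mz_tolerance_mda = 5.0,
                          ri_tolerance = 10) {
  stopifnot(is.data.frame(ffas), is.data.frame(library))
  tol <- mz_tolerance_mda / 1000
  n <- nrow(ffas)
  name <- formula <- class <- rep(NA_character_, n)
  merr <- rierr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dm <- ffas$mz[i] - library$mz_light
    dr <- ffas$ri[i] - library$reference_ri
    cand <- which(abs(dm) <= tol & abs(dr) <= ri_tolerance)
    if (!length(cand)) next
    j <- cand[order(abs(dm[cand]), abs(dr[cand]))][1]
    name[i] <- library$name[j]
    formula[i] <- library$formula[j]
    class[i] <- library$class[j]
    merr[i] <- dm[j] * 1000
    rierr[i] <- dr[j]
  }
  data.frame(ffa_id = ffas$ffa_id, mz = ffas$mz, ri = ffas$ri,
             status = ifelse(is.na(name), "unmatched", "library"),
             name = name, formula = formula, class = class,
             mass_error_mda = merr, ri_error = rierr,
             stringsAsFactors = FALSE)
}

#' Propose neutral acid formulas for an unmatched FFA
#'
#' The neutral labeled mass is light m/z minus the proton mass; candidate
#' derivative formulas are generated within `tolerance_mda` over the CHNO
#' bounds and back-transformed (- DMED + H2O, i.e. C-4, H-10, N-2, O+1) to
#' neutral acid formulas. Candidates whose back-transformation yields a
#' negative element count are dropped. An empty result is a valid outcome
#' (unassignable peak pair).
#'
#' @param light_mz Consensus light m/z of the FFA.
#' @param tolerance_mda Mass tolerance in mDa (default 5.0).
#' @param bounds Element bounds (see [default_element_bounds()]).
#' @return Data.frame: `acid_formula`, `derivative_formula`, `error_mda`,
#'   `rdbe` (of the neutral acid), ordered by |mass error|.
#' @export
annotate_formula <- function(light_mz, tolerance_mda = 5.0,
                             bounds = default_element_bounds()) {
  stopifnot(is.numeric(light_mz), length(light_mz) == 1L, light_mz > 0)
  neutral <- light_mz - proton_mass()
  cand <- generate_formulas(neutral, tolerance_mda, bounds)
  if (!nrow(cand)) return(.empty_annotation())
  aC <- cand$C - 4L; aH <- cand$H - 10L; aN <- cand$N - 2L; aO <- cand$O + 1L
  keep <- aC >= 0L & aH >= 0L & aN >= 0L
  if (!any(keep)) return(.empty_annotation())
  cand <- cand[keep, , drop = FALSE]
  aC <- aC[keep]; aH <- aH[keep]; aN <- aN[keep]; aO <- aO[keep]
  acid <- vapply(seq_along(aC), function(i)
    format_formula(new_formula(c(C = aC[i], H = aH[i], N = aN[i], O = aO[i]))),
    character(1))
  out <- data.frame(acid_formula = acid,
                    derivative_formula = cand$formula,
                    error_mda = cand$error_mda,
                    rdbe = aC - aH / 2 + aN / 2 + 1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.empty_annotation <- function() {
  data.frame(acid_formula = character(), derivative_formula = character(),
             error_mda = numeric(), rdbe = numeric(),
             stringsAsFactors = FALSE)
}

#' Classify a fatty-acid formula by saturation and chain length
#'
#' For a CnH(2n+2-2d)O2 acid, one RDBE is the carboxyl C=O, so the number
#' of C=C double bonds is RDBE - 1: 0 = saturated, 1 = monounsaturated,
#' >1 = polyunsaturated. Chain-length classes by carbon count: short
#' (2-5), medium (6-12), long (13-22), very long (>22). Formulas that are
#' not simple O2 acids are classified as "other" (bile acids are carried
#' as library metadata, not derivable from formula alone).
#'
#' @param formula Neutral acid formula (string or `chno_formula`).
#' @return List with `saturation`, `chain_length`, `double_bonds`,
#'   `carbons`.
#' @examples
#' classify_ffa("C16H32O2")  # saturated, long chain
#' classify_ffa("C18H34O2")  # monounsaturated
#' @export
classify_ffa <- function(formula) {
  f <- as_formula(formula)
  nC <- f[["C"]]
  if (f[["O"]] != 2L || f[["N"]] != 0L || nC < 2L) {
    return(list(saturation = "other", chain_length = "other",
                double_bonds = NA_integer_, carbons = nC))
  }
  db <- as.integer(rdbe(f) - 1)
  if (is.na(db) || db < 0 || rdbe(f) != floor(rdbe(f))) {
    return(list(saturation = "other", chain_length = "other",
                double_bonds = NA_integer_, carbons = nC))
  }
  sat <- if (db == 0) "saturated FA" else if (db == 1) {
    "monounsaturated FA"
  } else "polyunsaturated FA"
  chain <- if (nC > 22) "very long chain" else if (nC >= 13) {
    "long chain"
  } else if (nC >= 6) "medium chain" else "short chain"
  list(saturation = sat, chain_length = chain, double_bonds = db,
       carbons = nC)
}

#' Annotate a merged FFA table
#'
#' Library matching first; unmatched FFAs get de novo formula candidates.
#' Status is "library", "formula" (at least one acid candidate) or
#' "unassigned".
#'
#' @inheritParams match_library
#' @param tolerance_mda Mass tolerance for formula generation (default 5.0).
#' @return The [match_library()] table with `status` upgraded and
#'   `formula`/`class` filled from the top-ranked de novo candidate where
#'   available.
#' @export
annotate_ffas <- function(ffas, library, mz_tolerance_mda = 5.0,
                          ri_tolerance = 10, tolerance_mda = 5.0) {
  ann <- match_library(ffas, library, mz_tolerance_mda, ri_tolerance)
  todo <- which(ann$status == "unmatched")
  for (i in todo) {
    cand <- annotate_formula(ann$mz[i], tolerance_mda)
    if (nrow(cand)) {
      ann$status[i] <- "formula"
      ann$formula[i] <- cand$acid_formula[1]
      ann$class[i] <- classify_ffa(cand$acid_formula[1])$saturation
      ann$mass_error_mda[i] <- cand$error_mda[1]
    } else {
      ann$status[i] <- "unassigned"
    }
  }
  ann
}
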