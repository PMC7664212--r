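#' @keywords internal
"_PACKAGE"

# Monoisotopic atomic masses (CODATA/AME2020). D is deuterium (2H); it is
# kept as a distinct symbol so labeled species can be written explicitly,
# but it counts as H for ring-plus-double-bond arithmetic.
.ATOMIC_MASS <- c(
  C = 12,
  H = 1.00782503207,
  D = 2.01410177785,
  N = 14.0030740048,
  O = 15.9949146196
)

.PROTON_MASS <- 1.007276466879

#' Parse a Hill-order molecular formula string
#'
#' Accepts element-count strings such as `"C12H26N2O"`; an omitted count
#' means 1. Supported elements are C, H, N, O and D (deuterium).
#'
#' @param x A single formula string.
#' @return An object of class `chno_formula`: a named integer vector with
#'   one entry per supported element.
#' @examples
#' parse_formula("C8H16O2")
#' parse_formula("H2O")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  counts <- stats::setNames(integer(length(.ATOMIC_MASS)), names(.ATOMIC_MASS))
  x <- gsub("[[:space:]]", "", x)
  if (nzchar(x)) {
    m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
    tokens <- regmatches(x, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(x)) {
      stop("cannot parse formula string: '", x, "'", call. = FALSE)
    }
    for (tok in tokens) {
      sym <- gsub("[0-9]", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!sym %in% names(counts)) {
        stop("unknown element symbol '", sym, "' in formula '", x, "'",
             call. = FALSE)
      }
      counts[sym] <- counts[sym] + n
    }
  }
  new_formula(counts)
}

new_formula <- function(counts) {
  full <- stats::setNames(integer(length(.ATOMIC_MASS)), names(.ATOMIC_MASS))
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("negative element count in formula", call. = FALSE)
  structure(full, class = "chno_formula")
}

#' @export
print.chno_formula <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Format a formula in Hill order
#'
#' @param f A `chno_formula` (or named count vector).
#' @return A single string; `""` for the empty formula.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  ord <- c("C", "H", "D", "N", "O")
  parts <- vapply(ord, function(el) {
    n <- f[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste(parts[nzchar(parts)], collapse = "")
}

as_formula <- function(f) {
  if (inherits(f, "chno_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) return(new_formula(f))
  stop("cannot interpret object as a molecular formula", call. = FALSE)
}

#' Monoisotopic mass of a formula
#'
#' Sum of standard monoisotopic atomic masses over the element counts.
#' Deuterium contributes its own mass (2.0141018 Da).
#'
#' @param formula A `chno_formula` or formula string.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("C8H16O2")  # 144.1150
#' monoisotopic_mass("H2O")      # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula(formula)
  sum(unclass(f) * .ATOMIC_MASS[names(f)])
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1, with deuterium counted as hydrogen. A neutral
#' even-electron molecule must have integral RDBE >= 0.
#'
#' @param formula A `chno_formula` or formula string.
#' @return RDBE (possibly half-integral for radical compositions).
#' @export
rdbe <- function(formula) {
  f <- as_formula(formula)
  f[["C"]] - (f[["H"]] + f[["D"]]) / 2 + f[["N"]] / 2 + 1
}

#' Mass of a proton
#' @return The proton mass in Da, used for the \[M+H\]+ adduct.
#' @export
proton_mass <- function() .PROTON_MASS

# Neutral mass added to an acid on amidation with DMED (C4H12N2, losing H2O).
.light_label_delta <- function() {
  monoisotopic_mass("C4H12N2") - monoisotopic_mass("H2O")
}

#' Derivatization mass delta of a label
#'
#' The light tag is amidation with 2-dimethylaminoethylamine (DMED):
#' + C4H12N2 - H2O = +70.0895 Da on the neutral acid. The heavy tag
#' (d4-DMED) additionally replaces four hydrogens by deuterium.
#'
#' @param tag `"light"` or `"heavy"`.
#' @return Neutral mass delta in Da.
#' @export
label_delta <- function(tag = c("light", "heavy")) {
  tag <- match.arg(tag)
  d <- .light_label_delta()
  if (tag == "heavy") d <- d + pair_mass_delta()
  d
}

#' Mass difference between heavy and light derivatives
#'
#' Four deuterium-for-protium substitutions:
#' 4 x (2.0141018 - 1.0078250) = 4.0251 Da. The exact value (not the
#' 3-decimal 4.025 often printed) is used for all matching.
#'
#' @return The pairing mass delta in Da.
#' @examples
#' round(pair_mass_delta(), 4)  # 4.0251
#' @export
pair_mass_delta <- function() {
  4 * (.ATOMIC_MASS[["D"]] - .ATOMIC_MASS[["H"]])
}

#' Protonated m/z of a labeled fatty-acid derivative
#'
#' m/z of the \[M+H\]+ ion of the DMED (light) or d4-DMED (heavy) amide of
#' a neutral carboxylic acid. The caller is responsible for the formula
#' actually containing a carboxyl group; no structural validation is done.
#'
#' @param neutral_fa Neutral acid formula (`chno_formula` or string).
#' @param tag `"light"` or `"heavy"`.
#' @return m/z in Da.
#' @examples
#' derivative_mz("C8H16O2", "light")  # 215.2118 (caprylic acid + DMED)
#' derivative_mz("C8H16O2", "heavy")  # 219.2369
#' @export
derivative_mz <- function(neutral_fa, tag = c("light", "heavy")) {
  tag <- match.arg(tag)
  monoisotopic_mass(neutral_fa) + label_delta(tag) + .PROTON_MASS
}

#' Default element bounds for formula generation
#'
#' C 0-50, H 0-100, N 0-6, O 0-10: wide enough for very-long-chain FFA
#' derivatives (which carry two nitrogens from the label) within a typical
#' m/z 180-650 scan range.
#'
#' @return Named list of `c(min, max)` integer ranges.
#' @export
default_element_bounds <- function() {
  list(C = c(0L, 50L), H = c(0L, 100L), N = c(0L, 6L), O = c(0L, 10L))
}

#' Generate candidate molecular formulas from an accurate neutral mass
#'
#' Enumerates all CHNO compositions within `bounds` whose monoisotopic mass
#' lies within `tolerance_mda` of `neutral_mass`, optionally filtered to
#' chemically plausible neutral even-electron candidates (RDBE >= 0 and
#' integral). For each C/N/O combination the feasible hydrogen counts are
#' solved directly from the mass window, so the search is fast even for
#' wide bounds.
#'
#' @param neutral_mass Target neutral monoisotopic mass in Da (> 0).
#' @param tolerance_mda Mass tolerance in mDa (default 5.0).
#' @param bounds Per-element count ranges as from [default_element_bounds()].
#' @param rdbe_filter Keep only candidates with integral RDBE >= 0
#'   (default `TRUE`).
#' @return A data.frame with columns `formula` (Hill string), `C`, `H`,
#'   `N`, `O`, `mass`, `error_mda` (signed, observed - candidate) and
#'   `rdbe`, sorted by absolute mass error; ties broken by fewer
#'   heteroatoms (N+O), then fewer atoms.
#' @examples
#' generate_formulas(214.2045)  # contains C12H26N2O
#' @export
generate_formulas <- function(neutral_mass, tolerance_mda = 5.0,
                              bounds = default_element_bounds(),
                              rdbe_filter = TRUE) {
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1L ||
      !is.finite(neutral_mass) || neutral_mass <= 0) {
    stop("neutral_mass must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(tolerance_mda), tolerance_mda > 0)
  tol <- tolerance_mda / 1000
  b <- lapply(c("C", "H", "N", "O"), function(el) {
    r <- bounds[[el]]
    if (is.null(r)) c(0L, 0L) else as.integer(r)
  })
  names(b) <- c("C", "H", "N", "O")
  mH <- .ATOMIC_MASS[["H"]]

  out <- vector("list", 256L); k <- 0L
  for (nC in b$C[1]:b$C[2]) {
    mC <- nC * .ATOMIC_MASS[["C"]]
    if (mC > neutral_mass + tol) break
    for (nN in b$N[1]:b$N[2]) {
      mCN <- mC + nN * .ATOMIC_MASS[["N"]]
      if (mCN > neutral_mass + tol) break
      for (nO in b$O[1]:b$O[2]) {
        rest <- neutral_mass - mCN - nO * .ATOMIC_MASS[["O"]]
        if (rest < -tol) break
        hLo <- max(b$H[1], ceiling((rest - tol) / mH))
        hHi <- min(b$H[2], floor((rest + tol) / mH))
        if (hLo > hHi) next
        for (nH in hLo:hHi) {
          mass <- mCN + nO * .ATOMIC_MASS[["O"]] + nH * mH
          if (abs(mass - neutral_mass) > tol) next
          if (nC + nH + nN + nO == 0L) next
          r <- nC - nH / 2 + nN / 2 + 1
          if (rdbe_filter && (r < 0 || r != floor(r))) next
          k <- k + 1L
          if (k > length(out)) out <- c(out, vector("list", length(out)))
          out[[k]] <- c(nC, nH, nN, nO, mass, r)
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(formula = character(), C = integer(), H = integer(),
                      N = integer(), O = integer(), mass = numeric(),
                      error_mda = numeric(), rdbe = numeric(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out[seq_len(k)])
  df <- data.frame(C = as.integer(m[, 1]), H = as.integer(m[, 2]),
                   N = as.integer(m[, 3]), O = as.integer(m[, 4]),
                   mass = m[, 5], rdbe = m[, 6], stringsAsFactors = FALSE)
  df$error_mda <- (neutral_mass - df$mass) * 1000
  df$formula <- vapply(seq_len(nrow(df)), function(i) {
    format_formula(new_formula(c(C = df$C[i], H = df$H[i],
                                 N = df$N[i], O = df$O[i])))
  }, character(1))
  ord <- order(abs(df$error_mda), df$N + df$O, df$C + df$H + df$N + df$O)
  df <- df[ord, c("formula", "C", "H", "N", "O", "mass", "error_mda", "rdbe")]
  rownames(df) <- NULL
  df
}
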