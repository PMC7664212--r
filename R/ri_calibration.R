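#' Expected m/z values of the heavy-labeled alkanoic-acid ladder
#'
#' The retention-index ladder is the homologous series of straight-chain
#' alkanoic acids CnH2nO2 labeled with the heavy (d4-DMED) tag; by
#' convention each Cn:0 standard anchors RI = 100 * n.
#'
#' @param carbons Integer vector of chain lengths (default 5:24).
#' @return Data.frame with `carbon`, `formula`, `mz` (heavy derivative) and
#'   `ri`.
#' @export
ladder_mz <- function(carbons = 5:24) {
  stopifnot(all(carbons >= 1))
  formula <- sprintf("C%dH%dO2", carbons, 2 * carbons)
  data.frame(carbon = as.integer(carbons), formula = formula,
             mz = vapply(formula, derivative_mz, numeric(1),
                         tag = "heavy", USE.NAMES = FALSE),
             ri = 100 * as.integer(carbons), stringsAsFactors = FALSE)
}

#' Detect the internal-standard ladder in one run
#'
#' For each expected ladder m/z the most intense peak within
#' `mz_tolerance_mda` is taken as that standard's anchor. If one peak is
#' the best candidate for two adjacent standards it is assigned to the
#' closer expected m/z and the other standard counts as missing. Anchor
#' retention times must be strictly increasing with chain length
#' (a co-eluting homologous ladder is physically invalid).
#'
#' @param peaks A `peak_list` for a single run.
#' @param mz_tolerance_mda Matching tolerance in mDa (default 5.0).
#' @param carbons Ladder chain lengths (default 5:24).
#' @return An `ri_calibration` object: list with `anchors` (data.frame of
#'   detected standards: carbon, mz_expected, mz, rt, intensity, ri),
#'   `missing` (undetected chain lengths), `completeness` (detected /
#'   expected) and `n_expected`.
#' @export
detect_ladder <- function(peaks, mz_tolerance_mda = 5.0, carbons = 5:24) {
  stopifnot(is.data.frame(peaks))
  lad <- ladder_mz(carbons)
  tol <- mz_tolerance_mda / 1000
  hit <- integer(0)     # peak row index per matched standard
  hit_std <- integer(0) # row in lad
  for (i in seq_len(nrow(lad))) {
    cand <- which(abs(peaks$mz - lad$mz[i]) <= tol)
    if (!length(cand)) next
    j <- cand[which.max(peaks$intensity[cand])]
    if (j %in% hit) {
      prev <- hit_std[match(j, hit)]
      # one peak claimed by two standards: keep the closer expected m/z
      if (abs(peaks$mz[j] - lad$mz[i]) < abs(peaks$mz[j] - lad$mz[prev])) {
        keep <- hit != j
        hit <- hit[keep]; hit_std <- hit_std[keep]
      } else {
        next
      }
    }
    hit <- c(hit, j); hit_std <- c(hit_std, i)
  }
  ord <- order(lad$carbon[hit_std])
  hit <- hit[ord]; hit_std <- hit_std[ord]
  anchors <- data.frame(
    carbon = lad$carbon[hit_std],
    mz_expected = lad$mz[hit_std],
    mz = peaks$mz[hit],
    rt = peaks$rt[hit],
    intensity = peaks$intensity[hit],
    ri = lad$ri[hit_std],
    stringsAsFactors = FALSE
  )
  if (nrow(anchors) >= 2 && any(diff(anchors$rt) <= 0)) {
    stop("ladder anchors are not strictly increasing in retention time; ",
         "co-eluting standards are physically invalid", call. = FALSE)
  }
  structure(list(anchors = anchors,
                 missing = setdiff(lad$carbon, anchors$carbon),
                 completeness = nrow(anchors) / nrow(lad),
                 n_expected = nrow(lad)),
            class = "ri_calibration")
}

#' @export
print.ri_calibration <- function(x, ...) {
  cat(sprintf("RI calibration: %d/%d ladder standards detected\n",
              nrow(x$anchors), x$n_expected))
  if (length(x$missing)) {
    cat("missing: C", paste(x$missing, collapse = ", C"), "\n", sep = "")
  }
  invisible(x)
}

#' Map retention time to retention index
#'
#' Piecewise-linear interpolation between ladder anchors, with linear
#' extrapolation using the first/last segment slope outside the anchor
#' range; exact at anchors and strictly increasing in rt.
#'
#' @param cal An `ri_calibration` with at least 2 anchors.
#' @param rt Retention time(s), minutes.
#' @return Retention index value(s).
#' @export
rt_to_ri <- function(cal, rt) {
  stopifnot(inherits(cal, "ri_calibration"))
  a <- cal$anchors
  if (nrow(a) < 2) {
    stop("RI calibration needs at least 2 ladder anchors (got ",
         nrow(a), ")", call. = FALSE)
  }
  x <- a$rt; y <- a$ri; n <- length(x)
  seg <- findInterval(rt, x, all.inside = TRUE)  # clamp to end segments
  y[seg] + (rt - x[seg]) * (y[seg + 1] - y[seg]) / (x[seg + 1] - x[seg])
}

#' @rdname rt_to_ri
#' @param peaks A `peak_list`; its `ri` column is (re)computed from `rt`.
#' @return For `calibrate_peaks()`: the peak list with an `ri` column.
#' @export
calibrate_peaks <- function(peaks, cal) {
  peaks$ri <- rt_to_ri(cal, peaks$rt)
  peaks
}

#' Per-run calibration report
#'
#' @param cal An `ri_calibration`.
#' @return Data.frame: expected m/z, matched rt/intensity, assigned RI, and
#'   overall completeness (repeated per row for CSV friendliness).
#' @export
calibration_report <- function(cal) {
  stopifnot(inherits(cal, "ri_calibration"))
  a <- cal$anchors
  data.frame(a, completeness = cal$completeness, stringsAsFactors = FALSE)
}
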