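#' Sample QC by internal-standard ladder completeness
#'
#' Runs whose detected ladder completeness falls below
#' `required_fraction` of the expected standards are excluded (default:
#' all 20 must be present — a run with any partially detected standards is
#' removed, matching the strictest reading of the spiked-ladder design).
#'
#' @param calibrations Named list of `ri_calibration` objects, one per
#'   sample (names are sample ids).
#' @param required_fraction Fraction of expected standards required
#'   (default 1.0).
#' @return List with `kept` (sample ids), `excluded` (sample ids) and
#'   `report` (data.frame: sample_id, detected, expected, completeness,
#'   excluded, missing standards as a comma-joined string).
#' @export
qc_samples <- function(calibrations, required_fraction = 1.0) {
  stopifnot(is.list(calibrations), length(calibrations) > 0,
            !is.null(names(calibrations)))
  report <- do.call(rbind, lapply(names(calibrations), function(id) {
    cal <- calibrations[[id]]
    stopifnot(inherits(cal, "ri_calibration"))
    data.frame(sample_id = id,
               detected = nrow(cal$anchors),
               expected = cal$n_expected,
               completeness = cal$completeness,
               excluded = cal$completeness < required_fraction,
               missing = paste(cal$missing, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  kept <- report$sample_id[!report$excluded]
  if (!length(kept)) {
    stop("all samples excluded by ladder-completeness QC; ",
         "pipeline cannot proceed", call. = FALSE)
  }
  list(kept = kept, excluded = report$sample_id[report$excluded],
       report = report)
}

#' Normalize analyte intensities by the nearest internal standard
#'
#' Each analyte's normalized value is its intensity divided by the
#' intensity of the ladder standard with the nearest RI in the same run
#' (RI ties go to the lower carbon number). Normalization is per run, so
#' any global per-run intensity scale (injection/ionization drift) cancels
#' exactly.
#'
#' @param intensity Analyte intensities (one run).
#' @param ri Analyte retention indices (same length).
#' @param cal The run's `ri_calibration` (anchor intensities are the
#'   standard intensities).
#' @return Numeric vector of normalized relative concentrations.
#' @export
normalize_by_ladder <- function(intensity, ri, cal) {
  stopifnot(inherits(cal, "ri_calibration"))
  a <- cal$anchors
  if (!nrow(a)) stop("no ladder anchors available for normalization",
                     call. = FALSE)
  idx <- vapply(ri, function(r) {
    d <- abs(a$ri - r)
    which(d == min(d))[1]  # anchors sorted by carbon: ties -> lower carbon
  }, integer(1))
  intensity / a$intensity[idx]
}

#' Build a samples x FFAs abundance table
#'
#' Groups light analyte peaks across QC-passing samples into consensus
#' features (same windows as cross-sample pair merging), normalizes each
#' sample's intensities by its nearest-RI internal standard, and assembles
#' the samples x FFAs matrix. An FFA not detected in a sample is an
#' explicit `NA`, never zero.
#'
#' @param peaks_by_sample Named list of RI-calibrated `peak_list`s (light
#'   analyte peaks only; ladder peaks should be removed first, see
#'   [drop_ladder_peaks()]).
#' @param calibrations Named list of `ri_calibration`s for the same
#'   samples.
#' @param regions Named character vector: region per sample id.
#' @param params [pairing_params()]; the dedup windows are used for
#'   feature grouping.
#' @return An `abundance_table`: list with `values` (samples x FFAs matrix
#'   of normalized values), `samples` (data.frame sample_id, region,
#'   completeness), `features` (data.frame ffa_id, mz, ri).
#' @export
build_abundance_table <- function(peaks_by_sample, calibrations, regions,
                                  params = pairing_params()) {
  stopifnot(is.list(peaks_by_sample), !is.null(names(peaks_by_sample)),
            all(names(peaks_by_sample) %in% names(calibrations)))
  ids <- names(peaks_by_sample)
  long <- do.call(rbind, lapply(ids, function(id) {
    p <- peaks_by_sample[[id]]
    if (!nrow(p)) return(NULL)
    data.frame(sample_id = id, mz = p$mz, ri = p$ri,
               value = normalize_by_ladder(p$intensity, p$ri,
                                           calibrations[[id]]),
               intensity = p$intensity, stringsAsFactors = FALSE)
  }))
  if (is.null(long) || !nrow(long)) stop("no analyte peaks to quantify",
                                         call. = FALSE)
  grp <- .cluster_features(long$mz, long$ri, long$intensity,
                           params$dedup_mz_tolerance / 1000,
                           params$dedup_ri_tolerance)
  feat <- grp$centroids
  feat$ffa_id <- sprintf("FFA%04d", seq_len(nrow(feat)))
  values <- matrix(NA_real_, nrow = length(ids), ncol = nrow(feat),
                   dimnames = list(ids, feat$ffa_id))
  best <- matrix(-Inf, nrow = length(ids), ncol = nrow(feat),
                 dimnames = dimnames(values))
  for (k in seq_len(nrow(long))) {
    i <- long$sample_id[k]; j <- grp$cluster[k]
    # duplicate detections of one feature in one run: keep the more intense
    if (long$intensity[k] > best[i, j]) {
      best[i, j] <- long$intensity[k]
      values[i, j] <- long$value[k]
    }
  }
  structure(list(
    values = values,
    samples = data.frame(sample_id = ids,
                         region = unname(regions[ids]),
                         completeness = vapply(ids, function(id)
                           calibrations[[id]]$completeness, numeric(1)),
                         stringsAsFactors = FALSE),
    features = feat[, c("ffa_id", "mz", "ri")]
  ), class = "abundance_table")
}

# Consensus clustering in (mz, ri), shared by cross-sample pair merging
# and quantitation. Observations are first chained by single linkage in
# m/z (a gap > mz_tol starts a new chain: detections of one feature form a
# dense cloud, distinct features are well separated); each chain is then
# split along RI by a running-mean rule (an observation more than ri_tol
# from the current cluster's mean RI starts a new cluster). Deterministic
# and independent of input row order.
.cluster_features <- function(mz, ri, w, mz_tol, ri_tol) {
  n <- length(mz)
  o <- order(mz, ri, w)
  chain <- cumsum(c(1, diff(mz[o]) > mz_tol))
  cluster <- integer(n)
  nclust <- 0L
  for (ch in unique(chain)) {
    idx <- o[chain == ch]
    idx <- idx[order(ri[idx], mz[idx])]
    cm <- ri[idx[1]]; cn <- 1L; nclust <- nclust + 1L
    cluster[idx[1]] <- nclust
    for (i in idx[-1]) {
      if (abs(ri[i] - cm) <= ri_tol) {
        cm <- (cm * cn + ri[i]) / (cn + 1L); cn <- cn + 1L
      } else {
        nclust <- nclust + 1L; cm <- ri[i]; cn <- 1L
      }
      cluster[i] <- nclust
    }
  }
  cmz <- vapply(seq_len(nclust), function(k) {
    s <- cluster == k; sum(mz[s] * w[s]) / sum(w[s])
  }, numeric(1))
  cri <- vapply(seq_len(nclust), function(k) {
    s <- cluster == k; sum(ri[s] * w[s]) / sum(w[s])
  }, numeric(1))
  ord <- order(cmz, cri)
  list(cluster = match(cluster, ord),
       centroids = data.frame(mz = cmz[ord], ri = cri[ord]))
}

#' Remove internal-standard ladder peaks from a run
#'
#' Drops peaks within `mz_tolerance_mda` of any expected heavy ladder m/z,
#' so that only analyte features enter quantitation.
#'
#' @param peaks A `peak_list`.
#' @param mz_tolerance_mda Window in mDa (default 5.0).
#' @param carbons Ladder chain lengths (default 5:24).
#' @return The peak list without ladder peaks.
#' @export
drop_ladder_peaks <- function(peaks, mz_tolerance_mda = 5.0, carbons = 5:24) {
  lad <- ladder_mz(carbons)
  tol <- mz_tolerance_mda / 1000
  keep <- vapply(peaks$mz, function(m) all(abs(lad$mz - m) > tol), logical(1))
  peaks[keep, , drop = FALSE]
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d samples x %d FFAs (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  print(table(x$samples$region))
  invisible(x)
}

#' @export
as.data.frame.abundance_table <- function(x, ...) {
  data.frame(sample_id = x$samples$sample_id, region = x$samples$region,
             x$values, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write an abundance table (samples x FFAs with region column)
#'
#' @param x An `abundance_table`.
#' @param path Output path.
#' @param header Optional comment lines.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, header = NULL) {
  .write_csv(as.data.frame(x), path, header)
}
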