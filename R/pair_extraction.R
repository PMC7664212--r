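#' Pairing parameters
#'
#' Tolerances for light/heavy pair extraction and cross-sample merging.
#' The mass-difference tolerance reuses the instrument accuracy of 5.0 mDa;
#' "same retention index" is quantified as +/- 5 RI units and "similar
#' intensities" as a maximum fold difference of 5 (1:1 labeling implies a
#' near-unity ratio; the generous bound tolerates deuterium ionization
#' effects).
#'
#' @param mass_delta_tolerance mDa window around the exact 4.0251 Da delta.
#' @param ri_tolerance Maximum |RI(light) - RI(heavy)|.
#' @param max_intensity_fold Maximum fold difference light vs heavy (>= 1).
#' @param dedup_mz_tolerance mDa window for cross-sample merging.
#' @param dedup_ri_tolerance RI window for cross-sample merging.
#' @return A `pairing_params` list.
#' @export
pairing_params <- function(mass_delta_tolerance = 5.0, ri_tolerance = 5,
                           max_intensity_fold = 5,
                           dedup_mz_tolerance = 5.0, dedup_ri_tolerance = 5) {
  p <- list(mass_delta_tolerance = mass_delta_tolerance,
            ri_tolerance = ri_tolerance,
            max_intensity_fold = max_intensity_fold,
            dedup_mz_tolerance = dedup_mz_tolerance,
            dedup_ri_tolerance = dedup_ri_tolerance)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                   !is.finite(v) || v <= 0, logical(1)))) {
    stop("all pairing tolerances must be single positive numbers",
         call. = FALSE)
  }
  if (max_intensity_fold < 1) {
    stop("max_intensity_fold must be >= 1", call. = FALSE)
  }
  structure(p, class = "pairing_params")
}

#' Extract light/heavy peak pairs from one RI-calibrated run
#'
#' A pair (light, heavy) is emitted iff
#' |(heavy.mz - light.mz) - 4.0251| <= mass tolerance,
#' |RI difference| <= RI tolerance, and the intensity fold difference is at
#' most `max_intensity_fold`. Each peak participates in at most one pair:
#' candidates are assigned greedily in ascending |mass error|, ties broken
#' by ascending RI gap, then ascending light m/z. The result does not
#' depend on the input row order.
#'
#' @param peaks A `peak_list` for one run with `ri` set (see
#'   [calibrate_peaks()]).
#' @param params A [pairing_params()] object.
#' @return A `pair_table` data.frame: light/heavy mz, rt, ri, intensity,
#'   `mass_error_mda` (signed: observed delta - 4.0251, in mDa), `ri_gap`,
#'   `intensity_ratio` (light/heavy), `sample_id`, `region`.
#' @export
extract_pairs <- function(peaks, params = pairing_params()) {
  stopifnot(is.data.frame(peaks), inherits(params, "pairing_params"))
  if (!"ri" %in% names(peaks) || anyNA(peaks$ri)) {
    stop("extract_pairs requires RI-calibrated peaks; run calibrate_peaks()",
         call. = FALSE)
  }
  delta <- pair_mass_delta()
  tol <- params$mass_delta_tolerance / 1000
  ord <- order(peaks$mz, peaks$ri, peaks$intensity)
  pk <- peaks[ord, , drop = FALSE]
  n <- nrow(pk)
  # for each light candidate, heavy candidates lie in [mz + delta - tol, + tol]
  lo <- findInterval(pk$mz + delta - tol, pk$mz) + 1L
  hi <- findInterval(pk$mz + delta + tol, pk$mz)
  li <- rep.int(seq_len(n), pmax(hi - lo + 1L, 0L))
  hj <- unlist(lapply(seq_len(n)[hi >= lo], function(i) lo[i]:hi[i]),
               use.names = FALSE)
  if (!length(li)) return(.empty_pair_table())
  mass_err <- pk$mz[hj] - pk$mz[li] - delta
  ri_gap <- abs(pk$ri[hj] - pk$ri[li])
  ratio <- pk$intensity[li] / pk$intensity[hj]
  keep <- abs(mass_err) <= tol & ri_gap <= params$ri_tolerance &
    pmax(ratio, 1 / ratio) <= params$max_intensity_fold
  li <- li[keep]; hj <- hj[keep]
  mass_err <- mass_err[keep]; ri_gap <- ri_gap[keep]; ratio <- ratio[keep]
  if (!length(li)) return(.empty_pair_table())
  o <- order(abs(mass_err), ri_gap, pk$mz[li])
  used <- logical(n)
  sel <- logical(length(o))
  for (k in o) {
    if (!used[li[k]] && !used[hj[k]]) {
      used[li[k]] <- used[hj[k]] <- TRUE
      sel[k] <- TRUE
    }
  }
  li <- li[sel]; hj <- hj[sel]
  out <- data.frame(
    light_mz = pk$mz[li], heavy_mz = pk$mz[hj],
    light_rt = pk$rt[li], heavy_rt = pk$rt[hj],
    light_ri = pk$ri[li], heavy_ri = pk$ri[hj],
    light_intensity = pk$intensity[li], heavy_intensity = pk$intensity[hj],
    mass_error_mda = mass_err[sel] * 1000,
    ri_gap = ri_gap[sel],
    intensity_ratio = ratio[sel],
    sample_id = pk$sample_id[li],
    region = if ("region" %in% names(pk)) pk$region[li] else NA_character_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$light_mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pair_table", "data.frame"))
}

.empty_pair_table <- function() {
  structure(data.frame(light_mz = numeric(), heavy_mz = numeric(),
                       light_rt = numeric(), heavy_rt = numeric(),
                       light_ri = numeric(), heavy_ri = numeric(),
                       light_intensity = numeric(),
                       heavy_intensity = numeric(),
                       mass_error_mda = numeric(), ri_gap = numeric(),
                       intensity_ratio = numeric(),
                       sample_id = character(), region = character(),
                       stringsAsFactors = FALSE),
            class = c("pair_table", "data.frame"))
}

#' Merge peak pairs across samples into potential FFAs
#'
#' Pairs whose light m/z agree within `dedup_mz_tolerance` and RI within
#' `dedup_ri_tolerance` are merged into one potential FFA. Consensus m/z
#' and RI are intensity-weighted means over the member pairs; per-region
#' presence is recorded in one logical column per region. Merging is
#' deterministic (pairs are processed in ascending light m/z) and
#' independent of the order of the input tables.
#'
#' @param pair_tables A `pair_table` or list of them (one per run).
#' @param params A [pairing_params()] object.
#' @param regions Region vocabulary for the presence columns; defaults to
#'   the regions observed in the data.
#' @return A `ffa_table` data.frame: `ffa_id`, consensus `mz` (light),
#'   `ri`, `mean_intensity`, `n_samples`, `n_pairs`, then one logical
#'   `in_<region>` column per region.
#' @export
merge_pairs <- function(pair_tables, params = pairing_params(),
                        regions = NULL) {
  if (is.data.frame(pair_tables)) pair_tables <- list(pair_tables)
  all <- do.call(rbind, lapply(pair_tables, as.data.frame))
  if (is.null(all) || !nrow(all)) {
    out <- data.frame(ffa_id = character(), mz = numeric(), ri = numeric(),
                      mean_intensity = numeric(), n_samples = integer(),
                      n_pairs = integer(), stringsAsFactors = FALSE)
    return(structure(out, class = c("ffa_table", "data.frame")))
  }
  grp <- .cluster_features(all$light_mz, all$light_ri, all$light_intensity,
                           params$dedup_mz_tolerance / 1000,
                           params$dedup_ri_tolerance)
  cluster <- grp$cluster
  ids <- seq_len(nrow(grp$centroids))
  out <- data.frame(
    mz = grp$centroids$mz, ri = grp$centroids$ri,
    mean_intensity = vapply(ids, function(k)
      mean(all$light_intensity[cluster == k]), numeric(1)),
    n_samples = vapply(ids, function(k)
      length(unique(all$sample_id[cluster == k])), integer(1)),
    n_pairs = vapply(ids, function(k) sum(cluster == k), integer(1)),
    stringsAsFactors = FALSE
  )
  out$ffa_id <- sprintf("FFA%04d", ids)
  if (is.null(regions)) {
    regions <- sort(unique(stats::na.omit(all$region)))
  }
  for (rg in regions) {
    out[[paste0("in_", rg)]] <- vapply(seq_len(nrow(out)), function(k)
      any(all$region[cluster == k] == rg, na.rm = TRUE), logical(1))
  }
  out <- out[, c("ffa_id", setdiff(names(out), "ffa_id")), drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ffa_table", "data.frame"))
}
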