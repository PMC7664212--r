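#' Per-region presence sets of potential FFAs
#'
#' @param ffas A `ffa_table` from [merge_pairs()] with `in_<region>`
#'   presence columns.
#' @param regions Regions to extract; default: all presence columns, in
#'   the packaged 13-region order where applicable.
#' @return Named list of character vectors of `ffa_id`s per region.
#' @export
presence_sets <- function(ffas, regions = NULL) {
  stopifnot(is.data.frame(ffas))
  avail <- sub("^in_", "", grep("^in_", names(ffas), value = TRUE))
  if (is.null(regions)) {
    regions <- c(intersect(default_regions(), avail),
                 setdiff(avail, default_regions()))
  }
  unknown <- setdiff(regions, avail)
  if (length(unknown)) {
    stop("unknown region label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(regions, function(rg) ffas$ffa_id[ffas[[paste0("in_", rg)]]])
  names(sets) <- regions
  sets
}

#' Pairwise common-FFA counts between regions
#'
#' `M[a, b]` is the number of FFAs present in both region a and region b;
#' the diagonal holds per-region totals. Symmetric by construction.
#'
#' @param sets Named list of FFA-id sets (see [presence_sets()]).
#' @return Symmetric integer matrix with region dimnames.
#' @export
common_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  rg <- names(sets)
  m <- matrix(0L, length(rg), length(rg), dimnames = list(rg, rg))
  for (i in seq_along(rg)) {
    for (j in i:length(rg)) {
      m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}

#' Asymmetric ratio matrix of common FFAs
#'
#' `R[a, b] = common(a, b) / |set(a)|`: the fraction of region a's FFAs
#' that are also found in region b (the denominator is the row region).
#' The diagonal is 1 and `R[a,b] * |a| = R[b,a] * |b|` holds exactly.
#'
#' @param common Symmetric counts matrix from [common_matrix()].
#' @param sizes Named per-region set sizes; default: `diag(common)`.
#' @return Numeric matrix of ratios in (0, 1].
#' @export
ratio_matrix <- function(common, sizes = diag(common)) {
  stopifnot(is.matrix(common))
  if (any(sizes <= 0)) {
    stop("empty region set(s): ",
         paste(rownames(common)[sizes <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(common, 1, sizes, "/")
}
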