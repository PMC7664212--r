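#' The 13 brain-region abbreviations used as the default region vocabulary
#'
#' Olfactory bulb, frontal/parietal/occipital/temporal cortex, hippocampus,
#' striatum, midbrain, thalamus, hypothalamus, cerebellum, medulla-pons and
#' brainstem. Region labels in feature tables are free strings; this vector
#' is the packaged default ordering for region matrices.
#'
#' @return Character vector of region codes.
#' @export
default_regions <- function() {
  c("OB", "FC", "PC", "OC", "TC", "HP", "STR", "MID", "THA", "HYP",
    "CE", "MEA", "BS")
}

.required_peak_cols <- c("mz", "rt", "intensity", "sample_id")

#' Read a centroided LC-MS feature table
#'
#' Canonical interchange format: comma-delimited, UTF-8, dot decimal, with
#' header columns `mz`, `rt`, `intensity`, `sample_id` and optionally
#' `region` and `ri`. Rows violating the peak invariants (mz > 0, rt >= 0,
#' intensity > 0, ri >= 0 if present) are rejected, counted and reported
#' via a message; they are never silently dropped.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default `","`).
#' @return A `peak_list`: a data.frame of validated peaks in original row
#'   order, with attribute `n_rejected` (count of rejected rows) and
#'   `rejected` (their original line numbers).
#' @export
read_feature_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(.required_peak_cols, names(df))
  if (length(missing)) {
    stop("feature table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c("mz", "rt", "intensity", "ri"), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric ", col, " at data line(s): ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      df[[col]] <- vn
    }
  }
  df$sample_id <- as.character(df$sample_id)
  if ("region" %in% names(df)) df$region <- as.character(df$region)
  as_peak_list(df)
}

#' Validate a data.frame of peaks
#'
#' @param df Data.frame with at least `mz`, `rt`, `intensity`, `sample_id`.
#' @return A validated `peak_list` (see [read_feature_table()]).
#' @export
as_peak_list <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.required_peak_cols, names(df))
  if (length(missing)) {
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ok <- is.finite(df$mz) & df$mz > 0 &
    is.finite(df$rt) & df$rt >= 0 &
    is.finite(df$intensity) & df$intensity > 0
  if ("ri" %in% names(df)) ok <- ok & (is.na(df$ri) | df$ri >= 0)
  rejected <- which(!ok)
  if (length(rejected)) {
    message(length(rejected), " row(s) rejected by peak invariants (lines ",
            paste(utils::head(rejected, 10), collapse = ", "), ")")
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_rejected = length(rejected), rejected = rejected,
            class = c("peak_list", "data.frame"))
}

.fa_classes <- c("saturated FA", "monounsaturated FA", "polyunsaturated FA",
                 "bile acid", "other")

#' Read a labeled-standards FFA library
#'
#' Delimited file with columns `name`, `formula`, `reference_ri`, `class`.
#' Formulas are parsed via [parse_formula()]; the light/heavy derivative
#' m/z of each entry is precomputed. The packaged default is a synthetic
#' stand-in library (the original in-house web library is not published):
#' see `system.file("extdata", "ffa_library_synthetic.csv",
#' package = "cilffa")`.
#'
#' @param path Path to the library file; defaults to the packaged
#'   synthetic library.
#' @return A `ffa_library` data.frame with added columns `mass`,
#'   `mz_light`, `mz_heavy`.
#' @export
read_library <- function(path = system.file("extdata",
                                            "ffa_library_synthetic.csv",
                                            package = "cilffa")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("library file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "formula", "reference_ri", "class")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("library is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- df$name[duplicated(df$name)]
  if (length(dup)) {
    stop("duplicate library entry name(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$reference_ri) | df$reference_ri <= 0)) {
    stop("library reference_ri must be > 0", call. = FALSE)
  }
  bad_class <- setdiff(unique(df$class), .fa_classes)
  if (length(bad_class)) {
    stop("unknown compound class(es): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  df$mass <- vapply(df$formula, function(s) {
    tryCatch(monoisotopic_mass(s),
             error = function(e) stop("library entry with bad formula: '",
                                      s, "' (", conditionMessage(e), ")",
                                      call. = FALSE))
  }, numeric(1), USE.NAMES = FALSE)
  df$mz_light <- df$mass + label_delta("light") + proton_mass()
  df$mz_heavy <- df$mass + label_delta("heavy") + proton_mass()
  structure(df, class = c("ffa_library", "data.frame"))
}

#' @export
print.ffa_library <- function(x, ...) {
  cat("FFA library:", nrow(x), "entries\n")
  print(table(x$class))
  invisible(x)
}

#' Write / read a peak-pair table
#'
#' Plain CSV round trip; values survive to at least 6 significant figures.
#'
#' @param pairs A `pair_table` data.frame from [extract_pairs()].
#' @param path Output path.
#' @param header Optional comment lines (without `#`) written atop the file.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path, header = NULL) {
  .write_csv(as.data.frame(pairs), path, header)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("pair table not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write / read a labeled numeric matrix (e.g. region count/ratio matrix)
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param header Optional comment lines written atop the file.
#' @return `path`, invisibly ([write_matrix()]); a matrix ([read_matrix()]).
#' @export
write_matrix <- function(m, path, header = NULL) {
  stopifnot(is.matrix(m))
  df <- data.frame(region = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_csv(df, path, header)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

.write_csv <- function(df, path, header = NULL) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
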