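# Polynomial rolling hash of a deparsed object (mod 2^31 - 1); stamps
# output files so two runs with equal config hashes are identical.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.stage <- function(name, expr, log) {
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  log(name, res)
  res
}

.make_logger <- function(verbose) {
  records <- list()
  log <- function(stage, result) {
    n <- if (is.data.frame(result)) nrow(result) else length(result)
    records[[stage]] <<- n
    if (verbose) message(sprintf("[%s] ok (%s records)", stage, n))
  }
  list(log = log, records = function() records)
}

#' Run the qualitative pipeline end to end
#'
#' Stages, in order: ladder detection, RI calibration, light/heavy pair
#' extraction per run, cross-sample merging into potential FFAs, library /
#' formula annotation, and the region common-count and ratio matrices.
#' A failing stage aborts with a stage-named error; results computed up to
#' that point are preserved in the error condition's `partial` attribute
#' when `out_dir` is used.
#'
#' @param features A `peak_list` covering one run per sample (columns
#'   `sample_id`, `region`).
#' @param library A `ffa_library` or path to one.
#' @param params [pairing_params()].
#' @param out_dir Optional directory: intermediate CSV artifacts are
#'   written there, each stamped with the config hash and seed.
#' @param seed Seed recorded in output headers (the pipeline itself is
#'   deterministic).
#' @param verbose Emit per-stage log messages (default `FALSE`).
#' @return List: `calibrations`, `pairs` (per run), `ffas` (merged table),
#'   `annotation`, `sets`, `common`, `ratios`, `counts`, `log`.
#' @export
run_qualitative <- function(features, library = read_library(),
                            params = pairing_params(), out_dir = NULL,
                            seed = NA_integer_, verbose = FALSE) {
  if (is.character(library)) library <- read_library(library)
  lg <- .make_logger(verbose)
  runs <- split(as.data.frame(features), features$sample_id)
  cals <- .stage("ladder_detection",
                 lapply(runs, detect_ladder,
                        mz_tolerance_mda = params$mass_delta_tolerance),
                 lg$log)
  runs <- .stage("ri_calibration",
                 lapply(names(runs), function(id)
                   calibrate_peaks(runs[[id]], cals[[id]])),
                 lg$log)
  pairs <- .stage("pair_extraction",
                  lapply(runs, extract_pairs, params = params), lg$log)
  ffas <- .stage("merge", merge_pairs(pairs, params), lg$log)
  ann <- .stage("annotation", annotate_ffas(ffas, library), lg$log)
  sets <- .stage("presence_sets", presence_sets(ffas), lg$log)
  common <- .stage("common_matrix", common_matrix(sets), lg$log)
  ratios <- .stage("ratio_matrix", ratio_matrix(common), lg$log)
  out <- list(calibrations = cals, pairs = pairs, ffas = ffas,
              annotation = ann, sets = sets, common = common,
              ratios = ratios,
              counts = vapply(sets, length, integer(1)),
              log = lg$records())
  if (!is.null(out_dir)) .write_qual_outputs(out, out_dir, params, seed)
  out
}

.run_header <- function(params, seed) {
  sprintf("config_hash=%s seed=%s", .config_hash(unclass(params)), seed)
}

.write_qual_outputs <- function(out, out_dir, params, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .run_header(params, seed)
  all_pairs <- do.call(rbind, out$pairs)
  write_pair_table(all_pairs, file.path(out_dir, "pairs.csv"), hdr)
  .write_csv(as.data.frame(out$ffas), file.path(out_dir, "ffas.csv"), hdr)
  .write_csv(out$annotation, file.path(out_dir, "annotation.csv"), hdr)
  write_matrix(out$common, file.path(out_dir, "common_matrix.csv"), hdr)
  write_matrix(out$ratios, file.path(out_dir, "ratio_matrix.csv"), hdr)
  invisible(out_dir)
}

#' Run the quantitative pipeline end to end
#'
#' Stages, in order: ladder detection per sample, ladder-completeness QC,
#' RI calibration, internal-standard normalization into the samples x
#' FFAs abundance table, per-FFA transform gating + one-way ANOVA, PCA and
#' OPLS-DA on the imputed matrix, and the joint VIP > `vip_cut` and
#' p < `p_cut` selection.
#'
#' @param features A `peak_list` covering all sample runs (light analytes
#'   + heavy ladder per run).
#' @param params [pairing_params()].
#' @param required_fraction QC ladder completeness threshold (default 1.0).
#' @param p_cut,vip_cut Selection thresholds (defaults 0.05 and 1.0).
#' @param fdr Apply BH correction in the selection (default `FALSE`).
#' @param out_dir Optional output directory for CSV artifacts.
#' @param seed Seed recorded in output headers.
#' @param verbose Emit per-stage log messages.
#' @return List: `qc`, `abundance` (an `abundance_table`), `anova`,
#'   `pca`, `oplsda`, `selection` (selected ffa ids with decision table
#'   attribute), `log`.
#' @export
run_quantitative <- function(features, params = pairing_params(),
                             required_fraction = 1.0,
                             p_cut = 0.05, vip_cut = 1.0, fdr = FALSE,
                             out_dir = NULL, seed = NA_integer_,
                             verbose = FALSE) {
  lg <- .make_logger(verbose)
  runs <- split(as.data.frame(features), features$sample_id)
  cals <- .stage("ladder_detection",
                 lapply(runs, detect_ladder,
                        mz_tolerance_mda = params$mass_delta_tolerance),
                 lg$log)
  qc <- .stage("qc", qc_samples(cals, required_fraction), lg$log)
  runs <- runs[qc$kept]
  regions <- vapply(runs, function(r) r$region[1], character(1))
  analyte <- .stage("ri_calibration", lapply(qc$kept, function(id)
    drop_ladder_peaks(calibrate_peaks(runs[[id]], cals[[id]]),
                      params$mass_delta_tolerance)), lg$log)
  names(analyte) <- qc$kept
  ab <- .stage("normalization",
               build_abundance_table(analyte, cals, regions, params),
               lg$log)
  anova <- .stage("anova",
                  anova_table(ab$values, ab$samples$region), lg$log)
  prep <- .stage("prepare_matrix", prepare_matrix(ab), lg$log)
  pca <- .stage("pca", fit_pca(prep$X, ncomp = 2), lg$log)
  opls <- .stage("oplsda", fit_oplsda(prep$X, prep$groups), lg$log)
  p <- stats::setNames(anova$p, anova$ffa_id)[colnames(prep$X)]
  sel <- .stage("selection",
                select_significant(p, vip(opls), p_cut, vip_cut, fdr),
                lg$log)
  out <- list(qc = qc, abundance = ab, anova = anova, pca = pca,
              oplsda = opls, selection = sel, log = lg$records())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .run_header(params, seed)
    write_abundance_table(ab, file.path(out_dir, "abundance.csv"), hdr)
    .write_csv(qc$report, file.path(out_dir, "qc_report.csv"), hdr)
    .write_csv(anova, file.path(out_dir, "anova.csv"), hdr)
    .write_csv(attr(sel, "table"), file.path(out_dir, "selection.csv"), hdr)
    .write_csv(data.frame(metric = c("R2X", "R2Y", "Q2"),
                          value = c(opls$R2X, opls$R2Y, opls$Q2)),
               file.path(out_dir, "oplsda_summary.csv"), hdr)
  }
  out
}
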