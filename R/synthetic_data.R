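# Fixed chromatography model for simulated runs: anchor retention times of
# the Cn:0 ladder follow a mildly convex gradient (minutes), and any RI is
# mapped to RT by piecewise-linear interpolation through those anchors.
.sim_anchor_rt <- function(n) 2 + 0.28 * n + 0.004 * n^2

.sim_ri_to_rt <- function(ri, carbons = 5:24) {
  x <- 100 * carbons
  y <- .sim_anchor_rt(carbons)
  seg <- findInterval(ri, x, all.inside = TRUE)
  y[seg] + (ri - x[seg]) * (y[seg + 1] - y[seg]) / (x[seg + 1] - x[seg])
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic CIL-LC-MS data generator
#'
#' Defaults describe the study conditions emulated throughout the package:
#' 13 brain regions with region-specific FFA presence for the qualitative
#' design, 4 regions x 12 samples for the quantitative design, log-normal
#' peak intensities with 20 % multiplicative noise, 1 mDa m/z noise,
#' 1-unit RI jitter, a heavy-labeled C5:0-C24:0 ladder and uniformly
#' scattered isolated decoy features within the m/z 180-650 scan range.
#'
#' @param seed Integer seed fixing every draw.
#' @param regions Region labels.
#' @param panel FFA panel: data.frame with `ffa_id`, `mz_light`, `ri`
#'   (see [panel_from_library()] / [random_ffa_panel()]); `NULL` uses the
#'   packaged library.
#' @param presence_prob Probability an FFA is present in a given region
#'   (qualitative design).
#' @param base_log_mean,base_log_sd Log-normal base-intensity parameters.
#' @param intensity_cv Multiplicative intensity noise (coefficient of
#'   variation) for pair splitting and per-sample abundance.
#' @param mz_noise_mda m/z noise SD in mDa.
#' @param ri_jitter RI jitter SD.
#' @param drift Per-run affine RT drift: `c(intercept_sd, slope_sd)`; each
#'   run draws rt' = a + b * rt with a ~ N(0, intercept_sd),
#'   b ~ N(1, slope_sd).
#' @param decoys_per_run Number of isolated (unpairable) decoy peaks.
#' @param ladder_intensity Nominal ladder standard intensity.
#' @param samples_per_region Quantitative design replicates per region.
#' @param effects Named list: ffa_id -> named numeric vector of per-region
#'   fold changes (quantitative design).
#' @param dropout Named list: sample_id -> integer carbons of ladder
#'   standards to remove (plants QC failures).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              regions = default_regions(),
                              panel = NULL,
                              presence_prob = 0.55,
                              base_log_mean = log(1e6),
                              base_log_sd = 0.6,
                              intensity_cv = 0.2,
                              mz_noise_mda = 1.0,
                              ri_jitter = 1.0,
                              drift = c(0.1, 0.02),
                              decoys_per_run = 200,
                              ladder_intensity = 5e6,
                              samples_per_region = 12,
                              effects = list(),
                              dropout = list()) {
  cfg <- list(seed = as.integer(seed), regions = regions, panel = panel,
              presence_prob = presence_prob, base_log_mean = base_log_mean,
              base_log_sd = base_log_sd, intensity_cv = intensity_cv,
              mz_noise_mda = mz_noise_mda, ri_jitter = ri_jitter,
              drift = drift, decoys_per_run = decoys_per_run,
              ladder_intensity = ladder_intensity,
              samples_per_region = samples_per_region,
              effects = effects, dropout = dropout)
  stopifnot(length(cfg$seed) == 1L, !is.na(cfg$seed),
            length(regions) >= 1, presence_prob > 0, presence_prob <= 1,
            intensity_cv >= 0, mz_noise_mda >= 0, ri_jitter >= 0,
            decoys_per_run >= 0, ladder_intensity > 0,
            samples_per_region >= 1)
  if (length(effects) &&
      any(unlist(effects, use.names = FALSE) <= 0)) {
    stop("fold changes must be > 0", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' FFA panel derived from a standards library
#'
#' @param library A `ffa_library`.
#' @param n Optional number of entries (first `n` rows).
#' @return Panel data.frame: `ffa_id` (= library name), `mz_light`, `ri`.
#' @export
panel_from_library <- function(library = read_library(), n = NULL) {
  if (!is.null(n)) library <- library[seq_len(n), , drop = FALSE]
  data.frame(ffa_id = library$name, mz_light = library$mz_light,
             ri = library$reference_ri, stringsAsFactors = FALSE)
}

#' Random FFA panel of isolated light/heavy pair positions
#'
#' Light m/z values are rejection-sampled uniformly over the scan range so
#' that every emitted peak (light, heavy, ladder) keeps at least
#' `min_spacing_mda` from every other peak and from every other peak
#' shifted by +/- the label delta: planted pairs can never collide with or
#' fake additional pairs. Draws come from the current RNG state.
#'
#' @param n Number of FFAs.
#' @param mz_range Light m/z range (default within the 180-650 scan).
#' @param ri_range RI range (default within the ladder span).
#' @param min_spacing_mda Exclusion radius in mDa (default 10).
#' @return Panel data.frame: `ffa_id`, `mz_light`, `ri`.
#' @export
random_ffa_panel <- function(n, mz_range = c(185, 640),
                             ri_range = c(520, 2380),
                             min_spacing_mda = 10) {
  delta <- pair_mass_delta()
  m <- min_spacing_mda / 1000
  occ <- ladder_mz()$mz
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      L <- stats::runif(1, mz_range[1], mz_range[2])
      H <- L + delta
      forbid <- c(occ, occ + delta, occ - delta)
      if (min(abs(L - forbid)) >= m && min(abs(H - forbid)) >= m) break
    }
    out[i] <- L
    occ <- c(occ, L, H)
  }
  data.frame(ffa_id = sprintf("SIM%04d", seq_len(n)), mz_light = out,
             ri = stats::runif(n, ri_range[1], ri_range[2]),
             stringsAsFactors = FALSE)
}

.sim_decoys <- function(n_decoys, occupied_mz, min_spacing = 0.010,
                        mz_range = c(181, 649), ri_range = c(510, 2390),
                        log_mean = log(1e6), log_sd = 0.6) {
  delta <- pair_mass_delta()
  occ <- occupied_mz
  mz <- numeric(n_decoys)
  for (i in seq_len(n_decoys)) {
    forbid <- c(occ, occ + delta, occ - delta)
    repeat {
      d <- stats::runif(1, mz_range[1], mz_range[2])
      if (min(abs(d - forbid)) >= min_spacing) break
    }
    mz[i] <- d
    occ <- c(occ, d)
    forbid <- NULL
  }
  data.frame(mz = mz, ri = stats::runif(n_decoys, ri_range[1], ri_range[2]),
             intensity = stats::rlnorm(n_decoys, log_mean, log_sd),
             stringsAsFactors = FALSE)
}

.cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate qualitative 1:1 light/heavy labeled runs
#'
#' One run per region: every FFA present in that region emits a light peak
#' at its light derivative m/z and a heavy peak 4.0251 Da above (both with
#' m/z noise), near-equal retention indices, and a common base intensity
#' split with multiplicative ratio noise around 1 (the 1:1 mixing design).
#' The heavy ladder and isolated decoy peaks are added, and the per-run
#' affine RT drift is applied to all peaks including the ladder. The truth
#' manifest lists every planted pair, decoy, and per-region presence.
#'
#' @param config A [simulation_config()].
#' @return List: `features` (`peak_list` over all runs; one sample per
#'   region, sample_id `Q_<region>`), `manifest` (list with `pairs`,
#'   `decoys`, `panel`, `presence` matrix, `drift` per run).
#' @export
simulate_qualitative_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    panel <- config$panel
    if (is.null(panel)) panel <- panel_from_library()
    delta <- pair_mass_delta()
    sd_mz <- config$mz_noise_mda / 1000
    sd_split <- .cv_to_sdlog(config$intensity_cv)
    lad <- ladder_mz()
    presence <- matrix(stats::runif(nrow(panel) * length(config$regions)) <
                         config$presence_prob,
                       nrow = nrow(panel),
                       dimnames = list(panel$ffa_id, config$regions))
    feats <- list(); pairs <- list(); decoys <- list(); drifts <- list()
    for (rg in config$regions) {
      sid <- paste0("Q_", rg)
      a <- stats::rnorm(1, 0, config$drift[1])
      b <- stats::rnorm(1, 1, config$drift[2])
      warp <- function(rt) a + b * rt
      present <- panel[presence[, rg], , drop = FALSE]
      np <- nrow(present)
      base <- stats::rlnorm(np, config$base_log_mean, config$base_log_sd)
      ratio <- exp(stats::rnorm(np, 0, sd_split))
      li <- base * sqrt(ratio); hi <- base / sqrt(ratio)
      ri_l <- present$ri + stats::rnorm(np, 0, config$ri_jitter)
      ri_h <- present$ri + stats::rnorm(np, 0, config$ri_jitter)
      mz_l <- present$mz_light + stats::rnorm(np, 0, sd_mz)
      mz_h <- present$mz_light + delta + stats::rnorm(np, 0, sd_mz)
      dec <- .sim_decoys(config$decoys_per_run,
                         c(present$mz_light, present$mz_light + delta,
                           lad$mz),
                         log_mean = config$base_log_mean,
                         log_sd = config$base_log_sd)
      run <- data.frame(
        mz = c(mz_l, mz_h, lad$mz + stats::rnorm(nrow(lad), 0, sd_mz),
               dec$mz),
        rt = warp(c(.sim_ri_to_rt(ri_l), .sim_ri_to_rt(ri_h),
                    .sim_anchor_rt(lad$carbon) +
                      stats::rnorm(nrow(lad), 0, 0.002),
                    .sim_ri_to_rt(dec$ri))),
        intensity = c(li, hi,
                      config$ladder_intensity *
                        stats::rlnorm(nrow(lad), 0, 0.05),
                      dec$intensity),
        sample_id = sid, region = rg, stringsAsFactors = FALSE)
      feats[[rg]] <- run
      pairs[[rg]] <- data.frame(
        ffa_id = present$ffa_id, sample_id = sid, region = rg,
        mz_light = present$mz_light, mz_heavy = present$mz_light + delta,
        ri = present$ri, light_intensity = li, heavy_intensity = hi,
        stringsAsFactors = FALSE)
      decoys[[rg]] <- if (nrow(dec)) {
        data.frame(sample_id = sid, region = rg, dec,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(sample_id = character(), region = character(),
                   mz = numeric(), ri = numeric(), intensity = numeric(),
                   stringsAsFactors = FALSE)
      }
      drifts[[rg]] <- c(intercept = a, slope = b)
    }
    features <- as_peak_list(do.call(rbind, feats))
    rownames(features) <- NULL
    list(features = features,
         manifest = list(pairs = do.call(rbind, pairs),
                         decoys = do.call(rbind, decoys),
                         panel = panel, presence = presence,
                         drift = drifts))
  })
}

#' Simulate the quantitative multi-region study
#'
#' Per sample: light analyte peaks whose abundance is a per-FFA log-normal
#' base level times the region fold effect times multiplicative noise,
#' all multiplied by a per-sample global scale (injection drift); plus the
#' heavy internal-standard ladder, optionally with planted dropout to
#' exercise the QC rule; plus decoys. The manifest records true relative
#' abundances (analyte / nearest ladder standard), planted effects, and
#' the intended QC exclusions.
#'
#' @param config A [simulation_config()]; `regions` defaults to the four
#'   quantified regions if left at the 13-region default.
#' @return List: `features` (`peak_list` over all samples), `manifest`
#'   (list with `samples`, `panel`, `true_abundance` matrix,
#'   `effects`, `expected_excluded`).
#' @export
simulate_quantitative_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  regions <- config$regions
  if (identical(regions, default_regions())) {
    regions <- c("OB", "OC", "HP", "CE")
  }
  if (length(regions) < 2) stop("quantitative design needs >= 2 regions",
                                call. = FALSE)
  .with_seed(config$seed, {
    panel <- config$panel
    if (is.null(panel)) panel <- panel_from_library()
    nf <- nrow(panel)
    sd_mz <- config$mz_noise_mda / 1000
    sd_ab <- .cv_to_sdlog(config$intensity_cv)
    lad <- ladder_mz()
    base <- stats::rlnorm(nf, config$base_log_mean, config$base_log_sd)
    names(base) <- panel$ffa_id
    fold <- matrix(1, nf, length(regions),
                   dimnames = list(panel$ffa_id, regions))
    for (id in names(config$effects)) {
      eff <- config$effects[[id]]
      if (!id %in% panel$ffa_id) {
        stop("effect refers to FFA not in the panel: ", id, call. = FALSE)
      }
      if (!all(names(eff) %in% regions)) {
        stop("effect for '", id, "' names unknown region(s): ",
             paste(setdiff(names(eff), regions), collapse = ", "),
             call. = FALSE)
      }
      fold[id, names(eff)] <- eff
    }
    sample_ids <- unlist(lapply(regions, function(rg)
      sprintf("%s_%02d", rg, seq_len(config$samples_per_region))))
    sample_region <- rep(regions, each = config$samples_per_region)
    names(sample_region) <- sample_ids
    nearest_std <- vapply(panel$ri, function(r)
      which.min(abs(lad$ri - r)), integer(1))
    feats <- list()
    truth <- matrix(NA_real_, length(sample_ids), nf,
                    dimnames = list(sample_ids, panel$ffa_id))
    scales <- stats::rlnorm(length(sample_ids), 0, 0.3)
    names(scales) <- sample_ids
    for (s in seq_along(sample_ids)) {
      sid <- sample_ids[s]; rg <- unname(sample_region[sid])
      a <- stats::rnorm(1, 0, config$drift[1])
      b <- stats::rnorm(1, 1, config$drift[2])
      abund <- unname(base * fold[, rg]) * exp(stats::rnorm(nf, 0, sd_ab))
      lad_int <- config$ladder_intensity * stats::rlnorm(nrow(lad), 0, 0.05)
      truth[sid, ] <- abund / lad_int[nearest_std]
      drop_c <- config$dropout[[sid]]
      keep_lad <- if (is.null(drop_c)) rep(TRUE, nrow(lad)) else
        !(lad$carbon %in% drop_c)
      dec <- if (config$decoys_per_run > 0)
        .sim_decoys(config$decoys_per_run,
                    c(panel$mz_light, panel$mz_light + pair_mass_delta(),
                      lad$mz),
                    log_mean = config$base_log_mean,
                    log_sd = config$base_log_sd) else NULL
      run <- data.frame(
        mz = c(panel$mz_light + stats::rnorm(nf, 0, sd_mz),
               lad$mz[keep_lad] + stats::rnorm(sum(keep_lad), 0, sd_mz),
               dec$mz),
        rt = a + b * c(
          .sim_ri_to_rt(panel$ri + stats::rnorm(nf, 0, config$ri_jitter)),
          .sim_anchor_rt(lad$carbon[keep_lad]) +
            stats::rnorm(sum(keep_lad), 0, 0.002),
          if (is.null(dec)) NULL else .sim_ri_to_rt(dec$ri)),
        intensity = unname(scales[sid]) * c(abund, lad_int[keep_lad],
                                            dec$intensity),
        sample_id = sid, region = rg, stringsAsFactors = FALSE)
      feats[[sid]] <- run
    }
    features <- as_peak_list(do.call(rbind, feats))
    rownames(features) <- NULL
    list(features = features,
         manifest = list(
           samples = data.frame(sample_id = sample_ids,
                                region = unname(sample_region),
                                scale = unname(scales),
                                stringsAsFactors = FALSE),
           panel = panel, true_abundance = truth,
           effects = config$effects,
           expected_excluded = names(config$dropout)))
  })
}
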