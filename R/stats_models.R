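#' Choose a variance-stabilizing transform for one feature
#'
#' Transforms are tried in order none, square-root, base-10 log; the first
#' under which every group passes Shapiro-Wilk normality and the groups
#' pass Levene's homoscedasticity test (both at `alpha`) is accepted. If
#' none passes, base-10 log is used with a warning flag (falling back to
#' the untransformed values if the data contain non-positive values).
#' During automatic gating a transform that is undefined for the data
#' (negative values under sqrt, non-positive under log10) is skipped and
#' recorded; requesting such a transform explicitly via `transform` is an
#' error.
#'
#' @param values Numeric vector (NAs allowed, dropped for testing).
#' @param groups Group labels, same length.
#' @param alpha Test level for both gates (default 0.05).
#' @param transform Optional explicit transform ("none", "sqrt", "log10"),
#'   bypassing the gate.
#' @return List: `transform` (chosen name), `values` (transformed, NAs
#'   preserved), `passed` (did the chosen transform pass both tests),
#'   `skipped` (transforms skipped as undefined), `warning` (fallback
#'   flag).
#' @export
transform_gate <- function(values, groups, alpha = 0.05, transform = NULL) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  apply_tf <- function(v, tf, strict) {
    if (tf == "none") return(v)
    if (tf == "sqrt") {
      if (any(v < 0, na.rm = TRUE)) {
        if (strict) stop("sqrt transform requested for data with negative ",
                         "values", call. = FALSE)
        return(NULL)
      }
      return(sqrt(v))
    }
    if (any(v <= 0, na.rm = TRUE)) {
      if (strict) stop("log10 transform requested for data with ",
                       "non-positive values", call. = FALSE)
      return(NULL)
    }
    log10(v)
  }
  if (!is.null(transform)) {
    transform <- match.arg(transform, c("none", "sqrt", "log10"))
    tv <- apply_tf(values, transform, strict = TRUE)
    return(list(transform = transform, values = tv,
                passed = .gate_ok(tv, groups, alpha), skipped = character(),
                warning = FALSE))
  }
  skipped <- character()
  for (tf in c("none", "sqrt", "log10")) {
    tv <- apply_tf(values, tf, strict = FALSE)
    if (is.null(tv)) { skipped <- c(skipped, tf); next }
    if (.gate_ok(tv, groups, alpha)) {
      return(list(transform = tf, values = tv, passed = TRUE,
                  skipped = skipped, warning = FALSE))
    }
  }
  tv <- apply_tf(values, "log10", strict = FALSE)
  if (is.null(tv)) {
    return(list(transform = "none", values = values, passed = FALSE,
                skipped = skipped, warning = TRUE))
  }
  list(transform = "log10", values = tv, passed = FALSE, skipped = skipped,
       warning = TRUE)
}

.gate_ok <- function(v, groups, alpha) {
  ok <- !is.na(v)
  v <- v[ok]; g <- droplevels(groups[ok])
  if (nlevels(g) < 2 || any(table(g) < 3)) return(FALSE)
  shap <- vapply(levels(g), function(l) {
    x <- v[g == l]
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }, numeric(1))
  if (any(shap < alpha)) return(FALSE)
  lev <- tryCatch(car::leveneTest(v, g, center = mean)[1, "Pr(>F)"],
                  error = function(e) 0)
  lev >= alpha
}

#' Classical one-way ANOVA
#'
#' Between/within sum-of-squares decomposition; p from the F distribution
#' with (k-1, N-k) degrees of freedom. Zero within-group variance with
#' unequal means is reported as the smallest representable p with a
#' `degenerate` flag.
#'
#' @param values Numeric vector (NAs dropped).
#' @param groups Group labels, same length.
#' @return An `anova_result` list: `F`, `p`, `df1`, `df2`, `means`, `sds`,
#'   `n`, `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values)
  v <- values[ok]; g <- droplevels(as.factor(groups[ok]))
  k <- nlevels(g); N <- length(v)
  if (k < 2 || any(table(g) < 2)) {
    stop("one-way ANOVA needs >= 2 groups with >= 2 observations each",
         call. = FALSE)
  }
  m <- tapply(v, g, mean)
  n <- tapply(v, g, length)
  grand <- mean(v)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((v - m[g])^2)
  df1 <- k - 1; df2 <- N - k
  degenerate <- FALSE
  if (ssw == 0) {
    if (ssb == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- .Machine$double.xmin; degenerate <- TRUE
    }
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = f, p = p, df1 = df1, df2 = df2,
                 means = m, sds = tapply(v, g, stats::sd), n = n,
                 degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Per-feature ANOVA over an abundance matrix
#'
#' Applies [transform_gate()] then [one_way_anova()] to each column,
#' using available (non-missing) values.
#'
#' @param x Samples x features numeric matrix (column names = feature
#'   ids).
#' @param groups Group label per row.
#' @param gate Apply the transform gate first (default `TRUE`).
#' @param alpha Gate test level.
#' @return Data.frame: `ffa_id`, `transform`, `F`, `p`, `gate_warning`.
#' @export
anova_table <- function(x, groups, gate = TRUE, alpha = 0.05) {
  stopifnot(is.matrix(x), nrow(x) == length(groups))
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    tf <- "none"; warn <- FALSE
    if (gate) {
      gt <- transform_gate(v, groups, alpha)
      v <- gt$values; tf <- gt$transform; warn <- gt$warning
    }
    # features with too few detections per group are reported, not fitted
    a <- tryCatch(one_way_anova(v, groups), error = function(e)
      list(F = NA_real_, p = NA_real_))
    data.frame(ffa_id = colnames(x)[j], transform = tf, F = a$F, p = a$p,
               gate_warning = warn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# ---- latent-variable models -------------------------------------------

.autoscale <- function(X, scale = TRUE) {
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  scl[scl == 0 | is.na(scl)] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

.stratified_folds <- function(groups, nfold) {
  fold <- integer(length(groups))
  for (l in unique(groups)) {
    idx <- which(groups == l)
    fold[idx] <- (seq_along(idx) - 1L) %% nfold + 1L
  }
  fold
}

#' Principal component analysis with cross-validated Q2
#'
#' Columns are mean-centered and (by default) unit-variance scaled.
#' Components come from the singular value decomposition; R2X is the
#' cumulative explained variance. Q2 is estimated by row-wise k-fold
#' cross-validation: a PCA is fitted without the held-out rows and each
#' held-out matrix element is reconstructed from the remaining elements of
#' its row (leave-one-coordinate-out projection onto the training
#' loadings), giving an honest prediction error.
#'
#' @param X Samples x variables numeric matrix, no missing values.
#' @param ncomp Number of components (default 2; truncated to the matrix
#'   rank with a warning).
#' @param scale Unit-variance scaling (default `TRUE`); mean-centering is
#'   always applied.
#' @param nfold Cross-validation folds (default 7).
#' @return A `cil_pca` object: scores, loadings, per-component and
#'   cumulative R2X, cross-validated Q2, centering/scaling vectors.
#' @export
fit_pca <- function(X, ncomp = 2, scale = TRUE, nfold = 7) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("fit_pca requires a complete matrix; impute first ",
                     "(see prepare_matrix)", call. = FALSE)
  sc <- .autoscale(X, scale)
  sv <- svd(sc$X)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (ncomp > rank) {
    warning("ncomp reduced to matrix rank (", rank, ")")
    ncomp <- rank
  }
  ev <- sv$d^2
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  scores <- sc$X %*% loadings
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(ncomp)))
  structure(list(scores = scores, loadings = loadings,
                 R2X = ev[seq_len(ncomp)] / sum(ev),
                 R2X_cum = cumsum(ev)[seq_len(ncomp)] / sum(ev),
                 Q2 = .pca_q2(X, ncomp, scale, nfold),
                 center = sc$center, scale = sc$scale, ncomp = ncomp),
            class = "cil_pca")
}

.pca_q2 <- function(X, ncomp, scale, nfold) {
  n <- nrow(X)
  nfold <- min(nfold, n - 1)
  fold <- (seq_len(n) - 1L) %% nfold + 1L
  press <- tss <- 0
  for (f in seq_len(nfold)) {
    tr <- X[fold != f, , drop = FALSE]
    te <- X[fold == f, , drop = FALSE]
    sc <- .autoscale(tr, scale)
    a <- min(ncomp, min(dim(tr)) - 1)
    P <- svd(sc$X)$v[, seq_len(a), drop = FALSE]
    tes <- sweep(sweep(te, 2, sc$center), 2, sc$scale, "/")
    for (i in seq_len(nrow(tes))) {
      x <- tes[i, ]
      for (j in seq_along(x)) {
        Pj <- P[j, , drop = FALSE]
        G <- diag(a) - crossprod(Pj)
        t_hat <- solve(G, crossprod(P[-j, , drop = FALSE], x[-j]))
        press <- press + (x[j] - Pj %*% t_hat)^2
      }
      tss <- tss + sum(x^2)
    }
  }
  as.numeric(1 - press / tss)
}

#' @export
print.cil_pca <- function(x, ...) {
  cat(sprintf("PCA: %d component(s); R2X(cum) = %.3f; Q2 = %.3f\n",
              x$ncomp, x$R2X_cum[x$ncomp], x$Q2))
  invisible(x)
}

#' @export
summary.cil_pca <- function(object, ...) {
  data.frame(component = seq_len(object$ncomp), R2X = object$R2X,
             R2X_cum = object$R2X_cum)
}

#' @export
predict.cil_pca <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              object$scale, "/")
  Xs %*% object$loadings
}

#' @export
plot.cil_pca <- function(x, comps = c(1, 2), col = NULL, ...) {
  s <- x$scores[, comps, drop = FALSE]
  graphics::plot(s[, 1], s[, 2],
                 xlab = sprintf("PC%d (R2X %.2f)", comps[1], x$R2X[comps[1]]),
                 ylab = sprintf("PC%d (R2X %.2f)", comps[2], x$R2X[comps[2]]),
                 col = if (is.null(col)) 1 else col, pch = 19, ...)
  invisible(x)
}

# single NIPALS PLS component
.nipals_comp <- function(X, Y, tol = 1e-10, maxit = 500) {
  u <- Y[, which.max(colSums(Y^2))]
  w_old <- NULL
  for (it in seq_len(maxit)) {
    w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
    t <- X %*% w
    c <- crossprod(Y, t) / sum(t^2)
    u <- Y %*% c / sum(c^2)
    if (!is.null(w_old) && sum((w - w_old)^2) < tol^2) break
    w_old <- w
  }
  t <- X %*% w
  list(w = drop(w), t = drop(t), c = drop(c),
       p = drop(crossprod(X, t) / sum(t^2)))
}

.opls_core <- function(Xs, Y, npred, northo) {
  X0ss <- sum(Xs^2); Yss <- sum(Y^2)
  Wo <- Po <- NULL
  r2x_o <- numeric(0)
  for (o in seq_len(northo)) {
    cmp <- .nipals_comp(Xs, Y)
    wo <- cmp$p - sum(cmp$w * cmp$p) * cmp$w
    nw <- sqrt(sum(wo^2))
    if (nw < 1e-12) break
    wo <- wo / nw
    to <- drop(Xs %*% wo)
    po <- drop(crossprod(Xs, to) / sum(to^2))
    Xs <- Xs - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po)
    r2x_o <- c(r2x_o, sum(to^2) * sum(po^2) / X0ss)
  }
  W <- P <- NULL; C <- NULL; T <- NULL
  Xa <- Xs; Ya <- Y
  r2x_p <- numeric(0); ssy <- numeric(0)
  for (a in seq_len(npred)) {
    cmp <- .nipals_comp(Xa, Ya)
    if (sum(cmp$t^2) < 1e-12) break
    W <- cbind(W, cmp$w); T <- cbind(T, cmp$t)
    P <- cbind(P, cmp$p); C <- cbind(C, cmp$c)
    r2x_p <- c(r2x_p, sum(cmp$t^2) * sum(cmp$p^2) / X0ss)
    ssy <- c(ssy, sum(cmp$t^2) * sum(cmp$c^2))
    Xa <- Xa - tcrossprod(cmp$t, cmp$p)
    Ya <- Ya - tcrossprod(cmp$t, cmp$c)
  }
  list(W = W, P = P, C = C, T = T, Wo = Wo, Po = Po,
       R2Y = 1 - sum(Ya^2) / Yss,
       R2X = sum(r2x_o) + sum(r2x_p),
       ssy = ssy, n_ortho = if (is.null(Wo)) 0L else ncol(Wo))
}

.opls_filter <- function(Xs, Wo, Po) {
  if (is.null(Wo)) return(Xs)
  for (o in seq_len(ncol(Wo))) {
    to <- Xs %*% Wo[, o]
    Xs <- Xs - tcrossprod(drop(to), Po[, o])
  }
  Xs
}

.opls_predict_raw <- function(core, Xs) {
  Xf <- .opls_filter(Xs, core$Wo, core$Po)
  B <- core$W %*% solve(crossprod(core$P, core$W), t(core$C))
  Xf %*% B
}

#' Orthogonal PLS discriminant analysis with VIP scores
#'
#' X is mean-centered and unit-variance scaled (SIMCA-style); the group
#' factor is one-hot encoded and column-centered. The model carries
#' min(k - 1, rank) predictive components plus orthogonal components; the
#' orthogonal-component count is chosen by maximizing stratified 7-fold
#' cross-validated Q2 (up to `max_ortho`). VIP scores are computed over
#' the predictive components, weighted by the Y variance each explains;
#' they satisfy `sum(VIP^2) == ncol(X)` exactly.
#'
#' @param X Samples x variables numeric matrix, no missing values.
#' @param y Group labels (coerced to factor; >= 2 classes required).
#' @param n_ortho `"auto"` (Q2-maximizing, default) or a fixed count.
#' @param max_ortho Maximum orthogonal components tried (default 5).
#' @param nfold Cross-validation folds (default 7).
#' @param scale Unit-variance scaling of X (default `TRUE`).
#' @return A `cil_oplsda` object: predictive `scores`, `loadings`,
#'   `weights`, class loadings `C`, orthogonal `scores_ortho`, `R2X`,
#'   `R2Y`, `Q2`, `vip`, `n_ortho`, class levels, centering/scaling.
#' @export
fit_oplsda <- function(X, y, n_ortho = "auto", max_ortho = 5, nfold = 7,
                       scale = TRUE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("fit_oplsda requires a complete matrix; impute first ",
                     "(see prepare_matrix)", call. = FALSE)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("OPLS-DA requires at least two groups",
                           call. = FALSE)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  npred <- min(nlevels(y) - 1, ncol(X), nrow(X) - 1)
  sc <- .autoscale(X, scale)

  q2_for <- function(k) .opls_q2(X, Y, y, npred, k, nfold, scale)
  if (identical(n_ortho, "auto")) {
    q2s <- vapply(0:max_ortho, q2_for, numeric(1))
    n_ortho <- (0:max_ortho)[which.max(q2s)]
    q2 <- max(q2s)
  } else {
    stopifnot(is.numeric(n_ortho), n_ortho >= 0)
    q2 <- q2_for(n_ortho)
  }
  core <- .opls_core(sc$X, Yc, npred, n_ortho)
  p <- ncol(X)
  w2 <- sweep(core$W^2, 2, colSums(core$W^2), "/")
  vip <- sqrt(p * drop(w2 %*% core$ssy) / sum(core$ssy))
  names(vip) <- colnames(X)
  scores <- core$T
  dimnames(scores) <- list(rownames(X), paste0("p", seq_len(ncol(scores))))
  structure(list(scores = scores, loadings = core$P, weights = core$W,
                 C = core$C, weights_ortho = core$Wo,
                 loadings_ortho = core$Po,
                 scores_ortho = if (core$n_ortho)
                   .ortho_scores(sc$X, core) else NULL,
                 R2X = core$R2X, R2Y = core$R2Y, Q2 = q2,
                 vip = vip, n_pred = ncol(core$W), n_ortho = core$n_ortho,
                 levels = levels(y), y = y,
                 center = sc$center, scale = sc$scale,
                 y_center = attr(Yc, "scaled:center")),
            class = "cil_oplsda")
}

.ortho_scores <- function(Xs, core) {
  out <- matrix(NA_real_, nrow(Xs), core$n_ortho)
  for (o in seq_len(core$n_ortho)) {
    out[, o] <- Xs %*% core$Wo[, o]
    Xs <- Xs - tcrossprod(drop(out[, o]), core$Po[, o])
  }
  out
}

.opls_q2 <- function(X, Y, y, npred, northo, nfold, scale) {
  n <- nrow(X)
  fold <- .stratified_folds(y, min(nfold, n - 1))
  press <- tss <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f
    sc <- .autoscale(X[tr, , drop = FALSE], scale)
    ym <- colMeans(Y[tr, , drop = FALSE])
    Yc <- sweep(Y[tr, , drop = FALSE], 2, ym)
    core <- .opls_core(sc$X, Yc, npred, northo)
    if (is.null(core$W)) return(-Inf)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, sc$center), 2,
                 sc$scale, "/")
    pred <- .opls_predict_raw(core, Xte)
    resid <- sweep(Y[!tr, , drop = FALSE], 2, ym) - pred
    press <- press + sum(resid^2)
    tss <- tss + sum(sweep(Y[!tr, , drop = FALSE], 2, ym)^2)
  }
  1 - press / tss
}

#' @export
print.cil_oplsda <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA: %d predictive + %d orthogonal component(s), %d classes\n",
    x$n_pred, x$n_ortho, length(x$levels)))
  cat(sprintf("R2X = %.3f, R2Y = %.3f, Q2 = %.3f\n", x$R2X, x$R2Y, x$Q2))
  invisible(x)
}

#' @export
summary.cil_oplsda <- function(object, ...) {
  list(components = c(predictive = object$n_pred,
                      orthogonal = object$n_ortho),
       R2X = object$R2X, R2Y = object$R2Y, Q2 = object$Q2,
       vip = sort(object$vip, decreasing = TRUE))
}

#' @export
coef.cil_oplsda <- function(object, ...) {
  B <- object$weights %*%
    solve(crossprod(object$loadings, object$weights), t(object$C))
  dimnames(B) <- list(names(object$vip), object$levels)
  B
}

#' @export
predict.cil_oplsda <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              object$scale, "/")
  core <- list(W = object$weights, P = object$loadings, C = object$C,
               Wo = object$weights_ortho, Po = object$loadings_ortho)
  yhat <- sweep(.opls_predict_raw(core, Xs), 2, -object$y_center)
  cls <- object$levels[max.col(yhat)]
  list(y = yhat, class = cls)
}

#' @export
plot.cil_oplsda <- function(x, ...) {
  s1 <- x$scores[, 1]
  s2 <- if (ncol(x$scores) >= 2) x$scores[, 2] else
    if (!is.null(x$scores_ortho)) x$scores_ortho[, 1] else
      seq_along(s1)
  graphics::plot(s1, s2, col = as.integer(x$y), pch = 19,
                 xlab = "predictive score 1",
                 ylab = if (ncol(x$scores) >= 2) "predictive score 2" else
                   "orthogonal score 1", ...)
  graphics::legend("topright", legend = x$levels,
                   col = seq_along(x$levels), pch = 19, bty = "n")
  invisible(x)
}

#' VIP scores of a fitted OPLS-DA model
#'
#' @param model A `cil_oplsda` object.
#' @return Named numeric vector; `sum(vip^2)` equals the number of
#'   variables.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "cil_oplsda"))
  model$vip
}

#' Joint VIP / ANOVA feature selection
#'
#' A feature is selected iff its OPLS-DA VIP exceeds `vip_cut` and its
#' one-way ANOVA p value is below `p_cut`. No multiple-testing correction
#' is applied by default (the rule is a joint filter, not a calibrated
#' test); Benjamini-Hochberg FDR on the p values is available via `fdr`.
#'
#' @param p Named numeric vector of ANOVA p values.
#' @param vip Named numeric vector of VIP scores over the same features.
#' @param p_cut p-value threshold (default 0.05).
#' @param vip_cut VIP threshold (default 1.0).
#' @param fdr Apply BH correction to `p` before thresholding (default
#'   `FALSE`).
#' @return Character vector of selected feature ids, with the full
#'   decision table attached as attribute `"table"`.
#' @export
select_significant <- function(p, vip, p_cut = 0.05, vip_cut = 1.0,
                               fdr = FALSE) {
  if (is.null(names(p)) || is.null(names(vip)) ||
      !setequal(names(p), names(vip))) {
    stop("p and vip must be named over the same feature set", call. = FALSE)
  }
  vip <- vip[names(p)]
  padj <- if (fdr) stats::p.adjust(p, method = "BH") else p
  sel <- !is.na(padj) & !is.na(vip) & vip > vip_cut & padj < p_cut
  tab <- data.frame(ffa_id = names(p), p = unname(p), p_adj = unname(padj),
                    vip = unname(vip), selected = unname(sel),
                    stringsAsFactors = FALSE)
  structure(names(p)[sel], table = tab)
}

#' Prepare an abundance matrix for multivariate modelling
#'
#' Features missing in more than `max_missing` of the samples of any
#' region are dropped; remaining missing values are imputed by the
#' region-wise median (overall median if a region has none).
#'
#' @param x An `abundance_table` or samples x features matrix.
#' @param groups Region per row (taken from the table if omitted).
#' @param max_missing Maximum tolerated per-region missing fraction
#'   (default 0.5).
#' @return List: `X` (complete matrix), `groups`, `dropped` (feature ids).
#' @export
prepare_matrix <- function(x, groups = NULL, max_missing = 0.5) {
  if (inherits(x, "abundance_table")) {
    groups <- x$samples$region
    x <- x$values
  }
  stopifnot(is.matrix(x), length(groups) == nrow(x))
  gl <- unique(groups)
  frac <- sapply(gl, function(g)
    colMeans(is.na(x[groups == g, , drop = FALSE])))
  drop <- if (is.matrix(frac)) apply(frac, 1, max) > max_missing else
    frac > max_missing
  kept <- x[, !drop, drop = FALSE]
  for (j in seq_len(ncol(kept))) {
    if (!anyNA(kept[, j])) next
    for (g in gl) {
      sel <- groups == g & is.na(kept[, j])
      if (any(sel)) {
        med <- stats::median(kept[groups == g, j], na.rm = TRUE)
        if (is.na(med)) med <- stats::median(kept[, j], na.rm = TRUE)
        kept[sel, j] <- med
      }
    }
  }
  list(X = kept, groups = groups, dropped = colnames(x)[drop])
}
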