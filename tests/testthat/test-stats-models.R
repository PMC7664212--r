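test_that("the transform gate keeps Gaussian data untransformed and logs log-normals", {
  set.seed(51)
  none_hits <- log_hits <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    g <- rep(c("A", "B", "C"), each = 30)
    gauss <- rnorm(90)
    if (transform_gate(gauss, g)$transform == "none") {
      none_hits <- none_hits + 1
    }
    lnorm <- rlnorm(90, meanlog = 0, sdlog = 1)
    if (transform_gate(lnorm, g)$transform == "log10") {
      log_hits <- log_hits + 1
    }
  }
  expect_gte(none_hits / n_rep, 0.9)
  expect_gte(log_hits / n_rep, 0.9)
})

test_that("explicitly requested transforms error on invalid domains", {
  g <- rep(c("A", "B"), each = 5)
  v <- c(rnorm(9), -1)
  expect_error(transform_gate(v, g, transform = "sqrt"), "negative")
  expect_error(transform_gate(v, g, transform = "log10"), "non-positive")
  # automatic gating skips the inapplicable transforms instead
  gt <- transform_gate(v, g)
  expect_true(all(c("sqrt", "log10") %in% c(gt$skipped, gt$transform)) ||
                gt$transform == "none")
})

test_that("one-way ANOVA reproduces hand-computed decompositions", {
  # identical groups: F = 0, p = 1
  a0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)
  # groups (1,2) vs (3,4): SSB = 4 (df 1), SSW = 1 (df 2) -> F = 8
  a1 <- one_way_anova(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(a1$F, 8)
  expect_equal(a1$p, pf(8, 1, 2, lower.tail = FALSE))
  expect_equal(round(a1$p, 3), 0.106)
  # degenerate: zero within-group variance with unequal means
  ad <- one_way_anova(c(1, 1, 2, 2), c("A", "A", "B", "B"))
  expect_true(ad$degenerate)
  expect_lt(ad$p, 1e-300)
  expect_error(one_way_anova(c(1, 2), c("A", "B")), ">= 2")
})

test_that("ANOVA agrees with the linear-model fit across random data", {
  set.seed(52)
  for (r in 1:20) {
    g <- factor(rep(c("A", "B", "C", "D"), times = sample(3:8, 4, TRUE)))
    v <- rnorm(length(g), mean = as.integer(g) * runif(1, 0, 1))
    mine <- one_way_anova(v, g)
    ref <- anova(lm(v ~ g))
    expect_equal(mine$F, ref$`F value`[1])
    expect_equal(mine$p, ref$`Pr(>F)`[1])
  }
})

test_that("PCA explains collinear rows exactly and matches prcomp variance", {
  t <- seq(-2, 2, length.out = 9)
  X <- cbind(t, 2 * t, -t) + 5
  fit <- fit_pca(X, ncomp = 1, scale = FALSE)
  expect_equal(fit$R2X_cum[1], 1.0)
  set.seed(53)
  X2 <- matrix(rnorm(200), 20, 10)
  fit2 <- suppressWarnings(fit_pca(X2, ncomp = 4))
  pr <- prcomp(X2, center = TRUE, scale. = TRUE)
  expect_equal(fit2$R2X, (pr$sdev^2 / sum(pr$sdev^2))[1:4])
  expect_true(all(diff(fit2$R2X) <= 1e-12))
  # row permutation leaves explained variance unchanged
  fit3 <- fit_pca(X2[sample(20), ], ncomp = 4)
  expect_equal(fit3$R2X, fit2$R2X)
})

test_that("PCA separates a planted outlier group and reconstructs at full rank", {
  set.seed(54)
  X <- matrix(rnorm(40 * 8), 40, 8)
  grp <- rep(c("A", "B", "C", "D"), each = 10)
  X[grp == "D", 1:4] <- X[grp == "D", 1:4] + 4
  fit <- fit_pca(X, ncomp = 2)
  d_scores <- fit$scores[grp == "D", 1]
  others <- fit$scores[grp != "D", 1]
  expect_true(min(d_scores) > max(others) || max(d_scores) < min(others))
  expect_gt(fit$Q2, 0)
  # full-rank reconstruction is exact
  full <- suppressWarnings(fit_pca(X, ncomp = 8))
  Xs <- scale(X)
  rec <- full$scores %*% t(full$loadings)
  expect_equal(rec, Xs[, ], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("OPLS-DA puts informative variables above the VIP threshold", {
  set.seed(55)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  x1 <- ifelse(y == "A", 1, -1) + rnorm(n, 0, 0.5)
  X <- cbind(x1, matrix(rnorm(n * 5), n))
  colnames(X) <- paste0("v", 1:6)
  fit <- fit_oplsda(X, y)
  v <- vip(fit)
  expect_gt(v["v1"], 1)
  expect_true(all(v[paste0("v", 2:6)] < v["v1"]))
  # two classes -> exactly one predictive component
  expect_equal(fit$n_pred, 1L)
})

test_that("the VIP normalization identity holds on arbitrary fits", {
  set.seed(56)
  for (r in 1:5) {
    k <- sample(2:4, 1)
    X <- matrix(rnorm(30 * 12), 30, 12)
    colnames(X) <- paste0("v", 1:12)
    y <- rep(LETTERS[1:k], length.out = 30)
    X[, 1] <- X[, 1] + as.integer(factor(y))
    fit <- fit_oplsda(X, y, n_ortho = sample(0:2, 1))
    expect_equal(sum(vip(fit)^2), ncol(X), tolerance = 1e-9)
  }
})

test_that("strong class separation yields high cross-validated Q2", {
  set.seed(57)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[y == "B", 1:3] <- X[y == "B", 1:3] + 3
  colnames(X) <- paste0("v", 1:10)
  fit <- fit_oplsda(X, y)
  expect_gt(fit$Q2, 0.5)
  expect_gt(fit$R2Y, fit$Q2 - 0.05)
  pred <- predict(fit, X)
  expect_gte(mean(pred$class == y), 0.95)
})

test_that("predictive scores are invariant (up to sign) under variable reordering", {
  set.seed(58)
  X <- matrix(rnorm(30 * 8), 30, 8)
  colnames(X) <- paste0("v", 1:8)
  y <- rep(c("A", "B", "C"), each = 10)
  X[, 2] <- X[, 2] + as.integer(factor(y))
  f1 <- fit_oplsda(X, y, n_ortho = 1)
  perm <- sample(8)
  f2 <- fit_oplsda(X[, perm], y, n_ortho = 1)
  for (a in seq_len(ncol(f1$scores))) {
    expect_equal(abs(cor(f1$scores[, a], f2$scores[, a])), 1,
                 tolerance = 1e-6)
  }
  expect_equal(sort(names(sort(vip(f1), decreasing = TRUE)[1])), "v2")
  expect_equal(vip(f2)[colnames(X)], vip(f1)[colnames(X)])
})

test_that("the joint VIP/p rule selects and refuses as specified", {
  p <- c(a = 0.01, b = 0.2, c = 0.04)
  v <- c(a = 1.2, b = 1.2, c = 0.8)
  sel <- select_significant(p, v)
  expect_equal(as.character(sel), "a")
  tab <- attr(sel, "table")
  expect_equal(tab$selected, c(TRUE, FALSE, FALSE))
  expect_error(select_significant(p, v[1:2]), "same feature set")
  # BH option is monotone: never selects more than the raw rule
  sel_fdr <- select_significant(p, v, fdr = TRUE)
  expect_true(all(sel_fdr %in% sel))
})

test_that("missing-value policy drops sparse features and imputes the rest", {
  set.seed(59)
  X <- matrix(rlnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  g <- rep(c("A", "B"), each = 5)
  X[1:4, 1] <- NA          # 80% missing in group A -> dropped
  X[c(1, 6), 2] <- NA      # sparse missing -> imputed
  prep <- prepare_matrix(X, g)
  expect_equal(prep$dropped, "f1")
  expect_false(anyNA(prep$X))
  expect_equal(unname(prep$X[1, "f2"]), median(X[2:5, 2]))
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(60)
  n <- 48
  y <- rep(c("A", "B", "C", "D"), each = 12)
  X <- matrix(rlnorm(n * 20, 0, 0.3), n, 20)
  X[y == "A", 1] <- X[y == "A", 1] * 2.5
  X[y == "C", 2] <- X[y == "C", 2] * 2.5
  colnames(X) <- paste0("v", 1:20)
  mine <- fit_oplsda(X, y, n_ortho = 0)
  ref <- mixOmics::plsda(scale(X), factor(y), ncomp = 3)
  v_ref <- mixOmics::vip(ref)[, 3]
  expect_gt(cor(vip(mine), v_ref[names(vip(mine))]), 0.99)
  expect_equal(which(vip(mine) > 1.5), which(v_ref > 1.5))
})
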