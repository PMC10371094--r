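test_that("Welch t matches the closed-form textbook computation", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  # means 2 and 5, each variance 1: t = -3 / sqrt(2/3), df = 4
  expect_equal(w$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(w$t, 4), tolerance = 1e-12)

  expect_equal(welch_t(rep(2, 5), rep(2, 4))[c("t", "p")],
               list(t = 0, p = 1))
  expect_equal(welch_t(rep(1, 3), rep(2, 3))$p, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("null Welch p values are uniform", {
  set.seed(19)
  p <- replicate(800, welch_t(rnorm(6), rnorm(6))$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)  # rejection rate near nominal
})

test_that("two-stage FDR mask matches the independent step-up oracle", {
  expect_equal(bky_fdr(rep(1, 20)), rep(FALSE, 20))
  expect_equal(bky_fdr(rep(0, 20)), rep(TRUE, 20))
  p_fixed <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205,
               0.212, 0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.341,
               0.384, 0.569, 0.594, 0.696, 0.762, 0.94, 0.942, 0.975,
               0.986)
  expect_equal(bky_fdr(p_fixed, 0.05), oracle_bky(p_fixed, 0.05))
  set.seed(23)
  for (i in 1:200) {
    m <- sample(5:80, 1)
    p <- if (runif(1) < 0.5) runif(m) else
      pmin(1, c(rbeta(ceiling(m / 3), 0.2, 8), runif(floor(2 * m / 3))))
    for (q in c(0.01, 0.05, 0.1))
      expect_equal(bky_fdr(p, q), oracle_bky(p, q))
  }
  expect_error(bky_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-stage rejections contain the stage-1 step-up rejections", {
  set.seed(29)
  for (i in 1:50) {
    p <- c(rbeta(10, 0.2, 6), runif(40))
    q <- 0.05
    stage1 <- cffrag:::bh_stepup(p, q / (1 + q))
    expect_true(all(bky_fdr(p, q)[stage1]))
  }
})

test_that("q values track the mask around the nominal level", {
  set.seed(31)
  p <- c(rbeta(15, 0.1, 10), runif(60))
  mask <- bky_fdr(p, 0.05)
  qv <- bky_qvalues(p, 0.05)
  expect_true(all(qv >= 0 & qv <= 1))
  # monotone in p
  o <- order(p)
  expect_true(all(diff(qv[o]) >= -1e-12))
  # rejected features have q below unrejected ones
  if (any(mask) && any(!mask))
    expect_lt(max(qv[mask]), min(qv[!mask]) + 1e-12)
})

test_that("feature scan controls false rejections on null data and finds a
           planted effect", {
  set.seed(37)
  # null: mean false-rejection proportion at most q (50 reps x 300 features)
  fr <- replicate(50, {
    m <- matrix(rnorm(20 * 300), nrow = 20)
    s <- feature_scan(m, rep(c("a", "b"), each = 10), q = 0.05)
    mean(s$rejected, na.rm = TRUE)
  })
  expect_lte(mean(fr), 0.05 + 2 * sd(fr) / sqrt(50))

  # power: standardized effect 3 planted in 1 of 100 features, n = 10/group
  hits <- replicate(100, {
    m <- matrix(rnorm(20 * 100), nrow = 20)
    m[1:10, 1] <- m[1:10, 1] + 3
    s <- feature_scan(m, rep(c("a", "b"), each = 10))
    isTRUE(s$rejected[1])
  })
  expect_gt(mean(hits), 0.9)

  # degenerate inputs
  expect_equal(nrow(feature_scan(matrix(numeric(0), nrow = 4, ncol = 0),
                                 rep(c("a", "b"), 2))), 0L)
  m <- matrix(rnorm(8), nrow = 4)
  m[1:2, 1] <- NA
  s <- feature_scan(m, c("a", "a", "b", "b"))
  expect_true(is.na(s$p[1]))
  expect_error(feature_scan(m, c("a", "b", "c", "d")), "two groups")
})

test_that("AUC equals Mann-Whitney U over n1 n2, ties counted half", {
  expect_equal(as.numeric(roc_auc(c(1, 2, 8, 9), c(0, 0, 1, 1))), 1.0)
  expect_equal(as.numeric(roc_auc(rep(3, 6), c(0, 1, 0, 1, 0, 1))), 0.5)
  expect_equal(as.numeric(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both label classes")

  set.seed(41)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    scores <- if (runif(1) < 0.5) rnorm(n) else sample(1:4, n, TRUE)
    lab <- sample(c(TRUE, FALSE), n, TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(as.numeric(roc_auc(scores, lab)), oracle_auc(scores, lab))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(43)
  s <- rnorm(40); lab <- rbinom(40, 1, 0.5)
  if (length(unique(lab)) < 2) lab[1] <- 1 - lab[1]
  a0 <- as.numeric(roc_auc(s, lab))
  expect_equal(as.numeric(roc_auc(exp(s), lab)), a0)
  expect_equal(as.numeric(roc_auc(rank(s), lab)), a0)
  expect_equal(as.numeric(roc_auc(-s, lab)), 1 - a0)
  expect_equal(attr(roc_auc(-s, lab), "oriented"), max(a0, 1 - a0))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  for (i in 1:20) {
    s <- rnorm(30); lab <- rbinom(30, 1, 0.5)
    if (length(unique(lab)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(lab, s, direction = "<",
                                          quiet = TRUE)))
    expect_equal(as.numeric(roc_auc(s, lab)), ref, tolerance = 1e-12)
  }
})

test_that("PCA integration behaves like unit-scaled SVD", {
  # two perfectly correlated features: PC1 explains everything
  set.seed(53)
  v <- rnorm(12)
  pc <- pca_integrate(cbind(a = v, b = 2 * v + 5))
  expect_equal(pc$var_explained[1], 100, tolerance = 1e-8)

  m <- matrix(rnorm(15 * 8), nrow = 15)
  pc <- pca_integrate(m, n_components = 8)
  expect_equal(crossprod(pc$loadings), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(max(abs(cor(pc$scores)[upper.tri(diag(8))])), 0,
               tolerance = 1e-8)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 100 + 1e-9)

  # zero-variance features are dropped, not fatal
  pc <- pca_integrate(cbind(m, const = 1))
  expect_equal(pc$dropped_features, "const")

  # planted group shift on 30 of 92 features separates PC1
  set.seed(59)
  sep <- replicate(20, {
    m <- matrix(rnorm(20 * 92), nrow = 20)
    m[1:10, 1:30] <- m[1:10, 1:30] + 1.5
    p <- pc1_group_test(pca_integrate(m), rep(c("g1", "g2"), each = 10))$p
    p < 0.01
  })
  expect_gt(mean(sep), 0.95 - 1e-9)
})

test_that("cluster order groups correlated samples together", {
  set.seed(61)
  base1 <- rnorm(30); base2 <- rnorm(30)
  m <- rbind(base1 + rnorm(30, 0, 0.1), base1 + rnorm(30, 0, 0.1),
             base2 + rnorm(30, 0, 0.1), base2 + rnorm(30, 0, 0.1))
  ord <- cluster_order(m)
  pairs <- list(sort(ord[1:2]), sort(ord[3:4]))
  expect_true(identical(pairs, list(c(1L, 2L), c(3L, 4L))) ||
                identical(pairs, list(c(3L, 4L), c(1L, 2L))))
})
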