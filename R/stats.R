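#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p value (wraps [stats::t.test()]). Two groups that are both
#' constant with equal means return `t = 0, p = 1` by convention; constant
#' groups with different means return `p = 0`.
#'
#' @param x,y numeric vectors with at least 2 finite values each.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    df <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

# Linear (Benjamini-Hochberg) step-up at level `level`: reject the k
# smallest p values where k is the largest i with p_(i) <= i * level / m.
bh_stepup <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ok <- p[o] <= seq_len(m) / m * level
  k <- if (any(ok)) max(which(ok)) else 0L
  mask <- logical(m)
  if (k > 0L) mask[o[seq_len(k)]] <- TRUE
  mask
}

#' Two-stage step-up FDR control (Benjamini, Krieger & Yekutieli 2006)
#'
#' Adaptive linear step-up: stage 1 runs the step-up at level
#' `q' = q / (1 + q)` to estimate the number of true nulls
#' `m0 = m - r1`; if stage 1 rejects nothing the procedure stops with no
#' rejections, if it rejects everything all hypotheses are rejected;
#' otherwise stage 2 reruns the step-up at level `q' * m / m0`. By
#' construction the final rejection set contains the stage-1 set.
#'
#' @param pvalues numeric vector of p values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05, the Q = 5 percent
#'   convention).
#' @return logical rejection mask.
#' @export
bky_fdr <- function(pvalues, q = 0.05) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) return(logical(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  stopifnot(q > 0, q < 1)
  m <- length(p)
  q1 <- q / (1 + q)
  stage1 <- bh_stepup(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0L) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  bh_stepup(p, q1 * m / m0)
}

#' Per-feature q values on the two-stage scale
#'
#' BH-adjusted p values rescaled by the stage-1 null-proportion estimate
#' `m0 / m`, capped at 1 -- the per-feature q values reported alongside the
#' binary [bky_fdr()] mask for volcano-style output.
#'
#' @inheritParams bky_fdr
#' @return numeric vector of q values.
#' @export
bky_qvalues <- function(pvalues, q = 0.05) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  m <- length(p)
  r1 <- sum(bh_stepup(p, q / (1 + q)))
  m0 <- max(m - r1, 1L)
  pmin(stats::p.adjust(p, "BH") * m0 / m, 1)
}

#' Multi-feature two-group scan
#'
#' Per-feature Welch t tests between the two groups with two-stage FDR
#' control at level `q`, reporting the mean difference (group1 - group2),
#' the t statistic, p and q values and the rejection flag -- the table
#' behind volcano plots of binned coverage, fragment scores or end-motif
#' frequencies. Features with fewer than 2 finite values in either group
#' are masked (all-NA row, excluded from the FDR step).
#'
#' @param mat numeric matrix or data.frame, samples x features.
#' @param groups factor (or coercible) with exactly 2 levels, one entry per
#'   sample; group1 is the first level.
#' @param q target FDR.
#' @return `data.table` with columns `feature`, `diff`, `t`, `p`,
#'   `q_value`, `rejected`.
#' @export
feature_scan <- function(mat, groups, q = 0.05) {
  mat <- as.matrix(mat)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (length(groups) != nrow(mat))
    stop("one group label per sample (matrix row) is required")
  feats <- colnames(mat)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(mat)))
  g1 <- groups == levels(groups)[1L]

  res <- lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[g1, j]; y <- mat[!g1, j]
    if (sum(is.finite(x)) < 2L || sum(is.finite(y)) < 2L)
      return(list(diff = NA_real_, t = NA_real_, p = NA_real_))
    w <- welch_t(x, y)
    list(diff = mean(x[is.finite(x)]) - mean(y[is.finite(y)]),
         t = w$t, p = w$p)
  })
  out <- data.table::data.table(
    feature = feats,
    diff = vapply(res, `[[`, numeric(1), "diff"),
    t = vapply(res, `[[`, numeric(1), "t"),
    p = vapply(res, `[[`, numeric(1), "p"))
  out[, q_value := NA_real_]
  out[, rejected := NA]
  ok <- !is.na(out$p)
  if (any(ok)) {
    out$q_value[ok] <- bky_qvalues(out$p[ok], q)
    out$rejected[ok] <- bky_fdr(out$p[ok], q)
  }
  data.table::setattr(out, "q", q)
  out
}

#' ROC area under the curve
#'
#' Rank-based AUC: the Mann-Whitney U statistic divided by `n1 * n2`, with
#' ties counted half. Orientation: a higher score predicts the positive
#' label. Attribute `oriented` reports `max(AUC, 1 - AUC)` for direction-
#' free comparisons.
#'
#' @param scores numeric predictor.
#' @param labels binary labels (logical, 0/1, or 2-level factor; the
#'   second level / `TRUE` / `1` is positive unless `positive` is given).
#' @param positive optional value of `labels` treated as positive.
#' @return AUC in `[0, 1]` with attribute `oriented`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  if (!is.null(positive)) {
    pos <- labels == positive
  } else if (is.logical(labels)) {
    pos <- labels
  } else if (is.factor(labels)) {
    pos <- labels == levels(labels)[2L]
  } else {
    u <- sort(unique(labels))
    if (length(u) > 2L) stop("labels must be binary")
    pos <- labels == u[length(u)]
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both label classes must be present")
  r <- rank(scores)                      # midranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(auc, oriented = max(auc, 1 - auc))
}

#' PCA feature integration
#'
#' Centres and unit-variance-scales the feature matrix, decomposes it by
#' SVD ([stats::prcomp()]) and reports per-component variance explained.
#' Zero-variance features are dropped (recorded in `dropped_features`).
#'
#' @param mat numeric matrix or data.frame, samples x features.
#' @param n_components maximum number of components kept (default 20).
#' @return list of class `pca_integration`: `scores` (samples x k),
#'   `loadings` (features x k), `var_explained` (percent, length k),
#'   `dropped_features`.
#' @export
pca_integrate <- function(mat, n_components = 20L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("at least 2 samples are required")
  v <- apply(mat, 2, stats::var)
  dropped <- colnames(mat)[!is.finite(v) | v == 0]
  keep <- is.finite(v) & v > 0
  if (sum(keep) < 2L) stop("fewer than 2 informative features remain")
  mat <- mat[, keep, drop = FALSE]
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$x))
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_explained = ve[seq_len(k)],
                 dropped_features = dropped),
            class = "pca_integration")
}

#' @export
print.pca_integration <- function(x, ...) {
  cat("PCA integration:", nrow(x$scores), "samples,",
      nrow(x$loadings), "features,", ncol(x$scores), "components\n")
  cat("  variance explained (%):",
      paste(format(utils::head(x$var_explained, 5), digits = 3),
            collapse = " "), "...\n")
  invisible(x)
}

#' Welch test of PC1 scores between two groups
#' @param pca a `pca_integration`.
#' @param groups two-level grouping, one per sample.
#' @return list with `t`, `df`, `p` (see [welch_t()]).
#' @export
pc1_group_test <- function(pca, groups) {
  groups <- factor(groups)
  s <- pca$scores[, 1L]
  welch_t(s[groups == levels(groups)[1L]],
          s[groups == levels(groups)[2L]])
}

#' Sample ordering by hierarchical clustering
#'
#' Correlation-distance, average-linkage clustering of samples over a
#' feature matrix (typically the scan-significant features), returning the
#' dendrogram leaf order.
#'
#' @param mat numeric matrix, samples x features.
#' @return integer leaf order.
#' @export
cluster_order <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L) return(seq_len(nrow(mat)))
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  stats::hclust(d, method = "average")$order
}
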