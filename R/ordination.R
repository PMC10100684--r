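#' Principal coordinates analysis
#'
#' Gower double-centering of the squared distance matrix followed by an
#' eigendecomposition. Coordinates are returned for axes with positive
#' eigenvalues (scaled so that, for Euclidean-embeddable input, pairwise
#' distances are reproduced); negative eigenvalues are retained in the
#' output and flagged.
#'
#' @param d a `dist` object or symmetric matrix with zero diagonal.
#' @return A list with `eigenvalues` (all, decreasing), `coordinates`
#'   (samples x positive axes) and `negative_eigenvalues` (logical flag).
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(dm)
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(1e-10, 1e-8 * max(abs(e$values)))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(eigenvalues = e$values,
       coordinates = coords,
       negative_eigenvalues = any(e$values < -1e-8 * max(abs(e$values))))
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' Constrained ordination for group discrimination: PCoA of the dissimilarity
#' matrix, then canonical discriminant analysis on the first `m` principal
#' coordinate axes. When `m = "auto"` the number of axes is chosen to
#' minimise the leave-one-out misclassification rate of a linear discriminant
#' classifier (ties resolved to the smallest m). Squared canonical
#' correlations (delta^2) between the retained axes and group membership are
#' reported per canonical axis.
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param groups per-sample group labels (>= 2 groups, each with >= 2
#'   samples).
#' @param m number of PCoA axes to retain, or `"auto"`.
#' @return A list of class `cap_result`: `m`, `delta_sq` (non-increasing, in
#'   `[0, 1]`), `sample_scores` (canonical axis scores),
#'   `loo_misclassification_rate`, `groups`.
#' @export
cap <- function(d, groups, m = "auto") {
  dm <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(dm)
  if (length(groups) != n) stop("'groups' must match the number of samples")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  pc <- pcoa(dm)
  Q <- pc$coordinates
  m_max <- min(ncol(Q), n - nlevels(groups) - 1)
  if (m_max < 1) stop("too few samples for any PCoA axis")
  loo_rate <- function(mm) {
    fit <- MASS::lda(Q[, seq_len(mm), drop = FALSE], grouping = groups,
                     CV = TRUE)
    mean(fit$class != groups)
  }
  if (identical(m, "auto")) {
    rates <- vapply(seq_len(m_max), loo_rate, numeric(1))
    m_use <- which.min(rates)  # ties -> smallest m
    loo <- rates[m_use]
  } else {
    if (!is.numeric(m) || m < 1) stop("'m' must be a positive count or 'auto'")
    if (m >= n) stop("'m' must be smaller than the number of samples")
    m_use <- min(as.integer(m), m_max)
    loo <- loo_rate(m_use)
  }
  X <- Q[, seq_len(m_use), drop = FALSE]
  Y <- stats::model.matrix(~ groups - 1)
  Y <- Y[, -ncol(Y), drop = FALSE]  # full column rank after centering
  cc <- stats::cancor(X, Y)
  n_axes <- min(nlevels(groups) - 1, m_use)
  delta_sq <- sort(cc$cor[seq_len(n_axes)]^2, decreasing = TRUE)
  fit <- MASS::lda(X, grouping = groups)
  scores <- stats::predict(fit, X)$x
  structure(list(m = m_use, delta_sq = delta_sq, sample_scores = scores,
                 loo_misclassification_rate = loo, groups = groups),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("CAP: m = %d PCoA axes, LOO misclassification %.3f\n",
              x$m, x$loo_misclassification_rate))
  cat("  squared canonical correlations:",
      paste(sprintf("%.3f", x$delta_sq), collapse = ", "), "\n")
  invisible(x)
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance in Anderson's direct
#' distance formulation: SS_total = sum of squared dissimilarities / n,
#' SS_within pooled per group, pseudo-F = (SS_between/(a-1)) /
#' (SS_within/(n-a)). The p-value counts permuted statistics at least as
#' large as the observed one, with the +1 correction (p is never 0).
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param groups per-sample group labels (>= 2 groups).
#' @param n_permutations number of label permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return A list of class `permanova_result`: `pseudo_F`, `r_squared`,
#'   `p_value`, `n_permutations`, `df`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L) {
  dm <- as.matrix(d)
  groups <- droplevels(as.factor(groups))
  n <- nrow(dm)
  if (length(groups) != n) stop("'groups' must match the number of samples")
  a <- nlevels(groups)
  if (a < 2) stop("need at least 2 groups")
  if (n_permutations < 99) stop("'n_permutations' must be >= 99")
  if (any(table(groups) < 2)) {
    warning("group(s) of size 1 contribute no within-group sum of squares")
  }
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_for <- function(g) {
    sum(vapply(levels(g), function(lv) {
      idx <- which(g == lv)
      if (length(idx) < 2) return(0)
      sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }, numeric(1)))
  }
  f_for <- function(g) {
    ssw <- ss_within_for(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_for(groups)
  ssw_obs <- ss_within_for(groups)
  perm_f <- with_seed(derive_seed(seed, "permanova"), function() {
    vapply(seq_len(n_permutations), function(i) f_for(groups[sample.int(n)]),
           numeric(1))
  })
  p <- (sum(perm_f >= f_obs) + 1) / (n_permutations + 1)
  structure(list(pseudo_F = f_obs,
                 r_squared = (ss_total - ssw_obs) / ss_total,
                 p_value = p,
                 n_permutations = as.integer(n_permutations),
                 df = c(between = a - 1L, within = as.integer(n - a))),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.3f (df %d, %d), R2 = %.3f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$df[["between"]], x$df[["within"]], x$r_squared, x$p_value,
    x$n_permutations))
  invisible(x)
}
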