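# log-CPM, detection-rate diagnostics, and quantile-covariate-corrected PCA.

#' Log counts per million
#'
#' `log2((count + c) / (libsize + 2c) * 1e6)` with prior count `c = 0.5` by
#' default, evaluated per cell; monotone in the count.
#'
#' @param counts genes x cells matrix.
#' @param library_sizes per-cell totals; defaults to `colSums(counts)`.
#' @param prior_count pseudocount `c` (default 0.5).
#' @return genes x cells matrix of log2 CPM values.
#' @export
log_cpm <- function(counts, library_sizes = NULL, prior_count = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stop_input("library sizes must be > 0")
  if (length(library_sizes) != ncol(counts))
    stop_input("one library size per cell required")
  t(log2(t(counts + prior_count) / (library_sizes + 2 * prior_count) * 1e6))
}

#' Gene detection rate per cell
#'
#' Fraction of genes with at least one molecule detected in each cell; the
#' dominant technical covariate of log-CPM data.
#'
#' @param counts genes x cells matrix.
#' @return Numeric vector, one rate in `[0, 1]` per cell.
#' @export
detection_rate <- function(counts) {
  counts <- as.matrix(counts)
  colMeans(counts >= 1)
}

#' Per-cell expression quantile covariates
#'
#' For each cell, the quantiles of its non-zero log-CPM values at the given
#' probabilities (default the five probabilities 0, 0.25, 0.5, 0.75, 1).
#' Cells with no detected gene get the quantiles of the all-zero log-CPM
#' floor. Rows are nondecreasing left to right by construction.
#'
#' @param x genes x cells log-CPM matrix (from [log_cpm()]).
#' @param counts the matching count matrix (defines "non-zero").
#' @param probs quantile probabilities.
#' @return cells x `length(probs)` matrix `Q`.
#' @export
quantile_covariates <- function(x, counts, probs = c(0, 0.25, 0.5, 0.75, 1)) {
  x <- as.matrix(x); counts <- as.matrix(counts)
  stopifnot(all(dim(x) == dim(counts)))
  Q <- t(vapply(seq_len(ncol(x)), function(j) {
    v <- x[counts[, j] > 0, j]
    if (!length(v)) v <- x[, j]
    quantile(v, probs = probs, names = FALSE, type = 7)
  }, numeric(length(probs))))
  colnames(Q) <- sprintf("q%g", probs)
  Q
}

#' Quantile-covariate-corrected principal component analysis
#'
#' PCA of a samples x genes log-CPM matrix after removing the systematic
#' dependence of each gene on per-sample expression quantiles (the detection
#' rate artifact), in three steps: (1) per-gene least-squares regression of
#' expression on the quantile covariates `Q` (with intercept), keeping
#' residuals; (2) alternating estimation of per-sample means `u` and
#' per-gene means `v` (two-way mean decomposition, iterated to relative
#' change < `tol`, then shifted so `mean(u) = 0`); (3) singular value
#' decomposition of the final residual, whose top `k` right singular vectors
#' are the components.
#'
#' @param X samples x genes matrix (note: transposed relative to
#'   [log_cpm()] output).
#' @param Q samples x q quantile covariate matrix, or `NULL` to skip step 1
#'   (plain double-centered PCA). Collinear columns are dropped.
#' @param k number of components.
#' @param tol convergence tolerance of the mean decomposition.
#' @return List with `loadings` (samples x k, `Z`), `components`
#'   (genes x k, `W`), `pve` (proportion of the input's total variance --
#'   about its grand mean -- explained per component; nonincreasing), `u`,
#'   `v`, `d` (singular values).
#' @export
corrected_pca <- function(X, Q = NULL, k = 10L, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= k) stop_input("need more samples (%d) than components (%d)", n, k)
  tot <- sum((X - mean(X))^2)
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (nrow(Q) != n) stop_input("Q must have one row per sample")
    qr_Q <- qr(cbind(1, Q))
    if (qr_Q$rank < ncol(Q) + 1L) {
      keep <- qr_Q$pivot[seq_len(qr_Q$rank)]
      keep <- setdiff(keep, 1L) - 1L
      message(sprintf("corrected_pca: dropping %d collinear quantile column(s)",
                      ncol(Q) - length(keep)))
      Q <- Q[, keep, drop = FALSE]
      qr_Q <- qr(cbind(1, Q))
    }
    # per-gene least squares on shared design: one QR, all genes at once
    X <- qr.resid(qr_Q, X)
  }
  u <- numeric(n); v <- numeric(p)
  repeat {
    u_new <- rowMeans(X - matrix(v, n, p, byrow = TRUE))
    v_new <- colMeans(X - u_new)
    delta <- max(abs(u_new - u), abs(v_new - v))
    u <- u_new; v <- v_new
    if (delta < tol * max(1, max(abs(u), abs(v)))) break
  }
  v <- v + mean(u); u <- u - mean(u)        # identifiability: mean(u) = 0
  R <- X - outer(u, rep(1, p)) - matrix(v, n, p, byrow = TRUE)
  k <- min(k, n - 1L, p)
  sv <- svd(R, nu = k, nv = k)
  pve <- if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k)
  Z <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  colnames(Z) <- colnames(sv$v) <- paste0("PC", seq_len(k))
  list(loadings = Z, components = sv$v, pve = pve, u = u, v = v,
       d = sv$d[seq_len(k)])
}

#' Association between a principal component and a categorical covariate
#'
#' Recodes the covariate as binary indicators, regresses the PC loadings on
#' them, and returns the coefficient of determination. A constant loading or
#' a single-level covariate yields `R^2 = 0` with a warning.
#'
#' @param loadings samples x k loading matrix (or a single numeric vector).
#' @param covariate factor-like vector, one value per sample.
#' @return Numeric vector of `R^2` values, one per component.
#' @export
pc_covariate_assoc <- function(loadings, covariate) {
  Z <- as.matrix(loadings)
  f <- droplevels(as.factor(covariate))
  if (nlevels(f) < 2L) {
    warning("covariate has a single level; R^2 = 0")
    return(setNames(rep(0, ncol(Z)), colnames(Z)))
  }
  D <- cbind(1, centered_indicators(f))
  qr_D <- qr(D)
  vapply(seq_len(ncol(Z)), function(j) {
    z <- Z[, j]
    tss <- sum((z - mean(z))^2)
    if (tss < .Machine$double.eps * length(z)) {
      warning("constant component; R^2 = 0")
      return(0)
    }
    1 - sum(qr.resid(qr_D, z)^2) / tss
  }, numeric(1L)) -> r2
  setNames(r2, colnames(Z))
}
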