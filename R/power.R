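# Measurement-error-aware power analysis: closed-form power and sample size,
# empirical-Bayes effect-size distributions, phenotype deconvolution, and
# noise-ratio summaries.

#' Power to detect a standardized QTL effect under measurement error
#'
#' `Pow(lambda, n, delta, alpha) = Phi(Phi^-1(alpha/2) + lambda *
#' sqrt(n / (1 + delta)))` where `lambda = b / sigma_r` is the effect size in
#' units of phenotypic residual standard deviation, `n` the number of
#' individuals, and `delta = sigma^2_m / sigma^2_r` the noise ratio
#' (measurement-error variance over residual variance). Only the
#' correctly-signed tail is counted, so power at `lambda = 0` equals
#' `alpha / 2`. A noise ratio of 1 is exactly equivalent to halving the
#' sample size.
#'
#' @param lambda_std standardized effect size (vectorized).
#' @param n number of individuals.
#' @param delta noise ratio, >= 0 (default 0).
#' @param alpha two-sided significance level in (0, 1).
#' @return Power (probability, vectorized).
#' @export
qtl_power <- function(lambda_std, n, delta = 0, alpha = 0.05) {
  if (any(alpha <= 0 | alpha >= 1)) stop_input("alpha must lie in (0, 1)")
  if (any(delta < 0)) stop_input("delta must be >= 0")
  if (any(n < 2)) stop_input("n must be >= 2")
  pnorm(qnorm(alpha / 2) + lambda_std * sqrt(n / (1 + delta)))
}

#' Calibrate a standardized effect size from a known power point
#'
#' Solves `Pow(lambda, n, delta, alpha) = target_power` for `lambda` in
#' closed form. Used e.g. to recover the effect size implied by a published
#' sample-size statement.
#'
#' @param n,delta,alpha as in [qtl_power()].
#' @param target_power desired power in (alpha/2, 1).
#' @return The standardized effect `lambda`.
#' @export
calibrate_lambda <- function(n, delta = 0, alpha = 0.05, target_power = 0.8) {
  (qnorm(target_power) - qnorm(alpha / 2)) / sqrt(n / (1 + delta))
}

#' Smallest sample size achieving a target power
#'
#' Closed-form continuous solution
#' `n* = (1 + delta) * ((Phi^-1(target) - Phi^-1(alpha/2)) / lambda)^2`,
#' then the smallest integer `n >= n*`. The `(1 + delta)` scaling law is
#' exact in the continuous relaxation.
#'
#' @param lambda_std standardized effect size, > 0.
#' @param delta noise ratio.
#' @param alpha significance level.
#' @param target_power target power in (alpha, 1).
#' @return Minimal integer number of individuals.
#' @export
solve_sample_size <- function(lambda_std, delta = 0, alpha = 0.05,
                              target_power = 0.8) {
  if (lambda_std <= 0) stop_input("lambda_std must be > 0 (target unreachable)")
  if (target_power <= alpha || target_power >= 1)
    stop_input("target_power must lie in (alpha, 1)")
  n_star <- (1 + delta) * ((qnorm(target_power) - qnorm(alpha / 2)) / lambda_std)^2
  n <- ceiling(n_star - 1e-9)
  # guard against floating point exactly on the power boundary
  eps <- 1e-12
  while (n > 2 && qtl_power(lambda_std, n - 1, delta, alpha) >= target_power - eps)
    n <- n - 1
  while (qtl_power(lambda_std, n, delta, alpha) < target_power - eps) n <- n + 1
  as.integer(max(n, 2))
}

# mixture component marginal likelihood of observation j under component k:
# normal components N(0, s2_k) convolved with N(., se_j^2); uniform
# components U(-a_k, a_k) convolved likewise; scale 0 = point mass at 0.
mix_lik_matrix <- function(x, se, scales, kind) {
  n <- length(x); K <- length(scales)
  L <- matrix(0, n, K)
  for (k in seq_len(K)) {
    a <- scales[k]
    if (a == 0) {
      L[, k] <- dnorm(x, 0, se)
    } else if (kind == "normal") {
      L[, k] <- dnorm(x, 0, sqrt(se^2 + a^2))
    } else {
      L[, k] <- (pnorm((x + a) / se) - pnorm((x - a) / se)) / (2 * a)
    }
  }
  L
}

#' Fit a unimodal effect-size distribution by empirical Bayes
#'
#' Adaptive-shrinkage-style estimation: the prior `g` over true effects is a
#' mixture over a fixed grid of zero-centered components (Gaussians for
#' effect sizes, symmetric uniforms for phenotype deconvolution) plus a
#' point mass at zero, and the mixture weights maximize the penalized
#' marginal likelihood `prod_j int N(x_j; b, se_j^2) g(db)` by EM. The
#' penalty places extra prior mass on the null component
#' (Dirichlet weight `penalty_on_null`), biasing the fit toward zero so the
#' estimated effects are conservative. The penalized marginal log-likelihood
#' is nondecreasing over EM iterations.
#'
#' @param beta_hat observed effects (or centered observed phenotypes).
#' @param se standard errors (or measurement-error standard deviations),
#'   same length, all > 0.
#' @param penalty_on_null Dirichlet weight on the null component
#'   (default 10; 1 = no penalty).
#' @param kind `"normal"` (effect sizes) or `"uniform"` (deconvolution).
#' @param scales optional component scale grid; default geometric from
#'   `min(se)/10` to `2 * max(|beta_hat|)` with ratio `sqrt(2)`, plus 0.
#' @param maxit,tol EM iteration cap and relative objective tolerance.
#' @return Object of class `effect_distribution`: list with `kind`,
#'   `scales`, `weights`, `loglik` (penalized objective trace),
#'   `marginal_loglik`, `n_iter`, and the data (`beta_hat`, `se`) needed for
#'   posterior summaries.
#' @export
fit_effect_distribution <- function(beta_hat, se, penalty_on_null = 10,
                                    kind = c("normal", "uniform"),
                                    scales = NULL, maxit = 500L, tol = 1e-10) {
  kind <- match.arg(kind)
  beta_hat <- as.numeric(beta_hat); se <- as.numeric(se)
  if (!length(beta_hat)) stop_input("empty input")
  if (length(se) != length(beta_hat)) stop_input("beta_hat and se lengths differ")
  if (any(se <= 0)) stop_input("se must be > 0")
  if (is.null(scales)) {
    lo <- min(se) / 10
    hi <- max(2 * max(abs(beta_hat)), lo * 2)
    scales <- lo * sqrt(2)^(0:ceiling(2 * log2(hi / lo)))
    scales <- scales[scales <= hi * sqrt(2)]
  }
  scales <- c(0, scales[scales > 0])
  K <- length(scales)
  pen <- c(penalty_on_null, rep(1, K - 1L))
  L <- mix_lik_matrix(beta_hat, se, scales, kind)
  L[L < 1e-300] <- 1e-300
  w <- rep(1 / K, K)
  obj <- function(w) sum(log(drop(L %*% w))) + sum((pen - 1) * log(pmax(w, 1e-300)))
  trace <- obj(w)
  for (it in seq_len(maxit)) {
    post <- t(t(L) * w)
    post <- post / rowSums(post)
    nk <- colSums(post) + pen - 1
    nk <- pmax(nk, 0)
    w_new <- nk / sum(nk)
    o <- obj(w_new)
    trace <- c(trace, o)
    done <- abs(o - trace[length(trace) - 1L]) <
      tol * (abs(o) + 1)
    w <- w_new
    if (done) break
  }
  structure(list(kind = kind, scales = scales, weights = w,
                 loglik = trace,
                 marginal_loglik = sum(log(drop(L %*% w))),
                 n_iter = length(trace) - 1L,
                 beta_hat = beta_hat, se = se),
            class = "effect_distribution")
}

#' @export
print.effect_distribution <- function(x, ...) {
  cat(sprintf("effect_distribution (%s mixture): %d components, null weight %.3f, sd %.4g\n",
              x$kind, length(x$scales), x$weights[1L], effect_sd(x)))
  invisible(x)
}

# standard deviation implied by the fitted mixture
effect_sd <- function(g) {
  v <- switch(g$kind,
              normal = sum(g$weights * g$scales^2),
              uniform = sum(g$weights * g$scales^2 / 3))
  sqrt(v)
}

#' Quantile of the absolute effect size under a fitted distribution
#'
#' Inverts the mixture CDF of `|b|` by bisection (tolerance 1e-10). For a
#' pure point mass at zero every quantile is 0.
#'
#' @param g an [fit_effect_distribution()] result.
#' @param prob probability in (0, 1), e.g. 0.99 for the strongest effects.
#' @return The `prob` quantile of `|b|`.
#' @export
effect_quantile <- function(g, prob) {
  if (prob <= 0 || prob >= 1) stop_input("prob must lie in (0, 1)")
  cdf_abs <- function(x) {
    contrib <- vapply(seq_along(g$scales), function(k) {
      a <- g$scales[k]
      if (a == 0) 1
      else if (g$kind == "normal") 2 * pnorm(x / a) - 1
      else min(x / a, 1)
    }, numeric(1L))
    sum(g$weights * contrib)
  }
  if (cdf_abs(0) >= prob) return(0)
  hi <- max(g$scales) * 10 + 1
  while (cdf_abs(hi) < prob) hi <- hi * 2
  lo <- 0
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (cdf_abs(mid) < prob) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# posterior mean of the true value given one observation, its measurement sd
# and the fitted mixture prior
posterior_means <- function(g, x = g$beta_hat, se = g$se) {
  L <- mix_lik_matrix(x, se, g$scales, g$kind)
  L[L < 1e-300] <- 1e-300
  post <- t(t(L) * g$weights)
  post <- post / rowSums(post)
  K <- length(g$scales)
  Em <- matrix(0, length(x), K)
  for (k in seq_len(K)) {
    a <- g$scales[k]
    if (a == 0) {
      Em[, k] <- 0
    } else if (g$kind == "normal") {
      Em[, k] <- x * a^2 / (a^2 + se^2)
    } else {
      # N(x, se^2) truncated to [-a, a]
      al <- (-a - x) / se; be <- (a - x) / se
      zden <- pnorm(be) - pnorm(al)
      zden[zden < 1e-300] <- 1e-300
      Em[, k] <- x + se * (dnorm(al) - dnorm(be)) / zden
    }
  }
  rowSums(post * Em)
}

#' Residual variance per gene by phenotype deconvolution
#'
#' Centers the observed phenotype within each gene, concatenates genes, fits
#' a common unimodal mixture-of-uniforms prior over true phenotypes given
#' per-observation measurement-error variances, and estimates each gene's
#' residual variance as the sample variance of the posterior mean true
#' phenotypes. When all measurement variances are zero the posterior means
#' equal the observations and the estimate reduces to the sample variance.
#'
#' @param y_tilde observed phenotype values (vector over individual-gene
#'   observations).
#' @param sigma2_m matching measurement-error variances, >= 0.
#' @param gene factor-like vector assigning each observation to a gene.
#' @param penalty_on_null see [fit_effect_distribution()].
#' @return List with `sigma2_r` (named per-gene residual variances),
#'   `posterior_mean` (per observation) and the fitted prior `g`.
#' @export
deconvolve_residual_variance <- function(y_tilde, sigma2_m, gene,
                                         penalty_on_null = 10) {
  y_tilde <- as.numeric(y_tilde); sigma2_m <- as.numeric(sigma2_m)
  gene <- as.factor(gene)
  stopifnot(length(y_tilde) == length(sigma2_m),
            length(y_tilde) == length(gene))
  if (any(sigma2_m < 0)) stop_input("sigma2_m must be >= 0")
  yc <- y_tilde - ave(y_tilde, gene)
  if (all(sigma2_m == 0)) {
    pm <- yc
  } else {
    se <- sqrt(pmax(sigma2_m, 1e-12 * max(sigma2_m)))
    g <- fit_effect_distribution(yc, se, penalty_on_null = penalty_on_null,
                                 kind = "uniform")
    pm <- posterior_means(g)
  }
  s2 <- tapply(pm, gene, var)
  out <- list(sigma2_r = setNames(as.numeric(s2), names(s2)),
              posterior_mean = pm)
  if (!all(sigma2_m == 0)) out$g <- g
  out
}

#' Noise-ratio summary across genes
#'
#' Aggregates per-individual, per-gene measurement-error variances to a
#' per-gene value by the median across individuals, forms the per-gene noise
#' ratio against the residual variances, and summarizes: `delta_hat` is the
#' median of per-gene ratios and `sigma_r_typical = sqrt(median(sigma2_r))`
#' is the typical residual standard deviation used to standardize an effect
#' size `b` into `lambda = b / sigma_r_typical`. Genes with zero residual
#' variance are excluded from the medians.
#'
#' @param sigma2_m_ind_gene data.frame with columns `gene`, `sigma2_m` (one
#'   row per individual-gene), or a named per-gene numeric vector of
#'   already-aggregated values.
#' @param sigma2_r_gene named per-gene residual variances (e.g. from
#'   [deconvolve_residual_variance()]).
#' @param b optional raw effect size to standardize.
#' @return List with `per_gene` (data.frame gene/sigma2_m/sigma2_r/delta),
#'   `delta_hat`, `sigma_r_typical`, and `lambda` (if `b` supplied).
#' @export
noise_ratio_summary <- function(sigma2_m_ind_gene, sigma2_r_gene, b = NULL) {
  if (is.data.frame(sigma2_m_ind_gene)) {
    s2m <- tapply(sigma2_m_ind_gene$sigma2_m, sigma2_m_ind_gene$gene, median)
    s2m <- setNames(as.numeric(s2m), names(s2m))
  } else {
    s2m <- sigma2_m_ind_gene
  }
  genes <- intersect(names(s2m), names(sigma2_r_gene))
  if (!length(genes)) stop_input("no shared genes between measurement and residual variances")
  s2m <- s2m[genes]; s2r <- sigma2_r_gene[genes]
  ok <- s2r > 0
  if (any(!ok)) message(sprintf("noise_ratio_summary: excluding %d gene(s) with zero residual variance", sum(!ok)))
  per_gene <- data.frame(gene = genes, sigma2_m = s2m, sigma2_r = s2r,
                         delta = ifelse(ok, s2m / s2r, NA_real_),
                         row.names = NULL, stringsAsFactors = FALSE)
  delta_hat <- median(per_gene$delta[ok])
  sigma_r_typical <- sqrt(median(s2r[ok]))
  out <- list(per_gene = per_gene, delta_hat = delta_hat,
              sigma_r_typical = sigma_r_typical)
  if (!is.null(b)) out$lambda <- b / sigma_r_typical
  out
}
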