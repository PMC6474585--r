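#' Bundle UMI counts for one individual-gene pair
#'
#' A `count_slice` holds the observed molecule counts of a single gene across
#' the cells of a single individual, together with the per-cell size factors
#' (total molecules detected per cell) and a matrix of technical confounders.
#' This is the unit of data that one ZINB fit consumes.
#'
#' Confounder columns are centered to mean zero over the cells in the slice
#' (the fitting set) unless `center = FALSE`, which is used when resampling
#' cells from an already-centered design (e.g. in the bootstrap, where the
#' original centering must be kept so the coefficients retain their meaning).
#'
#' @param counts non-negative integer vector of molecule counts, one per cell.
#' @param size_factors positive numeric vector, same length as `counts`;
#'   conventionally the total molecules detected in each cell.
#' @param confounders numeric matrix with one row per cell (or `NULL` for no
#'   confounders), e.g. centered chip indicators from [centered_indicators].
#' @param individual_id,gene_id optional labels carried through to results.
#' @param center center confounder columns to mean zero (default `TRUE`).
#' @return An object of class `count_slice`.
#' @export
count_slice <- function(counts, size_factors, confounders = NULL,
                        individual_id = NA_character_, gene_id = NA_character_,
                        center = TRUE) {
  counts <- as.numeric(counts)
  size_factors <- as.numeric(size_factors)
  if (length(counts) != length(size_factors))
    stop_input("counts and size_factors must have the same length (%d vs %d)",
               length(counts), length(size_factors))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop_input("counts must be finite non-negative integers")
  if (any(!is.finite(size_factors)) || any(size_factors <= 0))
    stop_input("size_factors must be finite and > 0")
  if (is.null(confounders)) {
    confounders <- matrix(0, nrow = length(counts), ncol = 0L)
  } else {
    confounders <- as.matrix(confounders)
    if (nrow(confounders) != length(counts))
      stop_input("confounders must have one row per cell (%d rows vs %d cells)",
                 nrow(confounders), length(counts))
    if (any(!is.finite(confounders)))
      stop_input("confounders must be finite")
    if (center && ncol(confounders) > 0L)
      confounders <- scale(confounders, center = TRUE, scale = FALSE)[, , drop = FALSE]
  }
  structure(list(counts = counts, size_factors = size_factors,
                 confounders = confounders,
                 individual_id = individual_id, gene_id = gene_id),
            class = "count_slice")
}

#' @export
print.count_slice <- function(x, ...) {
  cat(sprintf("count_slice: %d cells, gene %s, individual %s, %d confounder column(s)\n",
              length(x$counts), x$gene_id, x$individual_id, ncol(x$confounders)))
  invisible(x)
}

#' ZINB model parameters for one individual-gene pair
#'
#' Parameters of the zero-inflated negative binomial observation model in the
#' unconstrained parameterization: `log_mean` = ln(mu) where mu is
#' proportional to relative abundance, `log_disp` = ln(phi) where phi
#' controls the mean-variance relationship of latent expression
#' (V = mu^2 phi for the Gamma component), and `logit_zero` = logit(pi) where
#' pi is the proportion of excess zeros. `confounder_effects` is the vector
#' of per-gene coefficients on the (centered) confounder columns.
#'
#' @param log_mean,log_disp,logit_zero finite scalars.
#' @param confounder_effects numeric vector (may be length 0).
#' @return An object of class `zinb_params`.
#' @export
zinb_params <- function(log_mean, log_disp, logit_zero = -Inf,
                        confounder_effects = numeric(0)) {
  if (!is.finite(log_mean) || !is.finite(log_disp))
    stop_input("log_mean and log_disp must be finite")
  if (is.na(logit_zero)) stop_input("logit_zero must not be NA")
  structure(list(log_mean = as.numeric(log_mean),
                 log_disp = as.numeric(log_disp),
                 logit_zero = as.numeric(logit_zero),
                 confounder_effects = as.numeric(confounder_effects)),
            class = "zinb_params")
}

#' @export
print.zinb_params <- function(x, ...) {
  cat(sprintf("zinb_params: ln mu = %.4g, ln phi = %.4g, logit pi = %.4g, %d confounder effect(s)\n",
              x$log_mean, x$log_disp, x$logit_zero, length(x$confounder_effects)))
  invisible(x)
}

#' Numerical safety floors and optimizer settings for ZINB fitting
#'
#' `pi_eps` clips the zero-inflation probability into
#' `[pi_eps, 1 - pi_eps]` and `phi_min` floors the dispersion during
#' likelihood evaluation, avoiding log overflow at extreme parameter values.
#' The same bounds are used as box constraints by the optimizer. `maxit` and
#' `reltol` control the L-BFGS-B runs of both fitting stages.
#'
#' @param pi_eps floor on pi and 1 - pi.
#' @param phi_min floor on phi.
#' @param maxit iteration cap per optimizer stage.
#' @param reltol relative log-likelihood convergence tolerance (`factr` is
#'   derived from it).
#' @return A list of settings.
#' @export
zinb_control <- function(pi_eps = 1e-12, phi_min = 1e-8,
                         maxit = 1000L, reltol = 1e-10) {
  list(pi_eps = pi_eps, phi_min = phi_min,
       maxit = as.integer(maxit), reltol = reltol,
       logit_pi_bound = qlogis(1 - pi_eps),
       log_phi_min = log(phi_min))
}

# Per-cell scale s_j = R_j * exp(x_j' beta) * mu.
cell_scale <- function(slice, params) {
  eta <- if (ncol(slice$confounders) > 0L)
    drop(slice$confounders %*% params$confounder_effects) else 0
  slice$size_factors * exp(eta + params$log_mean)
}

# NB log pmf with mean s, dispersion phi (size = a = 1/phi), written so
# that large 1/phi (near-Poisson) stays accurate.
nb_log_pmf <- function(r, s, phi = NULL, a = NULL) {
  if (is.null(a)) a <- 1 / phi
  log_ratio <- log1p(s / a)                  # log((a + s)/a)
  lgamma(r + a) - lgamma(a) - lgamma(r + 1) - a * log_ratio +
    r * (log(s) - log(a) - log_ratio)
}

# Vector of per-cell ZINB log probabilities (Eqs 10-12 structure): zeros mix
# the point mass with the NB term on the log scale.
zinb_cell_loglik <- function(r, s, phi, pi) {
  nb <- nb_log_pmf(r, s, phi)
  out <- log1p(-pi) + nb
  z <- r == 0
  if (any(z)) out[z] <- logsumexp2(log(pi), out[z])
  out
}

clip_params <- function(params, control) {
  phi <- max(exp(params$log_disp), control$phi_min)
  pi <- min(max(plogis(params$logit_zero), control$pi_eps), 1 - control$pi_eps)
  list(phi = phi, pi = pi)
}

#' ZINB log likelihood of a count slice
#'
#' Sum over cells of the log probability of the observed molecule count under
#' the zero-inflated negative binomial model, with per-cell scale
#' `s_j = R_j exp(x_j' beta) mu`. Zero counts combine the point mass at zero
#' with the negative binomial component via log-sum-exp; the dispersion and
#' zero-inflation probability are floored per `control` for numerical safety.
#'
#' @param slice a [count_slice].
#' @param params a [zinb_params].
#' @param control numerical floors, see [zinb_control()].
#' @return Scalar log likelihood.
#' @export
zinb_log_likelihood <- function(slice, params, control = zinb_control()) {
  stopifnot(inherits(slice, "count_slice"))
  if (!inherits(params, "zinb_params")) stop_input("params must be zinb_params")
  if (!is.finite(params$log_mean) || !is.finite(params$log_disp))
    stop_input("non-finite parameters")
  if (length(params$confounder_effects) != ncol(slice$confounders))
    stop_input("confounder_effects length (%d) does not match confounder columns (%d)",
               length(params$confounder_effects), ncol(slice$confounders))
  cp <- clip_params(params, control)
  sum(zinb_cell_loglik(slice$counts, cell_scale(slice, params), cp$phi, cp$pi))
}

#' ZINB probability mass function
#'
#' Probability of observing count `r` in a cell with the given size factor
#' and confounder row, under `params`.
#'
#' @param r non-negative integer count (vectorized).
#' @param size_factor positive scalar.
#' @param params a [zinb_params].
#' @param confounders numeric vector of confounder values for the cell
#'   (default none).
#' @param control see [zinb_control()].
#' @return Probability (vector over `r`).
#' @export
zinb_pmf <- function(r, size_factor, params, confounders = numeric(0),
                     control = zinb_control()) {
  if (any(r < 0) || any(r != floor(r))) stop_input("r must be a non-negative integer")
  cp <- clip_params(params, control)
  eta <- if (length(confounders)) sum(confounders * params$confounder_effects) else 0
  s <- size_factor * exp(eta + params$log_mean)
  exp(zinb_cell_loglik(r, s, cp$phi, cp$pi))
}

#' ZINB cumulative distribution function
#'
#' `F(r)` for integer `r`; `r = -1` (or any negative value) returns 0, so the
#' randomized-quantile construction `Uniform(F(x - 1), F(x))` is well defined
#' at `x = 0`. Uses the closed form `pi + (1 - pi) * NB cdf` for `r >= 0`.
#'
#' @inheritParams zinb_pmf
#' @return Probability (vector over `r`).
#' @export
zinb_cdf <- function(r, size_factor, params, confounders = numeric(0),
                     control = zinb_control()) {
  cp <- clip_params(params, control)
  eta <- if (length(confounders)) sum(confounders * params$confounder_effects) else 0
  s <- size_factor * exp(eta + params$log_mean)
  out <- numeric(length(r))
  pos <- r >= 0
  out[pos] <- cp$pi + (1 - cp$pi) *
    pnbinom(floor(r[pos]), size = 1 / cp$phi, mu = s)
  out
}

#' Mean and variance of latent gene expression
#'
#' Moments of the latent expression level lambda under the point-Gamma
#' mixture: `E = (1 - pi) mu` and
#' `V = (1 - pi) mu^2 phi + pi (1 - pi) mu^2`. These are moments of latent
#' expression itself, so size factors and confounder effects do not enter.
#'
#' @param params a [zinb_params].
#' @return List with elements `mean` and `variance`.
#' @export
latent_moments <- function(params) {
  mu <- exp(params$log_mean)
  phi <- exp(params$log_disp)
  pi <- plogis(params$logit_zero)
  list(mean = (1 - pi) * mu,
       variance = (1 - pi) * mu^2 * phi + pi * (1 - pi) * mu^2)
}

#' Derived expression phenotypes for one individual-gene pair
#'
#' Computes the five quantitative phenotypes used for QTL mapping: latent
#' mean and variance, coefficient of variation (sd/mean), Fano factor
#' (variance/mean), and dispersion (ln phi). CV and Fano are undefined when
#' the latent mean is zero and are returned as `NA` rather than raising an
#' error.
#'
#' @param params a [zinb_params].
#' @return Named numeric vector with elements
#'   `mean`, `variance`, `cv`, `fano`, `dispersion`.
#' @export
derived_phenotypes <- function(params) {
  m <- latent_moments(params)
  cv <- if (m$mean > 0) sqrt(m$variance) / m$mean else NA_real_
  fano <- if (m$mean > 0) m$variance / m$mean else NA_real_
  c(mean = m$mean, variance = m$variance, cv = cv, fano = fano,
    dispersion = params$log_disp)
}
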