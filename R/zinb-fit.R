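# Two-stage maximum-likelihood fitting of the ZINB model, per individual-gene
# slice, plus dataset-level fitting and bootstrap measurement-error variances.

# Negative NB log likelihood and gradient in par = (log_mu, log_phi, beta).
# phi is box-bounded by the optimizer, so no clipping is needed here.
nb_obj <- function(par, r, R, X) {
  q <- ncol(X)
  log_mu <- par[1L]; log_phi <- par[2L]
  beta <- if (q) par[3L:(2L + q)] else numeric(0)
  eta <- if (q) drop(X %*% beta) else 0
  s <- R * exp(eta + log_mu)
  a <- exp(-log_phi)
  ll <- nb_log_pmf(r, s, a = a)
  # gradient pieces per cell
  d_logmu <- r - s * (r + a) / (a + s)
  d_logphi <- -a * (digamma(r + a) - digamma(a) - log1p(s / a) +
                      1 - (r + a) / (a + s))
  g <- c(sum(d_logmu), sum(d_logphi),
         if (q) drop(crossprod(X, d_logmu)) else numeric(0))
  list(value = -sum(ll), gradient = -g)
}

# Negative ZINB log likelihood and gradient in
# par = (log_mu, log_phi, logit_pi, beta).
zinb_obj <- function(par, r, R, X) {
  q <- ncol(X)
  log_mu <- par[1L]; log_phi <- par[2L]; t <- par[3L]
  beta <- if (q) par[4L:(3L + q)] else numeric(0)
  eta <- if (q) drop(X %*% beta) else 0
  s <- R * exp(eta + log_mu)
  a <- exp(-log_phi)
  p <- plogis(t)
  nb <- nb_log_pmf(r, s, a = a)
  d_logmu <- r - s * (r + a) / (a + s)
  d_logphi <- -a * (digamma(r + a) - digamma(a) - log1p(s / a) +
                      1 - (r + a) / (a + s))
  z <- r == 0
  lnb <- log1p(-p) + nb                      # log((1-p) * NB(r))
  ll <- lnb
  w <- rep(1, length(r))                      # weight on the NB branch
  d_t <- rep(-p, length(r))
  if (any(z)) {
    lz <- logsumexp2(log(p), lnb[z])          # log(p + (1-p) NB(0))
    ll[z] <- lz
    w[z] <- exp(lnb[z] - lz)
    # d/dt log(p + (1-p) e^nb) = p(1-p)(1 - e^nb) / (p + (1-p) e^nb)
    d_t[z] <- p * (1 - p) * (1 - exp(nb[z])) * exp(-lz)
  }
  g <- c(sum(w * d_logmu), sum(w * d_logphi), sum(d_t),
         if (q) drop(crossprod(X, w * d_logmu)) else numeric(0))
  list(value = -sum(ll), gradient = -g)
}

run_lbfgsb <- function(par0, obj, lower, upper, control, ...) {
  fn <- function(p) obj(p, ...)$value
  gr <- function(p) obj(p, ...)$gradient
  res <- tryCatch(
    optim(par0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = control$maxit,
                         factr = control$reltol / .Machine$double.eps)),
    error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$par)) || !is.finite(res$value) ||
      res$value > fn(par0)) {
    # fall back to a gradient-free polish from the initial point
    res2 <- tryCatch(
      optim(par0, function(p) fn(pmin(pmax(p, lower), upper)),
            method = "Nelder-Mead", control = list(maxit = 2000L)),
      error = function(e) NULL)
    if (!is.null(res2) && is.finite(res2$value) && res2$value <= fn(par0)) {
      res2$par <- pmin(pmax(res2$par, lower), upper)
      res2$counts <- c(res2$counts[1L], 0)
      res2$convergence <- 1L
      return(res2)
    }
    return(list(par = par0, value = fn(par0), counts = c(0, 0),
                convergence = 1L))
  }
  res
}

#' Stage-1 fit: negative binomial maximum likelihood
#'
#' Maximizes the NB log likelihood (the ZINB likelihood without zero
#' inflation) over `(ln mu, ln phi, beta)` using box-constrained quasi-Newton
#' optimization with analytic gradients. The box bounds implement the
#' numerical floors of [zinb_control()]. By default `ln mu` is initialized at
#' the moment estimate `ln(sum(r)/sum(R))` and `ln phi`, `beta` at zero; any
#' optimizer reaching the same log likelihood is equivalent.
#'
#' @param slice a [count_slice]; at least 2 cells and at least one nonzero
#'   count are required.
#' @param init optional numeric vector `(log_mean, log_disp, beta...)`.
#' @param control see [zinb_control()].
#' @return List with `log_mean`, `log_disp`, `confounder_effects`, `loglik`,
#'   `iterations`, `converged`.
#' @export
fit_nb_stage <- function(slice, init = NULL, control = zinb_control()) {
  stopifnot(inherits(slice, "count_slice"))
  r <- slice$counts
  if (length(r) < 2L) stop_degenerate("need at least 2 cells, got %d", length(r))
  if (all(r == 0)) stop_degenerate("all counts are zero; NB mean is not identifiable")
  X <- slice$confounders
  q <- ncol(X)
  par0 <- if (!is.null(init)) as.numeric(init)
          else c(log(sum(r) / sum(slice$size_factors)), 0, rep(0, q))
  if (length(par0) != 2L + q) stop_input("init has wrong length")
  lower <- c(-50, control$log_phi_min, rep(-20, q))
  upper <- c(50, 20, rep(20, q))
  par0 <- pmin(pmax(par0, lower), upper)
  res <- run_lbfgsb(par0, nb_obj, lower, upper, control, r = r,
                    R = slice$size_factors, X = X)
  list(log_mean = res$par[1L], log_disp = res$par[2L],
       confounder_effects = if (q) res$par[3L:(2L + q)] else numeric(0),
       loglik = -res$value, iterations = unname(res$counts[1L]),
       converged = res$convergence == 0L)
}

#' Stage-2 fit: zero-inflated negative binomial maximum likelihood
#'
#' Starts from the stage-1 NB solution with `logit(pi) = -8` (negligible
#' zero inflation) and maximizes the full ZINB log likelihood over
#' `(ln mu, ln phi, logit pi, beta)`. The final log likelihood is guaranteed
#' to be at least the likelihood at the initialization: if the optimizer
#' fails to improve, the initial point is returned with `converged = FALSE`.
#'
#' @param slice a [count_slice].
#' @param stage1 optional result of [fit_nb_stage()]; computed if missing.
#' @param control see [zinb_control()].
#' @param init_logit_pi initial value of `logit(pi)`; the default `-8`
#'   corresponds to negligible zero inflation. Warm-started refits (e.g. the
#'   bootstrap) pass the previously fitted value instead.
#' @return An object of class `zinb_fit`: list with `params`
#'   ([zinb_params]), `stage1_params`, `final_loglik`, `init_loglik`,
#'   `iterations`, `converged`, `n_cells`.
#' @export
fit_zinb <- function(slice, stage1 = NULL, control = zinb_control(),
                     init_logit_pi = -8) {
  stopifnot(inherits(slice, "count_slice"))
  if (is.null(stage1)) stage1 <- fit_nb_stage(slice, control = control)
  q <- ncol(slice$confounders)
  par0 <- c(stage1$log_mean, stage1$log_disp, init_logit_pi,
            stage1$confounder_effects)
  lower <- c(-50, control$log_phi_min, -control$logit_pi_bound, rep(-20, q))
  upper <- c(50, 20, control$logit_pi_bound, rep(20, q))
  par0 <- pmin(pmax(par0, lower), upper)
  init_nll <- zinb_obj(par0, slice$counts, slice$size_factors,
                       slice$confounders)$value
  res <- run_lbfgsb(par0, zinb_obj, lower, upper, control, r = slice$counts,
                    R = slice$size_factors, X = slice$confounders)
  params <- zinb_params(res$par[1L], res$par[2L], res$par[3L],
                        if (q) res$par[4L:(3L + q)] else numeric(0))
  structure(list(params = params,
                 stage1_params = stage1,
                 final_loglik = -res$value,
                 init_loglik = -init_nll,
                 iterations = unname(res$counts[1L]) + stage1$iterations,
                 converged = res$convergence == 0L && stage1$converged,
                 n_cells = length(slice$counts)),
            class = "zinb_fit")
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat(sprintf("zinb_fit: %d cells, loglik %.3f, converged: %s\n",
              x$n_cells, x$final_loglik, x$converged))
  print(x$params)
  invisible(x)
}

#' Fit the ZINB model to every individual-gene pair of a dataset
#'
#' Runs the two-stage fit independently for each individual and each gene in
#' a dataset bundle (see [read_counts()] / [simulate_counts()]), controlling
#' for the supplied confounder column (by default the C1 chip, recoded as
#' centered binary indicators with one level dropped). Genes whose fit fails
#' in an individual (e.g. all-zero counts) yield missing phenotype values
#' with the reason recorded in the fit table.
#'
#' @param bundle dataset bundle with fields `counts` (genes x cells),
#'   `cells` (metadata with columns `cell`, `individual`, and the confounder
#'   columns), `genes` (metadata with column `gene`).
#' @param confounders character vector of `cells` columns to recode as
#'   centered indicators (default `"chip"`); use `character(0)` for none.
#' @param size_factor_col `cells` column with total molecules per cell, or
#'   `NULL` to use the column sums of `counts`.
#' @param control see [zinb_control()].
#' @return List with `fits` (data.frame: individual, gene, ln_mu, ln_phi,
#'   logit_pi, loglik, converged, n_cells, reason) and `phenotypes`, a named
#'   list of five individuals x genes matrices
#'   (`mean`, `variance`, `cv`, `fano`, `dispersion`).
#' @export
fit_dataset <- function(bundle, confounders = "chip",
                        size_factor_col = "total_molecules",
                        control = zinb_control()) {
  counts <- as.matrix(bundle$counts)
  cells <- bundle$cells
  genes <- as.character(bundle$genes$gene)
  inds <- unique(as.character(cells$individual))
  confounders <- intersect(confounders, colnames(cells))
  sf_all <- if (!is.null(size_factor_col) && size_factor_col %in% colnames(cells))
    as.numeric(cells[[size_factor_col]]) else colSums(counts)
  phen_kinds <- c("mean", "variance", "cv", "fano", "dispersion")
  phen <- lapply(phen_kinds, function(k)
    matrix(NA_real_, length(inds), length(genes), dimnames = list(inds, genes)))
  names(phen) <- phen_kinds
  rows <- vector("list", length(inds) * length(genes))
  idx <- 0L
  for (i in seq_along(inds)) {
    sel <- which(as.character(cells$individual) == inds[i])
    X <- if (length(confounders))
      do.call(cbind, lapply(confounders, function(cc) centered_indicators(cells[[cc]][sel])))
    else NULL
    for (k in seq_along(genes)) {
      idx <- idx + 1L
      fit <- tryCatch({
        sl <- count_slice(counts[k, sel], sf_all[sel], X,
                          individual_id = inds[i], gene_id = genes[k],
                          center = FALSE)
        fit_zinb(sl, control = control)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[idx]] <- data.frame(individual = inds[i], gene = genes[k],
                                  ln_mu = NA_real_, ln_phi = NA_real_,
                                  logit_pi = NA_real_, loglik = NA_real_,
                                  converged = FALSE, n_cells = length(sel),
                                  reason = conditionMessage(fit),
                                  stringsAsFactors = FALSE)
        next
      }
      ph <- derived_phenotypes(fit$params)
      for (kind in phen_kinds) phen[[kind]][i, k] <- ph[[kind]]
      rows[[idx]] <- data.frame(individual = inds[i], gene = genes[k],
                                ln_mu = fit$params$log_mean,
                                ln_phi = fit$params$log_disp,
                                logit_pi = fit$params$logit_zero,
                                loglik = fit$final_loglik,
                                converged = fit$converged,
                                n_cells = fit$n_cells, reason = "",
                                stringsAsFactors = FALSE)
    }
  }
  list(fits = do.call(rbind, rows), phenotypes = phen)
}

#' Bootstrap measurement-error variance of a derived phenotype
#'
#' Nonparametrically resamples cells (count, size factor, confounder row
#' triplets) with replacement, refits the ZINB model warm-started from the
#' original fit, and returns the sample variance of the chosen phenotype
#' across bootstrap replicates -- the measurement-error variance
#' `sigma^2_m` of that individual-gene phenotype. Replicates with all-zero
#' counts are dropped (and counted in `n_dropped`).
#'
#' @param slice the original [count_slice].
#' @param fit the [fit_zinb()] result for `slice`.
#' @param phenotype_kind one of `"mean"`, `"variance"`, `"cv"`, `"fano"`,
#'   `"dispersion"`.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer seed; results are reproducible and independent of
#'   processing order via a derived stream.
#' @param control see [zinb_control()].
#' @return List with `sigma2_m`, `n_bootstrap` (surviving replicates),
#'   `n_dropped`, `phenotype_kind`, `individual_id`, `gene_id`, `values`.
#' @export
bootstrap_measurement_variance <- function(slice, fit,
                                           phenotype_kind = "dispersion",
                                           n_boot = 100L, seed = 1L,
                                           control = zinb_control()) {
  stopifnot(inherits(slice, "count_slice"), inherits(fit, "zinb_fit"))
  phenotype_kind <- match.arg(phenotype_kind,
                              c("mean", "variance", "cv", "fano", "dispersion"))
  n <- length(slice$counts)
  set.seed(derive_seed(seed, 1L, 0L))
  warm <- c(fit$params$log_mean, fit$params$log_disp, fit$params$logit_zero,
            fit$params$confounder_effects)
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (all(slice$counts[idx] == 0)) next
    bs <- count_slice(slice$counts[idx], slice$size_factors[idx],
                      slice$confounders[idx, , drop = FALSE],
                      individual_id = slice$individual_id,
                      gene_id = slice$gene_id, center = FALSE)
    st1 <- list(log_mean = warm[1L], log_disp = warm[2L],
                confounder_effects = warm[-(1:3)],
                loglik = NA_real_, iterations = 0L, converged = TRUE)
    bf <- tryCatch(fit_zinb(bs, stage1 = st1, control = control,
                            init_logit_pi = warm[3L]),
                   error = function(e) NULL)
    if (!is.null(bf)) vals[b] <- derived_phenotypes(bf$params)[[phenotype_kind]]
  }
  ok <- vals[is.finite(vals)]
  if (length(ok) < 2L)
    stop_degenerate("fewer than 2 surviving bootstrap replicates")
  list(sigma2_m = var(ok), n_bootstrap = length(ok),
       n_dropped = n_boot - length(ok), phenotype_kind = phenotype_kind,
       individual_id = slice$individual_id, gene_id = slice$gene_id,
       values = ok)
}
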