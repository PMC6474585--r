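# Randomized-quantile goodness-of-fit testing of fitted ZINB models.

#' Randomized quantiles of observed counts under a fitted ZINB model
#'
#' For each cell, draws `u ~ Uniform(F(x - 1), F(x))` where `F` is the fitted
#' ZINB cdf for that cell (each cell has its own distribution because the
#' size factor and confounder values are cell-specific). If the model is
#' correct, the `u` are exactly Uniform(0, 1), which makes them the basis of
#' a distribution-free goodness-of-fit test for discrete data.
#'
#' @param slice the observed [count_slice].
#' @param fit the [fit_zinb()] result (or a [zinb_params] object).
#' @param seed integer seed for the uniform draws.
#' @param control see [zinb_control()].
#' @return Numeric vector of randomized quantiles in `[0, 1]`, one per cell.
#' @export
randomized_quantiles <- function(slice, fit, seed = 1L,
                                 control = zinb_control()) {
  stopifnot(inherits(slice, "count_slice"))
  params <- if (inherits(fit, "zinb_fit")) fit$params else fit
  if (!inherits(params, "zinb_params")) stop_input("fit must be zinb_fit or zinb_params")
  cp <- clip_params(params, control)
  s <- cell_scale(slice, params)
  size <- 1 / cp$phi
  F_hi <- cp$pi + (1 - cp$pi) * pnbinom(slice$counts, size = size, mu = s)
  F_lo <- ifelse(slice$counts > 0,
                 cp$pi + (1 - cp$pi) * pnbinom(slice$counts - 1, size = size, mu = s),
                 0)
  set.seed(derive_seed(seed, 2L, 1L))
  runif(length(s), F_lo, F_hi)
}

#' One-sample Kolmogorov-Smirnov test against Uniform(0, 1)
#'
#' Wraps [stats::ks.test()]; the p-value is exact for n < 100 and asymptotic
#' otherwise (the `ks.test` default for one-sample tests without ties --
#' randomized quantiles are continuous, so ties occur with probability 0).
#'
#' @param u numeric vector in `[0, 1]`, length >= 5.
#' @return List with `statistic` and `p_value`.
#' @export
ks_uniformity_test <- function(u) {
  if (length(u) < 5L) stop_input("need at least 5 values, got %d", length(u))
  kt <- ks.test(u, "punif")
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Goodness-of-fit test for one fitted individual-gene pair
#'
#' Convenience wrapper: randomized quantiles followed by the KS uniformity
#' test.
#'
#' @inheritParams randomized_quantiles
#' @return data.frame row with `individual`, `gene`, `ks_stat`, `p_value`,
#'   `n_cells`.
#' @export
gof_test <- function(slice, fit, seed = 1L, control = zinb_control()) {
  u <- randomized_quantiles(slice, fit, seed = seed, control = control)
  kt <- ks_uniformity_test(u)
  data.frame(individual = slice$individual_id, gene = slice$gene_id,
             ks_stat = kt$statistic, p_value = kt$p_value,
             n_cells = length(u), stringsAsFactors = FALSE)
}

#' Family-wise summary of goodness-of-fit records
#'
#' Applies a Bonferroni threshold `family_alpha / n_records` across all
#' individual-gene tests and counts rejections. No correction is applied for
#' the fact that the fitted cdf was estimated from the same data, which
#' makes the test slightly conservative.
#'
#' @param records data.frame with a `p_value` column (e.g. rows from
#'   [gof_test()]).
#' @param family_alpha family-wise error level (default 0.05).
#' @return List with `threshold`, `n_rejected`, `n_tests`, and the input
#'   `table` augmented with a logical `rejected` column.
#' @export
gof_summary <- function(records, family_alpha = 0.05) {
  if (NROW(records) == 0L) stop_input("records must be non-empty")
  threshold <- family_alpha / nrow(records)
  rej <- records$p_value < threshold
  list(threshold = threshold, n_rejected = sum(rej), n_tests = nrow(records),
       table = cbind(records, rejected = rej))
}
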