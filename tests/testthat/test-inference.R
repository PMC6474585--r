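test_that("analytic gradients agree with finite differences", {
  sl <- sim_slice(-9, -1, logit_zero = -1, seed = 5,
                  confounders = list(X = scvqtl:::centered_indicators(rep(c("a", "b"), length.out = 95)),
                                     beta = 0.3))
  num_grad <- function(obj, par, ...) {
    vapply(seq_along(par), function(j) {
      h <- 1e-6 * max(1, abs(par[j]))
      pp <- par; pp[j] <- par[j] + h
      pm <- par; pm[j] <- par[j] - h
      (obj(pp, ...)$value - obj(pm, ...)$value) / (2 * h)
    }, numeric(1L))
  }
  p_nb <- c(-8.8, -0.9, 0.2)
  gn <- scvqtl:::nb_obj(p_nb, sl$counts, sl$size_factors, sl$confounders)
  expect_equal(unname(gn$gradient),
               num_grad(scvqtl:::nb_obj, p_nb, sl$counts, sl$size_factors,
                        sl$confounders), tolerance = 1e-5)
  p_z <- c(-8.8, -0.9, -0.5, 0.2)
  gz <- scvqtl:::zinb_obj(p_z, sl$counts, sl$size_factors, sl$confounders)
  expect_equal(unname(gz$gradient),
               num_grad(scvqtl:::zinb_obj, p_z, sl$counts, sl$size_factors,
                        sl$confounders), tolerance = 1e-5)
})

test_that("NB stage recovers simulated parameters at study scale", {
  errs <- vapply(1:50, function(i) {
    sl <- sim_slice(-9, -1, seed = 100 + i)
    st <- fit_nb_stage(sl)
    c(st$log_mean + 9, st$log_disp + 1)
  }, numeric(2L))
  expect_true(all(abs(errs[1L, ]) < 0.2))
  expect_true(all(abs(errs[2L, ]) < 0.5))
})

test_that("NB stage hits the Poisson limit when counts are Poisson", {
  set.seed(7)
  R <- rep(1e5, 95)
  r <- rpois(95, R * exp(-9))
  sl <- count_slice(r, R)
  st <- fit_nb_stage(sl)
  expect_lt(st$log_disp, -5)   # driven toward the dispersion floor
  pois_ll <- sum(dpois(r, R * exp(st$log_mean), log = TRUE))
  expect_lt(abs(st$loglik - pois_ll), 0.1)
})

test_that("degenerate slices are rejected with a typed condition", {
  expect_error(fit_nb_stage(count_slice(5, 1)), class = "scvqtl_degenerate_input")
  expect_error(fit_nb_stage(count_slice(c(0, 0, 0), rep(1, 3))),
               class = "scvqtl_degenerate_input")
})

test_that("stage-2 likelihood never decreases from its initialization", {
  for (i in 1:50) {
    sl <- sim_slice(runif(1, -10, -7), runif(1, -2, 0),
                    logit_zero = runif(1, -4, 1), seed = 300 + i)
    if (all(sl$counts == 0)) next
    ft <- fit_zinb(sl)
    expect_gte(ft$final_loglik, ft$init_loglik - 1e-8)
  }
})

test_that("ZINB fit recovers NB parameters and the latent mean, not logit pi", {
  # negligible zero inflation: mu, phi recovered
  errs <- vapply(1:20, function(i) {
    sl <- sim_slice(-8, -1, logit_zero = -8, seed = 400 + i)
    ft <- fit_zinb(sl)
    c(ft$params$log_mean + 8, ft$params$log_disp + 1)
  }, numeric(2L))
  expect_lt(median(abs(errs[1L, ])), 0.1)
  expect_lt(median(abs(errs[2L, ])), 0.5)
  # strong zero inflation at high expression: latent mean ~ (1 - pi) mu,
  # unbiased to ~10% with per-replicate error within the 20% recovery band
  rel <- vapply(1:20, function(i) {
    sl <- sim_slice(-7, -1, logit_zero = 0, seed = 500 + i)
    ft <- fit_zinb(sl)
    latent_moments(ft$params)$mean / (0.5 * exp(-7))
  }, numeric(1L))
  expect_lt(abs(mean(rel) - 1), 0.1)
  expect_lt(median(abs(rel - 1)), 0.2)
})

test_that("likelihood is invariant to rescaling size factors against mu", {
  sl <- sim_slice(-9, -1, logit_zero = -1, seed = 9)
  params <- zinb_params(-9, -1, -1)
  sl2 <- count_slice(sl$counts, sl$size_factors * 10)
  params2 <- zinb_params(-9 - log(10), -1, -1)
  expect_equal(zinb_log_likelihood(sl, params),
               zinb_log_likelihood(sl2, params2), tolerance = 1e-10)
})

test_that("dataset fitting honours the shape contract, determinism, isolation", {
  b <- tiny_bundle()
  res <- fit_dataset(b)
  expect_equal(nrow(res$fits), 15L)
  expect_named(res$phenotypes, c("mean", "variance", "cv", "fano", "dispersion"))
  for (m in res$phenotypes) expect_equal(dim(m), c(3L, 5L))
  # the all-zero individual-gene cell is missing, all others present
  expect_true(is.na(res$phenotypes$mean["i2", "g3"]))
  expect_equal(sum(is.na(res$phenotypes$mean)), 1L)
  expect_match(res$fits$reason[res$fits$individual == "i2" &
                                 res$fits$gene == "g3"], "zero")
  res2 <- fit_dataset(b)
  expect_identical(res$phenotypes, res2$phenotypes)
})

test_that("bootstrap measurement variance is deterministic and shrinks with cells", {
  sl <- sim_slice(-8, -1, seed = 42)
  ft <- fit_zinb(sl)
  b1 <- bootstrap_measurement_variance(sl, ft, "dispersion", n_boot = 30, seed = 7)
  b2 <- bootstrap_measurement_variance(sl, ft, "dispersion", n_boot = 30, seed = 7)
  expect_identical(b1$sigma2_m, b2$sigma2_m)
  expect_gte(b1$n_bootstrap, 2L)
  # paired simulations: more cells -> smaller measurement variance
  smaller <- vapply(1:50, function(i) {
    s50 <- sim_slice(-8, -1, n_cells = 50, seed = 600 + i)
    s500 <- sim_slice(-8, -1, n_cells = 500, seed = 700 + i)
    f50 <- fit_zinb(s50); f500 <- fit_zinb(s500)
    v50 <- bootstrap_measurement_variance(s50, f50, "dispersion",
                                          n_boot = 30, seed = i)$sigma2_m
    v500 <- bootstrap_measurement_variance(s500, f500, "dispersion",
                                           n_boot = 30, seed = i)$sigma2_m
    v500 < v50
  }, logical(1L))
  expect_gte(mean(smaller), 0.9)
})

test_that("bootstrap variance tracks the true sampling variance of dispersion", {
  # fresh-data oracle: sampling variance of ln phi across 200 independent
  # re-simulations from the same truth
  truth_fits <- vapply(1:200, function(i)
    fit_zinb(sim_slice(-8, -1, seed = 800 + i))$params$log_disp, numeric(1L))
  true_var <- var(truth_fits)
  sl <- sim_slice(-8, -1, seed = 801)
  ft <- fit_zinb(sl)
  bv <- bootstrap_measurement_variance(sl, ft, "dispersion", n_boot = 100,
                                       seed = 3)$sigma2_m
  expect_gt(bv, true_var / 2)
  expect_lt(bv, true_var * 2)
})
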