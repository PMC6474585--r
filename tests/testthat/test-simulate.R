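test_that("simulated counts honour degenerate and moment checks", {
  design <- simulation_design(4, 2, cells_per_individual = 10,
                              molecules_per_cell = 1e5, molecule_cv = 0,
                              chip_effect_sd = 0, seed = 1)
  # pi = 1 -> all counts zero
  b0 <- simulate_counts(design, list(log_mean = c(-8, -8),
                                     log_disp = c(-1, -1),
                                     logit_zero = c(Inf, Inf)), seed = 1)
  expect_true(all(b0$counts == 0))
  # moment oracle over 1e5 cells: mean count = R (1 - pi) mu
  big <- simulation_design(4, 1, cells_per_individual = 25000,
                           molecules_per_cell = 1e5, molecule_cv = 0,
                           chip_effect_sd = 0, seed = 1)
  bb <- simulate_counts(big, list(log_mean = -9, log_disp = -1,
                                  logit_zero = -1), seed = 2)
  r <- as.numeric(bb$counts)
  expected <- 1e5 * (1 - plogis(-1)) * exp(-9)
  expect_lt(abs(mean(r) - expected), 3 * sd(r) / sqrt(length(r)))
  # determinism
  b1 <- simulate_counts(design, list(log_mean = c(-8, -9), log_disp = c(-1, 0),
                                     logit_zero = c(-2, -2)), seed = 5)
  b2 <- simulate_counts(design, list(log_mean = c(-8, -9), log_disp = c(-1, 0),
                                     logit_zero = c(-2, -2)), seed = 5)
  expect_identical(b1$counts, b2$counts)
})

test_that("the mixed chip design shares chips across individuals", {
  design <- simulation_design(8, 3, seed = 2)
  layout <- scvqtl:::cell_layout(design)
  per_chip <- tapply(layout$individual, layout$chip,
                     function(x) length(unique(x)))
  per_ind <- tapply(layout$chip, layout$individual,
                    function(x) length(unique(x)))
  expect_true(all(per_chip > 1))
  expect_true(all(per_ind > 1))
})

test_that("chip effects injected at simulation are visible in log-CPM PCs", {
  design <- simulation_design(6, 120, cells_per_individual = 25,
                              chip_effect_sd = 0.4, seed = 6)
  b <- simulate_counts(design, list(log_mean = rep(-9, 120),
                                    log_disp = rep(-1, 120),
                                    logit_zero = rep(-4, 120)), seed = 6)
  x <- log_cpm(b$counts, b$cells$total_molecules)
  pc <- corrected_pca(t(x), NULL, k = 3)
  r2_chip <- pc_covariate_assoc(pc$loadings, b$cells$chip)
  # no-effect baseline
  design0 <- simulation_design(6, 120, cells_per_individual = 25,
                               chip_effect_sd = 0, seed = 6)
  b0 <- simulate_counts(design0, list(log_mean = rep(-9, 120),
                                      log_disp = rep(-1, 120),
                                      logit_zero = rep(-4, 120)), seed = 6)
  x0 <- log_cpm(b0$counts, b0$cells$total_molecules)
  pc0 <- corrected_pca(t(x0), NULL, k = 3)
  r2_chip0 <- pc_covariate_assoc(pc0$loadings, b0$cells$chip)
  expect_gt(max(r2_chip), max(r2_chip0) + 0.1)
})

test_that("study simulation produces polymorphic cis variants and a round-trippable truth table", {
  design <- simulation_design(10, 6, cells_per_individual = 5, seed = 3)
  st <- simulate_study(design, causal_genes = 1:2, b_mean = 0.1,
                       b_disp = 0.2, maf = 0.1, seed = 3)
  expect_true(all(apply(st$genotypes$dosages, 2, function(d) length(unique(d)) > 1)))
  expect_true(all(abs(st$genotypes$map$pos - st$bundle$genes$tss) <= 99999))
  expect_equal(st$gene_truth$b_mean, c(0.1, 0.1, 0, 0, 0, 0))
  tmp <- tempfile(fileext = ".tsv")
  scvqtl:::write_tsv_det(st$truth, tmp)
  back <- scvqtl:::read_tsv(tmp)
  expect_equal(back$log_mean, st$truth$log_mean, tolerance = 1e-5)
  expect_identical(back$gene, st$truth$gene)
  expect_error(simulate_study(design, maf = 0.01), class = "scvqtl_input_error")
})

test_that("a strong mean effect puts its gene at the top of the eQTL scan", {
  top <- vapply(1:20, function(s) {
    design <- simulation_design(53, 20, cells_per_individual = 5, seed = s)
    st <- simulate_study(design, causal_genes = 7L, b_mean = 0.04,
                         maf = 0.3, seed = s)
    ph <- quantile_normalize(st$phenotypes_true$log_mean)
    colnames(ph) <- st$bundle$genes$gene
    rownames(ph) <- rownames(st$genotypes$dosages)
    ann <- st$bundle$genes
    sc <- cis_scan(ph, st$genotypes, ann, n_permutations = 100, seed = s)
    sc$gene[which.max(abs(sc$z))] == "gene0007"
  }, logical(1L))
  expect_gte(mean(top), 0.95)
})

test_that("the simulation grid is exact in size, unique, and anchored at the corner", {
  g <- simulation_grid(2451)
  expect_equal(nrow(g), 2451L)
  expect_equal(nrow(unique(g)), 2451L)
  expect_true(any(g$log_mean == -14 & g$log_disp == -6 & g$logit_zero == -4))
  # prime count still works
  g7 <- simulation_grid(7)
  expect_equal(nrow(g7), 7L)
  expect_equal(nrow(unique(g7)), 7L)
})

test_that("fitting simulated counts recovers latent moments at moderate expression", {
  rel <- vapply(1:15, function(i) {
    sl <- sim_slice(-8, -1, logit_zero = -2, seed = 900 + i)
    ft <- fit_zinb(sl)
    m <- latent_moments(ft$params)
    truth <- latent_moments(zinb_params(-8, -1, -2))
    c(m$mean / truth$mean, m$variance / truth$variance)
  }, numeric(2L))
  expect_lt(median(abs(rel[1L, ] - 1)), 0.2)
  expect_lt(median(abs(rel[2L, ] - 1)), 0.2)
})
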