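test_that("quantile normalization maps ranks to normal scores", {
  m <- matrix(c(5, 1, 3), 3, 1)
  qn <- quantile_normalize(m)
  expect_equal(drop(qn), c(qnorm(5/6), qnorm(1/6), 0), tolerance = 1e-6)
  # mean zero by symmetry; rank invariance under monotone transforms
  set.seed(16)
  v <- matrix(rnorm(40), 40, 1)
  expect_equal(mean(quantile_normalize(v)), 0, tolerance = 1e-12)
  expect_equal(quantile_normalize(exp(v)), quantile_normalize(v))
  # missing values preserved, constant genes zeroed with warning
  vm <- v; vm[3, 1] <- NA
  expect_true(is.na(quantile_normalize(vm)[3, 1]))
  expect_warning(qc <- quantile_normalize(matrix(2, 5, 1)), "constant")
  expect_true(all(qc == 0))
})

# small deterministic genotype/annotation fixture
scan_fixture <- function(n = 40, seed = 17) {
  set.seed(seed)
  dos <- cbind(v1 = rbinom(n, 2, 0.4), v2 = rbinom(n, 2, 0.3),
               v3 = rbinom(n, 2, 0.25))
  rownames(dos) <- sprintf("i%02d", 1:n)
  map <- data.frame(variant = c("v1", "v2", "v3"), chrom = c(1, 1, 1),
                    pos = c(500000, 600000, 600001), stringsAsFactors = FALSE)
  ann <- data.frame(gene = "gA", chrom = 1, tss = 500000,
                    stringsAsFactors = FALSE)
  list(geno = list(dosages = dos, map = map), ann = ann)
}

test_that("cis scan finds self-association and honours the inclusive window", {
  fx <- scan_fixture()
  ph <- matrix(fx$geno$dosages[, "v1"], ncol = 1,
               dimnames = list(rownames(fx$geno$dosages), "gA"))
  sc <- cis_scan(ph, fx$geno, fx$ann, window = 1e5, n_permutations = 200,
                 seed = 1)
  expect_equal(sc$variant, "v1")
  expect_lt(sc$nominal_p, 1e-10)
  expect_equal(sc$slope, 1, tolerance = 1e-8)
  # v2 at TSS + 100,000 is tested; v3 at TSS + 100,001 is not
  pairs <- attr(sc, "all_pairs")
  expect_setequal(pairs$variant, c("v1", "v2"))
})

test_that("flipping dosage coding flips the slope sign only", {
  fx <- scan_fixture()
  set.seed(2)
  ph <- matrix(fx$geno$dosages[, "v1"] * 0.5 + rnorm(40), ncol = 1,
               dimnames = list(rownames(fx$geno$dosages), "gA"))
  sc1 <- cis_scan(ph, fx$geno, fx$ann, n_permutations = 200, seed = 3)
  flipped <- fx$geno
  flipped$dosages <- 2 - flipped$dosages
  sc2 <- cis_scan(ph, flipped, fx$ann, n_permutations = 200, seed = 3)
  expect_equal(sc2$slope, -sc1$slope, tolerance = 1e-10)
  expect_equal(sc2$gene_p, sc1$gene_p)
  expect_equal(abs(sc2$z), abs(sc1$z), tolerance = 1e-10)
})

test_that("BH discovery calls match hand-computed thresholds", {
  recs <- data.frame(gene = c("a", "b", "c"), gene_p = c(0.01, 0.02, 0.2))
  d <- qtl_calls(recs, 0.10)
  expect_equal(nrow(d), 2L)
  expect_setequal(d$gene, c("a", "b"))
  expect_equal(nrow(qtl_calls(data.frame(gene = "x", gene_p = 1), 0.1)), 0L)
  many <- data.frame(gene = sprintf("g%d", 1:100), gene_p = rep(1e-6, 100))
  expect_equal(nrow(qtl_calls(many, 0.1)), 100L)
})

test_that("BH on uniform p-values controls the false discovery proportion", {
  set.seed(18)
  any_disc <- vapply(1:200, function(i) {
    p <- runif(200)
    nrow(qtl_calls(data.frame(gene = seq_len(200), gene_p = p), 0.1)) > 0
  }, logical(1L))
  # all-null FDP equals P(any discovery); expectation <= q
  expect_lte(mean(any_disc), 0.1 + 2 * sqrt(0.1 * 0.9 / 200))
})

test_that("covariate-PC selection returns trivial candidates and applies the tie rule", {
  design <- simulation_design(20, 8, cells_per_individual = 5, seed = 4)
  st <- simulate_study(design, seed = 4)
  ph <- quantile_normalize(st$phenotypes_true$log_mean)
  dimnames(ph) <- list(rownames(st$genotypes$dosages), st$bundle$genes$gene)
  ann <- st$bundle$genes
  one <- select_covariate_pcs(ph, st$genotypes, ann, candidate_counts = 0,
                              n_permutations = 100, seed = 5)
  expect_equal(one$n_pcs, 0)
  # null data: all candidates tie at zero discoveries -> smallest returned
  tie <- select_covariate_pcs(ph, st$genotypes, ann, candidate_counts = c(2, 3),
                              n_permutations = 100, seed = 5)
  expect_equal(tie$n_pcs, 2)
  odd_only <- ann[ann$chrom %% 2 == 1, , drop = FALSE]
  expect_error(select_covariate_pcs(ph, st$genotypes, odd_only,
                                    candidate_counts = 0),
               class = "scvqtl_input_error")
})

test_that("covariate PCs recover discoveries lost to a shared batch factor", {
  design <- simulation_design(60, 30, cells_per_individual = 5, seed = 19)
  st <- simulate_study(design, causal_genes = 1:10, b_mean = 0.08,
                       maf = 0.3, seed = 19)
  ph <- st$phenotypes_true$log_mean
  set.seed(20)
  batch <- rnorm(60)                      # latent per-individual factor
  ph <- ph + outer(batch, rnorm(30, 0, 0.2))
  ph <- quantile_normalize(ph)
  dimnames(ph) <- list(rownames(st$genotypes$dosages), st$bundle$genes$gene)
  sel <- select_covariate_pcs(ph, st$genotypes, st$bundle$genes,
                              candidate_counts = c(0, 1, 2),
                              n_permutations = 1000, seed = 21)
  expect_gte(sel$n_pcs, 1)
  expect_gte(max(sel$counts), sel$counts["0"])
})

test_that("replication requires both BH significance and sign concordance", {
  disc <- data.frame(gene = c("a", "b"), variant = c("v1", "v2"),
                     slope = c(1, -1))
  rep1 <- data.frame(gene = c("a", "b"), variant = c("v1", "v2"),
                     slope = c(0.8, -0.5), nominal_p = c(0.001, 0.9))
  rr <- replication_rate(disc, rep1)
  expect_equal(rr$rate, 0.5)
  expect_equal(rr$n_tested, 2L)
  # concordant p but flipped sign does not replicate
  rep2 <- data.frame(gene = c("a", "b"), variant = c("v1", "v2"),
                     slope = c(-0.8, -0.5), nominal_p = c(0.001, 0.9))
  expect_equal(replication_rate(disc, rep2)$rate, 0)
  # untested pairs drop from the denominator
  rep3 <- data.frame(gene = "a", variant = "v1", slope = 1, nominal_p = 0.01)
  expect_equal(replication_rate(disc, rep3)$n_tested, 1L)
})

test_that("strong shared effects replicate across simulated cohorts", {
  mk <- function(seed) {
    design <- simulation_design(60, 25, cells_per_individual = 5, seed = seed)
    st <- simulate_study(design, causal_genes = 1:25, b_mean = 0.12,
                         maf = 0.3, seed = seed)
    ph <- quantile_normalize(st$phenotypes_true$log_mean)
    dimnames(ph) <- list(rownames(st$genotypes$dosages), st$bundle$genes$gene)
    list(st = st, ph = ph)
  }
  d <- mk(22)
  sc_d <- cis_scan(d$ph, d$st$genotypes, d$st$bundle$genes,
                   n_permutations = 500, seed = 23)
  disc <- qtl_calls(sc_d, 0.1)
  expect_gt(nrow(disc), 5)
  # replication cohort: same variants and effect sizes, fresh individuals
  r <- mk(24)
  r$st$genotypes$map <- d$st$genotypes$map  # same variant coordinates
  sc_r <- cis_scan(r$ph, r$st$genotypes, r$st$bundle$genes,
                   n_permutations = 500, seed = 25)
  rr <- replication_rate(disc, attr(sc_r, "all_pairs"))
  expect_gt(rr$rate, 0.7)
})

test_that("variance residualization is orthogonal to the mean and kills linear structure", {
  set.seed(26)
  m <- matrix(rnorm(120), 40, 3)
  v_lin <- 2 * m + 1                      # exactly linear in the mean
  res <- residualize_variance(v_lin, m)
  expect_true(all(abs(res) < 1e-10))
  v <- m + matrix(rnorm(120), 40, 3)
  res2 <- residualize_variance(v, m)
  for (j in 1:3) expect_lt(abs(cor(res2[, j], m[, j])), 1e-10)
  expect_warning(residualize_variance(matrix(rnorm(10)), matrix(1, 10, 1)),
                 "constant")
})
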