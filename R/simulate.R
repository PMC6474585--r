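# Synthetic-data generation: ZINB counts at realistic single-cell scale,
# mixed-individual chip designs, and full QTL studies with genetic effects on
# log-mean and log-dispersion.

#' Describe a synthetic single-cell study design
#'
#' Defaults match the scale of a typical multi-individual C1 experiment:
#' 95 cells per individual and 114,026 molecules per cell (the medians this
#' package is calibrated around), with per-cell library sizes drawn
#' log-normally around `molecules_per_cell` (CV `molecule_cv`). Individuals
#' are assigned to chips in a mixed design: chips are sliding windows of
#' `individuals_per_chip` individuals with stride `individuals_per_chip / 2`,
#' so every chip hosts more than one individual and every individual appears
#' on more than one chip, which is what makes technical chip effects
#' separable from individual effects.
#'
#' @param n_individuals number of individuals (>= 4 for the mixed design).
#' @param n_genes number of genes.
#' @param cells_per_individual cells per individual (default 95).
#' @param molecules_per_cell median library size (default 114,026).
#' @param molecule_cv log-normal coefficient of variation of library sizes
#'   (default 0.3); set 0 for constant sizes.
#' @param individuals_per_chip individuals pooled on one chip (default 4).
#' @param chip_effect_sd standard deviation of per-gene, per-chip log-scale
#'   technical effects (default 0.1); set 0 for no chip effects.
#' @param seed integer seed used for the design-level draws (chip effects).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_individuals, n_genes,
                              cells_per_individual = 95L,
                              molecules_per_cell = 114026,
                              molecule_cv = 0.3,
                              individuals_per_chip = 4L,
                              chip_effect_sd = 0.1,
                              seed = 1L) {
  if (n_individuals < individuals_per_chip)
    stop_input("need at least %d individuals for the mixed chip design",
               individuals_per_chip)
  stride <- max(1L, individuals_per_chip %/% 2L)
  starts <- seq(1L, n_individuals, by = stride)
  chips <- lapply(starts, function(s)
    ((s - 1L + seq_len(individuals_per_chip) - 1L) %% n_individuals) + 1L)
  n_chips <- length(chips)
  set.seed(derive_seed(seed, 7L, 7L))
  chip_effects <- matrix(rnorm(n_genes * n_chips, 0, chip_effect_sd),
                         n_genes, n_chips)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_genes = as.integer(n_genes),
                 cells_per_individual = as.integer(cells_per_individual),
                 molecules_per_cell = molecules_per_cell,
                 molecule_cv = molecule_cv,
                 individuals_per_chip = as.integer(individuals_per_chip),
                 chips = chips, n_chips = n_chips,
                 chip_effects = chip_effects,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

# Per-cell assignment of (individual, chip): each individual's cells are
# split evenly across the chips hosting it.
cell_layout <- function(design) {
  hosts <- lapply(seq_len(design$n_individuals), function(i)
    which(vapply(design$chips, function(ch) i %in% ch, logical(1L))))
  ind <- rep(seq_len(design$n_individuals), each = design$cells_per_individual)
  chip <- unlist(lapply(seq_len(design$n_individuals), function(i) {
    h <- hosts[[i]]
    rep_len(h, design$cells_per_individual)
  }))
  data.frame(cell = sprintf("cell%05d", seq_along(ind)),
             individual = sprintf("ind%03d", ind),
             chip = sprintf("chip%02d", chip),
             stringsAsFactors = FALSE)
}

#' Simulate ZINB molecule counts for a study design
#'
#' For each cell, latent expression is drawn from the point-Gamma mixture
#' (zero with probability pi, else Gamma with mean mu and shape 1/phi) and
#' the molecule count from a Poisson with rate
#' `R * exp(chip effect) * lambda`. Parameters may be supplied per gene
#' (recycled across individuals) or per individual-gene.
#'
#' @param design a [simulation_design].
#' @param truth list with `log_mean`, `log_disp`, `logit_zero`: each either a
#'   vector of length `n_genes` or an `n_individuals x n_genes` matrix.
#' @param seed integer seed.
#' @return A dataset bundle: list with `counts` (genes x cells integer
#'   matrix), `cells` (cell, individual, chip, total_molecules), `genes`
#'   (gene, chrom, tss), and the realized `truth` matrices as an attribute.
#' @export
simulate_counts <- function(design, truth, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  G <- design$n_genes; N <- design$n_individuals
  as_mat <- function(x) {
    if (is.matrix(x)) { stopifnot(nrow(x) == N, ncol(x) == G); x }
    else matrix(rep(as.numeric(x), each = N), N, G)
  }
  lm <- as_mat(truth$log_mean); ld <- as_mat(truth$log_disp)
  lz <- as_mat(truth$logit_zero)
  layout <- cell_layout(design)
  n_cells <- nrow(layout)
  set.seed(derive_seed(seed, 11L, 13L))
  R <- if (design$molecule_cv > 0) {
    sdlog <- sqrt(log1p(design$molecule_cv^2))
    rlnorm(n_cells, log(design$molecules_per_cell), sdlog)
  } else rep(design$molecules_per_cell, n_cells)
  R <- pmax(round(R), 1)
  ind_idx <- as.integer(factor(layout$individual,
                               levels = sprintf("ind%03d", seq_len(N))))
  chip_idx <- as.integer(factor(layout$chip,
                                levels = sprintf("chip%02d", seq_len(design$n_chips))))
  counts <- matrix(0L, G, n_cells)
  for (k in seq_len(G)) {
    mu <- exp(lm[ind_idx, k]); phi <- exp(ld[ind_idx, k])
    pi <- plogis(lz[ind_idx, k])
    lam <- ifelse(runif(n_cells) < pi, 0,
                  rgamma(n_cells, shape = 1 / phi, scale = mu * phi))
    rate <- R * exp(design$chip_effects[k, chip_idx]) * lam
    counts[k, ] <- rpois(n_cells, rate)
  }
  genes <- data.frame(gene = sprintf("gene%04d", seq_len(G)),
                      chrom = ((seq_len(G) - 1L) %% 22L) + 1L,
                      tss = 1e6 * (((seq_len(G) - 1L) %/% 22L) + 1L),
                      stringsAsFactors = FALSE)
  rownames(counts) <- genes$gene
  colnames(counts) <- layout$cell
  # size factor = total molecules detected per cell across the whole
  # transcriptome; the simulated genes are a subset of it, so the drawn
  # library size (not the column sum over simulated genes) is recorded
  layout$total_molecules <- R
  bundle <- list(counts = counts, cells = layout, genes = genes)
  attr(bundle, "truth") <- list(log_mean = lm, log_disp = ld, logit_zero = lz)
  bundle
}

#' Simulate a complete cis-QTL study with known genetic effects
#'
#' Draws genotype dosages Binomial(2, maf) per individual at one cis variant
#' per gene (placed inside the 100 kb window around the gene's TSS),
#' generates individual-level `ln mu` and `ln phi` as
#' `baseline + dosage * effect + Normal residual`, and simulates counts via
#' [simulate_counts()]. Only genes listed in `causal_genes` receive nonzero
#' effects. Monomorphic variants are redrawn.
#'
#' @param design a [simulation_design].
#' @param causal_genes integer indices of genes with genetic effects
#'   (default none).
#' @param b_mean,b_disp per-copy effect on `ln mu` / `ln phi` at causal
#'   genes.
#' @param maf minor allele frequency in `[0.05, 0.5]`.
#' @param baseline_log_mean,baseline_log_disp,baseline_logit_zero per-gene
#'   baselines; scalars are recycled, or vectors of length `n_genes`.
#'   Defaults spread baselines over typical single-cell ranges.
#' @param sd_log_mean,sd_log_disp across-individual residual standard
#'   deviations of the two phenotypes. The defaults (0.04 and 0.15) were
#'   chosen so that, at the default study scale (95 cells, 114,026
#'   molecules/cell, where the sampling standard deviations of the fitted
#'   `ln mu` and `ln phi` are roughly 0.07 and 0.2-0.35), the
#'   measurement-to-residual noise ratios fall in the 3-4 range typical of
#'   this assay.
#' @param seed integer seed.
#' @return List with `bundle` (the count dataset), `genotypes` (list:
#'   `dosages` individuals x variants, `map` data.frame variant/chrom/pos,
#'   `maf`), and `truth` (a data.frame per individual-gene of true
#'   parameters plus per-gene effect sizes and variant ids).
#' @export
simulate_study <- function(design, causal_genes = integer(0),
                           b_mean = 0, b_disp = 0, maf = 0.2,
                           baseline_log_mean = NULL,
                           baseline_log_disp = NULL,
                           baseline_logit_zero = -2,
                           sd_log_mean = 0.04, sd_log_disp = 0.15,
                           seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  if (maf < 0.05 || maf > 0.5) stop_input("maf must lie in [0.05, 0.5]")
  G <- design$n_genes; N <- design$n_individuals
  if (is.null(baseline_log_mean))
    baseline_log_mean <- seq(-9.5, -7.5, length.out = G)
  if (is.null(baseline_log_disp))
    baseline_log_disp <- seq(-2, 0, length.out = G)
  baseline_log_mean <- rep_len(baseline_log_mean, G)
  baseline_log_disp <- rep_len(baseline_log_disp, G)
  baseline_logit_zero <- rep_len(baseline_logit_zero, G)
  set.seed(derive_seed(seed, 3L, 5L))
  dos <- matrix(NA_real_, N, G)
  for (k in seq_len(G)) {
    repeat {
      d <- rbinom(N, 2L, maf)
      if (length(unique(d)) > 1L) break     # redraw monomorphic variants
    }
    dos[, k] <- d
  }
  bm <- bd <- numeric(G)
  bm[causal_genes] <- b_mean; bd[causal_genes] <- b_disp
  lm <- outer(rep(1, N), baseline_log_mean) + sweep(dos, 2L, bm, `*`) +
    matrix(rnorm(N * G, 0, sd_log_mean), N, G)
  ld <- outer(rep(1, N), baseline_log_disp) + sweep(dos, 2L, bd, `*`) +
    matrix(rnorm(N * G, 0, sd_log_disp), N, G)
  lz <- outer(rep(1, N), baseline_logit_zero)
  bundle <- simulate_counts(design, list(log_mean = lm, log_disp = ld,
                                         logit_zero = lz), seed = seed)
  genes <- bundle$genes
  # one cis variant per gene, offset < 100 kb from the TSS
  pos <- genes$tss + sample(c(-1L, 1L), G, TRUE) * sample.int(99999L, G, TRUE)
  map <- data.frame(variant = sprintf("var%04d", seq_len(G)),
                    chrom = genes$chrom, pos = pmax(pos, 1L),
                    stringsAsFactors = FALSE)
  dimnames(dos) <- list(sprintf("ind%03d", seq_len(N)), map$variant)
  inds <- rownames(dos)
  truth <- data.frame(
    individual = rep(inds, G),
    gene = rep(genes$gene, each = N),
    log_mean = as.vector(lm), log_disp = as.vector(ld),
    logit_zero = as.vector(lz),
    stringsAsFactors = FALSE)
  gene_truth <- data.frame(gene = genes$gene, variant = map$variant,
                           b_mean = bm, b_disp = bd,
                           causal = seq_len(G) %in% causal_genes,
                           stringsAsFactors = FALSE)
  list(bundle = bundle,
       genotypes = list(dosages = dos, map = map, maf = colMeans(dos) / 2),
       truth = truth, gene_truth = gene_truth,
       phenotypes_true = list(log_mean = lm, log_disp = ld))
}

#' Deterministic grid of ZINB parameter sets for recovery experiments
#'
#' Covers the ranges over which estimation accuracy is assessed:
#' `ln mu` in `[-14, -4]`, `ln phi` in `[-6, 2]`, `logit pi` in `[-4, 4]` by
#' default. `n_points` is factorized into three per-axis counts as evenly as
#' possible (largest count on `ln mu`), so the grid has exactly `n_points`
#' unique points and always contains the corner of axis minima.
#'
#' @param n_points total number of parameter sets.
#' @param log_mean_range,log_disp_range,logit_zero_range numeric length-2
#'   ranges.
#' @return data.frame with columns `log_mean`, `log_disp`, `logit_zero`.
#' @export
simulation_grid <- function(n_points,
                            log_mean_range = c(-14, -4),
                            log_disp_range = c(-6, 2),
                            logit_zero_range = c(-4, 4)) {
  if (n_points < 1L) stop_input("n_points must be >= 1")
  # balanced factor triple a >= b >= c with a*b*c == n_points
  best <- c(n_points, 1L, 1L)
  for (c1 in seq_len(floor(n_points^(1 / 3)))) {
    if (n_points %% c1 != 0) next
    m <- n_points %/% c1
    for (b in seq_len(floor(sqrt(m)))) {
      if (m %% b != 0 || b < c1) next
      a <- m %/% b
      if (max(a, b, c1) < max(best)) best <- c(a, b, c1)
    }
  }
  ax <- function(rng, k) if (k == 1L) rng[1L] else seq(rng[1L], rng[2L], length.out = k)
  g <- expand.grid(log_mean = ax(log_mean_range, best[1L]),
                   log_disp = ax(log_disp_range, best[2L]),
                   logit_zero = ax(logit_zero_range, best[3L]),
                   KEEP.OUT.ATTRS = FALSE)
  g[seq_len(n_points), , drop = FALSE]
}
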