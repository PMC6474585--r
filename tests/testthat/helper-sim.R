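# Shared fixture builders: all synthetic, generated in code at test time.

# One individual-gene count slice drawn from the point-Gamma / Poisson model
# at the default study scale (95 cells, 114,026 molecules per cell).
sim_slice <- function(log_mean, log_disp, logit_zero = -Inf, n_cells = 95L,
                      seed = 1L, molecules = 114026, molecule_cv = 0.3,
                      confounders = NULL) {
  set.seed(seed)
  R <- if (molecule_cv > 0)
    pmax(round(rlnorm(n_cells, log(molecules), sqrt(log1p(molecule_cv^2)))), 1)
  else rep(molecules, n_cells)
  mu <- exp(log_mean); phi <- exp(log_disp); pi0 <- plogis(logit_zero)
  lam <- ifelse(runif(n_cells) < pi0, 0,
                rgamma(n_cells, shape = 1 / phi, scale = mu * phi))
  eta <- if (is.null(confounders)) 0
         else drop(confounders$X %*% confounders$beta)
  r <- rpois(n_cells, R * exp(eta) * lam)
  count_slice(r, R, if (is.null(confounders)) NULL else confounders$X)
}

# Tiny multi-individual dataset bundle built directly (no randomness):
# 3 individuals x 5 genes, constant-ish counts, with one gene all-zero for
# one individual.
tiny_bundle <- function() {
  set.seed(99)
  ni <- 3L; G <- 5L; cells <- 20L
  ind <- rep(sprintf("i%d", 1:ni), each = cells)
  chip <- rep(rep(c("c1", "c2"), length.out = cells), ni)
  R <- rep(5000, ni * cells)
  counts <- matrix(0L, G, ni * cells)
  for (k in 1:G) counts[k, ] <- rpois(ni * cells, R * exp(-7 - 0.3 * k))
  counts[3L, ind == "i2"] <- 0L   # isolated failure case
  rownames(counts) <- sprintf("g%d", 1:G)
  colnames(counts) <- sprintf("cell%02d", seq_len(ni * cells))
  list(counts = counts,
       cells = data.frame(cell = colnames(counts), individual = ind,
                          chip = chip, total_molecules = R,
                          stringsAsFactors = FALSE),
       genes = data.frame(gene = rownames(counts), stringsAsFactors = FALSE))
}
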