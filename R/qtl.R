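# Phenotype normalization and cis-window QTL scanning with permutation-based
# gene-level error control.

#' Quantile-normalize a phenotype matrix to a standard normal
#'
#' Per gene (column): ranks (ties averaged) are mapped to standard normal
#' quantiles at `(rank - 0.5) / n` over the non-missing individuals; missing
#' values are preserved. Any monotone transform of the input leaves the
#' output unchanged. Constant genes become all zeros with a warning.
#'
#' @param pheno individuals x genes numeric matrix.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(pheno) {
  pheno <- as.matrix(pheno)
  out <- pheno
  warned <- FALSE
  for (j in seq_len(ncol(pheno))) {
    ok <- which(!is.na(pheno[, j]))
    if (length(ok) == 0L) next
    v <- pheno[ok, j]
    if (length(unique(v)) == 1L) {
      out[ok, j] <- 0
      warned <- TRUE
      next
    }
    r <- rank(v, ties.method = "average")
    out[ok, j] <- qnorm((r - 0.5) / length(ok))
  }
  if (warned) warning("constant gene(s) set to zero after normalization")
  out
}

# residualize y (vector or matrix columns) on covariates with intercept
resid_on <- function(y, C) {
  qr_C <- qr(cbind(1, C))
  qr.resid(qr_C, y)
}

#' Scan for cis QTLs with permutation-based gene-level p-values
#'
#' For each gene, tests every variant whose position lies within `window`
#' base pairs of the gene's TSS (inclusive at both endpoints, 1-based
#' positions) by linear regression of the (normalized) phenotype on the
#' genotype dosage, with optional covariates regressed out of both.
#' The gene-level p-value is obtained by permuting phenotype values across
#' individuals and recording the best absolute correlation over the cis
#' variants of each permutation:
#' `p = (1 + #{perm best >= observed best}) / (1 + n_permutations)`.
#' Individuals with missing phenotype are dropped per gene.
#'
#' @param pheno individuals x genes matrix (rownames = individual ids),
#'   typically from [quantile_normalize()].
#' @param geno list with `dosages` (individuals x variants, rownames ids)
#'   and `map` (data.frame: variant, chrom, pos).
#' @param annotation data.frame with columns `gene`, `chrom`, `tss`.
#' @param window cis window in bp (default 100,000).
#' @param covariates individuals x q matrix or `NULL`.
#' @param n_permutations permutations per gene (default 1,000).
#' @param seed integer seed (per-gene streams are derived, so results do not
#'   depend on gene order).
#' @return data.frame with one row per gene (best variant): `gene`,
#'   `variant`, `n`, `slope`, `se`, `z`, `nominal_p`, `gene_p`, plus one row
#'   per tested variant in attribute `"all_pairs"`.
#' @export
cis_scan <- function(pheno, geno, annotation, window = 1e5,
                     covariates = NULL, n_permutations = 1000L, seed = 1L) {
  pheno <- as.matrix(pheno)
  dos <- as.matrix(geno$dosages)
  map <- geno$map
  ids <- intersect(rownames(pheno), rownames(dos))
  if (length(ids) < 3L) stop_input("fewer than 3 individuals shared between phenotypes and genotypes")
  pheno <- pheno[ids, , drop = FALSE]
  dos <- dos[ids, , drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(ids))
      covariates <- covariates[ids, , drop = FALSE]
  }
  best_rows <- list(); pair_rows <- list()
  for (g in seq_len(nrow(annotation))) {
    gene <- as.character(annotation$gene[g])
    if (!gene %in% colnames(pheno)) next
    vsel <- which(map$chrom == annotation$chrom[g] &
                    abs(map$pos - annotation$tss[g]) <= window)
    if (!length(vsel)) next
    y <- pheno[, gene]
    ok <- which(!is.na(y))
    if (length(ok) < 3L) next
    n <- length(ok)
    G <- dos[ok, vsel, drop = FALSE]
    yv <- y[ok]
    qdf <- 0L
    if (!is.null(covariates)) {
      C <- covariates[ok, , drop = FALSE]
      yv <- resid_on(yv, C)
      G <- resid_on(G, C)
      qdf <- ncol(C)
    }
    # drop variants that are constant within the analyzed individuals
    gsd <- apply(G, 2L, sd)
    keep <- which(gsd > 0)
    if (!length(keep)) next
    G <- G[, keep, drop = FALSE]; vsel <- vsel[keep]; gsd <- gsd[keep]
    ysd <- sd(yv)
    if (ysd == 0) next
    Gs <- scale(G); ys <- (yv - mean(yv)) / ysd
    r <- drop(crossprod(Gs, ys)) / (n - 1)
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    df <- n - 2L - qdf
    tstat <- r * sqrt(df / (1 - r^2))
    slope <- r * ysd / gsd
    se <- slope / tstat
    nominal_p <- 2 * pt(-abs(tstat), df)
    # permutations: best |r| per permuted phenotype, shared across variants
    set.seed(derive_seed(seed, g, 17L))
    P <- matrix(0, n, n_permutations)
    for (b in seq_len(n_permutations)) P[, b] <- ys[sample.int(n)]
    pr <- abs(crossprod(Gs, P)) / (n - 1)
    perm_best <- apply(pr, 2L, max)
    obs_best <- max(abs(r))
    gene_p <- (1 + sum(perm_best >= obs_best)) / (1 + n_permutations)
    i_best <- which.max(abs(r))
    best_rows[[length(best_rows) + 1L]] <- data.frame(
      gene = gene, variant = map$variant[vsel[i_best]], n = n,
      slope = slope[i_best], se = se[i_best], z = tstat[i_best],
      nominal_p = nominal_p[i_best], gene_p = gene_p,
      stringsAsFactors = FALSE)
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      gene = gene, variant = map$variant[vsel], n = n, slope = slope,
      se = se, z = tstat, nominal_p = nominal_p,
      stringsAsFactors = FALSE)
  }
  out <- if (length(best_rows)) do.call(rbind, best_rows) else
    data.frame(gene = character(0), variant = character(0), n = integer(0),
               slope = numeric(0), se = numeric(0), z = numeric(0),
               nominal_p = numeric(0), gene_p = numeric(0))
  attr(out, "all_pairs") <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
  out
}

#' Gene-level discoveries at a target FDR
#'
#' Benjamini-Hochberg across genes on the gene-level permutation p-values.
#'
#' @param records output of [cis_scan()].
#' @param fdr_level target FDR (default 0.10).
#' @return `records` with a `q_value` column, restricted to discoveries
#'   (`q_value <= fdr_level`); the full annotated table is in attribute
#'   `"all_genes"`.
#' @export
qtl_calls <- function(records, fdr_level = 0.10) {
  records <- as.data.frame(records)
  records$q_value <- p.adjust(records$gene_p, method = "BH")
  disc <- records[!is.na(records$q_value) & records$q_value <= fdr_level, ,
                  drop = FALSE]
  attr(disc, "all_genes") <- records
  disc
}

#' Choose the number of covariate PCs by even-chromosome discovery count
#'
#' For each candidate number of phenotype PCs, runs the cis scan restricted
#' to genes on even chromosomes with that many PCs as covariates, counts
#' FDR-10% discoveries, and returns the candidate with the most discoveries
#' (ties broken toward fewer PCs). Odd-chromosome genes are held out so the
#' selection does not overfit the discovery set.
#'
#' @param pheno normalized individuals x genes matrix.
#' @param geno,annotation,window,n_permutations,seed as in [cis_scan()].
#' @param candidate_counts integer vector of PC counts to try.
#' @param fdr_level FDR for counting discoveries (default 0.10).
#' @return List with `n_pcs` (chosen count), `counts` (named discovery
#'   counts), and `pcs` (the full PC matrix, columns usable as covariates).
#' @export
select_covariate_pcs <- function(pheno, geno, annotation,
                                 candidate_counts = 0:5, window = 1e5,
                                 n_permutations = 500L, fdr_level = 0.10,
                                 seed = 1L) {
  even <- annotation[annotation$chrom %% 2 == 0, , drop = FALSE]
  if (!nrow(even)) stop_input("no genes on even chromosomes")
  cc <- pheno[, colSums(is.na(pheno)) == 0, drop = FALSE]
  pc <- prcomp(cc, center = TRUE, scale. = FALSE)
  kmax <- min(max(candidate_counts), ncol(pc$x))
  counts <- setNames(integer(length(candidate_counts)),
                     as.character(candidate_counts))
  for (i in seq_along(candidate_counts)) {
    k <- min(candidate_counts[i], kmax)
    cov <- if (k > 0) pc$x[, seq_len(k), drop = FALSE] else NULL
    sc <- cis_scan(pheno, geno, even, window = window, covariates = cov,
                   n_permutations = n_permutations, seed = seed)
    counts[i] <- nrow(qtl_calls(sc, fdr_level))
  }
  best <- candidate_counts[which.max(counts)]  # which.max takes first tie
  list(n_pcs = best, counts = counts, pcs = pc$x)
}

#' Replication rate of discovered QTLs in an independent cohort
#'
#' Each discovery SNP-gene pair is looked up in the replication statistics;
#' BH is applied at `level` restricted to exactly the tested pairs, and a
#' pair replicates if it passes BH and its slope has the same sign as in the
#' discovery cohort. Pairs absent from the replication set are excluded from
#' the denominator.
#'
#' @param discoveries data.frame with `gene`, `variant`, `slope`.
#' @param replication data.frame with `gene`, `variant`, `slope`,
#'   `nominal_p` (per-pair statistics in the replication cohort).
#' @param level BH level (default 0.10).
#' @return List with `rate`, `n_tested`, `n_replicated`, and the per-pair
#'   `table`.
#' @export
replication_rate <- function(discoveries, replication, level = 0.10) {
  key <- function(d) paste(d$gene, d$variant, sep = "\r")
  m <- match(key(discoveries), key(replication))
  tested <- which(!is.na(m))
  if (!length(tested))
    return(list(rate = NA_real_, n_tested = 0L, n_replicated = 0L,
                table = NULL))
  rep_p <- replication$nominal_p[m[tested]]
  rep_slope <- replication$slope[m[tested]]
  q <- p.adjust(rep_p, method = "BH")
  concordant <- sign(rep_slope) == sign(discoveries$slope[tested])
  replicated <- q <= level & concordant
  tab <- data.frame(gene = discoveries$gene[tested],
                    variant = discoveries$variant[tested],
                    slope_discovery = discoveries$slope[tested],
                    slope_replication = rep_slope,
                    replication_p = rep_p, q_value = q,
                    concordant = concordant, replicated = replicated,
                    stringsAsFactors = FALSE)
  list(rate = mean(replicated), n_tested = length(tested),
       n_replicated = sum(replicated), table = tab)
}

#' Residualize a variance phenotype on the mean phenotype
#'
#' Per gene, regresses the variance phenotype on the mean phenotype across
#' individuals (least squares with intercept) and returns the residuals,
#' which are orthogonal to the mean. Used to ask whether variance QTLs
#' survive once mean effects are removed. If the mean is constant for a
#' gene, the centered variance is returned with a warning.
#'
#' @param variance_pheno,mean_pheno matched individuals x genes matrices.
#' @return Residual phenotype matrix of the same shape.
#' @export
residualize_variance <- function(variance_pheno, mean_pheno) {
  v <- as.matrix(variance_pheno); m <- as.matrix(mean_pheno)
  if (!all(dim(v) == dim(m))) stop_input("phenotype matrices must match in shape")
  out <- v * NA_real_
  warned <- FALSE
  for (j in seq_len(ncol(v))) {
    ok <- which(!is.na(v[, j]) & !is.na(m[, j]))
    if (length(ok) < 3L) next
    x <- m[ok, j]; y <- v[ok, j]
    if (sd(x) == 0) {
      out[ok, j] <- y - mean(y)
      warned <- TRUE
      next
    }
    b <- cov(x, y) / var(x)
    out[ok, j] <- y - mean(y) - b * (x - mean(x))
  }
  if (warned) warning("constant mean phenotype for some gene(s); centered variance returned")
  out
}
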