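# Internal helpers shared across modules.

# Numerically stable log(exp(a) + exp(b)) for vectors.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf -> -Inf, avoid NaN from -Inf - -Inf
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

stop_input <- function(...) {
  stop(structure(class = c("scvqtl_input_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("scvqtl_degenerate_input", "scvqtl_input_error",
                           "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

# Deterministic per-(i, k) seed stream derived from a master seed, so that
# results do not depend on the order in which individual-gene pairs are
# processed. Plain 32-bit-safe integer hashing.
derive_seed <- function(master_seed, i, k = 0L) {
  h <- (as.double(master_seed) %% 2147483647) + 1
  for (x in c(i, k)) {
    h <- (h * 48271 + as.double(x) * 16807 + 11) %% 2147483647
  }
  as.integer(h)
}

# Centered indicator coding of a factor: one column per non-reference level,
# centered to mean zero over the rows supplied. Returns a matrix with zero
# columns for single-level factors.
centered_indicators <- function(f) {
  f <- droplevels(as.factor(f))
  lev <- levels(f)
  if (length(lev) < 2L) {
    return(matrix(0, nrow = length(f), ncol = 0L))
  }
  m <- vapply(lev[-1L], function(l) as.numeric(f == l), numeric(length(f)))
  m <- as.matrix(m)
  colnames(m) <- paste0("x_", lev[-1L])
  scale(m, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

# Fixed-format numeric rendering for deterministic writers: 6 significant
# digits, "NA" for missing.
format_num <- function(x) {
  out <- formatC(signif(as.numeric(x), 6L), format = "g", digits = 6L)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_det <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], format_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
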