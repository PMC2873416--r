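# Small programmatic fixtures shared across test files.

make_aln <- function(seqs, pops = NULL, locus_id = "locus", offset = 1L) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  if (is.null(pops)) pops <- setNames(rep("wild", length(seqs)), names(seqs))
  if (is.null(names(pops))) pops <- setNames(pops, names(seqs))
  locus_alignment(seqs, populations = pops, locus_id = locus_id,
                  coordinate_offset = offset)
}

# Random alignment with optional missing characters sprinkled in.
random_aln <- function(n, L, seed, p_missing = 0, pops = NULL) {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (p_missing > 0) {
    idx <- which(runif(n * L) < p_missing)
    mat[idx] <- sample(c("-", "N"), length(idx), replace = TRUE)
  }
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  if (is.null(pops))
    pops <- setNames(rep("wild", n), rownames(mat))
  locus_alignment(mat, populations = pops)
}

# Brute-force oracle: per-site nucleotide diversity as the average hamming
# distance over all unordered pairs, on complete-deletion columns.
oracle_pi <- function(aln, population) {
  keep <- aln$samples[aln$populations %in% population]
  m <- aln$seq[keep, , drop = FALSE]
  m <- m[, colSums(m == "-" | m == "N") == 0L, drop = FALSE]
  n <- nrow(m)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ]); np <- np + 1
  }
  (tot / np) / ncol(m)
}

# Brute-force oracle: segregating sites by per-column set size.
oracle_S <- function(aln, population) {
  keep <- aln$samples[aln$populations %in% population]
  m <- aln$seq[keep, , drop = FALSE]
  m <- m[, colSums(m == "-" | m == "N") == 0L, drop = FALSE]
  sum(apply(m, 2, function(col) length(unique(col))) >= 2)
}

# Independent evaluation of Tajima's D from published constant formulas.
oracle_tajima_d <- function(pi_total, S, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Exhaustive longest monotone subsequence (both directions) for n <= 12.
oracle_best_chain <- function(b_ranks) {
  n <- length(b_ranks)
  best <- 0
  for (k in n:1) {
    for (comb in utils::combn(n, k, simplify = FALSE)) {
      v <- b_ranks[comb]
      if (all(diff(v) > 0) || all(diff(v) < 0)) return(k)
    }
  }
  0
}

cultivar_samples <- function(aln) {
  aln$samples[aln$populations %in% c("japonica", "indica")]
}

ingroup_subaln <- function(aln) {
  ing <- aln$samples[aln$populations != "outgroup"]
  locus_alignment(aln$seq[ing, , drop = FALSE], samples = ing,
                  populations = aln$populations[ing],
                  locus_id = aln$locus_id)
}
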