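#' Construct a region gene set
#'
#' An ordered gene list for one genomic region: coordinates (1-based
#' inclusive), strand and CDS sequence per gene. Genes are sorted by start.
#'
#' @param genes Data frame with columns `gene_id`, `start`, `end`, `strand`.
#' @param cds Named character vector of CDS sequences (names = gene ids).
#' @param region_id Region label.
#' @return Object of class `region_gene_set`.
#' @export
region_gene_set <- function(genes, cds, region_id = "region") {
  stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(genes)))
  missing_cds <- setdiff(genes$gene_id, names(cds))
  if (length(missing_cds))
    stop("missing CDS for: ", paste(missing_cds, collapse = ", "),
         call. = FALSE)
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(region_id = region_id, genes = genes,
                 cds = toupper(cds[genes$gene_id])),
            class = "region_gene_set")
}

#' Read a region gene set from a GFF-like TSV plus a CDS FASTA
#'
#' @param gff_path TSV with columns `gene_id`, `start`, `end`, `strand`
#'   (header required).
#' @param cds_path FASTA of CDS sequences named by gene id.
#' @param region_id Region label (default: gff file name).
#' @export
read_region_gene_set <- function(gff_path, cds_path,
                                 region_id = sub("\\.[^.]*$", "",
                                                 basename(gff_path))) {
  genes <- read.delim(gff_path, stringsAsFactors = FALSE)
  ss <- Biostrings::readBStringSet(cds_path)
  cds <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  region_gene_set(genes, cds, region_id)
}

#' @export
print.region_gene_set <- function(x, ...) {
  cat(sprintf("<region_gene_set> %s: %d genes spanning %d..%d\n",
              x$region_id, nrow(x$genes), min(x$genes$start),
              max(x$genes$end)))
  invisible(x)
}

# Best local-alignment hit of each query CDS against a set of subject CDS.
# Scoring: match +1, mismatch -1, gap open -2, gap extend -1.
local_align_stats <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  alen <- Biostrings::nchar(pa)
  list(score = Biostrings::score(pa),
       identity = if (alen > 0) Biostrings::nmatch(pa) / alen else 0,
       coverage = alen / min(nchar(a), nchar(b)))
}

#' Homologous gene pairs between two regions by reciprocal best hit
#'
#' Scores every cross-region CDS pair with a local aligner (match +1,
#' mismatch -1, gap open -2, gap extend -1), keeps reciprocal best matches,
#' and filters by alignment identity and by aligned coverage of the shorter
#' CDS.
#'
#' @param set_a,set_b [region_gene_set] objects.
#' @param min_identity Minimum alignment identity (default 0.6).
#' @param min_coverage Minimum aligned fraction of the shorter CDS
#'   (default 0.5).
#' @return Data frame with `gene_a`, `gene_b`, `score`, `identity`,
#'   `coverage`, `a_rank`, `b_rank` (positional ranks within each region),
#'   ordered by `a_rank`.
#' @export
homolog_pairs <- function(set_a, set_b, min_identity = 0.6,
                          min_coverage = 0.5) {
  na <- nrow(set_a$genes); nb <- nrow(set_b$genes)
  stopifnot(na > 0L, nb > 0L)
  score <- ident <- cover <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    st <- local_align_stats(set_a$cds[[i]], set_b$cds[[j]])
    score[i, j] <- st$score; ident[i, j] <- st$identity
    cover[i, j] <- st$coverage
  }
  best_a <- max.col(score, ties.method = "first")
  best_b <- max.col(t(score), ties.method = "first")
  rows <- list()
  for (i in seq_len(na)) {
    j <- best_a[i]
    if (best_b[j] == i && score[i, j] > 0 &&
        ident[i, j] >= min_identity && cover[i, j] >= min_coverage) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = set_a$genes$gene_id[i], gene_b = set_b$genes$gene_id[j],
        score = score[i, j], identity = ident[i, j],
        coverage = cover[i, j], a_rank = i, b_rank = j,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0), a_rank = integer(0),
                      b_rank = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$a_rank), , drop = FALSE]
}

#' Longest collinear chain of homolog pairs
#'
#' Finds the longest chain of pairs strictly increasing in region-A order
#' and monotone in region-B order. Both orientations (same, inverted) are
#' tried and the longer chain kept; at equal length the same-orientation
#' chain wins, and within an orientation ties prefer the chain whose A-ranks
#' are lexicographically smallest (lowest starting A-rank first).
#'
#' @param pairs Data frame from [homolog_pairs] (needs `a_rank`, `b_rank`).
#' @return Object of class `synteny_block`: `pairs` (the chained subset),
#'   `orientation` (`"same"` or `"inverted"`), `length`.
#' @export
collinear_chain <- function(pairs) {
  stopifnot(nrow(pairs) >= 1L)
  ord <- order(pairs$a_rank)
  p <- pairs[ord, , drop = FALSE]
  same <- lis_indices(p$b_rank)
  inv <- lis_indices(-p$b_rank)
  pickinv <- length(inv) > length(same)
  idx <- if (pickinv) inv else same
  structure(list(pairs = p[idx, , drop = FALSE],
                 orientation = if (pickinv) "inverted" else "same",
                 length = length(idx)),
            class = "synteny_block")
}

# Longest strictly increasing subsequence (indices); among maximal chains
# returns the lexicographically smallest index sequence.
lis_indices <- function(v) {
  n <- length(v)
  len <- rep(1L, n); nxt <- rep(NA_integer_, n)
  # len[i]: longest chain starting at i; built right-to-left so that the
  # reconstruction can greedily take the earliest feasible element.
  for (i in n:1) {
    for (j in seq_len(n - i) + i) {
      if (v[j] > v[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L; nxt[i] <- j
      }
    }
  }
  best <- max(len)
  start <- which(len == best)[1L]
  idx <- integer(0); cur <- start
  while (!is.na(cur)) { idx <- c(idx, cur); cur <- nxt[cur] }
  idx
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("<synteny_block> %d collinear pairs (%s orientation)\n",
              x$length, x$orientation))
  print(x$pairs[, c("gene_a", "gene_b", "identity")], row.names = FALSE)
  invisible(x)
}
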