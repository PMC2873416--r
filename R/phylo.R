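#' Pairwise distance matrix
#'
#' Computes a symmetric distance matrix from a [locus_alignment] (models
#' `p`, `jc`, `protein_p`) or a [genotype_matrix] (model `allele_sharing`).
#' Nucleotide and protein distances use pairwise deletion: each pair is
#' compared only at columns where both carry an unambiguous state.
#'
#' * `p` - mismatch proportion.
#' * `jc` - Jukes-Cantor correction `-(3/4) ln(1 - (4/3) p)`; `p >= 3/4`
#'   yields a saturated (`NA`) entry.
#' * `protein_p` - p-distance on the translated sequences (codons with gaps
#'   or `N` translate to missing).
#' * `allele_sharing` - one minus the fraction of shared alleles over
#'   jointly non-missing biallelic sites.
#'
#' @param x A [locus_alignment] or [genotype_matrix].
#' @param model Distance model (see above).
#' @return Symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
distance_matrix <- function(x, model = c("p", "jc", "protein_p",
                                         "allele_sharing")) {
  model <- match.arg(model)
  if (model == "allele_sharing") {
    stopifnot(inherits(x, "genotype_matrix"))
    g <- x$geno
    n <- nrow(g)
    d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      d[i, j] <- d[j, i] <- if (any(ok)) mean(g[i, ok] != g[j, ok]) else NA_real_
    }
    return(d)
  }
  stopifnot(inherits(x, "locus_alignment"))
  m <- x$seq
  if (model == "protein_p") m <- translate_matrix(m)
  miss <- if (model == "protein_p") c("X", "-") else MISSING_CHARS
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !(m[i, ] %in% miss) & !(m[j, ] %in% miss)
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else NA_real_
    if (model == "jc") p <- jc_correct(p)
    d[i, j] <- d[j, i] <- p
  }
  d
}

# Translate an aligned character matrix codon-wise; codons containing
# anything outside ACGT become 'X' (missing).
translate_matrix <- function(m) {
  L <- ncol(m) - ncol(m) %% 3
  nc <- L / 3
  gc <- genetic_code()
  t(apply(m[, seq_len(L), drop = FALSE], 1L, function(row) {
    cods <- paste0(row[3 * seq_len(nc) - 2], row[3 * seq_len(nc) - 1],
                   row[3 * seq_len(nc)])
    aa <- gc[cods]
    aa[is.na(aa)] <- "X"
    aa
  }))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with a fixed deterministic contract: ties in
#' the Q criterion are broken by the lexicographically smallest (sorted)
#' taxon-label pair, and a negative branch length is clamped to zero with
#' the deficit moved to its sister branch. Returns an unrooted `ape::phylo`
#' tree (basal trifurcation).
#'
#' @param dm Symmetric distance matrix with taxon labels (zero diagonal).
#' @return An `ape` `phylo` object.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("need >= 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("input error: distance matrix not symmetric", call. = FALSE)
  if (any(is.na(dm))) stop("input error: NA (saturated?) distances", call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # working nodes: tips 1..n, internals n+1.. ; ape wants root = n+1, so
  # internal ids are assigned descending from 2n-2 and remapped at the end.
  node_id <- seq_len(n)            # current node id per active row
  node_lab <- labels               # for tie-breaking: representative label
  edges <- matrix(0L, 0L, 2L); elen <- numeric(0)
  next_internal <- 2L * n - 2L
  D <- dm
  while (nrow(D) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(node_lab[ij[1]], node_lab[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    # clamp negatives, moving the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    if (vi < 0) vi <- 0
    if (vj < 0) vj <- 0
    new_id <- next_internal; next_internal <- next_internal - 1L
    edges <- rbind(edges, c(new_id, node_id[i]), c(new_id, node_id[j]))
    elen <- c(elen, vi, vj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node_id <- c(node_id[keep], new_id)
    node_lab <- c(node_lab[keep], min(node_lab[c(i, j)]))
  }
  # terminal 3-node star: three-point formulas
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  vv <- c(v1, v2, v3)
  for (k in 1:3) if (vv[k] < 0) {
    sis <- which.max(vv[-k]); sis <- setdiff(1:3, k)[sis]
    vv[sis] <- vv[sis] + vv[k]; vv[k] <- 0
  }
  root <- n + 1L
  edges <- rbind(edges, cbind(root, node_id[1:3]))
  elen <- c(elen, pmax(vv, 0))
  # remap internal ids (descending 2n-2..) into ape order while keeping root
  used <- sort(unique(edges[edges > n]))
  map <- integer(2L * n); map[seq_len(n)] <- seq_len(n)
  map[root] <- n + 1L
  others <- setdiff(used, root)
  map[others] <- n + 1L + seq_along(others)
  edges[] <- map[edges]
  tr <- structure(list(edge = edges, edge.length = elen,
                       tip.label = labels, Nnode = length(used)),
                  class = "phylo", order = NULL)
  ape::reorder.phylo(tr, "cladewise")
}

# Nontrivial bipartitions of an unrooted phylo as canonical strings: the
# side not containing the alphabetically first taxon, sorted and joined.
tree_splits <- function(tree, trivial = FALSE) {
  tips <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  desc <- descendant_sets(tree)
  canon <- function(set) {
    if (tips[1L] %in% set) set <- setdiff(tree$tip.label, set)
    paste(sort(set), collapse = "\r")
  }
  internal <- tree$edge[, 2L] > ntip
  sets <- desc[tree$edge[internal, 2L] - ntip]
  sp <- vapply(sets, function(s) canon(s), character(1))
  sizes <- vapply(sets, function(s)
    min(length(s), ntip - length(s)), integer(1))
  sp <- sp[sizes >= 2L]
  if (trivial)
    sp <- c(sp, vapply(tree$tip.label, function(t) canon(t), character(1)))
  unique(sp)
}

# Tip labels descending from each internal node (index 1 = node ntip+1),
# by postorder accumulation over the edge list.
descendant_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", tree$Nnode)
  kids <- vector("list", tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L] - ntip
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2L])
  }
  get_set <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    idx <- node - ntip
    if (!is.null(sets[[idx]])) return(sets[[idx]])
    s <- unlist(lapply(kids[[idx]], get_set), use.names = FALSE)
    sets[[idx]] <<- s
    s
  }
  for (i in seq_len(tree$Nnode)) get_set(i + ntip)
  sets
}

#' Robinson-Foulds distance
#'
#' Number of nontrivial bipartitions present in exactly one of two unrooted
#' trees over the same leaf set.
#'
#' @param t1,t2 `phylo` trees with identical tip labels.
#' @return Integer count (the symmetric-difference RF distance).
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("input error: leaf sets differ", call. = FALSE)
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Monophyly of a taxon subset on an unrooted tree
#'
#' `TRUE` iff some edge of the unrooted tree separates exactly the given
#' subset from all remaining taxa (single leaves and complements of single
#' leaves are trivially monophyletic).
#'
#' @param tree `phylo` tree.
#' @param taxa Non-empty proper subset of `tree$tip.label`.
#' @return Logical.
#' @export
monophyly_check <- function(tree, taxa) {
  stopifnot(length(taxa) >= 1L, all(taxa %in% tree$tip.label),
            length(taxa) < length(tree$tip.label))
  tips <- sort(tree$tip.label)
  set <- taxa
  if (tips[1L] %in% set) set <- setdiff(tree$tip.label, set)
  key <- paste(sort(set), collapse = "\r")
  key %in% tree_splits(tree, trivial = TRUE)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree on the full alignment, then resamples alignment
#' columns with replacement `reps` times, rebuilds the tree and records for
#' each internal edge of the full tree the fraction of replicates containing
#' its bipartition. Supports are stored as internal node labels (root label
#' empty).
#'
#' @param aln A [locus_alignment].
#' @param model Distance model passed to [distance_matrix].
#' @param reps Bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return `phylo` tree with `node.label` support fractions.
#' @export
bootstrap_support <- function(aln, model = "jc", reps = 100L, seed = 1L) {
  base_tree <- neighbor_joining(distance_matrix(aln, model))
  set.seed(seed)
  L <- ncol(aln$seq)
  all_splits <- character(0)
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    baln <- locus_alignment(aln$seq[, cols, drop = FALSE],
                            samples = aln$samples,
                            populations = aln$populations,
                            locus_id = aln$locus_id)
    btr <- neighbor_joining(distance_matrix(baln, model))
    all_splits <- c(all_splits, tree_splits(btr))
  }
  counts <- table(all_splits)
  ntip <- length(base_tree$tip.label)
  # per internal node of the base tree, look up its split's replicate count
  desc <- descendant_sets(base_tree)
  tips <- sort(base_tree$tip.label)
  labs <- vapply(seq_len(base_tree$Nnode), function(i) {
    s <- desc[[i]]
    if (min(length(s), ntip - length(s)) < 2L) return("")
    if (tips[1L] %in% s) s <- setdiff(base_tree$tip.label, s)
    key <- paste(sort(s), collapse = "\r")
    sprintf("%.3f", if (key %in% names(counts)) counts[[key]] / reps else 0)
  }, character(1))
  base_tree$node.label <- labs
  base_tree
}
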