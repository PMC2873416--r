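# Site-wise complete deletion within the analyzed sample: a column is retained
# only if every retained sequence carries an unambiguous base there. '-' and
# 'N' are both treated as missing. Returns the sub-matrix of retained rows and
# an index of retained columns (relative to the input slice).
pop_matrix <- function(aln, population, cols = NULL) {
  keep <- aln$samples[aln$populations %in% population]
  if (!length(keep)) stop("insufficient-sample: no samples in population '",
                          paste(population, collapse = ","), "'", call. = FALSE)
  m <- aln$seq[keep, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  ok <- colSums(m == "-" | m == "N") == 0L
  list(mat = m[, ok, drop = FALSE], retained = which(ok), n = length(keep))
}

check_n <- function(n, min_n, what) {
  if (n < min_n)
    stop("insufficient-sample: ", what, " requires >= ", min_n,
         " sequences, got ", n, call. = FALSE)
}

# Allele counts per retained column: 4 x L_eff matrix of A/C/G/T counts.
site_allele_counts <- function(mat) {
  vapply(c("A", "C", "G", "T"),
         function(b) colSums(mat == b),
         numeric(ncol(mat)))
}

#' Segregating sites
#'
#' Counts columns with at least two distinct bases among the samples of one
#' population, after site-wise complete deletion of columns containing `-` or
#' `N` within that population.
#'
#' @param aln A [locus_alignment].
#' @param population Population label (or vector of labels pooled together).
#' @return List with `S` (segregating sites) and `L_eff` (columns retained).
#' @export
segregating_sites <- function(aln, population) {
  pm <- pop_matrix(aln, population)
  check_n(pm$n, 2L, "segregating_sites")
  if (ncol(pm$mat) == 0L) return(list(S = 0L, L_eff = 0L))
  cnt <- site_allele_counts(pm$mat)
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
  S <- sum(rowSums(cnt > 0L) >= 2L)
  list(S = as.integer(S), L_eff = ncol(pm$mat))
}

# Total (not per-site) mean number of pairwise differences, via per-column
# allele counts: pi_col = 1 - sum(C(n_a,2))/C(n,2).
mean_pairwise_diffs <- function(mat) {
  n <- nrow(mat)
  if (ncol(mat) == 0L) return(0)
  cnt <- site_allele_counts(mat)
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
  same <- rowSums(cnt * (cnt - 1) / 2)
  sum(1 - same / (n * (n - 1) / 2))
}

#' Nucleotide diversity (per site)
#'
#' Mean pairwise difference count over all unordered sequence pairs, divided
#' by the number of retained columns.
#'
#' @inheritParams segregating_sites
#' @return Per-site nucleotide diversity (theta-pi).
#' @export
nucleotide_diversity <- function(aln, population) {
  pm <- pop_matrix(aln, population)
  check_n(pm$n, 2L, "nucleotide_diversity")
  if (ncol(pm$mat) == 0L) return(0)
  mean_pairwise_diffs(pm$mat) / ncol(pm$mat)
}

harmonic <- function(n, power = 1) sum(1 / seq_len(n - 1)^power)

#' Watterson's theta (per site)
#'
#' `S / (a1 * L_eff)` with `a1 = sum_{i=1..n-1} 1/i`.
#'
#' @inheritParams segregating_sites
#' @return Per-site Watterson estimator.
#' @export
watterson_theta <- function(aln, population) {
  pm <- pop_matrix(aln, population)
  check_n(pm$n, 2L, "watterson_theta")
  ss <- segregating_sites(aln, population)
  if (ss$L_eff == 0L) return(0)
  ss$S / (harmonic(pm$n) * ss$L_eff)
}

# Tajima (1989) normalizing constants for sample size n.
tajima_constants <- function(n) {
  a1 <- harmonic(n); a2 <- harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_from_counts <- function(pi_total, S, n) {
  if (S == 0L) return(NA_real_)
  k <- tajima_constants(n)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Scaled difference between the pairwise-difference and segregating-site
#' estimates of theta, using total (not per-site) quantities and the standard
#' sample-size constants. Undefined (`NA`) when there are no segregating
#' sites.
#'
#' @inheritParams segregating_sites
#' @return Tajima's D, or `NA` when `S = 0`.
#' @export
tajimas_d <- function(aln, population) {
  pm <- pop_matrix(aln, population)
  check_n(pm$n, 3L, "tajimas_d")
  ss <- segregating_sites(aln, population)
  tajima_d_from_counts(mean_pairwise_diffs(pm$mat), ss$S, pm$n)
}

#' Parametric-bootstrap significance for Tajima's D
#'
#' Simulates neutral constant-size coalescent genealogies for the observed
#' sample size, drops the observed number of segregating sites onto branches
#' in proportion to branch length, and compares the observed D to the
#' simulated distribution. Assumption-explicit alternative to the beta
#' approximation; fully seeded.
#'
#' @inheritParams segregating_sites
#' @param reps Number of bootstrap genealogies (default 10000).
#' @param seed Integer seed.
#' @return List with `d` (observed), `p_lower` = P(D_sim <= D_obs),
#'   `p_upper`, and `p_two` = 2*min(p_lower, p_upper) capped at 1.
#' @export
tajima_d_test <- function(aln, population, reps = 10000L, seed = 1L) {
  pm <- pop_matrix(aln, population)
  check_n(pm$n, 3L, "tajima_d_test")
  ss <- segregating_sites(aln, population)
  d_obs <- tajima_d_from_counts(mean_pairwise_diffs(pm$mat), ss$S, pm$n)
  if (is.na(d_obs)) stop("Tajima's D undefined (S = 0)", call. = FALSE)
  set.seed(seed)
  sims <- replicate(reps, sim_tajima_d_at_s(pm$n, ss$S))
  p_lo <- mean(sims <= d_obs)
  p_hi <- mean(sims >= d_obs)
  list(d = d_obs, p_lower = p_lo, p_upper = p_hi,
       p_two = min(1, 2 * min(p_lo, p_hi)), reps = reps)
}

# One neutral-coalescent D value conditional on S segregating sites: simulate
# the genealogy, place S mutations multinomially by branch length, tally the
# folded frequency of each mutation.
sim_tajima_d_at_s <- function(n, S) {
  k <- n:2
  times <- rexp(n - 1L, rate = k * (k - 1) / 2)   # time while k lineages
  # branch lengths per lineage: each of the k lineages present during epoch k
  # accrues times[which]. Track descendant counts by explicit coalescence.
  desc <- rep(1L, n)
  lens <- rep(0, n)
  active <- seq_len(n)
  br_desc <- integer(0); br_len <- numeric(0)
  for (i in seq_along(k)) {
    lens[active] <- lens[active] + times[i]
    pick <- sample(active, 2L)
    br_desc <- c(br_desc, desc[pick]); br_len <- c(br_len, lens[pick])
    new <- length(desc) + 1L
    desc <- c(desc, sum(desc[pick])); lens <- c(lens, 0)
    active <- c(setdiff(active, pick), new)
  }
  if (S == 0L) return(NA_real_)
  counts <- as.vector(stats::rmultinom(1L, S, br_len))
  freqs <- rep(br_desc, counts)
  pi_tot <- sum(freqs * (n - freqs)) / (n * (n - 1) / 2)
  tajima_d_from_counts(pi_tot, S, n)
}

#' Haplotype classification
#'
#' Groups sequences that are identical at all retained columns (site-wise
#' complete deletion across the included samples) into types. Types are
#' numbered 1..k by descending member count; ties broken by first occurrence
#' in input order. Haplotype diversity is `n(1 - sum p_i^2)/(n-1)`.
#'
#' @param aln A [locus_alignment].
#' @param populations Population labels to include (default: all
#'   non-outgroup).
#' @return List with `types` (named list type id -> member sample ids),
#'   `assignment` (named integer vector sample -> type), `hap_count` and
#'   `hap_div`.
#' @export
haplotype_classify <- function(aln,
                               populations = setdiff(unique(aln$populations),
                                                     "outgroup")) {
  pm <- pop_matrix(aln, populations)
  n <- pm$n
  haps <- if (ncol(pm$mat)) apply(pm$mat, 1L, paste0, collapse = "")
          else rep("", n)
  first <- match(unique(haps), haps)
  sizes <- as.vector(table(haps)[unique(haps)])
  ord <- order(-sizes, first)
  type_of <- match(haps, unique(haps)[ord])
  members <- split(rownames(pm$mat), type_of)
  names(members) <- paste0("type", names(members))
  p <- sizes[ord] / n
  hd <- if (n >= 2L) n * (1 - sum(p^2)) / (n - 1) else 0
  list(types = members,
       assignment = setNames(type_of, rownames(pm$mat)),
       hap_count = length(members), hap_div = hd)
}

#' Per-population locus statistics
#'
#' Bundles sample size, retained length, segregating sites, nucleotide
#' diversity, Watterson's theta, Tajima's D and haplotype summaries for one
#' population at one locus.
#'
#' @inheritParams segregating_sites
#' @return Object of class `locus_stats` (list with the report fields).
#' @export
locus_stats <- function(aln, population) {
  pm <- pop_matrix(aln, population)
  check_n(pm$n, 2L, "locus_stats")
  ss <- segregating_sites(aln, population)
  pi_tot <- mean_pairwise_diffs(pm$mat)
  hap <- haplotype_classify(aln, population)
  structure(list(
    locus_id = aln$locus_id,
    population = paste(population, collapse = "+"),
    n = pm$n, L_eff = ss$L_eff, S = ss$S,
    pi = if (ss$L_eff) pi_tot / ss$L_eff else 0,
    theta_w = if (ss$L_eff) ss$S / (harmonic(pm$n) * ss$L_eff) else 0,
    tajima_d = if (pm$n >= 3L) tajima_d_from_counts(pi_tot, ss$S, pm$n)
               else NA_real_,
    hap_count = hap$hap_count, hap_div = hap$hap_div),
    class = "locus_stats")
}

#' @export
as.data.frame.locus_stats <- function(x, ...) {
  data.frame(x[STATS_COLUMNS], stringsAsFactors = FALSE)
}

#' @export
print.locus_stats <- function(x, ...) {
  cat(sprintf(
    "<locus_stats> %s / %s: n=%d L_eff=%d S=%d pi=%.6f thetaW=%.6f D=%s\n",
    x$locus_id, x$population, x$n, x$L_eff, x$S, x$pi, x$theta_w,
    ifelse(is.na(x$tajima_d), "NA", sprintf("%.4f", x$tajima_d))))
  invisible(x)
}

#' Sliding-window statistic track
#'
#' Evaluates one statistic on successive column slices of the alignment.
#' Windows advance by `step` bp; the number of full windows is
#' `floor((L - window)/step) + 1`. Reported bounds are 1-based inclusive on
#' the coordinate scale of the alignment (`coordinate_offset`). The deletion
#' rule is applied within each window.
#'
#' @inheritParams segregating_sites
#' @param window,step Window and step sizes in alignment columns (bp).
#' @param stat One of `"pi"`, `"theta_w"`, `"tajima_d"`, `"S"`, `"hap_div"`.
#' @param partial Report a trailing partial window (default `FALSE`).
#' @return Data frame of class `window_track` with columns `locus_id`,
#'   `population`, `window_start`, `window_end`, `stat`, `value`.
#' @export
sliding_windows <- function(aln, population, window, step,
                            stat = c("pi", "theta_w", "tajima_d", "S",
                                     "hap_div"),
                            partial = FALSE) {
  stat <- match.arg(stat)
  L <- ncol(aln$seq)
  if (window > L) stop("config error: window larger than alignment", call. = FALSE)
  if (step < 1L) stop("config error: step must be >= 1", call. = FALSE)
  starts <- seq(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  if (partial && tail(ends, 1L) < L) {
    starts <- c(starts, tail(starts, 1L) + step)
    ends <- c(ends, L)
  }
  vals <- mapply(function(s, e) {
    sub <- window_slice(aln, s, e)
    st <- locus_stats(sub, population)
    as.numeric(st[[stat]])
  }, starts, ends)
  structure(data.frame(
    locus_id = aln$locus_id, population = paste(population, collapse = "+"),
    window_start = starts + aln$coordinate_offset - 1L,
    window_end = ends + aln$coordinate_offset - 1L,
    stat = stat, value = vals, stringsAsFactors = FALSE),
    class = c("window_track", "data.frame"),
    window = window, step = step)
}

# Column slice [from, to] (alignment-local, 1-based) as a new alignment.
window_slice <- function(aln, from, to) {
  locus_alignment(aln$seq[, from:to, drop = FALSE], samples = aln$samples,
                  populations = aln$populations, locus_id = aln$locus_id,
                  coordinate_offset = aln$coordinate_offset + from - 1L)
}

#' Near-fixed differences between two populations
#'
#' Scans retained columns for sites where the major allele of population A
#' has frequency at least `freq_threshold` in A and at most
#' `1 - freq_threshold` in B ("almost fixed" differences; default 0.95).
#' Columns with missing data in either population are dropped.
#'
#' @param aln A [locus_alignment].
#' @param pop_a,pop_b Population labels.
#' @param freq_threshold Fraction in `(0.5, 1]`.
#' @return Data frame with `site` (1-based, on the alignment coordinate
#'   scale), `allele_a` (major allele of A), `allele_b` (major allele of B),
#'   `freq_a` and `freq_b` (frequency of `allele_a` in each population).
#' @export
fixed_differences <- function(aln, pop_a, pop_b, freq_threshold = 0.95) {
  if (freq_threshold <= 0.5 || freq_threshold > 1)
    stop("config error: freq_threshold must be in (0.5, 1]", call. = FALSE)
  pa <- pop_matrix(aln, pop_a); pb <- pop_matrix(aln, pop_b)
  check_n(pa$n, 2L, "fixed_differences"); check_n(pb$n, 2L, "fixed_differences")
  cols <- intersect(pa$retained, pb$retained)
  if (!length(cols))
    return(data.frame(site = integer(0), allele_a = character(0),
                      allele_b = character(0), freq_a = numeric(0),
                      freq_b = numeric(0)))
  ma <- pa$mat[, match(cols, pa$retained), drop = FALSE]
  mb <- pb$mat[, match(cols, pb$retained), drop = FALSE]
  ca <- site_allele_counts(ma); cb <- site_allele_counts(mb)
  if (is.null(dim(ca))) { ca <- matrix(ca, nrow = 1L); cb <- matrix(cb, nrow = 1L) }
  bases <- c("A", "C", "G", "T")
  maj_a_i <- max.col(ca, ties.method = "first")
  maj_b_i <- max.col(cb, ties.method = "first")
  fa <- ca[cbind(seq_len(nrow(ca)), maj_a_i)] / pa$n
  fb_of_a <- cb[cbind(seq_len(nrow(cb)), maj_a_i)] / pb$n
  hit <- fa >= freq_threshold & fb_of_a <= 1 - freq_threshold
  data.frame(site = cols[hit] + aln$coordinate_offset - 1L,
             allele_a = bases[maj_a_i[hit]],
             allele_b = bases[maj_b_i[hit]],
             freq_a = fa[hit], freq_b = fb_of_a[hit],
             stringsAsFactors = FALSE)
}
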