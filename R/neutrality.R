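#' Polymorphism and divergence counts for one locus
#'
#' Classifies alignment columns for the HKA test: `S` counts sites segregating
#' within the ingroup (all non-outgroup samples, columns with no missing
#' ingroup base), `D` counts sites monomorphic in the ingroup but different
#' from the single outgroup sequence (columns additionally requiring an
#' unambiguous outgroup base). `L_poly` and `L_div` are the respective
#' numbers of surveyed columns.
#'
#' @param aln A [locus_alignment] containing exactly one sample labelled
#'   `outgroup`.
#' @param outgroup_label Population label of the outgroup (default
#'   `"outgroup"`).
#' @param ingroup Optional vector of population labels forming the ingroup
#'   (default: all non-outgroup populations).
#' @return List of class `hka_row`: `locus_id`, `S`, `n` (ingroup sample
#'   size), `L_poly`, `D`, `L_div`.
#' @export
polymorphism_divergence_counts <- function(aln, outgroup_label = "outgroup",
                                           ingroup = NULL) {
  og <- aln$samples[aln$populations == outgroup_label]
  if (length(og) != 1L)
    stop("input error: exactly one outgroup sample required, found ",
         length(og), call. = FALSE)
  if (is.null(ingroup)) ingroup <- setdiff(unique(aln$populations),
                                           outgroup_label)
  pin <- pop_matrix(aln, ingroup)
  check_n(pin$n, 2L, "polymorphism_divergence_counts")
  cnt <- site_allele_counts(pin$mat)
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
  seg <- rowSums(cnt > 0L) >= 2L
  S <- sum(seg)
  ogseq <- aln$seq[og, pin$retained]
  ok_og <- !(ogseq %in% MISSING_CHARS)
  mono <- !seg & ok_og
  D <- sum(pin$mat[1L, ][mono] != ogseq[mono])
  structure(list(locus_id = aln$locus_id, S = as.integer(S), n = pin$n,
                 L_poly = ncol(pin$mat), D = as.integer(D),
                 L_div = sum(ok_og)),
            class = "hka_row")
}

#' Assemble HKA input from explicit counts
#'
#' @param S Segregating sites within species.
#' @param n Sample size used for polymorphism.
#' @param L_poly Sites surveyed for polymorphism.
#' @param D Fixed differences to the outgroup.
#' @param L_div Sites surveyed for divergence.
#' @param locus_id Label.
#' @return An `hka_row` list.
#' @export
hka_row <- function(S, n, L_poly, D, L_div, locus_id = "locus") {
  stopifnot(S >= 0, D >= 0, L_poly > 0, L_div > 0, S <= L_poly, D <= L_div,
            n >= 2)
  structure(list(locus_id = locus_id, S = S, n = n, L_poly = L_poly, D = D,
                 L_div = L_div), class = "hka_row")
}

#' Hudson-Kreitman-Aguade neutrality test (two loci)
#'
#' Tests homogeneity of the within-species polymorphism to between-species
#' divergence ratio between a candidate locus and a neutral reference locus.
#' Two methods are provided and clearly labelled:
#'
#' * `hka1987` - the classic moment-equation form: solves for per-length
#'   mutation parameters and the scaled divergence time `T` (with population
#'   size ratio `f`, default 1), then forms the goodness-of-fit statistic
#'   `X^2 = sum_i (S_i - E S_i)^2/Var S_i + (D_i - E D_i)^2/Var D_i` with
#'   `E S_i = theta_i L_poly_i a1(n_i)`,
#'   `Var S_i = E S_i + (theta_i L_poly_i)^2 a2(n_i)`,
#'   `E D_i = theta_i L_div_i (T + (1+f)/2)` and
#'   `Var D_i = E D_i + (theta_i L_div_i (1+f)/2)^2`; p from chi-square with
#'   1 df.
#' * `contingency` - the 2x2 table `[[S_cand, D_cand], [S_ref, D_ref]]`
#'   tested by chi-square without continuity correction, plus Fisher's exact
#'   test (reported whenever any expected cell is below 5).
#'
#' @param candidate,reference `hka_row` objects (see
#'   [polymorphism_divergence_counts], [hka_row]).
#' @param f Ratio of the outgroup-species to ingroup-species population size
#'   (default 1).
#' @param method `"hka1987"`, `"contingency"` or `"both"`.
#' @return Object of class `hka_result`: for each requested method the
#'   statistic, df, p-value, and for `hka1987` the fitted `theta` per site
#'   and `T_hat` plus expected counts.
#' @export
hka_test <- function(candidate, reference, f = 1,
                     method = c("both", "hka1987", "contingency")) {
  method <- match.arg(method)
  loci <- list(candidate, reference)
  stopifnot(all(vapply(loci, inherits, TRUE, "hka_row")))
  out <- list(candidate = candidate, reference = reference, f = f)
  if (method %in% c("hka1987", "both"))
    out$hka1987 <- hka_moment_fit(loci, f)
  if (method %in% c("contingency", "both")) {
    tab <- rbind(c(candidate$S, candidate$D), c(reference$S, reference$D))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("degenerate-input: zero row or column in contingency table",
           call. = FALSE)
    suppressWarnings(ch <- chisq.test(tab, correct = FALSE))
    fe <- fisher.test(tab)
    out$contingency <- list(
      table = tab, statistic = unname(ch$statistic), df = 1L,
      p_value = unname(ch$p.value), fisher_p = fe$p.value,
      small_counts = any(ch$expected < 5))
  }
  structure(out, class = "hka_result")
}

# Moment-equation fit (two loci, one ingroup species + single outgroup
# sequence). Unknowns theta_1, theta_2 (per site) and tau = T + (1+f)/2.
hka_moment_fit <- function(loci, f) {
  S <- vapply(loci, `[[`, 0, "S");  D <- vapply(loci, `[[`, 0, "D")
  Lp <- vapply(loci, `[[`, 0, "L_poly"); Ld <- vapply(loci, `[[`, 0, "L_div")
  n <- vapply(loci, `[[`, 0, "n")
  a1 <- vapply(n, harmonic, 0); a2 <- vapply(n, harmonic, 0, power = 2)
  K <- Lp * a1
  th2 <- function(tau) (S[2] + D[2]) / (K[2] + Ld[2] * tau)
  th1 <- function(tau) (sum(S) - th2(tau) * K[2]) / K[1]
  g <- function(tau) tau * (th1(tau) * Ld[1] + th2(tau) * Ld[2]) - sum(D)
  sol <- tryCatch(stats::uniroot(g, c(1e-9, 1e9), tol = 1e-12),
                  error = function(e)
                    stop("numerical error: HKA moment equations did not ",
                         "converge (", conditionMessage(e), ")", call. = FALSE))
  tau <- sol$root
  theta <- c(th1(tau), th2(tau))
  T_hat <- tau - (1 + f) / 2
  ES <- theta * K
  VS <- ES + (theta * Lp)^2 * a2
  ED <- theta * Ld * tau
  VD <- ED + (theta * Ld * (1 + f) / 2)^2
  x2 <- sum((S - ES)^2 / VS + (D - ED)^2 / VD)
  list(statistic = x2, df = 1L, p_value = pchisq(x2, 1L, lower.tail = FALSE),
       theta_locus = theta * Lp, theta_per_site = theta,
       T_hat = T_hat, tau = tau,
       expected = list(S = ES, D = ED), variance = list(S = VS, D = VD))
}

#' @export
print.hka_result <- function(x, ...) {
  cat("<hka_result> candidate:", x$candidate$locus_id,
      " reference:", x$reference$locus_id, "\n")
  cat(sprintf("  counts: S=%d/%d D=%d/%d (candidate/reference)\n",
              x$candidate$S, x$reference$S, x$candidate$D, x$reference$D))
  if (!is.null(x$hka1987))
    cat(sprintf("  HKA (1987 moment form): X2 = %.4f, df = 1, p = %.4g; T_hat = %.3f\n",
                x$hka1987$statistic, x$hka1987$p_value, x$hka1987$T_hat))
  if (!is.null(x$contingency))
    cat(sprintf("  contingency 2x2: X2 = %.4f, p = %.4g (Fisher p = %.4g)\n",
                x$contingency$statistic, x$contingency$p_value,
                x$contingency$fisher_p))
  invisible(x)
}

#' Simulate polymorphism/divergence counts under shared neutral parameters
#'
#' Generates `(S, D)` pairs for two loci under the null model of the HKA
#' test: `S_i` is Poisson with mean `theta_i * L_poly_i * Ttot/2` where
#' `Ttot` is the total length of a neutral coalescent genealogy of `n_i`
#' sequences, and `D_i` is Poisson with mean `theta_i * L_div_i * (T + tc)`
#' where `tc` is exponential with mean `(1+f)/2`. Used to calibrate the
#' type-I error of [hka_test].
#'
#' @param theta Per-site mutation parameters for the two loci (length 2).
#' @param T_div Scaled species divergence time.
#' @param n Ingroup sample sizes (length 2 or scalar).
#' @param L_poly,L_div Surveyed lengths (length 2).
#' @param f Population size ratio (default 1).
#' @return List of two `hka_row` objects.
#' @export
simulate_hka_counts <- function(theta, T_div, n, L_poly, L_div, f = 1) {
  n <- rep_len(n, 2L)
  rows <- lapply(1:2, function(i) {
    k <- n[i]:2
    ttot <- sum(k * rexp(n[i] - 1L, rate = k * (k - 1) / 2))
    S <- rpois(1L, theta[i] * L_poly[i] * ttot / 2)
    tc <- rexp(1L) * (1 + f) / 2
    D <- rpois(1L, theta[i] * L_div[i] * (T_div + tc))
    hka_row(S = min(S, L_poly[i]), n = n[i], L_poly = L_poly[i],
            D = min(D, L_div[i]), L_div = L_div[i],
            locus_id = c("candidate", "reference")[i])
  })
  names(rows) <- c("candidate", "reference")
  rows
}
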