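# Codon machinery for Nei-Gojobori (1986) counting under the standard
# nuclear genetic code (Biostrings::GENETIC_CODE). Site fractions and
# pathway-averaged difference counts are cached per codon (pair) at first
# use.
.kaks_cache <- new.env(parent = emptyenv())

genetic_code <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) unname(genetic_code()[codon])

is_stop <- function(codon) translate_codon(codon) == "*"

codon_neighbors <- function(codon, pos) {
  b <- strsplit(codon, "")[[1]]
  vapply(setdiff(c("A", "C", "G", "T"), b[pos]), function(nb) {
    b2 <- b; b2[pos] <- nb; paste0(b2, collapse = "")
  }, character(1))
}

#' Nei-Gojobori synonymous/nonsynonymous site fractions of a codon
#'
#' For each codon position, the fraction of the three possible point
#' mutations that are synonymous, excluding mutations that create stop
#' codons (the remaining mutations at that position are renormalized to sum
#' to one). Fractions sum to 3 per codon.
#'
#' @param codon Three-letter string over `A,C,G,T`; must not be a stop.
#' @return Named numeric vector `c(syn = ..., nonsyn = ...)`.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("input error: ambiguous or invalid codon '", codon, "'", call. = FALSE)
  if (is_stop(codon))
    stop("input error: stop codon '", codon, "'", call. = FALSE)
  key <- paste0("sites_", codon)
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])
  aa <- translate_codon(codon)
  syn <- 0
  for (pos in 1:3) {
    nbs <- codon_neighbors(codon, pos)
    keep <- !vapply(nbs, is_stop, TRUE)
    if (!any(keep)) next
    syn <- syn + sum(translate_codon(nbs[keep]) == aa) / sum(keep)
  }
  res <- c(syn = syn, nonsyn = 3 - syn)
  .kaks_cache[[key]] <- res
  res
}

#' Nei-Gojobori difference counts between two codons
#'
#' Zero differences give `(0, 0)`; one difference is classified directly;
#' two or three differences are averaged over all mutational pathways with
#' equal weights, discarding pathways that pass through a stop codon (if
#' every pathway does, unrestricted pathways are used with a warning).
#'
#' @param codon_a,codon_b Codons over `A,C,G,T`.
#' @return Named numeric vector `c(syn = Sd, nonsyn = Nd)`.
#' @export
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b))
    if (!grepl("^[ACGT]{3}$", cd) || is_stop(cd))
      stop("input error: invalid codon '", cd, "'", call. = FALSE)
  key <- paste0("diff_", codon_a, "_", codon_b)
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])
  ba <- strsplit(codon_a, "")[[1]]; bb <- strsplit(codon_b, "")[[1]]
  diffpos <- which(ba != bb)
  res <- if (length(diffpos) == 0L) c(syn = 0, nonsyn = 0)
         else ng86_pathways(ba, bb, diffpos)
  .kaks_cache[[key]] <- res
  res
}

# Average step classification over orderings of the differing positions.
ng86_pathways <- function(ba, bb, diffpos) {
  perms <- if (length(diffpos) == 1L) list(diffpos)
           else if (length(diffpos) == 2L)
             list(diffpos, rev(diffpos))
           else {
    idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(o) diffpos[o])
  }
  walk <- function(order) {
    cur <- ba; syn <- 0; nonsyn <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- bb[pos]
      cd_cur <- paste0(cur, collapse = ""); cd_nxt <- paste0(nxt, collapse = "")
      if (is_stop(cd_nxt)) return(NULL)
      if (translate_codon(cd_cur) == translate_codon(cd_nxt)) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  walk_any <- function(order) {  # unrestricted fallback
    cur <- ba; syn <- 0; nonsyn <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- bb[pos]
      aa1 <- translate_codon(paste0(cur, collapse = ""))
      aa2 <- translate_codon(paste0(nxt, collapse = ""))
      if (!is.na(aa1) && !is.na(aa2) && aa1 == aa2 && aa1 != "*") syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  paths <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(paths)) {
    warning("all mutational pathways pass through stop codons; ",
            "using unrestricted pathways")
    paths <- lapply(perms, walk_any)
  }
  Reduce(`+`, paths) / length(paths)
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)   # saturated/undefined
  -0.75 * log(1 - 4 * p / 3)
}

round_half_up <- function(x) floor(x + 0.5)

#' Pairwise Ka/Ks by the Nei-Gojobori method
#'
#' Computes fractional synonymous/nonsynonymous site and difference counts
#' over all analyzable codons (codons containing gaps, `N` or a stop in
#' either sequence are dropped pairwise), the proportions `pN = Nd/N` and
#' `pS = Sd/S`, Jukes-Cantor corrected rates
#' `d = -(3/4) ln(1 - (4/3) p)`, their ratio, and a Fisher exact test of
#' neutrality on the 2x2 table `{nonsyn, syn} x {differences,
#' non-differences}` with fractional counts rounded half-up.
#'
#' A proportion at or above 3/4 yields a saturated (`NA`) corrected rate and
#' sets `saturated = TRUE`. Identical sequences give `Ka = Ks = 0` and an
#' undefined (`NA`) ratio.
#'
#' @param seq_a,seq_b In-frame coding DNA strings of equal length, a
#'   multiple of 3, codon-aligned.
#' @return Object of class `codon_pair` with fields `N_sites`, `S_sites`,
#'   `Nd`, `Sd`, `pN`, `pS`, `Ka`, `Ks`, `ratio`, `fisher_p`, `codons_used`,
#'   `saturated`.
#' @export
kaks_pair <- function(seq_a, seq_b) {
  seq_a <- toupper(gsub("\\s", "", seq_a))
  seq_b <- toupper(gsub("\\s", "", seq_b))
  if (nchar(seq_a) != nchar(seq_b))
    stop("frame error: sequences differ in length", call. = FALSE)
  if (nchar(seq_a) %% 3 != 0)
    stop("frame error: length not a multiple of 3", call. = FALSE)
  nc <- nchar(seq_a) / 3
  ca <- substring(seq_a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cb <- substring(seq_b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  valid <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  valid[valid] <- !vapply(ca[valid], is_stop, TRUE) &
                  !vapply(cb[valid], is_stop, TRUE)
  if (any(!valid & (grepl("[^ACGT-]", ca) | grepl("[^ACGT-]", cb))))
    warning("codons with ambiguous bases skipped")
  ca <- ca[valid]; cb <- cb[valid]
  if (!length(ca)) stop("no analyzable codons", call. = FALSE)
  sa <- vapply(ca, ng86_sites, numeric(2))
  sb <- vapply(cb, ng86_sites, numeric(2))
  S_sites <- (sum(sa["syn", ]) + sum(sb["syn", ])) / 2
  N_sites <- (sum(sa["nonsyn", ]) + sum(sb["nonsyn", ])) / 2
  dd <- mapply(ng86_differences, ca, cb)
  Sd <- sum(dd["syn", ]); Nd <- sum(dd["nonsyn", ])
  pN <- Nd / N_sites; pS <- Sd / S_sites
  Ka <- jc_correct(pN); Ks <- jc_correct(pS)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  tab <- rbind(c(round_half_up(Nd), round_half_up(N_sites - Nd)),
               c(round_half_up(Sd), round_half_up(S_sites - Sd)))
  fisher_p <- if (any(tab < 0)) NA_real_ else fisher.test(tab)$p.value
  structure(list(codons_used = length(ca), N_sites = N_sites,
                 S_sites = S_sites, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 Ka = Ka, Ks = Ks, ratio = ratio, fisher_p = fisher_p,
                 saturated = isTRUE(pN >= 0.75) || isTRUE(pS >= 0.75)),
            class = "codon_pair")
}

#' @export
print.codon_pair <- function(x, ...) {
  cat(sprintf("<codon_pair> %d codons: N=%.2f S=%.2f Nd=%.2f Sd=%.2f\n",
              x$codons_used, x$N_sites, x$S_sites, x$Nd, x$Sd))
  cat(sprintf("  Ka=%s Ks=%s Ka/Ks=%s Fisher p=%.3g%s\n",
              fmt_or_na(x$Ka), fmt_or_na(x$Ks), fmt_or_na(x$ratio),
              x$fisher_p, if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}

fmt_or_na <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Molecular-clock duplication/divergence dating
#'
#' `T = Ks / (2 * rate)`: the synonymous divergence between two paralogs
#' accumulated along both lineages since duplication, divided by twice the
#' neutral substitution rate. The default rate is the commonly used
#' 6.5e-9 substitutions per silent site per year for rice nuclear genes.
#'
#' @param Ks Synonymous substitutions per synonymous site (>= 0).
#' @param rate Substitutions per silent site per year (> 0).
#' @return List of class `clock_estimate`: `Ks`, `rate`, `T_years`, `T_mya`.
#' @export
duplication_time <- function(Ks, rate = 6.5e-9) {
  if (rate <= 0) stop("config error: rate must be > 0", call. = FALSE)
  if (Ks < 0) stop("Ks must be >= 0", call. = FALSE)
  T_years <- Ks / (2 * rate)
  structure(list(Ks = Ks, rate = rate, T_years = T_years,
                 T_mya = T_years / 1e6),
            class = "clock_estimate")
}

#' @export
print.clock_estimate <- function(x, ...) {
  cat(sprintf("<clock_estimate> Ks = %.4f, rate = %.3g /site/year -> T = %.1f MYA\n",
              x$Ks, x$rate, x$T_mya))
  invisible(x)
}

#' Mean Ks over a set of codon pairs
#'
#' Arithmetic mean of the pairwise Ks values; saturated pairs are excluded
#' with a warning (all saturated is an error). Used to date a segmental
#' duplication from several flanking homolog pairs.
#'
#' @param pairs List of `codon_pair` objects (or numeric Ks values).
#' @return Mean Ks.
#' @export
mean_ks_over_pairs <- function(pairs) {
  ks <- vapply(pairs, function(p)
    if (inherits(p, "codon_pair")) p$Ks else as.numeric(p), numeric(1))
  bad <- is.na(ks)
  if (all(bad)) stop("estimation error: all pairs saturated", call. = FALSE)
  if (any(bad)) warning(sum(bad), " saturated pair(s) excluded from mean Ks")
  mean(ks[!bad])
}
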