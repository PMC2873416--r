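#' Scenario for the synthetic germplasm generator
#'
#' Parameterizes the demography the analysis assumes: a wild population
#' (optionally structured into two demes that split `wild_split_time` ago),
#' two cultivated subpopulations (japonica derived from deme 1, indica from
#' deme 2) that pass through a domestication bottleneck, an optional
#' selective sweep at the simulated (focal) locus, optional introgression
#' (the cultivated focal-locus haplotypes coalesce as a single recent
#' cluster shared by both subpopulations), and a distant outgroup sequence.
#' Time is in units of 2N generations; `theta` is the per-locus scaled
#' mutation rate under infinite sites.
#'
#' Defaults emulate a 25-cultivar (12 japonica + 13 indica) / 25-wild
#' resequencing panel at a ~4.6-kb locus with wild per-site diversity near
#' 0.01 and ~10% outgroup divergence.
#'
#' @param n_wild,n_japonica,n_indica Sample sizes.
#' @param L Locus length (bp).
#' @param theta Per-locus scaled mutation rate (4N mu L).
#' @param bottleneck_time Start (looking backward) of the cultivated
#'   bottleneck.
#' @param bottleneck_severity Relative size of the cultivated populations
#'   during the bottleneck, in (0, 1].
#' @param bottleneck_duration Length of the bottleneck phase; the cultivated
#'   lineages merge into their wild source deme at
#'   `bottleneck_time + bottleneck_duration`.
#' @param sweep Force near-simultaneous coalescence of each cultivated
#'   subpopulation's lineages at `sweep_time` (star approximation of a
#'   domestication sweep at this locus).
#' @param sweep_time Sweep time (must be < `bottleneck_time`).
#' @param introgression Sweep the two cultivated subpopulations jointly:
#'   all cultivated lineages coalesce to one at `sweep_time`, placing the
#'   shared haplotype in wild deme 1 (gene-tree cultivar monophyly).
#' @param outgroup_divergence Expected substitutions per site on the
#'   outgroup lineage.
#' @param wild_split_time Split time of the two wild demes; 0 = panmictic
#'   wild. Must exceed `bottleneck_time + bottleneck_duration` when
#'   positive.
#' @param seed Integer seed (mandatory for pipeline use).
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_wild = 25L, n_japonica = 12L, n_indica = 13L,
                         L = 4600L, theta = 40,
                         bottleneck_time = 0.05, bottleneck_severity = 0.05,
                         bottleneck_duration = 0.025,
                         sweep = FALSE, sweep_time = 0.02,
                         introgression = FALSE,
                         outgroup_divergence = 0.1,
                         wild_split_time = 0.3, seed = 1L) {
  if (bottleneck_severity <= 0 || bottleneck_severity > 1)
    stop("config error: bottleneck_severity must be in (0, 1]", call. = FALSE)
  if (theta < 0 || L < 1 || outgroup_divergence < 0)
    stop("config error: invalid theta/L/outgroup_divergence", call. = FALSE)
  if ((sweep || introgression) && sweep_time >= bottleneck_time)
    stop("config error: sweep_time must precede bottleneck_time", call. = FALSE)
  if (n_wild + n_japonica + n_indica < 2L)
    stop("config error: need at least 2 sampled sequences", call. = FALSE)
  if (wild_split_time > 0 && (n_japonica + n_indica) > 0 &&
      wild_split_time <= bottleneck_time + bottleneck_duration)
    stop("config error: wild_split_time must exceed the bottleneck end",
         call. = FALSE)
  structure(list(n_wild = n_wild, n_japonica = n_japonica,
                 n_indica = n_indica, L = as.integer(L), theta = theta,
                 bottleneck_time = bottleneck_time,
                 bottleneck_severity = bottleneck_severity,
                 bottleneck_duration = bottleneck_duration,
                 sweep = sweep, sweep_time = sweep_time,
                 introgression = introgression,
                 outgroup_divergence = outgroup_divergence,
                 wild_split_time = wild_split_time, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("<sim_scenario> wild=%d japonica=%d indica=%d L=%d ",
                     "theta=%.3g\n  bottleneck t=%.3g sev=%.3g dur=%.3g; ",
                     "sweep=%s introgression=%s; outgroup div=%.3g; seed=%d\n"),
              x$n_wild, x$n_japonica, x$n_indica, x$L, x$theta,
              x$bottleneck_time, x$bottleneck_severity, x$bottleneck_duration,
              x$sweep, x$introgression, x$outgroup_divergence, x$seed))
  invisible(x)
}

# Backward-in-time structured Kingman coalescent for one locus. Returns the
# branch list: for every lineage that coalesced, its length and the set of
# sampled tips below it.
coalesce_panel <- function(scn) {
  labels <- c(if (scn$n_wild) sprintf("wild_%02d", seq_len(scn$n_wild)),
              if (scn$n_japonica) sprintf("jap_%02d", seq_len(scn$n_japonica)),
              if (scn$n_indica) sprintf("ind_%02d", seq_len(scn$n_indica)))
  pops <- c(rep("wild", scn$n_wild), rep("japonica", scn$n_japonica),
            rep("indica", scn$n_indica))
  nsamp <- length(labels)
  structured_wild <- scn$wild_split_time > 0 && (scn$n_japonica +
                                                 scn$n_indica) > 0
  deme <- character(nsamp)
  deme[pops == "japonica"] <- "japonica"
  deme[pops == "indica"] <- "indica"
  wi <- which(pops == "wild")
  deme[wi] <- if (structured_wild)
    ifelse(seq_along(wi) %% 2L == 1L, "wild1", "wild2") else "wild1"

  lin <- lapply(seq_len(nsamp), function(i)
    list(tips = i, birth = 0, deme = deme[i]))
  branches <- list()
  t_now <- 0
  bt0 <- scn$bottleneck_time
  bt1 <- scn$bottleneck_time + scn$bottleneck_duration
  tw <- if (structured_wild) scn$wild_split_time else Inf
  do_sweep <- scn$sweep || scn$introgression

  close_branch <- function(l, t) {
    branches[[length(branches) + 1L]] <<- list(tips = l$tips,
                                               len = t - l$birth)
  }
  # star-coalesce the lineages at positions `idx` (in `lin`) at time t,
  # sequentially with negligible spacing; resulting lineage joins `into`.
  star_merge <- function(idx, t, into) {
    eps <- 1e-9
    while (length(idx) > 1L) {
      a <- idx[1L]; b <- idx[2L]
      close_branch(lin[[a]], t); close_branch(lin[[b]], t)
      lin[[a]] <<- list(tips = c(lin[[a]]$tips, lin[[b]]$tips), birth = t,
                        deme = into)
      lin[idx[2L]] <<- NULL
      idx <- c(idx[1L], idx[-(1:2)] - 1L)  # positions shift after removal
      t <- t + eps
    }
    lin[[idx[1L]]]$deme <<- into
  }

  pending_sweep <- do_sweep
  repeat {
    if (length(lin) == 1L) break
    demes <- vapply(lin, `[[`, "", "deme")
    sizes <- vapply(unique(demes), function(d) {
      if (d %in% c("japonica", "indica") && t_now >= bt0 && t_now < bt1)
        scn$bottleneck_severity else 1
    }, numeric(1))
    names(sizes) <- unique(demes)
    ks <- table(demes)
    rates <- vapply(names(ks), function(d)
      ks[[d]] * (ks[[d]] - 1) / 2 / sizes[[d]], numeric(1))
    total <- sum(rates)
    t_next <- if (total > 0) t_now + rexp(1L, total) else Inf
    # nearest demographic boundary
    bounds <- c(if (pending_sweep) scn$sweep_time else Inf,
                if (t_now < bt0) bt0 else Inf,
                if (t_now < bt1) bt1 else Inf,
                if (t_now < tw) tw else Inf)
    b_next <- min(bounds)
    if (t_next < b_next) {
      t_now <- t_next
      d <- sample(names(ks), 1L, prob = rates / total)
      here <- which(demes == d)
      pick <- if (length(here) == 2L) here else sample(here, 2L)
      a <- pick[1L]; b <- pick[2L]
      close_branch(lin[[a]], t_now); close_branch(lin[[b]], t_now)
      lin[[a]] <- list(tips = c(lin[[a]]$tips, lin[[b]]$tips), birth = t_now,
                       deme = d)
      lin[[b]] <- NULL
      next
    }
    t_now <- b_next
    if (pending_sweep && b_next == scn$sweep_time) {
      demes <- vapply(lin, `[[`, "", "deme")
      if (scn$introgression) {
        # the shared haplotype descends from a diverged donor lineage that
        # rejoins the wild pool only at the wild-deme split
        into <- if (structured_wild) "donor" else "japonica"
        idx <- which(demes %in% c("japonica", "indica"))
        if (length(idx) > 1L) star_merge(idx, t_now, into)
        else if (length(idx) == 1L) lin[[idx]]$deme <- into
      } else {
        for (d in c("japonica", "indica")) {
          idx <- which(vapply(lin, `[[`, "", "deme") == d)
          if (length(idx) > 1L) star_merge(idx, t_now + 1e-7, d)
        }
      }
      pending_sweep <- FALSE
    } else if (b_next == bt1) {
      # cultivated lineages rejoin their wild source demes
      for (i in seq_along(lin)) {
        if (lin[[i]]$deme == "japonica")
          lin[[i]]$deme <- "wild1"
        else if (lin[[i]]$deme == "indica")
          lin[[i]]$deme <- if (structured_wild) "wild2" else "wild1"
      }
    } else if (b_next == tw) {
      for (i in seq_along(lin)) lin[[i]]$deme <- "wild1"
      tw <- Inf
    }
  }
  list(branches = branches, labels = labels, pops = pops,
       tmrca = t_now)
}

#' Simulate one locus alignment under the scenario
#'
#' Runs the structured coalescent of [sim_scenario], drops
#' `Poisson(theta * branch_length / 2)` mutations on each branch under
#' infinite sites (each mutation occupies a distinct alignment column), adds
#' a single outgroup sequence carrying `Poisson(L * outgroup_divergence)`
#' private substitutions, and returns the alignment plus the generating
#' truth. Deterministic for a given scenario (the seed is part of the
#' scenario).
#'
#' @param scn A [sim_scenario].
#' @param include_outgroup Add the `outgroup_1` sequence (default `TRUE`).
#' @return List with `aln` (a [locus_alignment]) and `truth` (mutation
#'   table, per-branch tip sets, sweep flag, TMRCA).
#' @export
simulate_locus <- function(scn, include_outgroup = TRUE) {
  stopifnot(inherits(scn, "sim_scenario"))
  set.seed(scn$seed)
  simulate_locus_impl(scn, include_outgroup)
}

# Internal: assumes RNG already seeded (used by the panel generator to keep
# one generator threaded through all loci).
simulate_locus_impl <- function(scn, include_outgroup = TRUE,
                                locus_id = "locus1") {
  gen <- coalesce_panel(scn)
  nsamp <- length(gen$labels)
  L <- scn$L
  ancestor <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  n_mut <- vapply(gen$branches, function(b)
    rpois(1L, scn$theta * b$len / 2), integer(1))
  n_og <- if (include_outgroup) rpois(1L, L * scn$outgroup_divergence) else 0L
  total <- sum(n_mut) + n_og
  if (total > L)
    stop("infinite-sites overflow: more mutations (", total,
         ") than columns (", L, "); increase L or lower theta", call. = FALSE)
  sites <- sample.int(L, total)
  mat <- matrix(rep(ancestor, each = nsamp), nrow = nsamp)
  rownames(mat) <- gen$labels
  mut_rows <- list()
  k <- 0L
  for (bi in seq_along(gen$branches)) {
    if (n_mut[bi] == 0L) next
    for (m in seq_len(n_mut[bi])) {
      k <- k + 1L
      site <- sites[k]
      derived <- sample(setdiff(c("A", "C", "G", "T"), ancestor[site]), 1L)
      carriers <- gen$branches[[bi]]$tips
      mat[carriers, site] <- derived
      mut_rows[[k]] <- data.frame(site = site, ancestral = ancestor[site],
                                  derived = derived,
                                  n_carriers = length(carriers))
    }
  }
  pops <- gen$pops
  labels <- gen$labels
  og_sites <- integer(0)
  if (include_outgroup) {
    og <- ancestor
    if (n_og > 0L) {
      og_sites <- sites[sum(n_mut) + seq_len(n_og)]
      og[og_sites] <- vapply(og_sites, function(s)
        sample(setdiff(c("A", "C", "G", "T"), ancestor[s]), 1L), "")
    }
    mat <- rbind(mat, outgroup_1 = og)
    labels <- c(labels, "outgroup_1")
    pops <- c(pops, "outgroup")
  }
  aln <- locus_alignment(mat, samples = labels,
                         populations = setNames(pops, labels),
                         locus_id = locus_id)
  truth <- list(
    mutations = if (k) do.call(rbind, mut_rows)
                else data.frame(site = integer(0), ancestral = character(0),
                                derived = character(0),
                                n_carriers = integer(0)),
    branches = gen$branches, tmrca = gen$tmrca,
    outgroup_sites = og_sites, sweep = scn$sweep || scn$introgression,
    populations = setNames(pops, labels), ancestor = ancestor)
  list(aln = aln, truth = truth)
}

#' Simulate a multi-locus germplasm panel
#'
#' Simulates `n_loci` loci under one scenario: the focal locus carries the
#' scenario's sweep/introgression settings, all other loci evolve neutrally
#' under the same demography (bottleneck and population structure apply
#' genome-wide). A genome-wide [genotype_matrix] is assembled from the
#' biallelic sites of the non-focal loci (ancestral allele coded 0).
#'
#' @param scn A [sim_scenario].
#' @param n_loci Number of loci (>= 2).
#' @param focal_locus_index Which locus carries the sweep (default 1).
#' @return List with `loci` (list of [locus_alignment]), `truths`,
#'   `genotypes` (a [genotype_matrix] over the ingroup samples), `focal`.
#' @export
simulate_germplasm_panel <- function(scn, n_loci = 5L,
                                     focal_locus_index = 1L) {
  stopifnot(inherits(scn, "sim_scenario"), n_loci >= 2L,
            focal_locus_index >= 1L, focal_locus_index <= n_loci)
  set.seed(scn$seed)
  neutral <- scn; neutral$sweep <- FALSE; neutral$introgression <- FALSE
  loci <- vector("list", n_loci); truths <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    use <- if (i == focal_locus_index) scn else neutral
    sim <- simulate_locus_impl(use, include_outgroup = TRUE,
                               locus_id = sprintf("locus%d", i))
    loci[[i]] <- sim$aln; truths[[i]] <- sim$truth
  }
  names(loci) <- names(truths) <- vapply(loci, `[[`, "", "locus_id")
  geno <- panel_genotypes(loci, truths, focal_locus_index)
  list(loci = loci, truths = truths, genotypes = geno,
       focal = names(loci)[focal_locus_index])
}

# 0/1 genotype matrix over ingroup samples from the biallelic (segregating)
# sites of all non-focal loci.
panel_genotypes <- function(loci, truths, focal_locus_index) {
  cols <- list(); ids <- character(0)
  for (i in seq_along(loci)) {
    if (i == focal_locus_index) next
    aln <- loci[[i]]; truth <- truths[[i]]
    ing <- aln$samples[aln$populations != "outgroup"]
    mut <- truth$mutations
    if (!nrow(mut)) next
    seg <- unique(mut$site[mut$n_carriers > 0 &
                           mut$n_carriers < length(ing)])
    for (s in seg) {
      anc <- truth$ancestor[s]
      cols[[length(cols) + 1L]] <- as.integer(aln$seq[ing, s] != anc)
      ids <- c(ids, sprintf("%s_s%d", aln$locus_id, s))
    }
  }
  if (!length(cols)) stop("no segregating non-focal sites for genotypes",
                          call. = FALSE)
  g <- do.call(cbind, cols)
  ing <- loci[[1L]]$samples[loci[[1L]]$populations != "outgroup"]
  rownames(g) <- ing
  genotype_matrix(g, sites = ids)
}

#' Evolve a codon-sequence pair at a controlled Ka/Ks
#'
#' Duplicates a random stop-free coding sequence and applies point
#' substitutions to the two copies: proposals are uniform over sequence
#' positions and alternative bases, synonymous changes are always accepted,
#' nonsynonymous changes are accepted with probability `omega`, and changes
#' creating stop codons are rejected. Substitution stops once the expected
#' synonymous divergence (accepted synonymous changes per synonymous site)
#' reaches `target_pS`.
#'
#' @param n_codons Number of codons.
#' @param omega Nonsynonymous relative acceptance rate (> 0).
#' @param target_pS Target synonymous divergence in (0, 0.7).
#' @param seed Integer seed.
#' @return List with `seq_a`, `seq_b` (character strings) and the realized
#'   substitution counts `syn_subs`, `nonsyn_subs`.
#' @export
evolve_codon_pair <- function(n_codons, omega, target_pS = 0.3, seed = 1L) {
  stopifnot(omega > 0, target_pS > 0, target_pS < 0.7, n_codons >= 2L)
  set.seed(seed)
  codons <- names(genetic_code())[genetic_code() != "*"]
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  anc <- sample(codons, n_codons, replace = TRUE)
  seqs <- list(strsplit(paste0(anc, collapse = ""), "")[[1]],
               strsplit(paste0(anc, collapse = ""), "")[[1]])
  s_sites <- sum(vapply(anc, function(cd) ng86_sites(cd)["syn"], 0))
  target_syn <- target_pS * s_sites
  syn_n <- 0L; nonsyn_n <- 0L
  bases <- c("A", "C", "G", "T")
  while (syn_n < target_syn) {
    w <- sample.int(2L, 1L)
    pos <- sample.int(3L * n_codons, 1L)
    cur <- seqs[[w]]
    nb <- sample(setdiff(bases, cur[pos]), 1L)
    ci <- (pos - 1L) %/% 3L
    old_codon <- paste0(cur[ci * 3L + 1:3], collapse = "")
    newb <- cur; newb[pos] <- nb
    new_codon <- paste0(newb[ci * 3L + 1:3], collapse = "")
    if (is_stop(new_codon)) next
    syn <- translate_codon(old_codon) == translate_codon(new_codon)
    if (syn) {
      seqs[[w]] <- newb; syn_n <- syn_n + 1L
    } else if (runif(1L) < omega) {
      seqs[[w]] <- newb; nonsyn_n <- nonsyn_n + 1L
    }
  }
  list(seq_a = paste0(seqs[[1]], collapse = ""),
       seq_b = paste0(seqs[[2]], collapse = ""),
       syn_subs = syn_n, nonsyn_subs = nonsyn_n)
}
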