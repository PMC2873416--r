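# Enumeration oracle over the codon table: fraction of non-stop point
# mutations per position that preserve the amino acid.
oracle_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  b <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(c("A", "C", "G", "T"), b[pos]), function(nb) {
      b2 <- b; b2[pos] <- nb; paste0(b2, collapse = "")
    }, "")
    aas <- code[muts]
    keep <- aas != "*"
    if (any(keep)) syn <- syn + sum(aas[keep] == code[codon]) / sum(keep)
  }
  c(syn = syn, nonsyn = 3 - syn)
}

test_that("NG86 site fractions match codon-table enumeration", {
  expect_equal(ng86_sites("TTT"), c(syn = 1/3, nonsyn = 8/3),
               tolerance = 1e-12)
  expect_equal(ng86_sites("TTA"), c(syn = 2/3, nonsyn = 7/3),
               tolerance = 1e-12)
  expect_equal(ng86_sites("GGG"), c(syn = 1, nonsyn = 2), tolerance = 1e-12)
  codons <- names(Biostrings::GENETIC_CODE)
  codons <- codons[Biostrings::GENETIC_CODE != "*" &
                   grepl("^[ACGT]{3}$", codons)]
  for (cd in codons)
    expect_equal(ng86_sites(cd), oracle_sites(cd), tolerance = 1e-12)
  # every codon contributes 3 sites total
  expect_true(all(abs(vapply(codons, function(cd) sum(ng86_sites(cd)), 0) - 3)
                  < 1e-12))
  expect_error(ng86_sites("TGA"), "stop codon")
  expect_error(ng86_sites("TNA"), "invalid|ambiguous")
})

# Exhaustive pathway oracle for difference counting.
oracle_diffs <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  ba <- strsplit(a, "")[[1]]; bb <- strsplit(b, "")[[1]]
  dp <- which(ba != bb)
  if (!length(dp)) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(dp) == 1) list(dp) else
    if (length(dp) == 2) list(dp, rev(dp)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                  c(3,2,1)), function(o) dp[o])
  paths <- list()
  for (p in perms) {
    cur <- ba; s <- 0; n <- 0; ok <- TRUE
    for (pos in p) {
      nxt <- cur; nxt[pos] <- bb[pos]
      if (code[paste0(nxt, collapse = "")] == "*") { ok <- FALSE; break }
      if (code[paste0(cur, collapse = "")] ==
          code[paste0(nxt, collapse = "")]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) paths[[length(paths) + 1]] <- c(syn = s, nonsyn = n)
  }
  Reduce(`+`, paths) / length(paths)
}

test_that("NG86 difference counting averages over stop-free pathways", {
  expect_equal(ng86_differences("ACG", "ACG"), c(syn = 0, nonsyn = 0))
  expect_equal(ng86_differences("TTT", "TTA"), c(syn = 0, nonsyn = 1))
  expect_equal(ng86_differences("TTT", "GTA"), oracle_diffs("TTT", "GTA"),
               tolerance = 1e-12)
  set.seed(42)
  codons <- names(Biostrings::GENETIC_CODE)
  codons <- codons[Biostrings::GENETIC_CODE != "*" &
                   grepl("^[ACGT]{3}$", codons)]
  for (i in 1:40) {
    a <- sample(codons, 1); b <- sample(codons, 1)
    got <- suppressWarnings(ng86_differences(a, b))
    want <- oracle_diffs(a, b)
    if (!is.null(want)) expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pairwise Ka/Ks reproduces hand NG86+JC evaluation and symmetry", {
  same <- kaks_pair("ATGGCT", "ATGGCT")
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$ratio))

  kp <- kaks_pair("TTT", "TTA")
  expect_equal(kp$Nd, 1)
  expect_equal(kp$Sd, 0)
  expect_equal(kp$N_sites, 2.5)
  expect_equal(kp$S_sites, 0.5)
  expect_equal(kp$Ka, -0.75 * log(1 - 4 * 0.4 / 3), tolerance = 1e-9)
  expect_equal(kp$Ka, 0.571605, tolerance = 1e-6)
  expect_equal(kp$Ks, 0)

  # symmetry in all numeric fields
  p <- evolve_codon_pair(60, omega = 0.5, target_pS = 0.2, seed = 8)
  ab <- kaks_pair(p$seq_a, p$seq_b)
  ba <- kaks_pair(p$seq_b, p$seq_a)
  for (f in c("N_sites", "S_sites", "Nd", "Sd", "Ka", "Ks", "fisher_p"))
    expect_equal(ab[[f]], ba[[f]], tolerance = 1e-12)

  # sites conservation: N + S = 3 * codons analyzed
  expect_equal(ab$N_sites + ab$S_sites, 3 * ab$codons_used,
               tolerance = 1e-9)

  # gap/N codons dropped pairwise
  kg <- kaks_pair("TTTA-G", "TTAACG")
  expect_equal(kg$codons_used, 1L)
  expect_error(kaks_pair("TTTA", "TTTA"), "frame error")
  expect_error(kaks_pair("TTT", "TTTTTT"), "frame error")
})

test_that("published-scale ratio arithmetic and clock dating behave", {
  # ratio of Ka to Ks as reported per locus pair
  expect_lt(abs(0.120098 / 0.436208 - 0.275322), 1e-6)
  expect_lt(abs(0.124126 / 0.738313 - 0.168121), 1e-6)

  ct <- duplication_time(0.57, 6.5e-9)
  expect_equal(ct$T_years, 0.57 / (2 * 6.5e-9), tolerance = 1e-12)
  expect_equal(round(ct$T_mya), 44)
  expect_equal(duplication_time(0, 1e-8)$T_years, 0)
  # doubling the rate halves the estimate
  expect_equal(duplication_time(0.57, 1.3e-8)$T_years, ct$T_years / 2,
               tolerance = 1e-12)
  expect_error(duplication_time(0.5, 0), "config error")
})

test_that("mean Ks over pairs averages and excludes saturated pairs", {
  mk <- function(ks) structure(list(Ks = ks), class = "codon_pair")
  expect_equal(mean_ks_over_pairs(list(mk(0.5))), 0.5)
  expect_equal(mean_ks_over_pairs(list(mk(0.5), mk(0.6), mk(0.61))), 0.57)
  expect_warning(m <- mean_ks_over_pairs(list(mk(0.5), mk(NA_real_))),
                 "saturated")
  expect_equal(m, 0.5)
  expect_error(suppressWarnings(mean_ks_over_pairs(list(mk(NA_real_)))),
               "estimation error")
})
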