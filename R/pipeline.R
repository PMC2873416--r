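#' Configuration for a full domestication scan
#'
#' @param loci Named list of [locus_alignment] objects, or named character
#'   vector of FASTA paths (then `popmap` must be supplied).
#' @param popmap Named character vector (sample -> population) or popmap TSV
#'   path; only needed when `loci` are file paths.
#' @param candidate Locus id of the candidate (focal) locus.
#' @param reference Locus id of the neutral reference locus for the HKA
#'   test (optional).
#' @param cultivated Population labels treated as cultivated (default
#'   `c("japonica", "indica")`).
#' @param wild Population label of the wild sample (default `"wild"`).
#' @param window,step Sliding-window size and step in bp (default 500/100).
#' @param coding_pair Optional named list/vector with elements `a` and `b`:
#'   in-frame paralogous coding sequences for the Ka/Ks + dating stage.
#' @param fixed_diff_threshold "Almost fixed" frequency threshold
#'   (default 0.95).
#' @param clock_rate Neutral substitution rate per silent site per year
#'   (default 6.5e-9).
#' @param genotypes Optional [genotype_matrix] for the genome tree.
#' @param tree_model Distance model for gene trees (default `"jc"`).
#' @param seed Integer seed.
#' @return Object of class `scan_config`.
#' @export
scan_config <- function(loci, popmap = NULL, candidate, reference = NULL,
                        cultivated = c("japonica", "indica"), wild = "wild",
                        window = 500L, step = 100L, coding_pair = NULL,
                        fixed_diff_threshold = 0.95, clock_rate = 6.5e-9,
                        genotypes = NULL, tree_model = "jc", seed = 1L) {
  if (is.character(loci)) {
    if (is.null(popmap)) stop("popmap required with FASTA paths", call. = FALSE)
    if (is.character(popmap) && length(popmap) == 1L &&
        is.null(names(popmap))) popmap <- read_popmap(popmap)
    missing_files <- loci[!file.exists(loci)]
    if (length(missing_files))
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "),
           call. = FALSE)
    nm <- if (!is.null(names(loci))) names(loci) else
      sub("\\.[^.]*$", "", basename(loci))
    loci <- lapply(seq_along(loci), function(i)
      read_fasta_alignment(loci[[i]], popmap, locus_id = nm[i]))
    names(loci) <- nm
  }
  stopifnot(all(vapply(loci, inherits, TRUE, "locus_alignment")))
  if (is.null(names(loci)))
    names(loci) <- vapply(loci, `[[`, "", "locus_id")
  if (!candidate %in% names(loci))
    stop("candidate locus '", candidate, "' not among loci", call. = FALSE)
  if (!is.null(reference) && !reference %in% names(loci))
    stop("reference locus '", reference, "' not among loci", call. = FALSE)
  structure(list(loci = loci, candidate = candidate, reference = reference,
                 cultivated = cultivated, wild = wild, window = window,
                 step = step, coding_pair = coding_pair,
                 fixed_diff_threshold = fixed_diff_threshold,
                 clock_rate = clock_rate, genotypes = genotypes,
                 tree_model = tree_model, seed = as.integer(seed)),
            class = "scan_config")
}

stage_try <- function(report, name, expr) {
  res <- tryCatch(list(status = "ok", value = expr),
                  error = function(e) list(status = "error",
                                           message = conditionMessage(e)))
  report$stages[[name]] <- res[setdiff(names(res), "value")]
  if (res$status == "ok") report[[name]] <- res$value
  report
}

#' Run the full domestication-selection scan
#'
#' Executes, in order: per-locus per-population diversity statistics;
#' sliding-window pi and Tajima's D tracks on the candidate locus; the HKA
#' test of the candidate against the reference locus (both methods);
#' Nei-Gojobori Ka/Ks with molecular-clock dating for the configured
#' paralog pair; haplotype typing per locus; the near-fixed difference scan
#' (cultivated vs wild) on the candidate; neighbor-joining gene trees per
#' locus, the genome tree from the SNP genotype matrix, their
#' Robinson-Foulds distance and the cultivar-monophyly verdict on each.
#' A failing stage is recorded and the remaining stages still run.
#' Deterministic under the configured seed.
#'
#' @param cfg A [scan_config].
#' @return Object of class `scan_report`.
#' @export
run_scan <- function(cfg) {
  stopifnot(inherits(cfg, "scan_config"))
  set.seed(cfg$seed)
  report <- structure(list(stages = list(), config = scan_provenance(cfg)),
                      class = "scan_report")
  pops_of <- function(aln) intersect(c(cfg$cultivated, cfg$wild),
                                     unique(aln$populations))

  report <- stage_try(report, "stats", {
    rows <- list()
    for (aln in cfg$loci) for (p in pops_of(aln))
      rows[[length(rows) + 1L]] <- locus_stats(aln, p)
    do.call(rbind, lapply(rows, as.data.frame))
  })

  report <- stage_try(report, "windows", {
    aln <- cfg$loci[[cfg$candidate]]
    w <- min(cfg$window, ncol(aln$seq))
    tracks <- list()
    for (p in pops_of(aln)) for (st in c("pi", "tajima_d"))
      tracks[[length(tracks) + 1L]] <-
        sliding_windows(aln, p, window = w, step = cfg$step, stat = st)
    do.call(rbind, tracks)
  })

  if (!is.null(cfg$reference))
    report <- stage_try(report, "hka", {
      cand <- polymorphism_divergence_counts(cfg$loci[[cfg$candidate]],
                                             ingroup = cfg$cultivated)
      ref <- polymorphism_divergence_counts(cfg$loci[[cfg$reference]],
                                            ingroup = cfg$cultivated)
      hka_test(cand, ref, method = "both")
    })

  if (!is.null(cfg$coding_pair))
    report <- stage_try(report, "kaks", {
      cp <- kaks_pair(cfg$coding_pair[["a"]], cfg$coding_pair[["b"]])
      list(pair = cp,
           clock = if (!is.na(cp$Ks)) duplication_time(cp$Ks, cfg$clock_rate))
    })

  report <- stage_try(report, "haplotypes", {
    lapply(cfg$loci, haplotype_classify)
  })

  report <- stage_try(report, "fixed_diffs", {
    fixed_differences(cfg$loci[[cfg$candidate]], cfg$cultivated, cfg$wild,
                      cfg$fixed_diff_threshold)
  })

  report <- stage_try(report, "trees", {
    trees <- lapply(cfg$loci, function(aln) {
      ing <- aln$samples[aln$populations != "outgroup"]
      sub <- locus_alignment(aln$seq[ing, , drop = FALSE], samples = ing,
                             populations = aln$populations[ing],
                             locus_id = aln$locus_id)
      neighbor_joining(distance_matrix(sub, cfg$tree_model))
    })
    out <- list(gene_trees = trees)
    cultivars <- unlist(lapply(cfg$loci[[cfg$candidate]]$samples, function(s)
      if (cfg$loci[[cfg$candidate]]$populations[[s]] %in% cfg$cultivated) s))
    out$cultivar_monophyly_gene <- monophyly_check(trees[[cfg$candidate]],
                                                   cultivars)
    if (!is.null(cfg$genotypes)) {
      gt <- neighbor_joining(distance_matrix(cfg$genotypes,
                                             "allele_sharing"))
      out$genome_tree <- gt
      shared <- intersect(gt$tip.label, trees[[cfg$candidate]]$tip.label)
      gpr <- ape::keep.tip(gt, shared)
      gnr <- ape::keep.tip(trees[[cfg$candidate]], shared)
      out$rf_gene_vs_genome <- robinson_foulds(gpr, gnr)
      out$cultivar_monophyly_genome <-
        monophyly_check(gt, intersect(cultivars, gt$tip.label))
    }
    out
  })
  report
}

scan_provenance <- function(cfg) {
  desc <- list(
    loci = names(cfg$loci),
    n_samples = vapply(cfg$loci, function(a) nrow(a$seq), 0L),
    candidate = cfg$candidate, reference = cfg$reference,
    cultivated = cfg$cultivated, wild = cfg$wild,
    window = cfg$window, step = cfg$step,
    fixed_diff_threshold = cfg$fixed_diff_threshold,
    clock_rate = cfg$clock_rate, tree_model = cfg$tree_model,
    seed = cfg$seed)
  tf <- tempfile()
  writeLines(jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA), tf)
  desc$config_digest <- unname(tools::md5sum(tf))
  unlink(tf)
  desc$package_version <- as.character(utils::packageVersion("domestiscan"))
  desc
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report> candidate:", x$config$candidate, "\n")
  for (nm in names(x$stages))
    cat(sprintf("  stage %-12s %s\n", nm, x$stages[[nm]]$status))
  if (!is.null(x$hka) && !is.null(x$hka$hka1987))
    cat(sprintf("  HKA p = %.4g (moment) / %.4g (contingency)\n",
                x$hka$hka1987$p_value, x$hka$contingency$p_value))
  if (!is.null(x$kaks) && !is.null(x$kaks$clock))
    cat(sprintf("  Ka/Ks = %s; duplication ~ %.1f MYA\n",
                fmt_or_na(x$kaks$pair$ratio), x$kaks$clock$T_mya))
  invisible(x)
}

#' @export
summary.scan_report <- function(object, ...) object$stats

#' Write a scan report to disk
#'
#' Emits `report.json` (summary numbers + provenance), `stats.tsv` (the
#' per-locus per-population statistics table), `windows.tsv` (sliding-window
#' tracks) and `trees/<locus>.nwk` newick files. The JSON is deterministic
#' for a given configuration and seed.
#'
#' @param report A `scan_report`.
#' @param dir Output directory (created if needed).
#' @export
write_scan_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$stats))
    write_tsv_report(report$stats, file.path(dir, "stats.tsv"))
  if (!is.null(report$windows))
    write.table(report$windows, file.path(dir, "windows.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$trees)) {
    dir.create(file.path(dir, "trees"), showWarnings = FALSE)
    for (nm in names(report$trees$gene_trees))
      ape::write.tree(report$trees$gene_trees[[nm]],
                      file.path(dir, "trees", paste0(nm, ".nwk")))
    if (!is.null(report$trees$genome_tree))
      ape::write.tree(report$trees$genome_tree,
                      file.path(dir, "trees", "genome.nwk"))
  }
  js <- list(provenance = report$config,
             stages = lapply(report$stages, `[[`, "status"))
  if (!is.null(report$hka))
    js$hka <- list(
      moment = report$hka$hka1987[c("statistic", "df", "p_value", "T_hat")],
      contingency = report$hka$contingency[c("statistic", "p_value",
                                             "fisher_p")])
  if (!is.null(report$kaks)) {
    js$kaks <- report$kaks$pair[c("N_sites", "S_sites", "Nd", "Sd", "Ka",
                                  "Ks", "ratio", "fisher_p")]
    if (!is.null(report$kaks$clock))
      js$duplication_time_mya <- report$kaks$clock$T_mya
  }
  if (!is.null(report$haplotypes))
    js$haplotype_counts <- lapply(report$haplotypes, `[[`, "hap_count")
  if (!is.null(report$fixed_diffs))
    js$n_fixed_differences <- nrow(report$fixed_diffs)
  if (!is.null(report$trees)) {
    js$cultivar_monophyly_gene <- report$trees$cultivar_monophyly_gene
    if (!is.null(report$trees$genome_tree)) {
      js$cultivar_monophyly_genome <- report$trees$cultivar_monophyly_genome
      js$rf_gene_vs_genome <- report$trees$rf_gene_vs_genome
    }
  }
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
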