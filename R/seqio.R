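#' @importFrom stats pchisq chisq.test fisher.test rexp rpois runif setNames
#'   ks.test wilcox.test
#' @importFrom utils read.delim write.table head tail
NULL

MISSING_CHARS <- c("-", "N")

#' Construct a locus alignment
#'
#' The shared in-memory container for one aligned locus: an `n x L` character
#' matrix of upper-case bases over `{A,C,G,T,-,N}`, one row per sample, plus a
#' population label for every sample. All downstream statistics (diversity,
#' neutrality, trees) consume this object.
#'
#' @param seqs Character vector of equal-length sequences (one per sample), or
#'   a character matrix of single bases with one row per sample.
#' @param samples Sample identifiers (unique, same length as `seqs`).
#' @param populations Named character vector mapping sample id to population
#'   label (e.g. `japonica`, `indica`, `wild`, `outgroup`), or an unnamed
#'   vector parallel to `samples`.
#' @param locus_id Identifier for the locus.
#' @param coordinate_offset 1-based chromosomal position of alignment column 1;
#'   all reported site coordinates are 1-based inclusive on this scale.
#' @return An object of class `locus_alignment` with elements `locus_id`,
#'   `seq` (character matrix, rownames = samples), `samples`, `populations`
#'   and `coordinate_offset`.
#' @examples
#' aln <- locus_alignment(c(s1 = "ACGT", s2 = "ACTT"),
#'                        populations = c(s1 = "wild", s2 = "wild"))
#' aln$seq
#' @export
locus_alignment <- function(seqs, samples = NULL, populations,
                            locus_id = "locus", coordinate_offset = 1L) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(samples)) samples <- rownames(mat)
  } else {
    if (is.null(samples)) samples <- names(seqs)
    if (is.null(samples)) stop("sample ids required", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment-error: sequences differ in length", call. = FALSE)
    mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  }
  if (is.null(samples) || anyDuplicated(samples))
    stop("sample ids must be present and unique", call. = FALSE)
  if (ncol(mat) < 1L) stop("alignment-error: zero-length alignment", call. = FALSE)
  mat <- toupper(mat)
  mat[!(mat %in% c("A", "C", "G", "T", "-"))] <- "N"
  rownames(mat) <- samples
  if (is.null(names(populations))) {
    if (length(populations) != length(samples))
      stop("popmap-error: populations must be named or parallel to samples",
           call. = FALSE)
    populations <- setNames(as.character(populations), samples)
  }
  missing_pop <- setdiff(samples, names(populations))
  if (length(missing_pop))
    stop("popmap-error: no population label for ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  structure(
    list(locus_id = locus_id, seq = mat, samples = samples,
         populations = setNames(as.character(populations[samples]), samples),
         coordinate_offset = as.integer(coordinate_offset)),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d samples x %d columns\n",
              x$locus_id, nrow(x$seq), ncol(x$seq)))
  tab <- table(x$populations)
  cat("populations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.locus_alignment <- function(object, ...) {
  pops <- setdiff(unique(object$populations), "outgroup")
  do.call(rbind, lapply(pops, function(p)
    as.data.frame(locus_stats(object, p))))
}

#' Read a two-column population map
#'
#' @param path TSV file with columns `sample_id` and `population` (header
#'   optional; detected from the first line).
#' @return Named character vector mapping sample id to population label.
#' @export
read_popmap <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("popmap-error: expected two columns", call. = FALSE)
  if (tolower(df[1, 1]) %in% c("sample", "sample_id")) df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df[[1]]))
    stop("popmap-error: duplicated sample ids", call. = FALSE)
  pm <- setNames(df[[2]], df[[1]])
  if (!length(setdiff(unique(pm), "outgroup")))
    stop("popmap-error: at least one non-outgroup population required",
         call. = FALSE)
  pm
}

#' Write a population map
#' @param popmap Named character vector (sample id -> population).
#' @param path Output TSV path.
#' @export
write_popmap <- function(popmap, path) {
  write.table(data.frame(sample_id = names(popmap), population = popmap),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a FASTA alignment with population labels
#'
#' Parses a pre-aligned multi-FASTA file into a [locus_alignment]. Bases are
#' upper-cased; any character outside `{A,C,G,T,-}` becomes `N`.
#'
#' @param path FASTA file; all records must have equal aligned length.
#' @param popmap Named character vector (see [read_popmap]) or path to a
#'   popmap TSV. Every record id must be present.
#' @param locus_id Locus identifier; defaults to the file name without
#'   extension.
#' @param coordinate_offset See [locus_alignment].
#' @return A [locus_alignment].
#' @export
read_fasta_alignment <- function(path, popmap,
                                 locus_id = sub("\\.[^.]*$", "", basename(path)),
                                 coordinate_offset = 1L) {
  if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap) &&
      is.null(names(popmap)))
    popmap <- read_popmap(popmap)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- setNames(as.character(ss), ids)
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment-error: records differ in length in ", path, call. = FALSE)
  unmapped <- setdiff(ids, names(popmap))
  if (length(unmapped))
    stop("popmap-error: unmapped sample id(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  locus_alignment(seqs, populations = popmap[ids], locus_id = locus_id,
                  coordinate_offset = coordinate_offset)
}

#' Write a locus alignment to FASTA
#' @param aln A [locus_alignment].
#' @param path Output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$seq, 1L, paste0, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- aln$samples
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

# Fixed column order of the per-population statistics report.
STATS_COLUMNS <- c("locus_id", "population", "n", "L_eff", "S", "pi",
                   "theta_w", "tajima_d", "hap_count", "hap_div")

#' Write a TSV report of per-population locus statistics
#'
#' One row per locus (or window) and population; columns are fixed
#' (`locus_id, population, n, L_eff, S, pi, theta_w, tajima_d, hap_count,
#' hap_div`) and floats are written at 6 decimals. An undefined Tajima's D
#' (no segregating sites) is written as `NA`.
#'
#' @param stats A list of `locus_stats` objects or a data frame with the
#'   report columns.
#' @param path Output TSV path.
#' @export
write_tsv_report <- function(stats, path) {
  if (is.data.frame(stats)) df <- stats
  else df <- do.call(rbind, lapply(stats, as.data.frame))
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(STATS_COLUMNS)),
                                 STATS_COLUMNS))
  }
  df <- df[, STATS_COLUMNS, drop = FALSE]
  for (col in c("pi", "theta_w", "tajima_d", "hap_div"))
    df[[col]] <- ifelse(is.na(df[[col]]), NA, sprintf("%.6f", df[[col]]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV statistics report
#' @param path TSV written by [write_tsv_report].
#' @return Data frame with the fixed report columns.
#' @export
read_tsv_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' Biallelic genotypes coded 0 (ancestral/reference) / 1 (derived/alternate),
#' `NA` for missing, one row per sample. Used for the genome-wide SNP tree.
#'
#' @param mat Integer/numeric matrix of 0/1/NA, rownames = sample ids.
#' @param sites Optional site identifiers (default column names or s1..sK).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(mat, sites = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("sample ids required as rownames", call. = FALSE)
  if (!all(mat %in% c(0, 1, NA)))
    stop("genotypes must be 0, 1 or NA", call. = FALSE)
  if (any(rowSums(!is.na(mat)) == 0L))
    stop("all-missing sample in genotype matrix", call. = FALSE)
  if (is.null(sites)) sites <- colnames(mat)
  if (is.null(sites)) sites <- paste0("s", seq_len(ncol(mat)))
  colnames(mat) <- sites
  structure(list(geno = mat, samples = rownames(mat), sites = sites),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d biallelic sites\n",
              nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

#' Read a genotype matrix from TSV
#' @param path TSV with sample ids in the first column, one column per site.
#' @export
read_genotype_matrix <- function(path) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  genotype_matrix(as.matrix(df))
}

#' Write a genotype matrix to TSV
#' @param gm A [genotype_matrix].
#' @param path Output path.
#' @export
write_genotype_matrix <- function(gm, path) {
  df <- data.frame(sample_id = gm$samples, gm$geno, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
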