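BASES <- c("A", "C", "G", "U")

#' Align a product read to a reference template
#'
#' Semi-global alignment suited to 5'-anchored, possibly partial-length
#' polymerization products: the read is aligned globally from its 5' end,
#' while gaps over the uncovered 3' tail of the reference are free, so
#' truncation is distinguished from internal deletion. Scoring is match +1,
#' mismatch -1, gap -2 (linear); ties prefer mismatch over indel and a
#' deterministic gap placement.
#'
#' @param read,ref `rna_seq` or character.
#' @param read_id Identifier recorded on the result.
#' @return An `aligned_read`: list with `score`, per-reference-position
#'   `status` (0 uncovered, 1 match, 2 mismatch, 3 deletion), `mism_base`
#'   (read base at mismatches), `ins_count`/`ins_bases` per junction (entry
#'   j+1 holds bases inserted after reference position j; entry 1 precedes
#'   position 1), `span` (first, last covered positions) and `read_length`.
#' @export
align_to_reference <- function(read, ref, read_id = NULL) {
  r <- as_residues(read)
  f <- as_residues(ref)
  a <- align_semiglobal_cpp(r, f)
  a$mism_base <- ifelse(a$mism_base > 0L, BASES[pmax(a$mism_base, 1L)], "")
  a$read_id <- if (!is.null(read_id)) read_id else
    if (inherits(read, "rna_seq")) read$id else "read"
  structure(a, class = "aligned_read")
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("<aligned_read> %s: score %d, span %d-%d, %d nt read\n",
              x$read_id, x$score, x$span[1], x$span[2], x$read_length))
  invisible(x)
}

#' Tally per-position alignment outcomes into a fidelity table
#'
#' Counts matches, mismatches (keyed by incorporated base), deletions,
#' per-junction insertions, coverage and the read-length histogram across a
#' set of reads aligned to one reference. Uncovered positions of truncated
#' reads do not contribute to coverage. At every position,
#' matches + mismatches + deletions = coverage.
#'
#' @param reads `read_set`, character vector of reads, or list of `rna_seq`.
#' @param ref Reference `rna_seq` or character.
#' @param condition Free-text metadata (e.g. `"200 mM Mg2+"`).
#' @param full_length_only If TRUE, only reads whose aligned span covers the
#'   final reference position are tallied (used for the ligase analyses).
#' @return A `fidelity_table`.
#' @export
tally_fidelity <- function(reads, ref, condition = "", full_length_only = FALSE) {
  seqs <- reads_as_character(reads)
  f <- as_residues(ref)
  m <- nchar(f)
  agg <- align_tally_cpp(seqs, f)
  keep <- rep(TRUE, length(seqs))
  if (full_length_only) {
    keep <- agg$end_ref == m
    agg <- align_tally_cpp(seqs[keep], f)
  }
  ref_bases <- strsplit(f, "", fixed = TRUE)[[1]]
  mm <- t(agg$mismatch_by_base)
  colnames(mm) <- BASES
  tab <- list(
    reference_id = if (inherits(ref, "rna_seq")) ref$id else "ref",
    ref_bases = ref_bases,
    coverage = agg$coverage,
    matches = agg$matches,
    mismatches = mm,
    deletions = agg$deletions,
    insertions = agg$insertions,   # length m+1; [j+1] = after position j
    read_lengths = tabulate(agg$read_length + 1L)[-1L],
    n_reads = sum(keep),
    condition = condition)
  stopifnot(all(tab$matches + rowSums(tab$mismatches) + tab$deletions ==
                  tab$coverage))
  structure(tab, class = "fidelity_table")
}

reads_as_character <- function(reads) {
  if (inherits(reads, "read_set")) return(reads$seqs)
  if (is.character(reads)) return(chartr("T", "U", toupper(reads)))
  vapply(reads, as_residues, character(1))
}

#' @export
print.fidelity_table <- function(x, ...) {
  cat(sprintf("<fidelity_table> %s (%s): %d reads, %d positions\n",
              x$reference_id, x$condition, x$n_reads, length(x$coverage)))
  cat(sprintf("  average fidelity %.4f\n", average_fidelity(x)))
  invisible(x)
}

#' Average per-nucleotide fidelity
#'
#' Coverage-weighted fidelity: total matches divided by total covered
#' positions (matches + mismatches + deletions). Insertions live on
#' junctions and are excluded from the positional denominator; they are
#' reported separately by [mutation_spectrum()] as a per-covered-position
#' rate. `mode = "with_insertions"` folds inserted bases into the error
#' numerator for sensitivity analysis; `per_position_mean = TRUE` returns
#' the unweighted mean of per-position fidelities instead.
#'
#' @param table A `fidelity_table`.
#' @param mode `"positional"` (default) or `"with_insertions"`.
#' @param per_position_mean Use the unweighted per-position mean.
#' @return Fraction in \[0, 1\].
#' @export
average_fidelity <- function(table, mode = c("positional", "with_insertions"),
                             per_position_mean = FALSE) {
  mode <- match.arg(mode)
  cov <- table$coverage
  if (sum(cov) == 0) stop("fidelity table has zero coverage")
  if (per_position_mean) {
    ok <- cov > 0
    return(mean(table$matches[ok] / cov[ok]))
  }
  if (mode == "positional") return(sum(table$matches) / sum(cov))
  sum(table$matches) / (sum(cov) + sum(table$insertions))
}

#' Mutation spectrum from a fidelity table
#'
#' Per template-base mismatch rates (12 off-diagonal cells: count divided by
#' total coverage of positions with that template base), overall deletion
#' and insertion rates, and the wobble fraction: the share of all mismatches
#' that are template-U read as G or template-G read as U, the signature of
#' G*U wobble pairing during synthesis.
#'
#' @param table A `fidelity_table`.
#' @return List with `rates` (4x4 matrix, template base x incorporated
#'   base), `deletion_rate`, `insertion_rate` (insertions per covered
#'   position), `wobble_fraction`.
#' @export
mutation_spectrum <- function(table) {
  if (all(table$coverage == 0)) stop("fidelity table has zero coverage")
  rates <- matrix(0, 4, 4, dimnames = list(template = BASES, read = BASES))
  counts <- matrix(0, 4, 4, dimnames = list(template = BASES, read = BASES))
  for (b in BASES) {
    idx <- table$ref_bases == b
    covb <- sum(table$coverage[idx])
    cnt <- colSums(table$mismatches[idx, , drop = FALSE])
    counts[b, ] <- cnt
    if (covb > 0) rates[b, ] <- cnt / covb
  }
  total_mm <- sum(counts)
  wobble <- if (total_mm > 0) (counts["U", "G"] + counts["G", "U"]) / total_mm
            else NA_real_
  list(rates = rates,
       deletion_rate = sum(table$deletions) / sum(table$coverage),
       insertion_rate = sum(table$insertions) / sum(table$coverage),
       wobble_fraction = wobble)
}

#' Levenshtein distance
#'
#' Unit-cost edit distance between two sequences.
#' @param a,b `rna_seq` or character (a may be a vector).
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  av <- if (is.character(a)) a else reads_as_character(a)
  as.integer(levenshtein_cpp(av, as_residues(b)))
}

#' Distribution of Levenshtein distances from a reference
#'
#' @param reads `read_set`, character vector, or list of `rna_seq`.
#' @param ref Reference sequence.
#' @return A `distance_histogram`: list with `counts` (named by distance),
#'   `n_reads` and `mean_distance`.
#' @export
levenshtein_distribution <- function(reads, ref) {
  seqs <- reads_as_character(reads)
  if (length(seqs) == 0L) stop("no reads")
  d <- levenshtein(seqs, ref)
  counts <- table(factor(d, levels = 0:max(d)))
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 n_reads = length(d), mean_distance = mean(d)),
            class = "distance_histogram")
}

#' Per-position error rates from a fidelity table
#'
#' Error rate per covered position, (mismatches + deletions) / coverage;
#' used for parameter-recovery checks against simulators with known truth.
#'
#' @param table A `fidelity_table`.
#' @return Numeric vector, one rate per reference position (NA where
#'   coverage is zero).
#' @export
per_position_error <- function(table) {
  cov <- table$coverage
  err <- rowSums(table$mismatches) + table$deletions
  ifelse(cov > 0, err / cov, NA_real_)
}

#' Write a fidelity table as TSV
#'
#' One row per reference position (pos, ref_base, coverage, match, mismatch
#' counts by base, del), followed by junction insertion rows (`pos` of the
#' form `j/j+1`, holding the anchor convention: inserted bases follow
#' reference position j).
#'
#' @param table A `fidelity_table`.
#' @param path Output path.
#' @export
write_fidelity_table <- function(table, path) {
  m <- length(table$coverage)
  df <- data.frame(pos = seq_len(m), ref_base = table$ref_bases,
                   coverage = table$coverage, match = table$matches,
                   mm_A = table$mismatches[, "A"], mm_C = table$mismatches[, "C"],
                   mm_G = table$mismatches[, "G"], mm_U = table$mismatches[, "U"],
                   del = table$deletions)
  ins <- data.frame(pos = paste0(0:m, "/", 1:(m + 1L)), ref_base = "-",
                    coverage = NA, match = NA, mm_A = NA, mm_C = NA,
                    mm_G = NA, mm_U = NA, del = NA)
  ins$insertions <- table$insertions
  df$insertions <- 0L
  utils::write.table(rbind(df, ins), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
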