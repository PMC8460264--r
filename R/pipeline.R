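#' End-to-end fidelity analysis
#'
#' Wires the fidelity pipeline: (optional) read input from FASTQ/FASTA,
#' align to the reference, tally per-position outcomes, and summarize
#' average fidelity, mutation spectrum and the Levenshtein-distance
#' distribution. With `out` set, writes the fidelity table, distance
#' histogram and a summary JSON plus a run manifest (file checksums, the
#' configuration and the seed) for reproducibility audits.
#'
#' @param reads A `read_set`, character vector, or path to a FASTQ/FASTA
#'   file.
#' @param ref Reference `rna_seq`, character, or FASTA path (first record).
#' @param condition Condition metadata string.
#' @param full_length_only Restrict the tally to reads spanning the final
#'   reference position.
#' @param mode Fidelity mode, see [average_fidelity()].
#' @param out Optional output prefix; files `<out>_fidelity.tsv`,
#'   `<out>_distances.tsv`, `<out>_summary.json`, `<out>_manifest.json`.
#' @param seed Seed recorded in the manifest.
#' @return List with `table`, `average_fidelity`, `spectrum`, `distances`.
#' @export
run_fidelity <- function(reads, ref, condition = "",
                         full_length_only = FALSE,
                         mode = c("positional", "with_insertions"),
                         out = NULL, seed = NA_integer_) {
  mode <- match.arg(mode)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- if (grepl("\\.(fq|fastq)$", reads)) read_fastq(reads) else
      read_set(vapply(read_fasta(reads), `[[`, character(1), "residues"))
  }
  if (is.character(ref) && length(ref) == 1L && file.exists(ref))
    ref <- read_fasta(ref)[[1]]
  tab <- tally_fidelity(reads, ref, condition = condition,
                        full_length_only = full_length_only)
  fid <- average_fidelity(tab, mode = mode)
  spec <- mutation_spectrum(tab)
  dist <- levenshtein_distribution(reads, ref)
  message(sprintf("fidelity run: %d reads tallied, average fidelity %.4f",
                  tab$n_reads, fid))
  res <- list(table = tab, average_fidelity = fid, spectrum = spec,
              distances = dist)
  if (!is.null(out)) {
    files <- c(fidelity = paste0(out, "_fidelity.tsv"),
               distances = paste0(out, "_distances.tsv"),
               summary = paste0(out, "_summary.json"))
    write_fidelity_table(tab, files["fidelity"])
    utils::write.table(
      data.frame(distance = names(dist$counts), count = dist$counts),
      files["distances"], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(average_fidelity = fid,
           wobble_fraction = spec$wobble_fraction,
           deletion_rate = spec$deletion_rate,
           insertion_rate = spec$insertion_rate,
           mean_distance = dist$mean_distance,
           n_reads = tab$n_reads, condition = condition),
      files["summary"], auto_unbox = TRUE, digits = NA)
    write_manifest(files, paste0(out, "_manifest.json"),
                   config = list(condition = condition,
                                 full_length_only = full_length_only,
                                 mode = mode), seed = seed)
  }
  res
}

#' End-to-end population tracking analysis
#'
#' Quality-filters each round sample, runs [track_clusters()] over the
#' tracked region, and (with `out` set) writes the frequency matrix,
#' cluster table and manifest. Filtering counts per round are logged.
#'
#' @param samples List of `round_sample` (or a manifest data frame with
#'   columns `round`, `file` pointing at per-round FASTQ files).
#' @param ref Reference sequence or FASTA path.
#' @param region `region_spec` or region string like `"9-17,83-95"`.
#' @param min_len,min_phred Quality-filter thresholds.
#' @param rep_threshold,singleton_threshold Retention thresholds.
#' @param out Optional output prefix.
#' @param seed Seed recorded in the manifest.
#' @return The `frequency_matrix`.
#' @export
run_tracking <- function(samples, ref, region, min_len = 150, min_phred = 33,
                         rep_threshold = 0.01, singleton_threshold = 0.05,
                         out = NULL, seed = NA_integer_) {
  if (is.data.frame(samples)) {
    samples <- lapply(seq_len(nrow(samples)), function(i)
      round_sample(samples$round[i], read_fastq(samples$file[i])))
  }
  if (is.character(ref) && length(ref) == 1L && file.exists(ref))
    ref <- read_fasta(ref)[[1]]
  if (is.character(region)) region <- region_spec(region)
  filtered <- lapply(samples, function(s) {
    f <- quality_filter(s, min_len = min_len, min_phred = min_phred)
    message(sprintf("round %d: %d/%d reads pass filters",
                    s$round, f$n_kept, s$n_kept))
    f
  })
  fm <- track_clusters(filtered, ref, region,
                       rep_threshold = rep_threshold,
                       singleton_threshold = singleton_threshold)
  message(sprintf("%d clusters retained; retained fraction %.3f-%.3f",
                  nrow(fm$freq), min(fm$retained_fraction),
                  max(fm$retained_fraction)))
  if (!is.null(out)) {
    files <- c(matrix = paste0(out, "_matrix.tsv"))
    write_frequency_matrix(fm, files["matrix"])
    write_manifest(files, paste0(out, "_manifest.json"),
                   config = list(rep_threshold = rep_threshold,
                                 singleton_threshold = singleton_threshold,
                                 min_len = min_len, min_phred = min_phred),
                   seed = seed)
  }
  fm
}

# Run manifest: outputs, md5 checksums, configuration and seed.
write_manifest <- function(files, path, config = list(), seed = NA_integer_) {
  entries <- lapply(unname(files), function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(list(outputs = entries, config = config, seed = seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
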