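#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Sequences are normalized to the RNA alphabet (T converted to U).
#'
#' @param path File path.
#' @return List of `rna_seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  mapply(function(s, nm) rna_seq(s, id = nm),
         as.character(x), names(x), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs List of `rna_seq`, a single `rna_seq`, or a named character
#'   vector.
#' @param path File path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_seq")) seqs <- list(seqs)
  if (is.character(seqs)) {
    v <- seqs
  } else {
    v <- vapply(seqs, function(s) s$residues, character(1))
    names(v) <- vapply(seqs, function(s) s$id, character(1))
  }
  x <- Biostrings::BStringSet(v)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 60L)
  invisible(path)
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' Reads containing ambiguous calls (N or any non-ACGUT letter) are dropped
#' with a message reporting the count: downstream analyses operate on called
#' bases only.
#'
#' @param path File path.
#' @return A `read_set`: list with `ids`, `seqs` (normalized RNA strings)
#'   and `quals` (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  seqs <- toupper(as.character(x))
  ok <- !grepl("[^ACGUT]", seqs)
  if (any(!ok)) {
    message(sprintf("dropped %d read(s) containing ambiguous calls", sum(!ok)))
  }
  q <- as.character(S4Vectors::mcols(x)$qualities)[ok]
  quals <- lapply(q, function(s) utf8ToInt(s) - 33L)
  read_set(ids = names(x)[ok], seqs = chartr("T", "U", seqs[ok]),
           quals = quals)
}

#' Write reads with qualities to FASTQ (Sanger Phred+33)
#'
#' @param reads A `read_set`.
#' @param path File path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::BStringSet(setNames(reads$seqs, reads$ids))
  q <- Biostrings::BStringSet(vapply(reads$quals, function(v)
    intToUtf8(v + 33L), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read set: vectorized carrier for quality-bearing reads
#'
#' The package-level representation of a list of reads with per-residue
#' Phred scores; stored as parallel vectors for efficiency.
#'
#' @param seqs Character vector of RNA strings.
#' @param quals List of integer Phred vectors (each in \[0, 60\] and as long
#'   as its read), a single integer recycled per read, or NULL (no
#'   qualities, e.g. FASTA input).
#' @param ids Read identifiers.
#' @return A `read_set`.
#' @export
read_set <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  if (is.numeric(quals) && length(quals) == 1L) {
    q0 <- as.integer(quals)
    quals <- lapply(nchar(seqs), function(n) rep(q0, n))
  }
  seqs <- unname(seqs)
  if (!is.null(quals)) {
    quals <- unname(quals)
    stopifnot(length(quals) == length(seqs))
    lens_ok <- all(lengths(quals) == nchar(seqs))
    if (!lens_ok) stop("quality length must equal read length")
    rng <- range(unlist(quals, use.names = FALSE))
    if (length(seqs) && (rng[1] < 0 || rng[2] > 60))
      stop("Phred scores must lie in [0, 60]")
  }
  structure(list(ids = ids, seqs = seqs, quals = quals), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$seqs)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads%s\n", length(x$seqs),
              if (is.null(x$quals)) " (no qualities)" else ""))
  invisible(x)
}

#' Parse mutation tokens from a comma-separated string or a file
#'
#' @param x Comma-separated tokens, or a path to a one-token-per-line file.
#' @return List of `mutation_spec`.
#' @export
read_mutations <- function(x) {
  toks <- if (length(x) == 1L && file.exists(x)) readLines(x) else
    unlist(strsplit(x, ",", fixed = TRUE))
  toks <- trimws(toks)
  lapply(toks[nzchar(toks)], parse_mutation)
}
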