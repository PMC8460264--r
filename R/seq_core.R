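#' RNA sequence object
#'
#' A validated RNA sequence: an identifier, residues over the alphabet
#' \{A, C, G, U\}, and an optional metadata map (e.g. Mg2+ condition or
#' evolution round). All coordinates in the package are 1-based inclusive.
#'
#' @param residues Character scalar; T is converted to U and case is
#'   normalized, so DNA-alphabet input is accepted.
#' @param id Short text label.
#' @param meta Optional named list of text metadata.
#' @return An object of class `rna_seq` with fields `id`, `residues`, `meta`.
#' @examples
#' rna_seq("TGCGAAGCGTG", id = "template")
#' @export
rna_seq <- function(residues, id = "seq", meta = list()) {
  residues <- normalize_residues(residues)
  structure(list(id = id, residues = residues, meta = meta),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("<rna_seq> %s (%d nt)\n", x$id, nchar(x$residues)))
  cat(x$residues, "\n")
  invisible(x)
}

#' @export
length.rna_seq <- function(x) nchar(x$residues)

normalize_residues <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- gsub("[[:space:]]", "", raw)
  if (nchar(s) < 1L) stop("sequence is empty after whitespace removal")
  s <- toupper(s)
  bad <- regexpr("[^ACGUT]", s)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at offset %d (alphabet is A/C/G/U/T)",
                 substr(s, bad, bad), as.integer(bad)))
  }
  chartr("T", "U", s)
}

#' Normalize raw sequence text to a validated RNA sequence
#'
#' Whitespace is stripped, case is upcased and T is converted to U.
#' Characters outside A/C/G/U/T are rejected with the offending character
#' and offset named in the error. The operation is idempotent.
#'
#' @param raw Character scalar or `rna_seq`.
#' @param id Label for the result.
#' @return An `rna_seq`.
#' @export
normalize_sequence <- function(raw, id = "seq") {
  if (inherits(raw, "rna_seq")) return(raw)
  rna_seq(raw, id = id)
}

as_residues <- function(x) {
  if (inherits(x, "rna_seq")) x$residues else normalize_residues(x)
}

#' Region on a reference sequence
#'
#' Ordered, non-overlapping 1-based inclusive intervals on a named
#' reference, e.g. the P7/P8 region `9-17,83-95`.
#'
#' @param intervals Two-column matrix (start, end) or a string like
#'   `"9-17,83-95"`.
#' @param name Region name.
#' @param ref_length Optional reference length used to validate `end`.
#' @return A `region_spec` with fields `name` and `intervals`.
#' @export
region_spec <- function(intervals, name = "region", ref_length = NULL) {
  if (is.character(intervals)) {
    parts <- strsplit(intervals, ",", fixed = TRUE)[[1]]
    iv <- t(vapply(parts, function(p) {
      se <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      if (length(se) == 1L) se <- c(se, se)
      se
    }, integer(2)))
    intervals <- unname(iv)
  }
  intervals <- matrix(as.integer(intervals), ncol = 2)
  colnames(intervals) <- c("start", "end")
  if (any(intervals[, 1] > intervals[, 2])) stop("interval start > end")
  if (any(intervals[, 1] < 1L)) stop("interval start < 1")
  if (nrow(intervals) > 1L) {
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    if (any(intervals[-1, 1] <= intervals[-nrow(intervals), 2]))
      stop("intervals overlap")
  }
  if (!is.null(ref_length) && any(intervals[, 2] > ref_length))
    stop("interval end exceeds reference length")
  structure(list(name = name, intervals = intervals), class = "region_spec")
}

#' All reference positions covered by a region
#'
#' @param region A `region_spec`.
#' @return Integer vector of 1-based positions, in interval order.
#' @export
region_positions <- function(region) {
  unlist(lapply(seq_len(nrow(region$intervals)), function(i)
    seq.int(region$intervals[i, 1], region$intervals[i, 2])), use.names = FALSE)
}

#' Parse a mutation token
#'
#' Dialects: `C12G` (substitution), `del17A` (deletion of A at 17),
#' `ins88_89:CA` (insertion of CA between positions 88 and 89; the inserted
#' bases follow the anchor position 88).
#'
#' @param token Character scalar.
#' @return A `mutation_spec` with fields `kind`, `position`, `ref_base`, `alt`.
#' @export
parse_mutation <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  token <- trimws(token)
  if (grepl("^ins[0-9]+_[0-9]+:[ACGUTacgut]+$", token)) {
    pos <- as.integer(sub("^ins([0-9]+)_.*$", "\\1", token))
    nxt <- as.integer(sub("^ins[0-9]+_([0-9]+):.*$", "\\1", token))
    if (pos < 1L) stop("insertion anchor position must be >= 1")
    if (nxt != pos + 1L) stop("insertion anchor must be ins<p>_<p+1>")
    alt <- normalize_residues(sub("^.*:", "", token))
    return(mutation_spec("insertion", pos, "", alt))
  }
  if (grepl("^del[0-9]+[ACGUTacgut]$", token)) {
    pos <- as.integer(sub("^del([0-9]+).*$", "\\1", token))
    if (pos < 1L) stop("deletion position must be >= 1")
    ref <- normalize_residues(sub("^del[0-9]+", "", token))
    return(mutation_spec("deletion", pos, ref, ""))
  }
  if (grepl("^[ACGUTacgut][0-9]+[ACGUTacgut]$", token)) {
    ref <- normalize_residues(substr(token, 1, 1))
    alt <- normalize_residues(substr(token, nchar(token), nchar(token)))
    pos <- as.integer(substr(token, 2, nchar(token) - 1L))
    if (pos < 1L) stop("substitution position must be >= 1")
    if (ref == alt) stop("substitution must change the base")
    return(mutation_spec("substitution", pos, ref, alt))
  }
  stop(sprintf("malformed mutation token '%s'", token))
}

mutation_spec <- function(kind, position, ref_base, alt) {
  structure(list(kind = kind, position = as.integer(position),
                 ref_base = ref_base, alt = alt),
            class = "mutation_spec")
}

#' Format a mutation back to token notation
#'
#' Inverse of [parse_mutation()].
#' @param m A `mutation_spec`.
#' @return Character scalar token.
#' @export
format_mutation <- function(m) {
  switch(m$kind,
    substitution = sprintf("%s%d%s", m$ref_base, m$position, m$alt),
    deletion = sprintf("del%d%s", m$position, m$ref_base),
    insertion = sprintf("ins%d_%d:%s", m$position, m$position + 1L, m$alt),
    stop("unknown mutation kind"))
}

#' Apply mutations to a sequence
#'
#' Substitution and deletion reference bases are checked against the
#' sequence; a mismatch signals a wrong reference or stale coordinates.
#' Mutations are applied in descending position order so earlier indels do
#' not shift later coordinates. Insertions are anchored to the reference
#' position they follow.
#'
#' @param seq `rna_seq` or character.
#' @param muts List of `mutation_spec`, or a character vector of tokens.
#' @return Mutated `rna_seq`.
#' @export
apply_mutations <- function(seq, muts) {
  s <- normalize_sequence(seq)
  if (is.character(muts)) muts <- lapply(muts, parse_mutation)
  if (inherits(muts, "mutation_spec")) muts <- list(muts)
  pos <- vapply(muts, `[[`, integer(1), "position")
  kind <- vapply(muts, `[[`, character(1), "kind")
  # a position may carry at most one substitution/deletion plus at most one
  # insertion anchored at it (they touch disjoint residues)
  if (anyDuplicated(pos[kind != "insertion"]) ||
      anyDuplicated(pos[kind == "insertion"]))
    stop("overlapping mutations at a single position")
  # descending position; at a tied position the insertion is applied first,
  # since it only shifts residues beyond its anchor
  muts <- muts[order(-pos, kind != "insertion")]
  res <- strsplit(s$residues, "", fixed = TRUE)[[1]]
  for (m in muts) {
    p <- m$position
    if (m$kind != "insertion" && (p > length(res)))
      stop("mutation position beyond sequence end")
    if (m$kind == "substitution") {
      if (res[p] != m$ref_base)
        stop(sprintf("ref base mismatch at %d: expected %s, found %s",
                     p, m$ref_base, res[p]))
      res[p] <- m$alt
    } else if (m$kind == "deletion") {
      if (res[p] != m$ref_base)
        stop(sprintf("ref base mismatch at %d: expected %s, found %s",
                     p, m$ref_base, res[p]))
      res <- res[-p]
    } else {
      if (p > length(res)) stop("insertion anchor beyond sequence end")
      res <- append(res, strsplit(m$alt, "", fixed = TRUE)[[1]], after = p)
    }
  }
  rna_seq(paste(res, collapse = ""), id = s$id, meta = s$meta)
}

#' Invert a mutation list
#'
#' Returns the mutation list that undoes `muts` on the mutated sequence
#' (substitutions swap bases; deletions become insertions and vice versa).
#' Valid for non-overlapping mutations expressed in original coordinates.
#'
#' @param muts List of `mutation_spec`.
#' @return List of `mutation_spec` in the mutated sequence's coordinates.
#' @export
invert_mutations <- function(muts) {
  if (inherits(muts, "mutation_spec")) muts <- list(muts)
  pos <- vapply(muts, `[[`, integer(1), "position")
  muts <- muts[order(pos)]
  shift <- 0L
  out <- vector("list", length(muts))
  for (i in seq_along(muts)) {
    m <- muts[[i]]
    p <- m$position + shift
    out[[i]] <- switch(m$kind,
      substitution = mutation_spec("substitution", p, m$alt, m$ref_base),
      deletion = {
        shift <- shift - 1L
        mutation_spec("insertion", p - 1L, "", m$ref_base)
      },
      insertion = {
        # inserted bases occupy p+1 .. p+k in the mutated coordinates;
        # one deletion per base, positions distinct so they can be applied
        # in descending order
        del <- lapply(seq_len(nchar(m$alt)), function(k)
          mutation_spec("deletion", p + k,
                        substr(m$alt, k, k), ""))
        shift <- shift + nchar(m$alt)
        del
      })
  }
  # flatten possible nested insertion inverses
  flat <- list()
  for (x in out) {
    if (inherits(x, "mutation_spec")) flat[[length(flat) + 1L]] <- x
    else flat <- c(flat, x)
  }
  flat
}
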