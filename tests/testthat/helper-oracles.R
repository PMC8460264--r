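# Independent oracles and small generators used across the suite.

# Top-down recursive scorer for the semi-global alignment problem:
# read is global, reference 3'-terminal gaps are free. Written as a direct
# enumeration over the three column types (memoized), independent of the
# package's bottom-up C++ implementation.
oracle_align_score <- function(read, ref, match = 1, mismatch = -1, gap = -2) {
  rc <- strsplit(read, "")[[1]]
  fc <- strsplit(ref, "")[[1]]
  n <- length(rc); m <- length(fc)
  memo <- matrix(NA_real_, n + 1, m + 1)
  best <- function(i, j) {
    if (i > n) return(0)                      # remaining reference tail free
    if (j > m) return(gap * (n - i + 1))      # remaining read is insertions
    if (!is.na(memo[i, j])) return(memo[i, j])
    s <- if (rc[i] == fc[j]) match else mismatch
    v <- max(best(i + 1, j + 1) + s,
             best(i, j + 1) + gap,
             best(i + 1, j) + gap)
    memo[i, j] <<- v
    v
  }
  best(1, 1)
}

# Fully exhaustive alignment enumeration (no memoization) for tiny inputs,
# used to validate the oracle itself.
exhaustive_align_score <- function(read, ref, match = 1, mismatch = -1,
                                   gap = -2) {
  rc <- strsplit(read, "")[[1]]
  fc <- strsplit(ref, "")[[1]]
  n <- length(rc); m <- length(fc)
  rec <- function(i, j) {
    if (i > n) return(0)
    if (j > m) return(gap * (n - i + 1))
    s <- if (rc[i] == fc[j]) match else mismatch
    max(rec(i + 1, j + 1) + s, rec(i, j + 1) + gap, rec(i + 1, j) + gap)
  }
  rec(1, 1)
}

random_rna <- function(len, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# Key list (with profiles) for a set of full-length variant sequences.
keys_for_variants <- function(seqs, counts, ref, region) {
  keys <- character(0); cnt <- integer(0); profiles <- list()
  for (i in seq_along(seqs)) {
    k <- extract_region(seqs[i], ref, region)
    keys <- c(keys, k$residues)
    cnt <- c(cnt, counts[i])
    profiles[[k$residues]] <- list(profile = attr(k, "profile"),
                                   insertions = attr(k, "insertions"))
  }
  list(keys = keys, counts = cnt, profiles = profiles)
}

fx <- riboevo_fixtures()
models <- load_structure_models()
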