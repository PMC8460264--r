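#' Round sample of population reads
#'
#' One sequenced evolution round: the round number, the reads (a
#' `read_set`), the raw input count and the count surviving filters.
#'
#' @param round Round number (>= 1).
#' @param reads A `read_set`.
#' @param n_raw Raw input read count (defaults to `length(reads)`).
#' @return A `round_sample`.
#' @export
round_sample <- function(round, reads, n_raw = length(reads)) {
  stopifnot(round >= 1)
  structure(list(round = as.integer(round), reads = reads,
                 n_raw = as.integer(n_raw),
                 n_kept = length(reads)),
            class = "round_sample")
}

#' @export
print.round_sample <- function(x, ...) {
  cat(sprintf("<round_sample> round %d: %d/%d reads kept\n",
              x$round, x$n_kept, x$n_raw))
  invisible(x)
}

#' Quality-filter a round sample
#'
#' Retains reads with length strictly greater than `min_len` and mean Phred
#' score strictly greater than `min_phred` (the mean-quality reading; set
#' `phred_mode = "min"` for the stricter per-base minimum). Samples without
#' qualities (FASTA input) skip the Phred criterion with a warning.
#'
#' @param sample A `round_sample`.
#' @param min_len Minimum length (exclusive), default 150.
#' @param min_phred Minimum Phred score (exclusive), default 33.
#' @param phred_mode `"mean"` (default) or `"min"`.
#' @return Filtered `round_sample` with `n_kept` updated.
#' @export
quality_filter <- function(sample, min_len = 150, min_phred = 33,
                           phred_mode = c("mean", "min")) {
  phred_mode <- match.arg(phred_mode)
  reads <- sample$reads
  keep <- nchar(reads$seqs) > min_len
  if (is.null(reads$quals)) {
    warning("reads carry no qualities; Phred filter skipped")
  } else {
    q <- if (phred_mode == "mean") vapply(reads$quals, mean, numeric(1))
         else vapply(reads$quals, min, numeric(1))
    keep <- keep & q > min_phred
  }
  out <- read_set(reads$seqs[keep],
                  if (is.null(reads$quals)) NULL else reads$quals[keep],
                  reads$ids[keep])
  res <- round_sample(sample$round, out, n_raw = sample$n_raw)
  res
}

#' Extract the region key of a read
#'
#' Aligns the read to the reference and concatenates the read bases aligned
#' within each region interval. Insertions anchored strictly inside an
#' interval are included; deletions shorten the key; reads not fully
#' spanning the region return NULL (callers count and log the discards).
#'
#' The result carries a `profile` attribute (read base or "-" per reference
#' position of the region) and an `insertions` attribute (inserted bases
#' keyed by the junction's left position), which downstream equivalence
#' merging uses to reason in reference coordinates.
#'
#' @param read,ref `rna_seq` or character.
#' @param region A `region_spec` on the reference.
#' @return `rna_seq` region key with attributes, or NULL.
#' @export
extract_region <- function(read, ref, region) {
  f <- as_residues(ref)
  if (max(region$intervals[, 2]) > nchar(f))
    stop("region extends beyond the reference")
  a <- align_to_reference(read, ref)
  project_region(a, f, region,
                 id = if (inherits(read, "rna_seq")) read$id else "key")
}

project_region <- function(a, ref_residues, region, id = "key") {
  pos <- region_positions(region)
  if (any(a$status[pos] == 0L)) return(NULL)
  ref_bases <- strsplit(ref_residues, "", fixed = TRUE)[[1]]
  profile <- character(length(pos))
  names(profile) <- pos
  key_parts <- character(0)
  ins_map <- list()
  for (r in seq_len(nrow(region$intervals))) {
    iv <- region$intervals[r, ]
    for (p in seq.int(iv[1], iv[2])) {
      st <- a$status[p]
      b <- if (st == 1L) ref_bases[p] else if (st == 2L) a$mism_base[p] else "-"
      profile[as.character(p)] <- b
      if (st != 3L) key_parts <- c(key_parts, b)
      if (p < iv[2] && a$ins_count[p + 1L] > 0L) {
        insb <- a$ins_bases[p + 1L]
        key_parts <- c(key_parts, insb)
        ins_map[[as.character(p)]] <- insb
      }
    }
  }
  key <- rna_seq(paste(key_parts, collapse = ""), id = id)
  attr(key, "profile") <- profile
  attr(key, "insertions") <- ins_map
  key
}

#' Batch region-key extraction for a round sample
#'
#' Deduplicates read sequences before alignment, so population samples with
#' many identical reads are processed once per distinct sequence.
#'
#' @param sample A `round_sample` (or `read_set`).
#' @param ref Reference.
#' @param region A `region_spec`.
#' @return List with `keys` (character), `counts` (integer, parallel to
#'   `keys`), `profiles` (list keyed by key string), `n_spanning`,
#'   `n_discarded`.
#' @export
extract_region_keys <- function(sample, ref, region) {
  reads <- if (inherits(sample, "round_sample")) sample$reads else sample
  seqs <- reads_as_character(reads)
  tab <- table(seqs)
  uniq <- names(tab)
  keys <- character(0); counts <- integer(0); profiles <- list()
  n_disc <- 0L
  for (i in seq_along(uniq)) {
    k <- extract_region(uniq[i], ref, region)
    if (is.null(k)) { n_disc <- n_disc + as.integer(tab[i]); next }
    ks <- k$residues
    j <- match(ks, keys)
    if (is.na(j)) {
      keys <- c(keys, ks)
      counts <- c(counts, as.integer(tab[i]))
      profiles[[ks]] <- list(profile = attr(k, "profile"),
                             insertions = attr(k, "insertions"))
    } else counts[j] <- counts[j] + as.integer(tab[i])
  }
  list(keys = keys, counts = counts, profiles = profiles,
       n_spanning = sum(counts), n_discarded = n_disc)
}

# cd-hit-style join rule at 100% identity with terminal slack: a key joins a
# representative iff one is a contiguous substring of the other, the total
# unmatched terminal length is <= max_unmatched and the length difference is
# <= max_len_diff (for substrings the two quantities coincide).
keys_joinable <- function(a, b, max_unmatched = 2L, max_len_diff = 2L) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > min(max_unmatched, max_len_diff)) return(FALSE)
  if (la == lb) return(a == b)
  if (la < lb) grepl(a, b, fixed = TRUE) else grepl(b, a, fixed = TRUE)
}

#' Greedy clustering of region keys at 100% identity with terminal slack
#'
#' Keys are processed in descending abundance (ties broken
#' lexicographically). A key joins the first (most abundant) existing
#' cluster whose representative it matches exactly over their overlap when
#' one is a contiguous substring of the other, with total unmatched terminal
#' length <= 2 and length difference <= 2; otherwise it seeds a new cluster.
#' The representative is the most abundant member.
#'
#' @param keys Character vector of keys, a list as returned by
#'   [extract_region_keys()], or a list of `rna_seq`.
#' @param counts Integer abundances parallel to `keys` (default 1 each).
#' @param max_unmatched,max_len_diff Terminal slack parameters (cd-hit -U/-S
#'   semantics), both default 2.
#' @return List of clusters: each has `representative`, `members` (named
#'   counts), `count`, `profile` (if available).
#' @export
cluster_region_keys <- function(keys, counts = NULL, max_unmatched = 2L,
                                max_len_diff = 2L) {
  profiles <- NULL
  if (is.list(keys) && !is.null(keys$keys)) {
    counts <- keys$counts; profiles <- keys$profiles; keys <- keys$keys
  } else if (is.list(keys)) {
    keys <- vapply(keys, as_residues, character(1))
  }
  if (is.null(counts)) counts <- rep(1L, length(keys))
  stopifnot(length(keys) == length(counts), length(keys) > 0L)
  agg <- tapply(counts, keys, sum)
  keys <- names(agg); counts <- as.integer(agg)
  o <- order(-counts, keys)
  keys <- keys[o]; counts <- counts[o]
  clusters <- list()
  for (i in seq_along(keys)) {
    placed <- FALSE
    for (c in seq_along(clusters)) {
      if (keys_joinable(keys[i], clusters[[c]]$representative,
                        max_unmatched, max_len_diff)) {
        clusters[[c]]$members[keys[i]] <- counts[i]
        clusters[[c]]$count <- clusters[[c]]$count + counts[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        representative = keys[i],
        members = setNames(counts[i], keys[i]),
        count = counts[i],
        profile = if (!is.null(profiles)) profiles[[keys[i]]] else NULL)
    }
  }
  clusters
}

# Representative equivalence used when merging clusters: differs only by
# the A-homopolymer adjacent to the junction position (A residues inserted
# or deleted between nucleotides 17 and 18 of the reference), or by a single
# substitution at a position outside the conserved cores.
profiles_equivalent <- function(pa, pb, core = c(11:16, 84:89), junction = 17L) {
  if (is.null(pa) || is.null(pb)) return(FALSE)
  a <- pa$profile; b <- pb$profile
  if (!identical(names(a), names(b))) return(FALSE)
  diff_pos <- as.integer(names(a)[a != b])
  ins_same <- identical(pa$insertions, pb$insertions)
  # rule (b): single substitution outside the cores, insertions identical
  if (ins_same && length(diff_pos) == 1L) {
    p <- as.character(diff_pos)
    if (a[p] != "-" && b[p] != "-" && !(diff_pos %in% core)) return(TRUE)
  }
  # rule (a): all differences are A-vs-gap within the A-run ending at the
  # junction position, insertions identical elsewhere (junction insertions
  # of A count too)
  arun <- junction
  while ((arun - 1L) %in% as.integer(names(a))) {
    prv <- as.character(arun - 1L)
    if (!(a[prv] %in% c("A", "-")) || !(b[prv] %in% c("A", "-"))) break
    arun <- arun - 1L
  }
  run_pos <- seq.int(arun, junction)
  pos_ok <- length(diff_pos) > 0L || !ins_same
  if (length(diff_pos)) {
    for (p in diff_pos) {
      pc <- as.character(p)
      if (!(p %in% run_pos) ||
          !all(c(a[pc], b[pc]) %in% c("A", "-"))) { pos_ok <- FALSE; break }
    }
  }
  if (!ins_same) {
    ia <- pa$insertions; ib <- pb$insertions
    keys <- union(names(ia), names(ib))
    for (k in keys) {
      va <- if (is.null(ia[[k]])) "" else ia[[k]]
      vb <- if (is.null(ib[[k]])) "" else ib[[k]]
      if (va == vb) next
      if (!(as.integer(k) %in% run_pos) ||
          grepl("[^A]", va) || grepl("[^A]", vb)) { pos_ok <- FALSE; break }
    }
  }
  pos_ok
}

#' Merge equivalent clusters
#'
#' Clusters whose representatives differ only by (a) the length of the
#' A homopolymer at the junction between reference positions 17 and 18, or
#' (b) a single substitution at a position outside 11-16 and 84-89, are
#' treated as the same cluster: counts are summed and the most abundant
#' representative is kept.
#'
#' @param clusters List of clusters from [cluster_region_keys()] (profiles
#'   required) or tracks from [track_clusters()].
#' @param core Integer positions excluded from single-substitution
#'   equivalence (default 11-16 and 84-89).
#' @param junction Left reference position of the A-indel junction
#'   (default 17).
#' @return Merged cluster list.
#' @export
merge_equivalent <- function(clusters, core = c(11:16, 84:89), junction = 17L) {
  n <- length(clusters)
  if (n <= 1L) return(clusters)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (profiles_equivalent(clusters[[i]]$profile, clusters[[j]]$profile,
                            core, junction)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    grp <- clusters[roots == r]
    tot <- vapply(grp, function(g) sum(g$count), numeric(1))
    best <- which.max(tot)
    merged <- grp[[best]]
    if (length(grp) > 1L) {
      for (g in grp[-best]) {
        merged$count <- merged$count + g$count
        merged$members <- c(merged$members, g$members)
        if (!is.null(merged$counts_by_round)) {
          merged$counts_by_round <- merged$counts_by_round + g$counts_by_round
        }
      }
    }
    out[[length(out) + 1L]] <- merged
  }
  out
}

#' Track cluster frequencies across evolution rounds
#'
#' Runs the full population pipeline over per-round samples: region-key
#' extraction, per-round greedy clustering, cross-round matching of clusters
#' by representative key under the same join rule, equivalence merging,
#' frequency computation, and the retention rules: clusters must exceed
#' `rep_threshold` frequency in at least one round, and clusters observed in
#' exactly one round at below `singleton_threshold` are dropped. Retained
#' clusters are named `"<round>.<rank>"` by the first round in which they
#' exceeded `rep_threshold` (rank by abundance, then lexicographic).
#'
#' @param samples List of `round_sample` (already quality-filtered).
#' @param ref Reference sequence.
#' @param region `region_spec` of the tracked region.
#' @param rep_threshold Representation threshold (default 0.01).
#' @param singleton_threshold Single-round exclusion threshold (default
#'   0.05).
#' @param merge Apply [merge_equivalent()] across tracks (default TRUE).
#' @param filter Apply the retention rules (default TRUE; FALSE returns all
#'   clusters, under which per-round frequencies sum to 1).
#' @param core,junction Passed to [merge_equivalent()].
#' @return A `frequency_matrix`: list with `freq` and `counts` matrices
#'   (clusters x rounds), `rounds`, `n_total` keys per round,
#'   `retained_fraction` per round, and `clusters` (id, representative).
#' @export
track_clusters <- function(samples, ref, region, rep_threshold = 0.01,
                           singleton_threshold = 0.05, merge = TRUE,
                           filter = TRUE, core = c(11:16, 84:89),
                           junction = 17L) {
  stopifnot(length(samples) >= 1L)
  rounds <- vapply(samples, function(s) s$round, integer(1))
  o <- order(rounds)
  samples <- samples[o]; rounds <- rounds[o]
  nr <- length(rounds)
  tracks <- list()
  n_total <- setNames(integer(nr), rounds)
  for (ri in seq_len(nr)) {
    ex <- extract_region_keys(samples[[ri]], ref, region)
    n_total[ri] <- ex$n_spanning
    if (ex$n_spanning == 0L) next
    cl <- cluster_region_keys(ex)
    # descending abundance within the round
    cl <- cl[order(-vapply(cl, function(c) c$count, numeric(1)),
                   vapply(cl, function(c) c$representative, character(1)))]
    for (cc in cl) {
      cand <- which(vapply(tracks, function(t)
        keys_joinable(cc$representative, t$representative), logical(1)))
      if (length(cand)) {
        tot <- vapply(tracks[cand], function(t) sum(t$counts_by_round),
                      numeric(1))
        tgt <- cand[order(-tot,
                          vapply(tracks[cand], function(t) t$representative,
                                 character(1)))][1]
        tracks[[tgt]]$counts_by_round[ri] <- tracks[[tgt]]$counts_by_round[ri] +
          cc$count
        tracks[[tgt]]$members <- c(tracks[[tgt]]$members, cc$members)
        tracks[[tgt]]$count <- tracks[[tgt]]$count + cc$count
      } else {
        cbr <- setNames(integer(nr), rounds)
        cbr[ri] <- cc$count
        tracks[[length(tracks) + 1L]] <- list(
          representative = cc$representative, members = cc$members,
          count = cc$count, profile = cc$profile, counts_by_round = cbr)
      }
    }
  }
  if (merge) tracks <- merge_equivalent(tracks, core, junction)
  counts <- do.call(rbind, lapply(tracks, function(t) t$counts_by_round))
  if (is.null(counts)) counts <- matrix(0L, 0, nr)
  colnames(counts) <- rounds
  freq <- sweep(counts, 2, pmax(n_total, 1L), "/")
  reps <- vapply(tracks, function(t) t$representative, character(1))
  keep <- rep(TRUE, length(tracks))
  if (filter && length(tracks)) {
    above <- apply(freq > rep_threshold, 1, any)
    seen <- rowSums(counts > 0)
    single_low <- seen == 1L & apply(freq, 1, max) < singleton_threshold
    keep <- above & !single_low
  }
  # name retained clusters by first round above rep_threshold
  ids <- rep(NA_character_, length(tracks))
  if (any(keep)) {
    first_round <- apply(freq[keep, , drop = FALSE] > rep_threshold, 1,
                         function(z) if (any(z)) rounds[which(z)[1]] else
                           rounds[1])
    ki <- which(keep)
    for (r in unique(sort(first_round))) {
      grp <- ki[first_round == r]
      grp <- grp[order(-vapply(tracks[grp], function(t) sum(t$count),
                               numeric(1)), reps[grp])]
      ids[grp] <- paste0(r, ".", seq_along(grp))
    }
  }
  retained_fraction <- colSums(counts[keep, , drop = FALSE]) /
    pmax(n_total, 1L)
  structure(list(
    freq = freq[keep, , drop = FALSE],
    counts = counts[keep, , drop = FALSE],
    rounds = rounds,
    n_total = n_total,
    retained_fraction = retained_fraction,
    clusters = data.frame(cluster_id = ids[keep],
                          representative = reps[keep],
                          stringsAsFactors = FALSE),
    all_freq = freq,
    all_representatives = reps),
    class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("<frequency_matrix> %d retained clusters x %d rounds\n",
              nrow(x$freq), length(x$rounds)))
  cat(sprintf("  retained fraction: %s\n",
              paste(sprintf("%.2f", x$retained_fraction), collapse = " ")))
  invisible(x)
}

#' Correlate paired 5'- and 3'-strand variant trajectories
#'
#' Pearson correlation across rounds between each 5'-strand variant
#' frequency trajectory and its paired 3'-strand trajectory; NA if either
#' trajectory has zero variance. Matrices must share the round axis.
#'
#' @param matrix5,matrix3 `frequency_matrix` objects built on the 5'- and
#'   3'-strand sub-regions.
#' @param pairing Named character vector: 5'-variant representative ->
#'   3'-variant representative.
#' @return Named numeric vector of correlations (named by the 5' key).
#' @export
strand_correlation <- function(matrix5, matrix3, pairing) {
  if (!identical(matrix5$rounds, matrix3$rounds))
    stop("round axes differ between the two matrices")
  out <- setNames(numeric(length(pairing)), names(pairing))
  for (i in seq_along(pairing)) {
    k5 <- names(pairing)[i]; k3 <- pairing[[i]]
    r5 <- match(k5, matrix5$clusters$representative)
    r3 <- match(k3, matrix3$clusters$representative)
    if (is.na(r5) || is.na(r3)) stop("pairing key not found in matrices")
    f5 <- matrix5$freq[r5, ]; f3 <- matrix3$freq[r3, ]
    out[i] <- if (stats::sd(f5) == 0 || stats::sd(f3) == 0) NA_real_
              else cor(f5, f3)
  }
  out
}

#' Write a frequency matrix (and cluster table) as TSV
#'
#' @param fm A `frequency_matrix`.
#' @param path Output path for the frequency matrix; a companion
#'   `*_clusters.tsv` is written next to it.
#' @export
write_frequency_matrix <- function(fm, path) {
  df <- data.frame(cluster_id = fm$clusters$cluster_id,
                   representative = fm$clusters$representative,
                   fm$freq, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
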