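test_that("quality filter applies strict length and mean-Phred thresholds", {
  set.seed(2)
  s <- round_sample(1, read_set(
    c(random_rna(150), random_rna(151), random_rna(200)),
    quals = list(rep(40L, 150), rep(40L, 151), rep(30L, 200))))
  f <- quality_filter(s)
  expect_equal(f$n_kept, 1L)           # only the 151-nt Q40 read survives
  expect_equal(nchar(f$reads$seqs), 151L)
  # FASTA input (no qualities): Phred criterion skipped with a warning
  s2 <- round_sample(1, read_set(c(random_rna(140), random_rna(160))))
  expect_warning(f2 <- quality_filter(s2), "Phred")
  expect_equal(f2$n_kept, 1L)
})

test_that("region extraction projects reads into reference coordinates", {
  ref <- fx$polymerase_ref
  region <- fx$region
  # identity read: 9 + 13 = 22-nt key equal to the reference's own region
  k <- extract_region(ref, ref, region)
  expect_equal(nchar(k$residues), 22L)
  refc <- strsplit(ref$residues, "")[[1]]
  expect_equal(k$residues, paste(refc[c(9:17, 83:95)], collapse = ""))

  # deletion at position 90 shortens the key
  k <- extract_region(apply_mutations(ref, "del90A"), ref, region)
  expect_equal(nchar(k$residues), 21L)

  # 2-nt insertion between 88 and 89 (strictly inside the interval)
  k <- extract_region(apply_mutations(ref, "ins88_89:CA"), ref, region)
  expect_equal(nchar(k$residues), 24L)

  # reads not spanning the region are discarded
  expect_null(extract_region(substr(ref$residues, 1, 60), ref, region))
})

test_that("greedy clustering joins substrings within terminal slack", {
  cl <- cluster_region_keys(c(rep("GCACCA", 5), rep("GCACC", 2)))
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$representative, "GCACCA")
  expect_equal(cl[[1]]$count, 7L)

  # internal mismatch breaks 100% identity
  cl <- cluster_region_keys(c(rep("GCACCA", 5), rep("GCAGCA", 3)))
  expect_equal(length(cl), 2L)

  # slack larger than 2 does not join
  cl <- cluster_region_keys(c(rep("GCACCAAA", 5), rep("GCACC", 2)))
  expect_equal(length(cl), 2L)
})

test_that("greedy clustering matches an independent reference implementation", {
  independent_cluster <- function(keys, counts) {
    o <- order(-counts, keys)
    keys <- keys[o]; counts <- counts[o]
    reps <- character(0); assign <- integer(length(keys))
    for (i in seq_along(keys)) {
      hit <- 0L
      for (r in seq_along(reps)) {
        a <- keys[i]; b <- reps[r]
        shorter <- if (nchar(a) <= nchar(b)) a else b
        longer <- if (nchar(a) <= nchar(b)) b else a
        if (abs(nchar(a) - nchar(b)) <= 2 &&
            length(grep(shorter, longer, fixed = TRUE)) == 1) { hit <- r; break }
      }
      if (hit == 0L) { reps <- c(reps, keys[i]); hit <- length(reps) }
      assign[i] <- hit
    }
    split(setNames(counts, keys), assign)
  }
  set.seed(31)
  for (rep_i in 1:10) {
    keys <- vapply(1:20, function(i)
      random_rna(sample(20:24, 1), bases = c("A", "C")), character(1))
    counts <- sample(1:50, 20, replace = TRUE)
    got <- cluster_region_keys(keys, counts)
    want <- independent_cluster(keys, counts)
    expect_equal(length(got), length(want))
    expect_setequal(vapply(got, function(c) c$count, integer(1)),
                    vapply(want, sum, integer(1)))
  }
})

test_that("equivalence merging follows the junction and core rules", {
  ref <- fx$polymerase_ref
  region <- fx$region
  base <- ref$residues
  mk <- function(...) apply_mutations(ref, c(...))$residues

  # (a) one fewer A at the 17/18 junction -> merged
  kl <- keys_for_variants(c(base, mk("del17A")), c(5L, 3L), ref, region)
  m <- merge_equivalent(cluster_region_keys(kl))
  expect_equal(length(m), 1L)
  expect_equal(m[[1]]$count, 8L)
  expect_equal(m[[1]]$representative,
               extract_region(base, ref, region)$residues)

  # (b) single substitution outside 11-16 / 84-89 -> merged
  kl <- keys_for_variants(c(base, mk("A10G")), c(5L, 3L), ref, region)
  expect_equal(length(merge_equivalent(cluster_region_keys(kl))), 1L)

  # substitution at position 12 (inside the core) -> NOT merged
  kl <- keys_for_variants(c(base, mk("C12G")), c(5L, 3L), ref, region)
  expect_equal(length(merge_equivalent(cluster_region_keys(kl))), 2L)

  # two substitutions (both outside cores) -> NOT merged
  kl <- keys_for_variants(c(base, mk("A10G", "A90C")), c(5L, 3L), ref, region)
  expect_equal(length(merge_equivalent(cluster_region_keys(kl))), 2L)
})

test_that("tracking applies the >1% and single-round-<5% retention rules", {
  ref <- fx$polymerase_ref
  gens <- c(a = ref$residues,
            b = apply_mutations(ref, "C15G")$residues,
            c = apply_mutations(ref, "C15U")$residues,
            d = apply_mutations(ref, "A16G")$residues)
  R <- 6
  traj <- matrix(0, R, 4)
  traj[, 2] <- 0.005          # never above 1% -> excluded
  traj[3, 3] <- 0.06          # single round at 6% -> retained
  traj[4, 4] <- 0.04          # single round at 4% -> excluded
  traj[, 1] <- 1 - rowSums(traj)
  pm <- population_model(gens, trajectories = traj, pop_size = 5000,
                         seed = 5L)
  sim <- simulate_rounds(pm)
  fm <- track_clusters(sim$samples, ref, fx$region)
  keys <- vapply(gens, function(g)
    extract_region(g, ref, fx$region)$residues, character(1))
  expect_setequal(fm$clusters$representative, unname(keys[c("a", "c")]))
  # dominant cluster named by its first >1% round
  expect_equal(fm$clusters$cluster_id[
    fm$clusters$representative == keys[["a"]]], "1.1")
  expect_equal(fm$clusters$cluster_id[
    fm$clusters$representative == keys[["c"]]], "3.1")
})

test_that("pre-filter frequencies sum to one and tracking is order-invariant", {
  ref <- fx$polymerase_ref
  gens <- c(a = ref$residues, b = apply_mutations(ref, "C15G")$residues)
  pm <- population_model(gens, trajectories = matrix(c(.7, .4, .3, .6), 2),
                         pop_size = 2000, seed = 9L)
  sim <- simulate_rounds(pm)
  fm_all <- track_clusters(sim$samples, ref, fx$region, filter = FALSE)
  expect_equal(unname(colSums(fm_all$freq)), rep(1, 2), tolerance = 1e-12)

  # permutation of reads within a round leaves the matrix unchanged
  shuf <- lapply(sim$samples, function(s) {
    set.seed(99)
    idx <- sample.int(length(s$reads))
    round_sample(s$round, read_set(s$reads$seqs[idx], s$reads$quals[idx],
                                   s$reads$ids[idx]))
  })
  fm1 <- track_clusters(sim$samples, ref, fx$region)
  fm2 <- track_clusters(shuf, ref, fx$region)
  expect_equal(fm1$freq, fm2$freq)
  expect_equal(fm1$clusters, fm2$clusters)
})

test_that("merging equivalent clusters never lowers the retained fraction", {
  ref <- fx$polymerase_ref
  gens <- c(a = ref$residues,
            b = apply_mutations(ref, "del17A")$residues,   # equivalent to a
            c = apply_mutations(ref, "C15G")$residues)
  traj <- matrix(c(.5, .5, .3, .3, .2, .2), 2)
  pm <- population_model(gens, trajectories = traj, pop_size = 3000,
                         seed = 17L)
  sim <- simulate_rounds(pm)
  fm_merged <- track_clusters(sim$samples, ref, fx$region, merge = TRUE)
  fm_plain <- track_clusters(sim$samples, ref, fx$region, merge = FALSE)
  expect_true(all(fm_merged$retained_fraction >=
                    fm_plain$retained_fraction - 1e-12))
  # the equivalent pair collapsed into one cluster
  expect_equal(nrow(fm_merged$freq), 2L)
})

test_that("strand correlation recovers planted co-variation", {
  ref <- fx$polymerase_ref
  gens <- c(a = ref$residues,
            b = apply_mutations(ref, c("C15G", "G85C"))$residues)
  R <- 10
  traj <- cbind(seq(0.95, 0.05, length.out = R),
                seq(0.05, 0.95, length.out = R))
  pm <- population_model(gens, trajectories = traj, pop_size = 10000,
                         seed = 23L)
  sim <- simulate_rounds(pm)
  m5 <- track_clusters(sim$samples, ref, fx$region5)
  m3 <- track_clusters(sim$samples, ref, fx$region3)
  k5 <- extract_region(gens[["b"]], ref, fx$region5)$residues
  k3 <- extract_region(gens[["b"]], ref, fx$region3)$residues
  r <- strand_correlation(m5, m3, setNames(k3, k5))
  expect_gt(unname(r), 0.9)
  # a trajectory correlated with itself is exactly 1
  r2 <- strand_correlation(m5, m5, setNames(k5, k5))
  expect_equal(unname(r2), 1.0)
  # mismatched round axes are rejected
  m3_trunc <- m3
  m3_trunc$rounds <- m3$rounds[-1]
  expect_error(strand_correlation(m5, m3_trunc, setNames(k3, k5)), "round")
})
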