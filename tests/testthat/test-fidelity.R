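test_that("alignment reproduces the worked examples", {
  a <- align_to_reference("UGCGAAGCGUG", "UGCGAAGCGUG")
  expect_equal(sum(a$status == 1L), 11L)
  expect_equal(a$span, c(1L, 11L))

  # internal deletion: ref C at position 3 unpaired
  a <- align_to_reference("UGGA", "UGCGA")
  expect_equal(a$status, c(1L, 1L, 3L, 1L, 1L))
  expect_equal(a$score, 4 - 2)

  # truncation: positions 9-11 uncovered, not deletions
  a <- align_to_reference("UGCGAAGC", "UGCGAAGCGUG")
  expect_equal(a$span, c(1L, 8L))
  expect_equal(a$status[9:11], c(0L, 0L, 0L))
  expect_equal(sum(a$status == 1L), 8L)
})

test_that("alignment score matches the recursive enumeration oracle", {
  # validate the oracle against a fully exhaustive enumerator first
  set.seed(5)
  for (i in 1:30) {
    r <- random_rna(sample(1:5, 1)); f <- random_rna(sample(1:5, 1))
    expect_equal(oracle_align_score(r, f), exhaustive_align_score(r, f))
  }
  # then the implementation against the oracle on longer pairs
  for (i in 1:100) {
    r <- random_rna(sample(1:8, 1)); f <- random_rna(sample(1:8, 1))
    expect_equal(align_to_reference(r, f)$score, oracle_align_score(r, f),
                 info = paste(r, f))
  }
})

test_that("alignment conserves read length across columns", {
  set.seed(9)
  for (i in 1:50) {
    r <- random_rna(sample(5:40, 1)); f <- random_rna(sample(5:40, 1))
    a <- align_to_reference(r, f)
    expect_equal(sum(a$status == 1L) + sum(a$status == 2L) + sum(a$ins_count),
                 a$read_length)
  }
})

test_that("tally accumulates matches, mismatches and deletions correctly", {
  ref <- "UGCGAAGCGUG"
  tab <- tally_fidelity(rep(ref, 10), ref)
  expect_equal(tab$coverage, rep(10L, 11))
  expect_equal(tab$matches, rep(10L, 11))
  expect_equal(sum(tab$mismatches), 0L)

  # one mismatch at position 3 (C -> G)
  tab <- tally_fidelity(c(ref, "UGGGAAGCGUG"), ref)
  expect_equal(unname(tab$mismatches[3, "G"]), 1L)
  expect_equal(tab$matches[3], 1L)

  # deletion from the verified alignment example
  tab <- tally_fidelity("UGGA", "UGCGA")
  expect_equal(tab$deletions[3], 1L)

  # conservation holds on random read sets
  set.seed(21)
  reads <- vapply(1:50, function(i) random_rna(sample(5:15, 1)), character(1))
  tab <- tally_fidelity(reads, ref)
  expect_equal(tab$matches + rowSums(tab$mismatches) + tab$deletions,
               tab$coverage)
})

test_that("average fidelity is the coverage-weighted match fraction", {
  # 3 positions, coverage 10 each, errors {0,2,1} -> 27/30
  ref <- "ACG"
  reads <- c(rep("ACG", 7), "AUG", "AGG", "ACU")
  tab <- tally_fidelity(reads, ref)
  expect_equal(average_fidelity(tab), 27 / 30)
  expect_equal(average_fidelity(tally_fidelity(rep(ref, 5), ref)), 1.0)
  expect_equal(average_fidelity(tally_fidelity("A", "G")), 0)
})

test_that("full-length-only tally drops truncated products", {
  ref <- "UGCGAAGCGUG"
  tab <- tally_fidelity(c(ref, "UGCGA"), ref, full_length_only = TRUE)
  expect_equal(tab$n_reads, 1L)
  expect_equal(tab$coverage, rep(1L, 11))
})

test_that("mutation spectrum separates wobble from other mismatches", {
  # only template-U -> G events: wobble fraction 1
  ref <- "AUA"
  tab <- tally_fidelity(c("AGA", "AGA"), ref)
  expect_equal(mutation_spectrum(tab)$wobble_fraction, 1.0)

  # simulated wobble-biased errors recover the configured expectation
  em <- error_model(sub_rate = 0.08, sub_matrix = wobble_sub_matrix(5),
                    seed = 42L)
  rs <- simulate_products(fx$hammerhead_ref, em, 20000)
  tab <- tally_fidelity(rs, fx$hammerhead_ref)
  sp <- mutation_spectrum(tab)
  expectation <- expected_wobble_fraction(fx$hammerhead_ref, em)
  n_mm <- sum(tab$mismatches)
  se <- sqrt(expectation * (1 - expectation) / n_mm)
  expect_lt(abs(sp$wobble_fraction - expectation), 3 * se)
})

test_that("uniform substitution spectrum has wobble fraction near 2/12", {
  em <- error_model(sub_rate = 0.08, seed = 3L)
  rs <- simulate_products(fx$hammerhead_ref, em, 20000)
  sp <- mutation_spectrum(tally_fidelity(rs, fx$hammerhead_ref))
  expectation <- expected_wobble_fraction(fx$hammerhead_ref, em)
  expect_lt(abs(sp$wobble_fraction - expectation), 0.02)
})

test_that("a known per-position error vector is recovered within 3 SE", {
  set.seed(4)
  ev <- runif(33, 0.02, 0.12)
  em <- error_model(sub_rate = ev, seed = 12L)
  rs <- simulate_products(fx$hammerhead_ref, em, 50000)
  est <- per_position_error(tally_fidelity(rs, fx$hammerhead_ref))
  se <- sqrt(ev * (1 - ev) / 50000)
  expect_lt(max(abs(est - ev) / se), 3)
})

test_that("ligase-condition fidelity carries only a small parsimony bias", {
  # at ~16% per-position error, maximum-score alignment explains some
  # substitution clusters with fewer events than generated; the pooled
  # fidelity estimate is expected to sit slightly above the truth, within
  # a few tenths of a percentage point
  p <- 1 - 0.841
  em <- error_model(sub_rate = p, sub_matrix = wobble_sub_matrix(5),
                    seed = 8L)
  rs <- simulate_products(fx$ligase_ref, em, 20000)
  tab <- tally_fidelity(rs, fx$ligase_ref, full_length_only = TRUE)
  fid <- average_fidelity(tab)
  expect_gte(fid, 0.841 - 0.001)
  expect_lt(fid, 0.841 + 0.005)
  # mean mutations per copy matches the printed-scale expectation (~12)
  expect_equal(levenshtein_distribution(rs, fx$ligase_ref)$mean_distance,
               76 * p, tolerance = 0.1)
})

test_that("levenshtein agrees with the generalized-distance oracle", {
  expect_equal(levenshtein("UGCGAAGCGUG", "UGCGAAGCGUG"), 0L)
  expect_equal(levenshtein("UGCGAAGCGUG", "UGCGAGCGUG"), 1L)
  expect_equal(levenshtein("UGCGAAGCGUG", "UGGGAAGGGUG"), 2L)
  set.seed(13)
  for (i in 1:50) {
    a <- random_rna(sample(1:20, 1)); b <- random_rna(sample(1:20, 1))
    expect_equal(levenshtein(a, b), as.integer(utils::adist(a, b)))
    expect_equal(levenshtein(a, b), levenshtein(b, a))  # symmetry
    expect_equal(levenshtein(a, a), 0L)
  }
  # triangle inequality on random triples
  for (i in 1:25) {
    a <- random_rna(10); b <- random_rna(12); c <- random_rna(8)
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
  }
})

test_that("distance histogram sums to the read count", {
  reads <- c("UGCGAAGCGUG", "UGCGAGCGUG", "UGGGAAGGGUG")
  h <- levenshtein_distribution(reads, "UGCGAAGCGUG")
  expect_equal(sum(h$counts), 3L)
  expect_equal(h$counts[["0"]], 1L)
  expect_equal(h$mean_distance, mean(c(0, 1, 2)))
})

test_that("fidelity table writes a well-formed TSV", {
  tab <- tally_fidelity(c("UGCGAAGCGUG", "UGGA"), "UGCGAAGCGUG")
  tmp <- tempfile(fileext = ".tsv")
  write_fidelity_table(tab, tmp)
  df <- utils::read.delim(tmp)
  expect_equal(nrow(df), 11 + 12)  # positions + junctions
  expect_equal(df$coverage[1], 2L)
})
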