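test_that("base-pair classification covers all 16 pairs and is symmetric", {
  expect_equal(classify_pair("G", "C"), "watson_crick")
  expect_equal(classify_pair("A", "U"), "watson_crick")
  expect_equal(classify_pair("G", "U"), "wobble")
  expect_equal(classify_pair("A", "C"), "unpaired")
  for (a in c("A", "C", "G", "U")) for (b in c("A", "C", "G", "U")) {
    expect_equal(classify_pair(a, b), classify_pair(b, a))
  }
  expect_equal(sum(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                         Vectorize(classify_pair)) == "watson_crick"), 4L)
  expect_error(classify_pair("N", "A"), "invalid")
})

test_that("stem validation detects disruption and compensatory restoration", {
  pol <- fx$polymerase_ref
  v <- validate_stem(pol, models$pseudoknot, "P8")
  expect_equal(v$n_watson_crick, 6L)
  expect_equal(nrow(v$pairs), 6L)

  single <- apply_mutations(pol, "C12G")
  expect_equal(validate_stem(single, models$pseudoknot, "P8")$n_watson_crick, 5L)

  double <- apply_mutations(pol, c("C12G", "G88C"))
  expect_equal(validate_stem(double, models$pseudoknot, "P8")$n_watson_crick, 6L)

  expect_error(validate_stem(pol, models$pseudoknot, "P9"), "not in model")
})

test_that("any WC-to-WC pair swap preserves the stem count", {
  pol <- fx$polymerase_ref
  wc <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
  set.seed(3)
  pairs <- models$pseudoknot$stems$P8
  for (i in 1:20) {
    pr <- pairs[sample(nrow(pairs), 1), ]
    new <- wc[[sample(4, 1)]]
    chars <- strsplit(pol$residues, "")[[1]]
    muts <- c()
    if (chars[pr[1]] != new[1])
      muts <- c(muts, sprintf("%s%d%s", chars[pr[1]], pr[1], new[1]))
    if (chars[pr[2]] != new[2])
      muts <- c(muts, sprintf("%s%d%s", chars[pr[2]], pr[2], new[2]))
    variant <- if (length(muts)) apply_mutations(pol, muts) else pol
    expect_equal(validate_stem(variant, models$pseudoknot, "P8")$n_watson_crick,
                 6L)
  }
})

test_that("pair-support verdicts follow the disruption/restoration thresholds", {
  expect_equal(assess_pair_support(1.0, 0.005, 0.01, 0.8)$verdict,
               "covariation_supported")
  expect_equal(assess_pair_support(1.0, 0.005, 0.01, 0.15)$verdict,
               "partially_restored")
  expect_equal(assess_pair_support(1.0, 0.005, 0.01, 0.02)$verdict,
               "not_restored")
  expect_equal(assess_pair_support(1.0, 0.5, 0.6, 0.9)$verdict,
               "not_disruptive")
  expect_error(assess_pair_support(1.0, -0.1, 0.01, 0.8), "non-negative")
})

test_that("probing normalization matches the worked arithmetic", {
  prof <- probing_profile(1:3, matrix(rep(c(100, 50, 200), 4), 3, 4),
                          rep(50, 3))
  norm <- normalize_probing(prof, region_spec("1-3"))$normalized
  expect_equal(unname(norm), c(1 / 3, 0, 1))

  # raw equal to background everywhere -> all zero with a warning
  flat <- probing_profile(1:3, matrix(50, 3, 4), rep(50, 3))
  expect_warning(norm0 <- normalize_probing(flat, region_spec("1-3")),
                 "zero")
  expect_equal(unname(norm0$normalized), c(0, 0, 0))

  # scale invariance: common factor on raw and background cancels
  prof10 <- probing_profile(1:3, 10 * matrix(rep(c(100, 50, 200), 4), 3, 4),
                            10 * rep(50, 3))
  expect_equal(normalize_probing(prof10, region_spec("1-3"))$normalized, norm)
})

test_that("probing simulation marks unpaired positions as cleavage-sensitive", {
  reg <- region_spec("11-16,83-96", ref_length = 182L)
  pp <- simulate_probing(models$pseudoknot, reg, flex_unpaired = 1,
                         flex_paired = 0, noise_cv = 0, seed = 1L)
  pp <- normalize_probing(pp, reg)
  # A90 and position 83 are the unpaired positions of the region
  expect_equal(unname(pp$normalized[as.character(90)]), 1)
  expect_equal(unname(pp$normalized[as.character(83)]), 1)
  paired <- setdiff(region_positions(reg), c(83, 90))
  expect_true(all(pp$normalized[as.character(paired)] == 0))
})

test_that("concordance is signed, antisymmetric, and model-discriminating", {
  reg <- region_spec("11-16,83-96", ref_length = 182L)
  pp <- simulate_probing(models$pseudoknot, reg, noise_cv = 0, seed = 1L)
  pp <- normalize_probing(pp, reg)
  expect_equal(structure_concordance(pp, models$pseudoknot, reg), 1.0)

  # a model pairing exactly the cleaved positions scores -1
  inverted <- structure_model("inverted", list(X = rbind(c(83, 90))))
  expect_equal(structure_concordance(pp, inverted, reg), -1.0)

  # pseudoknot-generated profiles prefer the pseudoknot over the old model
  for (s in 1:20) {
    ppn <- normalize_probing(
      simulate_probing(models$pseudoknot, reg, flex_paired = 0.05,
                       noise_cv = 0.2, seed = s), reg)
    expect_gt(structure_concordance(ppn, models$pseudoknot, reg),
              structure_concordance(ppn, models$old, reg))
  }
})

test_that("probing profiles round-trip through TSV", {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(position = 1:3, background = rep(50, 3),
                   t3 = c(60, 52, 80), t6 = c(70, 55, 110),
                   t12 = c(85, 49, 160), t24 = c(100, 50, 200))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_probing_tsv(tmp)
  expect_equal(prof$timepoints, c(3, 6, 12, 24))
  norm <- normalize_probing(prof, region_spec("1-3"))$normalized
  expect_equal(unname(norm), c(1 / 3, 0, 1))
})

test_that("shipped structure models satisfy their declared invariants", {
  expect_identical(
    unname(as.matrix(models$pseudoknot$stems$P8)),
    cbind(11:16, 89:84))
  # mutually exclusive topologies: old distal P7 is broken in the evolved
  # fixture while P8 is intact, and the proximal P7 holds in both
  expect_equal(validate_stem(fx$polymerase_ref, models$old,
                             "P7_distal")$n_watson_crick, 0L)
  expect_equal(validate_stem(fx$polymerase_ref, models$old,
                             "P7_proximal")$n_watson_crick, 6L)
})
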