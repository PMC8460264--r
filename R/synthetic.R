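#' Read error model for simulated polymerization products
#'
#' Per-position substitution, deletion and per-junction insertion
#' probabilities, a conditional substitution matrix over incorporated bases
#' given the template base (default uniform over the three mismatches, with
#' an optional G*U wobble bias via [wobble_sub_matrix()]), and a geometric
#' truncation (stop) probability per extension step.
#'
#' @param sub_rate Substitution probability per position (scalar or vector
#'   over reference positions).
#' @param sub_matrix 4x4 row-stochastic matrix over incorporated bases given
#'   the template base (diagonal must be zero).
#' @param ins_rate Insertion probability per junction.
#' @param del_rate Deletion probability per position.
#' @param truncation Stop probability after each extension step (0 = all
#'   full length).
#' @param seed Integer seed recorded with the model.
#' @return An `error_model`.
#' @export
error_model <- function(sub_rate = 0, sub_matrix = uniform_sub_matrix(),
                        ins_rate = 0, del_rate = 0, truncation = 0,
                        seed = 1L) {
  stopifnot(all(sub_rate >= 0), all(sub_rate < 1),
            ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1,
            truncation >= 0, truncation < 1)
  stopifnot(all(abs(rowSums(sub_matrix) - 1) < 1e-12),
            all(diag(sub_matrix) == 0))
  structure(list(sub_rate = sub_rate, sub_matrix = sub_matrix,
                 ins_rate = ins_rate, del_rate = del_rate,
                 truncation = truncation, seed = as.integer(seed)),
            class = "error_model")
}

#' Uniform substitution matrix
#'
#' Each template base substitutes uniformly to the three other bases.
#' @return 4x4 row-stochastic matrix.
#' @export
uniform_sub_matrix <- function() {
  m <- matrix(1 / 3, 4, 4, dimnames = list(template = BASES, read = BASES))
  diag(m) <- 0
  m
}

#' Wobble-biased substitution matrix
#'
#' U -> G and G -> U misincorporations (the G*U wobble-pairing signature)
#' are weighted `fold` times the other substitutions.
#'
#' @param fold Relative weight of the wobble cells (default 5).
#' @return 4x4 row-stochastic matrix.
#' @export
wobble_sub_matrix <- function(fold = 5) {
  m <- matrix(1, 4, 4, dimnames = list(template = BASES, read = BASES))
  diag(m) <- 0
  m["U", "G"] <- fold
  m["G", "U"] <- fold
  sweep(m, 1, rowSums(m), "/")
}

#' Expected wobble fraction under an error model
#'
#' Closed-form expectation of [mutation_spectrum()]'s `wobble_fraction` for
#' reads simulated from `ref` under `model` with uniform per-position
#' substitution rate: the template-base composition weights each row of the
#' substitution matrix.
#'
#' @param ref Reference sequence.
#' @param model An `error_model`.
#' @return Expected wobble fraction.
#' @export
expected_wobble_fraction <- function(ref, model) {
  comp <- table(factor(strsplit(as_residues(ref), "")[[1]], levels = BASES))
  comp <- as.numeric(comp) / sum(comp)
  names(comp) <- BASES
  # a uniform sub_rate cancels from numerator and denominator
  wob <- comp["U"] * model$sub_matrix["U", "G"] +
    comp["G"] * model$sub_matrix["G", "U"]
  unname(wob / sum(comp * rowSums(model$sub_matrix)))
}

#' Simulate ribozyme-synthesized product reads
#'
#' Draws `n` independent reads from the reference under the error model:
#' extension stops after each position with probability `truncation`
#' (geometric partial-length structure, 5'-anchored); each synthesized
#' position is deleted with probability `del_rate`, else substituted with
#' probability `sub_rate` via the substitution matrix; one uniform base is
#' inserted after each internal junction with probability `ins_rate`.
#' Qualities are uniform Phred 40.
#'
#' @param ref Reference `rna_seq` or character.
#' @param model An `error_model` (its `seed` drives the RNG).
#' @param n Number of reads.
#' @return A `read_set`.
#' @export
simulate_products <- function(ref, model, n) {
  stopifnot(n >= 1)
  f <- as_residues(ref)
  L <- nchar(f)
  ref_chars <- strsplit(f, "", fixed = TRUE)[[1]]
  set.seed(model$seed)
  tlen <- if (model$truncation > 0)
    pmin(L, rgeom(n, model$truncation) + 1L) else rep(L, n)
  sub_rate <- if (length(model$sub_rate) == 1L)
    rep(model$sub_rate, L) else model$sub_rate
  stopifnot(length(sub_rate) == L)
  mat <- matrix(rep(ref_chars, each = n), nrow = n)
  live <- outer(tlen, seq_len(L), ">=")
  u_del <- matrix(runif(n * L), n, L)
  del <- live & u_del < model$del_rate
  u_sub <- matrix(runif(n * L), n, L)
  sub <- live & !del & sweep(u_sub, 2, sub_rate, "<")
  # substitution targets via per-template-base conditional distribution
  if (any(sub)) {
    u_pick <- matrix(runif(n * L), n, L)
    for (b in BASES) {
      cols <- which(ref_chars == b)
      if (!length(cols)) next
      cum <- cumsum(model$sub_matrix[b, ])
      idx <- which(sub[, cols, drop = FALSE], arr.ind = TRUE)
      if (!nrow(idx)) next
      u <- u_pick[, cols, drop = FALSE][idx]
      pick <- BASES[findInterval(u, cum) + 1L]
      mcols <- mat[, cols, drop = FALSE]
      mcols[idx] <- pick
      mat[, cols] <- mcols
    }
  }
  mat[del] <- ""
  mat[!live] <- ""
  if (model$ins_rate > 0) {
    u_ins <- matrix(runif(n * L), n, L)
    ins <- u_ins < model$ins_rate &
      outer(tlen, seq_len(L), function(tl, j) j < tl)  # internal junctions
    if (any(ins)) {
      ib <- matrix("", n, L)
      ib[ins] <- sample(BASES, sum(ins), replace = TRUE)
      mat <- matrix(paste0(mat, ib), n, L)
    }
  }
  seqs <- do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
  ok <- nchar(seqs) > 0L
  read_set(seqs[ok], quals = 40L,
           ids = sprintf("sim%06d", which(ok)))
}

#' Population model for the evolving P7/P8 region
#'
#' Genotypes are carried as full-length sequences (their region keys are
#' recovered downstream by the tracking pipeline itself). Expected
#' per-round frequencies follow either explicit `trajectories` or a
#' selection-mutation update: p'_i proportional to p_i w_i, then mutation
#' moves mass between genotypes at `mut_rate` per base (renormalized over
#' the tracked genotypes); reads are then drawn multinomially.
#'
#' @param genotypes Named character vector (or list of `rna_seq`) of
#'   full-length genotype sequences.
#' @param fitness Positive per-genotype weights (selection-mutation mode).
#' @param init_freq Initial frequencies (default uniform).
#' @param trajectories Optional rounds x genotypes matrix of expected
#'   frequencies (rows renormalized), overriding the dynamic update.
#' @param mut_rate Per-base per-round mutation probability.
#' @param pop_size Reads sampled per round.
#' @param n_rounds Number of rounds.
#' @param rounds Round numbers (default `1:n_rounds`).
#' @param seed Integer seed.
#' @return A `population_model`.
#' @export
population_model <- function(genotypes, fitness = NULL, init_freq = NULL,
                             trajectories = NULL, mut_rate = 0,
                             pop_size = 10000, n_rounds = NULL,
                             rounds = NULL, seed = 1L) {
  if (is.list(genotypes))
    genotypes <- vapply(genotypes, as_residues, character(1))
  genotypes <- vapply(genotypes, normalize_residues, character(1))
  K <- length(genotypes)
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
    names(genotypes) <- paste0("g", seq_len(K))
  if (!is.null(trajectories)) {
    trajectories <- as.matrix(trajectories)
    stopifnot(ncol(trajectories) == K, all(trajectories >= 0))
    trajectories <- sweep(trajectories, 1, rowSums(trajectories), "/")
    n_rounds <- nrow(trajectories)
  } else {
    if (is.null(fitness)) fitness <- rep(1, K)
    stopifnot(length(fitness) == K, all(fitness > 0))
    if (is.null(init_freq)) init_freq <- rep(1 / K, K)
    stopifnot(length(init_freq) == K, abs(sum(init_freq) - 1) < 1e-8)
    if (is.null(n_rounds)) stop("n_rounds required without trajectories")
  }
  if (is.null(rounds)) rounds <- seq_len(n_rounds)
  stopifnot(length(rounds) == n_rounds, mut_rate >= 0, mut_rate < 1)
  structure(list(genotypes = genotypes, fitness = fitness,
                 init_freq = init_freq, trajectories = trajectories,
                 mut_rate = mut_rate, pop_size = pop_size,
                 n_rounds = as.integer(n_rounds),
                 rounds = as.integer(rounds), seed = as.integer(seed)),
            class = "population_model")
}

#' Expected (pre-sampling) genotype trajectory of a population model
#'
#' Deterministic per-round expected frequencies: explicit trajectories if
#' given, otherwise the selection-mutation update. Every row is a proper
#' simplex.
#'
#' @param model A `population_model`.
#' @return Matrix rounds x genotypes of expected frequencies.
#' @export
expected_trajectory <- function(model) {
  K <- length(model$genotypes)
  if (!is.null(model$trajectories)) {
    out <- model$trajectories
    dimnames(out) <- list(model$rounds, names(model$genotypes))
    return(out)
  }
  # per-base mutation kernel between tracked genotypes, renormalized
  L <- nchar(model$genotypes[1])
  M <- diag(K)
  if (model$mut_rate > 0 && K > 1) {
    d <- outer(seq_len(K), seq_len(K), Vectorize(function(i, j)
      sum(strsplit(model$genotypes[i], "")[[1]] !=
            strsplit(model$genotypes[j], "")[[1]])))
    M <- (model$mut_rate / 3)^d * (1 - model$mut_rate)^(L - d)
    M <- sweep(M, 1, rowSums(M), "/")
  }
  p <- model$init_freq
  out <- matrix(0, model$n_rounds, K,
                dimnames = list(model$rounds, names(model$genotypes)))
  for (r in seq_len(model$n_rounds)) {
    p <- p * model$fitness
    p <- p / sum(p)
    p <- as.numeric(p %*% M)
    p <- p / sum(p)
    out[r, ] <- p
  }
  out
}

#' Simulate per-round population samples
#'
#' Multinomial sampling of `pop_size` reads per round from the expected
#' trajectory; reads are exact copies of their genotype sequence at Phred
#' 40, shuffled within each round.
#'
#' @param model A `population_model`.
#' @return List with `samples` (list of `round_sample`), `expected`
#'   (rounds x genotypes), `sampled_freq` (realized frequencies).
#' @export
simulate_rounds <- function(model) {
  expected <- expected_trajectory(model)
  K <- length(model$genotypes)
  set.seed(model$seed)
  samples <- vector("list", model$n_rounds)
  sampled <- expected * 0
  for (r in seq_len(model$n_rounds)) {
    cnt <- as.integer(rmultinom(1, model$pop_size, expected[r, ]))
    sampled[r, ] <- cnt / model$pop_size
    seqs <- rep(unname(model$genotypes), cnt)
    seqs <- seqs[sample.int(length(seqs))]
    samples[[r]] <- round_sample(model$rounds[r],
                                 read_set(seqs, quals = 40L))
  }
  list(samples = samples, expected = expected, sampled_freq = sampled)
}

#' Simulate an in-line probing profile from a structure model
#'
#' Spontaneous phosphodiester cleavage accumulates with incubation time and
#' is faster at flexible, unpaired positions: raw counts are
#' `background + flex(position) * scale * t/24` with multiplicative
#' lognormal noise of coefficient of variation `noise_cv`; `flex` is
#' `flex_unpaired` at unpaired positions and `flex_paired` at paired ones.
#' The background lane receives the background counts under the same noise.
#'
#' @param model A `structure_model` (defines pairedness).
#' @param region `region_spec` of the simulated positions.
#' @param flex_unpaired,flex_paired Relative flexibilities
#'   (`flex_unpaired > flex_paired >= 0`).
#' @param background Background counts per position.
#' @param scale Count scale of the cleavage signal (default 1000).
#' @param noise_cv Coefficient of variation of the lognormal noise.
#' @param seed Integer seed.
#' @param variant Variant label.
#' @return A `probing_profile` (raw; normalize with [normalize_probing()]).
#' @export
simulate_probing <- function(model, region, flex_unpaired = 1,
                             flex_paired = 0, background = 50,
                             scale = 1000, noise_cv = 0, seed = 1L,
                             variant = model$name) {
  stopifnot(flex_unpaired > flex_paired, flex_paired >= 0)
  pos <- region_positions(region)
  paired_pos <- unlist(lapply(model$stems, as.vector))
  flex <- ifelse(pos %in% paired_pos, flex_paired, flex_unpaired)
  tp <- c(3, 6, 12, 24)
  set.seed(seed)
  noise <- function(n) {
    if (noise_cv == 0) return(rep(1, n))
    sdl <- sqrt(log(1 + noise_cv^2))
    rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  raw <- sapply(tp, function(h)
    (background + flex * scale * h / 24) * noise(length(pos)))
  bg <- background * noise(length(pos))
  probing_profile(pos, raw, bg, timepoints = tp, variant = variant)
}

#' Simulate a kinetic time course with known truth
#'
#' Evaluates the burst-exponential or linear model at the given times and
#' adds Gaussian noise; fraction data are clipped to \[0, 1\].
#'
#' @param truth List: either `list(model = "burst_exponential", A_b, A_s,
#'   k_obs)` (rates per minute) or `list(model = "linear", slope, unit)`
#'   with slope per `unit`.
#' @param times Time values.
#' @param unit Time unit of `times`.
#' @param kind Value kind.
#' @param noise_sd Gaussian noise SD (0 = noiseless).
#' @param seed Integer seed.
#' @return A `time_course`.
#' @export
simulate_timecourse <- function(truth, times, unit = "min",
                                kind = c("fraction", "mean_nt"),
                                noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  t_min <- times * time_unit_factor(unit)
  v <- if (truth$model == "burst_exponential") {
    burst_exponential_value(t_min, truth$A_b, truth$A_s, truth$k_obs)
  } else if (truth$model == "linear") {
    # slope is per truth$unit; evaluate on times expressed in that unit
    truth$slope * t_min / time_unit_factor(truth$unit)
  } else stop("unknown truth model")
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  if (kind == "fraction") v <- pmin(pmax(v, 0), 1)
  time_course(times, v, unit = unit, kind = kind)
}
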