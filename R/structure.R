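#' Secondary-structure model
#'
#' A named set of stems, each an ordered list of (5' position, 3' position)
#' base pairs in the reference numbering. Two models ship with the package
#' (see [load_structure_models()]): `"old"`, the original P7 stem-loop with
#' its distal pairs, and `"pseudoknot"`, in which the former J1/3 strand
#' pairs with the former distal P7 strand to form the six-pair P8 stem.
#'
#' @param name Model name.
#' @param stems Named list of two-column matrices (pos5, pos3).
#' @return A `structure_model`.
#' @export
structure_model <- function(name, stems) {
  stems <- lapply(stems, function(s) {
    s <- matrix(as.integer(s), ncol = 2)
    colnames(s) <- c("pos5", "pos3")
    if (any(s[, 1] >= s[, 2])) stop("pos5 must be < pos3 in every pair")
    s
  })
  all_pos <- unlist(lapply(stems, as.vector))
  if (anyDuplicated(all_pos))
    stop("a position appears in more than one pair of the model")
  structure(list(name = name, stems = stems), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %s\n", x$name,
              paste(sprintf("%s (%d bp)", names(x$stems),
                            vapply(x$stems, nrow, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Load the shipped structure models
#'
#' Reads the declarative stem table (model, stem, pos5, pos3) from
#' `inst/extdata/structure_models.tsv`, editable without code changes.
#'
#' @param path Optional path to an alternative stem table.
#' @return Named list of `structure_model` objects.
#' @export
load_structure_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "structure_models.tsv", package = "riboevo")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (m in unique(df$model)) {
    sub <- df[df$model == m, ]
    stems <- lapply(split(sub, sub$stem), function(s)
      cbind(pos5 = s$pos5, pos3 = s$pos3))
    out[[m]] <- structure_model(m, stems)
  }
  out
}

#' Classify a base pair
#'
#' Watson-Crick for A:U, U:A, G:C, C:G; wobble for G:U, U:G; otherwise
#' unpaired. Symmetric in its arguments.
#'
#' @param a,b Single bases in \{A, C, G, U\}.
#' @return One of `"watson_crick"`, `"wobble"`, `"unpaired"`.
#' @export
classify_pair <- function(a, b) {
  if (!(a %in% BASES) || !(b %in% BASES))
    stop(sprintf("invalid base(s): %s, %s", a, b))
  key <- paste0(sort(c(a, b)), collapse = "")
  if (key %in% c("AU", "CG")) return("watson_crick")
  if (key == "GU") return("wobble")
  "unpaired"
}

#' Evaluate a stem in a sequence variant
#'
#' Classifies every pair of the stem in the given sequence and counts the
#' Watson-Crick pairs. Compensatory double mutants that swap one WC pair
#' for another restore the full count, the covariation signature.
#'
#' @param seq `rna_seq` or character.
#' @param model A `structure_model`.
#' @param stem Stem name within the model.
#' @return List with `n_watson_crick` and a data frame `pairs`
#'   (pos5, pos3, base5, base3, class).
#' @export
validate_stem <- function(seq, model, stem) {
  if (!(stem %in% names(model$stems)))
    stop(sprintf("stem '%s' not in model '%s'", stem, model$name))
  s <- as_residues(seq)
  pr <- model$stems[[stem]]
  if (max(pr) > nchar(s)) stop("stem positions beyond sequence end")
  b5 <- substring(s, pr[, 1], pr[, 1])
  b3 <- substring(s, pr[, 2], pr[, 2])
  cls <- mapply(classify_pair, b5, b3, USE.NAMES = FALSE)
  list(n_watson_crick = sum(cls == "watson_crick"),
       pairs = data.frame(pos5 = pr[, 1], pos3 = pr[, 2],
                          base5 = b5, base3 = b3, class = cls,
                          stringsAsFactors = FALSE))
}

#' Verdict on disruptive/compensatory mutation support for a pair
#'
#' Relative activities (fractions of the reference polymerase's activity)
#' of the wild type, the two single mutants and the compensatory double
#' mutant are turned into a covariation verdict: `not_disruptive` if both
#' singles retain more than wt/`disrupt_fold`; otherwise
#' `covariation_supported` if the double recovers at least
#' `restore_frac` of wt, `partially_restored` if at least 0.1 of wt, else
#' `not_restored`.
#'
#' @param rel_activity_wt,rel_single5,rel_single3,rel_double Non-negative
#'   relative activities.
#' @param disrupt_fold Disruption threshold (default 50-fold).
#' @param restore_frac Restoration threshold (default 0.5).
#' @return A `pair_support` list with the activities and `verdict`.
#' @export
assess_pair_support <- function(rel_activity_wt, rel_single5, rel_single3,
                                rel_double, disrupt_fold = 50,
                                restore_frac = 0.5) {
  acts <- c(rel_activity_wt, rel_single5, rel_single3, rel_double)
  if (any(acts < 0)) stop("activities must be non-negative")
  wt <- rel_activity_wt
  verdict <- if (rel_single5 > wt / disrupt_fold &&
                 rel_single3 > wt / disrupt_fold) "not_disruptive"
    else if (rel_double >= restore_frac * wt) "covariation_supported"
    else if (rel_double >= 0.1 * wt) "partially_restored"
    else "not_restored"
  structure(list(rel_activity_wt = wt, rel_single5 = rel_single5,
                 rel_single3 = rel_single3, rel_double = rel_double,
                 verdict = verdict), class = "pair_support")
}

#' In-line probing profile
#'
#' Raw band counts per position and incubation timepoint, with background
#' counts from the unincubated lane; [normalize_probing()] fills the
#' `normalized` field.
#'
#' @param positions Integer reference positions.
#' @param raw Matrix positions x timepoints of raw counts.
#' @param background Numeric background counts per position.
#' @param timepoints Incubation times in hours (default 3, 6, 12, 24).
#' @param variant Variant label.
#' @return A `probing_profile`.
#' @export
probing_profile <- function(positions, raw, background,
                            timepoints = c(3, 6, 12, 24), variant = "variant") {
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) == length(positions),
            ncol(raw) == length(timepoints),
            length(background) == length(positions))
  colnames(raw) <- timepoints
  structure(list(variant = variant, positions = as.integer(positions),
                 raw = raw, background = as.numeric(background),
                 timepoints = timepoints, normalized = NULL),
            class = "probing_profile")
}

#' Normalize probing intensities over a region
#'
#' Raw counts at the chosen timepoint are background-corrected (negative
#' corrected counts clamp to zero) and scaled to the position within the
#' region of interest with the highest level of cleavage, so the maximum
#' normalized cleavage in the region is 1. An all-zero corrected region
#' yields an all-zero profile with a warning.
#'
#' @param profile A `probing_profile`.
#' @param region `region_spec` of the region of interest.
#' @param timepoint Timepoint in hours (default 24).
#' @return The profile with `normalized` filled (named by position).
#' @export
normalize_probing <- function(profile, region, timepoint = 24) {
  tp <- match(timepoint, profile$timepoints)
  if (is.na(tp)) stop(sprintf("timepoint %s hr not present", timepoint))
  pos <- region_positions(region)
  idx <- match(pos, profile$positions)
  if (anyNA(idx)) stop("region positions missing from the profile")
  corrected <- pmax(profile$raw[, tp] - profile$background, 0)
  mx <- max(corrected[idx])
  if (mx == 0) {
    warning("all corrected counts are zero over the region")
    norm <- rep(0, length(profile$positions))
  } else {
    norm <- corrected / mx
  }
  profile$normalized <- setNames(norm, profile$positions)
  profile$region <- region
  profile
}

#' Concordance between a probing profile and a structure model
#'
#' Point-biserial (Pearson) correlation over the region between
#' per-position pairedness under the model (1 = in a stem pair) and
#' protection from cleavage (1 - normalized cleavage). Higher scores mean
#' the model better explains the observed protection pattern; the score is
#' antisymmetric under complementing the pairedness vector.
#'
#' @param profile A normalized `probing_profile`.
#' @param model A `structure_model`.
#' @param region `region_spec` over which to score.
#' @return Correlation in \[-1, 1\], or NA for zero-variance inputs.
#' @export
structure_concordance <- function(profile, model, region) {
  if (is.null(profile$normalized))
    stop("profile must be normalized first (normalize_probing)")
  pos <- region_positions(region)
  idx <- match(pos, profile$positions)
  if (anyNA(idx)) stop("region positions missing from the profile")
  paired_pos <- unlist(lapply(model$stems, as.vector))
  paired <- as.numeric(pos %in% paired_pos)
  protection <- 1 - profile$normalized[idx]
  if (stats::sd(paired) == 0 || stats::sd(protection) == 0) return(NA_real_)
  unname(cor(paired, protection))
}

#' Read probing band counts from TSV
#'
#' Expected columns: `position`, `background`, then one count column per
#' timepoint named `t<hours>` (e.g. `t3 t6 t12 t24`).
#'
#' @param path TSV path.
#' @param variant Variant label.
#' @return A `probing_profile`.
#' @export
read_probing_tsv <- function(path, variant = "variant") {
  df <- utils::read.delim(path)
  tc <- grep("^t[0-9]+$", names(df), value = TRUE)
  probing_profile(df$position, as.matrix(df[tc]), df$background,
                  timepoints = as.numeric(sub("^t", "", tc)),
                  variant = variant)
}
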