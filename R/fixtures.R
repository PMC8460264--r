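filler_seq <- function(n, pattern) {
  substr(strrep(pattern, ceiling(n / nchar(pattern))), 1, n)
}

#' Synthetic reference fixtures
#'
#' Reference sequences used by the simulators and tests. These are
#' synthetic representatives satisfying the structural constraints of the
#' system, not copies of any deposited sequence:
#' \itemize{
#'   \item `hammerhead_ref`: a 33-nt hammerhead-like synthesis target.
#'   \item `ligase_ref`: a 76-nt ligase-core stand-in (at ~84% per-position
#'     fidelity a product of this length carries ~12 mutations on average).
#'   \item `polymerase_ref`: a 182-nt polymerase-like reference in which the
#'     P8 stem (pairs 11-89, 12-88, 13-87, 14-86, 15-85, 16-84) is fully
#'     Watson-Crick, the proximal P7 stem (73-78 paired with 91-96) is
#'     intact, position 90 is an unpaired A, and the old-model distal P7
#'     pairs (80-89, 81-88, 82-87) are not satisfied -- the evolved
#'     pseudoknot configuration.
#'   \item `region`: the tracked P7/P8 region, nucleotides 9-17 and 83-95.
#'   \item `region5`, `region3`: the 5'- and 3'-strand sub-regions used for
#'     strand-correlation analyses.
#'   \item `printed_template`: the favorable 11-nt template repeat
#'     UGCGAAGCGUG.
#' }
#'
#' @return Named list of fixtures.
#' @export
riboevo_fixtures <- function() {
  hammerhead <- rna_seq("GGAUGUACUGAUGAGGCCGUUAGGCCGAAACAU",
                        id = "hammerhead_33nt_synthetic")
  ligase <- rna_seq(filler_seq(76, "GGACUCAUCGUAAGCUGACCGUU"),
                    id = "ligase_76nt_synthetic")
  pol <- paste0(
    "GGACUCAU",              # 1-8
    "UA",                    # 9-10
    "GCACCA",                # 11-16  P8 5' strand
    "A",                     # 17     (A-run at the 17/18 junction)
    filler_seq(55, "GGCUACGUCAAGCUG"),  # 18-72
    "GGCGCC",                # 73-78  P7 proximal 5'
    "A",                     # 79
    "AAC",                   # 80-82  old-model distal positions, unpaired here
    "A",                     # 83
    "UGGUGC",                # 84-89  P8 3' strand
    "A",                     # 90     unpaired, cleavage-sensitive
    "GGCGCC",                # 91-96  P7 proximal 3'
    filler_seq(86, "CAGUCGAUGCAAGUC"))  # 97-182
  polymerase <- rna_seq(pol, id = "polymerase_182nt_synthetic")
  stopifnot(nchar(hammerhead$residues) == 33L,
            nchar(polymerase$residues) == 182L)
  list(
    hammerhead_ref = hammerhead,
    ligase_ref = ligase,
    polymerase_ref = polymerase,
    region = region_spec("9-17,83-95", name = "P7P8", ref_length = 182L),
    region5 = region_spec("9-17", name = "P8_5prime", ref_length = 182L),
    region3 = region_spec("83-95", name = "P8_3prime", ref_length = 182L),
    printed_template = rna_seq("UGCGAAGCGUG", id = "favorable_template"))
}
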