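---
title: "Methods: fidelity, population tracking, structure and kinetics of an evolving polymerase ribozyme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fidelity, population tracking, structure and kinetics of an evolving polymerase ribozyme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboevo)
```

# The system

An RNA polymerase ribozyme — a catalytic RNA that extends an RNA primer on
an RNA template using NTPs — is subjected to successive rounds of in vitro
evolution, selecting for the ability to synthesize a functional 33-nt
hammerhead ribozyme under decreasing Mg^2+^ concentrations. Over the course
of evolution the catalytic core rearranges: the distal portion of the P7
stem-loop and the former J1/3 joining strand pair with each other to form a
new six-base-pair stem, P8, creating a pseudoknot adjacent to the active
site. `riboevo` implements the computational analyses that trace this
process:

1. **Fidelity** — per-template-position classification of matches,
   mismatches, insertions and deletions in deep-sequenced synthesis
   products, giving average copying fidelity, the mutation spectrum and
   Levenshtein-distance distributions.
2. **Population tracking** — quality filtering, extraction of the P7/P8
   region (reference nucleotides 9–17 and 83–95), greedy clustering at 100%
   identity with two-nucleotide terminal slack, cluster-equivalence
   merging, frequency tracking across rounds, and 5′/3′ strand-variant
   correlation.
3. **Structure and covariation** — declarative secondary-structure models
   (old P7 stem-loop versus the P7+P8 pseudoknot), Watson–Crick/wobble pair
   classification, disruptive/compensatory mutation verdicts, and in-line
   probing quantitation mapped onto the models.
4. **Kinetics** — burst-phase exponential fits, linear initial-rate fits,
   and catalyzed/uncatalyzed rate comparison.
5. **Synthetic data** — generators with known ground truth for every input,
   so the whole pipeline runs and is tested without any external download.

All coordinates are 1-based and inclusive, in the numbering of the evolved
polymerase; insertions are anchored to the reference position they follow
(`ins88_89:CA` inserts CA between positions 88 and 89).

# Alignment and fidelity

Product reads are 5′-anchored at the primer, and synthesis frequently stops
early, so reads are aligned **semi-globally**: the read aligns globally
from its 5′ end while gaps over the uncovered 3′ tail of the reference are
free. Uncovered positions are truncation, not deletion, and do not enter
coverage. The scoring scheme is match +1, mismatch −1, gap −2 with linear
gap costs — the simplest scheme that separates truncation from internal
deletion. Among equal-scoring alignments the traceback prefers a mismatch
over an indel and then a fixed gap-placement order, making results
deterministic. The implementation (C++ dynamic programming) is verified in
the test suite against an independent recursive enumeration oracle over
random sequence pairs.

Per-position tallies obey the conservation law
`matches + mismatches + deletions = coverage` at every position, asserted
on every tally. **Average fidelity** is coverage-weighted:
total matches over total covered positions. Insertions live on junctions
between positions; they are excluded from the positional denominator and
reported as a separate per-covered-position rate
(`average_fidelity(..., mode = "with_insertions")` folds them into the
error numerator for sensitivity analysis, and `per_position_mean = TRUE`
gives the unweighted alternative). Coverage weighting is stable when
partial-length products are included; for ligase-style analyses
`full_length_only = TRUE` restricts the tally to reads whose aligned span
reaches the final reference position.

The mutation spectrum reports the 12 template→read substitution rates, and
a `wobble_fraction`: the share of mismatches that are template U read as G
or template G read as U, the signature of G•U wobble pairing during
synthesis, which is the dominant error mode in this system.

**Known limitation — parsimony bias.** A maximum-score alignment explains
clustered errors with the fewest events consistent with the sequences. At
moderate error rates (≤ ~10% per position) the per-position error estimates
recover simulated truth within three binomial standard errors at
n = 50,000 reads. At the ligase condition (~16% per position) the pooled
fidelity estimate sits a few tenths of a percentage point above the
generating truth, because some multi-error configurations admit
fewer-error explanations. This is inherent to alignment-based error
calling, affects any pipeline of this design, and is measured and asserted
at its observed magnitude in the test suite. Levenshtein distances are
computed on the product region as aligned, not on primer-derived bases.

# Population tracking

Reads are filtered to length strictly greater than 150 nt and mean Phred
score strictly greater than 33. The mean-quality reading was chosen because
a per-base minimum at Q33 would discard nearly all real data;
`phred_mode = "min"` provides the stricter interpretation. FASTA input
(no qualities) skips the Phred criterion with a warning, and reads
containing ambiguous calls are dropped with a logged count — the analyses
operate on called bases only.

The tracked region (nucleotides 9–17 and 83–95) is extracted by
reference-anchored pairwise alignment and coordinate projection, replacing
a multiple-alignment-plus-manual-trimming workflow with an equivalent,
dependency-free procedure. Insertions anchored strictly inside an interval
enter the region key; deletions shorten it; reads that do not fully span
the region are discarded and counted.

Clustering follows cd-hit-est semantics at 100% identity (`-c 1.0`) with a
maximum unmatched terminal length of two (`-U 2`) and a length-difference
cutoff of two (`-S 2`): a key joins a cluster representative exactly when
one is a contiguous substring of the other and the lengths differ by at
most two. Keys are processed in descending abundance (ties
lexicographic) — for fixed-length region keys abundance order is more
stable than the length order cd-hit uses, and it makes the representative
the most abundant member by construction.

Two clusters are **equivalent** and merged when their representatives
differ only by the length of the A homopolymer at the 17/18 junction, or by
a single substitution outside positions 11–16 and 84–89 (the conserved P8
cores). Merging sums counts and keeps the most abundant representative;
it can only increase each round's retained fraction.

Clusters are matched across rounds by their representative key under the
same join rule — the original analysis is silent on cross-round matching
after independent per-round clustering runs, so exact-key matching with
the same slack is this package's documented choice. Retention rules:
a cluster must exceed 1% frequency in at least one round, and clusters
observed in exactly one round at below 5% are ignored. Retained clusters
are named `"<round>.<rank>"` by the first round in which they exceeded 1%.
Frequencies are relative to the number of region keys extracted in the
round, so before retention filtering they sum to exactly 1.

Strand correlation computes, for each paired 5′/3′ variant, the Pearson
correlation of their frequency trajectories across rounds (NA for
zero-variance trajectories), quantifying whether complementary strand
variants rise and fall together.

# Structure models, covariation and probing

Structure models are declarative data (`inst/extdata/structure_models.tsv`),
editable without code changes. The pseudoknot model contains P8 with
exactly the pairs (11,89), (12,88), (13,87), (14,86), (15,85), (16,84) and
the proximal P7 pairs 73–78/91–96; the old model replaces P8 by the distal
P7 pairs (82,87), (81,88), (80,89) and keeps the same proximal P7. Pair
classification is Watson–Crick for A:U and G:C, wobble for G:U, unpaired
otherwise, and is symmetric.

`validate_stem()` counts Watson–Crick pairs of a stem in any sequence
variant: a single transversion in either strand removes one pair and the
corresponding compensatory double restores it, which is the covariation
logic used to test the P8 hypothesis. `assess_pair_support()` encodes the
activity-based verdicts: singles that both retain more than wt/50 are
`not_disruptive`; otherwise a double recovering ≥ 50% of wild type is
`covariation_supported`, ≥ 10% `partially_restored`, else `not_restored`.

In-line probing intensities are normalized as in the experimental
protocol: raw band counts at the chosen timepoint (default 24 hr) minus
the unincubated-lane background, clamped at zero (the protocol is silent
on over-subtraction), then scaled to the position with the highest
cleavage within the region of interest. The normalization is invariant
under a common rescaling of raw and background counts. Structure
concordance is the point-biserial correlation between per-position
pairedness under a model and protection (1 − normalized cleavage); it is
+1 when exactly the unpaired positions cleave, antisymmetric under
complementing the pairedness vector, and deliberately mechanism-free (no
in-line geometry or thermodynamic model; folding prediction is out of
scope).

# Kinetics

The burst model is F(t) = A~b~ + A~s~(1 − e^(−k~obs~ t)) with t in
minutes: A~b~ is the burst amplitude (fraction converted at t → 0+), A~s~
the slow-phase amplitude, k~obs~ the first-order rate constant. Fitting is
bounded Levenberg–Marquardt least squares. Starting values: A~b~ from the
earliest observation, A~s~ from the rise to the last observation, k~obs~
from the interpolated half-rise time, with a multi-start over
k~obs~ × {0.1, 1, 10}; the lowest-RSS fit wins, which makes noiseless
recovery deterministic (relative error < 10^−6^ in the tests). All
parameters are bounded below by zero, amplitudes above by one. Because
"the burst" can be read either as the amplitude A~b~ or as the fraction
converted within the first 10 s under the fitted model, both readouts are
reported (`burst_percent` and `fraction_at_10s`).

Time units (s, min, hr) are explicit on every time course and converted
internally to minutes; initial rates are reported per minute and ligation
rates per hour. The linear-regime window for ligation fits is an argument
defaulting to the full range — the source analyses do not state their fit
windows. Rate acceleration is k~cat~/k~uncat~ rounded to a stated number
of significant figures (default 2), with a unit-mismatch guard and
invariance under common rescaling.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised and tested:

* **Product reads** (`simulate_products`): per position, deletion with
  probability `del_rate`, else substitution with probability `sub_rate`
  through the substitution matrix (uniform by default;
  `wobble_sub_matrix(5)` weights U→G and G→U five-fold to emulate the
  wobble-dominated spectrum); one uniform base inserted per internal
  junction with probability `ins_rate`; geometric truncation with one stop
  probability per extension step. Qualities are constant Q40, since no
  downstream analysis is quality-aware beyond the filter. For the
  fidelity recovery checks the substitution rate is set to one minus the
  condition's stated fidelity (8.3% at 200 mM Mg^2+^, 5.6% at 50 mM) and
  50,000 reads are drawn.
* **Population rounds** (`simulate_rounds`): genotypes are full-length
  sequences (so region extraction is exercised end to end); expected
  frequencies follow either explicit trajectories or the
  selection–mutation update p′ ∝ p·w followed by a per-base mutation
  kernel renormalized over the tracked genotypes; reads are multinomial
  draws of `pop_size` per round. The tracking recovery checks use 14
  rounds of 10,000 reads with planted edge-case clusters at the 1% and 5%
  rule boundaries.
* **Probing lanes** (`simulate_probing`): counts are
  background + flexibility × scale × t/24 with multiplicative lognormal
  noise of a given CV; flexibility is high at unpaired and low at paired
  positions, reflecting that unstructured regions cleave faster.
* **Time courses** (`simulate_timecourse`): closed-form model values plus
  Gaussian noise, clipped to [0, 1] for fraction data.

All generators are seeded and bit-reproducible. What they deliberately do
**not** emulate: PCR amplification bias, chimera formation,
sequencer-specific error profiles, base-quality variation, and the
condition-dependent length distributions of real synthesis ladders
(truncation is a single geometric parameter). Passing recovery tests
therefore demonstrates correctness of the analysis logic under a clean
error model, not robustness to every artifact of real sequencing data.

The shipped reference fixtures (33-nt hammerhead-like target, 76-nt
ligase-core stand-in, 182-nt polymerase-like reference) are synthetic
representatives satisfying the published length and structural constraints
(P8 fully Watson–Crick, proximal P7 intact, old distal P7 broken, A90
unpaired); they are labeled synthetic and make no claim of sequence
identity with any deposited molecule. The ligase fixture length (76 nt)
was chosen so that at ~84% per-position fidelity a product carries ~12
mutations on average, matching the reported scale.

# Problem sizes and runtime

The default test suite and the acceptance script use: 50,000 reads per
fidelity condition (seconds per condition with the C++ aligner), 14 rounds
× 10,000 reads for tracking (reads deduplicate to a handful of genotype
sequences before alignment), 200 seeded noisy kinetic fits, 100 seeded
probing replicates, and 500 random alignment-oracle pairs. The whole suite
runs in well under a minute of compute.

# Known limitations

* Alignment parsimony bias at high error rates (quantified above).
* Cross-round cluster matching is exact-key with slack; a drifting
  representative that changes by more than the slack between adjacent
  rounds would start a new track.
* The equivalence-merge rules are specific to the P7/P8 region's
  coordinate conventions (junction 17/18, cores 11–16 and 84–89), though
  both are arguments.
* No ambiguity-code support: reads containing N are dropped, an assumption
  the source protocol leaves unstated.
* Probing concordance treats all unpaired positions as equally flexible;
  no mechanistic in-line geometry model.
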