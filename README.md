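# riboevo

Analysis pipeline for deep-sequencing and biochemical data from the
directed evolution of an RNA polymerase ribozyme — a catalytic RNA that
extends an RNA primer on an RNA template. As such a polymerase evolves,
three questions recur: how accurately does it copy a template, how does the
population of variants shift from round to round of selection, and which
secondary structure (here, an old P7 stem-loop versus a newly evolved
P7+P8 pseudoknot) do probing and covariation data support? `riboevo`
implements the computational side of all three, plus the kinetic fits used
to quantify activity, and a seeded synthetic-data generator so every stage
runs and is tested with no external data.

## What it computes

* **Copying fidelity.** Product reads are aligned to the reference
  template semi-globally (5′-anchored, free 3′-terminal reference gaps, so
  truncation is distinguished from internal deletion; match +1, mismatch
  −1, gap −2). Each reference position accumulates matches, mismatches by
  incorporated base, and deletions, with insertions on junctions. Average
  fidelity is coverage-weighted,

  fidelity = Σ matches / Σ (matches + mismatches + deletions),

  and the mutation spectrum reports the 12 substitution rates plus the
  wobble fraction — the share of mismatches that are template-U→G or
  template-G→U, the G•U wobble-pairing signature. Levenshtein-distance
  distributions summarize mutations per product.
* **Population tracking.** Reads are filtered (length > 150 nt, mean
  Phred > 33), the P7/P8 region (nucleotides 9–17 and 83–95) is extracted
  by alignment projection, and region keys are clustered greedily at 100%
  identity with two-nucleotide terminal slack (cd-hit-est `-c 1.0 -U 2
  -S 2` semantics). Clusters differing only by the A homopolymer at the
  17/18 junction or one substitution outside the conserved cores are
  merged; clusters must exceed 1% in some round, and single-round clusters
  below 5% are ignored. The result is a cluster × round frequency matrix
  and Pearson correlations between paired 5′/3′ strand-variant
  trajectories.
* **Structure and covariation.** Declarative stem models; Watson–Crick /
  wobble / unpaired classification; `validate_stem()` counts intact pairs
  in any mutant (singles disrupt, compensatory doubles restore);
  `normalize_probing()` background-corrects and max-scales in-line probing
  band counts; `structure_concordance()` correlates model pairedness with
  protection from cleavage.
* **Kinetics.** Burst-phase exponential F(t) = A_b + A_s(1 − e^(−k_obs t))
  by bounded multi-start least squares; linear initial rates (nt min⁻¹);
  ligation rates (hr⁻¹); and fold rate-acceleration at a stated number of
  significant figures.

See `vignettes/riboevo-methods.Rmd` for the full model and design notes.

## Worked example

```r
library(riboevo)
fx <- riboevo_fixtures()

# fidelity of simulated hammerhead synthesis at the 200 mM Mg2+ condition
em <- error_model(sub_rate = 1 - 0.917, sub_matrix = wobble_sub_matrix(5),
                  seed = 1)
reads <- simulate_products(fx$hammerhead_ref, em, 50000)
res <- run_fidelity(reads, fx$hammerhead_ref, condition = "200 mM Mg2+")
#> fidelity run: 50000 reads tallied, average fidelity 0.9170
res$spectrum$wobble_fraction
#> [1] 0.3917624

# the P8 stem of the evolved polymerase is fully Watson-Crick
models <- load_structure_models()
validate_stem(fx$polymerase_ref, models$pseudoknot, "P8")$n_watson_crick
#> [1] 6

# burst-phase kinetics recovered from a noiseless time course
tc <- simulate_timecourse(list(model = "burst_exponential", A_b = 0.18,
                               A_s = 0.6, k_obs = 0.031),
                          c(0.17, 0.5, 1, 2, 5, 10, 20, 40, 80, 120),
                          unit = "min")
fit_burst_exponential(tc)
#> <kinetic_fit> burst_exponential
#>   A_b   A_s k_obs
#> 0.180 0.600 0.031
#>   rss 1.77e-32 over 10 points

rate_acceleration(0.31, 0.00021)
#> <rate_comparison> 0.31 / 0.00021 hr^-1 = 1500-fold (2 s.f.)
```

The fidelity estimate (91.70%) recovers the configured simulation truth of
91.7%; the wobble fraction reflects the five-fold wobble bias configured in
the error model; the kinetic fit returns the generating burst amplitude
(18%), slow amplitude and rate constant exactly; and the two ligation
rates give a 1500-fold acceleration at two significant figures.

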