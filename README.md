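# aflpscan

Genome scans for divergent selection on dominant AFLP markers.

`aflpscan` is for population geneticists working with anonymous dominant
markers (AFLP presence/absence bands) in structured populations — the
classic setting of closely related colour morphotypes or ecotypes that
interbreed and show next to no genome-wide differentiation, sampled at
several locations where the same forms co-occur. The package finds loci
whose differentiation between forms exceeds neutral expectations
*repeatedly*, in independent locations, and separates candidate
selection-with-phenotype loci from candidate selection-with-geography loci.

## What it computes

For a dominant band with null-allele frequency *q*, band absence is the
homozygous-null phenotype with probability *q²* under Hardy–Weinberg.
From *x* band-absent individuals among *n*, the package estimates *q* as a
Bayesian posterior mean under a Beta prior fitted across loci, and builds
per-locus FST from variance components:

    FST = (s² − Σᵢ wᵢ vᵢ) / (q̄ (1 − q̄))

with the sample-size–weighted mean q̄, the k−1-divisor among-population
variance s², and the posterior variances vᵢ as the sampling-noise
correction. Multilocus means are ratios of summed components; pairwise
significance comes from permuting individuals (1000 permutations).

Outlier detection follows the fdist tradition: simulate dominant loci under
an island model at migration–drift equilibrium (Balding–Nichols frequencies,
ancestral distribution Beta(θ, θ) with θ = 4·Nₑ·µ; defaults Nₑ = 10⁴,
µ = 10⁻⁵, 50,000 loci, samples matched to the data), calibrate the
simulation so its 30%-trimmed mean FST closely matches — but never falls
below — the empirical trimmed mean, and flag observed loci in the upper tail
of the simulated FST distribution *conditional on heterozygosity*
(equal-count heterozygosity bins, mid-p tail probabilities, flags at
p ≤ 0.05 and p ≤ 0.01).

Loci flagged in **every** sympatric comparison of the same two morphotypes
in two or more locations are designated 95Sel/99Sel; loci flagged in all
allopatric same-morphotype comparisons of a morphotype but in none of its
sympatric comparisons are 95Geo/99Geo. Observed counts are tested against
the neutral expectation E = L·pᵐ with exact binomial tests, and repeated
outliers can be cross-tabulated against per-locus selection probabilities
from an independent method (support threshold 0.7).

Because AFLP field datasets of this design are rarely deposited, a
first-class synthetic generator (`generate_dataset()`,
`generate_peak_data()`) produces hierarchically structured
presence/absence surveys — by default 8 Caribbean locations × 5 colour
morphotypes, per-population n of 4–90, 436 loci, background FST ≈ 0.06
among locations and ≈ 0.058 between sympatric morphotypes — with planted
selected loci and known ground truth, plus raw peak heights with replicated
extractions for the scoring step.

## Worked example

Two locations where the same two morphotypes co-occur, 436 loci of which 20
are planted as divergently selected between the morphotypes (consistently
in both locations), 40 fish per population:

```r
library(aflpscan)

cfg <- synthetic_config(
  design = data.frame(location = rep(c("Curacao", "Panama"), each = 2),
                      morphotype = rep(c("chlorurus", "puella"), 2),
                      n = 40),
  n_loci = 436, n_selected_loci = 20,
  selected_pair = c("chlorurus", "puella"), selected_fst = 0.4,
  background_fst_location = 0.05, background_fst_morphotype = 0.05,
  seed = 42)
ds <- generate_dataset(cfg)

pops  <- morphotype_populations(ds$metadata)
pairs <- population_pairs(pops, "sympatric-different")
scans <- lapply(seq_len(nrow(pairs)), function(i)
  neutral_scan(ds$genotypes, ds$metadata, pairs[i, ],
               n_sim_loci = 20000, seed = 100 + i))

rep_out <- repeated_outliers(lapply(scans, `[[`, "outcome"),
                             c("chlorurus", "puella"), n_loci = 436)
```

Output for this seed:

```
chlorurus@Curacao vs puella@Curacao: trimmed mean FST 0.0133, 25/386 loci above the 95% envelope
chlorurus@Panama vs puella@Panama: trimmed mean FST 0.0136, 32/385 loci above the 95% envelope
95Sel loci: L020, L024, L074, L091, L110, L128, L169, L223, L228, L356, L370, L421
  (1.09 expected under neutrality, exact binomial p = 1.9e-09)
of these, 8 of 12 are planted selected loci
```

Reading it: each sympatric comparison flags 6–8% of loci at the 95% level
(the planted loci push this above the neutral 5%); twelve loci repeat in
*both* locations against an expectation of about one under neutrality
(binomial p ≈ 2×10⁻⁹), and eight of the twelve are genuinely planted —
repetition across locations concentrates true positives but does not
eliminate false ones, which is exactly why the design pairs it with an
independent consensus method (`consensus()`).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study design on a
synthetic survey shaped like the real one and write their tables under
`results/`:

1. `01_simulate_data.R` — generate the survey (matrix, metadata, truth,
   peak heights, replicate pairs);
2. `02_score_peaks.R` — optimise scoring thresholds against the double
   extractions and report repeatability (~97% at the default error model);
3. `03_population_differentiation.R` — pairwise multilocus FST with
   permutation significance for all sympatric and allopatric-same pairs;
4. `04_outlier_scan.R` — calibrated neutral-envelope scans per pair and the
   p-value balance diagnostic;
5. `05_repeated_outliers.R` — outlier-frequency table, Sel/Geo designation
   with exact binomial tests, and the consensus cross-tabulation.

Run them in order from the repository root (`Rscript analysis/01_simulate_data.R`,
and so on). The whole sequence takes a few minutes, most of it in the
permutation tests of step 3.

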