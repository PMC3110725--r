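---
title: "Detecting divergent selection on dominant AFLP markers: methods and design choices"
author: "aflpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting divergent selection on dominant AFLP markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflpscan)
```

## The problem

Closely related colour morphotypes that interbreed freely show almost no
genome-wide differentiation, yet individual loci tied to the diverging trait
can be strongly differentiated. A genome scan over anonymous dominant
markers (AFLPs) looks for such loci: markers whose differentiation between
morphotypes exceeds what neutral drift and sampling could plausibly produce,
*repeatedly*, in independent locations where the same two morphotypes
co-occur. Repetition across locations is the core design idea: a locus that
is an outlier between the same two colour forms at several reefs is unlikely
to be a type I error or a purely local event.

`aflpscan` implements that full design for binary presence/absence data:
threshold scoring of raw peak heights, Bayesian allele-frequency estimation
for dominant markers, multilocus FST with permutation significance, a
simulation-based neutral envelope conditional on heterozygosity, the
repeated-outlier ("Sel"/"Geo") classification, and a consensus step against
an independent per-locus analysis. A synthetic-data generator reproduces the
statistical shape of a multi-location, multi-morphotype survey so the whole
pipeline is testable without field data.

## Dominant markers and allele frequencies

An AFLP band is dominant: presence cannot distinguish heterozygotes from
presence-homozygotes, while absence implies the homozygous null genotype.
With null-allele frequency $q$ and Hardy-Weinberg proportions, an individual
lacks the band with probability $q^2$, so $x$ band-absent individuals among
$n$ give the likelihood $(q^2)^x (1-q^2)^{n-x}$. `bayes_allele_freq()`
returns the posterior mean (and variance) of $q$ under a Beta prior. This
Bayesian treatment avoids the degeneracies of the naive
$\hat q = \sqrt{x/n}$ estimator at $x = 0$ and weights information
correctly at small $n$.

The prior defaults to a Beta distribution fitted by method of moments to the
across-locus distribution of $\sqrt{x/n}$ (`fit_nonuniform_prior()`), i.e.
the data-driven prior variant customary for dominant-marker surveys; a
uniform prior is available. Fitted shapes are clamped to $[0.1, 100]$, and a
degenerate across-locus distribution falls back to the uniform prior with a
warning.

Posterior moments are computed by a fixed 4096-panel composite Simpson rule
with the prior folded into the integrand and a grid-doubling tolerance check
(relative $10^{-8}$). Fitted priors with a shape below 1 place an integrable
singularity at an endpoint that a fixed grid cannot represent; the doubling
check detects exactly those cases and they are refined by deterministic
adaptive quadrature. Everything is deterministic; tables over $x = 0..n$ are
cached per $(n, \text{prior})$.

## Per-locus and multilocus FST

For one locus with per-population estimates $\hat q_i$ (sample sizes $n_i$,
weights $w_i = n_i/\sum n_j$):

$$\bar q = \textstyle\sum_i w_i \hat q_i, \qquad
  s^2 = \frac{\sum_i n_i(\hat q_i - \bar q)^2}{(k-1)\,\bar n}, \qquad
  F_{ST} = \frac{s^2 - \sum_i w_i v_i}{\bar q (1 - \bar q)},$$

where $v_i$ is the sampling variance of $\hat q_i$. We use the posterior
variance of $q$ as $v_i$: it is the uncertainty the dominant-marker model
itself reports, and in simulation it makes the multilocus estimate
essentially unbiased over the background range of interest
($\theta = 0.02$-$0.10$ at $n = 40$), which the codominant textbook
correction $q(1-q)/2n$ does not (it under-corrects the larger sampling noise
of dominant data).

Three conventions matter downstream:

* negative per-locus values are retained - truncating them would bias the
  trimmed mean used for calibration;
* the multilocus mean is the ratio of summed variance components
  (numerator and denominator summed over loci), which is much less
  ratio-biased than averaging per-locus ratios;
* because the among-population variance uses the $k-1$ divisor (needed for
  the mean to be unbiased), a single locus in two populations fixed for
  opposite alleles takes the value $k/(k-1) = 2$. Per-locus values are
  variance-ratio estimates, not proportions; only their ensemble behaviour
  is interpretable.

Pairwise significance comes from permuting individuals between the two
populations and recomputing the multilocus mean (`permutation_test_fst()`;
default 1000 permutations, $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm}+1)$,
so $p$ is never zero). The prior is fitted once from the observed data and
held fixed across permutations.

## The neutral envelope

Outlier detection needs a null distribution of per-locus FST *given* the
locus's heterozygosity, because low-information loci produce wildly variable
estimates. `simulate_neutral_loci()` builds that null under an island model
at migration-drift equilibrium:

1. an ancestral presence frequency per locus from the stationary
   mutation-drift distribution $\mathrm{Beta}(\theta, \theta)$ with
   $\theta = 4 N_e \mu$ (defaults $N_e = 10^4$, $\mu = 10^{-5}$, so
   $\theta = 0.4$);
2. two deme frequencies from the Balding-Nichols model
   $\mathrm{Beta}(p(1-F)/F,\, (1-p)(1-F)/F)$, with
   $F = 1/(1 + 4M (d/(d-1))^2)$ for $M$ migrants per generation among $d$
   demes (default $d = 100$);
3. binomial sampling of the two dominant phenotype counts at the empirical
   sample sizes, discarding loci monomorphic across both samples (matching
   the polymorphism ascertainment of the observed loci);
4. the same Bayesian frequency and FST estimators applied to the empirical
   data - estimator bias and sampling noise therefore cancel between
   observed and simulated loci by construction.

The default of 50,000 simulated loci per comparison follows standard
practice for this class of scan; the distribution is insensitive to $N_e$
and $\mu$ individually, which enter only through $\theta$.

### Calibration

`calibrate_to_trimmed_mean()` bisects $M$ (geometrically, under common
random numbers so each candidate reuses one random substream) until the
simulated 30%-trimmed mean FST lands in $[t, t + 0.005]$, where $t$ is the
empirical trimmed mean - matched closely but never below, so the envelope
errs conservative. Within that admissible window the search keeps refining
towards the lower edge (to $5\times10^{-4}$), because trimmed means are
small numbers (a background of 0.05 gives trimmed means near 0.012) and
stopping anywhere in the window would otherwise overshoot the
differentiation parameter by tens of percent. If simulation noise at the
calibration size steps over the window, the tightest bracketing scaler is
re-evaluated once at four times the size. Datasets whose empirical trimmed
mean is zero or negative (possible by sampling noise at small $n$) are
calibrated to a floor of $10^{-3}$: the baseline is then effectively
panmictic.

### Conditioning and the flagging rule

Two window rules are implemented. The default (`"hbins"`) partitions the
simulated cloud into equal-count heterozygosity bins of roughly 2000 loci
and compares each observed locus against its bin. The alternative (`"knn"`)
takes the $k$ simulated loci nearest in heterozygosity. We made fixed bins
the default after measuring both under a matched neutral model: windows
*centred* on each observed locus place it at the centre of an
$h$-neighbourhood whose FST mixture is inflated by the local trend of FST
against heterozygosity, so the locus is not exchangeable with its window and
only ~3.7% of neutral loci exceed the windowed 95% quantile. With a fixed
partition, observed and simulated loci within a bin are exchangeable and the
rates are nominal.

Count data also make the per-locus FST support discrete at moderate $n$, so
tail probabilities carry atoms. P values therefore use the deterministic
mid-$p$ convention,

$$p = \frac{\#\{F_{sim} > F_{obs}\} + \tfrac12\#\{F_{sim} = F_{obs}\} + \tfrac12}{N + 1},$$

which is strictly inside $(0,1)$ and centres the atoms; flags are
$p \le 0.05$ (95% level) and $p \le 0.01$ (99% level), so a 99% outlier is
always a 95% outlier. A strict "exceeds the windowed quantile" rule was
measured to under-flag (ties sit exactly at the quantile); the mid-$p$ rule
restores nominal rates while staying deterministic. The per-bin 95% and 99%
quantile curves are still reported for plotting.

Two diagnostics accompany every scan: pooled neutral $p$ values should be
approximately uniform, and `pvalue_balance_diagnostic()` runs the one-sample
$t$ test of the per-comparison differences $\#\{p > 0.5\} - \#\{p < 0.5\}$
against zero - an accurate simulation returns about as many $p$ values above
0.5 as below.

## The repeated-outlier framework

For each design class of comparison (sympatric different-morphotype,
allopatric same-morphotype, allopatric different-morphotype; the allopatric
classes down-sampled to nine seeded random pairs so classes are comparable),
`outlier_frequency_table()` compares observed per-comparison outlier
percentages against the neutral expectations of 5% and 1% with a
Mann-Whitney U test. The expectation enters as an equal-length constant
sample at 5 (or 1) and the test uses the tie-corrected normal approximation;
a Kolmogorov-Smirnov normality check per group is recorded alongside (the
rank test is used precisely because percentages are often non-normal).

`repeated_outliers()` then classifies loci: **95Sel/99Sel** are flagged at
that level in *every* sympatric comparison of the same two morphotypes
across at least two locations (selection associated with the morphotype);
**95Geo/99Geo** are flagged in *all* allopatric same-morphotype comparisons
of one morphotype but in *no* sympatric different-morphotype comparison
involving it (selection associated with geography). Expected counts under
neutrality use $E = L\,p^m$ for $L$ polymorphic loci, per-test probability
$p$ (0.05 or 0.01) and $m$ comparisons, with exact binomial upper-tail
tests. `consensus()` finally cross-tabulates repeated outliers against
externally supplied per-locus probabilities of directional selection (e.g. a
Bayesian scan run on the same pairs), counting comparisons with probability
above 0.7: support in both, one, or neither.

Populations of six or fewer individuals are excluded throughout
(`filter_min_population_size()`, default minimum 7): they lack the
information to place a locus relative to the envelope.

## The synthetic generator

`generate_dataset()` draws, per locus, an ancestral presence frequency from
`ancestral_freq_prior` (default $\mathrm{Beta}(0.4, 0.4)$, the equilibrium
shape at the default $\theta$), location-level frequencies around it at
`background_fst_location` (default 0.060), and morphotype-level frequencies
within each location at `background_fst_morphotype` (default 0.058) - the
two background levels are deliberately of the same order, geographic
structure slightly above morphotype structure. Planted selected loci draw a
pair of divergent anchor frequencies once per locus at `selected_fst`
(default 0.4) and re-use them in every location, so their signal repeats
across locations while ordinary background jitter is added on top. Diploid
genotypes are collapsed to dominant phenotypes; loci monomorphic across the
whole dataset are resampled. The default `design` is a realistic
Caribbean-reef survey layout (8 locations x 5 colour morphotypes,
per-population $n$ from 4 to 90, 436 loci). `generate_peak_data()` adds
RFU-scale peak heights (signal 1000, noise 50, s.d. 100, truncated at zero)
and double-extraction replicates whose calls are flipped at 2.9% - the
repeatability regime typical of careful AFLP work.

Because anchors are *drawn* at `selected_fst` rather than fixed, the
realized divergence of planted loci varies (some land near fixation of the
same allele and are undetectable in principle); ground truth therefore
records per-population true frequencies and the realized pairwise FST, and
power statements condition on loci whose realized divergence is at least
0.35 in every location analysed.

What the generator does *not* emulate: scoring artifacts (size homoplasy,
co-migrating fragments), linkage between loci, non-equilibrium demography
(bottlenecks, expansions, isolation by distance) and within-population
inbreeding ($F_{IS} = 0$ everywhere, as the estimators also assume). Passing
tests demonstrate internal consistency of the whole pipeline under its own
model assumptions - not robustness of AFLP scans to those real-data
complications.

## Verification at desk scale

The test suite re-derives every numerical component against independent
oracles (fine-grid quadrature, brute-force counting, set algebra, binomial
pmf summation) and checks the pipeline's statistical promises by
simulation:

* self-consistent neutral calibration: across 20-24 neutral datasets
  (436 loci, $n = 40$ per population, background FST 0.05, clouds of
  20,000 simulated loci), the mean flagged fractions recover 5% and 1%
  within 1 and 0.5 percentage points;
* parameter recovery: the multilocus mean FST at $L = 2000$, $n = 40$ lies
  within three jackknife standard errors of $\theta \in \{0.02, 0.05,
  0.10\}$;
* end-to-end power: over 300 replicate two-location datasets with ten
  planted loci at `selected_fst = 0.4` (clouds of 10,000), at least 80% of
  planted loci with realized per-location FST $\ge 0.35$ are designated
  95Sel, while under no planted selection the 95Sel counts match
  $E = L\,p^2$ over the loci analysable in both comparisons;
* determinism: identical configuration and seed reproduce report bundles
  byte for byte.

These problem sizes (tens of datasets, clouds of $10^4$-$2\times10^4$, a
few hundred power replicates) are the package's verification scale; the
defaults used for real analyses (50,000 simulated loci, 1000 permutations)
are larger.

## Known limitations

* The envelope is an equilibrium island-model approximation; strong recent
  demographic events can shift the whole neutral FST distribution in ways a
  trimmed-mean calibration only partly absorbs.
* Dominant data at $n \lesssim 10$ carry little information per locus; the
  default size filter removes such populations rather than pretending the
  envelope can rank them.
* Per-locus FST values are noisy ratio estimates; interpretation should rest
  on the repeated-outlier design, not on any single comparison.
* The consensus step treats external per-locus probabilities as given; it
  does not model their uncertainty.
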