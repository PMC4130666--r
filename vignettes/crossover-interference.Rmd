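---
title: "Measuring crossover interference from tetrads, foci and chiasmata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crossover interference from tetrads, foci and chiasmata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiocross)
```

## The problem

During meiosis, crossovers (COs) reciprocally exchange chromosome segments
between homologs. Class I COs normally show *interference*: one CO
suppresses the formation of others nearby, so COs end up more widely and
evenly spaced than a random (Poisson) placement would produce. Mutants in
which this control is perturbed can show the opposite pattern — COs
bunched into tight clusters, i.e. *negative* interference — while keeping
the genome-wide CO count roughly constant. Detecting such a change
requires statistics at three levels of observation, all implemented here:

1. **Pollen tetrads** scored with three linked fluorescent markers
   (the fluorescent-tagged-line, FTL, assay in a *quartet* background),
   which give map distances and three interference statistics;
2. **Immunostained CO foci** (MLH1, HEI10) along pachytene/diplotene
   chromosome axes, which give focus counts, clustering phenotypes and a
   within-cluster spacing test;
3. **Metaphase I spreads**, which give ring/rod bivalent configurations
   and the minimum chiasma number.

No third-party data ship with the package; a synthetic meiosis simulator
with tunable interference generates all three data kinds so that every
statistic can be validated against a known truth.

## Tetrad genetics

A tetrad carries the four products of one meiosis. With three linked
markers present on one homolog and absent from the other, each marker
segregates 2:2 and each of the two marker intervals is, per tetrad, in
one of three states: parental ditype (**P**), tetratype (**T**) or
nonparental ditype (**NPD**, the signature of a four-strand double CO
within the interval). Jointly the two intervals admit exactly twelve
distinguishable spore-phenotype multisets, labelled `a`–`l`
(`tetrad_class_table()`); classes `h`–`l` are those with an NPD in at
least one interval. That the twelve classes are exhaustive is proved by
enumeration in the test suite.

Map distance uses the Perkins estimator,

$$d(\mathrm{cM}) = \frac{100\,(6\,\mathrm{NPD} + \mathrm{T})}{2\,(\mathrm{P} + \mathrm{T} + \mathrm{NPD})},$$

which corrects the tetratype frequency for double COs. Three
interference statistics are built on the P/T/NPD bookkeeping:

* **NPD ratio** (`npd_ratio()`): observed NPD frequency over the
  Papazian expectation
  $\mathrm{NPD}_{exp} = \tfrac12\!\left[1 - T - (1 - \tfrac{3T}{2})^{2/3}\right]$
  computed from the observed tetratype frequency $T$. The expectation is
  exact under a Poisson CO process with no chromatid interference, so
  NPDr = 1 means no interference, NPDr < 1 interference, NPDr > 1
  negative interference (an excess of close double COs).
* **Interference ratio** (`interference_ratio()`): the Perkins length of
  one interval among tetrads *with* a CO in the adjacent interval
  (T or NPD status there) divided by its length among tetrads *without*.
  Independence of the two intervals gives IR = 1.
* **Coefficient of coincidence** (`coefficient_of_coincidence()`):
  observed frequency of tetrads with COs in both intervals over the
  product of the single-interval CO frequencies.

Tetrads whose CO status in the adjacent interval is ambiguous do not
exist in this scheme: every class maps deterministically to a status
pair. NPD tetrads in the adjacent interval count as CO-containing.

### Significance machinery

The published tools behind these statistics do not document their tests,
so the package makes its own, stated choices: the NPD ratio is tested
against 1 with an exact binomial test of the observed NPD count at the
expected frequency; the IR (against 1, or against a reference genotype)
uses a seeded nonparametric bootstrap over tetrads — multinomial
resampling of the twelve class counts, 10,000 resamples by default —
with two-sided percentile p-values. Bootstrap standard errors and 95%
percentile intervals accompany every statistic. These choices are
distribution-free and match the ratio-of-distances structure of the IR;
they are not claimed to be numerically identical to any other
implementation.

## The crossover simulator

CO positions along a bivalent are drawn from a **stationary gamma
renewal process** on the genetic map: inter-CO distances are i.i.d.
Gamma(shape $\nu$, mean $L/\mathbb{E}[\text{COs}]$). The shape $\nu$ is
the interference dial — $\nu = 1$ is exactly a homogeneous Poisson
process (the no-interference null used for calibration), $\nu > 1$
spaces COs evenly (CO counts become under-dispersed), $\nu < 1$ clusters
them. Stationarity is achieved by starting the renewal sequence ten mean
spacings before the origin and discarding the run-in; at that depth the
residual non-stationarity is far below Monte-Carlo resolution at the
sample sizes used. With the default mean of 2 COs per bivalent on a map
of length 1, coordinates are true Morgans.

Each CO engages one chromatid of each homolog, chosen uniformly and
independently per CO (**no chromatid interference** — the assumption
under which NPD frequency detects four-strand doubles). Genotypes are
derived by tracking which structural chromatid each centromere-anchored
molecule travels on: a crossover swaps the two molecules currently on
the chromatids it joins, distal to its position. This occupancy
bookkeeping matters — swapping segment *contents* between fixed
chromatid labels instead would silently mis-genotype three-strand
doubles and bias IR and c.o.c. downward, which is why the null
calibration (IR = c.o.c. = 1 at $\nu = 1$) is part of the acceptance
tests. No map function is ever applied: recombination arises only from
simulated exchanges, so Perkins estimates are internally consistent by
construction. Tetrads are simulated restricted to the window between the
first and last marker, since COs outside it only permute spore labels.

The obligatory CO (every bivalent gets at least one) is *not* enforced
by default, because its loss is precisely what univalent-producing
mutants display; `obligate_co = TRUE` resamples bivalents until each
carries a CO.

Open choice, recorded here: real chromosomes show CO-rate heterogeneity
(e.g. telomere-proximal elevation). The simulator uses a homogeneous
rate; a position-dependent rate map would be an extension, not a default
we are prepared to guess.

## The within-cluster spacing test

For a cluster of $k + 2$ foci the outermost two define the span; under
the null hypothesis of no interference the $k$ internal foci are
i.i.d. uniform on it. With normalised gaps $d_1, \dots, d_{k+1}$
(summing to 1), the statistic

$$S = \Big[\textstyle\sum_i \big(d_i - \tfrac{1}{k+1}\big)^2\Big]\,(k+1)^2\,\frac{k+2}{k}$$

is the sum of squared centred gap deviations normalised by the null gap
variance $k/[(k+1)^2(k+2)]$ (gaps are jointly Dirichlet), so each gap
contributes 1 on average and $\mathbb{E}[S] = k + 1$ for any cluster
size. For $k = 1$ this reduces to $[(d_1 - 0.5)^2 + (d_2 - 0.5)^2]
\times 12$. The test statistic for a dataset is the plain **sum of
per-cluster S values**; its null distribution is obtained by direct
simulation (default $10^5$ datasets) with the same cluster sizes, and
the p-value is the proportion of simulated statistics **strictly
smaller** than the observed one — small S means more even spacing than
uniform, i.e. interference. The $(r+1)/(n+1)$ bias-corrected p-value is
available behind `corrected = TRUE` but off by default, to keep the
estimator exactly as defined. A sum of per-cluster gap CVs is offered as
an alternative statistic (`statistic = "cv"`) for comparison; S is the
authoritative one.

Null simulation draws gaps directly as normalised exponentials
(equivalent to sorting uniforms, without the sort), which makes the
$10^5$-replicate default cheap. Calibration — $\mathbb{E}[S_{total}] =
\sum_i (k_i + 1)$, uniform p-values under the null, 5% type-I error at
$\alpha = 0.05$ — is asserted in the acceptance tests at 10,000 null
draws and 500 replicate tests with `n_sim = 2000`.

## Cytology metrics

* `mcn()`: minimum chiasma number, scoring a rod bivalent as one chiasma
  and a ring bivalent as two (one per arm); univalent pairs score zero.
  `score_metaphase()` derives the ring/rod/univalent configuration from
  per-arm CO counts, and `metaphase_summary()` gives group means ± SD
  with Welch (unequal-variance) two-sample comparisons, using sample
  (n−1) standard deviations throughout.
* `cv_percent()`: 100·SD/mean of per-cell focus counts, the dispersion
  measure used to contrast genotypes.
* `detect_clusters()`: maximal runs of ≥ 2 consecutive foci whose
  successive gaps are each below a threshold fraction of the axis
  length. The default threshold of **1/90 of the axis** is the largest
  intra-cluster gap reported cytologically for class I CO clusters; the
  criterion is deliberately configurable (and echoed in the output)
  because published cluster calls rarely state an operational threshold.
  Because the threshold is a fraction, detection is invariant to axis
  rescaling.
* `fraction_to_physical()`: converts an axis/genome fraction to kb under
  homogeneous condensation. The default genome constant of 250,000 kb is
  the unique value consistent with the published conversions it is used
  for (1/400 → 625 kb; 1/1600 → ~150 kb; 1/90 → ~3,000 kb;
  1/200 → ~1,200 kb).

## The synthetic foci generator

`simulate_foci_cells()` emulates two regimes. Per-cell focus counts are
a rounded normal with SD = `dispersion` × mean (clamped at zero), so
`dispersion` is directly the target coefficient of variation; the
default 0.26 matches a wild-type-like CV, and 0.5 a mutant-like one.
`"dispersed"` mode spreads foci evenly with jitter — the wild-type
pattern, in which the spacing test accepts its null at the nominal rate.
`"clustered"` mode places about half the foci (configurable) into
planted groups of 2–5 foci, sizes weighted toward pairs (0.55, 0.25,
0.13, 0.07) to mimic the observed predominance of two-focus clusters
with a maximum of five; each group spans at most `cluster_extent` of the
axis (default 1/200, a published mean cluster span). The planted truth
is returned in `attr(, "planted")`, which is what the planted-recovery
tests consume.

What the generator does *not* emulate: multiple distinguishable axes per
cell (all foci are placed on one composite axis), measurement error in
focus positions, inhomogeneous axis condensation, and within-cluster
interference (planted foci are uniform inside their window — so the
spacing test is expected to *accept* its null on the generator's
clusters, which the calibration tests rely on). Passing tests therefore
demonstrate correctness of the statistics under these idealised
conditions, not biological realism of any particular parameter set.

## Numerical and design notes

* All randomness is seeded through function arguments; seeds are
  recorded in result objects and in the pipeline manifest, and a fixed
  seed reproduces outputs bit-identically (a tested property).
* A CO landing exactly on a marker position (probability zero in the
  continuous model) is rejected and the draw resampled.
* Duplicate focus positions yield zero-width gaps: allowed, flagged with
  a warning.
* `expected_npd()` refuses tetratype frequencies above 2/3, which the
  no-interference tetrad model cannot produce; the bootstrap clamps
  resampled frequencies at the boundary instead of failing.
* Degenerate IR subsets (no tetrads with, or without, an adjacent CO)
  raise a diagnostic error rather than returning an unstable ratio.
* Problem sizes used by the calibration suite: 200,000 tetrads for the
  null calibration of NPDr/IR/c.o.c. (two ~9 cM adjacent intervals,
  chosen so each interval's expected CO count is small but NPDs are
  still well represented); 10,000 draws for the Dirichlet mean of S;
  500 replicate spacing tests at 2,000 simulations each; 100,000
  bivalents for CO-count dispersion. These sizes put Monte-Carlo error
  well below the effect sizes being checked.

## A worked run

```{r example}
cfg <- sim_config(nu = 1, mean_co_per_bivalent = 2, n_tetrads = 20000,
                  seed = 42)
x <- simulate_tetrad_dataset(cfg)
npd_ratio(interval_ptn(x, 1), seed = 42)
interference_ratio(x, target_interval = 1, seed = 42)
coefficient_of_coincidence(x, seed = 42)
```

With `nu = 10` the same pipeline returns all three statistics well below
1, and with `nu < 1` above 1 — the negative-interference signature.

```{r clusters}
foci <- simulate_foci_cells(40, dispersion = 0.5,
                            clustering_mode = "clustered", seed = 42)
det <- detect_clusters(foci)
det
cluster_interference_test(det, n_sim = 10000, seed = 42)
```

## Limitations

* The tetrad statistics are specific to the three-marker, two-interval
  design; general multi-locus linkage mapping and map functions are out
  of scope (a Haldane expectation appears only as an internal check of
  the simulator).
* The bootstrap p-values are percentile-based and asymptotically
  uniform; at small tetrad counts or few resamples they inherit the
  usual discreteness of resampling tests.
* The spacing test conditions on observed cluster sizes and positions;
  it tests spacing *within* clusters, not whether clustering itself is
  unusual (that is the job of `detect_clusters()` plus the count CV).
* Chiasma scoring is a minimum: bivalents with more than two chiasmata
  are still scored 2 (ring) or 1 (rod).
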