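---
title: "Methods: spectral-count interactome scoring and expression filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count interactome scoring and expression filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectracall)
library(dplyr)
```

## The problem

In a label-free affinity-capture study, a tagged bait protein is
expressed in cells, captured on beads, and co-purifying preys are
quantified by spectral counting — the number of MS/MS spectra assigned
to each protein in each run. Preys bind beads non-specifically
("sticky background"), capture efficiency differs between bait
constructs, and runs are processed in batches, so deciding which preys
are genuine interactors is a statistical problem. `spectracall`
implements a consensus calling procedure (fold change, t-test, per-run
G-tests, a SAINT-style probabilistic score), bait-level normalisation
for comparing domain-deletion constructs, and the companion RNA-seq
workflow for separating bait-specific expression changes from
transfection artifacts, including estimation of endogenous expression
when a cDNA transgene shares exons with the endogenous gene.

Everything is testable without external data because the package ships
seeded generators (`simulate_apms()`, `simulate_rnaseq()`) that plant
known interactors and expression effects.

## The AP-MS generative model

`simulate_apms()` draws the count of prey $i$ in run $j$ from a
negative binomial with mean

$$\mu_{ij} = b_i \cdot m_{B(j)} \cdot e_{ij}, \qquad
  \mathrm{Var} = \mu + \phi\,\mu^2,$$

where $b_i$ is the prey's background (stickiness) mean, $m_{B(j)}$ a
multiplicative batch factor (two batches, A and B), and $e_{ij}$ an
enrichment term. For a true interactor of the run's construct,
$e_{ij} = f \cdot c_r$, where $f$ is the enrichment factor (default 8)
and $c_r$ the construct's bait-capture level relative to the wild-type
construct; for background preys $e_{ij} = 1$. The bait's own row
follows the construct-specific capture level directly.

Two points deserve emphasis:

* **Co-capture scales with captured bait.** A construct captured at
  half the wild-type level co-captures its true interactors at half
  their wild-type rate; this is precisely what the downstream
  correction factors (`bait_correction()`) exist to undo, and a
  generator without this coupling would make the correction step a
  source of bias instead of a remedy.
* **Dispersion is calibrated, not guessed.** Replicate spectral counts
  from well-behaved captures are highly consistent; method-of-moments
  estimates on published replicate rows give $\phi \approx 0.03$–$0.06$
  within batch, so the default is $\phi = 0.05$. At $\phi \to 0$ the
  law degrades gracefully to Poisson.

The default design mirrors a realistic study: 5 control runs, 4
wild-type runs, 3 runs per point mutant, 2 runs per deletion construct,
split across batches A and B. `default_interactors()` plants
interactors in the upper half of the background-abundance ladder, where
8-fold enrichment yields bait-run counts of roughly 10–100 spectra —
the range in which robust interactors are reported in practice. Planted
interactors below a handful of expected spectra per run are not
confidently detectable by any scorer and would measure the generator,
not the method.

## Enrichment statistics

**Pooled controls.** The control comparator for per-run tests is the
sum over all control runs (counts and totals). Pooling maximises
control depth and is deterministic; nothing in the procedure depends on
an arbitrary bait-run-to-control-run pairing.

**G-test.** For each bait run, each prey is tested on the 2×2 table
(prey vs all-other spectra) × (bait run vs pooled control):

$$G = 2 \sum_{\text{cells}} O \ln(O/E),$$

with $O \ln(O/E) \to 0$ as $O \to 0$ and $p$ from $\chi^2_1$. No
Williams correction is applied by default (`williams = TRUE` enables
it). "Significantly over-represented" additionally requires the bait
proportion to exceed the control proportion — the test statistic itself
is direction-blind, the call is one-sided.

**Fold change** is the ratio of replicate means with a pseudocount
(default 0.5) in both numerator and denominator, so preys absent from
controls stay finite. **Welch's t-test** is one-sided (bait > control)
on raw replicate counts; when both groups are constant the limiting
p-value is returned (0.5 for equal constants) with a warning, which
matters for all-zero preys.

## The SAINT-style score

The score is the posterior probability that a prey's bait counts come
from a true-interaction component rather than background, under a
two-component negative-binomial mixture:

$$\mathrm{post}_r = \frac{\pi f_1(y_r)}{\pi f_1(y_r) + (1-\pi) f_0(y_r)},
  \qquad \text{score} = \frac{1}{R}\sum_r \mathrm{post}_r,$$

with $f_0$ the NB density at the prey's background mean, $f_1$ at that
mean times a true-component factor, and prior $\pi = 0.1$. The factor
is fitted per prey by EM over that prey's bait runs, bounded to
$[2, 100]$, deterministically initialised at 4 (tolerance $10^{-6}$,
at most 500 iterations); factors hitting a bound are clamped with a
warning. Per-prey fitting matters: a single shared factor is dominated
by the bait row and the strongest interactors and under-scores
moderately enriched preys.

The background model (`fit_background()`) uses control means floored at
0.1 and a single pooled method-of-moments dispersion. When run metadata
carries a `batch` column the model is batch-aware: per-batch depth
factors are estimated from control column totals, control counts are
batch-adjusted before estimating means and dispersion, and scoring
rescales each run's expected means by its batch factor. Ignoring the
batch structure leaks the batch spread into the dispersion estimate
(roughly doubling it under the default generator) and mis-centres the
per-run likelihoods.

The original SAINT fits a Bayesian model by MCMC; this package
implements a deterministic simplification because only the thresholded
score (≥ 0.90) feeds the calling criteria and determinism makes the
behaviour testable. It is documented as SAINT-style, not SAINT.

Averaging order is fixed: posteriors are averaged across replicates
within a prey, never across preys. A consequence worth knowing: one
weak replicate out of four caps the score near 0.75, so the score
demands consistent enrichment — by design.

## Consensus calls and domain dependence

`call_interactors()` calls a prey iff **all** of: fold change ≥ 2,
one-sided t-test p ≤ 0.05, G-significant in ≥ 2 runs, score ≥ 0.90
(all thresholds configurable via `call_criteria()`). The called set is
exactly the intersection of the four single-criterion pass sets, and
the per-criterion booleans record which clause failed.

For deletion constructs, `bait_correction()` estimates per-construct
factors from the bait's own counts (reference mean over construct
mean), reported rounded to one decimal — the granularity at which such
factors are conventionally quoted — but applied at full precision by
`apply_correction()`, which leaves the bait row unscaled.
`classify_domain_dependence()` then classes each called prey per
deletion construct: *reduced* if the corrected deletion/WT mean ratio
is ≤ 0.5 with at least one deletion run significantly
under-represented by G-test against pooled WT runs; *enhanced* at
ratio ≥ 2 with over-representation; *unchanged* otherwise. A reduced
call is *selective* when every construct not itself reduced shows no
two-fold downward trend (ratio > 0.5), and symmetrically for enhanced;
the rule deliberately admits jointly-reduced construct subsets, since
preys genuinely dependent on two domains exist. The bait row is
excluded from the G-test margins here: bait levels differ between
constructs by design, and leaving the row in would distort the
all-other-spectra totals (and break exact invariance of the
classification under scale-then-correct).

`export_network()` writes the called network as SIF, GraphML and a node
TSV, with a `shade` node attribute mapped monotonically (min-max scaled
log2 fold change) for rendering enrichment intensity; output ordering
is deterministic so re-exports are byte-identical.

## The RNA-seq side

`simulate_rnaseq()` emulates a four-condition transient-transfection
design (untransfected, tag-alone, wild-type bait, mutant bait; 3
replicates each). Exon counts are negative binomial with means set by a
per-gene baseline expression, the exon's length share, the library size
and the condition's planted log2 effects; gene counts are the sums over
exons, so the two tables are consistent by construction. Baselines are
renormalised so expected column totals equal the library size, making
planted "baseline RPKM" self-consistent with RPKM computed from
realised totals. The dispersion default is 0.005, matching the 3–7%
replicate CVs observed in published per-replicate RPKM values for this
kind of FACS-normalised design — bulk-tissue defaults (0.05+) would
overstate the noise several-fold.

Planted transfection artifacts default to ±1.5 log2 (about 2.8-fold):
real artifact responses comfortably exceed the 2-fold screening
threshold, and planting exactly at a threshold turns recovery tests
into coin flips. Bait-specific effects are planted at ±1 log2, the
value the recovery criterion estimates.

**DE stand-in.** `nb_de_test()` is a deliberately lightweight
replacement for a full DE framework: library-size normalisation, a
single pooled method-of-moments dispersion, and a one-degree
likelihood-ratio test of separate versus shared condition means, with
Benjamini–Hochberg adjustment (`bh_adjust()`, a validated wrapper over
the standard step-up procedure; the adjustment method is configurable
in spirit — external (log2FC, adj_p) tables in the same layout feed
straight into the filter). Known caveat: size factors from raw totals
absorb part of strong asymmetric signal (composition bias), visible as
a few-percent attenuation of planted fold changes; a trimmed or
median-ratio normalisation would reduce it but is out of scope here.

**Filter cascade.** `matr3_specific_filter()` keeps genes that change
≥ 1.6-fold (linear scale, either direction) at adjusted p ≤ 0.05 in
the bait-vs-tag comparison, are not significant artifacts
(|log2FC| ≥ 1, adjusted p ≤ 0.01) in the tag-vs-untransfected
comparison, and reach 100 RPKM in at least one condition (maximum of
the condition means — the stricter of the two phrasings such thresholds
get). All thresholds sit in `filter_config()`. The cascade is applied
to the wild-type-vs-tag comparison; the mutant-vs-tag comparison is
computed with the same function and reported alongside rather than
folded into the gene-set definition, since requiring joint significance
would conflate two questions. A transgene-hosting gene will pass this
filter on whole-gene counts — its apparent induction is exactly the
artifact the endogenous estimator exists to resolve.

**Endogenous expression.** When a cDNA transgene shares exons with an
endogenous gene, `endogenous_expression()` restricts the RPKM
computation to the exons unique to the endogenous locus (reads on
non-shared exons over their summed length). The estimate is invariant
to the transgene multiplier in expectation; at the default noise level
it sits within a few percent of the planted level while whole-gene
RPKM inflates 20–30-fold. Requires at least one non-shared exon.

**Concordance.** `pairwise_pearson()` correlates all sample pairs and
average-linkage clusters on $1 - r$; replicates of distinguishable
conditions cluster adjacently. Conditions that share every planted
effect (wild-type and mutant bait, by default) are statistically
identical and form a single block — a useful reminder of what replicate
concordance can and cannot show.

## Phenotype counts

`percent_with_spheres()` is the display-rounding calculator for
categorical microscopy counts: round(100 × (spheres + large spheres) /
total), ties away from zero (base `round()` half-even rounding would
disagree at .5 boundaries). `phenotype_summary()` validates the row-sum
invariant and, when a reported percent column is present, flags rows
whose printed percent is not reproducible from their printed counts —
the bundled table contains exactly one such row (computed 45.7 → 46
against a printed 47), which is flagged, not corrected.

## Numerical choices and problem sizes

* Zero cells in the G-test contribute 0 (the $x \ln x$ limit); tiny
  negative round-off in $G$ is clamped at 0.
* Mixture posteriors are computed in log space; background means are
  floored at 0.1.
* EM: bounds [2, 100], init 4, tolerance $10^{-6}$, max 500
  iterations; the M-step uses one-dimensional bounded maximisation.
* Deterministic ordering (protein id, then construct) in every output
  table and network file.
* Seeds are explicit arguments everywhere; generators save and restore
  the global RNG state.
* Test and acceptance problem sizes: 200 proteins × 24 runs with 20
  planted interactors for the AP-MS side, 2000 genes × 12 samples for
  the RNA-seq side, 10 simulation seeds per property. These sizes give
  stable aggregate metrics (sensitivity, false-discovery proportion,
  recovery errors) while keeping a full suite run to a couple of
  minutes.

## Limitations

The generators emulate count structure, batch effects, capture-level
differences and exon-sharing transgenes — not peptide-to-protein
inference, shared-peptide ambiguity, run-to-run retention drift,
alignment or quantification artifacts, or correlated (non-NB) noise.
Tests passing on synthetic data show the statistics behave as specified
under the stated model; they do not certify performance on any real
dataset, where identification quality and annotation correctness
dominate. The SAINT-style score is a deterministic simplification and
will not numerically reproduce published SAINT outputs. The DE
stand-in is not a replacement for a mature DE framework on real data;
its role is to make the filter cascade self-contained and testable.
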