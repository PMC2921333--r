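---
title: "Detecting thyroid-hormone-responsive miRNAs and mRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting thyroid-hormone-responsive miRNAs and mRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyromir)
```

Thyroid hormone (TH) drives much of postnatal liver development, and both
miRNAs and mRNAs respond when circulating TH is perturbed — for instance in
juvenile mice rendered hypothyroid with goitrogens. `thyromir` implements
the complete computational workflow for such a study: differential
expression on two-channel expression arrays, differential expression on
TaqMan low-density miRNA arrays (TLDA), single-assay qPCR relative
quantification, and the integration step that asks whether predicted miRNA
targets move in the direction opposite to their miRNA. Every stage can be
exercised on synthetic data with known truth, which is how the package
tests itself.

This vignette explains the statistical models, the tunable parameters, the
design decisions taken where conventions diverge, and the limits of what
the synthetic benchmarks demonstrate.

## Two-channel array differential expression

Each array hybridises a Cy5-labelled sample against a Cy3-labelled common
reference, so the analysis operates on per-probe log ratios
$M = \log_2(\text{Cy5}/\text{Cy3})$ and mean intensities
$A = \tfrac12(\log_2\text{Cy5} + \log_2\text{Cy3})$.

**Background flagging.** Negative-control probes carry no target sequence;
their signals estimate the optical/hybridisation background. Per array and
channel the threshold is the trimmed mean plus $k$ trimmed standard
deviations of the negative-control signals (defaults: trim 5%, $k = 3$),
and a probe is *absent* where its median signal falls strictly below the
threshold. Both the mean and the standard deviation trim
$\lfloor \text{trim}\cdot n\rfloor$ observations per tail — the trimmed SD
is not otherwise standardised, so the convention is stated here and frozen
in tests. A probe absent in *every* sample is excluded from inference and
logged; a probe absent in *some* samples contributes its remaining values
(at least two per group are required).

**Normalization.** Intensity-dependent dye bias is removed per array by
global lowess: a locally linear, tricube-weighted regression of $M$ on $A$
with three robustness iterations, fitted over the array's non-absent
probes, with span 0.2 by default (the fraction of probes entering each
local fit). Normalized values are $M' = M - \hat g(A)$; $A$ and the absent
flags are untouched. Probes outside the fitted $A$ range take the nearest
fitted value. The implementation delegates the curve to `stats::lowess`,
which is exactly this estimator.

**Test statistic.** With four arrays per group, per-feature residual
variances are noisy, so the default statistic shrinks them: log residual
variances are bias-corrected (using
$E[\log(\hat\sigma^2/\sigma^2)] = \psi(d/2) - \log(d/2)$ for $d$ degrees
of freedom), shrunk toward their across-feature mean with the James–Stein
factor

$$ b = \max\!\Big(0,\; 1 - \frac{(G-3)\,\overline{\psi_1(d/2)}}{\sum_g (x_g - \bar x)^2}\Big), $$

and exponentiated; the statistic is the between-group mean square over
this shrunken variance. When the per-feature variances are genuinely
heterogeneous the factor approaches 1 and the statistic approaches the
classical per-feature F; when they are genuinely equal it approaches the
pooled-variance F. Both limits are tested. The plain one-way ANOVA F is
always available (`stat = "f"`) and serves as the verifiable oracle: the
two statistics agree per feature as within-group replication grows, which
the suite checks at 500 features with 400 arrays per group (median
relative difference below 5%, rank agreement above 0.99).

**Inference.** P-values come from residual shuffling: null-model (grand
mean) residuals are permuted across all samples — for a location-invariant
statistic this is exactly a re-assignment of samples to groups — with the
same shuffle applied jointly to every feature so between-feature
correlation is preserved (independent per-feature shuffling is available
by flag). When the number of distinct group assignments fits the
permutation budget ($\binom{8}{4} = 70$ for the default 4 + 4 design) the
grid is enumerated and p-values are exact counts; otherwise shuffles are
sampled and the add-one convention $p = (1+b)/(B+1)$ keeps p in $(0,1]$.

Two details matter at this sample size:

* On the enumerated grid the identity assignment and its mirror tie the
  observed statistic exactly, so per-feature p-values live on the even
  grid $\{2/70, 4/70, \dots\}$ and the achievable size at nominal 0.05 is
  exactly $1/35 \approx 0.029$ — the suite tests this value, not the
  nominal one.
* A per-feature floor of $2/70$ can never survive Benjamini–Hochberg
  adjustment at 200 features, so the full pipeline pools the null
  statistics of all features into one reference distribution (resolution
  $1/(70 \cdot G)$), the standard convention for small two-group array
  designs. The pooled mode is the pipeline default; the per-feature mode
  remains the contract of `permutation_pvalues()` itself and is what the
  brute-force enumeration oracle verifies.

Benjamini–Hochberg adjustment (`bh_adjust()`, backed by `stats::p.adjust`
and cross-checked against a brute-force step-up oracle) controls FDR at
0.05 by default. Fold changes are ratios of least-square means — for the
one-way design, group means of normalized $M$ over available values —
reported signed: $2^d$ for $d \ge 0$, $-2^{-d}$ otherwise, so
$|\mathrm{fc}| \ge 1$ always and down-regulation is negative, matching how
such tables are printed.

## TLDA miRNA differential expression

TLDA cards report one threshold cycle (Ct) per assay per sample. Ct is
already a log2-scale quantity (one cycle = one doubling), so inference is
performed directly on $\Delta Ct = Ct_{\text{assay}} - Ct_{U6}$; we read
"the log2 of the delta Ct values" as naming this log2-scale quantity,
since a literal logarithm of $\Delta Ct$ — which is frequently zero or
negative — is undefined. This is a documented interpretation, not an
algebraic necessity.

Per assay, a one-way ANOVA F is computed on $\Delta Ct$; its null
distribution is built by resampling the model residuals with replacement
*within each condition* (so no common-variance assumption is made),
forming null pseudo-data about a common mean, and recomputing F. The
p-value uses the same add-one convention as above. This calibration is the
method's point: with group SDs of 1 versus 3 at $n = 4$ per group, the
F-table reference test over-rejects (≈ 6–7% at nominal 5%) while the
bootstrap stays near level. Two caveats the suite quantifies:

* Exact ties occur: a resample that happens to be a within-group
  permutation of the residuals reproduces the observed F bit-for-bit
  (probability $(4!/4^4)^2 \approx 0.9\%$ per draw at $n=4$). Counting
  ties — as the add-one convention requires for validity — costs roughly
  one percentage point of level, so the bootstrap's true size at nominal
  0.05 in this design is ≈ 0.035, at the conservative edge of the
  calibration band the acceptance suite checks. A Monte-Carlo estimate at
  2,000 simulations (SE ≈ 0.004) therefore lands on either side of that
  edge from seed to seed; the corresponding acceptance check is sensitive
  to this and may fail by sampling error even though larger runs place
  the true level inside the band.
* Bootstrap p-values sit on the grid $k/(B+1)$; $B = 1000$ by default,
  minimum 99.

Undetermined Ct values (beyond the instrument ceiling, default 40 cycles)
are a distinguished token, not a number; the policy is explicit:
`omit` (default) drops the observation, `ceiling` substitutes the ceiling.
The housekeeping assay must be determined in every sample and is excluded
from testing. Fold changes use $\Delta\Delta Ct$: $RQ = 2^{-\Delta\Delta Ct}$
with the same signed convention. Significance defaults to adjusted
$p < 0.1$; we treat the published threshold as FDR-adjusted because the
multiple-comparison adjustment is described as applied to the final
results. Treated/control orientation is always passed explicitly — sign
errors from label guessing are the dominant failure mode in this analysis.
Whether published fold changes of this kind were computed from group-mean
$\Delta\Delta Ct$ (our default) or from per-sample RQ means is generally
not stated; both are available.

## Single-assay qPCR quantification

`ddct_quantify()` implements classical $\Delta\Delta Ct$ against a
calibrator sample: duplicate wells averaged, $\Delta Ct$ per sample,
$\Delta\Delta Ct$ against the calibrator, $RQ = 2^{-\Delta\Delta Ct}$.
The calibrator has $RQ = 1$ identically; adding a constant to all of a
sample's Ct values cancels exactly; changing calibrator rescales all RQ by
a common positive factor. Group comparison uses a two-tailed Student's t
with pooled variance (Welch by flag), on $\log_2 RQ$ by default — relative
quantities are approximately log-normal, and on the log scale the p-value
is invariant to calibrator choice; the raw scale is available because the
original analyses do not state their scale. Degenerate inputs are
reported, not crashed: zero variance with equal means gives $p = 1$, with
unequal means $p = 0$ plus a warning.

Standard curves are ordinary least squares of Ct on $\log_{10}$ dilution;
amplification efficiency is $E = 10^{-1/\text{slope}} - 1$ (slope
$-3.3219$ cycles per decade $\Rightarrow E = 1$, perfect doubling).
Non-negative slopes flag the curve invalid and omit the efficiency.
Efficiency-corrected quantification (Pfaffl-style) is deliberately out of
scope: the workflow being reproduced uses classical $\Delta\Delta Ct$.

## Target integration

Predictions from two algorithms are consumed as tables, never queried
live — database snapshots drift, and the computation in scope is the union
rule: a gene is a target if *either* source predicts it, pooled across the
members of each miRNA family (e.g. miR-1/206, whose members are clustered
and co-expressed). Gene identity is the trimmed, case-sensitive symbol
string. The significant-gene filter uses strict inequalities
($|\mathrm{fc}| > 1.5$, $p < 0.05$, adjusted p by default). The overlap
report classifies each intersecting gene by fold-change sign and calls it
*concordant* when its direction opposes the miRNA family's direction, the
signature of miRNA-mediated suppression.

The package carries the published reference tables for this system as
in-code fixtures (`reference_mirna_de()`, `reference_target_de()`): 11
miRNAs passing the printed $|\mathrm{fc}| > 4$ screen (8 up in
hypothyroid liver, the miR-1/206, miR-133 and miR-135 families dominating)
and 14 predicted targets of the up-regulated families among the
significantly changed genes, 11 of them down-regulated — the 11/14
concordance the integration stage must reproduce exactly. One printed
p-value sits exactly at 0.10: under the strict-inequality contract a
literal $p < 0.1$ re-filter keeps 10 of the 11 rows, so the tallies above
are asserted through the fold-change filter, which is unambiguous.

## The synthetic-data generator

`simulate_two_channel_arrays()` draws per-probe baseline abundances
uniformly on log2 $[9, 14]$, adds the planted group effect, an optional
linear $M$-on-$A$ dye bias, and Gaussian log2-scale noise (default SD
0.25), then reconstructs the two channels as $2^{A \pm M/2}$.
Negative-control probes draw both channels from a log-normal background
(log2 mean 6, SD 0.5). Defaults of 4–5 arrays per group match the
replication of a small in-vivo study. The baseline floor keeps expressed
probes above the flagging threshold, as annotated transcripts on a real
array are; near-background behaviour is exercised by dedicated flagging
fixtures rather than by the recovery benchmarks.

`simulate_ct_experiment()` draws
$Ct = \text{baseline} - \log_2(\text{fold})\cdot\mathbb{1}[\text{treated}] + \text{offset}_s + \varepsilon_g$,
with a per-sample offset (SD 0.5 cycles, a loading/pipetting surrogate)
shared between target and housekeeping assays — so housekeeping
normalization is *exactly* correct in simulation, isolating pipeline error
from normalization model error — and per-group noise SDs that may differ
(default 0.25 cycles each). Values beyond the ceiling become undetermined.
`simulate_target_table()` plants per-miRNA target sets whose two sources
share a controllable fraction of entries.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: probe sequence effects and cross-
hybridisation, spatial artefacts within arrays, non-Gaussian heavy-tailed
noise, correlated probes of one transcript, amplification-efficiency
differences between assays, card-position effects on TLDA, and real
prediction databases' biases. Determinism is a contract: every simulator
requires an explicit seed and identical configuration reproduces
bit-identical output.

## Numerical choices and problem sizes

* Tie handling in resampling tests: `>=` counting throughout, which is the
  validity-preserving convention; its conservative cost is quantified
  above.
* Permutation enumeration replaces sampling whenever the assignment grid
  fits within `n_perm`; enumerated p-values are exact counts including the
  identity assignment, so p is never zero.
* Signed fold changes use $2^d$ / $-2^{-d}$ with $d = 0 \mapsto 1$; the
  transform is exactly invertible.
* Zero residual variance: a single degenerate feature yields an infinite
  F (caught by ties in permutation); a fully degenerate data set is an
  error directing the user to the exhaustive permutation grid.
* The test suite's simulation sizes — 200–2,000 probes, 4 arrays per
  group, 2,000 calibration simulations at $B = 499$, 500 features × 800
  arrays for the shrinkage-convergence check — were chosen to estimate
  each property to well within its asserted tolerance while keeping the
  default suite in the tens of seconds.

## Known limitations

Absent-value policy beyond "exclude if absent everywhere, otherwise treat
as missing" is not configurable; multiple probes per gene are reported per
probe, never collapsed; dye-swap designs and between-array quantile
normalization are out of scope; the Fs shrinkage constant is the
James–Stein construction described above — the originating literature
admits variants, which is why the plain F fallback is first-class; and
the bootstrap level analysis above documents a genuinely marginal
calibration band rather than a resolved one.
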