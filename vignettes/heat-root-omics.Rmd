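---
title: "Methods: mixed-model differential expression, regulatory module networks, and iTRAQ quantification in rootheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model differential expression, regulatory module networks, and iTRAQ quantification in rootheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootheat)
```

`rootheat` reimplements, as a tested and reusable pipeline, the
computational analysis of a paired transcriptome/proteome study of
heat-stressed soybean roots, in which isolated root hairs (RH, a single
epidermal cell type) are compared with the stripped roots (STR) they
were removed from, at 25 °C versus 40 °C over a 0–24 h time course.
Because the raw reads and spectra behind such a study are not available
at desk scale, every stage is exercised end-to-end on synthetic data
with planted ground truth, generated by the package itself. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not establish.

## Gene-level differential expression

### Model

For each gene and each tissue × time contrast, counts are modelled as

$$y_{i} \sim \mathrm{Poisson}(\mu_i), \qquad
\log \mu_i = \beta_0 + \beta_t x_i + \log L_i + u_{r(i)} + v_{p(i)},$$

where $x_i$ indicates heat treatment, $L_i$ is the sample's library
size (offset), and $u_r \sim N(0, \sigma^2_{\mathrm{rep}})$,
$v_p \sim N(0, \sigma^2_{\mathrm{plate}})$ are independent random
intercepts for biological replicate and plate. Genes whose row total
across all samples is below 10 are removed first
(`filter_low_counts()`). Each gene is tested by a likelihood-ratio test
of $\beta_t = 0$ against $\chi^2_1$ (one treatment coefficient per
contrast), p-values are converted to Storey q-values within the
contrast, and a gene is called differentially expressed when
$q \le 0.01$ (estimated FDR 1%) **and** its fold change is at least
two, i.e. $|\beta_t| / \ln 2 \ge 1$ in log2 units.

Genes are analysed per (tissue, time) contrast — heat versus control
within RH, and separately within STR — matching how the contrasts are
reported; a pooled all-sample model with interaction terms is out of
scope. The log2 fold change is model-based ($\beta_t/\ln 2$, on the
count scale), not a ratio of RPKM values; `compute_rpkm()` is provided
for abundance reporting only.

### Numerical method

The marginal likelihood integrates the Poisson likelihood over the
random intercepts. `rootheat` evaluates it in compiled code by a
Laplace approximation over the joint random-effect vector (the default,
used for the per-gene fits where replicate and plate effects are
crossed), with an adaptive Gauss–Hermite refinement (15 nodes,
`method = "agq"`) available whenever a single grouping factor is
active, in which case the likelihood factors by group and the
quadrature is effectively exact. The test suite holds the quadrature
path to within $10^{-4}$ of brute-force numeric integration on tiny
instances, and cross-checks fits against `lme4::glmer` with adaptive
quadrature.

The outer optimisation is Nelder–Mead over
$(\beta_0, \beta_t, s_{\mathrm{rep}}, s_{\mathrm{plate}})$ with the
random-effect SDs clipped at zero, a relative tolerance of $10^{-8}$
and an iteration cap of 200 (restarted once from the best point if the
cap is hit). Variance estimates may legitimately sit on the boundary
$\hat\sigma^2 = 0$ — standard behaviour for variance components — and
are reported as zero with the fit still flagged converged. Fixed
effects are initialised at the closed-form Poisson GLM group-mean
estimates, which are also the exact MLE when both variances are zero.
Non-convergence is flagged per gene, never raised.

### Storey q-values

$\pi_0$ is estimated on the grid $\lambda = 0, 0.05, \ldots, 0.90$ as
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$, smoothed by
a cubic smoothing spline (3 degrees of freedom) and evaluated at
$\lambda = 0.9$, then clipped to $(0, 1]$. With fewer than 20 p-values
the estimate is unstable, so $\pi_0 = 1$ is used, which reduces the
procedure to Benjamini–Hochberg; `pi0` can also be fixed explicitly.
Q-values are made monotone by a running minimum from the largest
p-value down.

## Regulatory module networks

Module-network inference explains the expression of gene modules
(log2 fold changes across the tissue × time heat contrasts, the
"conditions") by binary decision trees over transcription-factor
states.

**Discretisation.** Each TF's values are grouped into
K ∈ {1, 2, 3} categories, where K is the number of expression ranges
the TF occupies among > 3, < −3, and in between; K-means with K
centers (initialised at the range means, hence deterministic) assigns
the labels 1 (highly expressed), 0 (normal), −1 (lowly expressed) by
center ordering. The ±3 cutoffs apply to the same scale as the input
matrix and are exposed as arguments, since a fold-change versus
log2-fold-change convention cannot be pinned down; K = 1 (a TF that
never leaves one range) is permitted and yields a constant state.

**Trees.** An internal node queries one TF with one of two predicates
— `is_up` (state 1) or `is_down` (state −1) — partitioning the
conditions; a node consumes one predicate and deeper nodes may reuse
the same TF with the other predicate. Leaves hold condition subsets
with a Gaussian model: the sample mean and maximum-likelihood variance
of all member-gene values under the leaf, floored at $10^{-4}$ to
prevent degenerate infinite likelihoods. Learning is greedy top-down:
the split maximising the summed Gaussian log-likelihood is accepted
only if the gain is positive and both children keep at least
`min_leaf_conditions = 2` conditions; `max_depth` defaults to 3. The
suite verifies the greedy depth-1 choice against exhaustive
enumeration of all (TF, query) splits.

**Alternation.** `fit_module_network()` seeds gene clusters with
K-means (k-means++ initialisation under the run seed; K is a user
parameter — the ten modules reported for the real data emerged from
that data, not from a selection rule), then alternates tree learning
and gene reassignment until the total log-likelihood improves by less
than `tol` or `max_iter` is reached. Reassignment moves each gene to
its best-scoring module, with ties keeping the current assignment and
then taking the lowest module index; empty modules are dropped and K
reduced. Because a freshly grown greedy tree is not guaranteed to beat
the previous structure refit to the new membership, each relearning
step keeps the better of the two per module — this makes the recorded
likelihood history non-decreasing by construction, which the package
asserts on every run.

## iTRAQ protein quantification

Scan-level reporter-ion fractions are converted to channel intensities
as $I_c = B \cdot r_c / \sum_k r_k$, where $B$ is the base-peak
intensity — so channel intensities always sum to the base peak. (The
verbal description of this step in the source methods, "dividing the
base peak intensity by the fraction", is arithmetically implausible —
it would inflate the weakest channels — so the multiplication form is
implemented; this is the one deliberate reading choice in the module.)
Multiple scans of a peptide are consolidated by channel-wise summation
before log2 transformation; channels that are zero after summation
become missing values, never $-\infty$.

Normalisation is two-step: (1) subtract from each peptide the mean of
its two pooled-reference channels, bridging plexes onto a common scale
— which two of the eight channels carry the pooled reference is
configurable (default 4 and 8), and bridging is per plex; (2) central
tendency normalisation, shifting every plex × channel column so its
median matches the global median, removing channel bias.

`rrollup_protein()` aggregates peptides to a protein profile: the
reference peptide is the one with the most presence (fewest missing
values), ties broken by highest median abundance and then input order;
every other peptide is shifted by the median difference to the
reference over shared samples (peptides sharing no samples are
excluded); the protein value per sample is the median of the scaled
peptides. Note the protein's absolute level is pinned to the reference
peptide — an arbitrary constant that cancels in all group differences.

Testing is a per-time-point one-way ANOVA between the 25 °C and 40 °C
groups, requiring at least two values per group (otherwise the protein
is marked untestable), with Benjamini–Hochberg correction across
proteins within each time point (matching per-time-point testing; a
global-correction switch exists) and
$\log_2 \mathrm{FC} = \overline{x}_{40} - \overline{x}_{25}$. A
protein is called at adjusted p < 0.05 and fold change ≥ 2.

## qPCR and integration

qPCR expression follows $E = P_\mathrm{eff}^{-\Delta C_t}$ with
$\Delta C_t = C_t(\mathrm{gene}) - C_t(cons6)$ (the housekeeping
normaliser; the sign convention is the package's, as only the
normaliser is specified) and primer efficiencies restricted to
$(1, 2]$. Fold changes are ratios of heat to control expression.

`overlap_partition()` partitions two directional DE sets per direction
into common and unique genes, preserving the identity
$|\mathrm{unique}_a| + |\mathrm{common}| = |a|$; genes regulated in
opposite directions in the two sets are excluded from the common sets
and reported separately as discordant, since their treatment in a
plain Venn count is ambiguous. `timepoint_core()` intersects
directional sets across time points; the fraction it reports has a
configurable denominator (union of all regulated genes, or mean
per-time-point set size) because the published "14% regulated at all
four time points" is not reproducible from the printed counts under
either convention (645/9246 ≈ 7%) — the discrepancy is documented, not
resolved. Term enrichment uses the exact hypergeometric upper tail per
term with BH (default) or Storey adjustment.

## The synthetic-data generators

Each generator emulates exactly the statistical structure its
downstream stage assumes, and emits the planted truth for recovery
testing:

* `gen_rnaseq_counts()` draws Poisson counts with log-mean
  `log(libsize) + baseline + treatment effect + replicate intercept +
  plate intercept`. Defaults mirror the study design: two tissues,
  times 0/3/6/12/24 h, two replicates, two plates,
  $\sigma_\mathrm{rep} = \sigma_\mathrm{plate} = 0.1$, 10% true DE
  genes at two-fold. Library sizes are uniform on 0.8–1.2 million —
  the study does not state per-sample depths, so this is a configurable
  package choice sized so that per-gene counts span roughly 5–5000;
  gene baselines get a log-normal spread (SD 1 natural-log unit).
* `gen_module_expression()` plants per-module regulator trees over
  discretisable TF profiles (states drawn per condition; continuous TF
  expression at ±5 with SD 0.5, consistent with the ±3 cutoffs), with
  leaf means spaced `leaf_sep` apart, a distinct offset per module so
  modules stay distinguishable even when two trees query the same TF,
  and i.i.d. Gaussian noise (`noise_sd`).
* `gen_itraq_peptides()` lays out one 8-plex per tissue × time block:
  three 25 °C and three 40 °C replicates plus two pooled-reference
  channels carrying the mean sample signal. Reporter intensities are
  the true log2 abundances on the linear scale times a lognormal
  per-scan factor, and the base peak is their sum, making the channel
  step exactly invertible. Missingness is completely at random at
  `missing_rate`, drawn per peptide × channel and applied to all scans
  of that peptide — scan-level zeroing would make consolidated sums
  systematically low (an artifact of summation), whereas whole-channel
  absence exercises the rollup's presence rules as intended.
* `gen_qpcr()` back-computes ΔCt so the requested fold changes are
  reproduced exactly at zero noise.

All generators are bit-reproducible given `seed`; stage seeds are
derived deterministically from the master seed.

**What passing tests do not show.** Counts are Poisson because that is
the fitted model; there is no overdispersion knob, so the calibration
results say nothing about negative-binomial-like biological
variability. Missingness is completely at random, not
intensity-dependent as in real reporter-ion data. Peptide
identification error (search FDR), isotope impurity, alignment and
base-calling artifacts are all upstream of the pipeline's scope and
absent from the simulations. Recovery of planted modules at
separation-to-noise ≥ 10 demonstrates algorithmic correctness, not
performance on the much noisier real fold-change matrices.

## Problem sizes and calibration checks

The package's own calibration checks (test suite and
`scripts/acceptance.R`) use: 2000 genes × 4 samples × 20 simulations
for gene-level FDR control at the 1% level; 500 proteins × one 8-plex
× 20 simulations for protein-level FDR control at the 5% level; 200
genes × 20 conditions × 20 seeds for module recovery (adjusted Rand
index 1 and planted split-TF recovery); 60 random tiny instances for
the quadrature-versus-integration oracle; and 100 random instances for
the greedy-versus-exhaustive tree oracle. These sizes are the
package's choice of a desk-scale experiment that keeps Monte-Carlo
error small relative to the tolerances being checked.

## Known limitations

* With two replicates and two plates per contrast (four observations),
  variance components are weakly identified and often sit at the
  boundary; the LRT is then effectively a Poisson GLM test. This
  matches the design being emulated but limits the benefit of the
  random terms at this scale.
* The Laplace approximation is used when both random terms are active
  (the crossed design does not factor by group); its error is small at
  the count magnitudes generated but is not separately bounded by the
  quadrature oracle in that regime.
* Greedy tree learning is locally optimal per node; only depth-1
  optimality is guaranteed (and checked) against enumeration.
* The module count K is user-specified; no model-selection rule is
  provided.
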