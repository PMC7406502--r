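---
title: "Methods: intrinsic connectomes, the network-based statistic, and outcome prediction"
author: "nbsconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic connectomes, the network-based statistic, and outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsconn)
```

## The scientific problem

Roughly half of PTSD patients do not respond to trauma-focused cognitive
behavior therapy (TF-CBT). A connectome-wide view asks whether the brain's
*intrinsic* functional architecture — the correlation structure of
spontaneous BOLD fluctuations, estimated here from task-fMRI residuals —
carries a signature of who will respond. `nbsconn` implements that analysis
chain as a reusable, testable pipeline:

1. build one Fisher-z connectome per subject and session from parcel-level
   time series (nuisance regression, motion censoring, band-pass filtering);
2. compute treatment-outcome scores from pre/post symptom totals
   (residualized change, the 50% responder rule);
3. find outcome-associated subnetworks with the network-based statistic
   (NBS), controlling familywise error through a permutation null of the
   maximal suprathreshold component;
4. summarize the identified subnetwork into a per-subject composite and
   per-network-pair means, and test group differences at baseline and
   group-by-time change;
5. quantify individual-level predictive value with leave-one-out
   cross-validated logistic models.

Because clinical imaging cohorts of this kind are rarely shareable, the
package ships a first-class synthetic-cohort generator with planted ground
truth, so every stage can be exercised and validated end to end.

## Intrinsic connectivity from task residuals

Each run is a nodes-by-time matrix with companion motion parameters, task
covariates, optional white-matter/ventricle signals, and a framewise
displacement (FD) trace.

**Censoring.** A frame is kept iff FD ≤ 0.5 mm *and* median-normalized
DVARS ≤ 1.5. The literature establishes censoring but rarely one canonical
threshold pair; both are configuration keys with these conventional
defaults. The first frame has no DVARS and is judged on FD alone. A run
keeping fewer than `max(5, 10%)` of frames is unusable and is dropped from
concatenation.

**Nuisance model.** Per run, node series are regressed (OLS) on: intercept,
linear drift, the task covariates, the Volterra expansion of the six
realignment parameters realized as the Friston-24 set
$[R, R_{t-1}, R^2, R_{t-1}^2]$, any additional nuisance signals, and one
spike indicator per censored frame. Zero-variance columns on retained
frames are dropped; rank-deficient designs fall back to pivoted least
squares (the residual projection is unaffected). Residuals are exactly
orthogonal to the design, which the tests assert.

**Filtering.** Residuals are band-pass filtered at 0.009–0.08 Hz with a
4th-order zero-phase Butterworth (`signal::filtfilt`). Two numerical
choices matter: series are demeaned first (so DC is removed exactly), and
each series is odd-reflection padded by about two periods of the low cutoff
before the forward–backward pass, because an unpadded forward–backward pass
leaks a large fraction of a constant input through edge transients. The
filter is applied on the regular temporal grid (spike regressors having
absorbed censored frames), and censored frames are excluded afterwards at
correlation time; computing on censored-in residuals is supported but not
default, since the study literature does not fix this order of operations.

**Connectome.** Retained frames are z-scored per run and concatenated
across usable runs; Pearson correlations are computed per node pair and
Fisher-z transformed, with $|r|$ clamped at $1-10^{-7}$ so degenerate pairs
stay finite. The diagonal is exactly zero and the matrix exactly symmetric.
Zero-variance node series get all-zero edges, with a warning. Runs are
concatenated rather than averaged per run: with per-run standardization the
two differ little, and concatenation uses short runs more efficiently.

## Outcome scores

The **residual change score** is the sign-flipped residual from the
least-squares regression of post-treatment on pre-treatment CAPS totals, so
higher scores mean greater improvement independent of initial severity.
In-sample scores have exactly zero mean and zero correlation with the
baseline score. One published sentence reads as regressing pre on post; the
residualized-gain convention (post on pre) is the default here, and the
alternative direction is available via `direction = "pre_on_post"`.
The **responder rule** is an inclusive 50% reduction:
$(\mathrm{pre}-\mathrm{post})/\mathrm{pre} \ge 0.5$. The two quantities are
kept separate: the residual score feeds the edgewise correlations, the
binary rule defines the responder split and the prediction target.

## The network-based statistic

For each of the $n(n-1)/2$ edges, the per-edge statistic is either the
Pearson correlation of edge z with a continuous outcome (p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df) or a pooled-variance two-sample
t. Edges with $p$ below the component-forming threshold (default 0.001)
define a graph; its connected components are scored by *extent* (edge
count). The null distribution of the maximal component extent is built by
reshuffling the outcome (or labels) with a seeded generator — 5000
permutations by default — and each observed component receives

$$p_{\mathrm{corr}} = \frac{1 + \#\{\text{perm max} \ge \text{size}\}}{1 + n_{\mathrm{perm}}},$$

so corrected p-values are never exactly zero and ties count toward the
null. Intensity scoring (sum of suprathreshold statistics) exists behind a
flag; extent is the default because component "size" is the conventional
reading. One-sided tails are run separately per sign by default in the
pipeline (a negative-direction association — lower connectivity, more
improvement — is the expected clinical pattern, but the opposite sign is
screened symmetrically); a two-sided variant is available.

With covariates, both the outcome and every edge are first residualized on
the covariates and the residualized outcome is permuted (Freedman–Lane
style) — the standard choice where no scheme is prescribed.

**Calibration and conservativeness.** On 200 null cohorts at the package's
test scale (40 nodes, 36 patients, 500 permutations), the default
two-tailed screen rejects on a fraction of datasets close to the nominal
5% (replications across seed streams range roughly 3–9%; the union of two
tails is bounded above by 10%, and the tie-conservativeness described next
pulls each tail well below its nominal level). A *single* two-sided extent
run is measurably conservative (≈1.5%) at these sparse settings: with ~0.8 expected
suprathreshold edges per dataset, the max-component extent is a small tied
integer, and the tie-conservative plus-one convention under-rejects. This
is a known property of extent-based permutation tests, not an
implementation artifact; intensity scoring or denser thresholds reduce the
discreteness.

## Composite and network-pair analyses

The **composite metric** is the unweighted mean z over the significant edge
set, one scalar per subject. Edges also aggregate by the unordered pair of
their endpoint networks; the edge-count-weighted mean of pair means equals
the composite to $10^{-10}$, an identity the tests enforce. Baseline
comparisons use a one-way ANOVA (pooled PTSD vs controls) plus pairwise
Welch contrasts (responders/nonresponders/controls); change over time uses
a mixed between-within ANOVA (`aov` with a subject error stratum), with
paired-t and Welch post hoc contrasts gated on a significant interaction
and BH-FDR adjusted. Welch between-group and paired within-group t-tests
are this package's choice where "post hoc tests" is otherwise unspecified.
Effects whose sum of squares is zero to machine precision report
$F = 0, p = 1$ rather than 0/0. Subjects missing a follow-up are excluded
listwise from time analyses only, mirroring follow-up attrition handling.
Across measures (whole network plus each pair), p-values are BH-FDR
adjusted within contrast type.

## LOOCV prediction

The classifier is an L2-regularized logistic model fit by IRLS with a
fixed, weak ridge penalty (λ = 1 on standardized features, intercept
unpenalized) — implemented in the package so that single-feature models and
deterministic fits are possible; there is no hyperparameter search by
design. Each subject is predicted by a model trained on the remaining
n−1, with features standardized by training-fold statistics only; the tests
assert the resulting leakage guard (flipping a held-out label never changes
its own prediction). The base feature set is {age, sex, baseline CAPS, the
three DASS subscales}; the augmented set adds the connectivity composite.
Class imbalance (about 25/11) is deliberately left unadjusted. Models are
compared by a paired permutation test on per-subject correctness
indicators (sign-flip within subject, two-sided, plus-one convention).

## The synthetic-cohort generator

`sim_config()` fixes the study conditions: 36 patients and 36 controls,
two sessions, five 120-frame runs at TR 2.5 s, a 40-node atlas (36
cortical nodes over six intrinsic networks plus four subcortical nodes)
for the simulation-scale work, and a connected 15-edge planted subnetwork.
The packaged 343-node atlas (333 cortical across 12 networks + 10
subcortical) is a synthetic label table with the structure of a standard
high-resolution parcellation, used for format- and scale-level checks.

**Connectome model.** The group mean matrix is a block structure: within-
network correlation 0.35, between-network 0.10 (z-transformed). Each
patient carries a scalar planted deviation δ ~ N(0, 0.15) added to all
planted edges; each edge additionally gets independent N(0, 0.1)
measurement noise per session. The improvement fraction is

$$\mathrm{improvement} = a - \beta \cdot \overline{z}_{\mathrm{planted}} + \varepsilon,\qquad \varepsilon \sim N(0, 0.1),$$

with slope β = 1.5 (lower connectivity → greater improvement, matching the
expected clinical direction; the sign is configurable) and intercept $a$
calibrated so the expected responder fraction is 25/36. These defaults
give per-edge outcome correlations around 0.7–0.8 — a strong but not
degenerate planted effect, chosen once so that recovery is a meaningful
test of the chain rather than of luck. Baseline CAPS is N(72, 14)
truncated to [45, 120], matching the printed cohort moments; post CAPS
derives from the improvement fraction and is clipped to the scale range
with a warning. At the post session the planted deviation shrinks by the
fraction `group_time_shift` (default 0.8) toward the control mean, so
responders (who start low) rise and nonresponders (who start high) fall
while controls only re-draw measurement noise — enough structure to
exercise the group-by-time interaction, without claiming a full
repeated-measures covariance model.

**Time-series model.** Node signals mix per-network latent AR(1) factors,
a global factor, and AR(1) node noise, with loadings chosen so the target
within/between-network correlations hold after denoising. Contaminants are
exponentially smoothed boxcar task covariates (raw boxcars produce
unphysiological frame-to-frame jumps that trip DVARS at block boundaries),
linear drift, and motion spikes: Bernoulli frames that receive a large
additive burst in the data, a jump in the realignment parameters, and an
FD value well above threshold. A burst also elevates DVARS on the
*following* frame, so default-threshold censoring removes roughly twice
the nominal spike rate; the FD criterion alone isolates exactly the spiked
frames, which is how the generator's rate is verified.

**What the generator does not emulate.** No hemodynamic forward model, no
voxel-level structure, no spatial autocorrelation between neighboring
parcels, no heavy-tailed motion, no site or session drift in the
connectome mean, and edge noise is independent across edges (real
connectome noise is correlated through shared nodes). Passing tests
demonstrate that the statistical machinery behaves as specified under a
known model — not that any particular clinical finding generalizes.

## Problem sizes and reproducibility

The validation suite and the acceptance script use the 40-node atlas, 36+36
subjects, 500 permutations, and 50–200 replicate cohorts — sizes at which
the full chain (200 null cohorts through NBS, both tails) completes in
about a minute on a single CPU while leaving the binomial error of the
measured rates small. All randomness flows through explicit integer seeds:
simulation via `sim_config(seed=)`, permutation streams via the `seed`
arguments, and the pipeline derives per-stage substreams from one master
seed. Identical configurations are bit-identical on rerun, including
written artifacts.

## Known limitations

- The empirical findings of any specific clinical cohort are not
  reproducible here; the package validates machinery, not results.
- A single extent-based NBS run is conservative at sparse suprathreshold
  densities (see calibration above).
- The mixed ANOVA uses `aov` sums of squares; with unbalanced groups the
  interaction test is conditional on main effects, which is standard but
  not the only convention.
- LOOCV within a single cohort over-estimates generalization when the
  feature was discovered in the same sample; the package reproduces the
  procedure and its guards, and the comparison-to-base test quantifies
  *additive* value only.

## A worked example

```{r example, eval = FALSE}
library(nbsconn)
report <- run_pipeline(sim = sim_config(seed = 1), n_perm = 500, seed = 1)
print(report)
#> <pipeline_report>
#>   NBS (negative tail): 1 component(s), 1 significant
#>   NBS (positive tail): 0 component(s), 0 significant
#>   significant edge set: 15 edges
#>   LOOCV accuracy: base 69.4%, augmented 77.8% (p = 0.3761)
```

The significant component recovers the planted 15-edge subnetwork; the
composite built on it improves response classification over the
demographic/clinical base model, as the design intends.
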