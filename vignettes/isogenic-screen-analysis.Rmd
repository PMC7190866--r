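---
title: "Methods: isogenic-panel drug-screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isogenic-panel drug-screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscreen)
```

## The analysis problem

An isogenic cell-line panel — here three lines derived from one p53-null
lung squamous carcinoma background, re-expressing either wild-type p53 or
the R158G gain-of-function mutant — is screened against a compound
library at one or two doses, read out by luminescent viability assay in
384-well plates. The questions the pipeline answers are the standard
ones for this design:

1. Which compounds are *efficacious* anywhere on the panel, and which
   are *selective* for one genotype?
2. For selective compounds, how large is the potency difference
   (ED50 fold-change) between lines?
3. Does a chosen modulator *synergize* with a cytotoxic drug, and in
   which genotype (Bliss independence)?
4. Which genes are *direct transcription-factor targets* — bound near
   their TSS and transcriptionally perturbed after treatment?

## Models and statistics

### Inhibition score

Each treated well is normalized to the vehicle wells of its own plate:

$$I\text{-score} = \left(1 - \frac{L_\text{well}}
{\operatorname{median}\, L_\text{DMSO}}\right)\times 100 .$$

The median (not mean) of the DMSO wells makes the baseline robust to a
few failed control wells. Scores are deliberately not clipped: 0 means
"equal to vehicle", 100 means "no signal", and negative values record
growth stimulation, which is real information for compound triage. The
DMSO median is computed **per plate** by default so that any plate-level
multiplicative effect (reagent batch, reader gain) cancels exactly;
pooled-run normalization is available for designs without per-plate
controls. With an even number of controls the median is the mean of the
central pair.

### Hit calling

A compound is *efficacious* when its I-score strictly exceeds 50% in at
least one line. A compound is *line-selective* when it is strictly above
50% in exactly one line and strictly below 50% in every other; above
everywhere is *pan-active*; any other efficacious pattern — including
scores landing exactly on the threshold — is *other_selective_pattern*.
Strict inequalities mirror the printed "> 50%" / "< 50%" rule; a score
of exactly 50 therefore deliberately fails both sides. Both thresholds
are configurable.

When a screen uses two doses (the default emulates 0.1 and 1 µM), the
compound-by-line profile takes the **maximum I-score over doses**: a
compound active at either dose counts as active. The aggregation rule is
recorded in the profile's metadata. This is a genuine design choice —
single-dose selection would also be defensible — and the chosen rule is
the more inclusive one.

Profiles are clustered by complete-linkage agglomeration on Euclidean
distances between compound rows (`stats::hclust`), the textbook choice
for inhibition heatmaps; the merge heights are verified in the test
suite against a brute-force all-pairs oracle.

### Dose-response

Viability curves use the four-parameter logistic

$$v(d) = \text{bottom} + \frac{\text{top} - \text{bottom}}
{1 + (d/\mathrm{ec}_{50})^{h}},$$

fitted by Levenberg–Marquardt least squares with an analytic Jacobian.
The free parameters are (bottom, span, log ec50, hill) with span ≥ 0 and
hill > 0, so top ≥ bottom and ec50 > 0 hold by construction and the
optimizer works on a well-scaled log-dose axis. Initialization is
top = max response, bottom = min response, ec50 = geometric-mean dose,
hill = 1, with one restart from a perturbed start on failure. Fits are
unconstrained by default; fixing bottom = 0 and/or top = 100 is exposed
via `constrain=` because published IC50s are often computed both ways.

Two potency summaries are reported because the field uses the terms
loosely: **ed50** is the curve midpoint (the ec50 parameter), and
**absolute IC50** is the dose where the fitted curve crosses 50%
viability, obtained in closed form; the two coincide exactly when
(bottom, top) = (0, 100). A curve that never crosses 50% has no absolute
IC50 and is flagged rather than extrapolated. Line selectivity at the
dose-response level uses fold = ed50(reference) / ed50(target), flagged
at ≥ 10-fold (inclusive at exactly 10). Modulator effects are the ratio
IC50(drug alone) / IC50(drug + modulator); > 1 means sensitization.

### Bliss independence

Responses enter the synergy module as fractional inhibition
f = clip(1 − viability/100, 0, 1). Treating single-agent inhibitions as
independent kill probabilities, the expected combination inhibition is
$f_A + f_B - f_A f_B$, and the per-cell combination index is

$$\mathrm{CI} = \text{expected} - \text{observed},$$

so CI < 0 is synergy (observed inhibition beat the independence
prediction) and CI > 0 antagonism. The difference form is chosen over a
ratio because it stays defined at zero expected inhibition; the sign
convention matches the screen's reporting. Expected values are computed
from the dose-0 margins of the same replicate-averaged matrix, so the
margins themselves always score 0. Interior cells where either single
agent already inhibits ≥ 0.99 are flagged saturated and excluded from
summary statistics: near full kill the score is numerically meaningless.
Clipping happens before averaging; raw mean viability is retained in the
matrix object for audit. One consequence worth knowing: at near-zero
inhibition, clipping negative per-replicate values to 0 biases margin
estimates slightly upward, so the mean CI of a truly independent pair
sits a few thousandths above zero rather than exactly at it.

### Direct-target calling

Peak coordinates are BED-convention 0-based half-open. Peaks are first
shortlisted at fold enrichment ≥ 5, pileup ≥ 25 (both inclusive, as
printed) and q < 0.01 (strict). Peak-to-TSS distance is 0 when the TSS
lies inside the peak and otherwise the distance to the nearest covered
base, `min(|tss - start|, |tss - (end - 1)|)` — boundary-anchored, not
summit-anchored, because summits are not among the shortlist fields. A
gene is called a direct target when a shortlisted peak lies strictly
within 10 kb of its TSS **and** its |log2 fold-change| strictly exceeds
1.5. The absolute-value reading is deliberate: both induced and
repressed genes count, with direction retained in the output. Calls are
verified against a brute-force all-peaks-by-all-genes oracle in the
tests.

## The synthetic-data generator

Every downstream stage is exercised on seeded synthetic data with
planted ground truth, so the whole pipeline is testable without any
external dataset.

**What it emulates.** A three-line panel screened in 384-well plates in
triplicate at 0.1 and 1 µM, with 16 DMSO wells in the right-most plate
columns (the plate map is explicit, not inferred). True inhibition
follows a Hill curve $f(d) = e_\max d^h / (\mathrm{ed}_{50}^h + d^h)$ —
the monotone special case of the 4PL fitted downstream, so the planted
truth is exactly recoverable. Well noise is multiplicative log-normal
with log-mean 0 and CV 5% by default: plate-reader error is
signal-proportional and positive, which additive Gaussian noise is not.
The default demonstration library is 200 compounds: 17 mutant-selective
(ed50 0.05 µM in the target line, 50 µM elsewhere — a 1000-fold
window), 5 selective for each other line, 20 pan-active, 5 dual-active,
and the rest inactive. The 17 matches the screen-scale hit count this
design emulates; the potency window is wide enough that recovery at 5%
noise is expected to be error-free, which is what the acceptance suite
asserts.

**Combination matrices** add a per-line Bliss deviation delta to the
expected inhibition in combination wells only (never the margins),
clipped to [0, 1]. The demonstration pair plants delta = +0.2 (synergy)
in the mutant line, −0.1 (antagonism) in wild-type and 0 in the null
line, mirroring the qualitative contrast the screen reports.

**Genomic fixtures** place genes 100 kb apart on one synthetic
chromosome so peak-gene assignment is unambiguous. Planted targets get a
shortlist-passing peak within 8 kb and |log2FC| in [2, 3.5]; every decoy
violates exactly one calling condition (peak 15–45 kb away, peak failing
the enrichment shortlist, or |log2FC| ≤ 1.2), cycling through the three
failure modes so each filter is exercised.

**What it does not emulate:** reader cross-talk, spatial/edge effects
(a plate-shift term exists but defaults to 0, since the emulated design
states no plate-level variance components), cell-cycle dynamics,
sequencing reads, or correlated noise between replicates. Passing tests
therefore demonstrate correctness of the *computations* under the
stated noise model, not robustness to every artifact of real plates.

## Numerical choices and degenerate inputs

- RNG state is saved and restored around every generator, so seeded
  generation never perturbs user code; pipeline stage seeds derive from
  the single run seed by fixed offsets.
- A constant response vector is flagged degenerate before fitting; a fit
  whose span collapses below 10⁻⁶ is reported unconverged rather than
  returning an arbitrary ec50.
- Scores exactly at a strict threshold fail it, by construction, and the
  relevant tests pin this (50% inhibition, 10 kb, log2FC 1.5).
- Validation is total: a malformed screen table (negative luminescence,
  duplicate wells, plates without controls) raises a structured error
  naming the offending rows, never a partial dataset.
- CSV output is deterministic (fixed column order, rows sorted by plate
  and physical well position, full-precision numbers), so same-seed
  runs are byte-identical and the pipeline manifest is reproducible.

## Problem sizes

The test and demonstration sizes are chosen to exercise every code path
at interactive speed: the full demonstration screen is 3 lines × 200
compounds × 2 doses in triplicate (about 4 000 wells); dose-response
calibration uses 100 seeded fits of 8-dose triplicate curves; synergy
matrices are 4 × 6 dose grids in triplicate; genomic fixtures are 50
genes with 5 planted targets. Each is comfortably larger than the
minimum needed to distinguish correct from incorrect behavior, and the
whole suite runs in seconds.

## Known limitations

- The hierarchical clustering delegates to `stats::hclust`; equal-
  distance merge ties follow its internal order rather than a
  documented lexicographic rule. Merge heights are unaffected.
- Bootstrap or profile-likelihood confidence intervals for ec50 are not
  implemented; `rss` and `n_points` are reported for downstream error
  propagation.
- The comet-assay tail moment implements the intensity-difference
  formula as printed in the emulated protocol; the classical
  centroid-distance Olive definition is available separately
  (`olive_tail_moment_canonical`) because the two differ and users
  should be able to compare.
- The ISH rubric has gaps at non-integer dot counts ("1–3", "4–9"); the
  implementation documents and uses half-open bins [0,1), [1,4),
  [4,10), [10,16), [16,∞) on the per-cell mean.

## A short worked example

```{r example, eval = FALSE}
library(isoscreen)

res <- run_pipeline(run_config(seed = 1, out_dir = "demo_run"))
table(res$hits$selectivity_class)
res$fold$fold                      # ED50 fold-change, mutant vs wt
sapply(res$surfaces, function(s) s$summary$mean_ci)
res$targets$gene_id                # called direct targets
```

The same computation, plus calibration summaries, is what
`scripts/acceptance.R` re-runs from scratch and writes as JSON.
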