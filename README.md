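# isoscreen

Analysis pipeline for high-throughput drug screens on **isogenic
cell-line panels** — panels that differ in a single genetic lesion, such
as a p53-null lung carcinoma background re-expressing wild-type p53 or a
gain-of-function point mutant. The package takes long-format
plate-reader tables from screen to biology: vehicle-normalized
inhibition scoring, genotype-selective hit calling, dose-response
potency comparison, Bliss-independence synergy surfaces, and
direct-transcription-factor-target annotation from ChIP peaks and
expression changes. A seeded synthetic-data generator with planted
ground truth makes the entire pipeline verifiable end to end.

Intended users: screening-facility analysts and computational biologists
who have plate-level viability data for a small isogenic panel and want
the standard analyses with explicit, auditable thresholds.

## The statistics at the core

**Inhibition score.** Each treated well is normalized to the vehicle
(DMSO) wells of its own plate:

    I-score = (1 − L_well / median(L_DMSO)) × 100

0 at the vehicle median, 100 at zero signal, negative under growth
stimulation (retained, not clipped).

**Selective hit calling.** Efficacious ⇔ I-score > 50% in ≥ 1 line
(strict). Line-selective ⇔ > 50% in exactly one line and < 50% in all
others; all lines above ⇒ pan-active. Profiles over the panel are
clustered by complete linkage on Euclidean distances.

**Dose-response.** Four-parameter logistic
`v(d) = bottom + (top − bottom) / (1 + (d/ec50)^hill)` fitted by
Levenberg–Marquardt with analytic gradients; reports the curve midpoint
(ed50) and the absolute 50%-viability crossing (IC50), potency
fold-changes between lines (flagged at ≥ 10-fold), and IC50 shifts under
a fixed modulator.

**Bliss independence.** With single-agent fractional inhibitions f_A,
f_B, the expected combination inhibition is `f_A + f_B − f_A·f_B` and
each dose pair scores `CI = expected − observed`: CI < 0 synergy,
CI > 0 antagonism.

**Direct targets.** Peaks shortlisted at fold enrichment ≥ 5, pileup
≥ 25, q < 0.01; a gene is a direct target when a shortlisted peak lies
< 10 kb from its TSS (BED 0-based half-open, boundary-anchored distance)
and |log2 fold-change| > 1.5.

## Worked example

The demonstration pipeline simulates a 3-line × 200-compound screen in
triplicate at 0.1 and 1 µM with 5% well noise, 17 planted
mutant-selective compounds, a planted synergy/antagonism drug pair, and
a 50-gene genomic fixture with 5 planted direct targets:

```r
library(isoscreen)
res <- run_pipeline(run_config(seed = 1, out_dir = "demo_run"))

table(res$hits$selectivity_class)
#>                inactive          NULL_selective other_selective_pattern
#>                     148                       5                       5
#>              pan_active         R158G_selective            WT_selective
#>                      20                      17                       5
```

All 17 planted mutant-selective compounds are recovered, none
misclassified. Dose-response confirmation of the first of them:

```r
res$fits$p53_R158G
#> dose_response_fit: bottom 5.37, top 98.8, hill 1.13, ec50 0.05991 uM (rss 5.15, n = 8)
round(res$fold$fold, 1)   # ED50 fold-change, wt vs mutant
#> [1] 1707.1
```

The fitted midpoint (0.06 µM) recovers the planted 0.05 µM within the
noise, and the mutant line is ~1700-fold more sensitive than wild-type
(planted: 1000-fold; the wild-type curve midpoint is only weakly
constrained by the tested dose range). The synergy contrast across the
panel:

```r
sapply(res$surfaces, function(s) s$summary$mean_ci)
#>  p53_null    p53_wt p53_R158G
#>     0.007     0.108    -0.197
round(res$ic50_shifts, 2)
#>  p53_null    p53_wt p53_R158G
#>      0.91      0.61      2.36
```

Mean interior CI is −0.197 in the mutant line (planted synergy
delta +0.2), +0.108 in wild-type (planted antagonism −0.1), ≈ 0 in the
null line — and the modulator shifts the cytotoxic drug's IC50 2.4-fold
in the mutant line only. Direct-target calling returns exactly the 5
planted genes:

```r
res$targets$gene_id
#> [1] "GENE048" "GENE025" "GENE018" "GENE013" "GENE047"
```

Every stage writes a CSV/TSV next to an md5 manifest and the resolved
thresholds (`run_config.txt`), so same-seed runs are byte-identical.

A thin command-line wrapper is installed at `inst/cli/isoscreen`
(`isoscreen demo --seed 7`, `isoscreen validate screen.csv --format 384`).

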