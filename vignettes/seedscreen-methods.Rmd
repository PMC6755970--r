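---
title: "Methods: B-score screening, seed-site scanning and assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: B-score screening, seed-site scanning and assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscreen)
```

# Overview

`seedscreen` implements the computational core of an arrayed
miRNA-inhibitor screen against a luciferase AR-activity reporter, and
the analyses that follow such a screen: positional-artifact-robust hit
calling on 96-well plates, canonical seed-site discovery in
arbitrary-length 3'UTRs, reporter/qPCR quantification, and association
of target expression with an AR pathway activity score. A synthetic-data
module generates every input with known ground truth, which is how the
package tests itself.

# The plate model and the B score

## Generative model

A screening plate is an 8 x 12 grid. The package models the log2 of a
well's raw luminescence (RLU) as

$$\log_2 \mathrm{RLU}_{ij} \;=\; \mu + \rho_i + \kappa_j + \beta_{p(ij)} + \varepsilon_{ij},$$

with $\mu$ the plate baseline, $\rho_i, \kappa_j$ additive row/column
positional artifacts (edge evaporation, dispensing gradients,
incubator position), $\beta_p$ the effect of the probe in the well
(zero for non-hits and for controls other than the death control), and
$\varepsilon \sim N(0, \sigma^2)$ measurement noise. Probe effects act
multiplicatively on RLU — reporter readouts are fold changes — hence
additively in log2; the polish and all scores therefore operate on
log2(RLU).

## Median polish and B score

`median_polish()` fits the two-way decomposition by Tukey's alternating
median sweeps (rows first, then columns), stopping when the reduction of
$\sum |r_{ij}|$ drops below `tol` or after `max_iter` sweeps. Medians,
unlike means, are unaffected by a minority of genuine hits in a row or
column, which is the reason this decomposition (rather than a two-way
ANOVA) underlies the B score. The fit reconstructs every non-missing
cell exactly and the effect vectors are median-centred.

The B score of a library well is its residual divided by the plate MAD,
$1.4826\,\mathrm{median}(|r - \mathrm{median}(r)|)$, the 1.4826 making
the MAD consistent for a Gaussian SD. B scores are invariant to
plate-wide additive log2 shifts and to multiplicative RLU rescaling, so
plates and cell lines are comparable without further normalisation.

Key choices, each configurable:

* **Controls are excluded from the polish and the MAD.** Negative and
  death controls are laid out in fixed columns; including them would
  bias exactly the positional estimates the polish is meant to remove,
  and the death control's large effect would inflate the MAD.
* **Sweep order rows-then-columns, `max_iter = 10`, `tol = 1e-6`** on
  the reduction of the absolute-residual sum (the conventional Tukey
  setup; 8 x 12 plates converge in a handful of sweeps).
* **Replicate aggregation by median** (`aggregate_probe_scores()`);
  a single replicate passes through unchanged, and probes with no
  usable wells are reported with status `"no-data"`, never dropped.
* **Hit rule:** $|B| \ge 6$ in at least one cell line (`call_hits()`,
  `threshold = 6`), direction from the sign of B (an inhibitor with
  B > 0 means inhibiting that miRNA *increases* AR reporter activity),
  and a common-hit flag when both lines clear the threshold with equal
  sign.

## What the null tail actually looks like

The package's own simulations (the type-I and recovery suites run by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`) show a
property of per-plate B scores worth stating plainly: under pure
Gaussian noise the B-score distribution is noticeably heavier-tailed
than standard normal. Median polish drives the residuals of cells near
their row/column medians toward zero, so the plate MAD underestimates
the spread of the remaining residuals and B scores are over-dispersed
(sd about 1.35 rather than 1). In a normal-tail idealisation
$P(|B| \ge 6)$ would be ~2e-9 and a null screen would essentially never
produce a hit; in the simulations a 983-probe, 13-plate, two-line null
screen instead produces on the order of one to two spurious
$|B| \ge 6$ calls, and the acceptance run reports the exact totals it
observed (`null_screen_hits_total`,
`hit_recovery_false_positives_total`). The rate is scale-free — it does
not depend on the noise SD or the positional-effect SDs — so it is a
property of the statistic, not of a parameter choice. Practically: the
+/-6 cutoff is already stringent, planted effects at 8x the noise SD
are recovered with sensitivity ~1 (`hit_recovery_sensitivity`), and a
rare spurious well-level call is the price of a scale estimate computed
per plate from 80 wells. Screens with replicate plates (the generator's
`n_replicates`) shrink the tail rapidly because per-probe medians are
taken before thresholding.

# Seed-site scanning

## Site taxonomy

For a mature miRNA (5'->3'), the seed is positions 2-7 (`seed6`) or 2-8
(`seed7`). Pairing is antiparallel, so in UTR coordinates (5'->3',
1-based, position 1 = first nucleotide after the stop codon) a site is
the reverse complement of the seed, with miRNA position 1 opposite the
site's 3'-most nucleotide:

| type    | definition                          | span |
|---------|-------------------------------------|------|
| 6mer    | WC pairing to positions 2-7         | 6 nt |
| 7mer-A1 | 6mer + A opposite position 1        | 7 nt |
| 7mer-m8 | WC pairing to positions 2-8         | 7 nt |
| 8mer    | pairing 2-8 + A opposite position 1 | 8 nt |

The A1 adenosine is a recognition feature of Argonaute, not a
Watson-Crick pair, which is why mutagenesis never targets it. At one
seed register only the strongest classification is reported
(8mer > 7mer-m8 > 7mer-A1 > 6mer); `types` then filters the report.
G:U wobble pairs are not accepted, `N` never matches, and the scan has
no length cap — the point of the exercise is UTRs (like AR's ~6.8 kb
one) far beyond the annotations most tools scan. DNA input is
normalised to RNA first, so T/U spelling cannot change a result.

## Wild-type vs variant UTRs, mutagenesis, conservation

`compare_wt_variant_sites()` calls a wild-type site and a variant site
the same physical site when their matched substring plus up to 15 nt of
flanking context per side are identical strings. This is a deliberately
alignment-free criterion: splice variants shift coordinates wholesale,
and 15 nt of exact context is ample to identify "the same place" while
never equating two distinct loci that merely share the 6-8 nt match.

`mutate_seed_site()` substitutes `n_mut >= 3` positions inside the
seed-pairing span, each to a base that is neither the original nor the
complement of the opposing miRNA base, then verifies by rescanning that
no site of any type survives at the locus and that all other sites of
that miRNA are untouched (retrying other position/base draws under the
given seed, erroring out if disruption is impossible within the
constraints).

`site_conservation()` maps a reference site through an alignment by
column bookkeeping and rescans each species' full ungapped sequence,
counting the species intact if a site of the same or stronger type
covers the homologous span; a site falling wholly into gaps counts as
lost, and the reference always counts as intact.

# The synthetic-data module

`simulate_screen()` draws exactly the plate model above: per-plate
row/column effects, per-well noise, planted hits with random sign and a
configurable probability of acting concordantly in further cell lines,
and a fixed large negative effect for death-control wells
(transfection-efficiency sentinels). The default layout reserves
columns 1 and 12 for controls (8 negative, 4 death, 4 empty), leaving
80 library wells, so 13 plates hold a 983-probe library; probes are
dealt evenly across plates (75-76 per plate) — a screen would not leave
its last plate nearly empty, and a sparsely populated plate makes the
plate-level MAD unstable. Defaults, chosen once as realistic for a
luminescent reporter screen: baseline 10 log2-RLU (~1000 RLU),
row/column effect SD 0.25 log2 (up to ~1.4-fold positional bias),
noise SD 0.25 log2 (~19% CV), hit fraction 0.02, hit effect 3 log2
(8-fold), cross-line concordance 1.

`simulate_utr()` plants exact site strings at requested coordinates in
a random background of specified GC content, places guard bases so a
planted 6mer is not accidentally upgraded by an adjacent A or
m8-complement, and rejection-resamples the background (capped at 1000
attempts) until rescanning returns exactly the planted truth — the
returned UTR is therefore its own certificate. miRNAs with degenerate,
self-overlapping seeds (e.g. homopolymeric cores) can make a requested
planting impossible; that raises a planting error rather than looping.

`simulate_qpcr()` writes Ct tables under perfect doubling:
`Ct = base_ct - log2(fold) + noise`, reference genes flat across
samples. At zero noise every quantification operation inverts it
exactly; at non-zero noise the mean recovered fold carries the
log-normal bias $2^{(\ln 2)\,k\sigma^2/2}$ (with $k$ the ddCt noise
variance multiplier, 3 for one target and two references), which the
tests check against a Monte-Carlo oracle rather than assuming away.

What the generators do **not** emulate: transfection-chemistry
variation, cell-density gradients beyond additive row/column terms,
probe cross-reactivity, amplification-efficiency drift, or sequence
composition of real UTRs beyond GC content. Passing the synthetic
suites therefore demonstrates the *procedures* are correct and
calibrated under the stated model, not that real screens are free of
artifacts outside it.

## The synthetic stand-in UTR panel

`synthetic_utr_panel()` deterministically builds stand-ins for the
extended wild-type AR 3'UTR (6.8 kb), the AR-V7 and AR-v567es variant
3'UTRs, and the ARHGDIA/TAGLN2/YWHAZ 3'UTRs, with miR-346, miR-361-3p
and miR-197-3p sites planted at the 1-based starts reported for the
real transcripts (407, 787, 5772, 6070 for miR-361-3p and 3185, 6283
for miR-346 and 3043, 4308 for miR-197 on wild-type AR; 981 on AR-V7;
8353 on AR-v567es; 556 and 1084 on ARHGDIA; 511 on TAGLN2; 17 and 1713
on YWHAZ). The v567es stand-in reuses the wild-type sequence verbatim
and appends a 3' extension, mirroring its biology and preserving
flanking context for the shared-site comparison. Planted types follow
the printed span lengths (6 nt spans as 6mers, 7 nt as 7mer-m8, 8 nt as
8mers, and the explicitly named 7mer-A1 at 3185). The backgrounds are
random — the annotated sequences are not redistributed — so the panel
validates the scanner and its coordinate conventions end-to-end against
known truth; it does not re-derive the coordinates from the public
annotation, and any analysis against the real sequences should load
them with `read_utr_fasta()` and expect to report, not absorb, a
constant offset if the annotation version differs.

# Quantification conventions

* **Reporter assays:** normalised activity = luciferase / beta-gal per
  replicate (transfection-efficiency correction); fold = condition mean
  over control mean, so the control is exactly 1; SEM across biological
  replicates.
* **ddCt:** several reference genes are combined by the arithmetic mean
  of their Cts (the geometric mean of their expression); amplification
  efficiency is fixed at 2.0 — no efficiency correction is applied, so
  folds from low-efficiency assays will be compressed. ddCt is
  invariant to adding a constant to all Cts of a sample. A sample
  missing a reference yields a per-sample error record, not a global
  failure.
* **Percent of input:** `100 * input_fraction * 2^(ct_input - ct_ip)`;
  the `input_fraction` term corrects for assaying only a fraction of
  the lysate as input (equivalently, adjusting the input Ct by
  `+log2(input_fraction)`), monotone decreasing in the IP Ct.
* **Transcript stability:** fraction remaining = (ddCt fold after
  transcription block) / (vehicle fold); ratios of fractions compare
  stabilisation between transfections.
* **Growth:** per-condition mean absorbance fold versus the day-0 mean;
  folds below 1 distinguish net cell loss from growth arrest.
* **Tests:** two-sided equal-variance Student's t, tiers `*`/`**`/`***`
  at 0.05 / 0.005 / 0.0001. Two constant, distinct groups return the
  machine-floor p rather than an error.

# AR activity score and association

The activity score of a sample is the sum of cross-sample z-scores of
log2(FPKM + 1) over the signature genes present in the matrix (genes
with zero variance contribute 0; `aggregate = "mean"` is available when
signatures of different sizes must be compared). Summing z-scores is
the simplest "accumulation" reading of a pathway score; it is invariant
to per-gene affine rescaling, needs at least two samples, and reports
how many signature genes were found. The signature itself is an input
file — the bundled 43-gene list of androgen-responsive genes is a
placeholder for tests and examples, not a published signature — and no
directionality weights are applied, so a signature containing
AR-repressed genes should be split or sign-adjusted by the user.
`linreg()` is ordinary least squares with the slope's two-sided t-test
p-value; distinct sub-populations in a scatter (as splice-variant
status can produce) are the user's grouping decision, via
`group_compare()`, not automated clustering.

# Problem sizes and numerical tolerances

The test and acceptance suites run, by the package's own choice of
scale: 100 full-size null screens and 50 planted-hit screens (983
probes, 13 plates, 2 lines each) for calling calibration; 100 random
plates against an independently coded median-polish sweep oracle at
1e-9; 200 random miRNA/UTR pairs plus 50 planted-truth UTRs against a
brute-force per-offset scan oracle (exact equality); 1000 replicates
for noisy-qPCR bias and for regression null-uniformity (KS test) and
slope recovery (within two Monte-Carlo SEs). Decompositions reconstruct
inputs to better than 1e-9 in log2 units; equality-type checks use
1e-10..1e-12; seed-determinism is bitwise.

# Known limitations

* Per-plate B scores have the heavy null tail quantified above; there
  is no plate-to-plate spatial smoothing or alternative robust-Z
  scoring, by scope.
* The seed scanner is purely sequence-based: no context/accessibility
  scoring, no 3'-compensatory sites, no wobble pairing.
* ddCt assumes perfect doubling; no standard-curve efficiency
  estimation.
* The activity score is unweighted and direction-blind with respect to
  the signature.
* The synthetic UTR panel certifies the scanner, not the annotation:
  coordinates on real transcripts depend on the annotation version and
  UTR start convention used.
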