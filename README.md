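# seedscreen

Analysis toolkit for microRNA-inhibitor reporter screens of androgen
receptor (AR) activity in prostate cancer cells, and for the follow-up
assays such screens feed: miRNA seed-site discovery in extended 3'UTRs,
reporter and qPCR quantification, and AR-pathway association in
expression data.

## Who it is for

Groups running (or re-analysing) arrayed 96-well perturbation screens
with a luminescent reporter readout — here, LNA miRNA-inhibitor
libraries against a luciferase AR-activity reporter in
androgen-dependent and castration-resistant prostate cancer lines — and
following hits into target-site mapping on 3'UTRs that extend far beyond
the standard annotations (the AR 3'UTR runs to ~6.8 kb via alternative
polyadenylation, versus the 436-nt annotation most prediction tools
scan).

## What it computes

**Plate screening (B score).** Each 96-well plate of raw luminescence is
log2-transformed and decomposed by Tukey two-way median polish,

    log2(RLU_ij) = mu + row_i + col_j + r_ij,

which removes additive row/column positional artifacts. The B score of a
well is its residual scaled by the plate's median absolute deviation,

    B_ij = r_ij / MAD,   MAD = 1.4826 * median(|r - median(r)|),

computed over the plate's library wells (controls and empty wells are
excluded). A probe is a hit when |B| >= 6 in at least one cell line; the
sign gives direction (inhibitor B > 0: inhibiting the miRNA increases AR
activity), and hits above threshold in both lines with equal sign are
common same-direction hits. Cross-line concordance (set partition plus
Pearson r of per-probe B scores) is reported alongside.

**Seed scanning.** Mature miRNA seeds (positions 2-7 and 2-8) are
matched by Watson-Crick reverse complementarity against arbitrary-length
UTRs and classified into the canonical taxonomy — 6mer, 7mer-A1
(6mer plus A opposite miRNA position 1), 7mer-m8 (pairing 2-8), 8mer —
with 1-based inclusive coordinates, strongest-type collapse per seed
register, no G:U wobble. Companion operations compare wild-type versus
splice-variant UTRs (e.g. AR-V7, AR-v567es), design seed-disrupting
mutants (>= 3 substitutions in the seed-pairing span), and score site
conservation across an alignment.

**Assay quantification.** Luciferase/beta-galactosidase normalisation
with fold versus control, relative expression by 2^-ddCt against
endogenous references (U18/L19 convention), RNA-IP percent-of-input,
transcript-stability fractions after Actinomycin D, day-0-relative
growth curves, and equal-variance Student's t tests with the
0.05/0.005/0.0001 asterisk tiers.

**Expression association.** A per-sample AR activity score (sum of
cross-sample z-scores of log2(FPKM+1) over a user-supplied signature,
canonically 43 AR-regulated genes) and ordinary least-squares regression
of target-gene expression on that score.

**Synthetic data.** Generators for whole screens (positional effects +
log-scale noise + planted hits with known sign and cross-line
concordance), UTRs with planted sites of known type and coordinate, and
qPCR Ct tables with known folds — so every stage is testable with ground
truth and no downloads.

## Worked example

```r
library(seedscreen)

# a 983-probe, 13-plate, 2-line screen with 20 planted hits
cfg <- screen_sim_config(hit_fraction = 20/983, hit_effect_log2 = 2,
                         rng_seed = 42)
sim <- simulate_screen(cfg)
res <- screen_bscore(sim$plates, threshold = 6)
print(res)
#> <screen_result> 1966 library wells, 1966 probe x line scores
#> <screen_hits> 983 probes, |B| >= 6: 20 hits (18 common same-direction)
#>   inhibitors increasing AR activity: 9 (45%), decreasing: 11 (55%)
```

All 20 planted hits are recalled; the 45%/55% split reflects the random
signs of the planted effects, and 18 of 20 hits clear the threshold in
both cell lines.

```r
mirs <- ar_modulatory_mirs()            # miR-346, miR-361-3p, miR-197-3p
panel <- synthetic_utr_panel(mirs)      # synthetic stand-in 3'UTRs
find_seed_sites(mirs[["hsa-miR-361-3p"]], panel$utrs$AR_3UTR_synthetic)
#>         mir_name            utr_id start  end site_type target_seq
#> 1 hsa-miR-361-3p AR_3UTR_synthetic   407  412      6mer     UGGGGG
#> 2 hsa-miR-361-3p AR_3UTR_synthetic   787  793   7mer-m8    CUGGGGG
#> 3 hsa-miR-361-3p AR_3UTR_synthetic  5772 5777      6mer     UGGGGG
#> 4 hsa-miR-361-3p AR_3UTR_synthetic  6070 6075      6mer     UGGGGG
```

The panel UTRs are synthetic stand-ins: random backgrounds with
miR-346/-361-3p/-197 sites planted at the coordinates reported for the
real transcripts (the annotated sequences themselves are not bundled),
so the scan demonstrates coordinate conventions end-to-end against known
truth. `UGGGGG` is the reverse complement of the miR-361-3p seed
(positions 2-7, `CCCCCA`).

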