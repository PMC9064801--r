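---
title: "Event-anchored analysis of preterm gut virome convergence"
author: "viroconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-anchored analysis of preterm gut virome convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroconverge)
```

## The scientific question

Necrotizing enterocolitis (NEC) is a sudden, necroinflammatory intestinal
disease of very preterm infants. Longitudinal stool metagenomics makes it
possible to ask whether the gut DNA virome carries a warning signal before
onset: do the viromes of infants who go on to develop NEC *converge* — lose
between-infant beta diversity — in the days immediately preceding the event,
and is that convergence carried by specific viral contigs with specific
bacterial partners?

`viroconverge` implements the full analysis chain for a matched case–control
design: infants who developed NEC (cases) are each matched to one or two
controls by gestational age and birth weight; every sample is anchored to
the case's day of NEC onset (controls inherit their matched case's event
day); and all pre-event analyses run on the days-before-event axis, not on
chronological age.

## The analysis chain

1. **RPK normalization** (`rpk_normalize`). Mapped-read counts per contig
   are scaled by `scale_reads / total_qc_reads` of the sample (default
   `scale_reads = 79000`) and divided by contig length in kilobases. Cells
   below the **noise floor** (0.5 RPK) are then set to zero. Flooring is
   applied per cell *after* full normalization. The floor is what defines
   presence–absence for all presence-based statistics downstream.
2. **Diversity** (`richness_and_shannon`, `bray_curtis`, `sorensen`,
   `hellinger`). Shannon diversity uses natural logs (base switchable).
   Hellinger is computed on `log(1 + RPK)` by default; the offset of 1
   keeps floored zeros finite and is a configuration choice, since any
   positive offset gives a valid transform. Pairs of all-empty samples are
   *missing*, never zero — a zero would fabricate similarity.
3. **Ordination and global tests** (`pcoa`, `permanova`,
   `within_between`, `alpha_trend`). PCoA is classical metric scaling:
   Gower double-centering plus eigendecomposition; axes with eigenvalues
   below `1e-10 * max|eigenvalue|` are treated as zero and negative axes
   are reported but dropped. PERMANOVA regresses the centered inner-product
   matrix on a single covariate (continuous or categorical) and permutes
   observations; p = (1 + #{F* >= F}) / (1 + permutations), with an
   exhaustive mode for tiny designs and an optional `strata` argument for
   within-infant permutation (the default is unstratified, with the
   stratified variant exposed for sensitivity analysis). Alpha-diversity
   trends use a random-intercept linear mixed model (infant as the grouping
   factor) with postmenstrual age as the fixed effect.
4. **Event anchoring and windows** (`anchor_samples`, `pair_samples`,
   `build_windows`, `convergence_series`). Days-before-event =
   `event_dol - day_of_life`; post-event samples are flagged and excluded.
   For each case sample, each matched control infant contributes its
   closest-in-age control sample within ±3.5 days (ties break toward the
   earlier sample, deterministically). Sliding windows are half-open
   `[k, k + 7)` at 2-day steps: the half-open convention is forced by the
   requirement that a window labeled "7–0 d" contain day-0 samples. Per
   window, the between-case multiset holds all cross-infant case sample
   pairs (same-infant pairs never enter; multiple samples of one infant all
   contribute cross-infant pairs, since no collapsing rule is defined for
   this design), the between-control multiset likewise over paired
   controls, and the two are compared by a two-sided Mann–Whitney U-test.
   Kruskal–Wallis with Dunn's z-tests compares windows within a group.
5. **Discriminant screen** (`lefse_screen`, `control_side_screen`). An LDA
   effect-size screen separates the late class (`[0, 10)` days before) from
   the early class (`[10, 46]`; the boundary day belongs to the early
   class). Samples are total-sum scaled to 1e6 over the full community
   *before* the 10% prevalence filter — scaling after filtering would make
   every contig's values depend on which other contigs survived, breaking
   threshold monotonicity. Contigs pass a per-contig Kruskal–Wallis gate at
   alpha = 0.05; the effect size is log10 of the bootstrap average (30
   subsamples of 2/3 of each class) of the mean of (a) the class-mean
   difference projected on the unit two-class discriminant axis, restricted
   to the contig, and (b) the raw class-mean difference, floored at 1; the
   axis solves a ridge-regularized pooled-covariance system, which keeps the
   discriminant defined when features outnumber samples. Features with
   effect size >= 2.0 are called for the class with the larger mean. The
   subclass stage of the published formulation is omitted: this design has
   no subclasses. Thresholds (alpha, LDA >= 2, 30 x 2/3 bootstraps) are the
   method's standard defaults, exposed in `lefse_config`.
6. **Trajectories** (`block_series`, `block_friedman_dunn`,
   `trajectory_slopes`). Discriminant contigs are summarized in 5-day
   blocks over `[0, 25)` days before the event: prevalence is the percent
   of block samples with a hit, abundance is the mean RPK over *all* block
   samples, zeros included; empty blocks are missing, not zero. Slopes are
   ordinary least squares against signed block midpoints
   (−22.5 … −2.5 days), so a positive slope always reads "rising toward
   the event". Friedman tests treat contigs as repeated-measures subjects
   across blocks — the only structure in which blocks are matched
   measurements.
7. **Bacterial side** (`rarefy_counts`, `unweighted_unifrac`,
   `weighted_unifrac`, `bacterial_convergence`). Genus counts are rarefied
   without replacement to 2,500 reads (shallow samples dropped, seeded).
   Unweighted UniFrac divides branch length unique to either sample's taxon
   set by the branch length of the *minimal spanning subtree* of their
   union (edges ancestral to the union's most recent common ancestor carry
   no information about the pair), so disjoint taxon sets are at distance
   1. Weighted UniFrac propagates relative abundances to branches; the
   normalized variant (the reported default, matching common pipeline
   defaults) divides by the abundance-weighted maximum and lives in [0, 1].
8. **Virus–bacteria interactions** (`associate`, `correlation_table`).
   For every (discriminant contig, genus) pair within one group, a
   random-intercept mixed model regresses `log(1 + TSS contig abundance)`
   on transformed genus relative abundance (`log1p` by default,
   arcsine-square-root available). Random intercept only: with a handful of
   samples per infant, random slopes are not identifiable. Significance is
   the dual gate **P < 0.05 and BH q < 0.25**, with q-values computed
   across all pairs tested within the group. When the contig table passed
   in is a subset, `sample_totals` should carry full-community totals so
   the response does not depend on the subset.

## The synthetic cohort

Real cohorts of this kind are small and irreplaceable, so the package ships
a generative model (`synthetic_params`, `generate_cohort`) that reproduces
the *structure* the analysis assumes and labels every planted effect:

- **Design**: 9 cases, 14 controls matched 1–2 per case; cases contribute a
  median of 4 samples, controls 7; case sampling always includes a sample
  within 3 days of onset and one at least 25 days out (collection
  concentrates around diagnosis), and control sampling days mirror the
  matched case's days with jitter so the matched pairing and every window
  are populated.
- **Communities**: each infant draws a baseline community from a symmetric
  Dirichlet with per-contig concentration 0.05 — strong individuality, so
  inter-individual variation dwarfs intra-individual variation — and
  carries contigs through time with persistence 0.8 (stationary occupancy
  0.75). Sequencing depth is log-normal with median 412,905 reads
  (IQR ≈ 289k–521k). Column sums of the count table equal the drawn depths
  exactly.
- **Taxonomy**: contig family labels are drawn so control samples are
  dominated by unclassified viruses (median share ~85%), with Myoviridae,
  Siphoviridae and Podoviridae as the main classified families and rare
  Microviridae/Anelloviridae/Circoviridae.
- **Planted effects**: 137 signature contigs gain occurrence (5% ramping to
  60%) and abundance (8x) inside the 10 days before onset, in cases only;
  the occurrence ramp is concave (square root of window position) so the
  convergence is well developed several days out, which is what makes
  windows spanning ~11–4 days detectably different. 11 early contigs decay
  toward the event in cases. ~100 control-late contigs ramp with *absolute
  age* in controls; each control infant is susceptible to only half of
  them. Both choices matter: ramping on days-before would synchronize
  control infants into a spurious control-side convergence, and universal
  susceptibility would do the same — the partially-overlapping,
  age-driven model reproduces the observed pattern of control-side
  turnover *without* control-side beta-diversity convergence. Eight
  signature contigs are coupled to bacterial genera (mixed signs, e^2-fold
  shifts while the phage is detectable) in cases only.
- **Null switch**: `signature_prevalence_lift = 0` with
  `signature_abundance_lift = 1` removes *all* planted structure, including
  couplings, and empties the truth labels — one switch yields the null
  cohorts used for calibration testing.
- **Lift calibration**: the analysis reports effects only graphically in
  real data, so lift magnitudes here are calibrated once so that the
  pipeline's detection is comfortably powered at desk scale (signature
  recovery >90%, coupling recovery most of 8), not to match any absolute
  dissimilarity value.

What the generator does **not** emulate: read-level error, assembly
artifacts, contaminant contigs, strain-level dynamics, antibiotic
perturbations, and real phage–host infection dynamics. Passing tests
demonstrate that the pipeline detects the structures it claims to detect
and stays quiet when they are absent — not that any particular biological
cohort will carry them.

## Numerical and design choices

- Half-open windows `[k, k + width)`; the boundary day of the discriminant
  classes belongs to the early class.
- Tie-breaks are deterministic everywhere (pairing prefers the earlier
  control sample; feature lists sort by effect size).
- Dunn's post hoc z-tests use Bonferroni adjustment by default
  (Benjamini–Hochberg switchable); they are implemented in-package because
  no installed package provides them.
- PERMANOVA permutation count defaults to 999, seeded; exhaustive
  enumeration uses the proportion of all n! permutations (identity
  included) at or above the observed F.
- Eigenvalue tolerance in PCoA: `1e-10 * max|eigenvalue|` separates zero
  from genuinely negative eigenvalues.
- Days-before-event values are snapped to 9 decimals so window membership
  is invariant under a common time translation despite floating-point
  subtraction.
- Degenerate inputs: all-zero samples are excluded from alpha diversity and
  undefined in beta diversity (missing, not zero); constant responses give
  flat trends by definition; fully tied Friedman data gives statistic 0,
  p = 1; zero-margin 2x2 tables give p = 1 with a warning.

## Known limitations

- The per-window Mann–Whitney test on dissimilarity multisets treats
  correlated pairs as independent observations (each sample and each infant
  enters many pairs). On null synthetic cohorts this inflates the fraction
  of windows reaching p <= 0.05 well above the nominal level (~25% at
  alpha = 0.05 in our simulations, and still ~14% with one sample per
  infant per window). This is a property of the test the analysis design
  prescribes, not of its implementation; window-level p-values should be
  read as descriptive weights of evidence, with the planted-effect
  recovery tests showing that true convergence produces dramatically
  smaller p-values than null fluctuation. A calibrated alternative would
  permute infant group labels, which is outside this design's scope.
- The discriminant effect size depends on the total-sum scaling constant
  and the regularization of the discriminant axis; both are documented
  configuration, and the raw-difference term dominates in practice.
- Mixed-model Wald p-values are approximate for small numbers of infants;
  the calibration suite bounds the type-I error at 2–9% for the designs
  used here.

## Problem sizes used by the test and acceptance suites

Module tests run on hand-built fixtures and a cached default synthetic
cohort (2,000 contigs, 23 infants, ~145 samples). Recovery and calibration
checks use 5–20 generator seeds, 200 replicates for type-I calibration, and
999-permutation PERMANOVA; the full suite and the acceptance script each
complete in a few minutes on a single CPU.
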