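# viroconverge

Event-anchored analysis of the preterm-infant gut virome before necrotizing
enterocolitis (NEC), for microbiome researchers working with longitudinal,
matched case–control metagenomic cohorts.

NEC strikes suddenly in very preterm infants, and the question this package
operationalizes is whether the stool DNA virome carries a detectable signal
beforehand. Given (i) a viral contig-by-sample mapped-read count table with
a contig catalog, (ii) a bacterial genus-by-sample count table with a rooted
genus tree, and (iii) infant/sample metadata with matched case–control
structure and NEC onset days, the package:

- normalizes counts to **RPK** with a noise floor:
  `RPK = (scale/total_qc_reads) × reads / (length_bp/1000)`, zeroing values
  `< 0.5`;
- computes alpha diversity (richness, Shannon `H = −Σ pᵢ ln pᵢ`) and beta
  diversity — weighted Bray–Curtis `Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`, Sørensen
  `1 − 2|A∩B|/(|A|+|B|)`, Hellinger, and weighted/unweighted UniFrac on
  rarefied genus counts;
- runs PCoA, PERMANOVA (seeded permutation p-values), within- vs
  between-infant comparisons, and mixed-model alpha-diversity trends;
- anchors every sample to the (matched) case's NEC onset day, pairs case
  and control samples by day of life (±3.5 d), and tests between-case vs
  between-control dissimilarity in sliding 7-day windows at 2-day steps —
  the **convergence** analysis;
- screens contigs for association with the 10 days before onset versus the
  antecedent period with an LDA effect-size (LEfSe-style) procedure
  (10% prevalence filter, Kruskal–Wallis gate, bootstrap-averaged log10
  discriminant effect size ≥ 2);
- summarizes discriminant-contig prevalence/abundance in 5-day blocks with
  Friedman/Dunn tests and per-day regression slopes; and
- tests virus–bacteria associations per group with random-intercept mixed
  models under the dual gate **P < 0.05 and BH q < 0.25**.

A synthetic-cohort generator (`generate_cohort`) reproduces the cohort's
structure — 9 cases, 14 matched controls, strong inter-individual virome
variation, an unclassified-dominated family profile, and programmable
planted signatures with truth labels — so every stage is testable at desk
scale. See the vignette in `vignettes/virome-convergence.Rmd` for the model
and every numerical choice.

## Worked example

```r
library(viroconverge)

co  <- generate_cohort(synthetic_params(seed = 1))
co$meta
#> cohort_metadata: 9 cases, 14 controls, 147 samples

rpk <- rpk_normalize(co$viral_counts, co$catalog, co$meta$samples)

## individuality: infants resemble themselves far more than each other
wb <- within_between(bray_curtis(rpk), co$meta$samples)
c(wb$median_within, wb$median_between)
#> [1] 0.278 0.954

## convergence: between-case Sorensen drops below between-control in the
## windows nearest NEC onset
anc  <- anchor_samples(co$meta)
prs  <- pair_samples(anc, co$meta)
conv <- convergence_series(sorensen(presence_matrix(rpk)),
                           build_windows(7, 2, 25), anc, prs)
as.data.frame(conv)[1:3, c("start", "end", "median_case",
                           "median_control", "p_value")]
#>   start end median_case median_control  p_value
#> 1     0   7       0.750          0.784 7.86e-43
#> 2     2   9       0.758          0.785 1.90e-17
#> 3     4  11       0.772          0.785 4.29e-04

## discriminant screen: contigs associated with the 10 d before onset
feats <- lefse_screen(rpk, anc, lefse_config(seed = 1))
table(feats$class)
#> early  late
#>    16   129
head(feats, 3)
#>     contig_id class         kw_p effect_size
#> 1 contig_1708  late 2.127454e-07    3.028020
#> 2 contig_1167  late 2.011478e-06    3.026240
#> 3 contig_0303  late 4.321981e-05    2.953944
```

The generated cohort planted 137 signature contigs; the screen calls 129
late-class contigs, of which >99% are planted (truth labels live in
`co$truth`). The convergence window medians read as: case viromes are
~0.03 Sørensen units more similar to each other than control viromes in
the week before onset — the convergence signal — while deeper windows show
no separation.

The full pipeline (simulation or file input → normalization → diversity →
convergence → discriminant screens → trajectories → bacterial UniFrac →
interactions, with a hash manifest) runs via:

```r
run_pipeline(list(simulation = list(), seed = 1), "out/")
```

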