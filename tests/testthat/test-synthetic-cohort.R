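test_that("default cohort has the expected shape and resolves matching", {
  co <- default_cohort()
  meta <- co$meta
  expect_equal(nrow(meta$infants), 23)
  expect_equal(sum(meta$infants$group == "case"), 9)
  expect_equal(sum(meta$infants$group == "control"), 14)
  # validation passes without warnings
  expect_silent(validate_cohort_metadata(meta))
  # every control resolves a matched case
  ctrl <- meta$infants[meta$infants$group == "control", ]
  expect_true(all(ctrl$matched_case_id %in%
                    meta$infants$infant_id[meta$infants$group == "case"]))
  # case sampling spans at least 25 days before the event
  anc <- anchor_samples(meta)
  spans <- tapply(anc$days_before_event[anc$group == "case"],
                  anc$infant_id[anc$group == "case"],
                  function(d) diff(range(d)))
  expect_true(all(spans >= 25))
})

test_that("viral column sums equal the drawn per-sample read totals", {
  co <- default_cohort()
  expect_identical(unname(colSums(co$viral_counts)),
                   as.numeric(co$meta$samples$total_qc_reads))
})

test_that("truth labels partition into disjoint planted sets", {
  co <- default_cohort()
  tr <- co$truth
  expect_equal(length(tr$signature), 137)
  expect_equal(length(tr$early), 11)
  expect_equal(length(tr$control_late), 100)
  expect_equal(length(intersect(tr$signature, tr$early)), 0)
  expect_equal(length(intersect(tr$signature, tr$control_late)), 0)
  expect_equal(length(intersect(tr$early, tr$control_late)), 0)
  expect_false(tr$null)
  expect_true(all(tr$couplings$contig_id %in% tr$signature))
})

test_that("same seed reproduces the cohort bit for bit; seeds differ", {
  p <- synthetic_params(seed = 99, n_contigs = 300,
                        n_signature_contigs = 20, n_early_contigs = 5,
                        n_control_late_contigs = 15)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$viral_counts, b$viral_counts)
  expect_identical(a$bacterial_counts, b$bacterial_counts)
  expect_identical(a$meta$samples, b$meta$samples)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  p2 <- p; p2$seed <- 100
  c2 <- generate_cohort(p2)
  expect_false(identical(a$viral_counts, c2$viral_counts))
})

test_that("null parameters mark zero planted effect", {
  p <- synthetic_params(seed = 3, n_contigs = 300,
                        signature_prevalence_lift = 0,
                        signature_abundance_lift = 1)
  co <- generate_cohort(p)
  expect_true(co$truth$null)
  expect_equal(length(co$truth$signature), 0)
  expect_equal(length(co$truth$early), 0)
  expect_equal(length(co$truth$control_late), 0)
  expect_equal(nrow(co$truth$couplings), 0)
})

test_that("infeasible planted sets are refused", {
  expect_error(synthetic_params(n_contigs = 100),
               "exceed the contig pool")
})

test_that("family profile shares sum to one and match worked arithmetic", {
  cat_df <- tiny_catalog(c("c1", "c2"))
  cat_df$family <- c("unclassified", "Myoviridae")
  a <- matrix(c(15, 5), 2, 1, dimnames = list(c("c1", "c2"), "s1"))
  fp <- family_profile(cat_df, a)
  expect_equal(fp["unclassified", "s1"], 0.75)
  expect_equal(fp["Myoviridae", "s1"], 0.25)
  # all contigs one family
  cat_df$family <- "Siphoviridae"
  expect_equal(unname(family_profile(cat_df, a)[1, 1]), 1)
  # all-zero sample is an error naming the sample
  a0 <- cbind(a, s2 = c(0, 0))
  expect_error(family_profile(tiny_catalog(c("c1", "c2")), a0), "s2")
})

test_that("control samples have an unclassified-dominated family profile", {
  co <- default_cohort()
  rpk <- cohort_rpk()
  fp <- family_profile(co$catalog, rpk)
  expect_lt(abs(sum(fp[, 1]) - 1), 1e-9)
  ctrl_inf <- co$meta$infants$infant_id[co$meta$infants$group == "control"]
  ctrl_smp <- co$meta$samples$sample_id[
    co$meta$samples$infant_id %in% ctrl_inf]
  med_uncl <- median(fp["unclassified", ctrl_smp])
  expect_gt(med_uncl, 0.80)
  expect_lt(med_uncl, 0.90)
})

test_that("within-infant Bray-Curtis is far below between-infant", {
  co <- default_cohort()
  rpk <- cohort_rpk()
  wb <- within_between(bray_curtis(rpk), co$meta$samples)
  expect_lt(wb$median_within, wb$median_between)
  expect_lt(wb$test$p_value, 0.01)
})

test_that("cohort artifacts roundtrip through their text formats", {
  p <- synthetic_params(seed = 5, n_contigs = 200,
                        n_signature_contigs = 10, n_early_contigs = 4,
                        n_control_late_contigs = 10)
  co <- generate_cohort(p)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back_meta <- read_metadata(paths["metadata"])
  expect_equal(back_meta$samples$sample_id, co$meta$samples$sample_id)
  back_counts <- read_count_table(paths["viral_counts"],
                                  feature_ids = co$catalog$contig_id)
  expect_identical(unname(back_counts), unname(co$viral_counts))
  back_tree <- read_genus_tree(paths["tree"])
  expect_setequal(back_tree$tip.label, rownames(co$bacterial_counts))
})
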