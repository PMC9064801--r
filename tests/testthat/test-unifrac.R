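test_that("rarefaction drops shallow samples and conserves depth exactly", {
  set.seed(31)
  counts <- matrix(rpois(40, 400), 8, 5,
                   dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  storage.mode(counts) <- "integer"
  counts[, 2] <- c(2400L, rep(0L, 7))          # total 2400 < 2500: dropped
  counts[, 3] <- c(2000L, 500L, rep(0L, 6))    # total exactly 2500
  rar <- rarefy_counts(counts, depth = 2500, seed = 1)
  expect_equal(rar$dropped, "s2")
  expect_true(all(colSums(rar$counts) == 2500))
  expect_equal(rar$counts[, "s3"], counts[, 3]) # exact-depth sample unchanged
  # deterministic under seed
  rar2 <- rarefy_counts(counts, depth = 2500, seed = 1)
  expect_identical(rar$counts, rar2$counts)
  expect_error(rarefy_counts(counts, depth = 0), "positive")
})

worked_counts <- function(s1, s2) {
  m <- cbind(s1 = s1, s2 = s2)
  rownames(m) <- c("A", "B", "C")
  storage.mode(m) <- "integer"
  m
}

test_that("unweighted UniFrac matches the worked branch enumerations", {
  tr <- worked_tree() # ((A:1,B:1):1,C:2)
  # {A} vs {B}: unique branches A:1 and B:1; spanning subtree is exactly
  # those two edges -> distance 1
  d <- unweighted_unifrac(worked_counts(c(5, 0, 0), c(0, 7, 0)), tr)
  expect_equal(d["s1", "s2"], 1)
  # {A} vs {C}: no shared branches on the spanning subtree -> 1
  d2 <- unweighted_unifrac(worked_counts(c(5, 0, 0), c(0, 0, 7)), tr)
  expect_equal(d2["s1", "s2"], 1)
  # identical taxon sets -> 0
  d3 <- unweighted_unifrac(worked_counts(c(5, 2, 0), c(1, 9, 0)), tr)
  expect_equal(d3["s1", "s2"], 0)
  # {A,B} vs {B}: unique branch A:1, span = {A:1, B:1} -> 0.5
  d4 <- unweighted_unifrac(worked_counts(c(5, 2, 0), c(0, 9, 0)), tr)
  expect_equal(d4["s1", "s2"], 0.5)
})

test_that("weighted UniFrac matches the worked branch enumeration", {
  tr <- worked_tree()
  # all A vs all C: raw = 1*1 + 1*0 + 1*1 + 2*1 = 4
  d <- weighted_unifrac(worked_counts(c(5, 0, 0), c(0, 0, 9)), tr,
                        normalized = FALSE)
  expect_equal(d["s1", "s2"], 4)
  # identical compositions -> 0
  d0 <- weighted_unifrac(worked_counts(c(4, 2, 2), c(8, 4, 4)), tr)
  expect_equal(d0["s1", "s2"], 0)
})

random_tree_counts <- function(n_tip = 8, n_smp = 5) {
  tr <- ape::rtree(n_tip)
  counts <- matrix(rpois(n_tip * n_smp, 3), n_tip, n_smp,
                   dimnames = list(tr$tip.label, paste0("s", 1:n_smp)))
  # ensure no empty sample
  for (j in seq_len(n_smp))
    if (sum(counts[, j]) == 0) counts[sample(n_tip, 1), j] <- 1L
  storage.mode(counts) <- "integer"
  list(tree = tr, counts = counts)
}

test_that("both UniFrac variants agree with the naive branch oracle", {
  set.seed(32)
  for (rep in 1:12) {
    fx <- random_tree_counts()
    du <- unweighted_unifrac(fx$counts, fx$tree)
    dw <- weighted_unifrac(fx$counts, fx$tree, normalized = FALSE)
    dn <- weighted_unifrac(fx$counts, fx$tree, normalized = TRUE)
    for (i in 1:4) for (j in (i + 1):5) {
      ta <- rownames(fx$counts)[fx$counts[, i] > 0]
      tb <- rownames(fx$counts)[fx$counts[, j] > 0]
      expect_equal(du[i, j],
                   oracle_unifrac_unweighted_pair(fx$tree, ta, tb),
                   tolerance = 1e-12)
      expect_equal(dw[i, j],
                   oracle_unifrac_weighted_pair(fx$tree, fx$counts[, i],
                                                fx$counts[, j]),
                   tolerance = 1e-12)
      expect_equal(dn[i, j],
                   oracle_unifrac_weighted_pair(fx$tree, fx$counts[, i],
                                                fx$counts[, j],
                                                normalized = TRUE),
                   tolerance = 1e-12)
    }
  }
})

test_that("unweighted UniFrac depends only on presence-absence; bounds hold", {
  set.seed(33)
  fx <- random_tree_counts()
  d1 <- unweighted_unifrac(fx$counts, fx$tree)
  scaled <- fx$counts
  scaled[, 1] <- scaled[, 1] * 7L
  expect_equal(unclass(unweighted_unifrac(scaled, fx$tree)), unclass(d1))
  expect_true(all(d1 >= 0 & d1 <= 1 + 1e-12))
  dn <- weighted_unifrac(fx$counts, fx$tree, normalized = TRUE)
  expect_true(all(dn >= 0 & dn <= 1 + 1e-12))
  dr <- weighted_unifrac(fx$counts, fx$tree, normalized = FALSE)
  expect_true(all(dr >= 0))
  expect_equal(unclass(dr), t(unclass(dr))) # symmetry
  # a genus absent from the tree is an error naming the genus
  bad <- rbind(fx$counts, mystery_genus = 1L)
  expect_error(unweighted_unifrac(bad, fx$tree), "mystery_genus")
})

test_that("picante cross-checks the unweighted variant on shared-MRCA pairs", {
  # picante::unifrac implements unique/total over the pruned pair tree;
  # restrict the comparison to sample pairs whose union spans the root, where
  # the two conventions coincide
  set.seed(34)
  fx <- random_tree_counts(8, 4)
  mine <- unweighted_unifrac(fx$counts, fx$tree)
  pic <- as.matrix(picante::unifrac(t(fx$counts), fx$tree))
  pic <- pic[rownames(mine), colnames(mine)]
  for (i in 1:3) for (j in (i + 1):4) {
    u <- which(fx$counts[, i] + fx$counts[, j] > 0)
    spans_root <- length(u) == length(fx$tree$tip.label)
    if (spans_root)
      expect_equal(mine[i, j], pic[i, j], tolerance = 1e-10)
  }
})

test_that("bacterial convergence shares the window-series interface", {
  co <- default_cohort()
  rar <- rarefy_counts(co$bacterial_counts, depth = 2500, seed = 1)
  wuf <- weighted_unifrac(rar$counts, co$tree)
  anc <- anchor_samples(co$meta)
  pr <- pair_samples(anc, co$meta)
  w <- build_windows(7, 2, 25)
  bs <- bacterial_convergence(wuf, w, anc, pr)
  expect_s3_class(bs, "window_series")
  expect_equal(nrow(bs), nrow(w))
  expect_true(any(bs$sufficient))
  # planted low case-side bacterial dispersion: case medians below control
  # in the windows with data
  ok <- bs$sufficient
  expect_gt(mean(bs$median_case[ok] < bs$median_control[ok]), 0.7)
})
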