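test_that("anchoring counts days backwards from the (matched) event", {
  meta <- tiny_meta()
  anc <- anchor_samples(meta)
  # caseA event at DOL 40: samples at 33 and 38 -> 7 and 2 days before
  expect_equal(anc$days_before_event[anc$sample_id == "s1"], 7)
  expect_equal(anc$days_before_event[anc$sample_id == "s2"], 2)
  # ctrl1 is matched to caseA: sample at DOL 38.5 -> 1.5 days before
  expect_equal(anc$days_before_event[anc$sample_id == "s6"], 1.5)
  expect_false(any(anc$post_event))
  # a sample collected after the event is flagged
  meta2 <- tiny_meta()
  meta2$samples$day_of_life[2] <- 41
  meta2$samples$pma_weeks[2] <- NA
  anc2 <- anchor_samples(meta2)
  expect_equal(anc2$days_before_event[anc2$sample_id == "s2"], -1)
  expect_true(anc2$post_event[anc2$sample_id == "s2"])
})

test_that("pairing minimizes |delta DOL| within tolerance, 1-2 controls per case", {
  meta <- tiny_meta()
  anc <- anchor_samples(meta)
  pr <- pair_samples(anc, meta, tolerance = 3.5)
  # caseA s1 at DOL 33: ctrl1 has samples at 32 (|d|=1) and 38.5; ctrl2 at
  # 31 (|d|=2) and 37 -> two pairs, one per matched control infant
  p1 <- pr$pairs[pr$pairs$case_sample_id == "s1", ]
  expect_equal(nrow(p1), 2)
  expect_setequal(p1$control_sample_id, c("s5", "s7"))
  expect_equal(sort(abs(p1$delta_dol)), c(1, 2))
  # caseB s3 at DOL 28: ctrl3 samples at 27.5 (|d|=0.5) and 33
  p3 <- pr$pairs[pr$pairs$case_sample_id == "s3", ]
  expect_equal(p3$control_sample_id, "s9")
  # out-of-tolerance case sample is reported unpaired
  meta2 <- tiny_meta()
  meta2$samples$day_of_life[meta2$samples$sample_id == "s9"] <- 23
  meta2$samples$day_of_life[meta2$samples$sample_id == "s10"] <- 39
  meta2$samples$pma_weeks <- NA
  anc2 <- anchor_samples(meta2)
  pr2 <- pair_samples(anc2, meta2, tolerance = 3.5)
  expect_true("s3" %in% pr2$unpaired) # nearest control now at |d| = 5
})

test_that("pairing ties break toward the earlier control sample", {
  meta <- tiny_meta()
  # put ctrl1 samples symmetric around caseA s1 (DOL 33): 31.5 and 34.5
  meta$samples$day_of_life[meta$samples$sample_id == "s5"] <- 34.5
  meta$samples$day_of_life[meta$samples$sample_id == "s6"] <- 31.5
  meta$samples$pma_weeks <- NA
  anc <- anchor_samples(meta)
  pr <- pair_samples(anc, meta)
  p1 <- pr$pairs[pr$pairs$case_sample_id == "s1" &
                   pr$pairs$control_infant_id == "ctrl1", ]
  expect_equal(p1$control_sample_id, "s6") # the earlier of the tied two
})

test_that("window construction enumerates half-open intervals", {
  w <- build_windows(width = 7, step = 2, max_lookback = 25)
  expect_equal(nrow(w), 10)
  expect_equal(w$start, seq(0, 18, by = 2))
  expect_equal(w$end, seq(7, 25, by = 2))
  # membership of a sample at exactly 7.0 days before
  members <- w$start <= 7 & 7 < w$end
  expect_equal(w$start[members], c(2, 4, 6)) # [2,9), [4,11), [6,13)
  # width = step gives a non-overlapping tiling
  w2 <- build_windows(width = 7, step = 7, max_lookback = 21)
  expect_equal(w2$start, c(0, 7, 14))
})

make_conv_fixture <- function(case_gap = 0.3) {
  # two case infants and two control infants, one sample each inside a
  # single window; case dissimilarity lower by construction
  inf <- data.frame(
    infant_id = c("cA", "cB", "k1", "k2"),
    group = c("case", "case", "control", "control"),
    matched_case_id = c(NA, NA, "cA", "cB"),
    gestational_age_weeks = 25, birth_weight_g = 800,
    event_dol = c(40, 40, NA, NA), stringsAsFactors = FALSE)
  smp <- data.frame(
    sample_id = paste0("s", 1:4),
    infant_id = c("cA", "cB", "k1", "k2"),
    day_of_life = c(37, 38, 37, 38),
    pma_weeks = NA_real_, total_qc_reads = 1000L,
    stringsAsFactors = FALSE)
  meta <- cohort_metadata(inf, smp)
  d <- matrix(0.9, 4, 4, dimnames = list(smp$sample_id, smp$sample_id))
  d[1, 2] <- d[2, 1] <- 0.9 - case_gap
  diag(d) <- 0
  list(meta = meta, d = d)
}

test_that("convergence series separates case and control multisets", {
  fx <- make_conv_fixture()
  anc <- anchor_samples(fx$meta)
  pr <- pair_samples(anc, fx$meta)
  w <- build_windows(7, 7, 7) # single [0,7) window
  cv <- convergence_series(fx$d, w, anc, pr)
  expect_equal(nrow(cv), 1)
  expect_equal(cv$n_case_pairs, 1)
  expect_equal(cv$n_control_pairs, 1)
  expect_equal(cv$median_case, 0.6)
  expect_equal(cv$median_control, 0.9)
  expect_equal(cv$case_values[[1]], 0.6)
  # one infant in a group -> insufficient
  fx2 <- make_conv_fixture()
  anc2 <- anchor_samples(fx2$meta)
  anc2 <- anc2[anc2$sample_id != "s2", ] # drop one case sample
  cv2 <- convergence_series(fx2$d, w, anc2, pr)
  expect_false(cv2$sufficient)
  expect_true(is.na(cv2$p_value))
})

test_that("window series is invariant to a common time translation", {
  co <- default_cohort()
  rpk <- cohort_rpk()
  sor <- sorensen(presence_matrix(rpk))
  w <- build_windows(7, 2, 25)
  anc <- anchor_samples(co$meta)
  pr <- pair_samples(anc, co$meta)
  cv1 <- convergence_series(sor, w, anc, pr)
  # shift every day_of_life and event_dol by +11 days
  meta2 <- co$meta
  meta2$infants$event_dol <- meta2$infants$event_dol + 11
  meta2$samples$day_of_life <- meta2$samples$day_of_life + 11
  meta2$samples$pma_weeks <- meta2$samples$pma_weeks + 11 / 7
  anc2 <- anchor_samples(meta2)
  pr2 <- pair_samples(anc2, meta2)
  cv2 <- convergence_series(sor, w, anc2, pr2)
  expect_equal(cv1$p_value, cv2$p_value)
  expect_equal(cv1$median_case, cv2$median_case)
  expect_equal(cv1$n_case_pairs, cv2$n_case_pairs)
})

test_that("no dissimilarity value comes from a same-infant pair", {
  co <- default_cohort()
  rpk <- cohort_rpk()
  sor <- sorensen(presence_matrix(rpk))
  anc <- anchor_samples(co$meta)
  pr <- pair_samples(anc, co$meta)
  w <- build_windows(7, 2, 25)
  cv <- convergence_series(sor, w, anc, pr)
  # structural check: count cross-infant pairs independently per window
  for (k in seq_len(nrow(w))) {
    cs <- anc[!anc$post_event & anc$group == "case" &
                anc$days_before_event >= w$start[k] &
                anc$days_before_event < w$end[k], ]
    n_cross <- 0
    if (nrow(cs) >= 2) {
      cmb <- utils::combn(nrow(cs), 2)
      n_cross <- sum(cs$infant_id[cmb[1, ]] != cs$infant_id[cmb[2, ]])
    }
    expect_equal(cv$n_case_pairs[k], n_cross)
  }
})

test_that("across-window Kruskal-Wallis/Dunn matches the worked rank example", {
  # windows with values {1,2,3},{4,5,6},{7,8,9}: KW statistic 7.2
  fx <- make_conv_fixture()
  anc <- anchor_samples(fx$meta)
  w <- build_windows(7, 7, 21)
  series <- convergence_series(fx$d, w, anc, NULL)
  series$sufficient <- TRUE
  series$case_values <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- across_window_test(series, "case")
  expect_equal(unname(res$test$statistic), 7.2)
  series$case_values <- list(c(1, 2), c(1, 2), c(1, 2))
  res0 <- across_window_test(series, "case")
  expect_equal(unname(res0$test$statistic), 0)
  expect_equal(res0$test$p_value, 1)
  expect_true(all(res0$pairwise$p_adjusted >= res0$pairwise$p_unadjusted))
})
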