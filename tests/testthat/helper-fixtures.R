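# Small hand-built cohort fixtures used across module tests.

tiny_infants <- function() {
  data.frame(
    infant_id = c("caseA", "caseB", "ctrl1", "ctrl2", "ctrl3"),
    group = c("case", "case", "control", "control", "control"),
    matched_case_id = c(NA, NA, "caseA", "caseA", "caseB"),
    gestational_age_weeks = c(25, 24.5, 25.5, 24.8, 24.2),
    birth_weight_g = c(780, 700, 820, 760, 690),
    event_dol = c(40, 35, NA, NA, NA),
    stringsAsFactors = FALSE)
}

tiny_samples <- function() {
  data.frame(
    sample_id = paste0("s", 1:10),
    infant_id = c("caseA", "caseA", "caseB", "caseB", "ctrl1", "ctrl1",
                  "ctrl2", "ctrl2", "ctrl3", "ctrl3"),
    day_of_life = c(33, 38, 28, 34, 32, 38.5, 31, 37, 27.5, 33),
    pma_weeks = NA_real_,
    total_qc_reads = rep(100000L, 10),
    stringsAsFactors = FALSE)
}

tiny_meta <- function() {
  smp <- tiny_samples()
  inf <- tiny_infants()
  smp$pma_weeks <- inf$gestational_age_weeks[match(smp$infant_id,
                                                   inf$infant_id)] +
    smp$day_of_life / 7
  cohort_metadata(inf, smp)
}

tiny_catalog <- function(ids, lengths = NULL) {
  data.frame(contig_id = ids,
             length_bp = if (is.null(lengths)) rep(1000L, length(ids))
               else lengths,
             family = rep("unclassified", length(ids)),
             circular = rep(FALSE, length(ids)),
             stringsAsFactors = FALSE)
}

# The worked three-leaf tree used in the UniFrac examples.
worked_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# A cached default synthetic cohort shared across test files (generated
# once per test run).
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(synthetic_params(seed = 1))
    cache
  }
})

cohort_rpk <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- default_cohort()
      cache <<- rpk_normalize(co$viral_counts, co$catalog,
                              co$meta$samples)
    }
    cache
  }
})
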