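#' Configuration for the LDA effect-size discriminant screen
#'
#' @param class_boundary_days Boundary (days before event) between the late
#'   class `[0, boundary)` and the early class `[boundary, lookback]`
#'   (default 10). The boundary day itself belongs to the early class.
#' @param lookback_days Furthest days-before value analysed (default 46).
#' @param prevalence_threshold Minimum fraction of analysed samples a contig
#'   must be detected in to enter the screen (default 0.10).
#' @param kw_alpha Significance level for the per-contig Kruskal-Wallis gate
#'   (default 0.05).
#' @param lda_threshold Minimum log10 effect size to call a feature
#'   (default 2.0).
#' @param n_bootstrap Number of bootstrap subsamples for effect-size
#'   averaging (default 30).
#' @param bootstrap_fraction Fraction of each class drawn per bootstrap
#'   (default 2/3).
#' @param tss_total Per-sample total-sum-scaling constant applied before
#'   testing (default 1e6).
#' @param seed Optional integer seed for the bootstrap stream.
#' @return A `lefse_config` list.
#' @export
lefse_config <- function(class_boundary_days = 10, lookback_days = 46,
                         prevalence_threshold = 0.10, kw_alpha = 0.05,
                         lda_threshold = 2.0, n_bootstrap = 30,
                         bootstrap_fraction = 2 / 3, tss_total = 1e6,
                         seed = NULL) {
  stopifnot(prevalence_threshold > 0, prevalence_threshold < 1,
            lda_threshold > 0, n_bootstrap >= 1,
            bootstrap_fraction > 0, bootstrap_fraction <= 1,
            class_boundary_days > 0, lookback_days > class_boundary_days)
  structure(list(class_boundary_days = class_boundary_days,
                 lookback_days = lookback_days,
                 prevalence_threshold = prevalence_threshold,
                 kw_alpha = kw_alpha, lda_threshold = lda_threshold,
                 n_bootstrap = n_bootstrap,
                 bootstrap_fraction = bootstrap_fraction,
                 tss_total = tss_total, seed = seed),
            class = "lefse_config")
}

# Two-class discriminant axis from a regularized pooled covariance:
# w proportional to solve(S + ridge I, mu_late - mu_early), unit-normalized.
discriminant_axis <- function(x, cls) {
  mu1 <- colMeans(x[cls == "late", , drop = FALSE])
  mu0 <- colMeans(x[cls == "early", , drop = FALSE])
  delta <- mu1 - mu0
  center <- x
  center[cls == "late", ] <- sweep(x[cls == "late", , drop = FALSE], 2, mu1)
  center[cls == "early", ] <- sweep(x[cls == "early", , drop = FALSE], 2, mu0)
  s <- crossprod(center) / max(1, nrow(x) - 2)
  ridge <- 1e-3 * mean(diag(s)) + 1e-8
  w <- tryCatch(solve(s + diag(ridge, ncol(s)), delta),
                error = function(e) delta / sqrt(diag(s) + ridge))
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) w else w / nrm
}

lefse_core <- function(abundance, anchored, config, group) {
  ank <- anchored[!anchored$post_event & anchored$group == group, ,
                  drop = FALSE]
  ank <- ank[ank$days_before_event <= config$lookback_days, , drop = FALSE]
  ank <- ank[ank$sample_id %in% colnames(abundance), , drop = FALSE]
  cls <- ifelse(ank$days_before_event < config$class_boundary_days,
                "late", "early")
  if (sum(cls == "late") < 3 || sum(cls == "early") < 3)
    stop("lefse_screen: each class needs at least 3 samples ",
         "(late = ", sum(cls == "late"), ", early = ", sum(cls == "early"),
         ")")
  a <- abundance[, ank$sample_id, drop = FALSE]
  # per-sample total-sum scaling over the full community (scaling before
  # the prevalence filter keeps every contig's scaled values, hence the
  # screen's decisions, independent of which other contigs are filtered:
  # this is what makes the threshold-monotonicity properties hold)
  totals <- colSums(a)
  if (any(totals == 0))
    stop("lefse_screen: sample(s) with zero total abundance: ",
         paste(colnames(a)[totals == 0], collapse = ", "))
  a <- sweep(a, 2, config$tss_total / totals, `*`)
  # prevalence filter over the analysed samples
  prev <- rowMeans(a > 0)
  a <- a[prev >= config$prevalence_threshold, , drop = FALSE]
  n_tested <- nrow(a)
  empty <- data.frame(contig_id = character(0), class = character(0),
                      kw_p = numeric(0), effect_size = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_tested == 0)
    return(structure(empty, n_tested = 0L, config = config, group = group))
  # Kruskal-Wallis gate
  g <- factor(cls)
  kw_p <- apply(a, 1, function(v) stats::kruskal.test(v, g)$p.value)
  keep <- !is.na(kw_p) & kw_p <= config$kw_alpha
  if (!any(keep))
    return(structure(empty, n_tested = n_tested, config = config,
                     group = group))
  x <- t(a[keep, , drop = FALSE]) # samples x surviving contigs
  kw_p <- kw_p[keep]
  # bootstrap-averaged LDA effect size
  if (!is.null(config$seed)) set.seed(config$seed)
  idx_late <- which(cls == "late")
  idx_early <- which(cls == "early")
  n_sub_late <- max(2, floor(config$bootstrap_fraction * length(idx_late)))
  n_sub_early <- max(2, floor(config$bootstrap_fraction * length(idx_early)))
  scores <- matrix(NA_real_, config$n_bootstrap, ncol(x))
  for (b in seq_len(config$n_bootstrap)) {
    take <- c(sample(idx_late, n_sub_late), sample(idx_early, n_sub_early))
    xb <- x[take, , drop = FALSE]
    cb <- cls[take]
    w <- discriminant_axis(xb, cb)
    d_raw <- colMeans(xb[cb == "late", , drop = FALSE]) -
      colMeans(xb[cb == "early", , drop = FALSE])
    scores[b, ] <- (abs(w * d_raw) + abs(d_raw)) / 2
  }
  effect <- log10(pmax(1, colMeans(scores)))
  mean_late <- colMeans(x[cls == "late", , drop = FALSE])
  mean_early <- colMeans(x[cls == "early", , drop = FALSE])
  res <- data.frame(contig_id = colnames(x),
                    class = ifelse(mean_late >= mean_early, "late", "early"),
                    kw_p = kw_p,
                    effect_size = effect,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[res$effect_size >= config$lda_threshold, , drop = FALSE]
  res <- res[order(-res$effect_size), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, n_tested = n_tested, config = config, group = group)
}

#' LDA effect-size screen for contigs associated with the pre-event period
#'
#' Identifies contigs discriminating the late class (samples collected within
#' `class_boundary_days` of NEC onset) from the early class (the antecedent
#' period up to `lookback_days`) among case samples. Pipeline: (1)
#' total-sum scale each sample to `tss_total` over the full community (so no
#' contig's scaled values depend on later filtering); (2) drop contigs
#' detected in fewer than `prevalence_threshold` of the analysed samples;
#' (3) per-contig Kruskal-Wallis gate at `kw_alpha`; (4) effect size per
#' surviving contig =
#' log10 of the bootstrap average (over `n_bootstrap` subsamples of
#' `bootstrap_fraction` of each class) of the mean of the discriminant-axis
#' projected class-mean difference restricted to that contig and the raw
#' class-mean difference, floored at 1 before the log; (5) keep contigs with
#' effect size at least `lda_threshold`, assigning each to the class with the
#' larger mean.
#'
#' @param abundance RPK abundance matrix (contigs x samples).
#' @param anchored Output of [anchor_samples()].
#' @param config A [lefse_config()].
#' @return data.frame `contig_id`, `class` ("late"/"early"), `kw_p`,
#'   `effect_size`, sorted by decreasing effect; attribute `n_tested` records
#'   how many contigs passed the prevalence filter.
#' @export
lefse_screen <- function(abundance, anchored, config = lefse_config()) {
  lefse_core(abundance, anchored, config, group = "case")
}

#' Control-side LDA effect-size screen
#'
#' The identical algorithm applied to control samples, anchored to the
#' matched case's NEC onset: identifies contigs associated with late versus
#' early periods of control-infant virome development.
#'
#' @inheritParams lefse_screen
#' @return As [lefse_screen()].
#' @export
control_side_screen <- function(abundance, anchored,
                                config = lefse_config()) {
  ctrl <- anchored[anchored$group == "control", , drop = FALSE]
  if (nrow(ctrl) == 0) stop("control_side_screen: no control samples")
  lefse_core(abundance, anchored, config, group = "control")
}
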