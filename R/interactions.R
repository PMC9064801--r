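#' Mixed-model virus-bacteria association screen
#'
#' For every (contig, genus) pair passing a 10% prevalence filter within the
#' chosen group, fits a random-intercept linear mixed model (infant as the
#' grouping factor) of the log(1 + total-sum-scaled) contig abundance on the
#' transformed genus relative abundance, and collects the slope and its Wald
#' p-value. Benjamini-Hochberg q-values are computed across all pairs tested
#' within the group; a pair is significant iff `p < 0.05` and `q < 0.25`
#' (the dual gate).
#'
#' @param contig_abundance RPK abundance matrix restricted to the contigs of
#'   interest (e.g. discriminant features).
#' @param genus_counts Genus-by-sample count matrix.
#' @param meta A `cohort_metadata`.
#' @param group "case" or "control": which infants' samples to analyse.
#' @param prevalence_threshold Minimum detection fraction for contigs and
#'   genera (default 0.10).
#' @param predictor_transform Transform for genus relative abundance:
#'   "log" (`log1p`, default) or "arcsine" (arcsine square root).
#' @param tss_total Total-sum-scaling constant for the contig response
#'   (default 1e6).
#' @param sample_totals Optional named vector of per-sample abundance totals
#'   of the full viral community, used for the total-sum scaling of the
#'   response. Supply these when `contig_abundance` is a subset (e.g. only
#'   discriminant contigs), so a contig's scaled abundance does not depend
#'   on which other contigs were selected; defaults to the column sums of
#'   `contig_abundance`.
#' @param p_gate,q_gate Dual significance gate (defaults 0.05 and 0.25).
#' @return data.frame `contig_id`, `genus`, `group`, `coefficient`, `p`, `q`,
#'   `significant`; pairs whose model fit failed carry `NA` coefficients and
#'   are never significant.
#' @export
associate <- function(contig_abundance, genus_counts, meta,
                      group = c("case", "control"),
                      prevalence_threshold = 0.10,
                      predictor_transform = c("log", "arcsine"),
                      tss_total = 1e6, sample_totals = NULL,
                      p_gate = 0.05, q_gate = 0.25) {
  group <- match.arg(group)
  predictor_transform <- match.arg(predictor_transform)
  inf <- meta$infants
  grp_infants <- inf$infant_id[inf$group == group]
  if (length(grp_infants) < 2)
    stop("associate: group '", group, "' needs at least 2 infants")
  smp <- meta$samples
  ids <- intersect(colnames(contig_abundance), colnames(genus_counts))
  ids <- ids[smp$infant_id[match(ids, smp$sample_id)] %in% grp_infants]
  if (length(ids) < 4)
    stop("associate: too few shared samples for group '", group, "'")
  va <- contig_abundance[, ids, drop = FALSE]
  ba <- genus_counts[, ids, drop = FALSE]
  va <- va[rowMeans(va > 0) >= prevalence_threshold, , drop = FALSE]
  ba <- ba[rowMeans(ba > 0) >= prevalence_threshold, , drop = FALSE]
  if (nrow(va) == 0 || nrow(ba) == 0)
    return(data.frame(contig_id = character(0), genus = character(0),
                      group = character(0), coefficient = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  vt <- if (is.null(sample_totals)) colSums(va) else {
    if (any(!ids %in% names(sample_totals)))
      stop("associate: sample_totals must cover every analysed sample")
    sample_totals[ids]
  }
  vt[vt == 0] <- 1
  resp_mat <- log1p(sweep(va, 2, tss_total / vt, `*`))
  brel <- sweep(ba, 2, pmax(colSums(ba), 1), `/`)
  pred_mat <- switch(predictor_transform,
                     log = log1p(brel),
                     arcsine = asin(sqrt(pmin(1, brel))))
  infant <- factor(smp$infant_id[match(ids, smp$sample_id)])
  res <- expand.grid(contig_id = rownames(va), genus = rownames(ba),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$coefficient <- NA_real_
  res$p <- NA_real_
  for (r in seq_len(nrow(res))) {
    df <- data.frame(y = resp_mat[res$contig_id[r], ],
                     x = pred_mat[res$genus[r], ],
                     infant = infant)
    if (stats::sd(df$x) == 0 || stats::sd(df$y) == 0) {
      res$coefficient[r] <- 0
      res$p[r] <- 1
      next
    }
    fit <- tryCatch(
      nlme::lme(y ~ x, random = ~1 | infant, data = df, method = "REML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next # singular fit: pair not estimable
    tt <- tryCatch(summary(fit)$tTable, error = function(e) NULL)
    if (is.null(tt) || !"x" %in% rownames(tt)) next
    res$coefficient[r] <- tt["x", "Value"]
    res$p[r] <- tt["x", "p-value"]
  }
  res$group <- group
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$p) & res$p < p_gate & res$q < q_gate
  res[, c("contig_id", "genus", "group", "coefficient", "p", "q",
          "significant")]
}

#' Signed coefficient matrix of significant associations
#'
#' Builds the contig-by-genus matrix of mixed-model slopes, keeping
#' significant pairs and zeroing the rest; rows and columns are ordered by
#' their mean coefficient (a deterministic, dendrogram-free surrogate for
#' clustering order).
#'
#' @param results Output of [associate()].
#' @return Numeric matrix (contigs x genera).
#' @export
correlation_table <- function(results) {
  contigs <- unique(results$contig_id)
  genera <- unique(results$genus)
  m <- matrix(0, length(contigs), length(genera),
              dimnames = list(contigs, genera))
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) > 0)
    m[cbind(match(sig$contig_id, contigs), match(sig$genus, genera))] <-
      sig$coefficient
  m <- m[order(rowMeans(m), rownames(m)), order(colMeans(m), colnames(m)),
         drop = FALSE]
  m
}
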