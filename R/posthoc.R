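#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Global Kruskal-Wallis rank test across groups followed by Dunn's z-tests
#' for all group pairs. Dunn's z uses mean ranks from the joint ranking with
#' the tie correction \eqn{\sum (t^3 - t) / (12 (N - 1))}; pairwise p-values
#' are adjusted for multiplicity (Bonferroni by default, Benjamini-Hochberg
#' switchable).
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels, same length.
#' @param p_adjust Multiplicity adjustment: "bonferroni" or "BH".
#' @return List with `test` (a `group_test_result` for the global KW test)
#'   and `pairwise` (data.frame: group1, group2, z, p_unadjusted,
#'   p_adjusted).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("kruskal_dunn: need at least 2 groups")
  kw <- stats::kruskal.test(values, groups)
  n_tot <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n_tot - 1))
  lv <- levels(groups)
  cmb <- utils::combn(lv, 2)
  z <- apply(cmb, 2, function(pair) {
    sigma <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) *
                    (1 / n_g[pair[1]] + 1 / n_g[pair[2]]))
    (mean_rank[pair[1]] - mean_rank[pair[2]]) / sigma
  })
  p_un <- 2 * stats::pnorm(-abs(z))
  pairwise <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                         z = as.numeric(z),
                         p_unadjusted = p_un,
                         p_adjusted = stats::p.adjust(p_un, method = p_adjust),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(test = group_test_result(kw$statistic, kw$p.value,
                                "Kruskal-Wallis", n = as.integer(n_g)),
       pairwise = pairwise)
}

#' Friedman test with Dunn's pairwise comparisons
#'
#' Global Friedman rank test on a subjects-by-treatments matrix followed by
#' Dunn's z-tests on mean within-subject ranks,
#' \eqn{z = (\bar R_j - \bar R_k) / \sqrt{k (k + 1) / (6 n)}}, with
#' multiplicity adjustment.
#'
#' @param m Numeric matrix, subjects in rows, treatments (e.g. time blocks)
#'   in columns; column names label the treatments.
#' @param p_adjust Multiplicity adjustment: "bonferroni" or "BH".
#' @return List with `test` and `pairwise` as in [kruskal_dunn()].
#' @export
friedman_dunn <- function(m, p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  m <- as.matrix(m)
  if (ncol(m) < 3) stop("friedman_dunn: need at least 3 treatments")
  if (nrow(m) < 2) stop("friedman_dunn: need at least 2 subjects")
  fr <- stats::friedman.test(m)
  # fully tied data (every subject constant across treatments) degenerates
  # to no evidence of block differences
  if (is.nan(fr$statistic)) {
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  n <- nrow(m)
  k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  mean_rank <- colMeans(ranks)
  labels <- if (!is.null(colnames(m))) colnames(m) else as.character(seq_len(k))
  cmb <- utils::combn(seq_len(k), 2)
  sigma <- sqrt(k * (k + 1) / (6 * n))
  z <- (mean_rank[cmb[1, ]] - mean_rank[cmb[2, ]]) / sigma
  p_un <- 2 * stats::pnorm(-abs(z))
  pairwise <- data.frame(group1 = labels[cmb[1, ]], group2 = labels[cmb[2, ]],
                         z = as.numeric(z),
                         p_unadjusted = p_un,
                         p_adjusted = stats::p.adjust(p_un, method = p_adjust),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(test = group_test_result(fr$statistic, fr$p.value, "Friedman",
                                n = n),
       pairwise = pairwise)
}
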