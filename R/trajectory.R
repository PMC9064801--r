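#' Prevalence/abundance block series for selected contigs
#'
#' Summarizes selected contigs in consecutive blocks of days-before-event
#' (default five 5-day blocks covering `[0, 25)`), separately for cases and
#' controls. Per contig, group and block: prevalence is the percentage of the
#' block's samples in which the contig is detected (RPK > 0); mean abundance
#' is the RPK averaged over ALL of the block's samples, zeros included.
#' Blocks containing no samples for a group are recorded as missing (`NA`),
#' not zero.
#'
#' @param abundance RPK abundance matrix.
#' @param anchored Output of [anchor_samples()].
#' @param contig_ids Contigs to summarize (e.g. discriminant features).
#' @param block_width Block width in days (default 5).
#' @param max_days Coverage limit in days-before-event (default 25).
#' @return A `block_series` data.frame: `contig_id`, `group`, `block_start`,
#'   `block_end`, `block_mid` (signed midpoint, negative days-before),
#'   `n_samples`, `prevalence` (percent), `mean_abundance`.
#' @export
block_series <- function(abundance, anchored, contig_ids, block_width = 5,
                         max_days = 25) {
  stopifnot(block_width > 0, max_days >= block_width)
  missing_id <- setdiff(contig_ids, rownames(abundance))
  if (length(missing_id) > 0)
    stop("block_series: contig(s) absent from abundance table: ",
         paste(head(missing_id), collapse = ", "))
  starts <- seq(0, max_days - block_width, by = block_width)
  ank <- anchored[!anchored$post_event &
                    anchored$days_before_event < max_days &
                    anchored$sample_id %in% colnames(abundance), ,
                  drop = FALSE]
  out <- list()
  for (grp in c("case", "control")) {
    sub <- ank[ank$group == grp, , drop = FALSE]
    for (s in starts) {
      in_block <- sub$sample_id[sub$days_before_event >= s &
                                  sub$days_before_event < s + block_width]
      n <- length(in_block)
      if (n > 0) {
        a <- abundance[contig_ids, in_block, drop = FALSE]
        prev <- 100 * rowMeans(a > 0)
        ab <- rowMeans(a)
      } else {
        prev <- ab <- rep(NA_real_, length(contig_ids))
      }
      out[[length(out) + 1]] <- data.frame(
        contig_id = contig_ids, group = grp, block_start = s,
        block_end = s + block_width,
        block_mid = -(s + block_width / 2),
        n_samples = n, prevalence = unname(prev),
        mean_abundance = unname(ab), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("block_series", "data.frame")
  res
}

#' Friedman/Dunn test across blocks of a trajectory series
#'
#' Treats contigs as the repeated-measures subjects and blocks as the
#' treatments: tests whether a group's contig prevalences (or mean
#' abundances) differ across time blocks, with Dunn's pairwise block
#' comparisons. Contigs missing any block value are dropped with a warning.
#'
#' @param series A `block_series` from [block_series()].
#' @param group "case" or "control".
#' @param measure "prevalence" or "mean_abundance".
#' @param p_adjust Multiplicity adjustment passed to [friedman_dunn()].
#' @return As [friedman_dunn()].
#' @export
block_friedman_dunn <- function(series, group = c("case", "control"),
                                measure = c("prevalence", "mean_abundance"),
                                p_adjust = c("bonferroni", "BH")) {
  group <- match.arg(group)
  measure <- match.arg(measure)
  sub <- series[series$group == group, , drop = FALSE]
  labels <- sort(unique(sub$block_start))
  m <- sapply(labels, function(s)
    sub[[measure]][sub$block_start == s][
      match(unique(sub$contig_id), sub$contig_id[sub$block_start == s])])
  rownames(m) <- unique(sub$contig_id)
  colnames(m) <- sprintf("[%g,%g)", labels,
                         labels + (sub$block_end - sub$block_start)[1])
  complete <- stats::complete.cases(m)
  if (!all(complete))
    warning("block_friedman_dunn: dropping ", sum(!complete),
            " contig(s) with missing block values")
  m <- m[complete, , drop = FALSE]
  friedman_dunn(m, p_adjust = p_adjust)
}

ols_slope <- function(x, y) {
  ok <- !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Per-contig regression slopes of prevalence and abundance over time
#'
#' Ordinary least-squares slopes of the block values against the signed block
#' midpoints (negative days-before, e.g. -22.5 ... -2.5), so a positive slope
#' means an increase approaching the event. Missing blocks are omitted
#' pairwise; a contig/group with fewer than two populated blocks has
#' undefined slopes (`NA`).
#'
#' @param series A `block_series` from [block_series()].
#' @return data.frame `contig_id`, `group`, `prevalence_slope`,
#'   `abundance_slope` (per-day coefficients).
#' @export
trajectory_slopes <- function(series) {
  out <- list()
  for (grp in unique(series$group)) {
    sub <- series[series$group == grp, , drop = FALSE]
    for (cid in unique(sub$contig_id)) {
      rows <- sub[sub$contig_id == cid, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        contig_id = cid, group = grp,
        prevalence_slope = ols_slope(rows$block_mid, rows$prevalence),
        abundance_slope = ols_slope(rows$block_mid, rows$mean_abundance),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
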