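#' Anchor samples to NEC onset
#'
#' Computes, for every sample, the number of days before the anchoring event:
#' `event_dol - day_of_life` using the infant's own NEC onset day for cases
#' and the matched case's onset day for controls. Samples collected after the
#' event (negative days-before) are flagged `post_event` and are excluded
#' from pre-event analyses downstream.
#'
#' @param meta A `cohort_metadata` object.
#' @return data.frame with columns `sample_id`, `infant_id`, `group`,
#'   `day_of_life`, `days_before_event`, `post_event`.
#' @export
anchor_samples <- function(meta) {
  inf <- meta$infants
  smp <- meta$samples
  i <- match(smp$infant_id, inf$infant_id)
  group <- inf$group[i]
  event <- inf$event_dol[i]
  is_ctrl <- group == "control"
  mc <- inf$matched_case_id[i][is_ctrl]
  case_event <- inf$event_dol[match(mc, inf$infant_id)]
  if (any(is.na(case_event)))
    stop("anchor_samples: matched case without event_dol for control(s): ",
         paste(unique(smp$infant_id[is_ctrl][is.na(case_event)]),
               collapse = ", "))
  event[is_ctrl] <- case_event
  if (any(is.na(event)))
    stop("anchor_samples: case(s) without event_dol: ",
         paste(unique(smp$infant_id[is.na(event)]), collapse = ", "))
  # snap to 9 decimals: keeps half-open window membership invariant under
  # common time translations despite floating-point subtraction
  days_before <- round(event - smp$day_of_life, 9)
  data.frame(sample_id = smp$sample_id, infant_id = smp$infant_id,
             group = group, day_of_life = smp$day_of_life,
             days_before_event = days_before,
             post_event = days_before < 0,
             stringsAsFactors = FALSE)
}

#' Pair case samples with matched control samples
#'
#' For each case sample and each control infant matched to that case, selects
#' the control sample minimizing the absolute day-of-life difference,
#' provided it is within `tolerance` days (default +/- 3.5 d). Ties are
#' broken toward the earlier control sample, deterministically. A case sample
#' with one or two matched control infants thus yields one or two pairs; case
#' samples with no admissible control sample are reported unpaired.
#'
#' @param anchored Output of [anchor_samples()].
#' @param meta The `cohort_metadata` the anchoring came from (provides the
#'   case-control matching).
#' @param tolerance Maximum |day-of-life difference| in days.
#' @return List with `pairs` (data.frame: case_sample_id, control_sample_id,
#'   case_infant_id, control_infant_id, delta_dol) and `unpaired` (character
#'   vector of case sample ids with no admissible pairing).
#' @export
pair_samples <- function(anchored, meta, tolerance = 3.5) {
  inf <- meta$infants
  ctrl_of_case <- split(inf$infant_id[inf$group == "control"],
                        inf$matched_case_id[inf$group == "control"])
  case_smp <- anchored[anchored$group == "case", , drop = FALSE]
  ctrl_smp <- anchored[anchored$group == "control", , drop = FALSE]
  rows <- list()
  unpaired <- character(0)
  for (ci in seq_len(nrow(case_smp))) {
    cs <- case_smp[ci, ]
    found <- FALSE
    for (ctrl_inf in ctrl_of_case[[cs$infant_id]]) {
      cand <- ctrl_smp[ctrl_smp$infant_id == ctrl_inf, , drop = FALSE]
      if (nrow(cand) == 0) next
      delta <- abs(cand$day_of_life - cs$day_of_life)
      # nearest first; ties broken toward the earlier control sample
      ord <- order(delta, cand$day_of_life)
      best <- ord[1]
      if (delta[best] <= tolerance) {
        rows[[length(rows) + 1]] <- data.frame(
          case_sample_id = cs$sample_id,
          control_sample_id = cand$sample_id[best],
          case_infant_id = cs$infant_id,
          control_infant_id = ctrl_inf,
          delta_dol = cand$day_of_life[best] - cs$day_of_life,
          stringsAsFactors = FALSE)
        found <- TRUE
      }
    }
    if (!found) unpaired <- c(unpaired, cs$sample_id)
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(case_sample_id = character(0),
               control_sample_id = character(0),
               case_infant_id = character(0),
               control_infant_id = character(0),
               delta_dol = numeric(0), stringsAsFactors = FALSE)
  list(pairs = pairs, unpaired = unpaired)
}

#' Build a sliding-window skeleton over days-before-event
#'
#' Windows are half-open intervals `[k, k + width)` in days-before-event for
#' `k = 0, step, 2 step, ...` while `k + width <= max_lookback`. The
#' half-open convention puts a sample exactly on a window's upper bound into
#' the next window, and ensures day-0 samples belong to the `[0, width)`
#' window.
#'
#' @param width Window width in days (default 7).
#' @param step Step between window starts in days (default 2).
#' @param max_lookback Largest days-before value covered.
#' @return data.frame with columns `window`, `start`, `end`.
#' @export
build_windows <- function(width = 7, step = 2, max_lookback) {
  stopifnot(width > 0, step > 0, step <= width, max_lookback >= width)
  starts <- seq(0, max_lookback - width, by = step)
  data.frame(window = seq_along(starts), start = starts,
             end = starts + width)
}

window_members <- function(windows, days_before) {
  lapply(seq_len(nrow(windows)), function(w)
    which(days_before >= windows$start[w] & days_before < windows$end[w]))
}

cross_infant_values <- function(d, sample_ids, infant_ids,
                                include_same_infant = FALSE) {
  if (length(sample_ids) < 2) return(numeric(0))
  sub <- d[sample_ids, sample_ids, drop = FALSE]
  pr <- which(upper.tri(sub), arr.ind = TRUE)
  keep <- if (include_same_infant) rep(TRUE, nrow(pr)) else
    infant_ids[pr[, 1]] != infant_ids[pr[, 2]]
  vals <- sub[pr][keep]
  vals[!is.na(vals)]
}

median_ci <- function(x, conf = 0.95) {
  # distribution-free CI of the median from binomial order statistics
  n <- length(x)
  if (n < 3) return(c(NA_real_, NA_real_))
  s <- sort(x)
  alpha <- (1 - conf) / 2
  lo <- stats::qbinom(alpha, n, 0.5)
  hi <- stats::qbinom(1 - alpha, n, 0.5) + 1
  c(s[max(lo, 1)], s[min(hi, n)])
}

#' Between-infant dissimilarity convergence series over sliding windows
#'
#' For every window, collects the between-case dissimilarity multiset (all
#' cross-infant pairs of non-post-event case samples whose days-before-event
#' fall in the window) and the between-control multiset (likewise, restricted
#' to control samples that appear in the matched pairing), and compares the
#' two with a two-sided Mann-Whitney U-test. Windows where either group has
#' samples from fewer than two infants are recorded as insufficient.
#'
#' @param d Symmetric distance matrix over samples.
#' @param windows Window skeleton from [build_windows()].
#' @param anchored Output of [anchor_samples()].
#' @param pairs Output of [pair_samples()]; pass `NULL` to use all control
#'   samples instead of paired-only (sensitivity option).
#' @param include_same_infant Include same-infant pairs in the between-group
#'   multisets (default FALSE: "between infants" means cross-infant).
#' @return A `window_series` data.frame: one row per window with interval,
#'   pair counts, group medians with 95% confidence bounds, the Mann-Whitney
#'   p-value and a `sufficient` flag; list columns `case_values` and
#'   `control_values` hold the dissimilarity multisets.
#' @export
convergence_series <- function(d, windows, anchored, pairs = NULL,
                               include_same_infant = FALSE) {
  d <- as.matrix(d)
  anchored <- anchored[!anchored$post_event, , drop = FALSE]
  case <- anchored[anchored$group == "case", , drop = FALSE]
  ctrl <- anchored[anchored$group == "control", , drop = FALSE]
  if (!is.null(pairs))
    ctrl <- ctrl[ctrl$sample_id %in% pairs$pairs$control_sample_id, ,
                 drop = FALSE]
  case <- case[case$sample_id %in% rownames(d), , drop = FALSE]
  ctrl <- ctrl[ctrl$sample_id %in% rownames(d), , drop = FALSE]
  out <- windows
  out$n_case_samples <- NA_integer_; out$n_control_samples <- NA_integer_
  out$n_case_pairs <- NA_integer_; out$n_control_pairs <- NA_integer_
  out$median_case <- NA_real_; out$median_control <- NA_real_
  out$case_ci_lo <- NA_real_; out$case_ci_hi <- NA_real_
  out$control_ci_lo <- NA_real_; out$control_ci_hi <- NA_real_
  out$p_value <- NA_real_
  out$sufficient <- FALSE
  case_v <- vector("list", nrow(windows))
  ctrl_v <- vector("list", nrow(windows))
  mem_case <- window_members(windows, case$days_before_event)
  mem_ctrl <- window_members(windows, ctrl$days_before_event)
  for (w in seq_len(nrow(windows))) {
    cs <- case[mem_case[[w]], , drop = FALSE]
    ks <- ctrl[mem_ctrl[[w]], , drop = FALSE]
    out$n_case_samples[w] <- nrow(cs)
    out$n_control_samples[w] <- nrow(ks)
    cv <- cross_infant_values(d, cs$sample_id, cs$infant_id,
                              include_same_infant)
    kv <- cross_infant_values(d, ks$sample_id, ks$infant_id,
                              include_same_infant)
    case_v[[w]] <- cv; ctrl_v[[w]] <- kv
    out$n_case_pairs[w] <- length(cv)
    out$n_control_pairs[w] <- length(kv)
    if (length(cv) > 0) {
      out$median_case[w] <- stats::median(cv)
      ci <- median_ci(cv); out$case_ci_lo[w] <- ci[1]; out$case_ci_hi[w] <- ci[2]
    }
    if (length(kv) > 0) {
      out$median_control[w] <- stats::median(kv)
      ci <- median_ci(kv)
      out$control_ci_lo[w] <- ci[1]; out$control_ci_hi[w] <- ci[2]
    }
    enough <- length(unique(cs$infant_id)) >= 2 &&
      length(unique(ks$infant_id)) >= 2 &&
      length(cv) > 0 && length(kv) > 0
    if (enough) {
      out$p_value[w] <- mann_whitney(cv, kv)$p_value
      out$sufficient[w] <- TRUE
    }
  }
  out$case_values <- case_v
  out$control_values <- ctrl_v
  class(out) <- c("window_series", "data.frame")
  out
}

#' Kruskal-Wallis/Dunn test across windows within one group
#'
#' Tests whether a group's between-infant dissimilarities differ across the
#' windows of a convergence series, with Dunn's pairwise window comparisons.
#'
#' @param series A `window_series` from [convergence_series()].
#' @param group "case" or "control".
#' @param p_adjust Multiplicity adjustment passed to [kruskal_dunn()].
#' @return As [kruskal_dunn()].
#' @export
across_window_test <- function(series, group = c("case", "control"),
                               p_adjust = c("bonferroni", "BH")) {
  group <- match.arg(group)
  col <- if (group == "case") "case_values" else "control_values"
  vals <- series[[col]]
  keep <- vapply(vals, length, 1L) > 0 & series$sufficient
  if (sum(keep) < 3)
    stop("across_window_test: need at least 3 windows with sufficient data")
  labels <- sprintf("[%g,%g)", series$start[keep], series$end[keep])
  values <- unlist(vals[keep])
  groups <- rep(labels, vapply(vals[keep], length, 1L))
  kruskal_dunn(values, factor(groups, levels = labels), p_adjust = p_adjust)
}

#' Serialize a window series to TSV (without the value multisets)
#' @param series A `window_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_window_series <- function(series, path) {
  df <- as.data.frame(series)
  df$case_values <- NULL
  df$control_values <- NULL
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) fmt_num(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
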