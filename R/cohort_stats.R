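group_test_result <- function(statistic, p_value, test, n = NULL, ...) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 test = test, n = n, ...),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic), ", p = ",
      format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers the squared distance matrix (Gower centering) and
#' eigendecomposes it. Axes with negative eigenvalues (which arise for
#' semi-metric dissimilarities such as Bray-Curtis) are reported but dropped
#' from the coordinates; eigenvalues within `1e-10 * max(|eigenvalue|)` of
#' zero are treated as zero.
#'
#' @param d Symmetric distance matrix.
#' @param k Number of axes requested (truncated with a warning if fewer
#'   positive eigenvalues exist).
#' @return List with `coordinates` (n x k'), `eigenvalues` (all, decreasing),
#'   `proportion` (share of positive-eigenvalue variance per returned axis)
#'   and `negative_eigenvalues`.
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("pcoa: need at least 3 samples")
  if (any(is.na(d))) stop("pcoa: distance matrix contains missing pairs")
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  tol <- 1e-10 * max(abs(e$values), 1e-300)
  pos <- e$values > tol
  npos <- sum(pos)
  if (k > npos) {
    if (npos < n - 1 || k > n - 1)
      warning("pcoa: k truncated to ", npos, " positive axes")
    k <- npos
  }
  if (k == 0) {
    coords <- matrix(0, n, 0)
    rownames(coords) <- rownames(d)
    return(list(coordinates = coords, eigenvalues = e$values,
                proportion = numeric(0),
                negative_eigenvalues = e$values[e$values < -tol]))
  }
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       eigenvalues = e$values,
       proportion = e$values[seq_len(k)] / sum(e$values[pos]),
       negative_eigenvalues = e$values[e$values < -tol])
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' PERMANOVA for a single covariate
#'
#' Permutational multivariate analysis of variance on a distance matrix with a
#' single continuous or categorical covariate. The pseudo-F statistic is
#' computed from the Gower-centered inner-product matrix projected on the
#' (column-centered) covariate design; the permutation p-value is
#' \eqn{(1 + \#\{F^* \ge F\}) / (1 + permutations)} under random permutation
#' of observations, or the exact proportion \eqn{\#\{F^* \ge F\}/n!} (the
#' identity included) under exhaustive enumeration.
#'
#' @param d Symmetric distance matrix.
#' @param covariate Numeric vector (continuous) or factor/character
#'   (categorical), one value per sample in matrix order.
#' @param permutations Number of random permutations (>= 99).
#' @param seed Optional integer seed for the permutation stream.
#' @param exhaustive Enumerate all `n!` permutations (only sensible for
#'   n <= 8).
#' @param strata Optional factor restricting permutations to occur within its
#'   levels (e.g. infant id for repeated measures).
#' @return A `group_test_result` with fields `statistic` (pseudo-F),
#'   `p_value`, `r_squared` and `df`.
#' @export
permanova <- function(d, covariate, permutations = 999, seed = NULL,
                      exhaustive = FALSE, strata = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(covariate) != n)
    stop("permanova: covariate must have one value per sample")
  if (is.character(covariate)) covariate <- factor(covariate)
  if (is.factor(covariate)) {
    if (nlevels(droplevels(covariate)) < 2)
      stop("permanova: degenerate design (constant covariate)")
    x <- stats::model.matrix(~covariate)[, -1, drop = FALSE]
  } else {
    if (stats::sd(covariate) == 0)
      stop("permanova: degenerate design (constant covariate)")
    x <- matrix(covariate, ncol = 1)
  }
  if (!exhaustive && permutations < 99)
    stop("permanova: at least 99 permutations required")
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  x <- scale(x, center = TRUE, scale = FALSE)
  m <- qr(x)$rank
  pseudo_f <- function(perm) {
    xp <- x[perm, , drop = FALSE]
    h <- xp %*% solve(crossprod(xp), t(xp))
    ss_model <- sum(h * g) # tr(HG); H idempotent symmetric
    ss_resid <- sum(diag(g)) - ss_model
    (ss_model / m) / (ss_resid / (n - m - 1))
  }
  f_obs <- pseudo_f(seq_len(n))
  if (exhaustive) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, pseudo_f)
    p <- mean(f_perm >= f_obs - 1e-12)
  } else {
    if (!is.null(seed)) set.seed(seed)
    shuffle <- function() {
      if (is.null(strata)) return(sample.int(n))
      p <- seq_len(n)
      for (lv in split(seq_len(n), strata)) p[lv] <- lv[sample.int(length(lv))]
      p
    }
    f_perm <- replicate(permutations, pseudo_f(shuffle()))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + permutations)
  }
  ss_model <- sum((x %*% solve(crossprod(x), t(x))) * g)
  group_test_result(f_obs, p, "PERMANOVA", n = n,
                    r_squared = ss_model / sum(diag(g)),
                    df = c(model = m, residual = n - m - 1))
}

#' Within- versus between-infant dissimilarity
#'
#' Splits all defined sample pairs into pairs sharing an infant (within) and
#' cross-infant pairs (between), and compares the two multisets with a
#' two-sided Mann-Whitney U-test.
#'
#' @param d Symmetric distance matrix over samples.
#' @param samples Sample metadata data.frame (`sample_id`, `infant_id`).
#' @return List with `median_within`, `median_between`, `within`, `between`
#'   (the pair value vectors) and `test` (a `group_test_result`).
#' @export
within_between <- function(d, samples) {
  d <- as.matrix(d)
  ids <- rownames(d)
  infant <- samples$infant_id[match(ids, samples$sample_id)]
  if (any(is.na(infant)))
    stop("within_between: sample(s) missing from metadata")
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  vals <- d[pairs]
  same <- infant[pairs[, 1]] == infant[pairs[, 2]]
  ok <- !is.na(vals)
  w <- vals[same & ok]
  b <- vals[!same & ok]
  if (length(w) == 0)
    stop("within_between: no infant has two or more samples")
  if (length(b) == 0)
    stop("within_between: need samples from at least two infants")
  test <- mann_whitney(w, b)
  list(median_within = stats::median(w), median_between = stats::median(b),
       within = w, between = b, test = test)
}

#' Alpha-diversity trend over postmenstrual age
#'
#' Random-intercept linear mixed model of a per-sample alpha-diversity value
#' on postmenstrual age, with infant as the grouping factor (fitted with
#' [nlme::lme()]); returns the fixed-effect PMA slope and its Wald p-value.
#' With a single infant the model degenerates and an ordinary regression is
#' used, with a warning.
#'
#' @param alpha data.frame with columns `sample_id` and `value` (e.g. Shannon
#'   diversity from [richness_and_shannon()], renamed).
#' @param samples Sample metadata (`sample_id`, `infant_id`, `pma_weeks`).
#' @return List with `slope`, `p_value`, `intercept` and `model_type`
#'   ("mixed" or "ols").
#' @export
alpha_trend <- function(alpha, samples) {
  i <- match(alpha$sample_id, samples$sample_id)
  if (any(is.na(i))) stop("alpha_trend: sample(s) missing from metadata")
  df <- data.frame(value = alpha$value,
                   pma = samples$pma_weeks[i],
                   infant = factor(samples$infant_id[i]))
  if (nrow(df) < 3) stop("alpha_trend: need at least 3 samples")
  if (stats::sd(df$value) == 0) # constant response: flat trend by definition
    return(list(slope = 0, p_value = 1, intercept = df$value[1],
                model_type = "degenerate"))
  if (nlevels(df$infant) < 2) {
    warning("alpha_trend: single infant; falling back to ordinary regression")
    fit <- stats::lm(value ~ pma, data = df)
    co <- summary(fit)$coefficients
    return(list(slope = co["pma", "Estimate"],
                p_value = co["pma", "Pr(>|t|)"],
                intercept = co["(Intercept)", "Estimate"],
                model_type = "ols"))
  }
  fit <- nlme::lme(value ~ pma, random = ~1 | infant, data = df,
                   method = "REML")
  tt <- summary(fit)$tTable
  list(slope = tt["pma", "Value"], p_value = tt["pma", "p-value"],
       intercept = tt["(Intercept)", "Value"], model_type = "mixed")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities not
#' exceeding that of the observed table (the convention of
#' [stats::fisher.test()], which reproduces the cohort-characteristics table
#' conventions of this analysis). A zero margin leaves the table
#' uninformative; p = 1 is returned with a warning.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A `group_test_result` with the odds-ratio estimate as statistic.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop("fisher_exact_2x2: table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("fisher_exact_2x2: counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("fisher_exact_2x2: zero margin; p = 1")
    return(group_test_result(NA_real_, 1, "Fisher exact (two-sided)",
                             n = sum(table)))
  }
  ft <- stats::fisher.test(table, alternative = "two.sided")
  group_test_result(unname(ft$estimate), ft$p.value,
                    "Fisher exact (two-sided)", n = sum(table))
}

#' Two-sided Mann-Whitney U-test
#'
#' Exact enumeration when both groups have at most `exact_max` observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric value vectors.
#' @param exact_max Largest group size for which the exact distribution is
#'   used (default 8).
#' @return A `group_test_result` with the U statistic.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney: both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE))
  group_test_result(wt$statistic, wt$p.value,
                    if (use_exact) "Mann-Whitney U (exact)"
                    else "Mann-Whitney U (normal approximation)",
                    n = c(length(x), length(y)))
}
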