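# Naive, loop-based oracle implementations of every dissimilarity metric,
# kept deliberately independent of the package's vectorized code paths.

oracle_bray <- function(a) {
  n <- ncol(a)
  d <- matrix(0, n, n, dimnames = list(colnames(a), colnames(a)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- den <- 0
    for (k in seq_len(nrow(a))) {
      num <- num + abs(a[k, i] - a[k, j])
      den <- den + a[k, i] + a[k, j]
    }
    d[i, j] <- if (den == 0) NA_real_ else num / den
  }
  d
}

oracle_sorensen <- function(pres) {
  n <- ncol(pres)
  d <- matrix(0, n, n, dimnames = list(colnames(pres), colnames(pres)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A <- which(pres[, i]); B <- which(pres[, j])
    d[i, j] <- if (length(A) == 0 || length(B) == 0) NA_real_ else
      1 - 2 * length(intersect(A, B)) / (length(A) + length(B))
  }
  d
}

oracle_hellinger <- function(a, log_transform = FALSE) {
  if (log_transform) a <- log1p(a)
  n <- ncol(a)
  d <- matrix(0, n, n, dimnames = list(colnames(a), colnames(a)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- sum(a[, i]); sj <- sum(a[, j])
    if (si == 0 || sj == 0) { d[i, j] <- NA_real_; next }
    s <- 0
    for (k in seq_len(nrow(a)))
      s <- s + (sqrt(a[k, i] / si) - sqrt(a[k, j] / sj))^2
    d[i, j] <- sqrt(s)
  }
  d
}

# Recursive descendant-tip sets per edge, independent of the package's
# postorder edge-mass accumulation.
oracle_edge_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc_of <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, desc_of)))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc_of(tree$edge[e, 2]))
}

oracle_unifrac_unweighted_pair <- function(tree, taxa_a, taxa_b) {
  tips <- oracle_edge_tips(tree)
  ia <- which(tree$tip.label %in% taxa_a)
  ib <- which(tree$tip.label %in% taxa_b)
  u <- union(ia, ib)
  uniq <- tot <- 0
  for (e in seq_along(tips)) {
    below <- intersect(tips[[e]], u)
    if (length(below) == 0 || length(below) == length(u)) next # not spanned
    in_a <- length(intersect(tips[[e]], ia)) > 0
    in_b <- length(intersect(tips[[e]], ib)) > 0
    tot <- tot + tree$edge.length[e]
    if (xor(in_a, in_b)) uniq <- uniq + tree$edge.length[e]
  }
  if (tot == 0) 0 else uniq / tot
}

oracle_unifrac_weighted_pair <- function(tree, counts_a, counts_b,
                                         normalized = FALSE) {
  tips <- oracle_edge_tips(tree)
  pa <- counts_a / sum(counts_a)
  pb <- counts_b / sum(counts_b)
  raw <- denom <- 0
  for (e in seq_along(tips)) {
    ma <- sum(pa[tips[[e]]])
    mb <- sum(pb[tips[[e]]])
    raw <- raw + tree$edge.length[e] * abs(ma - mb)
    denom <- denom + tree$edge.length[e] * (ma + mb)
  }
  if (normalized) (if (denom > 0) raw / denom else 0) else raw
}

random_abundance <- function(n_feat = 10, n_smp = 6, zero_frac = 0.3) {
  a <- matrix(stats::rexp(n_feat * n_smp, rate = 0.2), n_feat, n_smp,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("s", seq_len(n_smp))))
  a[stats::runif(length(a)) < zero_frac] <- 0
  a
}
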