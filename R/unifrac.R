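#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads uniformly without replacement to exactly
#' `depth` reads (via [vegan::rrarefy()], seeded for reproducibility).
#' Samples with fewer than `depth` total reads are dropped and listed.
#'
#' @param counts Genus-by-sample integer count matrix.
#' @param depth Rarefaction depth in reads (default 2500).
#' @param seed Optional integer seed.
#' @return List with `counts` (rarefied matrix, retained samples only),
#'   `depth`, `dropped` (sample ids with insufficient reads) and `seed`.
#' @export
rarefy_counts <- function(counts, depth = 2500, seed = NULL) {
  if (depth <= 0) stop("rarefy_counts: depth must be positive")
  validate_count_table(counts)
  totals <- colSums(counts)
  dropped <- colnames(counts)[totals < depth]
  keep <- counts[, totals >= depth, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  # rrarefy's advisory warning does not apply: counts are integer and every
  # retained sample's total is >= depth
  rar <- t(suppressWarnings(vegan::rrarefy(t(keep), sample = depth)))
  storage.mode(rar) <- "integer"
  list(counts = rar, depth = depth, dropped = dropped, seed = seed)
}

# Per-edge descendant tip indicator matrix (edges x tips), tips in
# tree$tip.label order. Row e is TRUE for tips descending from edge e's
# child node.
edge_tip_matrix <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  desc <- matrix(FALSE, n_node, n_tip)
  desc[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1]
    child <- ord$edge[i, 2]
    desc[parent, ] <- desc[parent, ] | desc[child, ]
  }
  desc[tree$edge[, 2], , drop = FALSE]
}

prep_unifrac <- function(counts, tree) {
  genera <- rownames(counts)
  validate_genus_tree(tree, genera = genera[rowSums(counts) > 0])
  present_in_tree <- intersect(genera, tree$tip.label)
  counts <- counts[present_in_tree, , drop = FALSE]
  desc <- edge_tip_matrix(tree)
  tip_idx <- match(rownames(counts), tree$tip.label)
  list(counts = counts, desc = desc[, tip_idx, drop = FALSE],
       len = tree$edge.length)
}

#' Unweighted UniFrac distance
#'
#' Presence-absence, phylogeny-aware dissimilarity: for a pair of samples,
#' the branch length unique to either sample's taxon set divided by the
#' total branch length spanned by their union. "Spanned" means the minimal
#' spanning subtree of the union taxon set: edges ancestral to the union's
#' most recent common ancestor carry no information about the pair and are
#' excluded, so two samples with disjoint taxon sets are at distance 1.
#'
#' @param counts Genus-by-sample count matrix (e.g. rarefied).
#' @param tree Rooted [ape::phylo] tree whose leaves cover the observed
#'   genera, with branch lengths.
#' @return Symmetric distance matrix in \[0, 1\] with attribute
#'   `metric = "unweighted_unifrac"`.
#' @export
unweighted_unifrac <- function(counts, tree) {
  pu <- prep_unifrac(counts, tree)
  pres <- pu$counts > 0
  # edge x sample: does any descendant tip occur in the sample?
  edge_pres <- (pu$desc %*% pres) > 0
  n_desc <- rowSums(pu$desc)
  ns <- ncol(pres)
  d <- matrix(0, ns, ns, dimnames = list(colnames(pres), colnames(pres)))
  union_sizes <- colSums(pres)
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      u <- pres[, i] | pres[, j]
      nu <- sum(u)
      in_union <- pu$desc %*% u
      # spanning subtree: edges with some, but not all, union taxa below
      span <- in_union > 0 & in_union < nu
      uniq <- span & (edge_pres[, i] != edge_pres[, j])
      tot <- sum(pu$len[span])
      d[i, j] <- d[j, i] <- if (tot > 0) sum(pu$len[uniq]) / tot else 0
    }
  }
  new_dist_matrix(d, "unweighted_unifrac")
}

#' Weighted UniFrac distance
#'
#' Abundance-weighted, phylogeny-aware dissimilarity. Relative abundances are
#' propagated from the tips to every branch; the raw distance is
#' \eqn{\sum_e \ell_e |p_A(e) - p_B(e)|}. The normalized variant (the
#' default) divides by the abundance-weighted maximum
#' \eqn{\sum_e \ell_e (p_A(e) + p_B(e))}, scaling the distance into \[0, 1\].
#'
#' @inheritParams unweighted_unifrac
#' @param normalized Return the normalized variant (default TRUE).
#' @return Symmetric distance matrix with attribute
#'   `metric = "weighted_unifrac"` (or `"weighted_unifrac_raw"`).
#' @export
weighted_unifrac <- function(counts, tree, normalized = TRUE) {
  pu <- prep_unifrac(counts, tree)
  totals <- colSums(pu$counts)
  if (any(totals == 0))
    stop("weighted_unifrac: sample(s) with zero counts: ",
         paste(colnames(pu$counts)[totals == 0], collapse = ", "))
  rel <- sweep(pu$counts, 2, totals, `/`)
  mass <- pu$desc %*% rel # edge x sample branch masses
  ns <- ncol(rel)
  d <- matrix(0, ns, ns, dimnames = list(colnames(rel), colnames(rel)))
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      raw <- sum(pu$len * abs(mass[, i] - mass[, j]))
      if (normalized) {
        denom <- sum(pu$len * (mass[, i] + mass[, j]))
        d[i, j] <- d[j, i] <- if (denom > 0) raw / denom else 0
      } else {
        d[i, j] <- d[j, i] <- raw
      }
    }
  }
  new_dist_matrix(d, if (normalized) "weighted_unifrac"
                  else "weighted_unifrac_raw")
}

#' Bacterial beta-diversity convergence series
#'
#' Applies the sliding-window convergence analysis to a bacterial distance
#' matrix (typically weighted UniFrac on rarefied genus counts), using the
#' same anchoring, pairing and window machinery as the viral series.
#'
#' @inheritParams convergence_series
#' @return A `window_series`, as [convergence_series()].
#' @export
bacterial_convergence <- function(d, windows, anchored, pairs = NULL,
                                  include_same_infant = FALSE) {
  convergence_series(d, windows, anchored, pairs = pairs,
                     include_same_infant = include_same_infant)
}
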