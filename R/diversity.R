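new_dist_matrix <- function(m, metric, transformation = NULL) {
  diag(m) <- 0
  attr(m, "metric") <- metric
  if (!is.null(transformation)) attr(m, "transformation") <- transformation
  m
}

#' Weighted Bray-Curtis dissimilarity
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} computed on RPK
#' vectors. A pair of all-zero samples has an undefined dissimilarity and is
#' reported as `NA` rather than silently zeroed.
#'
#' @param abundance Contig-by-sample RPK matrix.
#' @return Symmetric sample-by-sample dissimilarity matrix in \[0, 1\] with
#'   attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(abundance) {
  x <- t(abundance)
  num <- as.matrix(stats::dist(x, method = "manhattan"))
  cs <- colSums(abundance)
  den <- outer(cs, cs, `+`)
  d <- num / den
  d[den == 0] <- NA_real_ # both samples all-zero: undefined
  new_dist_matrix(d, "bray_curtis")
}

#' Sorensen (presence-absence) dissimilarity
#'
#' \eqn{D(A, B) = 1 - 2|A \cap B| / (|A| + |B|)} on per-sample contig presence
#' sets. Pairs involving a sample with no present contigs are undefined and
#' reported as `NA`.
#'
#' @param presence Logical contig-by-sample presence matrix (see
#'   [presence_matrix()]).
#' @return Symmetric dissimilarity matrix in \[0, 1\] with attribute
#'   `metric = "sorensen"`.
#' @export
sorensen <- function(presence) {
  p <- presence * 1
  shared <- crossprod(p)          # |A intersect B|
  sizes <- colSums(p)
  den <- outer(sizes, sizes, `+`)
  d <- 1 - 2 * shared / den
  d[sizes == 0, ] <- NA_real_
  d[, sizes == 0] <- NA_real_
  new_dist_matrix(d, "sorensen")
}

#' Hellinger distance
#'
#' \eqn{D(x, y) = \sqrt{\sum_i (\sqrt{x_i/\sum x} - \sqrt{y_i/\sum y})^2}} on
#' relative abundances; with `log_transform = TRUE` (the default used for RPK
#' tables) values are first transformed as \eqn{\log(1 + RPK)}, keeping
#' zero-RPK cells finite. Samples with all-zero abundance are undefined and
#' reported as `NA`.
#'
#' @param abundance Contig-by-sample RPK matrix.
#' @param log_transform Apply \eqn{\log(1 + x)} before forming relative
#'   abundances.
#' @return Symmetric distance matrix in \[0, sqrt(2)\] with attribute
#'   `metric = "hellinger"`.
#' @export
hellinger <- function(abundance, log_transform = TRUE) {
  a <- if (log_transform) log1p(abundance) else abundance
  totals <- colSums(a)
  ok <- totals > 0
  p <- a
  p[, ok] <- sweep(a[, ok, drop = FALSE], 2, totals[ok], `/`)
  d <- as.matrix(stats::dist(t(sqrt(p)), method = "euclidean"))
  d[!ok, ] <- NA_real_
  d[, !ok] <- NA_real_
  new_dist_matrix(d, "hellinger",
                  transformation = if (log_transform) "log1p" else "none")
}

#' Write a distance matrix to TSV
#' @param d Square distance matrix with sample dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d),
                   formatC(unclass(d), digits = 10, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix from TSV
#' @param path Path to a square TSV written by [write_dist_matrix()].
#' @return Symmetric numeric matrix with sample dimnames.
#' @export
read_dist_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
    stop("distance matrix error: not symmetric")
  m
}
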