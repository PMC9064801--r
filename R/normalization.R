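#' RPK-normalize a viral count table
#'
#' Converts mapped-read counts to reads-per-kilobase (RPK): each count is
#' scaled by `scale_reads / total_qc_reads` of its sample, then divided by the
#' contig length in kilobases. After normalization, values below `noise_floor`
#' are set to zero to suppress mapping noise; flooring is applied per cell
#' after the full normalization, not to the raw counts.
#'
#' @param counts Contig-by-sample integer count matrix.
#' @param catalog Contig catalog data.frame providing `length_bp` per contig.
#' @param samples Sample metadata data.frame providing `total_qc_reads` per
#'   `sample_id` (e.g. `meta$samples`).
#' @param scale_reads Depth-scaling constant (default 79000 reads).
#' @param noise_floor RPK threshold below which values are zeroed
#'   (default 0.5).
#' @return Numeric contig-by-sample matrix of RPK values with attributes
#'   `scale_reads` and `noise_floor`.
#' @export
rpk_normalize <- function(counts, catalog, samples, scale_reads = 79000,
                          noise_floor = 0.5) {
  stopifnot(scale_reads > 0, noise_floor >= 0)
  validate_count_table(counts)
  missing_contig <- setdiff(rownames(counts), catalog$contig_id)
  if (length(missing_contig) > 0)
    stop("rpk_normalize: contig(s) absent from catalog: ",
         paste(head(missing_contig), collapse = ", "))
  totals <- samples$total_qc_reads[match(colnames(counts),
                                         samples$sample_id)]
  if (any(is.na(totals)))
    stop("rpk_normalize: sample(s) absent from metadata: ",
         paste(colnames(counts)[is.na(totals)], collapse = ", "))
  if (any(totals == 0))
    stop("rpk_normalize: total_qc_reads is zero for sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  len_kb <- catalog$length_bp[match(rownames(counts),
                                    catalog$contig_id)] / 1000
  if (any(len_kb <= 0))
    stop("rpk_normalize: non-positive contig length in catalog")
  rpk <- sweep(counts, 2, scale_reads / totals, `*`)
  rpk <- sweep(rpk, 1, len_kb, `/`)
  rpk[rpk < noise_floor] <- 0
  structure(rpk, scale_reads = scale_reads, noise_floor = noise_floor)
}

#' Presence-absence matrix from an abundance table
#'
#' A contig is present in a sample iff its RPK is strictly positive, i.e. it
#' survived the noise floor.
#'
#' @param abundance RPK abundance matrix from [rpk_normalize()].
#' @return Logical matrix of the same dimensions.
#' @export
presence_matrix <- function(abundance) {
  abundance > 0
}

#' Per-sample richness and Shannon diversity
#'
#' Richness is the number of contigs with nonzero RPK; Shannon diversity is
#' \eqn{H = -\sum p_i \log p_i} over the sample's relative RPK, in natural
#' log units by default. Samples with all-zero abundance carry no community
#' information and are excluded (and listed in the `excluded` attribute).
#'
#' @param abundance RPK abundance matrix.
#' @param base Logarithm base for Shannon diversity (default `exp(1)`,
#'   i.e. nats).
#' @return data.frame with columns `sample_id`, `richness`, `shannon`;
#'   attribute `excluded` lists any all-zero samples.
#' @export
richness_and_shannon <- function(abundance, base = exp(1)) {
  totals <- colSums(abundance)
  keep <- totals > 0
  p <- sweep(abundance[, keep, drop = FALSE], 2, totals[keep], `/`)
  sh <- apply(p, 2, function(q) {
    q <- q[q > 0]
    -sum(q * log(q, base = base))
  })
  out <- data.frame(sample_id = colnames(abundance)[keep],
                    richness = colSums(abundance[, keep, drop = FALSE] > 0),
                    shannon = as.numeric(sh),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- colnames(abundance)[!keep]
  out
}
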