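#' @importFrom stats median quantile rbinom rgamma rlnorm rmultinom rnorm runif
#'   sd setNames complete.cases aggregate
#' @importFrom utils read.delim write.table head
NULL

# Minimum contig length admitted to the catalog (bp). Shorter assemblies are
# too unreliable for mapping-based quantification.
MIN_CONTIG_LENGTH <- 800

#' Construct and validate cohort metadata
#'
#' Bundles the infant table (one row per infant: group assignment, case-control
#' matching, gestational age, birth weight and, for cases, the day of life of
#' NEC onset) with the sample table (one row per stool sample: day of life,
#' postmenstrual age and total quality-controlled reads).
#'
#' @param infants data.frame with columns `infant_id`, `group` ("case" or
#'   "control"), `matched_case_id` (NA for cases), `gestational_age_weeks`,
#'   `birth_weight_g`, `event_dol` (NA for controls).
#' @param samples data.frame with columns `sample_id`, `infant_id`,
#'   `day_of_life`, `pma_weeks`, `total_qc_reads`.
#' @return An object of class `cohort_metadata`: a list with elements
#'   `infants` and `samples`.
#' @export
cohort_metadata <- function(infants, samples) {
  meta <- structure(list(infants = as.data.frame(infants),
                         samples = as.data.frame(samples)),
                    class = "cohort_metadata")
  validate_cohort_metadata(meta)
  meta
}

#' Validate cohort metadata invariants
#'
#' Checks referential integrity (every control resolves a matched case that is
#' itself a case), presence of event days for cases, uniqueness of identifiers,
#' positivity of gestational age and day of life, and consistency of
#' postmenstrual age with gestational age plus postnatal age (tolerance 0.2
#' weeks) where both are provided.
#'
#' @param meta A `cohort_metadata` object.
#' @return `meta`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cohort_metadata <- function(meta) {
  inf <- meta$infants
  smp <- meta$samples
  req_inf <- c("infant_id", "group", "matched_case_id",
               "gestational_age_weeks", "birth_weight_g", "event_dol")
  req_smp <- c("sample_id", "infant_id", "day_of_life", "pma_weeks",
               "total_qc_reads")
  miss <- setdiff(req_inf, names(inf))
  if (length(miss) > 0)
    stop("metadata schema error: missing infant column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(req_smp, names(smp))
  if (length(miss) > 0)
    stop("metadata schema error: missing sample column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(inf$infant_id))
    stop("metadata error: duplicate infant_id")
  if (anyDuplicated(smp$sample_id))
    stop("metadata error: duplicate sample_id")
  if (!all(inf$group %in% c("case", "control")))
    stop("metadata error: group must be 'case' or 'control'")
  if (any(!smp$infant_id %in% inf$infant_id))
    stop("metadata referential error: sample infant_id not in infant table: ",
         paste(unique(setdiff(smp$infant_id, inf$infant_id)), collapse = ", "))
  cases <- inf$infant_id[inf$group == "case"]
  ctrl <- inf[inf$group == "control", , drop = FALSE]
  bad <- is.na(ctrl$matched_case_id) | !(ctrl$matched_case_id %in% cases)
  if (any(bad))
    stop("metadata referential error: control(s) without resolvable ",
         "matched_case_id: ", paste(ctrl$infant_id[bad], collapse = ", "))
  case_rows <- inf[inf$group == "case", , drop = FALSE]
  if (any(is.na(case_rows$event_dol) | case_rows$event_dol <= 0))
    stop("metadata error: every case requires event_dol > 0; offending: ",
         paste(case_rows$infant_id[is.na(case_rows$event_dol) |
                                     case_rows$event_dol <= 0],
               collapse = ", "))
  if (any(is.na(inf$gestational_age_weeks) | inf$gestational_age_weeks <= 0))
    stop("metadata error: gestational_age_weeks must be > 0")
  if (any(is.na(smp$day_of_life) | smp$day_of_life <= 0))
    stop("metadata error: day_of_life must be > 0")
  if (any(is.na(smp$total_qc_reads) | smp$total_qc_reads < 0))
    stop("metadata error: total_qc_reads must be >= 0")
  # PMA consistency where both PMA and gestational age are available
  ga <- inf$gestational_age_weeks[match(smp$infant_id, inf$infant_id)]
  have <- !is.na(smp$pma_weeks) & !is.na(ga)
  dev <- abs(smp$pma_weeks[have] - (ga[have] + smp$day_of_life[have] / 7))
  if (any(dev > 0.2))
    stop("metadata error: pma_weeks inconsistent with gestational age + ",
         "day_of_life/7 (tolerance 0.2 weeks) for sample(s): ",
         paste(smp$sample_id[have][dev > 0.2], collapse = ", "))
  invisible(meta)
}

#' @export
print.cohort_metadata <- function(x, ...) {
  cat("cohort_metadata:", sum(x$infants$group == "case"), "cases,",
      sum(x$infants$group == "control"), "controls,",
      nrow(x$samples), "samples\n")
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

#' Write cohort metadata to a TSV file
#'
#' One row per sample with the infant-level columns embedded; missing values
#' (e.g. `event_dol` for controls) are written as the literal `NA`.
#'
#' @param meta A `cohort_metadata` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  inf <- meta$infants
  smp <- meta$samples
  i <- match(smp$infant_id, inf$infant_id)
  out <- data.frame(
    sample_id = smp$sample_id,
    infant_id = smp$infant_id,
    group = inf$group[i],
    matched_case_id = ifelse(is.na(inf$matched_case_id[i]), "NA",
                             inf$matched_case_id[i]),
    gestational_age_weeks = fmt_num(inf$gestational_age_weeks[i]),
    birth_weight_g = fmt_num(inf$birth_weight_g[i]),
    event_dol = fmt_num(inf$event_dol[i]),
    day_of_life = fmt_num(smp$day_of_life),
    pma_weeks = fmt_num(smp$pma_weeks),
    total_qc_reads = smp$total_qc_reads,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cohort metadata from a TSV file
#'
#' Inverse of [write_metadata()]: expects one row per sample with embedded
#' infant columns, reconstructs the infant table from the unique infant rows,
#' and validates the result.
#'
#' @param path Path to a tab-separated metadata file with a header.
#' @return A validated `cohort_metadata` object.
#' @export
read_metadata <- function(path) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
  req <- c("sample_id", "infant_id", "group", "matched_case_id",
           "gestational_age_weeks", "birth_weight_g", "event_dol",
           "day_of_life", "pma_weeks", "total_qc_reads")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("metadata schema error: missing column(s): ",
         paste(miss, collapse = ", "))
  first <- !duplicated(raw$infant_id)
  infants <- data.frame(
    infant_id = raw$infant_id[first],
    group = raw$group[first],
    matched_case_id = as.character(raw$matched_case_id[first]),
    gestational_age_weeks = as.numeric(raw$gestational_age_weeks[first]),
    birth_weight_g = as.numeric(raw$birth_weight_g[first]),
    event_dol = as.numeric(raw$event_dol[first]),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = raw$sample_id,
    infant_id = raw$infant_id,
    day_of_life = as.numeric(raw$day_of_life),
    pma_weeks = as.numeric(raw$pma_weeks),
    total_qc_reads = as.integer(raw$total_qc_reads),
    stringsAsFactors = FALSE)
  cohort_metadata(infants, samples)
}

#' Validate a contig catalog
#'
#' @param catalog data.frame with columns `contig_id`, `length_bp`, `family`,
#'   `circular`.
#' @param min_length Minimum admissible contig length in bp (default 800, the
#'   pipeline's assembly admission rule).
#' @return `catalog`, invisibly.
#' @export
validate_contig_catalog <- function(catalog, min_length = MIN_CONTIG_LENGTH) {
  req <- c("contig_id", "length_bp", "family", "circular")
  miss <- setdiff(req, names(catalog))
  if (length(miss) > 0)
    stop("catalog schema error: missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(catalog$contig_id))
    stop("catalog error: duplicate contig_id")
  if (any(is.na(catalog$length_bp) | catalog$length_bp < min_length))
    stop("catalog error: contig length below the ", min_length,
         " bp admission rule: ",
         paste(head(catalog$contig_id[catalog$length_bp < min_length]),
               collapse = ", "))
  invisible(catalog)
}

#' Write a contig catalog to TSV
#' @param catalog A contig catalog data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contig_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contig catalog from TSV
#' @param path Path to a tab-separated catalog (contig_id, length_bp, family,
#'   circular).
#' @return A validated catalog data.frame.
#' @export
read_contig_catalog <- function(path) {
  cat_df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  cat_df$circular <- as.logical(cat_df$circular)
  cat_df$length_bp <- as.integer(cat_df$length_bp)
  validate_contig_catalog(cat_df)
  cat_df
}

#' Validate a count table
#'
#' @param counts Numeric matrix, features in rows, samples in columns, with
#'   dimnames set.
#' @param feature_ids Optional character vector of admissible feature ids
#'   (e.g. from a contig catalog or genus list); unknown row ids are rejected.
#' @return `counts`, invisibly.
#' @export
validate_count_table <- function(counts, feature_ids = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table error: row and column names required")
  if (anyDuplicated(rownames(counts)))
    stop("count table error: duplicate feature ids")
  if (anyDuplicated(colnames(counts)))
    stop("count table error: duplicate sample ids")
  if (any(is.na(counts)))
    stop("count table parse error: missing value")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("count table parse error: negative value at row '",
         rownames(counts)[idx[1]], "', column '", colnames(counts)[idx[2]],
         "'")
  }
  if (any(counts != round(counts))) {
    idx <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop("count table parse error: non-integer value at row '",
         rownames(counts)[idx[1]], "', column '", colnames(counts)[idx[2]],
         "'")
  }
  if (!is.null(feature_ids)) {
    unknown <- setdiff(rownames(counts), feature_ids)
    if (length(unknown) > 0)
      stop("count table error: unknown feature id(s): ",
           paste(head(unknown), collapse = ", "))
  }
  invisible(counts)
}

#' Read a feature-by-sample count table from TSV
#'
#' Rows are features (contigs or genera), columns are samples; the first
#' column holds the feature id.
#'
#' @inheritParams validate_count_table
#' @param path Path to the TSV file.
#' @return Integer matrix with feature rownames and sample colnames.
#' @export
read_count_table <- function(path, feature_ids = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  validate_count_table(m, feature_ids)
  storage.mode(m) <- "integer"
  m
}

#' Write a feature-by-sample count table to TSV
#' @param counts Count matrix with dimnames.
#' @param path Output file path.
#' @param id_column Name for the feature-id column (first column).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, id_column = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted genus tree from a newick file
#'
#' Wraps [ape::read.tree()] and enforces the invariants the UniFrac
#' computations need: unique leaf labels, branch lengths on every edge, and a
#' rooted topology.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
read_genus_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree))
    stop("tree format error: could not parse newick file ", path)
  validate_genus_tree(tree)
  tree
}

#' Validate a genus tree
#' @param tree An [ape::phylo] object.
#' @param genera Optional character vector of genus ids that must all be
#'   leaves of the tree.
#' @return `tree`, invisibly.
#' @export
validate_genus_tree <- function(tree, genera = NULL) {
  if (is.null(tree$edge.length) || any(is.na(tree$edge.length)))
    stop("tree format error: branch lengths missing")
  if (any(tree$edge.length < 0))
    stop("tree format error: negative branch length")
  if (is.null(tree$tip.label) || any(tree$tip.label == "") ||
      anyDuplicated(tree$tip.label))
    stop("tree format error: leaf labels must be present and unique")
  if (!ape::is.rooted(tree))
    stop("tree format error: tree must be rooted")
  if (!is.null(genera)) {
    missing <- setdiff(genera, tree$tip.label)
    if (length(missing) > 0)
      stop("tree error: genus absent from tree: ",
           paste(missing, collapse = ", "))
  }
  invisible(tree)
}

#' Write a genus tree to a newick file
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genus_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
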