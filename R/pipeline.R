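#' Assemble and validate a pipeline configuration
#'
#' A configuration either names the input files (`inputs`: metadata, viral
#' counts, catalog, bacterial counts, tree) or carries a `simulation` block
#' of [synthetic_params()] arguments — exactly one of the two. All stage
#' parameters have the pipeline's defaults and can be overridden.
#'
#' @param config A named list, or a path to a YAML file holding one.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- list(
    inputs = NULL, simulation = NULL, seed = 1L,
    scale_reads = 79000, noise_floor = 0.5,
    window_width = 7, window_step = 2, max_lookback = 25,
    pair_tolerance = 3.5,
    lefse = list(), rarefaction_depth = 2500,
    trajectory_block_width = 5, trajectory_max_days = 25,
    association_prevalence = 0.10)
  cfg <- utils::modifyList(defaults, config)
  has_inputs <- !is.null(cfg$inputs)
  has_sim <- !is.null(cfg$simulation)
  if (has_inputs == has_sim)
    stop("pipeline config error: exactly one of 'inputs' and 'simulation' ",
         "must be present")
  if (has_inputs) {
    req <- c("metadata", "viral_counts", "catalog", "bacterial_counts",
             "tree")
    miss <- setdiff(req, names(cfg$inputs))
    if (length(miss) > 0)
      stop("pipeline config error: missing input path(s): ",
           paste(miss, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

hash_file <- function(path) unname(tools::md5sum(path))

#' Run the full event-anchored virome analysis pipeline
#'
#' Orchestrates all stages: cohort acquisition (simulation or file input),
#' RPK normalization, alpha/beta diversity with within/between testing,
#' anchoring + matched pairing + sliding-window Sorensen convergence, the
#' case- and control-side discriminant screens, prevalence/abundance
#' trajectories with slopes, bacterial rarefaction + weighted UniFrac
#' convergence, and mixed-model virus-bacteria associations. Every stage
#' output is written as plain TSV under `outdir`, together with a manifest
#' recording stage, file and MD5 hash; identical configuration and seed give
#' identical manifests.
#'
#' @param config A [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param outdir Output directory.
#' @return Invisibly, a list with all in-memory stage results plus the
#'   `manifest` data.frame.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "pipeline_config")) config
    else pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path)
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = basename(path), md5 = hash_file(path),
      stringsAsFactors = FALSE)

  ## stage 1: cohort
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cohort <- generate_cohort(do.call(synthetic_params, sim_args))
    paths <- write_cohort(cohort, outdir)
    for (pp in paths) note("simulate", pp)
    meta <- cohort$meta; viral <- cohort$viral_counts
    catalog <- cohort$catalog; bact <- cohort$bacterial_counts
    tree <- cohort$tree
  } else {
    meta <- read_metadata(cfg$inputs$metadata)
    catalog <- read_contig_catalog(cfg$inputs$catalog)
    viral <- read_count_table(cfg$inputs$viral_counts,
                              feature_ids = catalog$contig_id)
    bact <- read_count_table(cfg$inputs$bacterial_counts)
    tree <- read_genus_tree(cfg$inputs$tree)
    cohort <- NULL
  }

  ## stage 2: normalization
  rpk <- rpk_normalize(viral, catalog, meta$samples,
                       scale_reads = cfg$scale_reads,
                       noise_floor = cfg$noise_floor)
  alpha <- richness_and_shannon(rpk)
  f <- file.path(outdir, "alpha_diversity.tsv")
  write.table(alpha, f, sep = "\t", quote = FALSE, row.names = FALSE)
  note("normalize", f)

  ## stage 3: diversity
  bc <- bray_curtis(rpk)
  sor <- sorensen(presence_matrix(rpk))
  wb <- within_between(bc, meta$samples)
  f <- file.path(outdir, "bray_curtis.tsv"); write_dist_matrix(bc, f)
  note("diversity", f)
  f <- file.path(outdir, "sorensen.tsv"); write_dist_matrix(sor, f)
  note("diversity", f)
  f <- file.path(outdir, "within_between.tsv")
  write.table(data.frame(median_within = wb$median_within,
                         median_between = wb$median_between,
                         p_value = wb$test$p_value), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("diversity", f)

  ## stage 4: convergence
  anchored <- anchor_samples(meta)
  pairs <- pair_samples(anchored, meta, tolerance = cfg$pair_tolerance)
  windows <- build_windows(cfg$window_width, cfg$window_step,
                           cfg$max_lookback)
  conv <- convergence_series(sor, windows, anchored, pairs)
  f <- file.path(outdir, "convergence_sorensen.tsv")
  write_window_series(conv, f); note("convergence", f)

  ## stage 5: discriminant screen
  lcfg <- do.call(lefse_config, utils::modifyList(list(seed = cfg$seed),
                                                  cfg$lefse))
  feats_case <- lefse_screen(rpk, anchored, lcfg)
  feats_ctrl <- control_side_screen(rpk, anchored, lcfg)
  f <- file.path(outdir, "discriminant_case.tsv")
  write.table(feats_case, f, sep = "\t", quote = FALSE, row.names = FALSE)
  note("discriminant", f)
  f <- file.path(outdir, "discriminant_control.tsv")
  write.table(feats_ctrl, f, sep = "\t", quote = FALSE, row.names = FALSE)
  note("discriminant", f)

  ## stage 6: trajectories of late-class (event-associated) contigs
  late_ids <- feats_case$contig_id[feats_case$class == "late"]
  blocks <- slopes <- NULL
  if (length(late_ids) >= 2) {
    blocks <- block_series(rpk, anchored, late_ids,
                           block_width = cfg$trajectory_block_width,
                           max_days = cfg$trajectory_max_days)
    slopes <- trajectory_slopes(blocks)
    f <- file.path(outdir, "trajectory_blocks.tsv")
    write.table(blocks, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("trajectory", f)
    f <- file.path(outdir, "trajectory_slopes.tsv")
    write.table(slopes, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("trajectory", f)
  }

  ## stage 7: bacterial side
  rar <- rarefy_counts(bact, depth = cfg$rarefaction_depth,
                       seed = cfg$seed)
  wuf <- weighted_unifrac(rar$counts, tree, normalized = TRUE)
  bconv <- bacterial_convergence(wuf, windows, anchored, pairs)
  f <- file.path(outdir, "weighted_unifrac.tsv")
  write_dist_matrix(wuf, f); note("bacterial", f)
  f <- file.path(outdir, "convergence_unifrac.tsv")
  write_window_series(bconv, f); note("bacterial", f)

  ## stage 8: virus-bacteria interactions
  assoc_case <- assoc_ctrl <- NULL
  disc_ids <- unique(feats_case$contig_id)
  if (length(disc_ids) >= 2) {
    assoc_case <- associate(rpk[disc_ids, , drop = FALSE], bact, meta,
                            group = "case",
                            prevalence_threshold = cfg$association_prevalence,
                            sample_totals = colSums(rpk))
    assoc_ctrl <- associate(rpk[disc_ids, , drop = FALSE], bact, meta,
                            group = "control",
                            prevalence_threshold = cfg$association_prevalence,
                            sample_totals = colSums(rpk))
    f <- file.path(outdir, "associations_case.tsv")
    write.table(assoc_case, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("interactions", f)
    f <- file.path(outdir, "associations_control.tsv")
    write.table(assoc_ctrl, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("interactions", f)
    cm <- correlation_table(assoc_case)
    f <- file.path(outdir, "correlation_matrix_case.tsv")
    write.table(data.frame(contig_id = rownames(cm), cm,
                           check.names = FALSE),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("interactions", f)
  }

  manifest <- do.call(rbind, manifest)
  f <- file.path(outdir, "manifest.tsv")
  write.table(manifest, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cohort = cohort, meta = meta, rpk = rpk, alpha = alpha,
                 bray_curtis = bc, sorensen = sor, within_between = wb,
                 anchored = anchored, pairs = pairs, windows = windows,
                 convergence = conv, discriminant_case = feats_case,
                 discriminant_control = feats_ctrl, blocks = blocks,
                 slopes = slopes, rarefied = rar, weighted_unifrac = wuf,
                 bacterial_convergence = bconv,
                 associations_case = assoc_case,
                 associations_control = assoc_ctrl,
                 manifest = manifest))
}
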