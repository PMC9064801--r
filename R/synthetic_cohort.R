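DEFAULT_GENERA <- c(
  "Escherichia", "Klebsiella", "Enterobacter", "Streptococcus",
  "Staphylococcus", "Enterococcus", "Veillonella", "Clostridium",
  "Bacteroides", "Bifidobacterium", "Lactobacillus", "Haemophilus",
  "Proteus", "Acinetobacter", "Corynebacterium", "Propionibacterium",
  "Dialister", "Serratia", "Citrobacter", "Pseudomonas", "Prevotella",
  "Fusobacterium", "Gemella", "Rothia", "Actinomyces", "Neisseria",
  "Moraxella", "Stenotrophomonas", "Raoultella", "Morganella")

# Virus family labels and their catalog shares; the unclassified-dominated
# profile mirrors what family-level taxonomy assignment achieves for
# preterm-infant stool viromes.
FAMILY_PROBS <- c(unclassified = 0.850, Myoviridae = 0.050,
                  Siphoviridae = 0.040, Podoviridae = 0.020,
                  Microviridae = 0.010, Anelloviridae = 0.008,
                  Circoviridae = 0.008, Gokushovirinae = 0.006,
                  Herelleviridae = 0.005, Tectiviridae = 0.003)

#' Parameters for the synthetic cohort generator
#'
#' Defaults emulate the matched preterm NEC case-control cohort the pipeline
#' targets: 9 cases and 14 gestational-age-matched controls, a median of 4
#' (cases) or 7 (controls) stool samples per infant, sequencing depth
#' log-normal around a median of 412,905 quality-filtered reads, strong
#' inter-individual community variation (symmetric Dirichlet with
#' concentration 0.05 per contig), temporal persistence of contig carriage,
#' and three disjoint planted contig sets: a signature set whose occurrence
#' ramps from 5% to 60% (and whose abundance is lifted 8x) inside the 10 days
#' before NEC onset in cases, an early set that decays toward the event in
#' cases, and a control-late set that ramps toward the matched event time in
#' controls. Signature contigs can be coupled to bacterial genera in cases
#' only, with signed effects.
#'
#' @param n_cases,n_controls Cohort sizes (defaults 9 and 14).
#' @param n_contigs Size of the viral contig pool (default 2000).
#' @param n_signature_contigs,n_early_contigs,n_control_late_contigs Planted
#'   set sizes (defaults 137, 11, 100); the sets are disjoint.
#' @param signature_window_days Width of the pre-event window carrying the
#'   planted signature (default 10 days).
#' @param signature_prevalence_lift Occurrence-probability increase at the
#'   event itself; occurrence ramps linearly from `baseline_occurrence` at
#'   the window edge to `baseline_occurrence + lift` at day 0 (default 0.55,
#'   i.e. 5% to 60%).
#' @param signature_abundance_lift Multiplicative abundance enrichment for
#'   planted contigs in their active phase (default 8).
#' @param baseline_occurrence Occurrence probability of planted contigs
#'   outside their active phase (default 0.05).
#' @param special_weight Relative community weight of a planted contig when
#'   present, before any lift (default 2e-4, keeping the aggregate in-window
#'   signature share near 10%).
#' @param control_late_susceptibility Probability that a given control
#'   infant is susceptible to a given control-late contig (default 0.5):
#'   control-side turnover involves partially overlapping contig sets, so it
#'   does not synchronize control infants into a beta-diversity convergence,
#'   matching the stable between-control series the analysis expects.
#' @param community_concentration Per-contig symmetric Dirichlet
#'   concentration for infant baseline communities (default 0.05; smaller
#'   means stronger individuality).
#' @param temporal_persistence Probability a baseline contig present at one
#'   sample is still present at the infant's next sample (default 0.8).
#' @param baseline_occupancy Stationary presence probability of a baseline
#'   contig within its infant's community (default 0.75).
#' @param reads_meanlog,reads_sdlog Log-normal sequencing-depth parameters
#'   (defaults reproduce median 412,905, IQR 288,727-521,394).
#' @param event_pma_center,event_pma_sd Normal parameters for NEC-onset
#'   postmenstrual age in weeks (default center 31.4, sd 1.7; median ~31.1).
#' @param n_genera Number of bacterial genera (default 30).
#' @param coupled_genus_map data.frame (`contig_index`, `genus`, `sign`)
#'   linking signature contigs (by index into the signature set) to genera in
#'   cases; `NULL` installs a default 8-pair map with mixed signs.
#' @param coupling_strength Log-scale shift of a coupled genus when its
#'   contig is present in a case sample (default 2, i.e. an e^2-fold
#'   enrichment or depletion while the phage is detectable).
#' @param bacterial_reads_meanlog,bacterial_reads_sdlog 16S depth
#'   distribution (defaults give ~1% of samples under the 2500-read
#'   rarefaction depth).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A `synthetic_params` list.
#' @export
synthetic_params <- function(n_cases = 9, n_controls = 14, n_contigs = 2000,
                             n_signature_contigs = 137, n_early_contigs = 11,
                             n_control_late_contigs = 100,
                             signature_window_days = 10,
                             signature_prevalence_lift = 0.55,
                             signature_abundance_lift = 8,
                             baseline_occurrence = 0.05,
                             special_weight = 2e-4,
                             control_late_susceptibility = 0.5,
                             community_concentration = 0.05,
                             temporal_persistence = 0.8,
                             baseline_occupancy = 0.75,
                             reads_meanlog = log(412905),
                             reads_sdlog = 0.438,
                             event_pma_center = 31.4, event_pma_sd = 1.7,
                             n_genera = 30, coupled_genus_map = NULL,
                             coupling_strength = 2,
                             bacterial_reads_meanlog = log(8000),
                             bacterial_reads_sdlog = 0.5,
                             seed = 1L) {
  n_planted <- n_signature_contigs + n_early_contigs + n_control_late_contigs
  if (n_planted > n_contigs)
    stop("synthetic_params: planted contig sets exceed the contig pool")
  if (n_controls < n_cases || n_controls > 2 * n_cases)
    stop("synthetic_params: need 1-2 controls per case")
  stopifnot(signature_prevalence_lift >= 0,
            signature_prevalence_lift + baseline_occurrence <= 1,
            signature_abundance_lift >= 1,
            temporal_persistence >= 0, temporal_persistence <= 1,
            baseline_occupancy > 0, baseline_occupancy < 1,
            community_concentration > 0, signature_window_days > 0)
  structure(as.list(environment()), class = "synthetic_params")
}

# Activity ramp (in [0, 1]) of a planted contig given role, group and
# timing. Occurrence probability is baseline + prevalence_lift * ramp, and
# the present-contig weight is scaled by 1 + (abundance_lift - 1) * ramp, so
# occurrence and abundance rise together through a contig's active phase.
# Signature contigs ramp toward the event inside the pre-onset window (cases
# only); early contigs ramp away from the event (so they decay toward it);
# control-late contigs ramp with absolute age (day of life) in controls,
# which ties them to late sampling times without synchronizing control
# infants at a common days-before value.
planted_ramp <- function(role, group, d, dol, p) {
  w <- p$signature_window_days
  # concave ramp: the convergence is already well developed at the window's
  # far edge (the analysis expects significance out to windows spanning
  # ~11-4 d), while occurrence still spans baseline -> baseline + lift
  if (role == "signature" && group == "case" && d >= 0 && d < w)
    return(sqrt(1 - d / w))
  if (role == "early" && group == "case" && d >= 0)
    return(min(1, d / 25))
  if (role == "control_late" && group == "control" && d >= 0)
    return(min(1, max(0, (dol - 25) / 25)))
  0
}

#' Generate a synthetic matched case-control cohort
#'
#' Draws infants, longitudinal samples, a viral contig count table with its
#' catalog, a bacterial genus count table with a rooted genus tree, and truth
#' labels for every planted effect. Case infants are always sampled both
#' within 3 days of NEC onset and at least 25 days before it (stools are
#' collected at diagnosis and throughout the stay), and control sampling days
#' mirror the matched case's collection days with jitter, so matched pairing
#' and every sliding window are populated. Setting
#' `signature_prevalence_lift = 0` together with
#' `signature_abundance_lift = 1` switches off all planted structure
#' (including genus couplings) and yields a null cohort with empty truth
#' labels.
#'
#' @param params A [synthetic_params()] object.
#' @return A list of class `synthetic_cohort`: `meta` (cohort_metadata),
#'   `viral_counts`, `catalog`, `bacterial_counts`, `tree`, `truth`.
#' @export
generate_cohort <- function(params = synthetic_params()) {
  p <- params
  set.seed(p$seed)
  null_effect <- p$signature_prevalence_lift <= 0 &&
    p$signature_abundance_lift == 1

  ## ---- infants -----------------------------------------------------------
  case_ids <- sprintf("case_%02d", seq_len(p$n_cases))
  ctrl_ids <- sprintf("ctrl_%02d", seq_len(p$n_controls))
  n_extra <- p$n_controls - p$n_cases
  ctrl_case <- c(case_ids, case_ids[seq_len(n_extra)])[seq_len(p$n_controls)]
  ga_case <- pmin(27, pmax(23, rnorm(p$n_cases, 25, 0.9)))
  bw_case <- pmin(1200, pmax(450, rnorm(p$n_cases, 780, 150)))
  i_match <- match(ctrl_case, case_ids)
  ga_ctrl <- pmin(27, pmax(23, ga_case[i_match] + runif(p$n_controls, -1.5, 1.5)))
  bw_ctrl <- pmin(1200, pmax(450, bw_case[i_match] + runif(p$n_controls, -200, 200)))
  event_pma <- pmin(35, pmax(29.5, rnorm(p$n_cases, p$event_pma_center,
                                         p$event_pma_sd)))
  event_dol <- pmin(70, pmax(32, (event_pma - ga_case) * 7))
  infants <- data.frame(
    infant_id = c(case_ids, ctrl_ids),
    group = c(rep("case", p$n_cases), rep("control", p$n_controls)),
    matched_case_id = c(rep(NA_character_, p$n_cases), ctrl_case),
    gestational_age_weeks = c(ga_case, ga_ctrl),
    birth_weight_g = round(c(bw_case, bw_ctrl)),
    event_dol = c(round(event_dol, 1), rep(NA_real_, p$n_controls)),
    stringsAsFactors = FALSE)
  event_dol <- infants$event_dol[seq_len(p$n_cases)]

  ## ---- sampling days -----------------------------------------------------
  # cases: one sample at/near diagnosis, one >= 25 d earlier, rest uniform
  case_days <- vector("list", p$n_cases)
  for (i in seq_len(p$n_cases)) {
    n_s <- sample(3:8, 1, prob = c(0.08, 0.42, 0.20, 0.15, 0.10, 0.05))
    hi <- min(46, event_dol[i] - 2)
    # stool collection concentrates around diagnosis: two samples in the
    # final 10 d, one mid-range, one >= 25 d out, any extras anywhere
    d <- c(runif(1, 0, 3), runif(1, 28, min(42, hi + 16)),
           if (n_s > 2) runif(1, 10, 25),
           if (n_s > 3) runif(1, 3, 9.5),
           if (n_s > 4) runif(n_s - 4, 0, hi))
    d[2] <- min(d[2], event_dol[i] - 1.5)
    case_days[[i]] <- round(sort(unique(round(d, 1)), decreasing = TRUE), 1)
  }
  ctrl_days <- vector("list", p$n_controls)
  for (j in seq_len(p$n_controls)) {
    n_s <- sample(5:9, 1, prob = c(0.10, 0.25, 0.30, 0.25, 0.10))
    ev <- event_dol[i_match[j]]
    base <- case_days[[i_match[j]]]
    d <- base + runif(length(base), -2, 2)
    if (n_s > length(d)) d <- c(d, runif(n_s - length(d), 0, min(46, ev - 2)))
    d <- pmin(pmax(d[seq_len(min(n_s, length(d)))], 0.2), ev - 1.2)
    ctrl_days[[j]] <- round(sort(unique(round(d, 1)), decreasing = TRUE), 1)
  }
  smp <- list()
  anchor_event <- c(event_dol, event_dol[i_match])
  all_days <- c(case_days, ctrl_days)
  for (k in seq_along(infants$infant_id)) {
    d <- all_days[[k]]
    dol <- round(anchor_event[k] - d, 1)
    smp[[k]] <- data.frame(
      infant_id = infants$infant_id[k],
      group = infants$group[k],
      day_of_life = dol,
      days_before_event = round(anchor_event[k] - dol, 1),
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, smp)
  samples$sample_id <- sprintf("S%03d", seq_len(nrow(samples)))
  samples$pma_weeks <- round(
    infants$gestational_age_weeks[match(samples$infant_id,
                                        infants$infant_id)] +
      samples$day_of_life / 7, 2)
  samples$total_qc_reads <- pmax(
    50000L, as.integer(round(rlnorm(nrow(samples), p$reads_meanlog,
                                    p$reads_sdlog))))

  ## ---- contig catalog and planted roles ----------------------------------
  contig_ids <- sprintf("contig_%04d", seq_len(p$n_contigs))
  lengths <- pmin(60000L, pmax(800L, as.integer(round(
    rlnorm(p$n_contigs, log(1500), 0.55)))))
  family <- sample(names(FAMILY_PROBS), p$n_contigs, replace = TRUE,
                   prob = FAMILY_PROBS)
  catalog <- data.frame(contig_id = contig_ids, length_bp = lengths,
                        family = family,
                        circular = runif(p$n_contigs) < 0.017,
                        stringsAsFactors = FALSE)
  role <- rep("baseline", p$n_contigs)
  if (!null_effect) {
    n_planted <- p$n_signature_contigs + p$n_early_contigs +
      p$n_control_late_contigs
    planted_idx <- sample(p$n_contigs, n_planted)
    role[planted_idx[seq_len(p$n_signature_contigs)]] <- "signature"
    role[planted_idx[p$n_signature_contigs + seq_len(p$n_early_contigs)]] <-
      "early"
    role[planted_idx[p$n_signature_contigs + p$n_early_contigs +
                       seq_len(p$n_control_late_contigs)]] <- "control_late"
  }
  baseline_idx <- which(role == "baseline")
  planted_tab <- which(role != "baseline")

  ## ---- genus map ---------------------------------------------------------
  genera <- if (p$n_genera <= length(DEFAULT_GENERA))
    DEFAULT_GENERA[seq_len(p$n_genera)] else
      c(DEFAULT_GENERA, sprintf("genus_%02d",
                                seq_len(p$n_genera - length(DEFAULT_GENERA))))
  if (is.null(p$coupled_genus_map)) {
    n_cpl <- min(8, p$n_signature_contigs, p$n_genera)
    cpl_genera <- intersect(c("Escherichia", "Streptococcus", "Clostridium",
                              "Haemophilus", "Lactobacillus", "Proteus",
                              "Bifidobacterium", "Corynebacterium"), genera)
    cpl_genera <- cpl_genera[seq_len(min(n_cpl, length(cpl_genera)))]
    cmap <- data.frame(contig_index = seq_along(cpl_genera),
                       genus = cpl_genera,
                       sign = rep(c(1, 1, 1, 1, 1, -1, -1, -1),
                                  length.out = length(cpl_genera)),
                       stringsAsFactors = FALSE)
  } else cmap <- p$coupled_genus_map
  sig_ids <- contig_ids[role == "signature"]
  couplings <- if (null_effect || length(sig_ids) == 0)
    data.frame(contig_id = character(0), genus = character(0),
               sign = numeric(0), stringsAsFactors = FALSE) else
    data.frame(contig_id = sig_ids[cmap$contig_index], genus = cmap$genus,
               sign = cmap$sign, stringsAsFactors = FALSE)

  ## ---- viral counts ------------------------------------------------------
  n_s_total <- nrow(samples)
  viral <- matrix(0L, p$n_contigs, n_s_total,
                  dimnames = list(contig_ids, samples$sample_id))
  coupled_present <- matrix(FALSE, nrow(couplings), n_s_total)
  genus_base <- rgamma(p$n_genera, 0.8) + 1e-6
  genus_base <- genus_base / sum(genus_base)
  bacterial <- matrix(0L, p$n_genera, n_s_total,
                      dimnames = list(genera, samples$sample_id))
  bact_reads <- pmax(1000L, as.integer(round(
    rlnorm(n_s_total, p$bacterial_reads_meanlog, p$bacterial_reads_sdlog))))
  entry_prob <- (1 - p$temporal_persistence) * p$baseline_occupancy /
    (1 - p$baseline_occupancy)
  entry_prob <- min(1, entry_prob)

  for (k in seq_along(infants$infant_id)) {
    grp <- infants$group[k]
    rows <- which(samples$infant_id == infants$infant_id[k])
    rows <- rows[order(samples$day_of_life[rows])]
    pi_inf <- rgamma(length(baseline_idx), p$community_concentration)
    pi_inf <- pi_inf / sum(pi_inf)
    theta <- if (grp == "case") 60 else 15
    g_inf <- rgamma(p$n_genera, genus_base * p$n_genera * theta / 30) + 1e-9
    g_inf <- g_inf / sum(g_inf)
    mask <- rbinom(length(baseline_idx), 1, p$baseline_occupancy)
    # per-infant susceptibility gates the planted ramp (baseline occurrence
    # is unaffected): control-late turnover overlaps only partially between
    # control infants
    sus <- rep(1, length(planted_tab))
    if (grp == "control")
      sus[role[planted_tab] == "control_late"] <-
        as.numeric(runif(sum(role[planted_tab] == "control_late")) <
                     p$control_late_susceptibility)
    for (s in rows) {
      d <- samples$days_before_event[s]
      dol <- samples$day_of_life[s]
      w <- numeric(p$n_contigs)
      w[baseline_idx] <- pi_inf * mask
      if (length(planted_tab) > 0) {
        ramp <- sus * vapply(planted_tab, function(ci)
          planted_ramp(role[ci], grp, d, dol, p), 1.0)
        occ <- runif(length(planted_tab)) <
          p$baseline_occurrence + p$signature_prevalence_lift * ramp
        w[planted_tab] <- occ * p$special_weight *
          (1 + (p$signature_abundance_lift - 1) * ramp)
      }
      if (sum(w) == 0) w[baseline_idx] <- pi_inf # degenerate mask fallback
      viral[, s] <- rmultinom(1, samples$total_qc_reads[s], w)
      if (nrow(couplings) > 0)
        coupled_present[, s] <-
          viral[match(couplings$contig_id, contig_ids), s] > 0
      # bacterial sample: infant profile with within-infant wobble
      g_s <- rgamma(p$n_genera, g_inf * 150) + 1e-9
      if (grp == "case" && nrow(couplings) > 0) {
        gi <- match(couplings$genus, genera)
        shift <- tapply(couplings$sign * p$coupling_strength *
                          coupled_present[, s], gi, sum)
        g_s[as.integer(names(shift))] <-
          g_s[as.integer(names(shift))] * exp(as.numeric(shift))
      }
      bacterial[, s] <- rmultinom(1, bact_reads[s], g_s / sum(g_s))
      # persistence-thinned occupancy carried to the next sample
      mask <- ifelse(mask == 1,
                     rbinom(length(mask), 1, p$temporal_persistence),
                     rbinom(length(mask), 1, entry_prob))
    }
  }

  tree <- ape::rtree(p$n_genera, tip.label = genera)

  meta <- cohort_metadata(
    infants,
    samples[, c("sample_id", "infant_id", "day_of_life", "pma_weeks",
                "total_qc_reads")])
  truth <- list(signature = contig_ids[role == "signature"],
                early = contig_ids[role == "early"],
                control_late = contig_ids[role == "control_late"],
                couplings = couplings,
                null = null_effect)
  structure(list(meta = meta, viral_counts = viral, catalog = catalog,
                 bacterial_counts = bacterial, tree = tree, truth = truth,
                 params = p),
            class = "synthetic_cohort")
}

#' Per-sample virus family relative-abundance profile
#'
#' Aggregates RPK abundance by the catalog's family labels (with
#' "unclassified" as a first-class category) and converts to per-sample
#' shares summing to one.
#'
#' @param catalog Contig catalog providing a `family` per contig.
#' @param abundance RPK abundance matrix.
#' @return Family-by-sample matrix of relative abundances.
#' @export
family_profile <- function(catalog, abundance) {
  fam <- catalog$family[match(rownames(abundance), catalog$contig_id)]
  if (any(is.na(fam)))
    stop("family_profile: contig(s) absent from catalog")
  totals <- colSums(abundance)
  if (any(totals == 0))
    stop("family_profile: undefined shares for all-zero sample(s): ",
         paste(colnames(abundance)[totals == 0], collapse = ", "))
  agg <- rowsum(abundance, fam)
  sweep(agg, 2, totals, `/`)
}

#' Write all synthetic cohort artifacts to a directory
#'
#' Serializes the metadata, viral counts, catalog, bacterial counts, genus
#' tree and truth labels in the package's plain-text formats.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    metadata = file.path(dir, "metadata.tsv"),
    viral_counts = file.path(dir, "viral_counts.tsv"),
    catalog = file.path(dir, "contig_catalog.tsv"),
    bacterial_counts = file.path(dir, "bacterial_counts.tsv"),
    tree = file.path(dir, "genus_tree.nwk"),
    truth = file.path(dir, "truth.tsv"))
  write_metadata(cohort$meta, paths["metadata"])
  write_count_table(cohort$viral_counts, paths["viral_counts"],
                    id_column = "contig_id")
  write_contig_catalog(cohort$catalog, paths["catalog"])
  write_count_table(cohort$bacterial_counts, paths["bacterial_counts"],
                    id_column = "genus")
  write_genus_tree(cohort$tree, paths["tree"])
  tr <- cohort$truth
  truth_df <- rbind(
    data.frame(feature = tr$signature, label = "signature", partner = "",
               sign = "", stringsAsFactors = FALSE),
    data.frame(feature = tr$early, label = "early", partner = "", sign = "",
               stringsAsFactors = FALSE),
    data.frame(feature = tr$control_late, label = "control_late",
               partner = "", sign = "", stringsAsFactors = FALSE),
    if (nrow(tr$couplings) > 0)
      data.frame(feature = tr$couplings$contig_id, label = "coupling",
                 partner = tr$couplings$genus,
                 sign = as.character(tr$couplings$sign),
                 stringsAsFactors = FALSE))
  write.table(truth_df, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
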