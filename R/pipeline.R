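PIPELINE_KEYS <- c("seed", "simulate", "input", "thresholds", "min_shared",
                   "ld", "phylo", "divergence", "keep_fail")

#' Verify a two-panel study end to end
#'
#' Convenience composition of [merge_panels()] (with het masking),
#' [ibs_similarity()] and [classify_accessions()] for a simulated or loaded
#' study: the dense panel's samples are the queries, the array-side samples
#' (suffixed on ID collision) plus any planted duplicates are the
#' references, and the expected-counterpart map is carried through the merge
#' renaming.
#'
#' @param study list with `seq_panel`, `array_panel` and `truth` (as from
#'   [simulate_study()]).
#' @param thresholds verdict thresholds, see [classify_accessions()].
#' @param min_shared minimum co-called sites per valid pair.
#' @return a [classify_accessions()] match report.
#' @export
verify_study <- function(study,
                         thresholds = list(confirm = 0.99, floor = 0.90,
                                           gap_max = 0.03),
                         min_shared = 100) {
  merged <- merge_panels(study$seq_panel, study$array_panel, mask_hets = TRUE)
  expected <- study$truth$expected
  renamed <- expected %in% names(merged$rename_map)
  expected[renamed] <- merged$rename_map[expected[renamed]]
  sim <- ibs_similarity(merged$panel, min_shared = min_shared)
  queries <- intersect(study$seq_panel$samples, merged$panel$samples)
  references <- setdiff(merged$panel$samples, queries)
  classify_accessions(sim, expected, queries = queries,
                      references = references, thresholds = thresholds)
}

#' Validate a pipeline configuration
#'
#' Accepts a list or a YAML file path. Top-level keys: `seed` (integer,
#' required when simulating), `simulate` (fields of [sim_config()]),
#' `input` (`vcf_a`, `vcf_b`, `metadata` to run on existing files instead of
#' simulating), `thresholds` (`confirm`, `floor`, `gap_max`), `min_shared`,
#' `ld` (`baseline`, `max_dist_bp`), `phylo` (`step`, `offset`,
#' `het_policy`), `divergence` (`ref`, `bin_size`), `keep_fail`. Unknown keys
#' are rejected by name.
#'
#' @param config list or YAML path.
#' @return the validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$input)) {
    if (is.null(config$seed)) stop("config needs `seed` when simulating")
    sim_args <- config$simulate
    if (is.null(sim_args)) sim_args <- list()
    unknown <- setdiff(names(sim_args),
                       setdiff(names(formals(sim_config)), "seed"))
    if (length(unknown)) {
      stop("unknown simulate key(s): ", paste(unknown, collapse = ", "))
    }
    config$simulate <- do.call(sim_config,
                               c(sim_args, list(seed = config$seed)))
  } else {
    for (f in c("vcf_a", "vcf_b")) {
      if (is.null(config$input[[f]])) stop("input needs `", f, "`")
      if (!file.exists(config$input[[f]])) {
        stop("input file not found: ", config$input[[f]])
      }
    }
  }
  config
}

#' Run the full verification pipeline
#'
#' Executes, in dependency order: simulate (or load) the two genotype panels;
#' hard-filter the dense panel; merge with allele harmonization and het
#' masking; identity-by-state verification against expected counterparts;
#' per-chromosome Hill-Weir LD decay; SNP-alignment neighbor-joining tree
#' (rooted between the two species groups when the metadata defines exactly
#' two); binned divergence profiles against a reference accession. All stage
#' outputs land under `outdir` together with a machine-readable run manifest
#' (JSON: config hash, file checksums, per-stage counts, package version,
#' seed). Reruns with identical config and seed produce identical stage
#' outputs. Stage progress is logged to stderr.
#'
#' @param config list or YAML path; see [validate_config()].
#' @param outdir output directory (created if absent).
#' @param quiet suppress stage logging.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message("[germpanel] ", sprintf(...))
  manifest <- list(tool = "germpanel",
                   version = as.character(utils::packageVersion("germpanel")),
                   seed = config$seed, stages = list())
  paths <- character()

  if (is.null(config$input)) {
    log_stage("simulate: seed %d", config$seed)
    study <- simulate_study(config$simulate)
    seq_panel <- study$seq_panel
    array_panel <- study$array_panel
    metadata <- study$metadata
    expected_raw <- study$truth$expected
    paths["seq_vcf"] <- file.path(outdir, "seq.vcf.gz")
    paths["array_vcf"] <- file.path(outdir, "array.vcf.gz")
    write_vcf(seq_panel, paths["seq_vcf"])
    write_vcf(array_panel, paths["array_vcf"])
    paths["metadata"] <- file.path(outdir, "metadata.tsv")
    utils::write.table(metadata, paths["metadata"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["truth"] <- file.path(outdir, "truth.json")
    jsonlite::write_json(list(mislabels = study$truth$mislabels,
                              duplicates = study$truth$duplicates,
                              populations = study$truth$samples,
                              rho_per_bp = as.list(study$truth$rho_per_bp)),
                         paths["truth"], auto_unbox = TRUE, digits = NA)
    manifest$stages$simulate <- list(
      n_samples = n_samples(seq_panel), n_sites = n_sites(seq_panel),
      n_array_sites = n_sites(array_panel),
      n_mislabels = nrow(study$truth$mislabels),
      n_duplicates = nrow(study$truth$duplicates))
  } else {
    log_stage("load: %s + %s", config$input$vcf_a, config$input$vcf_b)
    seq_panel <- read_vcf(config$input$vcf_a)
    array_panel <- read_vcf(config$input$vcf_b)
    metadata <- if (!is.null(config$input$metadata)) {
      utils::read.delim(config$input$metadata, stringsAsFactors = FALSE)
    } else NULL
    shared <- intersect(seq_panel$samples, array_panel$samples)
    expected_raw <- stats::setNames(shared, shared)
    if (!is.null(metadata) && "expected_id" %in% names(metadata)) {
      has <- !is.na(metadata$expected_id) & nzchar(metadata$expected_id)
      expected_raw <- stats::setNames(metadata$expected_id[has],
                                      metadata$sample_id[has])
    }
    manifest$stages$load <- list(
      n_samples_a = n_samples(seq_panel), n_sites_a = n_sites(seq_panel),
      n_samples_b = n_samples(array_panel), n_sites_b = n_sites(array_panel),
      n_skipped_a = attr(seq_panel, "n_skipped"),
      n_skipped_b = attr(array_panel, "n_skipped"))
  }

  log_stage("filter: %d sites in", n_sites(seq_panel))
  flags <- hard_filter(seq_panel$sites)
  keep_fail <- isTRUE(config$keep_fail)
  if (!keep_fail) seq_panel <- subset_sites(seq_panel, which(flags == "PASS"))
  manifest$stages$filter <- list(
    n_pass = sum(flags == "PASS"), n_fail = sum(flags == "FAIL"),
    n_missing_info = attr(flags, "n_missing_info"), kept_fail = keep_fail)

  log_stage("merge: %d x %d sites", n_sites(seq_panel), n_sites(array_panel))
  merged <- merge_panels(seq_panel, array_panel, mask_hets = TRUE)
  paths["merged_vcf"] <- file.path(outdir, "merged.vcf.gz")
  write_vcf(merged$panel, paths["merged_vcf"])
  paths["merge_report"] <- file.path(outdir, "merge_report.tsv")
  rep_df <- data.frame(n_common_sites = merged$n_common_sites,
                       n_allele_swapped = merged$n_allele_swapped,
                       n_dropped_strand_ambiguous = merged$n_dropped_strand_ambiguous,
                       n_dropped_incompatible = merged$n_dropped_incompatible,
                       missing_het_fraction = merged$missing_het_fraction)
  utils::write.table(rep_df, paths["merge_report"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$stages$merge <- as.list(rep_df)

  log_stage("verify: %d samples in merged panel", n_samples(merged$panel))
  expected <- expected_raw
  renamed <- expected %in% names(merged$rename_map)
  expected[renamed] <- merged$rename_map[expected[renamed]]
  thr <- config$thresholds
  if (is.null(thr)) thr <- list()
  thr <- utils::modifyList(list(confirm = 0.99, floor = 0.90, gap_max = 0.03),
                           thr)
  min_shared <- if (is.null(config$min_shared)) 100 else config$min_shared
  sim <- ibs_similarity(merged$panel, min_shared = min_shared)
  queries <- intersect(seq_panel$samples, merged$panel$samples)
  references <- setdiff(merged$panel$samples, queries)
  report <- classify_accessions(sim, expected, queries = queries,
                                references = references, thresholds = thr)
  paths["verify_report"] <- file.path(outdir, "verify_report.tsv")
  write_match_report(report, paths["verify_report"])
  manifest$stages$verify <- as.list(table(report$verdict))

  log_stage("ld: fitting decay per chromosome")
  ld_cfg <- utils::modifyList(list(baseline = 0.2, max_dist_bp = 1e6,
                                   group_floor = 10),
                              if (is.null(config$ld)) list() else config$ld)
  # population structure masks within-group decay, so fit per species group
  # (given enough samples) as well as over all accessions
  groups <- list(all = seq_panel$samples)
  if (!is.null(metadata)) {
    for (sp in unique(metadata$species)) {
      ids <- intersect(metadata$sample_id[metadata$species == sp],
                       seq_panel$samples)
      if (length(ids) >= ld_cfg$group_floor) groups[[sp]] <- ids
    }
  }
  ld_out <- NULL
  manifest$stages$ld <- list()
  for (grp in names(groups)) {
    sub <- subset_samples(seq_panel, groups[[grp]])
    ld_tab <- ld_chromosome_summary(sub, baseline = ld_cfg$baseline,
                                    max_dist_bp = ld_cfg$max_dist_bp)
    tab <- rbind(ld_tab,
                 data.frame(chromosome = c("average", "size_decay_r2"),
                            chromosome_size_mb = NA,
                            decay_distance_mb = c(attr(ld_tab, "mean_decay_mb"),
                                                  attr(ld_tab, "size_decay_r2"))))
    tab <- cbind(group = grp, tab)
    ld_out <- rbind(ld_out, tab)
    manifest$stages$ld[[grp]] <- list(
      n_samples = length(groups[[grp]]),
      mean_decay_mb = attr(ld_tab, "mean_decay_mb"),
      size_decay_r2 = attr(ld_tab, "size_decay_r2"))
  }
  paths["ld_summary"] <- file.path(outdir, "ld_summary.tsv")
  utils::write.table(ld_out, paths["ld_summary"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  log_stage("phylo: thinning and building tree")
  ph_cfg <- utils::modifyList(list(step = 5, offset = 0, het_policy = "iupac"),
                              if (is.null(config$phylo)) list() else config$phylo)
  # tree over the sequenced accessions on the merged (common-site) panel
  thinned <- thin_sites(subset_samples(merged$panel, queries),
                        step = ph_cfg$step, offset = ph_cfg$offset)
  aln <- panel_to_alignment(thinned, het_policy = ph_cfg$het_policy)
  if (!is.null(metadata)) {
    aln_lab <- label_with_origin(aln, metadata)
  } else aln_lab <- aln
  paths["alignment"] <- file.path(outdir, "alignment.fna")
  write_alignment_fasta(aln_lab, paths["alignment"])
  dmat <- p_distance_matrix(aln)
  tree <- nj_tree(dmat)
  if (!is.null(metadata) && length(unique(metadata$species)) == 2) {
    grp <- stats::setNames(metadata$species, metadata$sample_id)
    grp <- grp[tree$tip.label[tree$tip.label %in% names(grp)]]
    if (length(unique(grp)) == 2 && all(tree$tip.label %in% names(grp))) {
      tree <- root_between_groups(tree, grp)
      manifest$stages$phylo <- list(mixing_count = attr(tree, "mixing_count"))
    }
  }
  if (!is.null(metadata)) tree <- label_with_origin(tree, metadata)
  paths["tree"] <- file.path(outdir, "tree.nwk")
  ape::write.tree(tree, paths["tree"])
  manifest$stages$phylo <- c(manifest$stages$phylo,
                             list(alignment_length = aln$length,
                                  n_leaves = length(tree$tip.label)))

  div_cfg <- utils::modifyList(list(ref = NULL, bin_size = 500000),
                               if (is.null(config$divergence)) list()
                               else config$divergence)
  ref_id <- if (is.null(div_cfg$ref)) seq_panel$samples[1] else div_cfg$ref
  log_stage("divergence: binned differences vs %s", ref_id)
  prof <- binned_differences(seq_panel, ref_id, bin_size = div_cfg$bin_size)
  paths["divergence"] <- file.path(outdir, "divergence.bed")
  write_divergence_bed(prof, paths["divergence"])
  manifest$stages$divergence <- list(ref = ref_id, n_bins = nrow(prof))

  paths["run_config"] <- file.path(outdir, "run_config.json")
  cfg_json <- config
  cfg_json$simulate <- unclass(cfg_json$simulate)
  jsonlite::write_json(cfg_json, paths["run_config"], auto_unbox = TRUE,
                       digits = NA)
  manifest$config_hash <- unname(tools::md5sum(paths["run_config"]))
  manifest$checksums <- as.list(tools::md5sum(unname(paths)))
  paths["manifest"] <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  log_stage("done: %d outputs in %s", length(paths), outdir)
  invisible(manifest)
}
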