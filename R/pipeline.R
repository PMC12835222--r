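#' Assemble and validate a full-run configuration
#'
#' Either point `counts`/`samples` at input files or set `simulate` to a
#' list of [cohort_spec()] arguments to generate the cohort in-run. All
#' stage parameters default to the pipeline's canonical values: CPM filter
#' 1, 2000 negative-control genes, 5 correcting variables, 2500 variable
#' genes for clustering, FDR 0.05, log2FC-difference 0.5.
#'
#' @param out_dir run directory (created by [run_all()]).
#' @param counts,samples input paths (ignored when simulating).
#' @param format count-matrix format, `"tsv"` or `"mtx"`.
#' @param gene_sets optional GMT path; when simulating, the module gene set
#'   is derived from the generator truth if no GMT is given.
#' @param module_set,alt_gene gene-set name of the primary module and the id
#'   of its alternative member, for the asymmetry-scoring stage.
#' @param simulate `NULL` or a list of [cohort_spec()] overrides.
#' @param onset_rule,cpm_filter,n_control_genes,k_factors stage parameters
#'   (see [de_config()]).
#' @param n_top_genes,expression_floor,linkage,cut_k clustering parameters
#'   (see [top_variable_genes()] and [select_similar_subset()]).
#' @param fdr,delta_lfc classification thresholds (see [classify_genes()]).
#' @param zscore_scope `"PD_only"` or `"all"` (see [zscore_genes()]).
#' @param n_perm,exponent enrichment parameters.
#' @param seed master seed for every stochastic stage.
#' @return a validated `hd_config` list.
#' @export
run_config <- function(out_dir,
                       counts = NULL, samples = NULL, format = "tsv",
                       gene_sets = NULL, module_set = "module_primary",
                       alt_gene = "MODALT",
                       simulate = NULL,
                       onset_rule = "contralateral",
                       cpm_filter = 1, n_control_genes = 2000, k_factors = 5,
                       n_top_genes = 2500, expression_floor = 1,
                       linkage = "average", cut_k = 2,
                       fdr = 0.05, delta_lfc = 0.5,
                       zscore_scope = "PD_only",
                       n_perm = 1000, exponent = 1,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "hd_config"
  if (is.null(cfg$simulate)) {
    for (f in c("counts", "samples")) {
      if (is.null(cfg[[f]]))
        stop_hd("config: '%s' path required when not simulating", f)
      if (!file.exists(cfg[[f]]))
        stop_hd("config: %s file does not exist: %s", f, cfg[[f]])
    }
  }
  if (!is.null(cfg$gene_sets) && !file.exists(cfg$gene_sets))
    stop_hd("config: gene_sets file does not exist: %s", cfg$gene_sets)
  if (!cfg$zscore_scope %in% c("PD_only", "all"))
    stop_hd("config: zscore_scope must be 'PD_only' or 'all'")
  for (f in c("cpm_filter", "n_control_genes", "k_factors", "n_top_genes",
              "fdr", "delta_lfc", "n_perm", "seed"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0)
      stop_hd("config: '%s' must be a single non-negative number", f)
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return an `hd_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_hd("config file does not exist: %s", path)
  do.call(run_config, yaml::read_yaml(path))
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[hemidiff] ", fmt), ...))

#' Run the full asymmetry pipeline
#'
#' Executes, in order: cohort simulation or loading; severity derivation;
#' two-stage moderated DE on the full cohort (disease and asymmetry
#' contrasts); rank-correlation clustering and selection of the most
#' similar paired subset; two-stage DE on the subset; per-subject module
#' asymmetry scoring and sign stratification; two-stage DE per stratum
#' (strata with fewer than 2 subjects are skipped with a warning);
#' cross-contrast gene classification; module correlation on both the CPM
#' and the nuisance-corrected scale; and preranked enrichment of the subset
#' asymmetry ranking. All tables are written under `out_dir` and a JSON
#' manifest with input/output checksums closes the run.
#'
#' @param config an `hd_config` from [run_config()] / [read_run_config()].
#' @return invisibly, a list with `manifest` and the in-memory `results`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "hd_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    if (is.matrix(obj)) {
      write_tsv_file(data.frame(gene_id = rownames(obj), obj,
                                check.names = FALSE), path)
    } else {
      write_tsv_file(obj, path)
    }
    outputs <<- c(outputs, path)
    path
  }

  # --- inputs -------------------------------------------------------------
  input_files <- character()
  if (!is.null(config$simulate)) {
    spec_args <- config$simulate
    spec_args$seed <- spec_args$seed %||% config$seed
    spec <- do.call(cohort_spec, spec_args)
    stage_log("simulating cohort: %d PD + %d control subjects, %d genes",
              spec$n_pd_subjects, spec$n_ctrl_subjects, spec$n_genes)
    sim <- simulate_cohort(spec)
    counts <- sim$counts
    samples <- sim$samples
    indir <- file.path(config$out_dir, "inputs")
    input_files <- write_cohort(sim, indir, format = config$format)
    module <- module_genes(spec)
    gene_sets <- stats::setNames(list(module$primary), config$module_set)
    alt_gene <- module$alt
  } else {
    stage_log("loading counts from %s", config$counts)
    counts <- read_counts(config$counts, format = config$format)
    samples <- read_sample_table(config$samples)
    input_files <- c(config$counts, config$samples)
    gene_sets <- NULL
    alt_gene <- config$alt_gene
  }
  if (!is.null(config$gene_sets)) {
    gene_sets <- read_gmt(config$gene_sets)
    input_files <- c(input_files, config$gene_sets)
  }
  if (is.null(gene_sets) || !config$module_set %in% names(gene_sets))
    stop_hd("module gene set '%s' not available; supply a GMT via 'gene_sets'",
            config$module_set)
  module_set <- gene_sets[[config$module_set]]

  if (!"severity" %in% names(samples))
    samples <- derive_severity(samples, rule = config$onset_rule)
  emit(samples, "samples_with_severity.tsv")
  stage_log("cohort: %d samples, %d PD / %d control subjects",
            nrow(samples), length(unique(samples$subject_id[samples$status == "PD"])),
            length(unique(samples$subject_id[samples$status == "control"])))

  decfg <- de_config(onset_rule = config$onset_rule,
                     cpm_filter = config$cpm_filter,
                     n_control_genes = config$n_control_genes,
                     k_factors = config$k_factors,
                     fdr_threshold = config$fdr)

  # --- full-cohort DE -----------------------------------------------------
  stage_log("stage: two-stage DE on the full cohort")
  full <- run_two_stage(counts, samples, decfg)
  emit(full$de_disease, "de_disease_full.tsv")
  emit(full$de_asymmetry, "de_asymmetry_full.tsv")
  emit(data.frame(sample_id = names(full$factors),
                  tmm_factor = as.numeric(full$factors)), "tmm_factors.tsv")

  # --- subset selection ---------------------------------------------------
  stage_log("stage: rank-correlation clustering (%d top genes)", config$n_top_genes)
  n_top <- min(config$n_top_genes, nrow(full$logcpm))
  tv <- top_variable_genes(full$logcpm, n = n_top,
                           min_mean = config$expression_floor)
  sim_mat <- rank_correlation_matrix(full$logcpm[tv, , drop = FALSE])
  emit(data.frame(sample_id = rownames(sim_mat), sim_mat, check.names = FALSE),
       "sample_similarity.tsv")
  subset_subjects <- select_similar_subset(sim_mat, samples,
                                           linkage = config$linkage,
                                           k_clusters = config$cut_k)
  stage_log("selected subset: %d PD subjects", length(subset_subjects))
  writeLines(subset_subjects, file.path(config$out_dir, "subset_subjects.txt"))
  outputs <- c(outputs, file.path(config$out_dir, "subset_subjects.txt"))

  keep_samples <- samples$subject_id %in% subset_subjects | samples$status == "control"
  sub_samples <- samples[keep_samples, , drop = FALSE]
  stage_log("stage: two-stage DE on the clustered subset (%d samples)",
            nrow(sub_samples))
  sub <- run_two_stage(counts[, sub_samples$sample_id, drop = FALSE],
                       sub_samples, decfg)
  emit(sub$de_disease, "de_disease_subset.tsv")
  emit(sub$de_asymmetry, "de_asymmetry_subset.tsv")

  # --- asymmetry scoring and stratification -------------------------------
  stage_log("stage: per-subject module asymmetry scores (%s scope)",
            config$zscore_scope)
  z <- zscore_genes(full$logcpm, samples, scope = config$zscore_scope)
  scores <- subject_asymmetry(z, samples, module_set,
                              set_name = config$module_set)
  emit(scores, "asymmetry_scores.tsv")
  strata <- stratify(scores)
  strata_runs <- list()
  for (nm in c("higher_in_severe", "higher_in_moderate")) {
    subj <- strata[[nm]]
    if (length(subj) < 2) {
      warn_hd("stratum '%s' has %d subject(s); stratified DE skipped",
              nm, length(subj))
      next
    }
    st_samples <- samples[samples$subject_id %in% subj |
                            samples$status == "control", , drop = FALSE]
    stage_log("stage: stratified DE for '%s' (%d subjects)", nm, length(subj))
    res <- run_two_stage(counts[, st_samples$sample_id, drop = FALSE],
                         st_samples, decfg)
    emit(res$de_asymmetry, sprintf("de_asymmetry_stratum_%s.tsv", nm))
    strata_runs[[nm]] <- res
  }

  # --- cross-contrast classification --------------------------------------
  stage_log("stage: cross-contrast gene classification")
  classes <- classify_genes(sub$de_disease, sub$de_asymmetry,
                            fdr = config$fdr, delta = config$delta_lfc)
  emit(classes, "gene_classes.tsv")
  summ <- attr(classes, "summary")
  jsonlite::write_json(
    list(n_asym_significant = summ$n_asym_significant,
         frac_asym_also_disease = summ$frac_asym_also_disease,
         frac_same_direction = summ$frac_same_direction,
         frac_opposite_direction = summ$frac_opposite_direction),
    file.path(config$out_dir, "classification_summary.json"),
    auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, file.path(config$out_dir, "classification_summary.json"))

  # --- module correlation on both display scales --------------------------
  modcor <- NULL
  if (alt_gene %in% full$genes_kept && sum(module_set %in% full$genes_kept) >= 2) {
    pd_cols <- samples$sample_id[samples$status == "PD"]
    cpm_m <- cpm_values(full$counts, full$factors)[, pd_cols, drop = FALSE]
    modcor <- module_correlation(cpm_m, module_set, alt_gene, "cpm")
    if (!is.null(full$nuisance)) {
      loadings <- full$fit$coefficients[, full$design$nuisance_names, drop = FALSE]
      corr_m <- corrected_counts(full$counts, full$factors, full$nuisance,
                                 loadings)[, pd_cols, drop = FALSE]
      modcor <- rbind(modcor,
                      module_correlation(corr_m, module_set, alt_gene, "corrected"))
    }
    emit(modcor, "module_correlation.tsv")
  }

  # --- enrichment ----------------------------------------------------------
  stage_log("stage: preranked enrichment (%d permutations)", config$n_perm)
  ranking <- rank_by_significance(sub$de_asymmetry)
  enr <- run_enrichment(ranking, gene_sets, n_perm = config$n_perm,
                        seed = sub_seed(config$seed, 999),
                        exponent = config$exponent)
  emit(enr, "enrichment_asymmetry.tsv")

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "hemidiff",
    version = as.character(utils::packageVersion("hemidiff")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(input_files)),
    output_checksums = as.list(tools::md5sum(sort(unique(outputs)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage_log("run complete: %d output files in %s", length(outputs), config$out_dir)

  invisible(list(manifest = manifest,
                 results = list(full = full, subset = sub,
                                subset_subjects = subset_subjects,
                                scores = scores, strata = strata,
                                strata_runs = strata_runs, classes = classes,
                                module_correlation = modcor, enrichment = enr)))
}
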