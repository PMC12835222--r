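#' Specify a simulated paired-hemisphere cohort
#'
#' Collects and validates every knob of the cohort generator. Defaults
#' emulate the structure of the motivating study: 25 Parkinson's disease
#' (PD) subjects and 10 controls, each contributing one left and one right
#' prefrontal-cortex library; a fraction of genes carrying a disease effect,
#' a fraction carrying a lateralized (side-of-onset-linked) effect; a
#' co-regulated chaperonin-like module of 8 genes plus one anti-correlated
#' alternative member; subject-level random effects; low-rank technical
#' batch factors; and log-normal library-size variation.
#'
#' @param n_pd_subjects,n_ctrl_subjects subject counts (each contributes two
#'   samples).
#' @param n_genes number of genes.
#' @param frac_disease_genes fraction of genes with a PD-vs-control effect.
#' @param frac_asym_genes fraction with a severe-vs-moderate asymmetry
#'   effect (includes the overlap with disease genes).
#' @param frac_asym_only_genes fraction asymmetric but not disease-affected.
#' @param disease_lfc,asym_lfc planted effect magnitudes, log2 units; the
#'   sign per gene is random.
#' @param module_size number of primary module genes (>= 2).
#' @param alt_member_anticorr latent correlation of the alternative module
#'   member with the primary members, in \[-1, 1\].
#' @param module_latent_sd SD (log2) of the shared per-sample module latent
#'   factor that makes primary members co-vary.
#' @param subject_sd SD (log2) of the per-subject, per-gene random effect
#'   shared by both hemispheres.
#' @param dispersion negative-binomial dispersion (1/size), > 0.
#' @param libsize_log_sd natural-log SD of library depth.
#' @param n_batch_factors,batch_sd number of nuisance batch factors and the
#'   SD (log2) of their gene loadings; factor values are standard normal.
#' @param frac_sign_flip_subjects fraction of unilateral PD subjects whose
#'   module asymmetry direction is inverted (the two observed strata).
#' @param frac_bilateral fraction of PD subjects with bilateral onset; they
#'   are generated and flagged but excluded from asymmetry contrasts.
#' @param base_log2_mean,base_log2_sd parameters of the log-normal baseline
#'   expression across genes (log2 scale).
#' @param target_libsize expected total count per library before the
#'   log-normal depth factor.
#' @param onset_rule severity mapping, shared with [derive_severity()] so
#'   simulator and analysis cannot disagree.
#' @param seed integer seed; one global stream plus a counter-based
#'   substream per subject, so a subject's draws do not depend on cohort
#'   size.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_pd_subjects = 25,
                        n_ctrl_subjects = 10,
                        n_genes = 2000,
                        frac_disease_genes = 0.10,
                        frac_asym_genes = 0.10,
                        frac_asym_only_genes = 0.05,
                        disease_lfc = 1.0,
                        asym_lfc = 1.0,
                        module_size = 8,
                        alt_member_anticorr = -0.6,
                        module_latent_sd = 1.0,
                        subject_sd = 0.3,
                        dispersion = 0.1,
                        libsize_log_sd = 0.2,
                        n_batch_factors = 2,
                        batch_sd = 0.5,
                        frac_sign_flip_subjects = 0,
                        frac_bilateral = 0,
                        base_log2_mean = 5,
                        base_log2_sd = 2,
                        target_libsize = 5e6,
                        onset_rule = "contralateral",
                        seed = 1) {
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  chk_count <- function(field, min = 1) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < min || v != round(v))
      stop_hd("invalid cohort spec: '%s' must be an integer >= %d (got %s)",
              field, min, format(spec[[field]]))
  }
  chk_prop <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
      stop_hd("invalid cohort spec: '%s' must be a proportion in [0,1] (got %s)",
              field, format(spec[[field]]))
  }
  chk_count("n_pd_subjects"); chk_count("n_ctrl_subjects")
  chk_count("n_genes", min = 20); chk_count("module_size", min = 2)
  chk_count("n_batch_factors", min = 0)
  for (f in c("frac_disease_genes", "frac_asym_genes", "frac_asym_only_genes",
              "frac_sign_flip_subjects", "frac_bilateral")) chk_prop(f)
  if (spec$frac_disease_genes + spec$frac_asym_only_genes > 1)
    stop_hd("invalid cohort spec: 'frac_disease_genes' + 'frac_asym_only_genes' exceeds 1")
  if (spec$frac_asym_only_genes > spec$frac_asym_genes)
    stop_hd("invalid cohort spec: 'frac_asym_only_genes' exceeds 'frac_asym_genes'")
  if (!is.numeric(spec$dispersion) || spec$dispersion <= 0)
    stop_hd("invalid cohort spec: 'dispersion' must be > 0")
  if (abs(spec$alt_member_anticorr) > 1)
    stop_hd("invalid cohort spec: 'alt_member_anticorr' must lie in [-1,1]")
  for (f in c("subject_sd", "libsize_log_sd", "batch_sd", "module_latent_sd",
              "base_log2_sd"))
    if (spec[[f]] < 0) stop_hd("invalid cohort spec: '%s' must be >= 0", f)
  if (!spec$onset_rule %in% c("contralateral", "ipsilateral"))
    stop_hd("invalid cohort spec: 'onset_rule' must be contralateral or ipsilateral")
  if (spec$module_size + 1 > spec$n_genes)
    stop_hd("invalid cohort spec: 'module_size' too large for 'n_genes'")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d PD + %d control subjects, %d genes, seed %d\n",
              x$n_pd_subjects, x$n_ctrl_subjects, x$n_genes, x$seed))
  cat(sprintf("  effects: disease %.2g / asym %.2g log2; module %d+1 (anticorr %.2g)\n",
              x$disease_lfc, x$asym_lfc, x$module_size, x$alt_member_anticorr))
  cat(sprintf("  noise: dispersion %.3g, subject_sd %.2g, %d batch factor(s) sd %.2g\n",
              x$dispersion, x$subject_sd, x$n_batch_factors, x$batch_sd))
  invisible(x)
}

#' Module gene ids of a simulated cohort
#'
#' @param spec a `cohort_spec`.
#' @return list with `primary` (character vector) and `alt` (single id).
#' @export
module_genes <- function(spec) {
  list(primary = sprintf("MOD%02d", seq_len(spec$module_size)), alt = "MODALT")
}
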