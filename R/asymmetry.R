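#' Per-gene z-scores across samples
#'
#' Standardizes each gene to mean 0, SD 1 across the in-scope samples. By
#' default the scope is the PD samples only, keeping the statistic internal
#' to the population being stratified; pass `scope = "all"` to standardize
#' across the full cohort. Zero-SD genes are excluded with a warning.
#'
#' @param expr gene x sample expression matrix (any scale).
#' @param samples sample sheet (required for `scope = "PD_only"`).
#' @param scope `"PD_only"` or `"all"`.
#' @return z-score matrix over the in-scope samples.
#' @export
zscore_genes <- function(expr, samples = NULL, scope = c("PD_only", "all")) {
  scope <- match.arg(scope)
  if (scope == "PD_only") {
    if (is.null(samples)) stop_hd("samples required for scope = 'PD_only'")
    cols <- intersect(colnames(expr), samples$sample_id[samples$status == "PD"])
    expr <- expr[, cols, drop = FALSE]
  }
  if (ncol(expr) < 3) stop_hd("z-scoring needs at least 3 in-scope samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warn_hd("%d zero-SD gene(s) excluded from z-scoring", sum(sds == 0))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  z <- t(scale(t(expr)))
  attr(z, "scope") <- scope
  z
}

#' Per-subject directional gene-set asymmetry scores
#'
#' For every unilateral PD subject with both hemispheres, computes the
#' severe-minus-moderate difference of per-gene z-scores over a gene set
#' and summarizes it as a mean and SD; the sign of the mean assigns the
#' subject to a stratum (`higher_in_severe` / `higher_in_moderate`, with
#' ties below `tie_tol` left unassigned).
#'
#' @param z z-score matrix from [zscore_genes()].
#' @param samples sample sheet with derived severity.
#' @param gene_set character vector of gene ids.
#' @param set_name label stored in the table.
#' @param tie_tol absolute tolerance below which a mean counts as a tie.
#' @return a data.frame: `subject_id`, `score_mean`, `score_sd`, `n_genes`,
#'   `gene_set`, `stratum`.
#' @export
subject_asymmetry <- function(z, samples, gene_set, set_name = "gene_set",
                              tie_tol = 1e-9) {
  validate_samples(samples, require_severity = TRUE)
  genes <- intersect(gene_set, rownames(z))
  if (length(genes) == 0) stop_hd("none of the gene-set genes are present")
  if (length(genes) < length(gene_set))
    warn_hd("%d gene-set gene(s) absent from the z matrix",
            length(gene_set) - length(genes))
  pd <- samples[samples$status == "PD" &
                  samples$onset_side %in% c("left", "right"), , drop = FALSE]
  subjects <- unique(pd$subject_id)
  rows <- lapply(subjects, function(sj) {
    sv <- pd$sample_id[pd$subject_id == sj & pd$severity == "severe"]
    md <- pd$sample_id[pd$subject_id == sj & pd$severity == "moderate"]
    if (length(sv) != 1 || length(md) != 1 ||
        !all(c(sv, md) %in% colnames(z))) {
      warn_hd("subject %s skipped: missing hemisphere in the z matrix", sj)
      return(NULL)
    }
    d <- z[genes, sv] - z[genes, md]
    m <- mean(d)
    data.frame(subject_id = sj, score_mean = m, score_sd = stats::sd(d),
               n_genes = length(genes), gene_set = set_name,
               stratum = if (abs(m) < tie_tol) "tie"
                         else if (m > 0) "higher_in_severe"
                         else "higher_in_moderate",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Partition subjects by the sign of their asymmetry score
#'
#' @param scores table from [subject_asymmetry()].
#' @return list with `higher_in_severe`, `higher_in_moderate` (subject id
#'   vectors) and `excluded` (tie subjects); empty strata trigger a warning.
#' @export
stratify <- function(scores) {
  out <- list(
    higher_in_severe = scores$subject_id[scores$stratum == "higher_in_severe"],
    higher_in_moderate = scores$subject_id[scores$stratum == "higher_in_moderate"],
    excluded = scores$subject_id[scores$stratum == "tie"])
  for (s in c("higher_in_severe", "higher_in_moderate"))
    if (length(out[[s]]) == 0)
      warn_hd("stratum '%s' is empty; downstream contrasts for it will be skipped", s)
  out
}

#' Correlation structure of a gene module
#'
#' Reports the mean pairwise Pearson correlation among the primary module
#' members and the correlation of an alternative member with the per-sample
#' mean of the primary members, on whatever expression scale is supplied.
#' Both are also rendered as `sign(r) * r^2`, the signed-coefficient-of-
#' determination convention sometimes used for anti-correlated module
#' members (a raw r-squared cannot be negative).
#'
#' @param expr gene x sample expression matrix.
#' @param primary character vector of primary member gene ids (>= 2).
#' @param alt single alternative member gene id.
#' @param scale_label label for the expression scale (e.g. `"cpm"`,
#'   `"corrected"`).
#' @return one-row data.frame: `scale`, `primary_mean_r`,
#'   `primary_r2_signed`, `alt_r`, `alt_r2_signed`, `n_samples`.
#' @export
module_correlation <- function(expr, primary, alt, scale_label = "cpm") {
  if (ncol(expr) < 4) stop_hd("module correlation needs at least 4 samples")
  present <- intersect(primary, rownames(expr))
  if (length(present) < 2) stop_hd("fewer than 2 primary module genes present")
  if (!alt %in% rownames(expr)) stop_hd("alternative member '%s' absent", alt)
  M <- expr[present, , drop = FALSE]
  sds <- apply(M, 1, stats::sd)
  if (any(sds == 0)) {
    warn_hd("zero-variance primary gene(s) excluded: %s",
            paste(present[sds == 0], collapse = ", "))
    M <- M[sds > 0, , drop = FALSE]
  }
  pw <- stats::cor(t(M))
  primary_r <- mean(pw[upper.tri(pw)])
  alt_r <- stats::cor(expr[alt, ], colMeans(M))
  data.frame(scale = scale_label,
             primary_mean_r = primary_r,
             primary_r2_signed = sign(primary_r) * primary_r^2,
             alt_r = alt_r,
             alt_r2_signed = sign(alt_r) * alt_r^2,
             n_samples = ncol(expr),
             stringsAsFactors = FALSE)
}
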