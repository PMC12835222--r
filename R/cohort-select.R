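#' Top variable, well-expressed genes
#'
#' Applies a mean-expression floor, then ranks the remaining genes by their
#' variance across samples and returns the top `n`, with deterministic ties
#' broken by gene id.
#'
#' @param expr gene x sample log2 expression matrix.
#' @param n number of genes (default 2500).
#' @param min_mean expression floor on the per-gene mean (same units as
#'   `expr`).
#' @return character vector of gene ids.
#' @export
top_variable_genes <- function(expr, n = 2500, min_mean = 1) {
  mu <- rowMeans(expr)
  keep <- mu >= min_mean
  if (sum(keep) < n)
    stop_hd("expression floor leaves %d genes but n = %d requested", sum(keep), n)
  v <- apply(expr[keep, , drop = FALSE], 1, stats::var)
  if (max(v) == 0)
    stop_hd("all candidate genes have zero variance; no variable genes to rank")
  ids <- names(v)
  ids[order(-v, ids)][seq_len(n)]
}

#' Sample-by-sample rank correlation matrix
#'
#' Spearman correlation (mid-ranks for ties) between every pair of samples,
#' computed over the supplied genes. Zero-variance samples produce `NA`
#' entries and are flagged with a warning.
#'
#' @param expr gene x sample expression matrix, usually restricted to the
#'   [top_variable_genes()].
#' @return symmetric matrix with unit diagonal.
#' @export
rank_correlation_matrix <- function(expr) {
  if (ncol(expr) < 3) stop_hd("rank correlation needs at least 3 samples")
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0))
    warn_hd("zero-variance sample(s), correlation undefined: %s",
            paste(colnames(expr)[sds == 0], collapse = ", "))
  sim <- suppressWarnings(stats::cor(expr, method = "spearman"))
  diag(sim) <- 1
  sim
}

#' Select the most similar subset of paired subjects
#'
#' Average-linkage hierarchical clustering on `1 - rank correlation` over
#' the samples of the target status, cut into `k_clusters` groups; the
#' cluster containing the most complete subjects (both hemispheres inside
#' the cluster) is returned. Subjects whose two hemispheres straddle
#' clusters are excluded. When all off-diagonal similarities are equal the
#' clustering carries no information and every complete subject is returned
#' (documented deterministic fallback).
#'
#' @param sim similarity matrix from [rank_correlation_matrix()].
#' @param samples sample sheet.
#' @param target_status status of the subjects to cluster (default `"PD"`).
#' @param linkage hclust agglomeration method.
#' @param k_clusters number of clusters to cut into.
#' @param tol tolerance for the all-equal-similarity fallback.
#' @return sorted character vector of selected subject ids.
#' @export
select_similar_subset <- function(sim, samples, target_status = "PD",
                                  linkage = "average", k_clusters = 2,
                                  tol = 1e-8) {
  ids <- samples$sample_id[samples$status == target_status]
  ids <- intersect(colnames(sim), ids)
  if (length(ids) < 4) stop_hd("need at least 4 target samples to cluster")
  S <- sim[ids, ids]
  if (anyNA(S)) stop_hd("similarity matrix has NA entries over the target samples")
  subj <- stats::setNames(samples$subject_id[match(ids, samples$sample_id)], ids)
  complete <- names(which(table(subj) == 2))

  off <- S[upper.tri(S)]
  if (max(off) - min(off) < tol) {
    return(sort(complete))
  }
  hc <- stats::hclust(stats::as.dist(1 - S), method = linkage)
  cl <- stats::cutree(hc, k = k_clusters)
  per_cluster <- lapply(sort(unique(cl)), function(k) {
    inside <- names(cl)[cl == k]
    cand <- intersect(complete, unique(subj[inside]))
    cand[vapply(cand, function(sj) all(names(subj)[subj == sj] %in% inside),
                logical(1))]
  })
  sizes <- lengths(per_cluster)
  best <- per_cluster[[which.max(sizes)]]
  if (length(best) < 2)
    stop_hd("no cluster contains at least 2 complete %s subjects", target_status)
  sort(best)
}
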