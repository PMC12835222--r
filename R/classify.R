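#' Classify genes across the disease and asymmetry contrasts
#'
#' Each gene is assigned one mutually exclusive class from the two DE
#' tables, using an FDR significance threshold in each contrast and a
#' minimum absolute difference in log2 fold change for the asymmetry-only
#' class:
#' \itemize{
#'   \item `both_same_direction` / `both_opposite_direction`: significant in
#'     both contrasts, split by the sign product of the two fold changes;
#'   \item `both_tie`: significant in both but one fold change is exactly
#'     zero (excluded from the direction split, counted separately);
#'   \item `asym_only_differential`: asymmetry-significant, not
#'     disease-significant, and `|lfc_disease - lfc_asym| >= delta`;
#'   \item `disease_only_stable`: disease-significant, not
#'     asymmetry-significant;
#'   \item `neither`: everything else.
#' }
#' The summary attribute reports the share of asymmetry-significant genes
#' that are also disease-significant and, among those, the same/opposite
#' direction split.
#'
#' @param de_disease,de_asym DE tables over the same gene universe.
#' @param fdr significance threshold (default 0.05).
#' @param delta minimum log2FC difference for the asymmetry-only class
#'   (default 0.5).
#' @return a data.frame (`gene_id`, `class`, `disease_log2fc`,
#'   `asym_log2fc`, `disease_fdr`, `asym_fdr`, `delta_lfc`) with a
#'   `summary` attribute; see [classification_summary()].
#' @export
classify_genes <- function(de_disease, de_asym, fdr = 0.05, delta = 0.5) {
  if (!setequal(de_disease$gene_id, de_asym$gene_id))
    stop_hd("gene universes differ between the two tables (%d genes not shared)",
            length(union(setdiff(de_disease$gene_id, de_asym$gene_id),
                         setdiff(de_asym$gene_id, de_disease$gene_id))))
  d <- de_disease[order(de_disease$gene_id), ]
  a <- de_asym[match(d$gene_id, de_asym$gene_id), ]
  sig_d <- d$fdr < fdr
  sig_a <- a$fdr < fdr
  delta_lfc <- abs(d$log2fc - a$log2fc)
  sp <- sign(d$log2fc) * sign(a$log2fc)
  cls <- rep("neither", nrow(d))
  cls[sig_d & sig_a & sp > 0] <- "both_same_direction"
  cls[sig_d & sig_a & sp < 0] <- "both_opposite_direction"
  cls[sig_d & sig_a & sp == 0] <- "both_tie"
  cls[sig_a & !sig_d & delta_lfc >= delta] <- "asym_only_differential"
  cls[sig_d & !sig_a] <- "disease_only_stable"
  out <- data.frame(gene_id = d$gene_id, class = cls,
                    disease_log2fc = d$log2fc, asym_log2fc = a$log2fc,
                    disease_fdr = d$fdr, asym_fdr = a$fdr,
                    delta_lfc = delta_lfc, stringsAsFactors = FALSE)
  attr(out, "summary") <- classification_summary(out, fdr = fdr)
  out
}

#' Headline fractions of a gene classification table
#'
#' @param tab table from [classify_genes()].
#' @param fdr the significance threshold the table was built with.
#' @return list: raw class counts, `n_asym_significant`,
#'   `frac_asym_also_disease` (share of asymmetry-significant genes that are
#'   also disease-significant), and among the doubly significant directional
#'   genes `frac_same_direction` / `frac_opposite_direction` (ties
#'   excluded).
#' @export
classification_summary <- function(tab, fdr = 0.05) {
  sig_d <- tab$disease_fdr < fdr
  sig_a <- tab$asym_fdr < fdr
  n_same <- sum(tab$class == "both_same_direction")
  n_opp <- sum(tab$class == "both_opposite_direction")
  n_tie <- sum(tab$class == "both_tie")
  n_both <- n_same + n_opp + n_tie
  n_asym_only <- sum(tab$class == "asym_only_differential")
  list(
    class_counts = table(factor(tab$class,
                                levels = c("both_same_direction",
                                           "both_opposite_direction", "both_tie",
                                           "asym_only_differential",
                                           "disease_only_stable", "neither"))),
    n_asym_significant = sum(sig_a),
    frac_asym_also_disease = if (any(sig_a)) mean(sig_d[sig_a]) else NA_real_,
    n_both_significant = n_both,
    n_direction_ties = n_tie,
    frac_same_direction = if (n_same + n_opp > 0) n_same / (n_same + n_opp) else NA_real_,
    frac_opposite_direction = if (n_same + n_opp > 0) n_opp / (n_same + n_opp) else NA_real_,
    n_asym_only = n_asym_only)
}

#' Compare human direction calls with an external DE table
#'
#' Maps a set of human genes with known directions onto an external
#' differential-expression table (for example a published mouse
#' aggregate-vs-non-aggregate analysis) through a two-column ortholog map
#' and reports per-gene direction agreement and significant
#' concordant/discordant counts. The external model is consumed as a table,
#' never refit.
#'
#' @param human data.frame with `gene_id` and `direction` (sign or log2FC).
#' @param external_de data.frame with `gene_id`, `log2fc`, `fdr`.
#' @param ortholog_map data.frame with columns `human`, `external`; `NULL`
#'   maps shared symbols onto each other.
#' @param ignore_case case-insensitive symbol matching (human vs rodent
#'   capitalization conventions).
#' @param fdr significance threshold for the external table.
#' @return data.frame of mapped genes with a `summary` attribute
#'   (`n_mapped`, `unmapped`, `n_sig_concordant`, `n_sig_discordant`).
#' @export
cross_dataset_compare <- function(human, external_de, ortholog_map = NULL,
                                  ignore_case = TRUE, fdr = 0.05) {
  key <- function(x) if (ignore_case) toupper(x) else x
  if (is.null(ortholog_map)) {
    shared <- intersect(key(human$gene_id), key(external_de$gene_id))
    ortholog_map <- data.frame(
      human = human$gene_id[match(shared, key(human$gene_id))],
      external = external_de$gene_id[match(shared, key(external_de$gene_id))],
      stringsAsFactors = FALSE)
  }
  idx_h <- match(key(ortholog_map$human), key(human$gene_id))
  idx_e <- match(key(ortholog_map$external), key(external_de$gene_id))
  ok <- !is.na(idx_h) & !is.na(idx_e)
  unmapped <- union(setdiff(human$gene_id, ortholog_map$human[ok]),
                    ortholog_map$human[!ok & !is.na(ortholog_map$human)])
  out <- data.frame(
    human_gene = human$gene_id[idx_h[ok]],
    external_gene = external_de$gene_id[idx_e[ok]],
    human_direction = sign(human$direction[idx_h[ok]]),
    external_log2fc = external_de$log2fc[idx_e[ok]],
    external_fdr = external_de$fdr[idx_e[ok]],
    stringsAsFactors = FALSE)
  out$significant <- out$external_fdr < fdr
  out$concordant <- out$human_direction * sign(out$external_log2fc) > 0
  attr(out, "summary") <- list(
    n_mapped = nrow(out),
    unmapped = unmapped,
    n_sig_concordant = sum(out$significant & out$concordant),
    n_sig_discordant = sum(out$significant & !out$concordant))
  out
}
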