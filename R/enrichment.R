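#' Preranked running-sum enrichment score
#'
#' Classic running-sum gene-set statistic on a weighted ranked list: walking
#' down the ranking, hits increment the sum proportionally to
#' `|weight|^exponent` (normalized over the set's hits) and misses decrement
#' it by `1 / (N - set size)`; the enrichment score is the value of maximal
#' absolute deviation from zero. With `exponent = 0` every hit contributes
#' equally.
#'
#' @param ranking named numeric vector of per-gene weights; sorted in
#'   decreasing order internally (ties broken by name for determinism).
#' @param set character vector of gene ids.
#' @param exponent weight exponent (default 1).
#' @return an `hd_es` list: `es`, `running` (full running sum), `hits`
#'   (logical vector along the ranking), `leading_edge` gene ids. `es` is
#'   `NA` when the set does not intersect the ranking.
#' @export
preranked_es <- function(ranking, set, exponent = 1) {
  if (is.null(names(ranking))) stop_hd("ranking must be a named numeric vector")
  ord <- order(-ranking, names(ranking))
  w <- ranking[ord]
  hits <- names(w) %in% set
  N <- length(w)
  m <- sum(hits)
  if (m == 0) {
    return(structure(list(es = NA_real_, running = rep(NA_real_, N),
                          hits = hits, leading_edge = character()),
                     class = "hd_es"))
  }
  if (m == N) stop_hd("gene set covers the entire ranking; score undefined")
  wexp <- abs(w)^exponent
  denom <- sum(wexp[hits])
  inc <- if (denom > 0) wexp / denom else rep(1 / m, N)
  step <- ifelse(hits, inc, -1 / (N - m))
  running <- cumsum(step)
  peak <- which.max(abs(running))
  es <- running[peak]
  le <- if (es >= 0) names(w)[seq_len(peak)][hits[seq_len(peak)]]
        else names(w)[peak:N][hits[peak:N]]
  structure(list(es = es, running = running, hits = hits, leading_edge = le),
            class = "hd_es")
}

#' Gene-label permutation p-value for an enrichment score
#'
#' Null enrichment scores are generated by re-drawing random gene sets of
#' the same size from the ranking (gene-label permutation); the p-value is
#' `(1 + #{|ES_perm| >= |ES|}) / (1 + n_perm)`.
#'
#' @inheritParams preranked_es
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list: `es`, `p`, `es_perm` (null scores), `n_perm`.
#' @export
permutation_p <- function(ranking, set, n_perm = 1000, seed = 1, exponent = 1) {
  if (n_perm < 100) stop_hd("n_perm must be at least 100")
  obs <- preranked_es(ranking, set, exponent)
  if (is.na(obs$es))
    return(list(es = NA_real_, p = NA_real_, es_perm = numeric(), n_perm = n_perm))
  m <- sum(obs$hits)
  genes <- names(ranking)
  es_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    preranked_es(ranking, sample(genes, m), exponent)$es
  }, numeric(1)))
  p <- (1 + sum(abs(es_perm) >= abs(obs$es))) / (1 + n_perm)
  list(es = obs$es, p = p, es_perm = es_perm, n_perm = n_perm)
}

#' Preranked enrichment over a gene-set collection
#'
#' Runs [preranked_es()] and [permutation_p()] for every set and controls
#' the FDR across sets by Benjamini-Hochberg. The normalized score is the
#' raw score divided by the mean absolute null score of that set.
#'
#' @param ranking named numeric vector of per-gene weights (see
#'   [rank_by_significance()]).
#' @param sets a `gene_set_collection` or named list of gene id vectors.
#' @param n_perm,seed,exponent as in [permutation_p()].
#' @return data.frame: `set`, `n_hits`, `es`, `nes`, `p`, `fdr`,
#'   `leading_edge` (comma-separated).
#' @export
run_enrichment <- function(ranking, sets, n_perm = 1000, seed = 1, exponent = 1) {
  rows <- lapply(seq_along(sets), function(i) {
    st <- sets[[i]]
    es <- preranked_es(ranking, st, exponent)
    if (is.na(es$es)) {
      return(data.frame(set = names(sets)[i], n_hits = 0, es = NA_real_,
                        nes = NA_real_, p = NA_real_,
                        leading_edge = "", stringsAsFactors = FALSE))
    }
    pp <- permutation_p(ranking, st, n_perm = n_perm,
                        seed = sub_seed(seed, i), exponent = exponent)
    data.frame(set = names(sets)[i], n_hits = sum(es$hits), es = es$es,
               nes = es$es / mean(abs(pp$es_perm)), p = pp$p,
               leading_edge = paste(es$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- stats::p.adjust(out$p[ok], "BH")
  out[, c("set", "n_hits", "es", "nes", "p", "fdr", "leading_edge")]
}

#' Significance-signed ranking metric from a DE table
#'
#' Default preranked input: `sign(log2fc) * -log10(p)`; `key = "t"` uses the
#' moderated t-statistic instead.
#'
#' @param de a DE table.
#' @param key `"signed_logp"` or `"t"`.
#' @return named numeric vector over the table's genes.
#' @export
rank_by_significance <- function(de, key = c("signed_logp", "t")) {
  key <- match.arg(key)
  v <- if (key == "signed_logp") {
    sign(de$log2fc) * -log10(pmax(de$p, 1e-300))
  } else {
    de$t_mod
  }
  stats::setNames(v, de$gene_id)
}

#' Hypergeometric over-representation test
#'
#' A plain one-sided over-representation test on the 2x2 membership table,
#' provided as a lightweight alternative to network-based enrichment
#' services (which this pipeline deliberately does not call).
#'
#' @param selected character vector of selected gene ids.
#' @param universe character vector of all tested gene ids.
#' @param sets gene-set collection.
#' @return data.frame: `set`, `n_set`, `n_overlap`, `p`, `fdr`.
#' @export
ora_hypergeometric <- function(selected, universe, sets) {
  selected <- intersect(selected, universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(s, selected))
    p <- stats::phyper(ov - 1, length(s), length(universe) - length(s),
                       length(selected), lower.tail = FALSE)
    data.frame(set = nm, n_set = length(s), n_overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out
}
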