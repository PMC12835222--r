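#' Trimmed mean of M-values scaling factors
#'
#' Between-sample scaling normalization for count matrices. The reference is
#' the sample whose 75th-percentile count fraction is closest to the mean
#' across samples. For every sample, gene-wise log2 ratios against the
#' reference (M) and average log2 abundances (A) are computed over genes
#' with positive counts in both libraries, doubly trimmed (30% of M, 5% of
#' A by default), and averaged with inverse asymptotic-variance weights; the
#' factor is 2 to that mean. Factors are rescaled to geometric mean 1.
#'
#' @param counts gene x sample count matrix.
#' @param trim_m,trim_a two-sided trim proportions for M and A.
#' @param do_weighting use inverse-variance weights (default) or a plain
#'   trimmed mean.
#' @return a `norm_factors` object: numeric vector of positive per-sample
#'   factors (geometric mean 1) with the reference sample id as an
#'   attribute.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, do_weighting = TRUE) {
  check_count_matrix(counts)
  if (ncol(counts) < 2) stop_hd("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop_hd("sample(s) with zero total count: %s",
            paste(colnames(counts)[lib <= 0], collapse = ", "))
  # reference: 75th-percentile count fraction closest to the mean
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(obs, nO, rf, nR) {
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- if (do_weighting) {
      sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    } else {
      mean(logR[keep], na.rm = TRUE)
    }
    if (!is.finite(f)) f <- 0
    2^f
  }

  fac <- vapply(seq_len(ncol(counts)), function(i)
    one_factor(counts[, i], lib[i], counts[, ref], lib[ref]), numeric(1))
  fac <- fac / exp(mean(log(fac)))
  structure(stats::setNames(fac, colnames(counts)),
            reference_sample = colnames(counts)[ref], class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("TMM scaling factors (%d samples, reference %s)\n",
              length(x), attr(x, "reference_sample")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (factor * libsize + 2 * prior) * 1e6)`, the
#' moderated log-CPM used for all statistical modelling. The effective
#' library size is the raw column total times its TMM factor.
#'
#' @param counts gene x sample count matrix.
#' @param factors [tmm_factors()] output (or a named numeric vector); `NULL`
#'   for unit factors.
#' @param prior pseudo-count added to every observation.
#' @return an expression matrix with attribute `scale = "log2cpm"`.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  check_count_matrix(counts)
  lib <- colSums(counts)
  f <- resolve_factors(factors, counts)
  eff <- lib * f
  y <- log2(t((t(counts) + prior) / (eff + 2 * prior)) * 1e6)
  attr(y, "scale") <- "log2cpm"
  y
}

resolve_factors <- function(factors, counts) {
  if (is.null(factors)) return(stats::setNames(rep(1, ncol(counts)), colnames(counts)))
  f <- unclass(factors)
  if (is.null(names(f)) || !setequal(names(f), colnames(counts)))
    stop_hd("normalization factors do not cover the same samples as the counts")
  f[colnames(counts)]
}

#' Counts per million on the linear scale
#'
#' Defined as `2^log_cpm` so that the corrected scale with zero nuisance
#' loadings reproduces it exactly.
#'
#' @inheritParams log_cpm
#' @return expression matrix with attribute `scale = "cpm"`.
#' @export
cpm_values <- function(counts, factors = NULL, prior = 0.5) {
  y <- 2^log_cpm(counts, factors, prior)
  attr(y, "scale") <- "cpm"
  y
}

#' Nuisance-corrected expression for display
#'
#' Removes the fitted contribution of the unwanted-variation factors from
#' log-scale expression and returns linear-scale values. This is a display
#' and correlation scale only; inference always uses the uncorrected log-CPM
#' with the factors as model covariates.
#'
#' @param counts gene x sample count matrix.
#' @param factors TMM factors.
#' @param nuisance a `ruv_factors` object from [estimate_nuisance()], or a
#'   samples x k factor matrix.
#' @param loadings optional gene x k coefficient matrix (e.g. the nuisance
#'   coefficients of the final fit); when `NULL`, loadings are estimated by
#'   regressing each gene's log-CPM on the factors (with intercept).
#' @param prior pseudo-count for the log-CPM.
#' @return expression matrix with attribute `scale = "corrected"`.
#' @export
corrected_counts <- function(counts, factors = NULL, nuisance, loadings = NULL,
                             prior = 0.5) {
  if (missing(nuisance) || is.null(nuisance))
    stop_hd("nuisance factors have not been estimated; run estimate_nuisance() first")
  W <- if (inherits(nuisance, "ruv_factors")) nuisance$W else as.matrix(nuisance)
  y <- log_cpm(counts, factors, prior)
  if (nrow(W) != ncol(y))
    stop_hd("nuisance factor matrix has %d rows but there are %d samples",
            nrow(W), ncol(y))
  if (is.null(loadings)) {
    X <- cbind(1, W)
    B <- t(stats::lm.fit(X, t(y))$coefficients)[, -1, drop = FALSE]
  } else {
    B <- as.matrix(loadings)
    if (nrow(B) != nrow(y) || ncol(B) != ncol(W))
      stop_hd("loadings must be a %d x %d matrix", nrow(y), ncol(W))
  }
  out <- 2^(y - B %*% t(W))
  attr(out, "scale") <- "corrected"
  out
}
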