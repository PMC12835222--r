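#' Build the means-model design matrix
#'
#' Columns are the combined-category levels (`~ 0 + category`), followed by
#' centered continuous covariates and, optionally, unwanted-variation
#' factors. Age is centered as the difference relative to the mean age;
#' library size enters as centered log2. Covariates that are constant across
#' samples are dropped with a message.
#'
#' @param samples validated sample sheet with derived severity.
#' @param covariates character vector among `duration`, `age`, `rin`,
#'   `library_size`, `nuclei_per_mg`, `pmi`.
#' @param nuisance optional samples x k factor matrix (or `ruv_factors`).
#' @return an `hd_design` list: `design` (matrix), `levels` (data.frame with
#'   per-level status and severity), `covariate_names`, `nuisance_names`.
#' @export
build_design <- function(samples,
                         covariates = c("duration", "age", "rin", "library_size",
                                        "nuclei_per_mg", "pmi"),
                         nuisance = NULL) {
  validate_samples(samples, require_severity = TRUE)
  combined <- build_combined_category(samples)
  combined <- droplevels(combined)
  X <- stats::model.matrix(~ 0 + combined)
  colnames(X) <- levels(combined)

  lev_status <- vapply(levels(combined), function(l)
    unique(samples$status[combined == l]), character(1))
  lev_sev <- vapply(levels(combined), function(l) {
    s <- unique(samples$severity[combined == l])
    if (length(s) != 1) NA_character_ else s
  }, character(1))

  # covariates that are constant, or collinear with the level structure
  # (inevitable when each level holds a single subject), are dropped with a
  # message rather than aborting the fit
  kept <- character()
  for (cv in covariates) {
    if (!cv %in% names(samples)) stop_hd("unknown covariate '%s'", cv)
    v <- samples[[cv]]
    if (cv == "library_size") v <- log2(v)
    v <- v - mean(v)
    if (stats::sd(v) < 1e-12) {
      message(sprintf("covariate '%s' is constant; dropped from the design", cv))
      next
    }
    Xc <- cbind(X, v)
    if (qr(Xc)$rank < ncol(Xc)) {
      message(sprintf("covariate '%s' is collinear with the design; dropped", cv))
      next
    }
    colnames(Xc)[ncol(Xc)] <- cv
    X <- Xc
    kept <- c(kept, cv)
  }

  nuis_names <- character()
  if (!is.null(nuisance)) {
    W <- if (inherits(nuisance, "ruv_factors")) nuisance$W else as.matrix(nuisance)
    if (nrow(W) != nrow(samples))
      stop_hd("nuisance factors have %d rows for %d samples", nrow(W), nrow(samples))
    nuis_names <- colnames(W) %||% paste0("ruv", seq_len(ncol(W)))
    colnames(W) <- nuis_names
    X <- cbind(X, W)
  }
  rownames(X) <- samples$sample_id

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_hd("design matrix is rank deficient; collinear column(s): %s",
            paste(drop_cols, collapse = ", "))
  }
  structure(list(design = X,
                 levels = data.frame(level = levels(combined),
                                     status = lev_status, severity = lev_sev,
                                     stringsAsFactors = FALSE),
                 covariate_names = kept, nuisance_names = nuis_names),
            class = "hd_design")
}

#' Contrast vector over a design
#'
#' The disease contrast averages the PD levels minus the control levels with
#' equal weight per level; the asymmetry contrast averages the severe levels
#' minus the moderate levels within PD. Covariate and nuisance columns get
#' zero weight.
#'
#' @param design_info an `hd_design`.
#' @param type `"disease"` or `"asymmetry"`.
#' @return a named numeric vector over the design columns.
#' @export
make_contrast <- function(design_info, type = c("disease", "asymmetry")) {
  type <- match.arg(type)
  lv <- design_info$levels
  cvec <- stats::setNames(rep(0, ncol(design_info$design)),
                          colnames(design_info$design))
  if (type == "disease") {
    plus <- lv$level[lv$status == "PD"]
    minus <- lv$level[lv$status == "control"]
  } else {
    plus <- lv$level[!is.na(lv$severity) & lv$severity == "severe"]
    minus <- lv$level[!is.na(lv$severity) & lv$severity == "moderate"]
  }
  if (length(plus) == 0 || length(minus) == 0)
    stop_hd("cannot form %s contrast: a side has no design levels", type)
  cvec[plus] <- 1 / length(plus)
  cvec[minus] <- -1 / length(minus)
  cvec
}

#' Gene-wise (weighted) least-squares fit
#'
#' Fits every gene's log-expression on a common design, optionally with
#' per-observation precision weights, giving identical answers to
#' gene-by-gene independent regression.
#'
#' @param expr gene x sample matrix of log2 expression.
#' @param design design matrix (samples x columns) or an `hd_design`.
#' @param weights optional gene x sample positive weight matrix.
#' @return an `hd_fit`: coefficients (gene x column), residuals, residual
#'   variance `sigma2`, residual df, unscaled coefficient covariance(s),
#'   average expression.
#' @export
fit_model <- function(expr, design, weights = NULL) {
  if (inherits(design, "hd_design")) design <- design$design
  if (!is.matrix(expr) || any(!is.finite(expr)))
    stop_hd("expr must be a finite matrix")
  if (nrow(design) != ncol(expr))
    stop_hd("design has %d rows for %d samples", nrow(design), ncol(expr))
  qrX <- qr(design)
  if (qrX$rank < ncol(design))
    stop_hd("design matrix is rank deficient; collinear column(s): %s",
            paste(colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]],
                  collapse = ", "))
  G <- nrow(expr); n <- ncol(expr); p <- ncol(design)
  df <- n - p
  if (df <= 0) stop_hd("no residual degrees of freedom (n = %d, p = %d)", n, p)

  if (is.null(weights)) {
    f <- stats::lm.fit(design, t(expr))
    coef <- t(f$coefficients)
    res <- t(f$residuals)
    s2 <- rowSums(res^2) / df
    cov_unscaled <- chol2inv(chol(crossprod(design)))
    shared_cov <- TRUE
  } else {
    if (!is.matrix(weights) || any(dim(weights) != dim(expr)) ||
        any(!is.finite(weights)) || any(weights <= 0))
      stop_hd("weights must be a positive finite matrix matching expr")
    coef <- matrix(NA_real_, G, p, dimnames = list(rownames(expr), colnames(design)))
    res <- matrix(NA_real_, G, n, dimnames = dimnames(expr))
    s2 <- numeric(G)
    cov_unscaled <- array(NA_real_, c(p, p, G))
    for (g in seq_len(G)) {
      w <- weights[g, ]
      fg <- stats::lm.wfit(design, expr[g, ], w)
      coef[g, ] <- fg$coefficients
      res[g, ] <- expr[g, ] - drop(design %*% fg$coefficients)
      s2[g] <- sum(w * res[g, ]^2) / df
      cov_unscaled[, , g] <- chol2inv(chol(crossprod(design * sqrt(w))))
    }
    shared_cov <- FALSE
  }
  rownames(coef) <- rownames(expr)
  colnames(coef) <- colnames(design)
  structure(list(coefficients = coef, residuals = res, sigma2 = s2,
                 df_resid = df, cov_unscaled = cov_unscaled,
                 shared_cov = shared_cov, design = design, weights = weights,
                 ave_expr = rowMeans(expr), gene_ids = rownames(expr)),
            class = "hd_fit")
}

#' Mean-variance trend precision weights
#'
#' The count-scale analogue of the precision-weight stage of moderated
#' RNA-seq modelling: fit the gene-wise square-root residual SD against
#' average log2 count with a lowess curve, then set each observation's
#' weight to the inverse fourth power of the predicted square-root SD at its
#' fitted log2 count.
#'
#' @param counts gene x sample count matrix (same genes as modelled).
#' @param design design matrix or `hd_design`.
#' @param factors TMM factors for effective library sizes.
#' @param span lowess span.
#' @param prior pseudo-count.
#' @return gene x sample weight matrix (unit weights with a warning when
#'   there are fewer than 50 genes).
#' @export
precision_weights <- function(counts, design, factors = NULL, span = 0.5,
                              prior = 0.5) {
  if (inherits(design, "hd_design")) design <- design$design
  if (nrow(counts) < 50) {
    warn_hd("fewer than 50 genes; precision weights set to 1")
    return(matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(counts)))
  }
  lib <- colSums(counts)
  eff <- lib * resolve_factors(factors, counts) + 1
  y <- log2(t((t(counts) + prior) / eff) * 1e6)
  f <- stats::lm.fit(design, t(y))
  sigma <- sqrt(colSums(f$residuals^2) / (ncol(y) - ncol(design)))
  sx <- rowMeans(y) + mean(log2(eff)) - log2(1e6)
  sy <- sqrt(sigma)
  ok <- is.finite(sx) & is.finite(sy)
  lo <- stats::lowess(sx[ok], sy[ok], f = span)
  predict_sqrt_sd <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_logcpm <- t(design %*% f$coefficients)
  fitted_logcount <- fitted_logcpm + matrix(log2(eff), nrow(y), ncol(y),
                                            byrow = TRUE) - log2(1e6)
  w <- 1 / pmax(predict_sqrt_sd(fitted_logcount), 1e-4)^4
  w <- matrix(w, nrow(y), ncol(y), dimnames = dimnames(counts))
  w
}

#' Select the least differentially expressed genes
#'
#' The `n` genes with the largest p-value in a DE table, ties broken by the
#' smallest absolute moderated statistic, then lexical gene id. These serve
#' as negative-control genes for unwanted-variation estimation.
#'
#' @param de a DE table (see [test_contrast()]).
#' @param n number of genes (default 2000).
#' @return character vector of gene ids.
#' @export
select_least_different <- function(de, n = 2000) {
  if (nrow(de) < n) {
    warn_hd("only %d genes available; returning all as control genes", nrow(de))
    n <- nrow(de)
  }
  ord <- order(-de$p, abs(de$t_mod), de$gene_id)
  de$gene_id[ord][seq_len(n)]
}

#' Estimate unwanted-variation factors from control-gene residuals
#'
#' Fits the reduced model, restricts the residual matrix to the control
#' genes, and takes the first `k` sample-space singular vectors as
#' correcting variables (columns orthonormal), the residual-based reading of
#' remove-unwanted-variation factor estimation.
#'
#' @param expr gene x sample log2 expression.
#' @param reduced_design design matrix or `hd_design` of the reduced model.
#' @param control_genes gene ids to restrict residuals to.
#' @param k number of factors (default 5).
#' @return a `ruv_factors` list: `W` (samples x k, orthonormal), singular
#'   values `d`, `k`, `control_genes`.
#' @export
estimate_nuisance <- function(expr, reduced_design, control_genes, k = 5) {
  if (inherits(reduced_design, "hd_design")) reduced_design <- reduced_design$design
  if (k < 1 || k != round(k)) stop_hd("k must be a positive integer")
  miss <- setdiff(control_genes, rownames(expr))
  if (length(miss) > 0)
    stop_hd("%d control gene(s) absent from expression matrix", length(miss))
  n <- ncol(expr)
  rk <- qr(reduced_design)$rank
  if (k >= n - rk)
    stop_hd("k = %d exceeds admissible rank (n - rank(design) = %d)", k, n - rk)
  f <- stats::lm.fit(reduced_design, t(expr))
  E <- f$residuals[, control_genes, drop = FALSE]  # samples x genes
  if (max(abs(E)) < 1e-10)
    stop_hd("control-gene residuals are numerically zero; no unwanted variation to estimate")
  sv <- svd(E, nu = k, nv = 0)
  W <- sv$u[, seq_len(k), drop = FALSE]
  dimnames(W) <- list(colnames(expr), paste0("ruv", seq_len(k)))
  structure(list(W = W, d = sv$d, k = k, control_genes = control_genes),
            class = "ruv_factors")
}

# Newton solve of trigamma(x) = y, vectorized; used by the moderation prior
trigamma_inverse <- function(y) {
  out <- y
  hi <- y > 1e7
  out[hi] <- 1 / sqrt(y[hi])
  lo <- y < 1e-6
  out[lo] <- 1 / y[lo]
  mid <- !hi & !lo
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates a scaled inverse-chi-square prior for the gene-wise residual
#' variances by method-of-moments matching of the log sample variances to a
#' scaled F distribution, then shrinks each variance to the posterior
#' `(d0 s0^2 + d s^2_g) / (d0 + d)`. When the observed spread of log
#' variances does not exceed its pure-sampling expectation the prior degrees
#' of freedom are infinite and every posterior variance equals the prior
#' `s0^2` (taken as the geometric mean of the sample variances, so that the
#' all-equal case reproduces the common variance exactly).
#'
#' @param fit an `hd_fit`.
#' @param min_d0 lower safeguard on the prior degrees of freedom.
#' @return an `hd_moderation` list: the fit, `s2_prior`, `d0`, per-gene
#'   `s2_post`, total df `d0 + d`.
#' @export
moderate <- function(fit, min_d0 = 0.5) {
  s2 <- fit$sigma2
  d <- fit$df_resid
  ok <- s2 > 1e-300
  if (!any(ok)) stop_hd("all residual variances are zero; nothing to moderate")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z))
    s2_post <- rep(s02, length(s2))
  } else {
    d0 <- max(2 * trigamma_inverse(evar), min_d0)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  }
  structure(list(fit = fit, s2_prior = s02, d0 = d0, s2_post = s2_post,
                 df_total = d0 + d), class = "hd_moderation")
}

#' Test a contrast with moderated t-statistics
#'
#' @param moderation an `hd_moderation` (from [moderate()]).
#' @param contrast numeric contrast vector over the design columns; a named
#'   vector is matched to column names (and must cover all of them when
#'   named partially it is an error to reference unknown columns).
#' @param name contrast label stored in the table.
#' @return a DE table: `gene_id`, `contrast`, `log2fc`, `t_mod`, `p`, `fdr`
#'   (Benjamini-Hochberg within the contrast), `ave_expr`.
#' @export
test_contrast <- function(moderation, contrast, name = "contrast") {
  fit <- moderation$fit
  p_cols <- ncol(fit$coefficients)
  if (!is.null(names(contrast))) {
    unknown <- setdiff(names(contrast), colnames(fit$coefficients))
    if (length(unknown) > 0)
      stop_hd("contrast references unknown design column(s): %s",
              paste(unknown, collapse = ", "))
    cv <- stats::setNames(rep(0, p_cols), colnames(fit$coefficients))
    cv[names(contrast)] <- contrast
    contrast <- cv
  }
  if (length(contrast) != p_cols)
    stop_hd("contrast has length %d for %d design columns", length(contrast), p_cols)
  lfc <- drop(fit$coefficients %*% contrast)
  vu <- if (fit$shared_cov) {
    rep(drop(t(contrast) %*% fit$cov_unscaled %*% contrast), nrow(fit$coefficients))
  } else {
    apply(fit$cov_unscaled, 3, function(S) drop(t(contrast) %*% S %*% contrast))
  }
  se <- sqrt(moderation$s2_post * vu)
  t_mod <- ifelse(se > 0, lfc / se, 0)
  pval <- 2 * stats::pt(-abs(t_mod), df = moderation$df_total)
  data.frame(gene_id = fit$gene_ids, contrast = name, log2fc = lfc,
             t_mod = t_mod, p = pval, fdr = stats::p.adjust(pval, "BH"),
             ave_expr = fit$ave_expr, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Default configuration of the two-stage DE workflow
#'
#' @param ... overrides of the defaults listed below.
#' @return a named list of parameters.
#' @export
de_config <- function(...) {
  cfg <- list(
    onset_rule = "contralateral",
    cpm_filter = 1,
    n_control_genes = 2000,
    k_factors = 5,
    prior_count = 0.5,
    use_weights = TRUE,
    covariates = c("duration", "age", "rin", "library_size", "nuclei_per_mg", "pmi"),
    reduced_covariates = c("duration", "age"),
    fdr_threshold = 0.05
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop_hd("unknown de_config parameter(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Two-stage moderated differential-expression workflow
#'
#' Stage 1 fits the full means-model design (combined category plus clinical
#' covariates) on TMM-normalized log-CPM with precision weights and tests
#' the disease contrast; the least statistically different genes from that
#' contrast become negative controls. Stage 2 estimates `k` correcting
#' variables from the control-gene residuals of a reduced model, adds them
#' to the design, refits, and tests both the disease and the asymmetry
#' (severe vs moderate hemisphere) contrast with FDR control per contrast.
#' With `k_factors = 0` the workflow reduces to the single-stage fit.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample sheet; severity is derived if absent.
#' @param config a [de_config()] list.
#' @return an `hd_two_stage` list: final `de_disease` and `de_asymmetry`
#'   tables, `stage1` tables, `nuisance` factors, TMM `factors`, the
#'   filtered `logcpm`, final `design`, `fit`, `moderation`, `samples`, and
#'   `genes_kept`.
#' @export
run_two_stage <- function(counts, samples, config = de_config()) {
  check_count_matrix(counts)
  if (!"severity" %in% names(samples))
    samples <- derive_severity(samples, rule = config$onset_rule)
  validate_samples(samples, require_severity = TRUE)
  if (!setequal(colnames(counts), samples$sample_id))
    stop_hd("count columns and sample sheet disagree")
  counts <- counts[, samples$sample_id, drop = FALSE]

  # expression filter: CPM above threshold in at least min-group-size samples
  raw_cpm <- t(t(counts) / colSums(counts)) * 1e6
  min_group <- min(table(samples$status))
  keep <- rowSums(raw_cpm > config$cpm_filter) >= min_group
  message(sprintf("expression filter: %d of %d genes kept (CPM > %g in >= %d samples)",
                  sum(keep), nrow(counts), config$cpm_filter, min_group))
  if (sum(keep) < 20) stop_hd("fewer than 20 genes pass the expression filter")
  counts <- counts[keep, , drop = FALSE]

  nf <- tmm_factors(counts)
  y <- log_cpm(counts, nf, prior = config$prior_count)

  design1 <- build_design(samples, covariates = config$covariates)
  w1 <- if (isTRUE(config$use_weights))
    precision_weights(counts, design1, nf, prior = config$prior_count) else NULL
  fit1 <- fit_model(y, design1, weights = w1)
  mod1 <- moderate(fit1)
  de_d1 <- test_contrast(mod1, make_contrast(design1, "disease"), "disease")
  de_a1 <- test_contrast(mod1, make_contrast(design1, "asymmetry"), "asymmetry")

  # cap the factor count so both the SVD and the final fit keep residual df
  n_s <- nrow(samples)
  k_use <- 0
  if (config$k_factors > 0) {
    reduced <- build_design(samples, covariates = config$reduced_covariates)
    k_adm <- min(n_s - qr(reduced$design)$rank - 1,
                 n_s - ncol(design1$design) - 1)
    k_use <- min(config$k_factors, max(k_adm, 0))
    if (k_use < config$k_factors)
      warn_hd("k_factors reduced from %d to %d (small cohort)",
              config$k_factors, k_use)
  }
  if (k_use > 0) {
    ctrl <- select_least_different(de_d1, n = config$n_control_genes)
    ruv <- estimate_nuisance(y, reduced, ctrl, k = k_use)
    design2 <- build_design(samples, covariates = config$covariates, nuisance = ruv)
    w2 <- if (isTRUE(config$use_weights))
      precision_weights(counts, design2, nf, prior = config$prior_count) else NULL
    fit2 <- fit_model(y, design2, weights = w2)
    mod2 <- moderate(fit2)
    de_d2 <- test_contrast(mod2, make_contrast(design2, "disease"), "disease")
    de_a2 <- test_contrast(mod2, make_contrast(design2, "asymmetry"), "asymmetry")
    message(sprintf("stage 2: %d correcting variable(s) from %d control genes",
                    ruv$k, length(ctrl)))
  } else {
    if (config$k_factors > 0)
      warn_hd("no admissible correcting variables; using the single-stage fit")
    ruv <- NULL
    design2 <- design1; fit2 <- fit1; mod2 <- mod1
    de_d2 <- de_d1; de_a2 <- de_a1
  }
  structure(list(de_disease = de_d2, de_asymmetry = de_a2,
                 stage1 = list(de_disease = de_d1, de_asymmetry = de_a1,
                               design = design1),
                 nuisance = ruv, factors = nf, logcpm = y, design = design2,
                 fit = fit2, moderation = mod2, samples = samples,
                 genes_kept = rownames(counts), counts = counts,
                 config = config), class = "hd_two_stage")
}
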