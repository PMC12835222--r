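# Independent oracle implementations used to cross-check the package.
# These are deliberately written from the published definitions, not by
# calling the package's own code paths.

# Direct implementation of the trimmed weighted mean of M-values for one
# sample against a reference, following the published formula: M and A over
# genes positive in both libraries, double trim (mid-ranks), inverse
# asymptotic-variance weights, 2^weighted-mean.
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  out <- numeric(ncol(counts))
  for (i in seq_len(ncol(counts))) {
    o <- counts[, i] / lib[i]
    r <- counts[, ref] / lib[ref]
    keep <- counts[, i] > 0 & counts[, ref] > 0
    M <- log2(o[keep] / r[keep])
    A <- (log2(o[keep]) + log2(r[keep])) / 2
    w <- (lib[i] - counts[keep, i]) / (lib[i] * counts[keep, i]) +
      (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref])
    if (length(M) == 0 || max(abs(M)) < 1e-6) { out[i] <- 1; next }
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    out[i] <- 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  out / exp(mean(log(out)))
}

# step-up false discovery rate from first principles
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# per-gene weighted least squares through the normal equations
oracle_wls <- function(X, y, w = rep(1, length(y))) {
  W <- diag(w)
  solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
}

# principal angles (degrees) between the column spans of two matrices
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1)) * 180 / pi
}

# small cohort spec for fast tests
quick_spec <- function(...) {
  args <- list(n_pd_subjects = 8, n_ctrl_subjects = 6, n_genes = 300,
               seed = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_spec, args)
}

# engine configuration used for recovery benchmarks: the duration covariate
# is excluded because simulated duration carries no expression effect but is
# structurally confounded with diagnosis (controls have duration zero)
recovery_config <- function(...) {
  de_config(covariates = c("age", "rin", "library_size", "nuclei_per_mg", "pmi"),
            reduced_covariates = "age", ...)
}

# hand-built minimal sample sheet: one left/right pair per subject
make_sheet <- function(status, onset, sex = NULL) {
  n <- length(status)
  sex <- sex %||% rep_len(c("male", "female"), n)
  ids <- sprintf("s%02d", seq_len(n))
  data.frame(
    sample_id = as.vector(rbind(paste0(ids, "_L"), paste0(ids, "_R"))),
    subject_id = rep(ids, each = 2),
    hemisphere = rep(c("left", "right"), n),
    status = rep(status, each = 2),
    onset_side = rep(ifelse(status == "PD", onset, NA_character_), each = 2),
    sex = rep(sex, each = 2),
    age = rep(seq(60, 90, length.out = n), each = 2),
    duration = rep(ifelse(status == "PD", 10, 0), each = 2),
    rin = 7, library_size = 1e6, nuclei_per_mg = 1000, pmi = 10,
    braak = rep(ifelse(status == "PD", 3, 0), each = 2),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
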