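test_that("gene-wise fits equal the normal-equations oracle, weighted and not", {
  set.seed(11)
  n <- 12; p <- 4; G <- 50
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- paste0("x", 1:p)
  rownames(X) <- paste0("s", 1:n)
  Y <- matrix(rnorm(G * n), G, n, dimnames = list(paste0("g", 1:G), rownames(X)))
  W <- matrix(rgamma(G * n, 4, 4), G, n)

  fit <- fit_model(Y, X)
  fitw <- fit_model(Y, X, weights = W)
  for (g in c(1, 17, 50)) {
    expect_equal(fit$coefficients[g, ], drop(oracle_wls(X, Y[g, ])),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fitw$coefficients[g, ], drop(oracle_wls(X, Y[g, ], W[g, ])),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }

  # intercept-only design: coefficient is the gene mean; exact fit has zero
  # residual variance
  fit0 <- fit_model(Y, matrix(1, n, 1, dimnames = list(rownames(X), "mu")))
  expect_equal(drop(fit0$coefficients), rowMeans(Y), tolerance = 1e-12)
  Yexact <- matrix(rep(X[, 2], each = 2), 2, n, byrow = FALSE,
                   dimnames = list(c("a", "b"), rownames(X)))
  fex <- fit_model(Yexact, X[, 1:2])
  expect_equal(fex$sigma2, c(a = 0, b = 0), tolerance = 1e-20, ignore_attr = TRUE)

  # rank-deficient designs are refused with the collinear column named
  Xbad <- cbind(X, dup = X[, 2])
  expect_error(fit_model(Y, Xbad), "dup")
})

test_that("precision weights track the planted mean-variance trend", {
  set.seed(21)
  G <- 400; n <- 10
  X <- matrix(1, n, 1, dimnames = list(paste0("s", 1:n), "mu"))
  base <- seq(3, 12, length.out = G)

  # homoskedastic log-scale data: nearly constant weights
  counts_h <- matrix(round(2^(base + rnorm(G * n, 0, 0.3))), G, n,
                     dimnames = list(paste0("g", 1:G), rownames(X)))
  w_h <- precision_weights(counts_h, X)
  expect_lt(max(w_h) / min(w_h), 2)

  # decreasing mean-variance trend: weights increase with expression
  sds <- seq(1.0, 0.15, length.out = G)
  counts_t <- matrix(round(2^(base + rnorm(G * n, 0, rep(sds, n)))), G, n,
                     dimnames = dimnames(counts_h))
  w_t <- precision_weights(counts_t, X)
  lo <- mean(w_t[1:80, ]); hi <- mean(w_t[321:400, ])
  expect_gt(hi / lo, 3)

  expect_warning(precision_weights(counts_h[1:20, ], X), "fewer than 50")
})

test_that("least-different gene selection equals a brute-force sort", {
  toy <- data.frame(gene_id = paste0("g", 1:5), t_mod = c(.1, .2, .5, 2, 5),
                    p = c(.9, .8, .7, .2, .01))
  expect_equal(select_least_different(toy, 2), c("g1", "g2"))
  expect_equal(suppressWarnings(select_least_different(toy, 10)), toy$gene_id)

  set.seed(3)
  de <- data.frame(gene_id = sprintf("g%03d", 1:300),
                   t_mod = rnorm(300), p = runif(300))
  got <- select_least_different(de, 100)
  ord <- de[order(-de$p, abs(de$t_mod), de$gene_id), ]
  expect_equal(got, ord$gene_id[1:100])
})

test_that("nuisance factors recover planted sample-space structure", {
  set.seed(5)
  n <- 16; G <- 200
  X <- cbind(mu = 1, grp = rep(0:1, each = n / 2))
  rownames(X) <- paste0("s", 1:n)
  # rank-1 residual structure orthogonal to the design
  pat <- rnorm(n)
  pat <- drop(pat - X %*% solve(crossprod(X), crossprod(X, pat)))
  pat <- pat / sqrt(sum(pat^2))
  load <- rnorm(G)
  Y <- outer(rep(1, G), drop(X %*% c(5, 1))) + outer(load, pat) +
    matrix(rnorm(G * n, 0, 0.01), G, n)
  dimnames(Y) <- list(paste0("g", 1:G), rownames(X))
  ruv <- estimate_nuisance(Y, X, rownames(Y), k = 1)
  expect_gt(abs(cor(ruv$W[, 1], pat)), 0.999)

  # two planted factors, k = 2: subspace recovered within 10 degrees
  P2 <- qr.Q(qr(cbind(pat, rnorm(n))))
  L2 <- matrix(rnorm(G * 2), G, 2)
  Y2 <- outer(load, drop(X %*% c(1, 0))) + L2 %*% t(P2) +
    matrix(rnorm(G * n, 0, 0.05), G, n)
  dimnames(Y2) <- dimnames(Y)
  P2r <- apply(P2, 2, function(v)
    drop(v - X %*% solve(crossprod(X), crossprod(X, v))))
  ruv2 <- estimate_nuisance(Y2, X, rownames(Y2), k = 2)
  expect_lt(max(principal_angles(ruv2$W, P2r)), 10)

  expect_error(estimate_nuisance(Y, X, rownames(Y), k = n), "admissible")
  exact <- outer(rep(1, G), drop(X %*% c(5, 1)))
  dimnames(exact) <- dimnames(Y)
  expect_error(estimate_nuisance(exact, X, rownames(exact), k = 1), "zero")
})

test_that("moderation matches the equal-variance limit and brackets the variances", {
  set.seed(13)
  n <- 10
  X <- cbind(mu = 1, x = rnorm(n))
  rownames(X) <- paste0("s", 1:n)
  base <- rnorm(n)
  res0 <- drop(base - X %*% solve(crossprod(X), crossprod(X, base)))
  signs <- rep(c(1, -1), 25)
  Y <- outer(rep(1, 50), drop(X %*% c(2, 1))) + outer(signs, res0)
  dimnames(Y) <- list(paste0("g", 1:50), rownames(X))
  fit <- fit_model(Y, X)
  expect_lt(diff(range(fit$sigma2)), 1e-12)
  mod <- moderate(fit)
  expect_true(is.infinite(mod$d0))
  expect_equal(unname(mod$s2_post), rep(fit$sigma2[[1]], 50), tolerance = 1e-10)
  # moderated t equals the ordinary t computed with the common variance
  ct <- make_named <- setNames(c(0, 1), colnames(X))
  de <- test_contrast(mod, ct)
  vu <- drop(t(c(0, 1)) %*% chol2inv(chol(crossprod(X))) %*% c(0, 1))
  t_ord <- fit$coefficients[, "x"] / sqrt(fit$sigma2[[1]] * vu)
  expect_equal(de$t_mod, unname(t_ord), tolerance = 1e-8)

  # dispersed variances: posterior lies between gene and prior variance
  Y2 <- matrix(rnorm(200 * n, 0, rep(c(0.2, 3), each = 100)), 200, n,
               dimnames = list(paste0("g", 1:200), rownames(X)))
  m2 <- moderate(fit_model(Y2, X))
  expect_true(is.finite(m2$d0) && m2$d0 > 0)
  lo <- pmin(m2$fit$sigma2, m2$s2_prior)
  hi <- pmax(m2$fit$sigma2, m2$s2_prior)
  expect_true(all(m2$s2_post >= lo - 1e-12 & m2$s2_post <= hi + 1e-12))
})

test_that("moderated statistics agree with the reference empirical-Bayes implementation", {
  set.seed(19)
  n <- 14; G <- 300
  X <- cbind(a = rep(c(1, 0), each = 7), b = rep(c(0, 1), each = 7),
             x = rnorm(n))
  rownames(X) <- paste0("s", 1:n)
  Y <- matrix(rnorm(G * n, sd = rep(exp(rnorm(G, 0, .5)), n)), G, n,
              dimnames = list(paste0("g", 1:G), rownames(X)))
  mod <- moderate(fit_model(Y, X))
  de <- test_contrast(mod, c(-1, 1, 0))
  ref <- limma::eBayes(limma::contrasts.fit(limma::lmFit(Y, X), c(-1, 1, 0)))
  expect_equal(mod$d0, ref$df.prior, tolerance = 1e-10)
  expect_equal(mod$s2_prior, ref$s2.prior, tolerance = 1e-10)
  expect_equal(de$t_mod, unname(ref$t[, 1]), tolerance = 1e-10)
  expect_equal(de$p, unname(ref$p.value[, 1]), tolerance = 1e-10)
})

test_that("contrast testing handles zero contrasts, known effects, and BH", {
  set.seed(31)
  n <- 12
  X <- cbind(a = rep(c(1, 0), each = 6), b = rep(c(0, 1), each = 6))
  rownames(X) <- paste0("s", 1:n)
  delta <- 1.7
  Y <- outer(rep(1, 60), c(rep(0, 6), rep(delta, 6))) +
    matrix(rnorm(60 * n, 0, 0.01), 60, n)
  dimnames(Y) <- list(paste0("g", 1:60), rownames(X))
  mod <- moderate(fit_model(Y, X))

  zero <- test_contrast(mod, c(0, 0))
  expect_true(all(zero$log2fc == 0))
  expect_true(all(zero$p == 1))

  de <- test_contrast(mod, c(-1, 1), "delta")
  expect_equal(mean(de$log2fc), delta, tolerance = 0.01)

  expect_error(test_contrast(mod, setNames(1, "missing_col")), "missing_col")

  # Benjamini-Hochberg equals the hand-computed step-up values and the
  # brute-force oracle on random vectors
  expect_equal(p.adjust(c(.01, .02, .03, .9), "BH"), c(.04, .04, .04, .9))
  set.seed(77)
  for (i in 1:5) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("two-stage workflow: k = 0 equals single stage, gene permutation is equivariant, and no-batch fold changes agree across stages", {
  sim <- simulate_cohort(quick_spec(n_pd_subjects = 8, n_ctrl_subjects = 6,
                                    n_genes = 300, subject_sd = 0,
                                    n_batch_factors = 0, seed = 12))
  cfg0 <- recovery_config(k_factors = 0)
  r0 <- suppressMessages(run_two_stage(sim$counts, sim$samples, cfg0))
  expect_identical(r0$de_disease, r0$stage1$de_disease)

  cfg <- recovery_config(k_factors = 2, n_control_genes = 100)
  r <- suppressMessages(run_two_stage(sim$counts, sim$samples, cfg))
  eff <- r$de_disease$gene_id %in%
    sim$truth$genes$gene_id[sim$truth$genes$disease_lfc_true != 0]
  expect_gt(cor(r$stage1$de_disease$log2fc[eff], r$de_disease$log2fc[eff]), 0.95)

  # permuting gene rows permutes every per-gene output identically
  perm <- sample(nrow(sim$counts))
  rp <- suppressMessages(run_two_stage(sim$counts[perm, ], sim$samples, cfg))
  reord <- match(r$de_disease$gene_id, rp$de_disease$gene_id)
  expect_equal(rp$de_disease$log2fc[reord], r$de_disease$log2fc, tolerance = 1e-9)
  expect_equal(rp$de_disease$p[reord], r$de_disease$p, tolerance = 1e-9)
})

test_that("swapping severity labels negates asymmetry fold changes exactly", {
  sim <- simulate_cohort(quick_spec(n_pd_subjects = 8, n_ctrl_subjects = 6,
                                    n_genes = 250, seed = 14))
  cfg <- recovery_config(k_factors = 2, n_control_genes = 100)
  r <- suppressMessages(run_two_stage(sim$counts, sim$samples, cfg))
  flip <- sim$samples
  flip$severity <- ifelse(is.na(flip$severity), NA_character_,
                          ifelse(flip$severity == "severe", "moderate", "severe"))
  rf <- suppressMessages(run_two_stage(sim$counts, flip, cfg))
  expect_equal(rf$de_asymmetry$log2fc, -r$de_asymmetry$log2fc, tolerance = 1e-10)
  expect_equal(rf$de_asymmetry$p, r$de_asymmetry$p, tolerance = 1e-10)
})
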