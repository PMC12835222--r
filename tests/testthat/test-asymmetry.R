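test_that("z-scoring standardizes genes within scope and responds to scope changes", {
  sim <- simulate_cohort(quick_spec(n_genes = 150, disease_lfc = 1.5, seed = 21))
  y <- log_cpm(sim$counts, tmm_factors(sim$counts))
  z <- zscore_genes(y, sim$samples, scope = "PD_only")
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
  expect_equal(ncol(z), sum(sim$samples$status == "PD"))

  zall <- zscore_genes(y, sim$samples, scope = "all")
  dis <- sim$truth$genes$gene_id[sim$truth$genes$disease_lfc_true != 0][1]
  pd_cols <- colnames(z)
  # a disease gene shifts when controls enter the standardization scope
  expect_gt(max(abs(z[dis, ] - zall[dis, pd_cols])), 0.1)

  flat <- y; flat[3, ] <- 5
  expect_warning(zscore_genes(flat, sim$samples), "zero-SD")
})

test_that("subject scores summarize severe-minus-moderate z differences", {
  sheet <- derive_severity(make_sheet(c("PD", "PD"), c("right", "left")))
  z <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), sheet$sample_id))
  sc0 <- subject_asymmetry(z, sheet, paste0("g", 1:4))
  expect_true(all(sc0$score_mean == 0))
  expect_true(all(sc0$stratum == "tie"))

  # severe exceeds moderate by a constant: SD 0, mean = constant
  sev1 <- sheet$sample_id[sheet$subject_id == "s01" & sheet$severity == "severe"]
  z1 <- z; z1[, sev1] <- 0.8
  sc1 <- subject_asymmetry(z1, sheet, paste0("g", 1:4))
  r1 <- sc1[sc1$subject_id == "s01", ]
  expect_equal(r1$score_mean, 0.8)
  expect_equal(r1$score_sd, 0)
  expect_equal(r1$stratum, "higher_in_severe")

  # score invariance to gene-set order
  perm <- subject_asymmetry(z1, sheet, c("g3", "g1", "g4", "g2"))
  expect_equal(perm$score_mean, sc1$score_mean)

  expect_error(subject_asymmetry(z, sheet, c("nope1", "nope2")), "present")
})

test_that("stratification recovers planted directions and splits by sign", {
  scores <- data.frame(subject_id = c("a", "b", "c"),
                       score_mean = c(.5, -.2, 0), score_sd = 1,
                       n_genes = 8, gene_set = "m",
                       stratum = c("higher_in_severe", "higher_in_moderate", "tie"))
  st <- suppressWarnings(stratify(scores))
  expect_equal(st$higher_in_severe, "a")
  expect_equal(st$higher_in_moderate, "b")
  expect_equal(st$excluded, "c")
  expect_warning(stratify(scores[1, , drop = FALSE]), "empty")

  sp <- quick_spec(n_pd_subjects = 12, n_genes = 300, asym_lfc = 2,
                   frac_sign_flip_subjects = 0.5, dispersion = 0.05,
                   subject_sd = 0, n_batch_factors = 0, seed = 33)
  sim <- simulate_cohort(sp)
  y <- log_cpm(sim$counts, tmm_factors(sim$counts))
  z <- zscore_genes(y, sim$samples, "PD_only")
  sc <- subject_asymmetry(z, sim$samples, module_genes(sp)$primary)
  truth <- sim$truth$subjects
  dir_hat <- ifelse(sc$stratum == "higher_in_severe", 1, -1)
  expect_equal(dir_hat,
               truth$module_direction_true[match(sc$subject_id, truth$subject_id)])
})

test_that("flipping severity labels negates every score and swaps strata", {
  sim <- simulate_cohort(quick_spec(n_pd_subjects = 10,
                                    frac_sign_flip_subjects = 0.3, seed = 41))
  y <- log_cpm(sim$counts, tmm_factors(sim$counts))
  z <- zscore_genes(y, sim$samples, "PD_only")
  mod <- module_genes(quick_spec())$primary
  a <- subject_asymmetry(z, sim$samples, mod)
  flip <- sim$samples
  flip$severity <- ifelse(is.na(flip$severity), NA_character_,
                          ifelse(flip$severity == "severe", "moderate", "severe"))
  b <- subject_asymmetry(z, flip, mod)
  expect_equal(b$score_mean, -a$score_mean, tolerance = 1e-12)
  sa <- stratify(a); sb <- stratify(b)
  expect_equal(sb$higher_in_severe, sa$higher_in_moderate)
  expect_equal(sb$higher_in_moderate, sa$higher_in_severe)
})

test_that("null cohorts split 50/50 between strata", {
  hits <- 0; n_subj <- 0
  for (s in 1:6) {
    sim <- simulate_cohort(quick_spec(n_pd_subjects = 20, n_ctrl_subjects = 4,
                                      n_genes = 150, asym_lfc = 0,
                                      disease_lfc = 0, seed = 500 + s))
    y <- log_cpm(sim$counts, tmm_factors(sim$counts))
    z <- zscore_genes(y, sim$samples, "PD_only")
    sc <- subject_asymmetry(z, sim$samples, module_genes(quick_spec())$primary)
    hits <- hits + sum(sc$stratum == "higher_in_severe")
    n_subj <- n_subj + nrow(sc)
  }
  expect_gt(binom.test(hits, n_subj, 0.5)$p.value, 0.01)
})

test_that("module correlation reports cohesion and the alternative-member relation", {
  set.seed(51)
  n <- 40
  base <- rnorm(n)
  M <- rbind(m1 = base + rnorm(n, 0, .05), m2 = base + rnorm(n, 0, .05),
             m3 = base + rnorm(n, 0, .05))
  colnames(M) <- paste0("s", 1:n)

  # alternative identical to the primary mean: r = 1
  e1 <- rbind(M, alt = colMeans(M))
  r1 <- module_correlation(e1, c("m1", "m2", "m3"), "alt")
  expect_equal(r1$alt_r, 1, tolerance = 1e-12)
  expect_gt(r1$primary_mean_r, 0.9)

  # anti-correlated alternative: negative r and negative signed r-squared
  e2 <- rbind(M, alt = -colMeans(M) + rnorm(n, 0, .2))
  r2 <- module_correlation(e2, c("m1", "m2", "m3"), "alt")
  expect_lt(r2$alt_r, 0)
  expect_lt(r2$alt_r2_signed, 0)
  expect_equal(r2$alt_r2_signed, sign(r2$alt_r) * r2$alt_r^2)

  # generative anti-correlation is recovered from a low-noise cohort
  sp <- cohort_spec(n_pd_subjects = 24, n_ctrl_subjects = 2,
                    n_genes = 300, alt_member_anticorr = -0.6,
                    module_latent_sd = 1, dispersion = 0.02, subject_sd = 0,
                    n_batch_factors = 0, asym_lfc = 0, disease_lfc = 0, seed = 6)
  sim <- simulate_cohort(sp)
  y <- log_cpm(sim$counts, tmm_factors(sim$counts))
  pd <- sim$samples$sample_id[sim$samples$status == "PD"]
  mc <- module_correlation(y[, pd], module_genes(sp)$primary,
                           module_genes(sp)$alt, "log2cpm")
  expect_lt(abs(mc$alt_r - (-0.6)), 0.15)
})
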