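de_pair <- function(lfc_d, fdr_d, lfc_a, fdr_a) {
  g <- sprintf("g%02d", seq_along(lfc_d))
  list(d = data.frame(gene_id = g, contrast = "disease", log2fc = lfc_d,
                      t_mod = 1, p = fdr_d, fdr = fdr_d, ave_expr = 5),
       a = data.frame(gene_id = g, contrast = "asymmetry", log2fc = lfc_a,
                      t_mod = 1, p = fdr_a, fdr = fdr_a, ave_expr = 5))
}

test_that("a constructed table hits every class exactly as hand-assigned", {
  tp <- de_pair(
    lfc_d = c( 1.0, 1.0,  0.1, 1.0, 0.2, 0.0),
    fdr_d = c(.01, .01,  .50, .01, .50, .01),
    lfc_a = c( 0.8, -0.7, 0.9, 0.1, 0.3, 0.5),
    fdr_a = c(.01, .01,  .01, .50, .50, .01))
  tab <- classify_genes(tp$d, tp$a, fdr = 0.05, delta = 0.5)
  expect_equal(tab$class,
               c("both_same_direction", "both_opposite_direction",
                 "asym_only_differential", "disease_only_stable",
                 "neither", "both_tie"))
  expect_equal(nrow(tab), 6)  # classes partition the universe
  s <- attr(tab, "summary")
  expect_equal(s$frac_same_direction, 0.5)
  expect_equal(s$frac_opposite_direction, 0.5)
  expect_equal(s$n_direction_ties, 1)
})

test_that("no asymmetry significance yields no both_* or asym-only classes", {
  tp <- de_pair(c(1, -1, 0.3), c(.01, .5, .01), c(1, 1, 1), c(1, 1, 1))
  tab <- classify_genes(tp$d, tp$a)
  expect_false(any(grepl("^both|^asym", tab$class)))
  expect_error(classify_genes(tp$d[1:2, ], tp$a), "universes")
})

test_that("summary fractions equal brute-force counting on random tables", {
  set.seed(61)
  for (i in 1:200) {
    n <- 40
    tp <- de_pair(rnorm(n), runif(n), rnorm(n), runif(n))
    tab <- classify_genes(tp$d, tp$a, fdr = 0.3, delta = 0.5)
    s <- attr(tab, "summary")
    sd_ <- tp$d$fdr < 0.3; sa_ <- tp$a$fdr < 0.3
    same <- sum(sd_ & sa_ & sign(tp$d$log2fc) * sign(tp$a$log2fc) > 0)
    opp <- sum(sd_ & sa_ & sign(tp$d$log2fc) * sign(tp$a$log2fc) < 0)
    expect_equal(s$n_asym_significant, sum(sa_))
    expect_equal(s$frac_asym_also_disease,
                 if (any(sa_)) mean(sd_[sa_]) else NA_real_)
    if (same + opp > 0) {
      expect_equal(s$frac_same_direction, same / (same + opp))
      expect_equal(s$frac_opposite_direction, opp / (same + opp))
    }
    expect_equal(sum(unclass(s$class_counts)), n)
  }
})

test_that("classification respects monotonicity and asymmetry-sign swap", {
  set.seed(62)
  n <- 200
  tp <- de_pair(rnorm(n), runif(n), rnorm(n), runif(n))
  cls1 <- classify_genes(tp$d, tp$a, fdr = 0.05)
  cls2 <- classify_genes(tp$d, tp$a, fdr = 0.20)
  called <- function(tab) sum(tab$class != "neither")
  expect_gte(called(cls2), called(cls1))

  neg <- tp$a; neg$log2fc <- -neg$log2fc
  swap <- classify_genes(tp$d, neg, fdr = 0.2)
  base <- classify_genes(tp$d, tp$a, fdr = 0.2)
  expect_equal(swap$class == "both_same_direction",
               base$class == "both_opposite_direction")
  expect_equal(swap$class == "both_opposite_direction",
               base$class == "both_same_direction")
})

test_that("planted classes are recovered at strong effects", {
  sp <- cohort_spec(n_pd_subjects = 12, n_ctrl_subjects = 8, n_genes = 600,
                    disease_lfc = 2, asym_lfc = 2, dispersion = 0.05,
                    subject_sd = 0, n_batch_factors = 0, seed = 63)
  sim <- simulate_cohort(sp)
  r <- suppressMessages(run_two_stage(sim$counts, sim$samples,
                                      recovery_config(k_factors = 0)))
  tab <- classify_genes(r$de_disease, r$de_asymmetry, fdr = 0.05, delta = 0.5)
  tr <- sim$truth$genes
  tr <- tr[match(tab$gene_id, tr$gene_id), ]
  map <- c(both_concordant = "both_same_direction",
           both_discordant = "both_opposite_direction",
           asym_only = "asym_only_differential",
           disease_only = "disease_only_stable")
  eff <- tr$class_true %in% names(map)
  agree <- mean(tab$class[eff] == map[tr$class_true[eff]])
  expect_gt(agree, 0.85)
})

test_that("cross-dataset comparison maps orthologs and scores concordance", {
  human <- data.frame(gene_id = c("CCT2", "BEX1", "TCP1"),
                      direction = c(1, -1, 1))
  ext <- data.frame(gene_id = c("Cct2", "Bex1", "Tcp1"),
                    log2fc = c(0.5, 0.4, -1), fdr = c(.01, .2, .01))
  # empty map: empty intersection
  empty <- cross_dataset_compare(human, ext,
                                 ortholog_map = data.frame(human = character(),
                                                           external = character()))
  expect_equal(nrow(empty), 0)
  # case-insensitive symbol matching: full concordance when directions agree
  ext2 <- data.frame(gene_id = c("Cct2", "Bex1", "Tcp1"),
                     log2fc = c(1, -1, 1), fdr = c(.01, .01, .01))
  full <- cross_dataset_compare(human, ext2)
  expect_equal(nrow(full), 3)
  expect_true(all(full$concordant))
  s <- attr(full, "summary")
  expect_equal(s$n_sig_concordant, 3)

  mixed <- cross_dataset_compare(human, ext)
  expect_equal(sum(mixed$significant & !mixed$concordant), 1)  # Tcp1 flipped
})

test_that("a planted-down module is reported discordant with an up-in-severe human list", {
  tg <- simulate_twogroup(25, module_lfc = -2, seed = 71)
  grp <- factor(tg$samples$group, levels = c("non_aggregate", "aggregate"))
  X <- model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  rownames(X) <- tg$samples$sample_id
  y <- log_cpm(tg$counts, tmm_factors(tg$counts))
  mod <- moderate(fit_model(y, X))
  de <- test_contrast(mod, c(-1, 1), "aggregate_vs_non")
  human <- data.frame(gene_id = grep("^MOD", rownames(y), value = TRUE),
                      direction = 1)  # "up in severe"
  cmp <- cross_dataset_compare(human, de)
  expect_equal(attr(cmp, "summary")$n_sig_discordant, nrow(human))
})
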