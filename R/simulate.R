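#' Simulate a paired-hemisphere RNA-seq cohort with planted structure
#'
#' Draws gamma-Poisson (negative binomial) counts whose log2 mean for gene g
#' in sample s is
#' `base_g + subject_(g,j) + disease_g * isPD_s + 0.5 * asym_g * sevsign_s
#'  (* direction_j for module genes) + module latent + batch loadings * factors`,
#' plus a log-normal library-depth offset. Every subject contributes exactly
#' one left and one right sample; PD subjects carry a side-of-onset label
#' from which severity is derived with the same onset rule the analysis
#' uses. Identical `(spec, seed)` gives bit-identical output; each subject's
#' random-effect and count draws come from a counter-based substream so they
#' do not change when the cohort grows.
#'
#' @param spec a [cohort_spec()].
#' @param onset_sides optional named character vector (per PD subject id)
#'   overriding the sampled onset sides; used to study label inversions.
#' @return list with `counts` (gene x sample integer matrix), `samples`
#'   (sample sheet with derived severity) and `truth` (a `sim_truth` list:
#'   per-gene classes and effects, per-sample factors, per-subject module
#'   directions, batch loadings, and the planted per-sample asymmetry shift
#'   matrix).
#' @export
simulate_cohort <- function(spec, onset_sides = NULL) {
  validate_cohort_spec(spec)
  G <- spec$n_genes
  mod <- module_genes(spec)
  gene_ids <- c(mod$primary, mod$alt,
                sprintf("G%05d", seq_len(G - spec$module_size - 1)))
  n_mod <- spec$module_size + 1

  glob <- with_seed(spec$seed, {
    base <- stats::rnorm(G, spec$base_log2_mean, spec$base_log2_sd)

    # gene allocation: module genes first, then both/asym-only/disease-only
    n_asym_total <- round(spec$frac_asym_genes * G)
    n_asym_only <- round(spec$frac_asym_only_genes * G)
    n_both <- max(n_asym_total - n_asym_only, 0)
    n_dis_only <- max(round(spec$frac_disease_genes * G) - n_both, 0)
    if (n_mod + n_both + n_asym_only + n_dis_only > G)
      stop_hd("invalid cohort spec: effect-gene fractions exceed available genes")
    rest <- setdiff(seq_len(G), seq_len(n_mod))
    idx_both <- rest[seq_len(n_both)]
    idx_asym <- rest[n_both + seq_len(n_asym_only)]
    idx_dis <- rest[n_both + n_asym_only + seq_len(n_dis_only)]

    disease_lfc_true <- numeric(G)
    asym_lfc_true <- numeric(G)
    sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
    disease_lfc_true[idx_both] <- spec$disease_lfc * sgn(n_both)
    asym_lfc_true[idx_both] <- spec$asym_lfc * sgn(n_both)
    disease_lfc_true[idx_dis] <- spec$disease_lfc * sgn(n_dis_only)
    asym_lfc_true[idx_asym] <- spec$asym_lfc * sgn(n_asym_only)
    asym_lfc_true[seq_len(spec$module_size)] <- spec$asym_lfc
    asym_lfc_true[n_mod] <- spec$asym_lfc * spec$alt_member_anticorr

    class_true <- rep("null", G)
    class_true[seq_len(spec$module_size)] <- "module_primary"
    class_true[n_mod] <- "module_alt"
    class_true[idx_both] <- ifelse(
      sign(disease_lfc_true[idx_both]) == sign(asym_lfc_true[idx_both]) |
        spec$disease_lfc == 0 | spec$asym_lfc == 0,
      "both_concordant", "both_discordant")
    if (spec$disease_lfc == 0) class_true[c(idx_both, idx_dis)] <- "null"
    if (spec$asym_lfc == 0) {
      class_true[idx_asym] <- "null"
      class_true[idx_both] <- if (spec$disease_lfc == 0) "null" else "disease_only"
    }
    if (spec$disease_lfc != 0) class_true[idx_dis] <- "disease_only"
    if (spec$asym_lfc != 0) class_true[idx_asym] <- "asym_only"

    # subjects
    pd_ids <- sprintf("pd%02d", seq_len(spec$n_pd_subjects))
    ctrl_ids <- sprintf("ct%02d", seq_len(spec$n_ctrl_subjects))
    subj_ids <- c(pd_ids, ctrl_ids)
    status <- rep(c("PD", "control"), c(spec$n_pd_subjects, spec$n_ctrl_subjects))
    # designed, balanced cohort composition: sex alternates within each
    # status group and onset side alternates within each sex, emulating a
    # case series selected for balance rather than an iid draw
    sex <- unlist(lapply(c(spec$n_pd_subjects, spec$n_ctrl_subjects),
                         function(n) rep_len(c("male", "female"), n)))
    n_bil <- round(spec$frac_bilateral * spec$n_pd_subjects)
    bil <- seq_len(spec$n_pd_subjects)[sample.int(spec$n_pd_subjects, n_bil)]
    onset <- rep(NA_character_, length(subj_ids))
    for (sx in c("male", "female")) {
      idx <- which(status == "PD" & sex == sx)
      onset[idx] <- rep_len(c("left", "right"), length(idx))
    }
    onset[bil] <- "bilateral"
    uni_pd <- which(status == "PD" & onset != "bilateral")
    direction <- rep(1, length(subj_ids))
    n_flip <- round(spec$frac_sign_flip_subjects * length(uni_pd))
    direction[uni_pd[sample.int(length(uni_pd), n_flip)]] <- -1

    # per-subject clinical covariates
    age <- round(stats::rnorm(length(subj_ids), 76, 8))
    duration <- ifelse(status == "PD", pmax(stats::rnorm(length(subj_ids), 12, 6), 1), 0)
    pmi <- pmax(stats::rnorm(length(subj_ids), 12, 4), 2)
    braak <- ifelse(status == "PD",
                    pmin(pmax(stats::rnorm(length(subj_ids), 2.5, 1), 1.5), 6), 0)

    # per-sample quantities (2 samples per subject: left then right)
    S <- 2 * length(subj_ids)
    rin <- pmin(pmax(stats::rnorm(S, 7, 0.5), 4), 10)
    nuclei <- pmax(stats::rnorm(S, 1000, 150), 200)
    depth <- exp(stats::rnorm(S, 0, spec$libsize_log_sd))
    # module co-regulation is an individual-level trait: both hemispheres
    # share the latent, so it cancels exactly in severe - moderate contrasts
    u <- rep(stats::rnorm(length(subj_ids), 0, spec$module_latent_sd), each = 2)
    v <- rep(stats::rnorm(length(subj_ids), 0, spec$module_latent_sd), each = 2)
    fac <- if (spec$n_batch_factors > 0)
      matrix(stats::rnorm(S * spec$n_batch_factors), S, spec$n_batch_factors)
    else matrix(0, S, 0)
    loadings <- if (spec$n_batch_factors > 0)
      matrix(stats::rnorm(G * spec$n_batch_factors, 0, spec$batch_sd),
             G, spec$n_batch_factors)
    else matrix(0, G, 0)
    list(base = base, disease_lfc_true = disease_lfc_true,
         asym_lfc_true = asym_lfc_true, class_true = class_true,
         subj_ids = subj_ids, status = status, sex = sex, onset = onset,
         direction = direction, age = age, duration = duration, pmi = pmi,
         braak = braak, rin = rin, nuclei = nuclei, depth = depth,
         u = u, v = v, fac = fac, loadings = loadings)
  })

  if (!is.null(onset_sides)) {
    idx <- match(names(onset_sides), glob$subj_ids)
    if (anyNA(idx)) stop_hd("onset_sides names unknown subject id(s)")
    glob$onset[idx] <- unname(onset_sides)
  }

  subj_of_sample <- rep(seq_along(glob$subj_ids), each = 2)
  hemi <- rep(c("left", "right"), length(glob$subj_ids))
  sample_ids <- paste(glob$subj_ids[subj_of_sample], ifelse(hemi == "left", "L", "R"),
                      sep = "_")
  samples <- data.frame(
    sample_id = sample_ids,
    subject_id = glob$subj_ids[subj_of_sample],
    hemisphere = hemi,
    status = glob$status[subj_of_sample],
    onset_side = ifelse(glob$status[subj_of_sample] == "PD",
                        glob$onset[subj_of_sample], NA_character_),
    sex = glob$sex[subj_of_sample],
    age = glob$age[subj_of_sample],
    duration = round(glob$duration[subj_of_sample], 2),
    rin = round(glob$rin, 2),
    library_size = NA_real_,
    nuclei_per_mg = round(glob$nuclei, 1),
    pmi = round(glob$pmi[subj_of_sample], 2),
    braak = round(glob$braak[subj_of_sample], 1),
    stringsAsFactors = FALSE
  )
  samples <- derive_severity(samples, rule = spec$onset_rule)
  sevsign <- ifelse(is.na(samples$severity), 0,
                    ifelse(samples$severity == "severe", 1, -1))

  # planted per-sample asymmetry shift (log2)
  S <- nrow(samples)
  asym_shift <- outer(glob$asym_lfc_true, 0.5 * sevsign)
  mod_rows <- seq_len(spec$module_size + 1)
  dir_s <- glob$direction[subj_of_sample]
  asym_shift[mod_rows, ] <- asym_shift[mod_rows, , drop = FALSE] *
    rep(dir_s, each = length(mod_rows))

  eta <- matrix(glob$base, G, S) + asym_shift +
    outer(glob$disease_lfc_true, as.numeric(samples$status == "PD"))
  rho <- spec$alt_member_anticorr
  eta[seq_len(spec$module_size), ] <- eta[seq_len(spec$module_size), , drop = FALSE] +
    rep(glob$u, each = spec$module_size)
  eta[spec$module_size + 1, ] <- eta[spec$module_size + 1, ] +
    rho * glob$u + sqrt(max(1 - rho^2, 0)) * glob$v
  if (ncol(glob$fac) > 0) eta <- eta + glob$loadings %*% t(glob$fac)

  rel <- 2^eta
  mu <- rel * rep(spec$target_libsize * glob$depth / sum(2^glob$base), each = G)

  counts <- matrix(0L, G, S, dimnames = list(gene_ids, sample_ids))
  size <- 1 / spec$dispersion
  for (j in seq_along(glob$subj_ids)) {
    cols <- which(subj_of_sample == j)
    counts[, cols] <- with_seed(sub_seed(spec$seed, j), {
      subj_eff <- if (spec$subject_sd > 0)
        stats::rnorm(G, 0, spec$subject_sd) else numeric(G)
      m <- mu[, cols, drop = FALSE] * 2^subj_eff
      matrix(stats::rnbinom(length(m), mu = m, size = size), G, length(cols))
    })
  }
  samples$library_size <- colSums(counts)

  truth <- structure(list(
    genes = data.frame(gene_id = gene_ids, class_true = glob$class_true,
                       disease_lfc_true = glob$disease_lfc_true,
                       asym_lfc_true = glob$asym_lfc_true,
                       stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_ids,
                         depth_factor = glob$depth,
                         module_latent = glob$u,
                         stringsAsFactors = FALSE),
    batch_factors = `dimnames<-`(glob$fac,
                                 list(sample_ids,
                                      if (ncol(glob$fac) > 0)
                                        paste0("batch", seq_len(ncol(glob$fac)))
                                      else NULL)),
    batch_loadings = `dimnames<-`(glob$loadings,
                                  list(gene_ids,
                                       if (ncol(glob$loadings) > 0)
                                         paste0("batch", seq_len(ncol(glob$loadings)))
                                       else NULL)),
    subjects = data.frame(subject_id = glob$subj_ids, status = glob$status,
                          sex = glob$sex, onset_side = glob$onset,
                          module_direction_true = glob$direction,
                          stringsAsFactors = FALSE),
    asym_shift = `dimnames<-`(asym_shift, list(gene_ids, sample_ids)),
    spec = spec), class = "sim_truth")

  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate a small two-group dataset (aggregate vs non-aggregate neurons)
#'
#' Emulates the structure of the external cross-validation input: two
#' labelled groups of libraries where the module genes are shifted by
#' `module_lfc` in the `"aggregate"` group.
#'
#' @param n_cells_per_group libraries per group (>= 2).
#' @param module_lfc log2 shift of module genes in the aggregate group.
#' @param seed integer seed.
#' @param n_genes,module_size,dispersion generator knobs.
#' @return list with `counts` and `samples` (`sample_id`, `group`).
#' @export
simulate_twogroup <- function(n_cells_per_group, module_lfc, seed,
                              n_genes = 300, module_size = 8, dispersion = 0.3) {
  if (!is.numeric(n_cells_per_group) || n_cells_per_group < 2 ||
      n_cells_per_group != round(n_cells_per_group))
    stop_hd("n_cells_per_group must be an integer >= 2")
  gene_ids <- c(sprintf("MOD%02d", seq_len(module_size)),
                sprintf("G%05d", seq_len(n_genes - module_size)))
  S <- 2 * n_cells_per_group
  group <- rep(c("aggregate", "non_aggregate"), each = n_cells_per_group)
  sample_ids <- sprintf("cell%03d", seq_len(S))
  with_seed(seed, {
    base <- stats::rnorm(n_genes, 4, 1.5)
    eta <- matrix(base, n_genes, S)
    eta[seq_len(module_size), group == "aggregate"] <-
      eta[seq_len(module_size), group == "aggregate"] + module_lfc
    mu <- 2^eta
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     n_genes, S, dimnames = list(gene_ids, sample_ids))
    list(counts = counts,
         samples = data.frame(sample_id = sample_ids, group = group,
                              stringsAsFactors = FALSE))
  })
}

#' Write simulator outputs as plain-text tables
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param format count-matrix format, `"tsv"` or `"mtx"`.
#' @return paths of the written files, invisibly.
#' @export
write_cohort <- function(sim, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- file.path(dir, if (format == "tsv") "counts.tsv.gz" else "counts.mtx")
  write_counts(sim$counts, cpath, format = format)
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  write_tsv_file(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv_file(sim$truth$subjects, file.path(dir, "truth_subjects.tsv"))
  write_tsv_file(
    data.frame(sim$truth$samples, sim$truth$batch_factors, check.names = FALSE),
    file.path(dir, "truth_samples.tsv"))
  invisible(c(cpath, file.path(dir, c("samples.tsv", "truth_genes.tsv",
                                      "truth_subjects.tsv", "truth_samples.tsv"))))
}
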