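SAMPLE_COLUMNS <- c("sample_id", "subject_id", "hemisphere", "status", "onset_side",
                    "sex", "age", "duration", "rin", "library_size",
                    "nuclei_per_mg", "pmi", "braak")

#' Validate a sample sheet
#'
#' Checks the paired left/right structure: every subject contributes exactly
#' one left and one right sample, control samples carry no onset side, and —
#' when a `severity` column is present — every unilateral-onset PD subject
#' has exactly one severe and one moderate hemisphere.
#'
#' @param samples data.frame with the columns documented in
#'   [read_sample_table()].
#' @param require_severity require a fully derived `severity` column.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_samples <- function(samples, require_severity = FALSE) {
  missing <- setdiff(SAMPLE_COLUMNS, names(samples))
  if (length(missing) > 0)
    stop_hd("sample sheet missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop_hd("duplicate sample_id(s): %s",
            paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  if (!all(samples$hemisphere %in% c("left", "right")))
    stop_hd("hemisphere must be 'left' or 'right'")
  if (!all(samples$status %in% c("PD", "control")))
    stop_hd("status must be 'PD' or 'control'")
  bad_subj <- names(Filter(function(h) !setequal(h, c("left", "right")) || length(h) != 2,
                           split(samples$hemisphere, samples$subject_id)))
  if (length(bad_subj) > 0)
    stop_hd("subject(s) without exactly one left and one right sample: %s",
            paste(bad_subj, collapse = ", "))
  ctrl_onset <- samples$status == "control" & !is.na(samples$onset_side)
  if (any(ctrl_onset))
    stop_hd("control sample(s) with a non-NA onset_side: %s",
            paste(samples$sample_id[ctrl_onset], collapse = ", "))
  if (require_severity || "severity" %in% names(samples)) {
    if (!"severity" %in% names(samples))
      stop_hd("severity column required but absent; run derive_severity() first")
    uni <- samples$status == "PD" & samples$onset_side %in% c("left", "right")
    counts <- table(samples$subject_id[uni], samples$severity[uni])
    if (any(uni)) {
      bad <- rownames(counts)[counts[, "severe", drop = TRUE] != 1 |
                                counts[, "moderate", drop = TRUE] != 1]
      if (length(bad) > 0)
        stop_hd("unilateral PD subject(s) without one severe and one moderate sample: %s",
                paste(bad, collapse = ", "))
    }
    if (any(samples$status == "control" & !is.na(samples$severity)))
      stop_hd("control samples must have severity NA")
  }
  invisible(samples)
}

#' Derive severe/moderate hemisphere labels from the side of symptom onset
#'
#' Dopaminergic degeneration in Parkinson's disease is more pronounced in the
#' hemisphere contralateral to the side of motor symptom onset, so under the
#' default rule a right-onset subject's left hemisphere is labelled severe.
#' The `ipsilateral` rule swaps the labels exactly; it is provided because
#' clinical sheets differ in whether they record the onset side of the body
#' or of the brain. Bilateral-onset subjects receive `NA` severity and are
#' excluded from asymmetry contrasts downstream; control samples are always
#' `NA`.
#'
#' @param samples sample sheet (see [read_sample_table()]).
#' @param rule `"contralateral"` (default) or `"ipsilateral"`.
#' @return the sample sheet with a `severity` column in
#'   `{"severe", "moderate", NA}`.
#' @export
derive_severity <- function(samples, rule = c("contralateral", "ipsilateral")) {
  rule <- match.arg(rule)
  validate_samples(samples[setdiff(names(samples), "severity")])
  pd <- samples$status == "PD"
  no_onset <- pd & (is.na(samples$onset_side) |
                      !samples$onset_side %in% c("left", "right", "bilateral"))
  if (any(no_onset))
    stop_hd("PD sample(s) missing onset_side: %s",
            paste(samples$sample_id[no_onset], collapse = ", "))
  sev <- rep(NA_character_, nrow(samples))
  uni <- pd & samples$onset_side %in% c("left", "right")
  opposite <- samples$hemisphere[uni] != samples$onset_side[uni]
  severe <- if (rule == "contralateral") opposite else !opposite
  sev[uni] <- ifelse(severe, "severe", "moderate")
  samples$severity <- sev
  attr(samples, "onset_rule") <- rule
  validate_samples(samples, require_severity = TRUE)
  samples
}

#' Build the combined-category design factor
#'
#' Each sample is labelled with the concatenation of its design-relevant
#' categorical covariates: `status.sex.onset_side.hemisphere` for PD samples
#' and the reduced `status.sex.hemisphere` for controls (whose onset side is
#' undefined). The resulting factor is the means-model (`~ 0 + category`)
#' term of the differential-expression design.
#'
#' @param samples sample sheet with severity derived.
#' @return a factor of length `nrow(samples)`.
#' @export
build_combined_category <- function(samples) {
  validate_samples(samples)
  need <- c("sex", "hemisphere")
  for (col in need) {
    if (anyNA(samples[[col]]))
      stop_hd("NA in required field '%s' for sample(s): %s", col,
              paste(samples$sample_id[is.na(samples[[col]])], collapse = ", "))
  }
  pd <- samples$status == "PD"
  if (any(pd & is.na(samples$onset_side)))
    stop_hd("NA onset_side for PD sample(s): %s",
            paste(samples$sample_id[pd & is.na(samples$onset_side)], collapse = ", "))
  lab <- ifelse(pd,
                paste(samples$status, samples$sex, samples$onset_side,
                      samples$hemisphere, sep = "."),
                paste(samples$status, samples$sex, samples$hemisphere, sep = "."))
  factor(lab)
}
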