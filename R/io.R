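#' Read a gene-by-sample count matrix
#'
#' Supports two plain-text layouts: a TSV with a header row of sample ids and
#' a first column named `gene_id`, or a MatrixMarket triplet file accompanied
#' by `<path>.genes` and `<path>.samples` index files (one id per line), the
#' layout written by [write_counts()].
#'
#' @param path path to the TSV (optionally gzipped) or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @return an integer-valued matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_hd("count file does not exist: %s", path)
  if (format == "tsv") {
    df <- read_tsv_file(path)
    if (ncol(df) < 2 || names(df)[1] != "gene_id")
      stop_hd("count TSV must have a first column named 'gene_id': %s", path)
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes))
      stop_hd("duplicate gene id(s) in %s: %s", path,
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m)))
      stop_hd("duplicate sample id(s) in %s", path)
    storage.mode(m) <- "double"
    rownames(m) <- genes
  } else {
    m <- as.matrix(Matrix::readMM(path))
    gfile <- paste0(path, ".genes")
    sfile <- paste0(path, ".samples")
    if (!file.exists(gfile) || !file.exists(sfile))
      stop_hd("missing index files %s / %s for MTX counts", gfile, sfile)
    rownames(m) <- readLines(gfile)
    colnames(m) <- readLines(sfile)
    if (anyDuplicated(rownames(m)))
      stop_hd("duplicate gene id(s) in %s", gfile)
    if (anyDuplicated(colnames(m)))
      stop_hd("duplicate sample id(s) in %s", sfile)
  }
  bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 5), 1, function(ij)
      sprintf("%s x %s = %s", rownames(m)[ij[1]], colnames(m)[ij[2]], m[ij[1], ij[2]]))
    stop_hd("non-integer or negative count entries (%d total), e.g. %s",
            nrow(bad), paste(cells, collapse = "; "))
  }
  m <- round(m)
  check_count_matrix(m)
  m
}

#' Write a count matrix as TSV or MatrixMarket
#'
#' The TSV rendering is canonical (UTF-8, header row of sample ids, first
#' column `gene_id`) so that write then read is an exact round trip. A path
#' ending in `.gz` is gzip-compressed.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param path output path (`.mtx` for MatrixMarket).
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  check_count_matrix(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv_file(df, path)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes"))
    writeLines(colnames(counts), paste0(path, ".samples"))
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT dialect: set name, description, then member
#' gene ids. Member order is preserved.
#'
#' @param path path to the GMT file.
#' @return a `gene_set_collection`: a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_hd("GMT file does not exist: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop_hd("GMT line %d has %d field(s); need name, description, >=1 member",
              i, length(fields))
    nm <- fields[1]
    if (nm %in% names(sets)) stop_hd("duplicate gene-set name '%s' (line %d)", nm, i)
    sets[[nm]] <- fields[-(1:2)]
    desc[nm] <- fields[2]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors (or `gene_set_collection`).
#' @param path output path.
#' @param descriptions optional named descriptions; defaults to the set name.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Sum technical replicate libraries into samples
#'
#' @param counts gene x library count matrix.
#' @param replicate_map named list: output sample id -> character vector of
#'   library ids (columns of `counts`). Every library must appear in exactly
#'   one group; libraries absent from the map are dropped.
#' @return gene x sample matrix with replicate libraries summed per gene.
#' @export
combine_technical_replicates <- function(counts, replicate_map) {
  check_count_matrix(counts, "counts")
  libs <- unlist(replicate_map, use.names = FALSE)
  dup <- unique(libs[duplicated(libs)])
  if (length(dup) > 0)
    stop_hd("library id(s) mapped to more than one sample: %s",
            paste(dup, collapse = ", "))
  missing <- setdiff(libs, colnames(counts))
  if (length(missing) > 0)
    stop_hd("library id(s) not present in counts: %s", paste(missing, collapse = ", "))
  out <- vapply(replicate_map, function(l)
    rowSums(counts[, l, drop = FALSE]), numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  colnames(out) <- names(replicate_map)
  out
}

#' Read a sample sheet TSV
#'
#' Expects the clinical column layout used throughout the pipeline:
#' `sample_id`, `subject_id`, `hemisphere`, `status`, `onset_side`, `sex`,
#' `age`, `duration`, `rin`, `library_size`, `nuclei_per_mg`, `pmi`, `braak`
#' and optionally a derived `severity` column.
#'
#' @param path path to the TSV.
#' @return a data.frame, validated by [validate_samples()].
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop_hd("sample sheet does not exist: %s", path)
  df <- read_tsv_file(path)
  validate_samples(df)
}

#' @rdname read_sample_table
#' @param samples sample table to write.
#' @export
write_sample_table <- function(samples, path) {
  write_tsv_file(samples, path)
}
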