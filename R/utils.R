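# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hd <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_hd <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, then restores the caller's RNG state, so that
#' seeded draws inside the package never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# counter-based substream: deterministic child seed, kept below 2^31 - 1
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

# canonical TSV writer: UTF-8, tab-separated, header, no quoting
write_tsv_file <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# assert a gene x sample count matrix is well formed
check_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts)) stop_hd("%s must be a matrix", what)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_hd("%s must have gene rownames and sample colnames", what)
  if (anyDuplicated(rownames(counts)))
    stop_hd("duplicate gene ids in %s: %s", what,
            paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_hd("duplicate sample ids in %s: %s", what,
            paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_hd("%s contains negative or non-finite entries", what)
  invisible(counts)
}
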