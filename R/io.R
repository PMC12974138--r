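# Tabular I/O: feature tables, taxonomy and sample metadata as TSV.
# Dialect: tab-separated, UTF-8, '#' comment lines ignored, first column = ID.
# Feature tables carry taxa as columns; a transposed file is auto-detected by
# ID overlap with supplied metadata and flipped with a warning.

METADATA_REQUIRED <- c("sample_id", "subject", "treatment", "timepoint")
TREATMENTS <- c("CON", "DF")
TIMEPOINTS <- c("G0", "G30", "G90", "G109", "L3", "L14")

#' Read a count, taxonomy or metadata table from TSV
#'
#' All three study tables share one dialect: tab-separated UTF-8 with a
#' header row, `#` comment lines ignored, first column the record ID.
#'
#' @param path file path.
#' @param kind one of `"counts"`, `"taxonomy"`, `"metadata"`.
#' @param metadata optional metadata tibble used to auto-detect a transposed
#'   feature table (taxa in rows) by sample-ID overlap.
#' @return a tibble. Counts: `sample_id` + one integer column per taxon.
#'   Taxonomy: `taxon_id`, `lineage`. Metadata: `sample_id`, `subject`,
#'   `treatment`, `timepoint` and any outcome columns.
#' @export
read_table <- function(path, kind = c("counts", "taxonomy", "metadata"),
                       metadata = NULL) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  switch(kind,
    counts = validate_counts_df(df, metadata = metadata),
    taxonomy = validate_taxonomy_df(df),
    metadata = validate_metadata_df(df)
  )
}

#' Write a table to TSV
#'
#' @param x tibble as produced by [read_table()] or the simulator.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

validate_counts_df <- function(df, metadata = NULL) {
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  # transposed input: first column holds taxa, header holds sample IDs
  if (!is.null(metadata)) {
    ids <- as.character(metadata$sample_id)
    col_overlap <- mean(names(df)[-1] %in% ids)
    row_overlap <- mean(df$sample_id %in% ids)
    if (col_overlap > row_overlap && col_overlap > 0.5) {
      warn("feature table appears transposed (taxa in rows); flipping")
      m <- as.matrix(df[, -1])
      rownames(m) <- df$sample_id
      df <- as_count_tibble(t(m))
    }
  }
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample IDs in feature table", class = "gutstab_duplicate_id")
  }
  m <- suppressWarnings(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    abort("non-numeric count cells", class = "gutstab_noninteger_count")
  }
  check_integer_counts(m)
  if (any(m < 0)) abort("negative counts", class = "gutstab_bad_counts")
  df[, -1] <- as.data.frame(m)
  tibble::as_tibble(df)
}

validate_taxonomy_df <- function(df) {
  names(df)[1:2] <- c("taxon_id", "lineage")
  df$taxon_id <- as.character(df$taxon_id)
  if (anyDuplicated(df$taxon_id)) {
    abort("duplicate taxon IDs in taxonomy", class = "gutstab_duplicate_id")
  }
  tibble::as_tibble(df)
}

validate_metadata_df <- function(df) {
  names(df)[1] <- "sample_id"
  missing <- setdiff(METADATA_REQUIRED, names(df))
  if (length(missing)) {
    abort(paste("metadata missing mandatory column(s):",
                paste(missing, collapse = ", ")),
          class = "gutstab_missing_metadata")
  }
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample IDs in metadata", class = "gutstab_duplicate_id")
  }
  bad_trt <- setdiff(unique(df$treatment), TREATMENTS)
  if (length(bad_trt)) {
    abort(paste("unknown treatment label(s):", paste(bad_trt, collapse = ", ")),
          class = "gutstab_missing_metadata")
  }
  df$sample_id <- as.character(df$sample_id)
  tibble::as_tibble(df)
}
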