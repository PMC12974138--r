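# Internal helpers shared across modules.

# A count table travels as a wide tibble: first column `sample_id`,
# remaining columns one per taxon, non-negative integer cells.

#' Convert a wide count tibble to an integer matrix
#'
#' @param table data frame with a `sample_id` column and one numeric column
#'   per taxon.
#' @return numeric matrix, samples in rows (rownames = sample IDs).
#' @keywords internal
#' @noRd
as_count_matrix <- function(table) {
  stopifnot(is.data.frame(table))
  if (!"sample_id" %in% names(table)) {
    abort("count table must have a 'sample_id' column", class = "gutstab_bad_table")
  }
  ids <- as.character(table$sample_id)
  if (anyDuplicated(ids)) {
    abort("duplicate sample IDs in count table", class = "gutstab_duplicate_id")
  }
  m <- as.matrix(table[setdiff(names(table), "sample_id")])
  if (anyDuplicated(colnames(m))) {
    abort("duplicate taxon IDs in count table", class = "gutstab_duplicate_id")
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0)) {
    abort("counts must be non-negative and non-missing", class = "gutstab_bad_counts")
  }
  rownames(m) <- ids
  m
}

# inverse of as_count_matrix
as_count_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "sample_id")
}

check_integer_counts <- function(m) {
  if (any(abs(m - round(m)) > 1e-8)) {
    abort("counts must be integers", class = "gutstab_noninteger_count")
  }
  invisible(m)
}

# One global seed expands to per-stage child seeds by fixed arithmetic so
# stages can be rerun independently. Kept below 2^31 - 1.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    basis = 11L, means = 23L, counts = 37L, depth = 41L, outcomes = 53L,
    rarefy = 61L, dirichlet = 71L, null = 83L, removal = 97L, boot = 101L,
    perm = 113L
  )
  if (!stage %in% names(offsets)) abort(paste0("unknown seed stage: ", stage))
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
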