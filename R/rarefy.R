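# Rarefaction, Good's coverage and relative abundance.

#' Rarefy a count table to a fixed depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to exactly `depth` reads.
#' Samples with fewer than `depth` total reads are dropped with a warning.
#'
#' @param table wide count tibble.
#' @param depth target reads per sample.
#' @param seed integer seed; the draw is reproducible.
#' @return rarefied wide count tibble (possibly fewer rows).
#' @export
rarefy_counts <- function(table, depth, seed = 1L) {
  stopifnot(depth >= 1)
  m <- as_count_matrix(table)
  check_integer_counts(m)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!all(keep)) {
    warn(paste0("dropping ", sum(!keep), " sample(s) with fewer than ",
                depth, " reads: ", paste(rownames(m)[!keep], collapse = ", ")))
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) return(as_count_tibble(m))
  set.seed(child_seed(seed, "rarefy"))
  # rrarefy speculates about non-count input whenever the smallest cell is
  # large; our inputs are validated integer counts, so silence that note
  out <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  as_count_tibble(out)
}

#' Good's coverage of a sample
#'
#' `1 - F1/n`, where `F1` is the number of taxa observed exactly once and
#' `n` the sample's total reads: the estimated fraction of the community
#' represented by the sample.
#'
#' @param counts non-negative integer vector for one sample.
#' @return real in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  n <- sum(counts)
  if (n <= 0) abort("all-zero sample", class = "gutstab_zero_sample")
  1 - sum(counts == 1) / n
}

#' Relative abundance matrix
#'
#' @param table wide count tibble; every sample must have positive total.
#' @return wide tibble of per-sample proportions (rows sum to 1).
#' @export
relative_abundance <- function(table) {
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    abort("sample(s) with zero total count", class = "gutstab_zero_sample")
  }
  as_count_tibble(m / totals)
}
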