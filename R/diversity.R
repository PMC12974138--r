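# Alpha diversity and the Firmicutes/Bacteroidetes ratio.

#' Shannon diversity of one sample
#'
#' `H = -sum p_i log p_i` over taxa with positive counts; natural log by
#' default (typical 3-5 range for gut communities), log2 by flag.
#'
#' @param counts non-negative count (or proportion) vector.
#' @param base logarithm base; `exp(1)` (default) or 2.
#' @return non-negative real.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (sum(counts) <= 0) abort("all-zero sample", class = "gutstab_zero_sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Chao1 richness of one sample
#'
#' Bias-corrected form `S_obs + F1(F1-1) / (2(F2+1))` by default (finite
#' when doubletons are absent); the classic `S_obs + F1^2/(2 F2)` by flag.
#'
#' @param counts non-negative integer vector.
#' @param bias_corrected logical; classic form when `FALSE`.
#' @return estimated richness, always `>= S_obs`.
#' @export
chao1_index <- function(counts, bias_corrected = TRUE) {
  if (sum(counts) <= 0) abort("all-zero sample", class = "gutstab_zero_sample")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' Per-sample alpha diversity table
#'
#' @param table wide count tibble.
#' @return tibble with `sample_id`, `shannon`, `chao1`, `observed`,
#'   `goods_coverage`.
#' @export
alpha_diversity <- function(table) {
  m <- as_count_matrix(table)
  tibble::tibble(
    sample_id = rownames(m),
    shannon = unname(apply(m, 1, shannon_index)),
    chao1 = unname(apply(m, 1, chao1_index)),
    observed = unname(rowSums(m > 0)),
    goods_coverage = unname(apply(m, 1, goods_coverage))
  )
}

#' Firmicutes/Bacteroidetes ratio per sample
#'
#' Operates on a phylum-level table (see [collapse_rank()]). Synonymous
#' labels (Bacteroidota for Bacteroidetes, Bacillota for Firmicutes) are
#' recognised. A zero Bacteroidetes count yields `NA` with a warning
#' rather than an infinite ratio.
#'
#' @param table wide count tibble collapsed to phylum.
#' @param firmicutes,bacteroidetes acceptable column labels for each phylum.
#' @return tibble with `sample_id`, `fb_ratio`.
#' @export
fb_ratio <- function(table,
                     firmicutes = c("Firmicutes", "Bacillota"),
                     bacteroidetes = c("Bacteroidetes", "Bacteroidota")) {
  m <- as_count_matrix(table)
  f_col <- intersect(firmicutes, colnames(m))
  b_col <- intersect(bacteroidetes, colnames(m))
  if (!length(f_col) && !length(b_col)) {
    abort("neither Firmicutes nor Bacteroidetes present in phylum table",
          class = "gutstab_missing_taxon")
  }
  f <- if (length(f_col)) rowSums(m[, f_col, drop = FALSE]) else rep(0, nrow(m))
  b <- if (length(b_col)) rowSums(m[, b_col, drop = FALSE]) else rep(0, nrow(m))
  ratio <- unname(ifelse(b > 0, f / b, NA_real_))
  if (anyNA(ratio)) {
    warn("samples with zero Bacteroidetes: ratio reported as NA")
  }
  tibble::tibble(sample_id = rownames(m), fb_ratio = ratio)
}
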