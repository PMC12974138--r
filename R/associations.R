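# Spearman association matrices, two-group comparisons, and the
# metabolite volcano filter.

#' Spearman association matrix between features and outcomes
#'
#' Rank correlation with average ranks for ties, p-values from the
#' t-approximation, pairwise-complete handling of missing outcomes, and
#' optional Benjamini-Hochberg adjustment across the whole matrix. Star
#' tiers: `*` p<0.05, `**` p<0.01, `***` p<0.001.
#'
#' @param features wide tibble (`sample_id` + numeric feature columns).
#' @param outcomes tibble (`sample_id` + numeric outcome columns).
#' @param adjust add BH-adjusted `q` across all cells.
#' @param min_pairs minimum complete pairs per cell (below: `NA` cell).
#' @return `association_matrix` tibble (long): `feature`, `outcome`,
#'   `rho`, `p`, (`q`), `stars`, `n`.
#' @export
spearman_matrix <- function(features, outcomes, adjust = TRUE, min_pairs = 4) {
  common <- intersect(features$sample_id, outcomes$sample_id)
  if (length(common) < min_pairs) {
    abort("too few aligned samples", class = "gutstab_bad_table")
  }
  fx <- features[match(common, features$sample_id),
                 setdiff(names(features), "sample_id"), drop = FALSE]
  oy <- outcomes[match(common, outcomes$sample_id),
                 setdiff(names(outcomes), "sample_id"), drop = FALSE]
  oy <- oy[vapply(oy, is.numeric, logical(1))]
  grid <- tidyr::expand_grid(feature = names(fx), outcome = names(oy))
  warned <- FALSE
  rows <- purrr::pmap_dfr(grid, function(feature, outcome) {
    x <- fx[[feature]]; y <- oy[[outcome]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < min_pairs) {
      return(tibble::tibble(feature = feature, outcome = outcome,
                            rho = NA_real_, p = NA_real_, n = n))
    }
    xr <- rank(x[ok]); yr <- rank(y[ok])
    if (sd(xr) == 0 || sd(yr) == 0) {
      warned <<- TRUE
      return(tibble::tibble(feature = feature, outcome = outcome,
                            rho = NA_real_, p = NA_real_, n = n))
    }
    rho <- cor(xr, yr)
    p <- if (abs(rho) >= 1) .Machine$double.xmin else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tt), df = n - 2)
    }
    tibble::tibble(feature = feature, outcome = outcome, rho = rho,
                   p = min(p, 1), n = n)
  })
  if (warned) warn("constant column(s): correlation undefined, reported NA")
  if (adjust) rows$q <- p.adjust(rows$p, "BH")
  rows$stars <- star_tier(rows$p)
  class(rows) <- c("association_matrix", class(rows))
  rows
}

star_tier <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Association heatmap
#'
#' @param object `association_matrix`.
#' @param ... unused.
#' @return a ggplot tile heatmap with star annotations (raw-p tiers).
#' @export
autoplot.association_matrix <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$outcome, .data$feature, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' Two-group comparison
#'
#' @param values numeric vector.
#' @param groups two-level vector aligned with `values`.
#' @param method `"welch_t"`, `"student_t"` or `"wilcoxon"`.
#' @return tibble: `statistic`, `p_value`, `method`.
#' @export
group_compare <- function(values, groups,
                          method = c("welch_t", "student_t", "wilcoxon")) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) abort("exactly two groups required",
                                  class = "gutstab_bad_grouping")
  if (any(table(groups) < 2)) abort("need at least 2 samples per group",
                                    class = "gutstab_bad_grouping")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (method %in% c("welch_t", "student_t") && sd(x) == 0 && sd(y) == 0) {
    abort("zero within-group variance: t-test degenerate",
          class = "gutstab_degenerate")
  }
  res <- switch(method,
    welch_t = t.test(x, y, var.equal = FALSE),
    student_t = t.test(x, y, var.equal = TRUE),
    wilcoxon = suppressWarnings(wilcox.test(x, y))
  )
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = res$p.value, method = method)
}

#' Volcano filter for feature intensities
#'
#' `log2FC = log2(mean_2 / mean_1)` on raw intensities (groups in factor
#' order), Welch t-test on log intensities, BH across features; kept
#' features satisfy `q < q_threshold` and `|log2FC| > lfc_threshold`.
#' Zeros are floored at half the feature's smallest positive value.
#'
#' @param features wide tibble (`sample_id` + positive feature columns).
#' @param groups two-level vector aligned with the rows.
#' @param q_threshold BH-adjusted significance cutoff.
#' @param lfc_threshold absolute log2 fold-change cutoff.
#' @return `volcano_result` tibble: `feature`, `log2_fc`, `p`, `q`,
#'   `direction`, `kept`.
#' @export
volcano_filter <- function(features, groups, q_threshold = 0.05,
                           lfc_threshold = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) abort("exactly two groups required",
                                  class = "gutstab_bad_grouping")
  fx <- features[setdiff(names(features), "sample_id")]
  floored_any <- FALSE
  rows <- purrr::map_dfr(names(fx), function(nm) {
    x <- fx[[nm]]
    pos <- x[x > 0]
    if (length(pos) < length(x)) {
      floored_any <<- TRUE
      fl <- if (length(pos)) min(pos) / 2 else 1e-6
      x[x <= 0] <- fl
    }
    m1 <- mean(x[groups == levels(groups)[1]])
    m2 <- mean(x[groups == levels(groups)[2]])
    lfc <- log2(m2 / m1)
    p <- tryCatch(group_compare(log(x), groups, "welch_t")$p_value,
                  error = function(e) NA_real_)
    tibble::tibble(feature = nm, log2_fc = lfc, p = p)
  })
  if (floored_any) warn("zero intensities floored at half-minimum")
  rows$q <- p.adjust(rows$p, "BH")
  rows$direction <- ifelse(rows$log2_fc > 0, "up", "down")
  rows$kept <- !is.na(rows$q) & rows$q < q_threshold &
    abs(rows$log2_fc) > lfc_threshold
  class(rows) <- c("volcano_result", class(rows))
  rows
}

#' Volcano plot
#'
#' @param object `volcano_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.volcano_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$log2_fc, -log10(.data$q),
                               colour = .data$kept)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}
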