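# Bray-Curtis dissimilarity, principal coordinates, PERMANOVA.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = 1 - 2 sum min(x_i, y_i) / (sum x + sum y)` on counts, via
#' [vegan::vegdist()]. Bray-Curtis is a semimetric: the triangle
#' inequality is not guaranteed.
#'
#' @param table wide count tibble; all sample sums positive.
#' @return a `dist` object labelled by sample ID.
#' @export
bray_curtis <- function(table) {
  m <- as_count_matrix(table)
  if (any(rowSums(m) <= 0)) {
    abort("sample(s) with zero total count", class = "gutstab_zero_sample")
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues are reported but excluded
#' from coordinates and from `proportion_explained` (computed over the
#' positive spectrum). No Cailliez/Lingoes correction is applied. Each
#' axis is flipped so its largest-magnitude sample coordinate is positive,
#' fixing the reflection ambiguity.
#'
#' @param d `dist` or symmetric distance matrix.
#' @param n_axes number of coordinate axes to return.
#' @return object of class `gutstab_pcoa`: `coordinates` tibble
#'   (`sample_id`, `Axis1`, ...), `eigenvalues`, `proportion_explained`.
#' @export
pcoa_ordination <- function(d, n_axes = 2) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      abort("distance matrix must be symmetric", class = "gutstab_bad_distance")
    }
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  # Gower centering done explicitly so the full spectrum is available
  D2 <- as.matrix(d)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev[1], 0) * 1e-12 & ev > 0)
  k <- min(n_axes, length(pos))
  coords <- matrix(0, n, n_axes)
  if (k > 0) {
    coords[, seq_len(k)] <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(ev[pos[seq_len(k)]]), k)
    for (j in seq_len(k)) {
      if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
    }
  }
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  prop <- if (length(pos)) ev[pos] / sum(ev[pos]) else numeric(0)
  structure(list(
    coordinates = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                   tibble::as_tibble(coords)),
    eigenvalues = ev,
    proportion_explained = prop
  ), class = "gutstab_pcoa")
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational MANOVA via [vegan::adonis2()]: pseudo-F from the
#' among/within partition of squared distances, permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`. Labels are permuted freely;
#' for repeated-measures designs run it per timepoint.
#'
#' @param d `dist` object.
#' @param grouping factor/character vector of group labels, aligned with `d`.
#' @param n_perm number of permutations (999 is customary).
#' @param seed integer seed for the permutation stream.
#' @return tibble with one row: `pseudo_F`, `p_value`, `r2`, `df_among`,
#'   `df_within`, `n_perm`.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = 1L) {
  grouping <- as.factor(grouping)
  tab <- table(grouping)
  if (length(tab) < 2) abort("need at least 2 groups", class = "gutstab_bad_grouping")
  if (any(tab < 2)) abort("every group needs at least 2 samples",
                          class = "gutstab_bad_grouping")
  set.seed(child_seed(seed, "perm"))
  df <- data.frame(g = grouping)
  fit <- vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  tibble::tibble(
    pseudo_F = fit$F[1],
    p_value = fit$`Pr(>F)`[1],
    r2 = fit$R2[1],
    df_among = fit$Df[1],
    df_within = fit$Df[2],
    n_perm = n_perm
  )
}

#' @export
tidy.gutstab_pcoa <- function(x, ...) x$coordinates

#' @export
glance.gutstab_pcoa <- function(x, ...) {
  tibble::tibble(
    n_positive_eig = sum(x$eigenvalues > 0),
    n_negative_eig = sum(x$eigenvalues < 0),
    prop_axis1 = x$proportion_explained[1] %||% NA_real_,
    prop_axis2 = if (length(x$proportion_explained) >= 2)
      x$proportion_explained[2] else NA_real_
  )
}

#' Ordination scatter plot
#'
#' @param object a `gutstab_pcoa`.
#' @param metadata optional metadata tibble joined on `sample_id`; its
#'   `treatment` column colours points when present.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gutstab_pcoa <- function(object, metadata = NULL, ...) {
  df <- object$coordinates
  lab <- function(i) {
    p <- object$proportion_explained
    pct <- if (length(p) >= i) sprintf(" (%.1f%%)", 100 * p[i]) else ""
    paste0("Axis ", i, pct)
  }
  if (!is.null(metadata)) df <- dplyr::left_join(df, metadata, by = "sample_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
  if (!is.null(metadata) && "treatment" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$treatment), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
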