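# SparCC: basis-correlation estimation for compositional counts.
#
# The algorithm estimates correlations between latent "basis" abundances
# from the variation matrix T (variances of pairwise log-ratios of
# fractions), under a sparsity assumption that lets the basis variances be
# solved from T's row sums. Pairs with strong apparent correlation are
# iteratively excluded from the linear system and it is re-solved.
# Pseudo-p-values come from a per-taxon permutation null (the published
# "bootstrap" count): resampling samples with replacement would preserve
# the correlations and cannot form a null, so each taxon's counts are
# permuted independently across samples instead.

#' Estimate taxon fractions from counts
#'
#' Each draw samples per-sample fractions from Dirichlet(counts + 1);
#' `n_draws = 0` degenerates to the deterministic pseudocount fractions
#' `(counts + 1) / (n + D)`.
#'
#' @param table wide count tibble.
#' @param n_draws number of Dirichlet draws (0 = deterministic mode).
#' @param seed integer seed.
#' @return list of fraction matrices (samples x taxa), length
#'   `max(1, n_draws)`.
#' @export
estimate_fractions <- function(table, n_draws = 1, seed = 1L) {
  m <- as_count_matrix(table)
  if (nrow(m) == 0 || ncol(m) == 0) {
    abort("empty count table", class = "gutstab_bad_table")
  }
  if (n_draws == 0) {
    f <- (m + 1) / (rowSums(m) + ncol(m))
    return(list(f))
  }
  set.seed(child_seed(seed, "dirichlet"))
  lapply(seq_len(n_draws), function(i) {
    g <- matrix(rgamma(length(m), shape = m + 1, rate = 1),
                nrow = nrow(m), dimnames = dimnames(m))
    g / rowSums(g)
  })
}

#' Variation matrix of log-ratio variances
#'
#' `t_ij = var(log(f_i / f_j))` over samples (n-1 denominator), computed
#' from the covariance matrix of log fractions.
#'
#' @param fractions samples x taxa matrix of positive fractions.
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
variation_matrix <- function(fractions) {
  if (any(fractions <= 0)) {
    abort("fractions must be strictly positive", class = "gutstab_bad_table")
  }
  lf <- log(fractions)
  C <- cov(lf)
  v <- diag(C)
  T_ <- outer(v, v, "+") - 2 * C
  T_[T_ < 0] <- 0          # numerical noise on near-constant log-ratios
  diag(T_) <- 0
  T_
}

#' Solve the SparCC linear system for basis correlations
#'
#' Basis variances are solved from the variation matrix's row sums under
#' the sparsity approximation, then
#' `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`, clipped to
#' `[-1, 1]`. The strongest-|rho| pair exceeding `exclusion_threshold` is
#' iteratively removed from the system and it is re-solved, up to
#' `max_exclusions` rounds. Negative solved variances are floored at 1e-10
#' with a warning.
#'
#' @param T_ variation matrix (at least 4 taxa for identifiability).
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded and the system re-solved.
#' @param max_exclusions maximum exclusion rounds.
#' @return symmetric correlation matrix with unit diagonal, plus
#'   attributes `excluded_pairs` (two-column index matrix) and
#'   `floored_taxa`.
#' @export
basis_correlations <- function(T_, exclusion_threshold = 0.1,
                               max_exclusions = 10) {
  D <- nrow(T_)
  if (D < 4) abort("need at least 4 taxa for the SparCC system",
                   class = "gutstab_bad_table")
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  t_vec <- rowSums(T_)
  excluded <- matrix(integer(0), ncol = 2)
  floored <- integer(0)

  solve_rho <- function() {
    w <- tryCatch(solve(M, t_vec), error = function(e) {
      abort("singular SparCC system: degenerate variation matrix",
            class = "gutstab_singular_system")
    })
    if (any(w <= 0)) {
      floored <<- union(floored, which(w <= 0))
      w[w <= 0] <- 1e-10
    }
    sw <- sqrt(w)
    rho <- (outer(w, w, "+") - T_) / (2 * outer(sw, sw))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }

  rho <- solve_rho()
  for (k in seq_len(max_exclusions)) {
    cand <- abs(rho)
    diag(cand) <- 0
    if (nrow(excluded)) cand[rbind(excluded, excluded[, 2:1, drop = FALSE])] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    t_vec[i] <- t_vec[i] - T_[i, j]
    t_vec[j] <- t_vec[j] - T_[i, j]
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    # an exclusion can exhaust a taxon's partners in small systems; if the
    # system degenerates, revert that exclusion and stop refining
    rho_new <- tryCatch(solve_rho(), gutstab_singular_system = function(e) NULL)
    if (is.null(rho_new)) {
      t_vec[i] <- t_vec[i] + T_[i, j]
      t_vec[j] <- t_vec[j] + T_[i, j]
      M[i, i] <- M[i, i] + 1
      M[j, j] <- M[j, j] + 1
      M[i, j] <- M[i, j] + 1
      M[j, i] <- M[j, i] + 1
      break
    }
    excluded <- rbind(excluded, c(i, j))
    rho <- rho_new
  }
  if (length(floored)) {
    warn(paste("negative basis variance floored for",
               length(floored), "taxon/taxa"))
  }
  dimnames(rho) <- dimnames(T_)
  attr(rho, "excluded_pairs") <- excluded
  attr(rho, "floored_taxa") <- floored
  rho
}

# one full pipeline on a count matrix: fractions -> T -> rho, for each
# inner draw; returns the element-wise median correlation matrix
sparcc_point <- function(m, n_inner, seed, exclusion_threshold, max_exclusions) {
  fracs <- estimate_fractions(as_count_tibble(m), n_draws = n_inner, seed = seed)
  rhos <- lapply(fracs, function(f) {
    suppressWarnings(basis_correlations(variation_matrix(f),
                                        exclusion_threshold, max_exclusions))
  })
  if (length(rhos) == 1) return(rhos[[1]])
  arr <- array(unlist(rhos), dim = c(dim(rhos[[1]]), length(rhos)))
  r <- apply(arr, c(1, 2), median)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- dimnames(rhos[[1]])
  r
}

#' SparCC correlation estimate
#'
#' Element-wise median over `n_inner` Dirichlet-draw pipelines of
#' `basis_correlations(variation_matrix(.))`.
#'
#' @param table wide count tibble (>= 4 taxa; a warning is emitted below
#'   10 samples).
#' @param n_inner number of inner Dirichlet draws (0 = deterministic
#'   pseudocount fractions, a single pipeline).
#' @param seed integer seed.
#' @param exclusion_threshold,max_exclusions see [basis_correlations()].
#' @return `sparcc_fit` object with elements `r` (correlation matrix),
#'   `p` (`NULL` until [sparcc_pvalues()] is run), `n_inner`, `seed`.
#' @export
sparcc <- function(table, n_inner = 20, seed = 1L,
                   exclusion_threshold = 0.1, max_exclusions = 10) {
  m <- as_count_matrix(table)
  if (ncol(m) < 4) abort("need at least 4 taxa", class = "gutstab_bad_table")
  if (nrow(m) < 10) warn("fewer than 10 samples: SparCC estimates unstable")
  r <- sparcc_point(m, n_inner, seed, exclusion_threshold, max_exclusions)
  structure(list(r = r, p = NULL, n_inner = n_inner, n_null = 0L,
                 seed = seed, exclusion_threshold = exclusion_threshold,
                 max_exclusions = max_exclusions),
            class = "sparcc_fit")
}

#' Permutation pseudo-p-values for SparCC correlations
#'
#' Null datasets are built by independently permuting each taxon's counts
#' across samples (destroying correlation, preserving marginals); the full
#' SparCC pipeline runs on each, and two-sided pseudo-p-values use the
#' add-one rule `(1 + #{null |r| >= |r_obs|}) / (1 + n_null)`.
#'
#' @param table wide count tibble.
#' @param fit a `sparcc_fit` from [sparcc()] (its settings are reused).
#' @param n_null number of null datasets.
#' @param seed integer seed for the null stream.
#' @return the `sparcc_fit` with `p` filled in.
#' @export
sparcc_pvalues <- function(table, fit, n_null = 100, seed = 1L) {
  stopifnot(inherits(fit, "sparcc_fit"), n_null >= 1)
  m <- as_count_matrix(table)
  abs_obs <- abs(fit$r)
  exceed <- matrix(0, nrow(abs_obs), ncol(abs_obs))
  null_seed <- child_seed(seed, "null")
  for (k in seq_len(n_null)) {
    set.seed((null_seed + k) %% 2147483647)
    perm <- apply(m, 2, sample)
    rownames(perm) <- rownames(m)
    r_null <- sparcc_point(perm, fit$n_inner,
                           seed = (null_seed + n_null + k) %% 2147483647,
                           fit$exclusion_threshold, fit$max_exclusions)
    exceed <- exceed + (abs(r_null) >= abs_obs)
  }
  p <- (1 + exceed) / (1 + n_null)
  p <- (p + t(p)) / 2
  diag(p) <- 1
  dimnames(p) <- dimnames(fit$r)
  fit$p <- p
  fit$n_null <- as.integer(n_null)
  fit
}

#' @export
tidy.sparcc_fit <- function(x, ...) {
  taxa <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  out <- tibble::tibble(
    taxon_1 = taxa[idx[, 1]],
    taxon_2 = taxa[idx[, 2]],
    r = x$r[idx]
  )
  if (!is.null(x$p)) out$p <- x$p[idx]
  out
}

#' @export
glance.sparcc_fit <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  tibble::tibble(
    n_taxa = ncol(x$r),
    n_inner = x$n_inner,
    n_null = x$n_null,
    mean_abs_r = mean(abs(off)),
    max_abs_r = max(abs(off))
  )
}

#' Threshold a SparCC result into a co-occurrence network
#'
#' Undirected graph with an edge wherever `|r| > r_threshold` and
#' `p < p_threshold` (both strict); edge weight is the signed correlation.
#' Isolated nodes are retained by default so the node set equals the taxon
#' set.
#'
#' @param fit `sparcc_fit` with p-values, or a list with `r` and `p`
#'   matrices.
#' @param r_threshold correlation magnitude threshold, in (0, 1].
#' @param p_threshold significance threshold, in (0, 1].
#' @param drop_isolates drop unconnected taxa from the node set.
#' @param stratum optional label carried on the network.
#' @return a `cooccurrence_network`: list with `nodes` and `edges` tibbles.
#' @export
build_network <- function(fit, r_threshold = 0.5, p_threshold = 0.05,
                          drop_isolates = FALSE, stratum = NULL) {
  if (r_threshold <= 0 || r_threshold > 1 || p_threshold <= 0 || p_threshold > 1) {
    abort("thresholds must lie in (0, 1]", class = "gutstab_bad_threshold")
  }
  r <- fit$r
  p <- fit$p
  if (is.null(p)) abort("fit carries no p-values; run sparcc_pvalues() first",
                        class = "gutstab_bad_table")
  taxa <- colnames(r) %||% as.character(seq_len(ncol(r)))
  keep <- abs(r) > r_threshold & p < p_threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = taxa[idx[, 1]], to = taxa[idx[, 2]],
    r = r[idx], p = p[idx]
  )
  nodes <- tibble::tibble(node = taxa)
  if (drop_isolates) {
    nodes <- dplyr::filter(nodes, .data$node %in% c(edges$from, edges$to))
  }
  structure(list(nodes = nodes, edges = edges, stratum = stratum),
            class = "cooccurrence_network")
}

#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @export
#' @method print cooccurrence_network
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network",
      if (!is.null(x$stratum)) paste0("[", x$stratum, "]"), "\n")
  cat("  nodes:", nrow(x$nodes), " edges:", nrow(x$edges), "\n")
  invisible(x)
}
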