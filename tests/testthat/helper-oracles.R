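# Independent oracles used to cross-check the network metrics: these
# deliberately avoid the code paths (igraph accessors, log-sum-exp) used
# by the implementation.

# adjacency matrix of an igraph as plain 0/1
adj01 <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  (A != 0) * 1
}

# natural connectivity by direct eigendecomposition, no stabilization
oracle_nc <- function(A) {
  k <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  log(mean(exp(k)))
}

# all-pairs unweighted shortest paths by breadth-first matrix powers
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n)
  P <- diag(n)
  for (step in seq_len(n)) {
    P <- (P %*% A > 0) * 1
    newly <- P > 0 & reach == 0
    D[newly] <- step
    reach[newly] <- 1
    if (all(reach > 0)) break
  }
  D
}

oracle_cpl <- function(A) {
  D <- oracle_distances(A)
  vals <- D[is.finite(D) & D > 0]
  if (length(vals)) mean(vals) else NA_real_
}

# mean local clustering, deg < 2 counted as zero, via triangle counting
oracle_clustering <- function(A) {
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  loc <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
  mean(loc)
}

oracle_topology <- function(A) {
  n <- nrow(A)
  e <- sum(A) / 2
  deg <- rowSums(A)
  mdeg <- mean(deg)
  list(
    n_nodes = n, n_edges = e, avg_neighbors = 2 * e / n,
    characteristic_path_length = oracle_cpl(A),
    clustering_coefficient = oracle_clustering(A),
    density = 2 * e / (n * (n - 1)),
    heterogeneity = if (mdeg > 0) sqrt(mean((deg - mdeg)^2)) / mdeg else 0,
    centralization = (n / (n - 2)) * (max(deg) / (n - 1) - 2 * e / (n * (n - 1)))
  )
}

# exhaustive maximal-clique enumeration over all vertex subsets (n <= 12)
oracle_max_cliques <- function(A) {
  n <- nrow(A)
  stopifnot(n <= 12)
  is_clique <- function(idx) {
    if (length(idx) < 2) return(length(idx) == 1)
    sub <- A[idx, idx]
    all(sub[upper.tri(sub)] == 1)
  }
  cliques <- list()
  for (code in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2 || !is_clique(idx)) next
    extendable <- any(vapply(setdiff(seq_len(n), idx), function(v) {
      all(A[v, idx] == 1)
    }, logical(1)))
    if (!extendable) cliques[[length(cliques) + 1]] <- idx
  }
  cliques
}

oracle_mcc <- function(A) {
  n <- nrow(A)
  score <- rep(0, n)
  for (cl in oracle_max_cliques(A)) {
    score[cl] <- score[cl] + factorial(length(cl) - 1)
  }
  score
}

random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p)
}

# minimal sparcc-like object for build_network tests
fake_fit <- function(r, p) {
  structure(list(r = r, p = p), class = "sparcc_fit")
}
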