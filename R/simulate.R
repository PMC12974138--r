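# Synthetic longitudinal two-arm compositional count studies with planted
# correlation structure, differential effects and outcome links.
#
# The generator emulates the study design this package targets: two dietary
# arms (CON, DF) x six sampling timepoints (G0..L14) x 16 sows per arm,
# genus-level compositional counts with a sparse planted basis-correlation
# structure, arm-by-time abundance effects on selected genera, per-subject
# random intercepts, log-normal sequencing-depth variation, and per-sow
# litter outcomes linked to selected genera.

#' Simulation configuration
#'
#' Defaults encode the target study design: 16 subjects per arm, six
#' timepoints spanning gestation (G0, G30, G90, G109) and lactation
#' (L3, L14), 150 genera, ~30k reads/sample with log-normal depth
#' variation, 10 planted correlated genus pairs at rho = 0.8, a handful of
#' arm-by-time differential genera at 4-fold (+2 log2) effects, subject
#' random-intercept SD 0.5 on the log scale, and three litter outcomes
#' (total_born, born_alive, healthy) linked to differential genera at G109.
#'
#' @param n_subjects_per_arm subjects per treatment arm.
#' @param timepoints ordered character vector of timepoint labels.
#' @param n_taxa number of taxa (genera).
#' @param depth_mean mean sequencing depth (reads per sample).
#' @param depth_dispersion log-normal sdlog of depth; 0 = fixed depth.
#' @param n_correlated_pairs number of planted correlated taxon pairs.
#' @param pair_rho planted basis correlation, in (-1, 1).
#' @param diff_taxa_spec list of planted effects, each
#'   `list(taxon =, arm =, timepoints =, log2_effect =)` (taxon is a 1-based
#'   index).
#' @param subject_sd SD of the per-subject, per-taxon random intercept on
#'   the natural-log abundance scale.
#' @param taxon_sd per-sample SD of the log-scale abundance noise. The
#'   default (0.6, i.e. roughly 1.8-fold sample-to-sample variation on top
#'   of the subject intercept) is calibrated so the planted 4-fold effects
#'   are detectable at 16 subjects/arm, the design the generator emulates.
#' @param taxon_log_means optional vector of per-taxon natural-log mean
#'   abundances; drawn from N(0, 2) when `NULL`. Supplying it lets
#'   recovery experiments plant effects on deliberately minor genera,
#'   where compositional closure leaves a log-linear effect nearly
#'   unattenuated on the relative-abundance scale.
#' @param outcome_spec list of outcome definitions, each
#'   `list(name =, taxa =, coef =, noise_sd =, timepoint =)`.
#' @param seed integer master seed; expanded to per-stage child seeds.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects_per_arm = 16,
                       timepoints = TIMEPOINTS,
                       n_taxa = 150,
                       depth_mean = 30000,
                       depth_dispersion = 0.3,
                       n_correlated_pairs = 10,
                       pair_rho = 0.8,
                       diff_taxa_spec = default_diff_spec(),
                       subject_sd = 0.5,
                       taxon_sd = 0.6,
                       taxon_log_means = NULL,
                       outcome_spec = default_outcome_spec(),
                       seed = 1L) {
  cfg <- list(
    n_subjects_per_arm = n_subjects_per_arm, timepoints = timepoints,
    n_taxa = n_taxa, depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    n_correlated_pairs = n_correlated_pairs, pair_rho = pair_rho,
    diff_taxa_spec = diff_taxa_spec, subject_sd = subject_sd,
    taxon_sd = taxon_sd, taxon_log_means = taxon_log_means,
    outcome_spec = outcome_spec, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

default_diff_spec <- function() {
  list(
    list(taxon = 21, arm = "DF",  timepoints = c("G30", "G90", "G109"), log2_effect = 2),
    list(taxon = 22, arm = "DF",  timepoints = c("G30", "G90", "G109"), log2_effect = 2),
    list(taxon = 23, arm = "DF",  timepoints = c("G109"),               log2_effect = 2),
    list(taxon = 26, arm = "CON", timepoints = c("G30", "G90", "G109"), log2_effect = 2),
    list(taxon = 27, arm = "CON", timepoints = c("G109"),               log2_effect = 2)
  )
}

default_outcome_spec <- function() {
  list(
    list(name = "total_born", taxa = c(21, 26), coef = c(1, -1),
         noise_sd = 1, timepoint = "G109"),
    list(name = "born_alive", taxa = 21, coef = 1, noise_sd = 1,
         timepoint = "G109"),
    list(name = "healthy", taxa = 22, coef = 1, noise_sd = 1,
         timepoint = "G109")
  )
}

validate_config <- function(cfg) {
  if (cfg$n_taxa < 1 || cfg$n_subjects_per_arm < 1 || !length(cfg$timepoints)) {
    abort("degenerate design: need at least 1 taxon, subject and timepoint",
          class = "gutstab_bad_config")
  }
  if (cfg$n_taxa < 2 * cfg$n_correlated_pairs) {
    abort("n_taxa must be at least 2 * n_correlated_pairs",
          class = "gutstab_bad_config")
  }
  if (cfg$depth_mean <= 0) abort("depth_mean must be positive",
                                 class = "gutstab_bad_config")
  if (abs(cfg$pair_rho) >= 1) abort("|pair_rho| must be < 1",
                                    class = "gutstab_bad_config")
  if (cfg$depth_dispersion < 0 || cfg$subject_sd < 0 || cfg$taxon_sd < 0) {
    abort("dispersion and SD parameters must be non-negative",
          class = "gutstab_bad_config")
  }
  if (!is.null(cfg$taxon_log_means) &&
      length(cfg$taxon_log_means) != cfg$n_taxa) {
    abort("taxon_log_means must have length n_taxa",
          class = "gutstab_bad_config")
  }
  for (d in cfg$diff_taxa_spec) {
    if (d$taxon > cfg$n_taxa) abort("diff_taxa index exceeds n_taxa",
                                    class = "gutstab_bad_config")
  }
  invisible(cfg)
}

#' Planted basis correlation matrix
#'
#' Identity except `n_pairs` disjoint off-diagonal pairs (taxa 1-2, 3-4, ...)
#' set to `rho`; block-diagonal 2x2 structure, hence positive definite with
#' smallest eigenvalue `1 - |rho|`.
#'
#' @param n_taxa matrix dimension.
#' @param n_pairs number of correlated pairs; `2 * n_pairs <= n_taxa`.
#' @param rho planted correlation, `|rho| < 1`.
#' @return `n_taxa` x `n_taxa` correlation matrix.
#' @export
generate_basis_correlation <- function(n_taxa, n_pairs, rho) {
  if (abs(rho) >= 1) abort("|rho| must be < 1 for a valid correlation",
                           class = "gutstab_bad_config")
  if (2 * n_pairs > n_taxa) abort("pairs would overlap: 2 * n_pairs > n_taxa",
                                  class = "gutstab_bad_config")
  R <- diag(n_taxa)
  if (n_pairs > 0) {
    i <- seq(1, by = 2, length.out = n_pairs)
    R[cbind(i, i + 1)] <- rho
    R[cbind(i + 1, i)] <- rho
  }
  R
}

#' Simulate a longitudinal two-arm compositional count study
#'
#' Per sample, correlated log-normal basis abundances are drawn from the
#' planted basis-correlation matrix around heterogeneous per-taxon log
#' means; arm-by-time effects and per-subject random intercepts are added
#' on the log scale; abundances are closed to fractions and counts drawn
#' multinomially at a log-normal depth. All planted structure is recorded
#' in the returned ground truth. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `sim_study` list: `counts` (wide tibble), `metadata` (tibble
#'   with sample_id, subject, treatment, timepoint), `truth` (list with
#'   `basis_correlation`, `differential_taxa` tibble, `outcome_spec`,
#'   `subject_effects` matrix, `taxon_log_means`).
#' @export
simulate_counts <- function(config) {
  validate_config(config)
  cfg <- config
  R <- generate_basis_correlation(cfg$n_taxa, cfg$n_correlated_pairs, cfg$pair_rho)
  taxa <- sprintf("g%03d", seq_len(cfg$n_taxa))

  set.seed(child_seed(cfg$seed, "means"))
  # heterogeneous log means: log-series-like unevenness so a few genera
  # dominate, as in real gut communities
  mu <- cfg$taxon_log_means %||% rnorm(cfg$n_taxa, mean = 0, sd = 2)

  subjects <- c(sprintf("CON%02d", seq_len(cfg$n_subjects_per_arm)),
                sprintf("DF%02d", seq_len(cfg$n_subjects_per_arm)))
  arms <- rep(c("CON", "DF"), each = cfg$n_subjects_per_arm)

  # per-subject, per-taxon random intercept, constant over time; a single
  # all-taxon shift would cancel under compositional closure
  set.seed(child_seed(cfg$seed, "basis"))
  subj_eff <- matrix(rnorm(length(subjects) * cfg$n_taxa, 0, cfg$subject_sd),
                     nrow = length(subjects),
                     dimnames = list(subjects, taxa))

  meta <- tidyr::expand_grid(subject = subjects, timepoint = cfg$timepoints)
  meta$treatment <- arms[match(meta$subject, subjects)]
  meta$sample_id <- paste0(meta$subject, "_", meta$timepoint)
  meta <- meta[, c("sample_id", "subject", "treatment", "timepoint")]

  # planted arm-by-time effects on the log scale
  eff <- matrix(0, nrow = nrow(meta), ncol = cfg$n_taxa)
  for (d in cfg$diff_taxa_spec) {
    rows <- meta$treatment == d$arm & meta$timepoint %in% d$timepoints
    eff[rows, d$taxon] <- eff[rows, d$taxon] + d$log2_effect * log(2)
  }

  L <- chol(R)
  set.seed(child_seed(cfg$seed, "counts"))
  eps <- matrix(rnorm(nrow(meta) * cfg$n_taxa, sd = cfg$taxon_sd),
                nrow = nrow(meta)) %*% L
  z <- sweep(eps, 2, mu, "+") + eff + subj_eff[meta$subject, , drop = FALSE]
  frac <- exp(z - apply(z, 1, max))
  frac <- frac / rowSums(frac)

  set.seed(child_seed(cfg$seed, "depth"))
  if (cfg$depth_dispersion == 0) {
    depths <- rep(cfg$depth_mean, nrow(meta))
  } else {
    depths <- pmax(1, round(rlnorm(nrow(meta),
                                   meanlog = log(cfg$depth_mean) -
                                     cfg$depth_dispersion^2 / 2,
                                   sdlog = cfg$depth_dispersion)))
  }
  counts <- t(vapply(seq_len(nrow(meta)),
                     function(i) rmultinom(1, depths[i], frac[i, ])[, 1],
                     numeric(cfg$n_taxa)))
  dimnames(counts) <- list(meta$sample_id, taxa)

  diff_tbl <- purrr::map_dfr(cfg$diff_taxa_spec, function(d) {
    tibble::tibble(taxon = taxa[d$taxon], arm = d$arm,
                   timepoints = paste(d$timepoints, collapse = ","),
                   log2_effect = d$log2_effect)
  })

  truth <- structure(list(
    basis_correlation = `dimnames<-`(R, list(taxa, taxa)),
    differential_taxa = diff_tbl,
    outcome_spec = cfg$outcome_spec,
    subject_effects = subj_eff,
    taxon_log_means = setNames(mu, taxa)
  ), class = "gutstab_truth")

  structure(list(counts = as_count_tibble(counts), metadata = meta,
                 truth = truth, config = cfg),
            class = "sim_study")
}

#' Simulate per-subject reproductive outcomes linked to taxa
#'
#' Each outcome is a linear combination of the subject's mean log10
#' relative abundances of the linked taxa at the designated timepoint,
#' plus Gaussian noise.
#'
#' @param table wide count tibble.
#' @param truth `gutstab_truth` from [simulate_counts()] (its
#'   `outcome_spec` defines the links).
#' @param metadata sample metadata tibble.
#' @param seed integer seed.
#' @return `metadata` with one added column per outcome (constant within
#'   subject).
#' @export
simulate_outcomes <- function(table, truth, metadata, seed = 1L) {
  spec <- truth$outcome_spec
  if (is.null(spec) || !length(spec)) {
    abort("truth carries no outcome_spec", class = "gutstab_bad_config")
  }
  rel <- as_count_matrix(relative_abundance(table))
  taxa <- colnames(rel)
  subjects <- unique(metadata$subject)
  set.seed(child_seed(seed, "outcomes"))
  for (o in spec) {
    linked <- if (is.character(o$taxa)) o$taxa else taxa[o$taxa]
    if (any(!linked %in% taxa)) {
      abort("linked taxon absent from table", class = "gutstab_missing_taxon")
    }
    vals <- vapply(subjects, function(s) {
      ids <- metadata$sample_id[metadata$subject == s &
                                metadata$timepoint == o$timepoint]
      ids <- intersect(ids, rownames(rel))
      if (!length(ids)) return(NA_real_)
      sub <- rel[ids, linked, drop = FALSE]
      logs <- log10(sub + 1e-6)
      sum(o$coef * colMeans(logs))
    }, numeric(1))
    vals <- vals + rnorm(length(subjects), 0, o$noise_sd)
    metadata[[o$name]] <- vals[match(metadata$subject, subjects)]
  }
  metadata
}
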