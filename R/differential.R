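# Longitudinal differential-abundance screening: per-genus linear mixed
# models, per-timepoint LEfSe effect-size screening, and the intersection
# logic that yields the key genera.

#' Linear mixed-effects screen over taxa (or an alpha metric)
#'
#' For each taxon, fits
#' `log10(relative abundance + delta) ~ treatment * timepoint + (1 | subject)`
#' by REML (via \pkg{lmerTest}), where `delta` is half that taxon's
#' smallest nonzero relative abundance; p-values are marginal
#' (type-III-style) Satterthwaite F tests of the treatment, timepoint and
#' interaction blocks. With `target = "alpha"`, a single model is fitted
#' to the chosen alpha-diversity metric instead.
#'
#' @param table wide count tibble.
#' @param metadata metadata tibble (`sample_id`, `subject`, `treatment`,
#'   `timepoint`).
#' @param target `"taxa"` or `"alpha"`.
#' @param alpha_metric `"shannon"` or `"chao1"` when `target = "alpha"`.
#' @param timepoint_levels timepoint factor order (reference first).
#' @return `lmm_screen` tibble: one row per response with `p_treatment`,
#'   `p_time`, `p_interaction`, BH-adjusted `q_*` columns, `converged`,
#'   `singular`, and a `coefs` list-column of fixed-effect estimates with
#'   Wald 95% intervals.
#' @export
fit_lmm <- function(table, metadata, target = c("taxa", "alpha"),
                    alpha_metric = "shannon",
                    timepoint_levels = TIMEPOINTS) {
  target <- match.arg(target)
  meta <- metadata[match(table$sample_id, metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    abort("samples missing from metadata", class = "gutstab_missing_metadata")
  }
  meta$treatment <- factor(meta$treatment, levels = TREATMENTS)
  meta$timepoint <- factor(meta$timepoint,
                           levels = intersect(timepoint_levels,
                                              unique(meta$timepoint)))
  if (nlevels(meta$timepoint) < 2) {
    abort("need at least 2 timepoints", class = "gutstab_rank_deficient")
  }
  cells <- table(meta$treatment, meta$timepoint)
  if (any(cells == 0)) {
    abort("rank-deficient design: a treatment is absent at some timepoint",
          class = "gutstab_rank_deficient")
  }

  if (target == "alpha") {
    alpha <- alpha_diversity(table)
    responses <- setNames(list(alpha[[alpha_metric]]), alpha_metric)
  } else {
    rel <- as_count_matrix(relative_abundance(table))
    responses <- lapply(setNames(colnames(rel), colnames(rel)), function(tx) {
      x <- rel[, tx]
      nz <- x[x > 0]
      if (!length(nz)) return(NULL)
      log10(x + min(nz) / 2)
    })
    responses <- responses[!vapply(responses, is.null, logical(1))]
  }

  rows <- purrr::map_dfr(names(responses), function(nm) {
    dat <- data.frame(y = responses[[nm]], treatment = meta$treatment,
                      timepoint = meta$timepoint, subject = meta$subject)
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(
        y ~ treatment * timepoint + (1 | subject), data = dat, REML = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(response = nm, p_treatment = NA_real_,
                            p_time = NA_real_, p_interaction = NA_real_,
                            converged = FALSE, singular = NA,
                            coefs = list(NULL)))
    }
    an <- suppressMessages(anova(fit, type = 3))
    pv <- setNames(an$`Pr(>F)`, rownames(an))
    msgs <- fit@optinfo$conv$lme4$messages
    ci <- suppressMessages(confint(fit, parm = "beta_", method = "Wald"))
    est <- lme4::fixef(fit)
    coefs <- tibble::tibble(term = names(est), estimate = unname(est),
                            conf_low = unname(ci[names(est), 1]),
                            conf_high = unname(ci[names(est), 2]))
    tibble::tibble(
      response = nm,
      p_treatment = pv[["treatment"]],
      p_time = pv[["timepoint"]],
      p_interaction = pv[["treatment:timepoint"]],
      converged = is.null(msgs) ||
        !any(grepl("failed to converge", msgs, ignore.case = TRUE)),
      singular = lme4::isSingular(fit),
      coefs = list(coefs)
    )
  })
  rows$q_treatment <- p.adjust(rows$p_treatment, "BH")
  rows$q_time <- p.adjust(rows$p_time, "BH")
  rows$q_interaction <- p.adjust(rows$p_interaction, "BH")
  class(rows) <- c("lmm_screen", class(rows))
  rows
}

#' @export
glance.lmm_screen <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    n_treatment_sig = sum(x$p_treatment < 0.05, na.rm = TRUE),
    n_time_sig = sum(x$p_time < 0.05, na.rm = TRUE),
    n_interaction_sig = sum(x$p_interaction < 0.05, na.rm = TRUE),
    n_nonconverged = sum(!x$converged, na.rm = TRUE)
  )
}

#' LEfSe two-class effect-size screen at one timepoint
#'
#' Stage 1: Kruskal-Wallis test per taxon on relative abundances scaled to
#' one million; taxa with `p < alpha` proceed. Stage 2: over `n_boot`
#' bootstrap rounds, a `boot_fraction` subsample per class is drawn and
#' the absolute difference of class means on the discriminant axis is
#' recorded (with one feature the discriminant axis coincides with the
#' scaled-abundance axis). The LDA score is the log10 of the mean effect,
#' floored at 1 before the log. No subclass tier is applied (the design
#' has two plain classes).
#'
#' @param table wide count tibble for one timepoint's samples.
#' @param classes two-level vector aligned with the table's samples.
#' @param alpha Kruskal-Wallis significance cutoff.
#' @param lda_threshold log10 effect-size threshold (the customary 2.0).
#' @param n_boot bootstrap rounds.
#' @param boot_fraction per-class subsample fraction.
#' @param seed integer seed.
#' @return `lefse_result` tibble: `taxon`, `kw_p`, `lda_score`,
#'   `enriched_class`, `passed`.
#' @export
lefse <- function(table, classes, alpha = 0.05, lda_threshold = 2.0,
                  n_boot = 30, boot_fraction = 2/3, seed = 1L) {
  m <- as_count_matrix(table)
  classes <- as.character(classes)
  lv <- sort(unique(classes))
  if (length(lv) != 2) abort("exactly two classes required",
                             class = "gutstab_bad_grouping")
  if (any(table(classes) < 3)) abort("need at least 3 samples per class",
                                     class = "gutstab_bad_grouping")
  rel <- m / rowSums(m) * 1e6
  i1 <- which(classes == lv[1]); i2 <- which(classes == lv[2])
  # bootstrap draws in canonical order (by sample content, not label
  # name) so that swapping class labels reproduces the same subsamples
  if (min(i1) <= min(i2)) { dA <- i1; dB <- i2 } else { dA <- i2; dB <- i1 }
  set.seed(child_seed(seed, "boot"))
  rows <- purrr::map_dfr(colnames(rel), function(tx) {
    x <- rel[, tx]
    kw <- suppressWarnings(kruskal.test(x, factor(classes)))$p.value
    if (is.na(kw) || kw >= alpha) {
      return(tibble::tibble(taxon = tx, kw_p = kw, lda_score = NA_real_,
                            enriched_class = NA_character_, passed = FALSE))
    }
    effects <- vapply(seq_len(n_boot), function(b) {
      sA <- sample(dA, max(1, round(boot_fraction * length(dA))))
      sB <- sample(dB, max(1, round(boot_fraction * length(dB))))
      abs(mean(x[sA]) - mean(x[sB]))
    }, numeric(1))
    score <- log10(max(mean(effects), 1))
    enriched <- if (mean(x[i2]) >= mean(x[i1])) lv[2] else lv[1]
    tibble::tibble(taxon = tx, kw_p = kw, lda_score = score,
                   enriched_class = enriched,
                   passed = score > lda_threshold)
  })
  class(rows) <- c("lefse_result", class(rows))
  attr(rows, "classes") <- lv
  rows
}

#' @export
glance.lefse_result <- function(x, ...) {
  lv <- attr(x, "classes")
  tibble::tibble(
    n_tested = nrow(x),
    n_passed = sum(x$passed),
    n_enriched_1 = sum(x$passed & x$enriched_class == lv[1]),
    n_enriched_2 = sum(x$passed & x$enriched_class == lv[2])
  )
}

#' Intersect LMM and LEfSe differential-genus sets
#'
#' The LMM tier keeps taxa with both a significant treatment effect and a
#' significant time effect; the intersection with the LEfSe passed set
#' gives the jointly supported genera; an abundance floor (overall mean
#' relative abundance) trims the display tier. All tiers are reported.
#'
#' @param lmm `lmm_screen` result.
#' @param lefse `lefse_result` (typically from the key timepoint).
#' @param table wide count tibble used for the abundance floor.
#' @param floor mean relative-abundance floor (0.001 = 0.1%).
#' @param p_threshold LMM per-effect significance cutoff.
#' @param require_interaction also require `p_interaction < p_threshold`
#'   in the LMM tier.
#' @return `differential_sets` list: `lmm_set`, `lefse_set`,
#'   `intersection`, `floored`, and a long `membership` tibble.
#' @export
intersect_differential <- function(lmm, lefse, table, floor = 0.001,
                                   p_threshold = 0.05,
                                   require_interaction = FALSE) {
  lmm_keep <- !is.na(lmm$p_treatment) & lmm$p_treatment < p_threshold &
    !is.na(lmm$p_time) & lmm$p_time < p_threshold
  if (require_interaction) {
    lmm_keep <- lmm_keep & !is.na(lmm$p_interaction) &
      lmm$p_interaction < p_threshold
  }
  lmm_set <- lmm$response[lmm_keep]
  lefse_set <- lefse$taxon[lefse$passed]
  inter <- intersect(lmm_set, lefse_set)
  rel <- as_count_matrix(relative_abundance(table))
  mean_rel <- colMeans(rel)
  floored <- inter[inter %in% names(mean_rel) & mean_rel[inter] > floor]
  universe <- union(union(lmm$response, lefse$taxon), colnames(rel))
  membership <- tibble::tibble(
    taxon = universe,
    lmm = universe %in% lmm_set,
    lefse = universe %in% lefse_set,
    intersection = universe %in% inter,
    floored = universe %in% floored,
    mean_rel_abundance = unname(mean_rel[universe])
  )
  structure(list(lmm_set = lmm_set, lefse_set = lefse_set,
                 intersection = inter, floored = floored,
                 membership = membership, floor = floor),
            class = "differential_sets")
}

#' @export
tidy.differential_sets <- function(x, ...) x$membership

#' @export
#' @method print differential_sets
print.differential_sets <- function(x, ...) {
  cat("Differential genus sets\n")
  cat("  LMM (treatment & time):", length(x$lmm_set), "\n")
  cat("  LEfSe passed:          ", length(x$lefse_set), "\n")
  cat("  intersection:          ", length(x$intersection), "\n")
  cat("  abundance >", format(x$floor), ":", length(x$floored), "\n")
  invisible(x)
}
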