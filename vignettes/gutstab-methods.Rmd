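---
title: "Models and methods behind gutstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gutstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutstab)
```

gutstab analyses gut-microbiota stability in two-arm longitudinal studies
of the kind run in sow nutrition trials: two dietary treatments (CON, DF),
repeated faecal sampling across gestation and lactation (G0, G30, G90,
G109, L3, L14), 16 subjects per arm, genus-level 16S count tables, and
per-sow reproductive outcomes. This vignette explains each model the
package implements, the tunable parameters that matter, and the choices
made where the design was genuinely open.

## The synthetic study generator

Every downstream method is exercised against simulated studies with known
ground truth, so the generator is first-class, tested code rather than a
fixture.

Counts are generated hierarchically. Per taxon $t$ a log-scale mean
$\mu_t \sim N(0, 2)$ is drawn once per configuration; the heavy spread
produces the strong dominance structure (a few abundant genera, a long
rare tail) typical of gut communities. Per sample, latent log abundances
are

$$z_{st} = \mu_t + b_{s(t)} + \delta_{st} + \varepsilon_{st}, \qquad
\varepsilon_s \sim N(0,\; \sigma^2 \, R),$$

where $R$ is the planted basis-correlation matrix (identity except
`n_correlated_pairs` disjoint pairs set to `pair_rho`), $\delta$ holds the
planted arm-by-timepoint effects in log units
(`log2_effect` $\times \ln 2$), and $b$ is a per-subject random intercept
constant over time. Abundances $e^{z}$ are closed to fractions and counts
drawn multinomially at a log-normal depth
(`depth_mean` = 30{,}000, `sdlog` = `depth_dispersion` = 0.3 by default,
emulating Illumina depth variation and motivating rarefaction).

Three choices deserve explanation:

* **Subject intercepts are per subject *and* per taxon.** A single
  per-subject constant added to every taxon's log abundance is removed
  exactly by compositional closure (all fractions unchanged), so it would
  be unobservable by construction. A subject-by-taxon intercept matrix
  with SD `subject_sd` (default 0.5) is what a per-genus mixed model's
  random intercept actually estimates, and is recorded in the ground
  truth.
* **Noise scale (`taxon_sd` = 0.6).** The paper-style design fixes the
  planted effect at +2 log2 (4-fold) and the sample size at 16/arm; the
  within-subject log-scale noise is the free parameter. 0.6 (about
  1.8-fold sample-to-sample variation, on top of the subject intercept)
  keeps those effects detectable at that sample size, which is the
  generator's job: effect magnitudes for differential genera are not
  published, so defaults are chosen for testability of the pipeline, not
  fidelity to any particular cohort.
* **Recovery experiments plant effects on minor genera.** A planted
  log-linear effect on a *dominant* taxon is attenuated on the
  relative-abundance scale, because raising its abundance inflates the
  sample total. Supplying `taxon_log_means` with the planted taxon at
  $\mu = -2$ (sub-1% abundance) makes the relative-abundance coefficient
  essentially equal to the planted one, so confidence-interval coverage
  is a meaningful check. This mirrors reality: differential genera in
  such studies are almost always minor taxa.

Zeros arise naturally from multinomial sampling; there is no explicit
zero-inflation term. The master seed expands to per-stage child seeds by
fixed arithmetic (`seed * 1009 + stage offset`, mod $2^{31}-1$) so stages
can be rerun independently and everything is bit-reproducible.

What the generator does **not** emulate: phylogenetic structure, read-level
error or chimeras, taxon-specific overdispersion beyond the log-normal,
and zero-inflation mechanisms beyond sampling. Passing recovery tests here
therefore demonstrates correctness of the estimators under the stated
model, not robustness to every failure mode of real amplicon data.

## Rarefaction, coverage, diversity

Rarefaction subsamples each sample without replacement (multivariate
hypergeometric) to a fixed depth; samples below the target are dropped
with a warning, mirroring the usual "rarefied to a common depth" contract.
Whether to compute alpha diversity on rarefied or raw counts is a
pipeline-level choice; the worked examples rarefy first, and every
function accepts either.

Shannon diversity uses the natural log (values 3–5 for gut communities;
log2 by flag). Chao1 uses the bias-corrected form
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, finite when doubletons are absent; the
classic form is available by flag. Good's coverage is $1 - F_1/n$.

Bray–Curtis dissimilarity is computed on counts via vegan. It is a
semimetric — the triangle inequality is not asserted anywhere. PCoA
performs Gower double-centering of $-d^2/2$ and an eigendecomposition;
negative eigenvalues (expected for Bray–Curtis) are reported but excluded
from coordinates and from the explained-variance denominator, and no
Cailliez/Lingoes correction is applied by default. Axis reflections are
fixed by flipping each axis so its largest-magnitude coordinate is
positive. PERMANOVA wraps `vegan::adonis2` with an explicit seed; labels
are permuted freely (one-way), so for the repeated-measures design the
documented usage is per-timepoint invocation.

## SparCC correlation inference

Compositional closure makes naive correlations of relative abundances
spurious. SparCC estimates correlations between latent *basis* abundances
from the variation matrix $t_{ij} = \mathrm{Var}\,\log(f_i/f_j)$, which is
invariant to per-sample scaling. Under a sparsity assumption the basis
variances $\omega_i^2$ solve the linear system
$M\omega^2 = \mathrm{rowSums}(T)$ with $M = (D-2)I + J$, and

$$\rho_{ij} = \frac{\omega_i^2 + \omega_j^2 - t_{ij}}
{2\,\omega_i\,\omega_j},$$

clipped to $[-1, 1]$. The strongest pair exceeding the exclusion
threshold (default 0.1) is iteratively removed from the system and it is
re-solved, up to 10 rounds (reference defaults). If an exclusion
degenerates the system — possible in small panels when a taxon's partners
are exhausted — the exclusion is reverted and refinement stops; an
initially singular system is an explicit error. Negative solved variances
are floored at $10^{-10}$ with a warning and the affected taxa flagged.

Fractions come from Dirichlet(counts + 1) draws; the point estimate is the
element-wise **median** over `n_inner` (default 20) draw pipelines, for
robustness to individual draws. `n_inner = 0` gives the deterministic
pseudocount fractions $(c+1)/(n+D)$, useful for order-invariance and
closure checks.

The published "100 bootstrap iterations" for significance are implemented
as a **per-taxon permutation null**: each taxon's counts are permuted
independently across samples, the full pipeline is re-run, and two-sided
pseudo-p-values use the add-one rule
$(1 + \#\{|r^{null}| \ge |r^{obs}|\})/(1 + n_{null})$. Resampling samples
*with* replacement would preserve the correlations and cannot form a null;
the permutation scheme is the cited algorithm's own pseudo-p procedure.

Networks keep edges with $|r| > 0.5$ (strictly, per the usual convention)
and $p < 0.05$; isolated nodes are retained by default so node counts are
comparable across strata, with a flag to drop them (both conventions
appear in published node counts). Networks are built per
treatment-by-timepoint stratum; with 16 samples per stratum the estimates
are noisy, which is surfaced as a warning below 10 samples rather than
hidden.

Under the planted design used for validation (50 taxa, 200 samples, depth
50k, 10 pairs at $\rho = 0.8$) the pipeline attains edge sensitivity
$\ge 0.8$ and specificity $\ge 0.95$ at those thresholds, with true-zero
mean $|\hat r| < 0.1$; see `scripts/acceptance.R`.

## Network topology, stability, hubs

The topology bundle follows the common network-analyzer definitions:
average neighbours $2E/N$; characteristic path length averaged over
*connected ordered pairs only* (the networks are usually disconnected);
mean local clustering with degree-<2 nodes counted as zero (a flag
excludes them instead — the two conventions differ and affect
comparability across tools); density $2E/(N(N-1))$; degree heterogeneity
$\sqrt{\mathrm{Var}_{pop}(k)}/\bar k$; degree centralization
$\frac{N}{N-2}\left(\frac{k_{max}}{N-1} - \text{density}\right)$.

**Natural connectivity** is
$\bar\lambda = \ln\!\big(\tfrac{1}{N}\sum_i e^{\lambda_i}\big)$ over the
eigenvalues of the *unweighted* 0/1 adjacency matrix (the log-mean Estrada
index), computed with log-sum-exp stabilisation. It measures redundancy of
closed walks: an edgeless graph scores exactly 0 and adding any edge
strictly increases it. Weights/signs are dropped because the printed
formula references the adjacency matrix; a weighted variant
(|r|-weighted) sits behind a flag. Robustness curves remove a fraction of
nodes — uniformly at random (averaged over `n_reps`, default 100) or in
descending degree order (deterministic) — and track the natural
connectivity of the surviving induced subgraph over a fraction grid
(0 to 0.8 by 0.05 by default; the removed-fraction axis is a choice, node
counts would do equally).

**MCC (maximal clique centrality)** scores each node by
$\sum_{C \ni v} (|C|-1)!$ over maximal cliques $C$. An edge that is itself
a maximal clique contributes $1! = 1$, so a node whose neighbours are
mutually non-adjacent scores exactly its degree — the reference special
case falls out of the general formula. Enumeration uses igraph's
Bron–Kerbosch implementation with a hard cap (default $10^6$ cliques)
that fails loudly rather than hanging on pathological graphs. Ties share
the smaller rank (competition ranking, "1, 2, 2, 4"), reported as
`rank/N`.

## Differential genera: LMM ∩ LEfSe

Per genus, the longitudinal screen fits

$$\log_{10}(\text{rel. abundance} + \delta) \sim
\text{treatment} \times \text{timepoint} + (1 \mid \text{subject})$$

by REML, with $\delta$ = half that genus's smallest nonzero relative
abundance (taxon-specific, so rare genera are not drowned by a global
pseudocount). P-values are marginal (type-III-style) Satterthwaite F
tests per fixed-effect block. Non-converged or singular fits are flagged,
never silently dropped. Following the published table layout, raw
$p < 0.05$ per effect defines the "affected by both treatment and stage"
set (treatment AND time; the interaction is reported and can be required
via a flag), and BH-adjusted columns are emitted alongside for
transparency.

LEfSe is implemented for the two-class, no-subclass design: (1)
Kruskal–Wallis on relative abundances scaled to $10^6$, $\alpha = 0.05$;
(2) over 30 bootstrap rounds, two-thirds of each class is subsampled and
the absolute difference of class means recorded; the LDA score is
$\log_{10}$ of the mean effect, floored at 1 before the log, thresholded
at 2. With a single feature the discriminant axis coincides with the
feature axis, so the effect size is the class-mean difference on the
scaled-abundance scale — this reproduces the familiar LDA-score
magnitudes (2–5). Bootstrap subsamples are drawn in an order determined
by sample membership, not label names, so swapping class labels flips the
enriched class but reproduces identical scores. The full published
algorithm's subclass/pairwise-Wilcoxon tier is deliberately omitted: the
design has no subclass structure.

The intersection logic reports all tiers — the LMM set, the LEfSe set,
their intersection, and the intersection filtered to overall mean
relative abundance > 0.1% — since each tier is a published display.
Tightening any threshold can only shrink every reported set.

## Associations and the volcano filter

Spearman matrices between features and outcomes use average ranks for
ties and the t-approximation for p-values, with pairwise-complete
handling of missing outcomes and at least 4 complete pairs per cell.
Constant columns yield `NA` with a warning rather than an arbitrary
number. Because the published heatmaps annotate raw p-values, the output
carries both raw-p star tiers (*, **, *** at 0.05/0.01/0.001) and BH
q-values, clearly labelled.

The metabolite-style volcano filter computes fold changes on raw
intensity means (groups in factor order) but tests on the log scale
(Welch t), adjusts BH across features, and keeps features with
$q < 0.05$ and $|\log_2 FC| > 1$. Zeros are floored at half the feature's
smallest positive intensity with a warning.

## Numerical and testing notes

* All stochastic functions take explicit seeds and expand them through
  the same child-seed arithmetic as the generator; identical inputs and
  seeds give bit-identical outputs.
* Natural connectivity, topology metrics and MCC are cross-checked in the
  test suite against independent oracles (direct eigendecomposition,
  matrix-power BFS, exhaustive subset clique enumeration) rather than
  against the implementation's own primitives.
* Validation problem sizes were chosen to exercise the paper-scale regime
  while staying quick: SparCC recovery at 50 taxa × 200 samples with 100
  permutation nulls; PERMANOVA calibration over 500 null datasets at 199
  permutations; LMM coverage over 200 simulated studies of 32 subjects ×
  6 timepoints; the end-to-end dry run at 150 genera × 192 samples with
  four stratified networks.
* Known limitations: SparCC per 16-sample stratum is noisy (warned, not
  hidden); CPL and clustering conventions on disconnected graphs differ
  across tools and both are provided; the LMM assumes a common residual
  variance across timepoints; LEfSe's omitted subclass tier means scores
  are not comparable to runs of the full published algorithm on designs
  *with* subclasses.

## A compact end-to-end run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 20)                 # 2 arms x 16 sows x 6 timepoints
st  <- simulate_counts(cfg)
md  <- simulate_outcomes(st$counts, st$truth, st$metadata, seed = 20)

rar   <- rarefy_counts(st$counts, depth = 15000, seed = 20)
keep  <- md[match(rar$sample_id, md$sample_id), ]
alpha <- alpha_diversity(rar)
ord   <- pcoa_ordination(bray_curtis(rar))
perm  <- permanova(bray_curtis(rar), keep$treatment, n_perm = 999, seed = 20)

g30_df <- rar$sample_id %in% keep$sample_id[keep$treatment == "DF" &
                                            keep$timepoint == "G30"]
fit <- sparcc(rar[g30_df, ], n_inner = 20, seed = 20)
fit <- sparcc_pvalues(rar[g30_df, ], fit, n_null = 100, seed = 20)
net <- build_network(fit, r_threshold = 0.5, p_threshold = 0.05,
                     stratum = "DF_G30")
topology_summary(net)
natural_connectivity(net)
mcc_scores(net)
autoplot(robustness_curve(net, "random", seed = 20))

lmm  <- fit_lmm(rar, keep)
g109 <- keep$timepoint == "G109"
lef  <- lefse(rar[g109, ], keep$treatment[g109], seed = 20)
sets <- intersect_differential(lmm, lef, rar)
assoc <- spearman_matrix(relative_abundance(rar[g109, ]),
                         keep[g109, c("sample_id", "total_born",
                                      "born_alive", "healthy")])
autoplot(assoc)
```
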