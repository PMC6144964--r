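---
title: "Methods: two-stage otolith-microchemistry connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage otolith-microchemistry connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Marine fish with several dispersive life stages (eggs/larvae, settled
juveniles, migrating adults) cannot be tracked individually from hatching
to spawning. Otoliths — the fish's incrementally growing ear stones —
incorporate trace elements from the ambient water, so different parts of
one otolith record the chemical environment of different life stages.
`otoconnect` implements a two-stage analysis of this record:

1. **Natal-source inference.** Laser-ablation (LA-ICP-MS) spots near the
   otolith core reflect the early larval environment. Because larvae are
   never sampled at their (unknown) hatching grounds, the number of
   distinct natal sources and their elemental signatures are inferred by
   *unsupervised* clustering of near-core chemistry.
2. **Mixed-stock assignment.** Whole dissolved juvenile otoliths
   (WS-ICP-MS) from known nursery sites form a *baseline*. The
   juvenile-growth core milled out of adult otoliths of the same
   year-class is chemically comparable material; each adult is assigned
   to baseline sites by a Bayesian mixture model, yielding per-area
   origin compositions — the connectivity between nursery grounds and
   adult spawning aggregations.

Everything operates on element:Ca ratios (or concentrations) for a small
panel of elements — by default Mg, Mn, Sr, Ba, the four that carry
geographic signal in North Sea settings: Mn decreasing and Ba increasing
with latitude, Sr and Mg varying at smaller scales.

# Calibration (LA-ICP-MS)

Raw ablation count data are converted to concentrations in three steps
(`blank_drift_correct()`, `internal_standardize()`, `to_ca_ratio()`):

- **Blank subtraction.** Each standard and sample block has the nearest
  preceding argon gas blank subtracted, floored at zero; a block whose
  signal is at or below blank level is flagged (`clipped`).
- **Drift correction.** Runs are structured standard–sample–…–standard.
  Per isotope, the standard's blank-corrected sensitivity is interpolated
  linearly in run order between the bracketing standards and each sample
  is divided by the interpolated sensitivity relative to the run's first
  standard. The linear bracketing model is the field-standard choice for
  this run structure; no claim is made about curvature between standards.
- **Internal standardization.** Concentrations follow the classic
  relation `C_smp(i) = C_std(i) · [n_smp(i)/n_std(i)] ·
  [n_std(IS)/n_smp(IS)] · [Ca_smp/Ca_std]` with a Ca isotope as internal
  standard. Consequences that the tests verify: a sample identical to the
  standard recovers certified values exactly; multiplying all of a
  sample's counts by any constant (ablation-yield variation) leaves its
  Ca ratios unchanged.

Two configuration values deserve note. The otolith Ca mass fraction is
assumed to be 38.8 wt% (388,000 µg/g, aragonite stoichiometry) and is a
parameter of `standard_reference()`, not a constant. The internal-standard
isotope is likewise configurable (default `Ca43`), since instruments
monitor different Ca isotopes and ratios may be reported against another;
one cannot ratio against an unmonitored isotope. `nist612()` ships
nominal preferred values for the usual reference glass; they are defaults,
not authority.

# Stage one: unsupervised random-forest clustering

Near-core chemistry is standardized (column-wise center/scale) and
contrasted against a *synthetic reference*: each element column resampled
independently with replacement (`synthetic_reference()`), i.e. a draw
from the product of the empirical marginals. A random forest is trained
to separate observed from synthetic rows; structure (dependence between
elements) is exactly what the synthetic class lacks, so the forest's
terminal nodes group chemically coherent fish. The proximity
`s_ij` = fraction of trees in which fish *i* and *j* share a terminal
node (all trees counted; the all-trees proximity is the classical
definition and is more stable at these sample sizes than OOB-restricted
variants). Dissimilarity is `d_ij = sqrt(1 − s_ij)`.

`pam_partition()` clusters the dissimilarity matrix by k-medoids. When
`choose(n, k)` ≤ `exact_limit` (default 1000) the optimum is found by
direct enumeration — at such sizes enumeration costs microseconds and,
unlike the BUILD+SWAP heuristic, is provably optimal (we measured
BUILD+SWAP, ours and the reference implementation in **cluster**, missing
the global optimum on roughly 15% of small random matrices). Above the
limit the deterministic BUILD+SWAP heuristic runs, with ties in point
assignment broken toward the lowest medoid index.

The number of clusters is scanned (default k = 2…8) and scored by the
Dunn index: minimum between-cluster separation over maximum
within-cluster diameter (`dunn_index()`, the classical single-linkage /
complete-diameter variant; `choose_k()` ties resolve to the smallest k).
`choose_k(override =)` supports fixing k from external evidence — e.g.
when the number of chemically similar coastal regions is known — while
retaining the full profile.

**What the Dunn profile can and cannot do.** On RF dissimilarities of
strongly overlapping clusters, within-cluster diameters saturate near 1
(some pair of same-cluster fish almost never co-occurs in a leaf), so
profiles flatten and the argmax becomes unstable. Under the default
synthetic scenario below, whose four natal sources overlap heavily, the
profile rarely peaks at the generating k = 4; with well-separated sources
(see `scenario_preset("north_south")`, or doubled separation) it does.
This mirrors the general experience that cluster-count selection is only
as sharp as the clusters themselves.

# Stage two: Bayesian mixed-stock assignment

The baseline model (`baseline_model()`) treats each site *j*'s
(optionally log-transformed) element vectors as multivariate normal with
unknown `(µ_j, Σ_j)` under a conjugate Normal–Inverse–Wishart prior, and
the adults as a finite mixture over sites with proportions π under a
Dirichlet(α = 1) prior. A Gibbs sampler (`fit_mixed_stock()`) alternates:

1. latent origins `z_i | π, {µ_j, Σ_j}` — categorical with weights
   `π_j · N(x_i; µ_j, Σ_j)`;
2. `π | z` — Dirichlet(α + counts);
3. `(µ_j, Σ_j)` — drawn from their NIW posterior.

Because the site parameters are *redrawn every sweep* rather than fixed
at point estimates, baseline sampling uncertainty propagates into the
assignment probabilities — the sense in which strict multivariate
normality with known, homogeneous covariances is relaxed. In the default
`"conditioned"` mode the NIW posterior uses baseline data only, so sites
retain their identities and no label switching can occur; the `"full"`
mode additionally lets currently assigned adults update site parameters
(more information, more model risk; off by default).

Priors are weakly informative and data-scaled: prior mean = baseline
grand mean, κ₀ = 0.01 pseudo-observations, ν₀ = p + 2, and the
inverse-Wishart scale set so the prior covariance expectation equals the
pooled within-site covariance. Sensitivity is part of the test suite:
α = 1 vs α = 0.1 moves recovered proportions by < 0.03. The
log-transform is on by default (ratios are positive and right-skewed); a
switch disables it.

Posterior per-adult origin probabilities are the frequencies of `z_i`
across kept draws (default 4 chains × 5,000 sweeps, 2,000 burn-in,
thinning 5; seeds give exact reproducibility). Decisions
(`threshold_classify()`) use the 0.5-threshold rule: a single site if its
probability exceeds τ = 0.5, else a region if its member sites' summed
probability exceeds τ, else unassigned. "Unassigned" is thus defined
operationally as failing both thresholds. Convergence is monitored by
rank-normalized split-R̂ and bulk effective sample size
(`mcmc_diagnostics()`), with a warning above R̂ = 1.05.

Per-area origin contributions come in two forms: hard-decision
tabulations (`contribution_summary()`) and the model-based
`posterior_contributions()` — the mean posterior probability row of the
adults in each area, which is the better estimator of the area's origin
mixture and the one compared against ground truth in the acceptance
checks. Note the model pools all adults into one mixture π; per-area
composition is read off the per-adult posteriors. Batch effects between
the juvenile and adult solution runs are deliberately *not* corrected
(matching how such data are produced); `scenario_config(batch_offset =)`
exists to study what an uncorrected offset would do.

# Supervised discrimination

`rf_site_confusion()` quantifies how well sites can be told apart at all:
out-of-bag (OOB) predictions — each fish predicted only by trees that
did not see it — averaged over many independent forests (default 100
repeats for ablation-sized data; for the larger whole-otolith stream, 10
repeats of balanced 80-fish subsamples, 8 per site, so no site dominates).
`rf_importance()` reports permutation importance as mean decrease in OOB
accuracy, in percentage points, unscaled and untruncated (noise elements
legitimately scatter around zero). `region_aggregate()` sums
classification mass into regions; row mass is conserved to floating-point
addition accuracy.

# Nonparametric spatial statistics

Geographic signal is established with rank methods, since element ratios
are skewed and heteroscedastic: Kruskal–Wallis per element across sites
(midranks, tie correction, χ² approximation); Dunn's post hoc z tests on
the pooled ranks with Bonferroni adjustment by default (Holm and
unadjusted available) and a compact letter display in which sharing a
letter is *exactly* pairwise non-significance (greedy insert-and-absorb;
displays are not unique and any valid display satisfies that contract);
Spearman rank correlation against latitude (per-fish values by default;
per-site medians can be passed just as well); and Wilcoxon matched-pair
tests of near-core vs edge values per site, zero differences dropped and
counted, exact null distribution for ≤ 25 untied pairs and the
tie-corrected normal approximation otherwise.

# The synthetic-data generator

`scenario_preset("study_default")` emulates the design of a North Sea
juvenile/adult survey: ten nursery sites with 15 ablation fish per site
(none at one site, 135 total) and 43 whole-otolith fish per site (~430);
four natal sources whose mean (SD) signatures are fixed at published
natal-cluster values (source A: Mg 85.9 (23.4), Mn 5.2 (2.7), Ba 4.0
(2.3), Sr 2031.4 (433.7); similarly B–D); site edge-chemistry medians
with a negative latitudinal Mn gradient spanning ~3×, a positive Ba
gradient spanning ~1.6×, ~3× ranges in Mg and Sr with Mg high on the
eastern side and Sr declining north-to-Skagerrak and Tay-to-south; and a
mostly diagonal origin→area connectivity (0.6 self-recruitment, the rest
spread within region) standing in for unknown true movement.

The measurement model is log-normal with diagonal covariance on the log
scale: ratios are strictly positive and right-skewed, and only marginal
means/SDs of the natal sources are available, so independence on the log
scale is the minimal assumption (an optional correlation structure would
be a straightforward extension; true inter-element covariance within fish
is simply unknown). Per fish: the natal source is drawn from the site's
mixing column; near-core values from the source signature; edge values
from the site's settlement chemistry; the whole otolith is the linear
blend `w·core-like + (1−w)·edge-like` with w = 0.3 — the whole otolith
integrates the full juvenile period, dominated by post-settlement growth
— times multiplicative log-normal measurement noise (CV 0.1). Adults'
milled cores reuse their origin site's whole-otolith process. The
core-vs-edge temperature offset hook (`core_edge_offset`) defaults to 1
for every element so that the natal-source means equal the configured
signatures exactly; users studying temperature-driven core depression of
Mn/Mg can set multipliers below 1.

What passing tests on these simulations do **not** show about real data:
the generator has no inter-element correlation, no temporal drift, no
batch structure by default, site distributions are exactly log-normal,
and the connectivity ground truth is far simpler than real dispersal. The
simulations validate the *machinery* (calibration algebra, rank
statistics, clustering and assignment inference, thresholds, plumbing),
not any ecological conclusion.

# Numerical choices and degenerate inputs

- Seeds: every stochastic function takes an integer seed;
  `run_pipeline()` derives stage seeds as `seed + stage` so stages rerun
  in isolation. Reruns are byte-identical, including written CSVs
  (numbers are written at 10 significant digits).
- Ties: PAM assignment ties go to the lowest medoid index; `choose_k`
  ties to the smallest k; rank tests use midranks with tie corrections
  throughout.
- Degenerate inputs raise errors rather than NaNs: all-identical values
  in Kruskal–Wallis (tie correction divides by zero), zero variance in
  Spearman, all-zero paired differences, Ca ≤ 0, k ≥ n, singleton-only
  partitions (Dunn index returns `Inf` with a warning), singular baseline
  covariances (error advises a stronger prior or fewer elements).
- Problem sizes used by the test suite and the acceptance script (chosen
  to probe each property at the smallest informative size): 100 random
  matrices of n ≤ 10 for the PAM-vs-enumeration check; 20 (tests) or 10
  (script) simulation seeds for cluster and mixture recovery; 10,000 null
  simulations for type-I error; 45 adults per area for the end-to-end
  origin-matrix check; MCMC at 2 chains × 1,500–2,500 sweeps in checks
  (inference error well below the tolerances probed) vs the 4 × 5,000
  default for analyses.

# Known limitations

- The Dunn-index k-selection is unreliable for heavily overlapping
  sources (see above); treat the profile as evidence, not an oracle, and
  prefer the override when external structure is known.
- The assignment model is a *reconstruction* of a Bayesian mixed-stock
  framework with baseline uncertainty — a hierarchical MVN mixture with
  conjugate NIW site priors and Dirichlet mixture prior — chosen for
  testability; it is documented as such, not as a transcription of any
  particular published sampler.
- A single pooled π is estimated for the adult set; per-area compositions
  are posterior summaries, not separate mixture fits. Fitting per area is
  possible by calling `fit_mixed_stock()` per subset.
- No within-ablation spike rejection, limits of detection, or certified
  reference-material recovery statistics; a QC flag travels with records
  but is not acted on.
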