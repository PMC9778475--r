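---
title: "Models and methods behind scmra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical procedures it
implements, the choices that were genuinely open when designing them, and
what validation on synthetic data does and does not establish.

# The analysis chain

`scmra` targets a two-condition, cell-hashed single-cell RNA-seq
perturbation experiment: a treated and a vehicle-control population are
tagged with hashtag oligos, pooled on one droplet lane and sequenced
together. The pipeline runs:

1. hashtag demultiplexing into control (`ctr`), treated (`pnb`) and
   ambiguous `multiplet` droplets;
2. quality filtering and log-normalization;
3. marker-based cell-cycle phase assignment;
4. per-gene Wilcoxon differential expression (DE) with
   Benjamini–Hochberg (BH) correction;
5. gene-set enrichment of the DE signature and per-cell enrichment
   projections;
6. regulon-based master-regulator analysis (MRA) on two networks with a
   consensus;
7. pseudobulk aggregation and rank-correlation comparison;
8. survival association and Fisher integration of multi-source TF
   evidence.

## Demultiplexing

For hashtag counts $(a, b)$ the rule is applied in this order: $(0,0)$ is a
multiplet; a zero on one side with $\ge 1$ on the other assigns the nonzero
side; otherwise the cell is assigned to a group whose count is at least
$t$ times the other's, with $t = 10$ by default and the comparison
*inclusive* ($a \ge t\,b$). The inclusive reading makes the boundary
testable; the threshold is exposed because the appropriate stringency
depends on hashtag staining quality. Raw hashtag counts are used: the ratio
of two counts from the same droplet is already depth-free, so normalization
would only complicate the zero rule.

## Filtering and normalization

Cells with fewer than 1,000 detected genes are dropped first, then genes
detected in fewer than 3 cells — one pass each, cells before genes. Both
cutoffs are parameters; both filters are idempotent. Normalized expression
is $\ln(1 + c \cdot s / C)$ with per-cell total $C$ and scale factor
$s = 10^4$, the convention of the standard single-cell toolkits, so zeros
stay zero and values are comparable across depths. Gene-level dispersion is
reported as variance/mean of the normalized values (0 for constant genes);
this is one of several dispersion conventions in use, so it is documented
and the statistics are returned raw for any alternative.

## Cell-cycle scoring

Phase scores follow the binned-control approach: genes are placed into 24
equal-frequency bins of dataset-average expression, and each marker gene's
contribution is its expression minus the mean of up to 100 control genes
from the same bin, averaged over the program. One deliberate refinement:
expression is centred per gene before scoring, so a score measures a cell
*relative to the dataset average*. This makes the zero threshold
meaningful by construction (a dataset of identical cells scores exactly 0)
rather than approximately so. Assignment is G1 when neither the S nor the
G2M score is positive, otherwise the larger score's phase, with exact ties
resolved to S (documented, arbitrary). Marker lists are explicit inputs
(character vectors or GMT): the package does not bundle a particular
S/G2M list, since list choice is a scientific decision and the synthetic
generator provides planted programs for validation.

## Differential expression

Per gene, a two-sided Wilcoxon rank-sum test via the normal approximation
with tie correction and continuity correction. The tie correction is not
optional at single-cell zero inflation; the normal approximation (rather
than exact enumeration) is the only practical choice at hundreds of cells
per group, and its agreement with exact enumeration is verified in tests
for group sizes up to 6 (absolute p difference at most 0.03). BH
adjustment delegates to `stats::p.adjust`; a brute-force step-up
implementation serves as the oracle in tests, not as the implementation.

The log2 fold change is computed on de-logged means,
$\log_2\frac{\overline{e^{x}-1}_{\text{treated}} + 1}
{\overline{e^{x}-1}_{\text{control}} + 1}$, with pseudocount 1 — the
convention of the mainstream toolkit; computed on the log scale the value
would be systematically smaller. The per-gene signature score is
$-\log_{10}(p_{\mathrm{adj}}) \cdot \mathrm{sign}(\log_2 FC)$ with
$p_{\mathrm{adj}}$ floored at $10^{-300}$ to keep scores finite.
Significance summaries use $p_{\mathrm{adj}} \le 0.01$ and strict
$|\log_2 FC| > 1$, symmetric for both directions.

## Gene-set enrichment

The enrichment score (ES) is the classical weighted running sum: genes
ranked by decreasing score (ties broken by gene identifier for
determinism), hits increment by $|s|^w$ normalized over the hits
($w = 1$ default; equal increments if all hit scores are 0), misses
decrement $1/(N - k)$. The ES is the running-sum value of maximal absolute
deviation; an exact tie between the positive and negative extremum
resolves to the positive one (a documented tie-break, with a $10^{-9}$
tolerance absorbing floating-point noise in the rational increments).

The null is gene-permutation: `nPerm` random same-size sets from the same
ranked list. NES divides the ES by the mean $|ES|$ of same-signed nulls;
the p-value counts nulls at least as extreme in absolute value, with a
plus-one correction so it is never exactly 0. Counting two-sidedly keeps
null p-values approximately uniform on $(0,1]$, which the tests verify by
a Kolmogorov–Smirnov check.

Per-cell signatures are each cell's normalized profile minus the per-gene
dataset mean — a contrast "relative to the average of the dataset". The
raw per-cell profile is an alternative strategy, but centering is the
default because uncentered profiles make every abundant housekeeping set
appear enriched in every cell.

## Master-regulator analysis

A regulon is a TF with targets carrying a mode of regulation
$m_i \in [-1, 1]$ and a likelihood $\ell_i \in (0, 1]$. The signature's
signed scores are rank-transformed to normal quantiles
$z_i = \Phi^{-1}\!\big(\frac{r_i - 0.5}{N}\big)$ — robust to the p-floor
and to heavy tails — and cumulated per TF as

$$\mathrm{NES} = \frac{\sum_i m_i\, \ell_i\, z_i}
{\sqrt{\sum_i \ell_i^2}},$$

standard normal under the null, giving an analytic two-sided p-value.
This is a likelihood-weighted Stouffer cumulation of mode-signed
z-scores: deliberately simpler than three-tail regulon-enrichment
implementations used elsewhere in the field. It is validated by
planted-truth recovery and null calibration (empirical SD within
[0.9, 1.1] over 2,000 null replicates), not by numerical identity with
any external package. TFs with fewer than two usable targets are skipped
with a message rather than zero-filled, so absence of evidence is not
reported as evidence of no activity.

Two networks are combined per shared TF by an equal-weight Stouffer sum
$(\mathrm{NES}_A + \mathrm{NES}_B)/\sqrt{2}$. Equal weights are the
neutral choice when there is no basis for trusting one cohort network
over the other; both inputs are returned for scatter-style inspection.

## Pseudobulk and comparison

Pseudobulk profiles are plain per-group sums of raw counts, normalized as
reads per million (RPM, summing to $10^6$). Comparisons use Spearman
correlation (Pearson on mid-ranks), appropriate for counts spanning
orders of magnitude. In synthetic runs the pipeline reports a split-half
correlation of the control pseudobulk — how well half the control cells
recapitulate the other half, the within-experiment analogue of a
single-cell-vs-bulk comparison — and the treated-vs-control pseudobulk
correlation.

## Survival and evidence integration

The Kaplan–Meier estimator is the textbook product-limit; the univariate
Cox model maximizes the Breslow partial likelihood by Newton–Raphson with
step-halving (at most 50 iterations, tolerance $10^{-9}$ on $\beta$,
score residual below $10^{-8}$ at convergence), with a Wald z and
two-sided normal p. Breslow tie handling is the simplest consistent
choice; tests cross-check the fit against `survival::coxph` with matching
ties. Expression stratification uses rank-based near-equal quantile bins
(quartiles by default — the number of strata is a parameter because the
choice is presentational).

Evidence integration combines per-TF p-values from heterogeneous sources
(own differential expression, network activity on each cohort network,
several survival cohorts) by Fisher's method,
$X^2 = -2\sum \ln p_i \sim \chi^2_{2k}$. Signed evidence is first mapped
to one-sided p-values in the direction of interest — repressed activity
and poor prognosis — via the normal CDF (`nesToOneSidedP`), since ranking
"most repressed and most prognostic" is a directional question; a
two-sided mode is available upstream by supplying two-sided p-values.
Missing sources are dropped per TF and the degrees of freedom adjust;
imputing them would manufacture evidence. Ties in the final ranking break
by TF identifier.

# The synthetic-data generator

The generator emulates the targeted experimental design: two hashed
conditions of `nCellsPerGroup` cells each (default 1,250, i.e. a ~2,500
cell experiment) over `nGenes` genes (default 18,000), plus a
`multipletRate` fraction (default 0.072) of ambiguous droplets.

* **Counts.** Gene baseline abundances are log-normal (sdlog 1.2,
  normalized to proportions); per-cell library sizes are log-normal
  (meanlog $\log 20{,}000$, sdlog 0.4, matching the coverage range of a
  typical droplet run); counts are negative-binomial with shared
  dispersion 0.3 (variance $\mu + 0.3\mu^2$). This is sufficient for
  rank-based downstream statistics; it is not a full generative model of
  droplet data.
* **Perturbation.** In treated cells, each planted TF shifts its targets'
  means by $e^{m_i \cdot \mathrm{effect}}$ and its own mean by
  $e^{\mathrm{effect}}$ — the TF itself moves with its regulon so that
  expression-based ("Exp") evidence is concordant with activity-based
  ("Act") evidence, as in a transcriptionally repressed regulator.
* **Cell cycle.** Disjoint 50-gene S and G2M programs (drawn outside the
  regulon network where possible) are multiplied by 2 in cells of the
  matching phase; G1 has no program, consistent with assignment-by-default.
  Default phase fractions plant a treated-group G1 arrest
  (25.39/49.52/25.09 → 47.65/36.25/16.10 percent for G1/S/G2M).
* **Hashtags.** Poisson counts: the cell's own hashtag around a signal
  mean (200), the other around a background mean (2); multiplets draw the
  signal mean on both. The magnitudes are free parameters of the design —
  real staining intensities vary widely — chosen so the three clouds
  (control, treated, ambiguous) are well separated on the log scale.
* **Survival.** Exponential event times with hazard
  $h_0 e^{\beta x}$, $\beta = \ln(\mathrm{HR})$, standard-normal
  expression, independent exponential censoring calibrated to the target
  censoring fraction.
* **Determinism.** All randomness flows from a single seed through an
  explicit save/restore of the RNG state; identical seeds give
  bit-identical matrices, and derived child seeds keep stages independent.

What passing on these data shows — and what it does not: recovery of
planted regulons, phases and groups demonstrates the statistical chain is
correctly wired and calibrated under a negative-binomial world with
log-normal depth variation. It does not demonstrate robustness to
ambient RNA, transcriptome-mixing doublets, batch structure, or empty
droplets, none of which the generator emulates.

Because a single inferred network cannot test the two-network consensus,
`perturbNetwork()` derives a cohort-style replicate (random 70% target
retention per regulon, Gaussian likelihood jitter of SD 0.1, modes
preserved) — emulating two networks inferred from different patient
cohorts over the same underlying regulation.

# Problem sizes used in validation

The shipped tests and the acceptance script scale the study design down so
the full suite runs in well under a minute of compute per scenario: 80–200
cells per group and 600–3,000 genes for recovery and calibration runs,
2,000 replicates for null-NES calibration, exhaustive oracles at small
sizes (all $\le 5$-gene sets in a 20-gene universe; all 4-subject
censoring patterns; group sizes $\le 6$ for exact Wilcoxon enumeration).
These sizes were chosen as the smallest at which the asymptotic
approximations under test are already in their working regime; the
generator's *defaults* remain at the full experiment scale.

# Known limitations

* The MRA statistic is an analytic approximation; it does not implement
  pleiotropy or shadow corrections, and regulons overlapping a planted
  regulon inherit some of its signal.
* DE treats cells as independent replicates (no pseudoreplication-aware
  model); with only one flask per condition this is a design constraint,
  not a modelling choice.
* The demultiplexer is rule-based for exactly two hashtags; likelihood
  mixture models and $k > 2$ designs are out of scope.
* Embedding projections (t-SNE and the like) are presentation, not
  inference; the pipeline does not compute them and no result depends on
  them.
* Survival modelling is univariate with Breslow ties; multivariate
  adjustment and proportional-hazards diagnostics are out of scope.
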