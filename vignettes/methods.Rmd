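---
title: "Methods: scoring and rewiring analysis of two-condition interaction screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and rewiring analysis of two-condition interaction screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical machinery of `giscreen`: the model
behind each stage, the parameters that matter and their defaults, what the
synthetic screen generator does and does not emulate, and the numerical
and design decisions taken where more than one reasonable choice existed.

## The measurement model

An arrayed double-mutant screen crosses `n_donors` query mutants against
`n_recipients` library mutants, pinning `n_replicates` colonies per pair
(default 8, i.e. duplicate screens in quadruplicate) in each of two
growth conditions, rich medium (RM) and minimal medium (MM). The observed
quantity is colony size, a proxy for double-mutant fitness, in arbitrary
intensity units.

Under genetic independence, relative fitness multiplies: a pair whose
single mutants have relative fitness $W_d$ and $W_r$ is expected to reach

$$E_{dr} = R \, W_d \, W_r,$$

where $R$ is the condition-wide reference colony size. An epistatic
interaction is a deviation from $E_{dr}$: negative (aggravating,
synthetic sick/lethal) or positive (alleviating, suppression).

## Normalization

`normalize_screen()` works in two steps, both within a condition:

1. **Row/column correction** (optional, on by default): one round of
   median polish on the log colony sizes of each plate. Only the fitted
   row and column effects are removed; the plate's overall level stays.
   This removes pinning gradients and the systematic size bonus of border
   colonies. Plates too sparse to identify row and column effects (fewer
   than three occupied rows or columns) are left untouched, as are plates
   whose incidence pattern makes the fit unstable.
2. **Plate-median scaling**: each plate is rescaled so its median
   non-missing colony size equals the condition-wide median of plate
   medians.

The polish iterates to a $10^{-13}$ effect tolerance, and a plate whose
fitted effects are all below $10^{-6}$ log units (far below any
measurable artifact) is treated as already corrected. Together with the
exactness of median scaling after a first pass, this makes normalization
idempotent: renormalizing a normalized screen is a no-op. Missing
colonies stay missing; zero sizes pass through the log-scale polish
unchanged.

Pairs whose genes lie within 30 kbp of each other on the circular
chromosome are removed before scoring (`filter_linked_pairs()`):
recombination frequency near the query locus is too low for reliable
double-mutant construction. The distance is circular
($\min(|p-q|, L - |p-q|)$) because the bacterial chromosome is a circle,
and the window boundary is inclusive.

## Single-mutant fitness

`estimate_fitness()` uses medians for robustness: $W_d$ is the median of
a donor's colony sizes across all recipients and replicates divided by
the condition-wide median size, and analogously for recipients. With a
few percent of pairs carrying true interactions, the median over hundreds
of partners is essentially unaffected by them. Genes with fewer than
`min_replicates` (default 4) usable colonies are flagged and excluded
from scoring rather than scored badly.

## Static interaction scores

**Multiplicative model** (`score_multiplicative()`): a t-like statistic

$$S = \frac{\bar{y}_{dr} - E_{dr}}{s_{dr}/\sqrt{n}},$$

where $s_{dr}$ is a *moderated* replicate SD: the per-pair sample
variance is shrunk toward the screen-median variance with
`moderation_df` (default 50) pseudo-degrees of freedom, then floored at
the 5th percentile of per-pair SDs. Moderation matters twice. With eight
replicates the raw SD estimate has roughly 27 % sampling error, which
(i) spreads the scores of equally strong interactions apart, costing
recovery power, and (ii) makes a strong pair's score differ between
conditions purely through independent variance estimates, which would
later masquerade as differential rewiring. The default weight leaves
about 12 % of the variance information to the individual pair —
appropriate for colony screens where replicate variance is dominated by
shared technical noise. `moderation_df = 0` restores the plain
floored-SD statistic.

**Gaussian-process model** (`score_gaussian_process()`): a GP regression
of the per-pair mean size on $(W_d, W_r)$ captures smooth
non-multiplicative trends (e.g. saturation of colony growth for very fit
pairs) that the product model cannot. Design choices:

* The **multiplicative surface is the GP's mean function**: the GP is fit
  on residuals $y - E_{dr}$ and its prediction added back. Where kernel
  support is thin (corners of fitness space), the prediction reverts to
  the multiplicative expectation instead of extrapolating freely; free
  extrapolation was observed to disagree between conditions at
  high-leverage points and to fabricate differential signal.
* **Heteroscedastic known noise**: each pair's mean carries sampling
  variance $s^2_{dr}/n$ from its own moderated replicate SD; the
  marginal-likelihood optimisation fits only the kernel (squared
  exponential, one length scale) and a shared extra white-noise term.
  Scores are therefore standardized by a predictive SD that reflects each
  pair's own replication quality.
* **Outlier-trimmed fitting**: training points whose multiplicative
  residual exceeds 3 noise SDs are excluded up front (these residuals
  cannot absorb an epistatic outlier, unlike the GP's own leave-in
  residuals), followed by up to two GP-residual trimming passes. Without
  trimming, planted epistasis inflates the fitted noise and compresses
  all scores.
* **Determinism and scale**: hyperparameters are optimised by L-BFGS-B
  from a fixed set of starting points on a fixed-seed subsample of at
  most `opt_cap = 250` pairs; the predictive distribution is conditioned
  on at most `fit_cap = 500` pairs, and all pairs are predicted from that
  set. The fit is a deterministic function of the data and `gp_control()`.
  Predictive SDs below $10^{-6}$ of the colony-size scale are floored;
  this matters only for noise-free inputs, where the score would
  otherwise be a ratio of numerical zeros.

The score is $S = (\bar{y}_{dr} - \mu_{dr})/\sigma_{dr}$ with $\mu, \sigma$
the posterior predictive moments.

**Standardization** (`standardize_scores()`): within a condition,
$Z = (S - \bar S)/\mathrm{sd}(S)$ over all scored pairs and
$P = 2(1-\Phi(|Z|))$, so the two-SD threshold $|Z| \ge 2$ corresponds to
$P \le 0.0455$. A robust variant (median/MAD) is available and is used
internally by the differential stage (below); classical moments remain
the calling default.

**Calling** (`call_static_network()`): a pair is significant only when
*both* models classify it non-neutral with the same sign. Non-neutral
under a model means the score falls at or outside the model's neutral
band for the condition — defaults are the two-SD bands multiplicative RM
$(-0.3, 1.8)$, MM $(-1.4, 3.0)$ and Gaussian-process RM $(-0.9, 1.3)$,
MM $(-2.3, 1.9)$ — with $|Z| \ge 2$ and $P \le 0.05$. All comparisons are
inclusive. Significant edges carry the Gaussian-process score. Sign
concordance (not mere co-significance) is required by default because it
is the stricter and more interpretable rule; `scoring_thresholds()`
exposes the switch.

## Differential network

`compute_differential()` forms $S_{DF} = S_{MM} - S_{RM}$ on a common
scale: within each condition the GP scores are centred by their median
and scaled by their MAD. Two properties motivate this:

* Without a common scale, any difference between the conditions' score
  scales (fitted noise, reference size) would shift every strong
  interaction's $S_{DF}$, flooding the differential network with
  condition-stable pairs.
* The scale must be estimated from the *neutral background*: a classical
  SD is inflated by the interaction signal itself, which would shrink
  genuine rewiring below the cut-offs.

Significance comes from an empirical null (`difference_null()`): within
each condition the replicates are split in half, each half is scored
through the same pipeline (fitness re-estimation, GP scoring, robust
standardization), and the within-condition half-score differences are
pooled over conditions and `n_splits` random splits. These differences
carry the full scoring noise but no condition effect. Each half holds
half the replicates, yet its own standardization would hide that extra
noise, so the differences are multiplied by $\sqrt{2}$ to restore the
variance ratio between a split half and the full screen — the null is
deliberately conservative on the full-replicate scale.
$P_{DF}$ is the add-one-smoothed two-sided empirical tail, never zero.

`call_differential()` applies the cut-offs $S_{DF} \le -2.6$
(aggravating) or $S_{DF} \ge 1.7$ (alleviating) with $P_{DF} \le 0.05$,
boundaries inclusive. `classify_gain_loss()` restricts to
$|S_{DF}| \ge 5$ and $P_{DF} \le 0.05$ and labels pairs neutral in the
static RM network but significant in MM as gains, the mirror case as
losses, and pairs significant (or neutral) in both by the dominant shift
($|S_{MM}| > |S_{RM}|$ is a gain). Records are ordered by average-linkage
hierarchical clustering of $(S_{RM}, S_{MM})$ with Euclidean distance,
on input sorted by pair id so the leaf order is deterministic. Note the
magnitude cut-off is quoted on the published score scale; on this
package's robust-Z scale the default planted effect reaches
$|S_{DF}| \approx 15$, so the cut is meaningful but its absolute value is
scale-specific.

## Network statistics

* `hypergeom_upper_tail(k, n, M, N)`: exact $P(X \ge k)$ for the number
  of significant interactions between two categories ($n$ possible)
  drawn from a network with $M$ significant of $N$ possible; BH
  adjustment via `bh_fdr()`. Fuzzy bioprocess membership counts a gene
  pair once per category pair it instantiates, and $M, N$ are totals on
  the same fuzzy universe, keeping the four parameters consistent.
  Intraconnectivity is the self-pair case. With 13 major categories,
  91 category pairs are testable; a 53-category minor universe yields
  1431.
* `module_crosstalk_permutation()`: observed inter-module interaction
  counts against a null that reassigns gene-to-module labels (sizes
  preserved; default 1000 shuffles), $Z = (obs - \mu)/\sigma$, significant
  at $Z \ge 1.65$ (one-sided 5 %). Degenerate permutation spreads yield a
  flagged missing Z, never an infinity.
* `profile_correlation()` / `autocorrelation()`: Pearson correlation of
  interaction-score profiles over shared partners (≥ 30 by default,
  excluding the genes themselves); autocorrelation compares one gene's
  RM and MM profiles, with the 0.25 boundary assigned to the high class.
  Pearson is used throughout; reported $r$ values in this literature are
  conventionally Pearson.
* `degree_stats()`: degree, hub flag (≥ 100 interactions, inclusive),
  aggravating:alleviating ratio (missing when the denominator is zero),
  and edge summaries by regulator scope and orphan status.

## Evolutionary analyses

`co_conserved()` implements the all-phyla rule: a pair is co-conserved
only if both genes are present in every phylum of the panel (default 17
bacterial phyla; presence means at least one orthologous species).
Restricting the panel (e.g. to γ-Proteobacteria) relaxes the rule
monotonically. `conservation_enrichment()` counts co-conserved
significant interactions per process pair against profile shuffling.
`paralog_filter()` keeps pairs with alignment coverage ≥ 50 %, E-value ≤
5e−2 and identity ≥ 30 % — boundaries inclusive, one qualifying
direction suffices (reciprocity is not required). `paralog_gi_bias()`
compares the aggravating fraction among paralog pairs with resampled
non-paralog pairs (add-one-smoothed empirical P).

## The synthetic screen generator

`simulate_screen()` emulates the screen at the level downstream
statistics can sense:

* colony size = $B \, W_d W_r$ + planted effect + row/column offsets +
  edge bonus + truncated Gaussian noise, with a configurable missing
  fraction;
* single-mutant fitness from a normal truncated to $(0, 1.2]$, centred at
  0.95 with SD 0.1 — deletion libraries are mostly near-neutral with a
  tail of sick mutants; the exact distribution is a free choice as no
  empirical one is available at this level;
* planted interactions: `round(fraction × pairs)` per sign (defaults 5 %
  + 5 %), effect ±6 replicate-noise SDs on the expected size; 30 % of
  each sign rewired into exactly one condition, split evenly RM/MM, so
  truth bookkeeping is exact arithmetic;
* fitness is identical across conditions, so *all* genuine differential
  signal comes from planted rewiring — which is what makes the
  stable-pair false-call rate measurable;
* plate structure: each donor's recipient × replicate colonies fill its
  16 × 24 plate set densely, with positions randomized within the set.
  Spatial randomization is standard screen design; it is also what makes
  row/column artifacts statistically identifiable. (A contiguous
  replicate layout leaves ~3 recipients per plate row, and median polish
  then confounds recipient fitness with row artifacts.)
* seeding: one root seed; every sub-generator derives a child stream
  from a fixed label, so adding a generator never perturbs existing
  draws, and identical configurations are bit-reproducible.

What it does **not** emulate: conjugation efficiency, selection failures,
image segmentation error, growth saturation kinetics, batch effects
across days, or biologically structured interaction networks (planted
pairs are uniform over the donor × recipient grid). Passing tests on
synthetic screens therefore demonstrate the statistical machinery —
calibration, recovery, determinism — not robustness to every artifact of
real plates.

Companion generators produce gene annotations (13 major bioprocesses with
fuzzy 1–3 membership, 41 minor categories, orphan/global quotas assigned
exactly — e.g. 72 of 304 orphans), phylogenetic presence profiles over
the 17-phylum panel, and alignment hit tables with planted paralogs and
decoys that each fail at least one filter criterion.

## Problem sizes used in validation

The packaged checks simulate 50 donors × 60 recipients × 8 replicates
(3000 pairs per condition): large enough for stable score distributions
and spatial normalization, small enough to run the whole suite in
minutes. Null calibration uses 10 seeds, static recovery 5, differential
rewiring 3 (with 4 null splits), permutation calibration 20; the
acceptance script repeats the same computations from a root seed.

## Known limitations

* The GP subsampling caps trade a little predictive sharpness for run
  time; screens beyond ~100k pairs are predicted from a 500-pair
  conditioning set, which is coarse if the fitness surface is rough.
* The split-half null requires ≥ 4 replicates and assumes replicates are
  exchangeable within a condition.
* Robust differential scaling assumes interactions are a minority
  (≲ 25 % of pairs); a screen where most pairs interact would break the
  neutral-background assumption.
* The gain/loss rule for pairs significant in both conditions
  (dominant-shift labelling) is a convention; no published rule exists
  for that case.
* `recount_differential()` reproduces published headline counts only
  when applied to the corresponding deposited table; on synthetic data
  it reports the analogous counts for the simulated screen.
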