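---
title: "Carbon-use phenotyping and niche overlap among foliar endophytes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon-use phenotyping and niche overlap: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

A Biolog SF-P2 plate exposes one microbial isolate to 95 single-carbon
substrates plus one water-control well; growth after a fixed incubation is
read as optical density at 590 nm. `endoniche` treats the water well as the
plate's blank: every substrate well is corrected by subtracting the plate's
water absorbance, and a substrate counts as *used* when the corrected OD is
at least 0.005. The comparison is inclusive (a corrected OD of exactly 0.005
is usage), and the implementation allows a one-part-per-billion tolerance so
that floating-point subtraction cannot flip a value that is exactly on the
boundary. Negative corrected ODs are physically meaningful records (the well
grew less than water) and are retained in the profile, but every statistic
that requires a nonnegative abundance — Bray–Curtis, overlap ratios,
evenness, per-substrate group means — uses the corrected OD clipped at zero.

## Per-isolate metrics

For an isolate with corrected ODs $x_1,\dots,x_{95}$ and usage set $U$:

* **Niche width** $NW = |U|$, the number of substrates used;
* **Total growth** $TG = \sum_{n \in U} x_n$ — sub-threshold wells
  contribute nothing even when positive;
* **Growth efficiency** $GE = TG / NW$, mean growth per used substrate,
  undefined (rendered as an empty field, never 0) when $NW = 0$;
* **Evenness** $J = -\sum_{n \in U} p_n \ln p_n / \ln NW$ with
  $p_n = x_n / TG$, Pielou's index over the used substrates, undefined when
  $NW < 2$.

Evenness is computed over used substrates rather than all 95 because the
log-based index is undefined at zero proportions; with typical niche widths
of 80–90 substrates the two conventions differ little. High $J$ reads as a
generalist strategy (similar growth on everything used), low $J$ as
specialization on a few substrates.

## Directional niche overlap

For an ordered pair of isolates $(i, j)$ sharing a leaf, and every substrate
$n$ on which **both** meet the usage criterion,

$$\omega_{i \to j, n} = \min\!\left(\frac{x_{i,n}}{x_{j,n}},\, 1\right),
\qquad
\bar\omega_{i \to j} = \frac{1}{95} \sum_{n=1}^{95} \omega_{i \to j, n},$$

with non-co-used substrates contributing zero. $\bar\omega_{i\to j}$ is the
fraction of $j$'s realized resource niche that $i$ covers: a proxy for the
competitive pressure $i$ exerts on $j$. It is directional — a strong grower
covers a weak grower's niche almost fully while the reverse does not hold —
and bounded by $\min(NW_i, NW_j)/95$.

Two readings of the average were possible: dividing by the full plate size
(95) or by the number of co-used substrates. The plate-size denominator is
the implemented default — it keeps $\bar\omega_{i\to i} = NW_i/95$ and makes
pairs with small shared niches count as weak interactions — and the co-used
denominator is available via `pairwise_overlap(denominator = "shared")` and
`overlap_table(denominator = "shared")` for sensitivity analysis. Similarly,
the ratio is capped at 1: an uncapped ratio would exceed 1 whenever $i$
outgrows $j$ and would destroy the $[0,1]$ interpretation. "Both grow" is
operationalized as the same usage criterion that defines $NW$, so a single
consumption definition governs every statistic.

All reported summaries restrict pairs to sympatry (both isolates cultured
from the same leaf); within a leaf carrying $m$ isolates all $m(m-1)$
ordered pairs are enumerated and classed by source:target kingdom
(B:B, F:F, B:F, F:B).

# Inference battery

* **Taxon relative abundances** are compared between treatments with the
  two-sample test of equal proportions (chi-squared on the 2×2 table with
  Yates continuity correction, df = 1).
* **Evenness and overlap comparisons** route through a Shapiro–Wilk screen
  (level 0.05 per sample): Welch's *t* when both samples retain normality,
  otherwise a Wilcoxon rank-sum test (exact below 10 per group without
  ties; normal approximation with continuity and tie corrections
  otherwise). The battery of such comparisons forms one Benjamini–Hochberg
  family at FDR 0.05.
* **Carbon-use profiles** are compared via Bray–Curtis dissimilarity of the
  clipped corrected ODs over all 95 substrates. A pair of all-zero profiles
  has no defined dissimilarity; it is set to 1 and counted in an attribute
  flag. PERMANOVA (`vegan::adonis2`, sequential sums of squares in the
  order kingdom, treatment, interaction; free row permutation) and PERMDISP
  (`vegan::betadisper` on a principal-coordinates embedding, spatial-median
  centers, permutation F test, Tukey HSD on group mean distances) test
  location and dispersion. Permutation p values follow the $(b+1)/(B+1)$
  convention, so p = 0 cannot occur.
* **Metric models**: NW is a count bounded well away from 95's ceiling in
  practice and is modelled as Poisson with log link; TG and GE are
  log-transformed Gaussian. All three use a kingdom × treatment interaction
  and a leaf random intercept (isolates from one leaf are not independent).
  A singular random-effect fit falls back to the fixed-effects model, with
  the event recorded in the returned warnings. Estimated marginal means are
  contrasted per cell; the within-kingdom treatment contrast is the single
  pre-specified comparison of interest and is reported unadjusted, while
  the full six-way pairwise table carries a Tukey adjustment.
* **Phylogeny–phenotype association**: per kingdom (16S and ITS alignments
  are never mixed), pairwise distances are the uncorrected p-distance over
  pairwise-complete sites (gaps and ambiguity codes dropped per pair), with
  the Jukes–Cantor correction $-\tfrac34\ln(1-\tfrac43 p)$ available; the
  correction is undefined at $p \ge 0.75$ and returns NA there. The Mantel
  test (Pearson, 999 permutations) and an ordinary least-squares regression
  of carbon-use dissimilarity on phylogenetic distance per kingdom ×
  treatment stratum quantify association; pairwise observations share
  isolates and are not independent, so regression p values are nominal and
  flagged as such.

# The synthetic study generator

Real plate absorbances for this system are not published, so the package
ships a generator that emulates the field design and the reported group
structure; every pipeline stage is exercised against it.

**Design.** Two treatments (ambient control and NPKμ nutrient amendment,
stored as `NPKu`), two plots per treatment, three plants per plot, one leaf
per plant: six leaves per treatment. Ten bacterial and ten fungal isolates
per leaf, except one deficient control leaf with five bacteria — 115
bacteria + 120 fungi = 235 isolates, which also fixes the sympatric ordered
B:F pair counts (550 control, 600 amended).

**Generative model.** For isolate $i$ on substrate $n$:

* usage is Bernoulli with probability
  $\mathrm{logit}^{-1}(c_{kt} + u_n + e_i)$, where $u_n$ is a fixed
  substrate "easiness" profile (logit sd 1.2, shared by all isolates — easy
  substrates are used by nearly everyone, emulating plates where every
  substrate is used by some isolates and none by all), $e_i$ is an isolate
  offset (sd 0.4), and $c_{kt}$ is solved so the kingdom × treatment
  marginal matches its configured value;
* the latent OD of a used substrate is Gamma with mean
  $\mu_{kt} \cdot b_n \cdot \ell_{leaf} \cdot s_i$ and shape $\kappa_{kt}$:
  $\mu_{kt}$ is the kingdom mean times a treatment multiplier, $b_n$ a fixed
  substrate baseline (lognormal spread, sd log 0.67, mean 1, rank-aligned
  with easiness), $\ell$ and $s$ lognormal leaf (sdlog 0.05) and isolate
  (sdlog 0.30) effects;
* the recorded well value is water mean (0.05) + latent OD + Gaussian read
  noise (sd 0.003); the water well is water mean + noise.

**Calibration.** The defaults are the study's reported conditions: kingdom
mean ODs 0.103 (bacteria) and 0.245 (fungi) with per-cell means 0.098/0.107
(bacteria) and 0.273/0.217 (fungi); fungal usage marginals 0.889/0.823 so
realized mean niche widths land at 85.5 (control) and 79.2 (amended) after
sub-threshold losses; Gamma shapes 2.6 (bacteria), 3.0/2.1 (fungi) chosen so
mean Pielou evenness reproduces the reported 0.906–0.918 range with the
fungal decline under amendment. The split between the shared substrate
baseline and the independent Gamma spread matters: the baseline cancels in
between-isolate OD ratios, so it shapes evenness without diluting the
overlap statistic's response to kingdom mean differences. With all structure
placed in independent draws instead, simulated F:B overlap sits far below
plausible levels and the B:F response to treatment nearly vanishes; the
chosen split reproduces both the evenness distributions and overlap levels
near the reported ones simultaneously.

The isolate-level lognormal effect (CV ≈ 30%) represents genuine
isolate-to-isolate variation in overall growth capacity; without it,
group-mean contrasts at n = 55–60 per cell would be unrealistically
overpowered relative to a study that reported non-significant bacterial
differences of ~9%. The bacterial treatment multiplier is planted at 1.01 —
a slight positive shift, deliberately below detectability at the study's
sample sizes. Leaf-level variance is set small (ICC ≈ 3% on log TG),
consistent with treatment effects being detectable with only six leaves per
treatment.

**Presets.** `"paper-like"` as above; `"null"` equalizes every treatment
column (no planted effects); `"strong"` doubles each fungal gap. The
`truth.json` sidecar echoes the full configuration and seed, sufficient to
re-derive any expected value.

**What the generator does not emulate.** Taxon identity below kingdom (no
genus structure), substrate chemistry (guilds of related carbon sources),
plate-position artifacts, kinetic reads, and any correlation between an
isolate's usage pattern and its phylogeny (the phylogeny module is instead
exercised with distances drawn at a configurable correlation to the
phenotype dissimilarity). Passing tests therefore demonstrate that the
statistics behave correctly under the design's sampling structure, not that
they would detect any particular real-world effect.

# Numerical and design choices

* **Threshold boundary**: usage is `corrected OD − threshold ≥ −1e−9`; the
  tolerance only protects exact-boundary values from floating-point
  subtraction error.
* **Tie-breaks**: preferred-substrate ranking (top-10 by group mean clipped
  OD) breaks ties by substrate name ascending, so output is deterministic.
* **Degenerate inputs**: an isolate using nothing has undefined GE and J
  (propagated as NA, written as empty fields); a pair with no co-used
  substrates has overlap 0; identical multivariate points give all-zero
  PERMDISP distances; all-tied two-sample inputs return p = 1.
* **Seeds**: every randomized routine takes an explicit seed; the pipeline
  derives independent child seeds per stage from one master seed so
  changing one stage's permutation count cannot perturb another.
* **Calibration suites**: the type-I calibration of PERMANOVA / PERMDISP /
  the two-sample router runs on null-preset studies with the leaf effect
  removed — row-permutation tests assume exchangeable rows, which leaf
  clustering deliberately violates in the full design — and at 40 isolates
  (20 per treatment), outside the small-sample regime in which
  spatial-median PERMDISP is known to be conservative. Direction-recovery
  runs use 50 full 235-isolate replicates; the calibration suite uses 500
  small replicates. These sizes keep the whole suite under a few minutes
  while leaving Monte-Carlo error (SE ≈ 1 percentage point at 500
  replicates) well inside the asserted bands.

# Known limitations

* Overlap values of pairs sharing an isolate are correlated; the
  two-sample tests on pair-level overlap treat pairs as independent, as is
  conventional, so their p values are somewhat anti-conservative (this is
  visible in the generator's intra-kingdom B:B cell, a planted null whose
  naive test over-rejects).
* The overlap denominator question (95 vs co-used substrates) changes
  overlap levels by roughly the ratio of niche width to plate size
  (~10–15% here); both are exposed, one is default.
* The p-distance treats all ambiguity codes as missing rather than
  partially informative; for short marker alignments with few ambiguities
  this is negligible.
* NMDS ordination is not implemented; the principal-coordinates embedding
  inside PERMDISP serves visualization needs, and no stress-based statistic
  is produced.
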