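---
title: "Methods: classifying synergistic and additive gene regulation in factorial RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying synergistic and additive gene regulation in factorial RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyseq)
```

## The problem

When endothelial cells (or any cell system) are stimulated with two
cytokines separately and together, each responsive gene can behave in one
of a few qualitatively different ways: the combined response may equal the
sum of the single responses on the log scale (additive), exceed it
(synergistic, in either direction), or collapse below one of the single
responses (antagonistic). Distinguishing these regimes gene by gene
requires per-gene effect estimates *with uncertainty*, because the
interesting comparisons — combined versus sum, combined versus each single
effect — are hypothesis tests, not threshold rules.

`synergyseq` implements this classification for a 2×2 factorial bulk
RNA-seq design: four conditions (control, A, B, AB), a handful of
replicates each, integer counts.

## Effect estimation

Counts are normalized by per-sample size factors (median-of-ratios by
default, library totals as an alternative), rescaled to geometric mean 1
so all results are invariant to their overall scale. For a treatment
condition with replicate mean $\bar n_t$ and the control mean $\bar n_0$
(both on the normalized scale, both with a pseudocount $c$ added), the
log2 fold change and its delta-method standard error under Poisson
sampling are

$$\widehat{\mathrm{lfc}} = \log_2\frac{\bar n_t + c}{\bar n_0 + c},
\qquad
\mathrm{se}^2 = \frac{1}{(\ln 2)^2}
\left(\frac{1}{n_t\,\mu_t} + \frac{1}{n_0\,\mu_0}\right),$$

with $\mu$ the pseudocounted means and $n$ the replicate counts. The
pseudocount (default 0.5, in normalized-count units) exists purely to keep
estimates finite at zero counts; the differential-expression test below
never uses it. The Poisson variance assumption is deliberate — see
*Limitations*.

## Differential expression

The Poisson-based DE call is an exact conditional test. Replicates are
pooled within condition (sums of independent Poissons are Poisson), and
conditional on the two pooled counts $k_t + k_c$, the treatment count is
$\mathrm{Binomial}(k_t + k_c,\ E_t/(E_t + E_c))$, where the exposures $E$
are summed size factors. We chose this test because it is transparent and
checkable against exhaustive enumeration to machine precision, which the
test suite and acceptance script both do for totals up to 100.

Two-sided p-values double the smaller inclusive tail, capped at 1 — the
convention that reduces to the familiar $2\times$ tail probability in the
symmetric case and is always conservative. Adjustment across genes is
Benjamini–Hochberg; the procedure behind "adjusted p" is a configurable
choice here, and BH is the field default for transcriptome-wide screens. A
gene is differentially expressed when $\max(FC, 1/FC) > 1.5$ and adjusted
$p < 0.05$ (both thresholds configurable; `fc_threshold` is a linear-scale
ratio, `de_alpha` a probability).

## The classification cascade

Let $x$, $y$, $xy$ be the three log2 effects of one gene with standard
errors $s_x, s_y, s_{xy}$. Two Wald tests drive the decision:

* **Test 1 (sum):** $z = (xy - x - y)/\sqrt{s_{xy}^2 + s_x^2 + s_y^2}$,
  two-sided normal p-value.
* **Test 2 (dominance):** $z = (xy - x)/\sqrt{s_{xy}^2 + s_x^2}$ and the
  analogue for $y$.

The cascade, applied to each eligible gene, is a strict partition:

1. **synergistic** if Test 1 rejects at `test_alpha` *and*
   $|xy| > |x + y|$; the synergy increase $|xy| - |x+y|$ is then positive
   by construction. The call is `synergistic_positive` when $xy > 0$ and
   `synergistic_negative` when $xy < 0$.
2. otherwise **antagonistic_excluded** if a Test 2 comparison rejects
   while the combined effect is *smaller* in magnitude than that single
   effect.
3. otherwise **additive** if Test 2 rejects against both $x$ and $y$ with
   $|xy| > |x|$ and $|xy| > |y|$.
4. otherwise **not_classified**.

Three design points deserve a note, because the verbal definitions of
these categories admit more than one reading:

* *Positive versus negative synergism.* A synergy increase
  $|xy| - |x+y|$ is positive for every synergistic gene, so "positive if
  the increase is positive" cannot be the discriminator. We interpret the
  polarity as the direction of the combined response: synergistically
  *induced* genes are positive, synergistically *repressed* genes
  negative. This matches how synergistic gene lists are reported split
  into up- and downregulated halves.
* *Antagonism.* "Antagonistic" is given no formula in the verbal scheme.
  We operationalize it as a significant magnitude reversal — the combined
  effect significantly below a single effect — because that is the one
  situation where calling a gene "additive or synergistic" would be
  actively misleading, and it keeps the cascade an exact partition.
* *Eligibility.* Which genes enter classification is its own choice. The
  default admits genes differentially expressed in the combined-vs-control
  contrast (the combined response is what is being decomposed); union-of-
  any-contrast and no-filter modes are available via `eligibility`.

Test 1/Test 2 p-values are used raw per gene by default
(`adjust_interaction = FALSE`): the false-discovery control is applied
once, at the DE stage that defines eligibility. BH adjustment of each test
family across genes is available for users who want genome-wide control of
the interaction calls themselves.

## The simulator

`simulate_factorial_counts()` exists so every downstream stage is testable
against known truth without any sequencing data. It emulates the study
design the package targets: 4 conditions × 3 replicates = 12 samples,
expected counts

$$\mu_{gs} = f_s\, 2^{\,b_g + x_g[s \in A,AB] + y_g[s \in B,AB] + i_g[s = AB]},$$

Poisson draws by default, negative binomial with size $1/\mathrm{dispersion}$
when overdispersion is requested. Genes are assigned to six truth
categories (null, single-only, additive, synergistic up/down,
antagonistic) by a deterministic largest-remainder quota, so category
counts are exact and testable rather than binomially noisy. Antagonistic
truth genes get an interaction term that shrinks the combined effect to a
quarter of the larger single effect, guaranteeing
$|x + y + i| < \max(|x|, |y|)$ and exercising the exclusion branch.

Default parameters and why:

* `baseline_log2_mean = 6`, `baseline_log2_sd = 2` — control means from
  tens to thousands of counts, the magnitude range of a typical bulk
  RNA-seq library after gene-level filtering; most genes sit above the
  detection floor of a 3-replicate Poisson design.
* `effect_size_log2`: single effects 0.6–2 log2 units (the lower end just
  above the 1.5-fold DE threshold of ~0.585), interaction 1.5–2.5 log2
  units.
* `sim_config_strong()` — the benchmark scenario used in the recovery
  tests: baseline log2 drawn from N(8, 1) truncated below at 6 (control
  mean ≥ 64 counts), interactions ≥ 1.5 log2 units, 1000 genes. Under
  these conditions misclassification is dominated by the ~5% of additive
  genes whose Test 1 fires by chance, so macro precision and recall for
  the three recoverable classes are expected well above 0.8.

What the simulator does *not* model — and what passing tests therefore do
not demonstrate about real data: replicate-level overdispersion when run
in the default Poisson mode (real bulk RNA-seq is overdispersed; the exact
test's p-values are then anti-conservative, which is the main reason the
DE engine is configurable rather than a recommendation), batch effects,
GC/length bias, correlated genes, and read-level artifacts. The
`dispersion` knob gives negative-binomial counts for robustness
exploration, but the DE test itself remains Poisson-based by design.

## Numerical and interface choices

* Zero-count genes: pseudocounted fold changes are finite; the exact test
  gives $p = 1$ at zero total, never NaN. Standard errors are strictly
  positive whenever pseudocounts are (default), so the Wald statistics are
  always defined.
* Exact ties: a gene with $xy$ exactly equal to $x + y$ has Test 1
  $z = 0$, $p = 1$ — never synergistic. Direction is `"up"` only when
  $xy > 0$ strictly.
* Size factors are rescaled to geometric mean 1 wherever they enter, so
  every result is invariant to their overall scale (tested).
* All writers emit TSV with fixed column order and rows sorted by gene id,
  numerics via `%.15g`, so repeated runs are byte-identical and outputs
  are diffable (tested via MD5).
* Assay utilities follow the standard formulas exactly: $2^{-\Delta\Delta
  Ct}$ with per-group Ct averaging by default (per-replicate pairing is an
  option, since replicate handling before $\Delta Ct$ is a lab-convention
  choice); cytotoxicity $= 100 (OD_{ctrl} - OD_{exp})/OD_{ctrl}$, negative
  values preserved unless clamped; geometric mean intensity
  $\exp(\mathrm{mean}(\log v))$; Student's t with pooled variance
  (the equal-variance form is what "Student's t-test" denotes; Welch is
  deliberately not silently substituted).

## Problem sizes in the test suite

The suite runs at desk scale, chosen to keep every stochastic check many
standard errors away from its bound: oracle enumeration over count grids
(totals ≤ 100) and 60 random small universes; 5000-gene null simulations
for type-I control; the 1000-gene strong-effect scenario for recovery;
300-gene runs for partition identities; a 200-gene run for pipeline
determinism. The whole suite completes in well under a minute.

## Limitations

* The Poisson exact test understates variance on overdispersed real data;
  treat its adjusted p-values as a screening criterion, as in the original
  analysis style it reproduces, not as calibrated error rates.
* Wald tests on log2 effects rely on approximate normality of the
  estimator; at very low counts (control mean below ~10) the
  pseudocount biases effects toward zero and power drops.
* Identifier handling is case-insensitive string matching only; mapping
  between species' gene symbols (e.g. porcine measurements against human
  ligand–receptor catalogs) is the caller's responsibility.
* A single timepoint is assumed; no dose–response or Bliss/Loewe-style
  interaction surface is modeled.
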