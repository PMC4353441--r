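---
title: "Linking radiation-responsive lncRNAs to mRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking radiation-responsive lncRNAs to mRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnclink)
```

## The problem

Low-dose ionizing radiation (LDIR, here 10 cGy) induces coordinated
transcriptional changes in mouse mammary tissue, and long noncoding RNAs
(lncRNAs) are candidates for orchestrating part of the coding-gene
response. The experimental design this package serves profiles two inbred
strains with different radiation susceptibility (BALB/c, sensitive;
SPRET/EiJ, resistant) at several times after sham or IR exposure: BALB/c
at 2, 4 and 8 weeks and SPRET/EiJ at 4 weeks, sham and irradiated — 8
experimental treatment groups with 3 biological replicates each, 24
arrays in total, each probing both mRNAs and lncRNAs.

The statistical question is: which lncRNA–mRNA pairs co-vary across these
8 conditions more strongly than chance allows, given that only 8 group
means per transcript are available? With so few observations, parametric
correlation p-values are fragile; the pipeline instead uses a permutation
test, for which the small sample size is an asset — the full permutation
space (8! = 40,320) is enumerable, so the test can be made exact.

## Pipeline overview

`run_all()` executes the stages in fixed order:

1. **Normalization** — log2 transform with an intensity floor, then
   per-sample 75th-percentile shift.
2. **Differential expression** — per contrast (IR vs sham within strain
   and timepoint), pooled-variance Student's t-test plus fold-change
   gate.
3. **Radiation-responsive set** — union of DE probes over contrasts.
4. **Signature exclusion** — optional removal of genes in an
   estrous-cycle variable-gene signature.
5. **Group means** — replicate averaging to one length-8 vector per
   transcript.
6. **Permutation correlation** — every remaining lncRNA × mRNA pair.
7. **Network summaries** — bipartite graph and threshold-robustness
   report.

Each stage is also exposed as a plain function on tibbles, so any prefix
of the pipeline can be run and inspected interactively.

## Normalization

Arrays are made comparable by subtracting, from each sample's log2
signals, that sample's 75th percentile — division by the
75th-percentile intensity on the linear scale. No per-probe baseline
transformation is applied, so absolute per-probe levels remain
interpretable within a sample.

Two conventions needed fixing because "75th percentile" alone does not
determine a number:

* **Percentile definition.** Linear interpolation between order
  statistics, placing percentile $q$ of sorted $x_{(1)} \le \dots \le
  x_{(n)}$ at rank $1 + (n-1)q/100$ (R's `type = 7`, the most widespread
  default). For a column of log2 values $(1,2,3,4)$ the 75th percentile
  is 3.25, and the normalized column is $(-2.25,-1.25,-0.25,0.75)$.
* **Probe universe.** The percentile is computed over all probes, not a
  detected subset; detection calls are platform-specific and would make
  the normalization irreproducible from the matrix alone.

The shift happens in log2 space, keeping downstream t-tests on the log
scale where replicate noise is closer to additive and symmetric. The
linear-scale floor (default 1.0, log2 value 0) guards against
non-positive or vanishing intensities. Normalization is idempotent,
preserves within-sample ranks, and records every sample's shift in a
report retrievable with `norm_report()`.

## Differential expression

For each contrast, each probe gets a pooled-variance two-sample
Student's t (df $= n_a + n_b - 2$; not Welch — the classical test is
what the motivating workflow names) and a fold change computed
symmetrically from log2 group means as $2^{|\bar{b} - \bar{a}|}$ with
direction carried separately. A probe is called differentially expressed
when **both** strict gates pass: $p < p_\mathrm{cutoff}$ and
$\mathrm{FC} > \mathrm{fc}_\mathrm{cutoff}$. Defaults are 0.05 and 1.5
for IR-vs-sham contrasts, with 0.001 the conventional choice for
baseline strain comparisons. Boundary values fail: FC exactly 1.5 is not
"more than 1.5".

Raw p-values gate the calls. That mirrors the raw-cutoff convention of
the array workflow this reproduces; a Benjamini–Hochberg `p_adj` column
is emitted for reference but never used in `is_de`. With n = 3 per
group, zero pooled variance can occur; equal means then give $t = 0, p =
1$, and unequal means are flagged `degenerate` with $p = 0$ (perfect
separation, no variance estimate).

The radiation-responsive set of a strain is the union of DE probes over
that strain's per-timepoint contrasts, and the cross-strain set is the
union over strains (`de_union()`); which samples constitute a "baseline"
strain contrast is a user decision, so contrasts are always declared,
never inferred.

## Signature exclusion

Genes whose mammary expression fluctuates across the mouse estrous cycle
can masquerade as radiation-responsive. The pipeline therefore accepts a
gene-level signature list and removes matching probes before the
correlation stage. Matching is case-insensitive exact symbol matching —
mouse symbol casing varies across platforms, and silent non-overlap is
worse than the rare false merge. Probes with an empty symbol can never
match and are retained (absence of annotation is not membership).
Because the signature is gene-level while calls are probe-level, every
probe of a matching gene is removed. The overlap report emits the
fraction with the DE set as denominator, both for all DE probes and per
class, since the published overlap percentages do not state their
denominator.

## The permutation correlation test

For each transcript the 3 replicates of each group are averaged, giving
a length-8 group-mean vector (averaging happens on the log2 scale, like
every other step). For a (lncRNA, mRNA) pair with vectors $x, y$:

* the observed statistic is the Pearson correlation $r_\mathrm{obs}$
  (Pearson is the default; the correlation is computed on log2 group
  means);
* the entries of $x$ are rearranged — uniformly at random `n_perms`
  times (default 10,000) in Monte-Carlo mode, or all $8! = 40{,}320$
  ways in exhaustive mode — and the statistic recomputed;
* $p$ is the plain fraction of rearrangements whose statistic
  **strictly** exceeds the observed one.

Three deliberate choices:

* **Two-sided by default.** "A higher correlation" is ambiguous when
  strong negative correlations are biologically meaningful, and both
  signs are reported in the motivating analysis; the default statistic
  is $|r|$ (`comparison = "abs_greater"`), with the literal one-sided
  reading (`"greater"`) selectable.
* **Strict counting, plain proportion.** Ties never count as exceeding,
  and $p = b/m$ can be exactly 0 (no pseudo-count), matching the
  fraction-of-permutations definition. A $(b+1)/(m+1)$ corrected p is
  reported alongside for users who need guaranteed-positive p-values.
  Floating-point ties are absorbed by a $10^{-12}$ tolerance so the
  identity rearrangement never counts against itself.
* **Exactness as oracle.** With 8 groups the exhaustive test is cheap,
  so it serves both as a user-facing exact mode and as the ground truth
  the Monte-Carlo mode is validated against (agreement within
  $3\sqrt{p(1-p)/m}$).

Constant vectors have no defined correlation; such pairs are recorded
with a `skip_reason`, not dropped, and lncRNAs whose every pair was
skipped are excluded from connectivity denominators (they were never
testable).

**Seeding.** One scan seed governs `correlate_all_pairs()`; each pair's
shuffle stream is derived from a hash of (seed, lnc\_id, mrna\_id), so
results are bit-identical regardless of row order or how a scan is
partitioned. The permutation engine is compiled (Rcpp) with its own
seeded generator — a splitmix64-seeded xorshift64\* stream with
Fisher–Yates shuffles — because 10,000 shuffles per pair over many
thousands of pairs is the pipeline's hot loop.

## Networks and threshold robustness

Edges are pairs with $p < $ threshold (strict). The headline summary is,
per threshold (defaults $5\times10^{-2}, 5\times10^{-3},
5\times10^{-4}$), the count and fraction of lncRNAs correlated with at
least one mRNA. At a loose threshold this fraction is expected to be
near 1 by multiplicity alone: with $M$ candidate mRNAs per lncRNA and
independent nulls the expected fraction is $1 - (1-\alpha)^M$, which for
$M$ in the hundreds is essentially 1 at $\alpha = 0.05$. The
three-threshold report exists precisely to probe whether connectivity
survives thresholds where this inflation mechanism cannot carry it; the
package tests that mechanism quantitatively on null data. Graphs export
to GraphML (round-trippable, with class and edge attributes) or a flat
edge TSV for external tools.

## The synthetic-data generator

`simulate_dataset()` emulates the study's statistical structure — not
microarray physics. Per probe $i$, group $g$, replicate $k$, log2
expression is

$$ \mathrm{baseline}_i + \mathrm{strain}_i[g] + \mathrm{LDIR}_i[g] +
a\, z_{j(i),g} + \varepsilon_{igk}, \qquad \varepsilon \sim N(0,
\sigma^2) $$

with the emitted matrix $2^{(\cdot)}$ on the linear scale. Planted LDIR
effects (magnitude `de_effect_log2`, random sign) apply to the IR groups
of one randomly assigned strain; planted strain effects apply to all
SPRET groups. Coupling: each regulator lncRNA $j$ has a latent per-group
factor $z_{j,g} \sim N(0,1)$ added, scaled by $a$, to its own and its
targets' group means. The loading is chosen as $a^2 = \sigma_g^2\,
c/(1-c)$ with $\sigma_g = \sigma/\sqrt{n_\mathrm{reps}}$, which makes
the population correlation of two coupled group-mean vectors equal the
config's `coupling_strength` $c$ exactly — the planted effect is
analytically controllable, and the truth table records the expected
correlation per pair. Coupled probes receive no additional fixed
effects, so planted correlations are not contaminated by shared
IR-response structure.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_mrna`, `n_lnc` | 2000, 800 | desk-scale universe preserving the ~2.4:1 coding/noncoding probe ratio |
| `n_reps` | 3 | the study design |
| `noise_sd_log2` | 0.25 | typical replicate-level log2 sd for inbred-mouse array data |
| `de_effect_log2` | 2 | a clearly-detectable planted effect (4-fold), the regime the power analysis targets |
| `frac_de`, `frac_strain_de` | 0.1 each | minority planted structure, majority null |
| `coupling_strength` | 0.98 | near-deterministic regulation, the regime where detection should be nearly certain |
| `n_regulators` × `targets_per_regulator` | 50 × 5 | a few hundred planted pairs, enough to estimate sensitivity |
| `baseline_mean_log2`, `baseline_sd_log2` | 8, 2 | wide dynamic range around mid-intensity |
| `signature_fraction` | 0.2 | mirrors the ~20% DE/signature overlap scale so the exclusion stage has nontrivial work |

The synthetic estrous signature is a random subset of planted-DE mRNA
symbols; it exercises the exclusion machinery without claiming
biological fidelity. What the generator does **not** emulate: spatial
array artifacts, dye bias, intensity-dependent variance, probe
cross-hybridization, correlated baseline structure between unplanted
genes, or mechanistic estrous dynamics. Passing tests therefore
demonstrate correctness of the statistical machinery under the model's
assumptions, not robustness to real-array pathologies.

`simulate_pair()` is the micro-fixture: a bivariate-normal pair of
length-$n$ vectors with population correlation exactly `target_r`, used
for calibration and oracle tests of the permutation engine.

## Numerical and degenerate-input choices

* Percentile: `type = 7` interpolation; post-normalization percentile
  within $10^{-12}$ of 0.
* Permutation tie tolerance $10^{-12}$; strictly-greater counting.
* Degenerate t: see above; degenerate correlation pairs skipped with a
  reason, never silently dropped.
* Fold-change ties (`delta == 0`) report direction "up" by convention.
* Gene symbols normalized to upper case once, at `gene_set()`
  construction.
* Probe-level analysis throughout: whether to collapse probes to genes
  is left to the user, since the analyzed platform's probe→gene map is
  many-to-one and collapsing rules are not part of this method.

## Problem sizes used by the test suite

The suite validates the engine against an R brute-force enumeration at
$n = 6$ (720 permutations), runs Monte-Carlo/exhaustive agreement over
60 random pairs at 10,000 draws, calibration over 2,000 exact null
p-values, a 5,000-pair scan for the significance-vs-correlation
correspondence, DE type-I/power on a 4,000-probe simulated dataset with
600 planted effects against a noncentral-t oracle, and planted-coupling
recovery on a 200 × 600-probe dataset with 100 planted pairs. These
sizes give binomial confidence intervals tight enough for the stated
tolerances while keeping the default test run in minutes.

## Known limitations

* With 8 groups the permutation p has granularity $1/40320$; p-values
  below $2.5\times10^{-5}$ are not resolvable, and Monte-Carlo mode at
  10,000 draws cannot distinguish p below $10^{-4}$.
* The strict-minimum of $|r|$ among pairs significant at $5\times
  10^{-4}$ is not a robust statistic: rare value configurations (one
  extreme coordinate) make a pair's permutation null light-tailed, so a
  moderate $|r|$ can rank in the top 20/40320. The bulk correspondence
  (the large majority of such pairs having $|r| > 0.9$) is the stable
  phenomenon.
* Group-mean correlations inherit any group-level confounding (e.g.
  batch aligned with group); the permutation null conditions on the
  observed values and does not remove such structure.
* The union-of-contrasts DE rule inflates the candidate set as
  timepoints are added; the connectivity summary's multiplicity
  mechanism (above) is the reason the multi-threshold robustness report
  should always be read alongside the α = 0.05 result.
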