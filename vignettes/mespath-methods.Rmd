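---
title: "Methods: running-sum enrichment and mitochondrial assay derivations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: running-sum enrichment and mitochondrial assay derivations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mespath)
```

# Scope

`mespath` packages the bespoke computations of a longitudinal App knock-in
transcriptome and mitochondrial-function study design: a running-sum
pathway-enrichment statistic with a permutation null, keyword-defined GO
gene sets with Fisher-exact overrepresentation, and the derivation rules
for plate-based mitochondrial assays. A synthetic-data generator emulates
every input with known ground truth, so the full pipeline runs and is
testable without any external download. Read alignment, count modelling
(DESeq2 itself), t-SNE embedding and image quantification are out of scope:
the package starts from per-contrast differential-expression tables and
plate traces.

# The enrichment statistic

Genes are ranked by decreasing log2 fold change. For a pathway with $G$
members in a universe of $N$ ranked genes, each rank contributes a step
$X_i$ to a running sum $S_j = \sum_{i \le j} X_i$; the Maximum Estimate
Score (MES) is an extremum of $S$. The two step magnitudes are
$\sqrt{(N-G)/G}$ and $\sqrt{G/(N-G)}$, and two sign conventions are
offered:

* **`as_printed`** — members get $-\sqrt{G/(N-G)}$, non-members
  $+\sqrt{(N-G)/G}$.
* **`balanced`** (default) — the signs swapped: members
  $+\sqrt{(N-G)/G}$, non-members $-\sqrt{G/(N-G)}$, which makes the
  increments sum to exactly zero ($G\sqrt{(N-G)/G} =
  (N-G)\sqrt{G/(N-G)} = \sqrt{G(N-G)}$).

The default is the balanced form because only it makes the intended
direction semantics true: a positive MES should mean up-enrichment, i.e.
members concentrated at the top of the ranking must *raise* the running
sum. Under the printed signs top-ranked members would lower it. Similarly,
a literal "maximum running sum" is non-negative whenever the increments
sum to $\ge 0$ (always, at $j = N$, under the balanced convention), so a
negative score — which down-regulated pathways must produce — could never
occur. The default `mode = "signed_extremum"` therefore returns the
partial sum of largest absolute value, with exact-magnitude ties resolved
toward the positive value (the comparison carries a $10^{-9}$ relative
tolerance so floating-point rounding cannot flip a tie between
algebraically equivalent computation routes). `mode = "literal_max"` and
`convention = "as_printed"` are retained for literal replication.

Because the statistic depends only on the membership pattern over ranks,
any strictly increasing transform of the log2 fold changes leaves every
result unchanged; this rank invariance is property-tested.

## Permutation null, FDR and Z scores

The null hypothesis is "the pathway is not enriched in the ranking":
member positions are uniform over $\binom{N}{G}$ patterns, which is
equivalent to permuting the ranking itself. (Whether the original analysis
permuted gene ranks or sample labels is not determinable from the
statistic's definition; gene-rank permutation is the only null available
to a statistic defined on a single ranked list.) When
$\binom{N}{G} \le$ `exhaustive_threshold` (default 10,000) the null is
enumerated and the p-value is the exact proportion of patterns with
$|\mathrm{MES}|$ at least the observed value; otherwise `n_perm` patterns
(default 1000) are sampled and the add-one estimator
$p = (1 + \#\{|\mathrm{MES}_{perm}| \ge |\mathrm{MES}_{obs}|\})/(n_{perm}+1)$
is used, flooring p at $1/(n_{perm}+1)$ and avoiding $p = 0$.
Two-sidedness is on $|\mathrm{MES}|$.

Within one contrast, the tested collection forms a single
Benjamini–Hochberg family (families are not pooled across contrasts,
matching per-contrast FDR reporting). A pathway is *significant* when its
nominal p is below 0.05 **and** its BH q is below 0.1. For heatmap
display, $Z = \mathrm{sign}(\mathrm{MES}) \cdot \Phi^{-1}(1 - p/2)$; the
two-sided mapping is used because 1.96 — the conventional display
threshold — is the two-sided 5% critical value. Cells with $|Z| < 1.96$
are masked, not zeroed: the threshold gates display, it does not censor
values.

Gene sets are intersected with the ranked universe first; sets with
$G < 5$ or $G > N - 5$ are skipped with a message (their increments are
degenerate or nearly so). $G = 0$ and $G = N$ are hard errors.

# Keyword gene sets and overrepresentation

`filter_genes_by_keyword()` collects genes annotated to any GO term whose
*name* contains the keyword as a case-insensitive literal substring
("autophag" matches both "autophagy" and "macroautophagy"). No GO-graph
ancestor propagation is performed — the procedure operates on the flat
annotation table as given, and the input format is a plain TSV rather
than OBO/GAF (a converter is a one-liner; graph semantics are not).

`fisher_overrepresentation()` tests each term set one-sidedly for
enrichment of a DEG set: the p-value is the upper hypergeometric tail
$P[X \ge k]$, $X \sim \mathrm{Hypergeom}(N, K, n)$. One-sidedness is the
deliberate choice: overrepresentation is the stated purpose of such
screens. Adjustment is Bonferroni over the terms tested, with
significance at adjusted $p \le 0.05$. DEGs are genes with BH-adjusted
p below 0.1; a missing adjusted p (the DESeq2 independent-filtering NA)
means "not a DEG".

# Plate-assay derivations

## Phase segmentation

Traces are long-format (well, time, signal) with an injection schedule.
Samples belong to the phase of the most recent injection; the first
post-injection cycle is discarded by default (`discard_first = 1`) as a
mixing artifact. The per-phase summary is the mean of retained cycles —
the exact per-phase reduction used on the original instrument is not
documented anywhere authoritative, so the simplest estimator was chosen
and made configurable. A phase whose samples are all discarded is an
error, not a silent NA.

## Respiratory states and complex activities

For the coupling assay (substrate → ADP → oligomycin → FCCP →
antimycin A), the antimycin phase is residual non-mitochondrial
respiration; every state is its phase mean minus that residual
(baseline → state II, ADP → state III, oligomycin → state IVo,
FCCP → state IIIu), floored at zero — a state below the residual is
measurement noise and is floored with a warning rather than reported
negative. RCR = III/IVo is reported only when IVo > 0. Because every
state subtracts the same residual, adding any constant to a trace leaves
all states, activities and the RCR unchanged (property-tested).

For the electron-flow assay (pyruvate/malate/FCCP → rotenone → succinate
→ antimycin A → ascorbate/TMPD, phases P1–P5), activities are
CxI = P1−P2, CxII = P3−P2, CxIII = P3−P4, CxIV = P5−P4. The original
protocol reports four activities from five phases without writing the
differences out; this mapping subtracts, for each complex, the adjacent
phase in which that complex is newly inhibited or newly fed, and is the
standard reading of sequential-inhibitor electron-flow data. Negative
activities are reported as-is but flagged — inhibitor failures happen and
hiding them would bias summaries.

## Calcium retention capacity

After each CaCl₂ pulse the extramitochondrial indicator jumps and then
decays as mitochondria take up the Ca²⁺. "Area under the curve after the
pulses" admits two readings, and both are implemented:

* `mode = "uptake"` (default): the trapezoidal area between the post-pulse
  peak and the trace, clipped at zero, summed over pulses — the amount of
  added Ca²⁺ cleared from the medium. This is zero when nothing is taken
  up (e.g. uptake rate $k = 0$) and grows with the organelles' capacity.
* `mode = "trace_auc"`: the area of the above-baseline transient. For an
  exponential transient of amplitude $A$ and rate $k$ that decays fully
  this converges to $A/k$ per pulse ($\int_0^\infty A e^{-kt}\,dt$).

The default is the uptake reading because the quantity of interest is the
Ca²⁺ *taken up*; the literal trace-AUC mode is kept for comparison since
the two differ exactly when uptake fails. Retention is additive over
pulses and invariant to baseline shifts.

## H₂O₂ slope, ATP standards, morphometry, statistics

H₂O₂ production is the OLS slope of the kinetic fluorescence read,
converted to per-minute units, with its standard error and $R^2$. ATP is
quantified by fitting log10(luminescence) against log10(concentration)
over a serial-dilution standard curve and inverting; inversions more than
0.5 log10 units outside the standards' range are refused as
extrapolation. ER elongation is major/minor axis. `mann_whitney_exact()`
enumerates the full labeling permutation distribution of U whenever
$\binom{n_a+n_b}{n_a} \le 2\times10^5$ (which covers all the per-group
sizes such experiments use, n = 4–8) and otherwise falls back to the
normal approximation with tie and continuity corrections; midranks handle
ties in both branches. `effect_size()` is the difference of group means
(reference first, so treatment increases are positive) with the unpooled
quadrature SEM $\sqrt{s_a^2/n_a + s_b^2/n_b}$ — pooling was not chosen
because group variances in small animal cohorts are routinely unequal.
An optional outlier filter was deliberately *not* bundled into the
derivations: the proprietary ROUT procedure is not re-implementable from
its description, and silently filtering would change reported ns.

# The synthetic-data generator

The generator is first-class, tested code that states a world once:

* **DE tables** — null genes draw log2FC from $\mathcal N(0, 0.5)$
  (`null_sd = 0.5`, a typical null spread for brain bulk RNA-seq at n=3
  per group); planted sets shift members by $\pm\delta$. Gene p-values
  come from the two-sided normal test of log2FC/`se_per_gene`
  (default 0.25) and adjusted values from the same `bh_fdr()` the
  enrichment module uses. No count-level simulation: the pipeline only
  consumes (log2FC, padj), so a closed-form gene-level model is exact for
  its purpose and fast. What a green test does *not* establish: realism
  of count overdispersion, library-size effects, or gene–gene
  correlation (the null permutes memberships, so correlated modules in
  real data can inflate the effective type-I error relative to the
  calibrated value).
* **OCR traces** — piecewise-constant phase means (defaults 50, 120, 40,
  130, 10 signal units for baseline/ADP/oligomycin/FCCP/antimycin, a
  shape typical of coupled mitochondria with RCR ≈ 3.7) with Gaussian
  noise, 6 cycles per phase at 360 s.
* **CRC traces** — after a 3-minute baseline, 5 pulses of amplitude 10 at
  3-minute intervals; between pulses the latent signal decays toward
  baseline at rate $k$ (default 0.05 s⁻¹, near-complete clearance within
  an interval) while cumulative cleared signal stays below the capacity
  $C$; past $C$ decay stops and pulses accumulate — the simplest
  mechanism that reproduces loss of buffering capacity. $C$ is expressed
  in cleared-signal units (the same units as the amplitude), since that
  is the quantity the saturation rule compares. Noise is added to the
  *observed* signal only, so zero-noise configs round-trip the dynamics
  exactly.
* **H₂O₂ traces** — a line in time (20 min at 30 s sampling) plus noise.

All draws flow from one seeded stream per call and the caller's RNG state
is restored, so identical config + seed gives byte-identical output
(tested on the serialized objects).

# Numerical choices

* Permutation hit-counting uses `|MES_perm| >= |MES_obs| - 1e-12`; the
  tolerance is shared by the exhaustive and sampled paths, and errs
  conservative.
* BH is the standard step-up `min`-over-tail, capped at 1; inputs outside
  (0, 1] are errors (a p of exactly 0 would be a floor violation
  upstream).
* Ranking ties break by C-locale lexicographic gene id after a stable
  sort — deterministic across platforms and reruns.
* The permutation null is computed from member positions in $O(G)$ per
  pattern (the running sum is linear between member positions, so its
  extrema occur only at, or just before, member positions, at rank 1, or
  at rank N); a property test pins this against the naive
  full-prefix-sum oracle over random cases, both conventions and modes.
* Config/manifest serialization is JSON and schedules are CSV: the
  pre-installed R stack has no YAML parser, and nothing in the formats
  needs one.

# Known limitations

* The permutation null treats genes as exchangeable; correlated gene
  modules in real data make the sampled null anti-conservative to a
  degree the synthetic world cannot measure.
* The electron-flow complex mapping and the per-phase summary are one
  defensible reading of an under-specified protocol; both are
  configurable or documented rather than hidden.
* `as_printed` + `literal_max` reproduces the literal printed formulas
  but cannot represent down-enrichment; it exists for comparison, not
  analysis.
* Vendor instrument files (native Seahorse exports), plate-layout
  normalization and protein-content normalization beyond a scalar are
  not parsed or modelled.
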