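---
title: "Methods: quantitative analysis of a genome-wide QPCR splicing screen"
author: "splicescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of a genome-wide QPCR splicing screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

# The measurement problem

A reverse-genetic splicing screen grows ~5500 yeast mutant strains in
384-well plates, extracts total RNA, reverse-transcribes it, and measures
specific RNA species — above all intron-containing *precursors* such as
the unspliced U3 snoRNA — by QPCR. A strain whose mutation impairs
splicing accumulates precursor. The raw readout per well is a crossing
point Cp (the cycle at which fluorescence crosses threshold); everything
downstream is a fight against nuisance variation: how much RNA each well
yielded, how efficiently each primer pair amplifies, and how each plate
run drifted.

This package implements the full quantitative chain — quantification,
quality filtering, composite normalization, significance calling, rank
synthesis, splicing-efficiency indices and gene-set enrichment — together
with a synthetic-screen generator so every stage can be exercised and
validated at desk scale.

# Quantification

Each primer pair gets a standard curve: an ordinary least-squares fit of
Cp against log10 of known template amounts from a 4-fold genomic-DNA
dilution series (`fit_standard_curve()`). The slope gives the
amplification efficiency $E = 10^{-1/\text{slope}} - 1$; perfect doubling
per cycle means slope $-1/\log_{10}2 \approx -3.3219$ and $E = 1$.
Well-behaved primers sit between roughly 86% and 97%. Unknown wells are
inverted through the curve, $q = 10^{(C_p - b)/m}$ (`cp_to_quantity()`),
yielding *relative* nanogram quantities — genomic-DNA equivalents, never
absolute copy numbers, which is all the downstream ratios need. The
fitting base is log10 (the dilution-series convention); all screen
statistics downstream work in log2. The two never meet inside one
formula.

ChIP-QPCR fold enrichment (`chip_fold_enrichment()`) is the
mock-subtracted percent-input signal at a region divided by the same
difference at an intronless control locus (a PMA1-style region,
configurable).

# Quality filters and composite normalization

Two technical replicates per biologically independent sample give, per
strain, biological replicate and primer pair, a coefficient of variation
on the linear quantity scale. Samples with CV **greater than** 0.25 for a
target are excluded for that target; the boundary value passes. A sample
whose *reference* measurement fails the CV filter is excluded entirely,
since its normalization constant would be corrupted.

No single spike-in can absorb well-to-well differences in culture
density, extraction and reverse transcription, so the screen measures six
reference RNAs of diverse function spanning a ~300-fold abundance range
(U1 snRNA, Scr1, Tef5, Tub1, Srb2, Faa1). For each sample, every
reference quantity is divided by that primer pair's median on the same
QPCR plate, and the ratios are averaged into a composite normalization
constant $C_{norm}$ (`compute_cnorm()`). Per-plate medians absorb the
subtle run-to-run batch drift.

**Aggregation choice.** We aggregate the six ratios by geometric mean.
Rationale: the empirical distribution of $\log_2 C_{norm}$ in such
screens is normal in log space, which is the natural signature of a
log-space average; and the geometric mean makes *yield invariance* exact
— multiplying every measurement of one sample by any $c > 0$ scales
$C_{norm}$ by exactly $c$ and leaves every relative level untouched
(exact whenever the sample is not itself the plate-median holder).
Arithmetic mean and median are available as configuration alternatives.

A sample needs at least 4 of the 6 references measurable (`min_refs`);
fewer and the "composite" constant would not be composite. A second
filter removes samples with very little cDNA: $\log_2 C_{norm} < -3$ (an
8-fold drop below the plate median) is eliminated; $-3$ itself passes.

For passing samples, each target's normalized level is $ng / C_{norm}$,
and its relative level is the normalized level divided by the per-plate
median of normalized levels for that primer pair:

$$\mathrm{Rel} = \frac{ng / C_{norm}}{\mathrm{median}_{plate}(ng / C_{norm})}$$

so a typical strain sits at Rel = 1 and, by construction, the per-plate
median of Rel over passing samples is exactly 1. Rel is kept on the
linear scale; log2 happens only at the significance and reporting stages.

Relative levels are computed for *all* targets, references included: the
Tef5 mRNA primer pair is simultaneously a reference and the denominator
of the Tef5 splicing-efficiency index, so restricting Rel to non-reference
targets would make that index uncomputable. Reference Rel values hover at
1 by construction and are harmless.

**Granularity choices left open by the protocol.** The CV is computed per
(strain, biological replicate, target) across the two technical
replicates, on the linear scale; plate medians are computed after CV
exclusions so corrupted wells cannot drag the normalizer. These are
package decisions where the bench protocol admits several readings.

# Significance: one-class SAM

Each strain contributes four log2 Rel values (2 biological × 2 technical
replicates), tested against $\mu_0 = 0$ (Rel = 1). The moderated
statistic is

$$d_i = \frac{\bar{x}_i - \mu_0}{se_i + s_0}$$

with $se_i$ the standard error of the mean and $s_0$ a fudge factor that
stops low-variance strains from dominating. $s_0$ is chosen by the
standard recipe (`estimate_s0()`): candidates are the percentiles
{0, 5, …, 100} of the $se$ distribution; for each candidate the
coefficient of variation of the median absolute deviation of $d$ within
$se$-quantile windows is evaluated, and the minimizer wins, ties to the
smallest candidate. The number of windows defaults to
$\max(3, \min(100, \lfloor G/10 \rfloor))$ so the criterion remains
estimable at desk scale and matches the canonical 100 windows for
genome-scale inputs. With $s_0 = 0$, $d$ is exactly the one-sample t
statistic.

**The null.** In a one-class design the exchangeable unit is the sample,
not the (strain, replicate) cell: a permutation draws a sign vector over
the $n$ replicate columns and applies it to every strain's deviations
from $\mu_0$ at once, then recomputes and sorts all $d$. The expected
order statistics $\bar{d}_{(i)}$ are means of the sorted permuted
statistics. With $n \le 12$ replicates all $2^n$ sign assignments are
enumerated (16 permutations for the screen's 4 replicates) — the
permutation distribution is then exact, not sampled; otherwise sign
vectors are sampled with a mandatory seed, and the sampled expectation
converges to the enumeration at the usual $1/\sqrt{B}$ rate.

**Calling and FDR.** Strains are ordered by $d$ and paired rank-for-rank
with $\bar{d}_{(i)}$ (ties in $d$ broken by strain label, for
reproducibility). Walking up from the smallest non-negative $d$, the
first strain with $d - \bar{d} \ge \Delta$ sets the upper cut; everything
at or beyond it is called positive, with the mirror rule for negative
calls (precursor *depletion*, which the screen also reports, comes from
this side with no extra machinery). The FDR estimate is the median over
permutations of the count of permuted $d$ beyond the cuts, divided by the
number of calls, capped at 1. No $\pi_0$ correction is applied by
default, matching the basic SAM estimate.

`sam_one_class()` sweeps $\Delta$ over the breakpoints of
$|d - \bar{d}|$ and, when no $\Delta$ is supplied, picks the smallest
value attaining the minimum FDR with at least one call — the screen's
"$\Delta$ adjusted to minimize the FDR" operating rule, resolved toward
the most calls among minimizers. One property worth knowing: because the
chosen $\Delta$ sits exactly at a call boundary, the realized
false-discovery proportion can exceed the median-based estimate by about
one borderline call; the estimate is conservative at fixed $\Delta$ (a
tested property) but optimistic by that quantum at the selected one.
Strains missing any of the four replicates are dropped from SAM, not
imputed, with a logged count.

# Screen synthesis

Per target, strains are summarized by the mean of their four log2 Rel
values (the same summary SAM sees) and ranked descending — rank 1 is the
strongest precursor accumulator — with average ranks for ties
(`rank_strains()`). The composite rank is the arithmetic mean of the
per-target ranks over the five canonical splicing substrates (U3,
Rpl31b, Tef5, Tub3, Ubc13 precursors); strains with fewer than 3 of 5
targets available are flagged and placed last (`composite_rank()`).

The splicing-efficiency index is relative precursor over relative total
for a transcript (`splicing_efficiency()`): a pure splicing defect raises
it; a transcriptional increase raises numerator and denominator together
and cancels. The index inherits Rel's yield invariance.

Gene-set over-representation among top strains uses the exact one-sided
hypergeometric tail (`enrichment_test()`), summed in log space so that
p-values down to ~1e-300 come out exact — no approximation at any point.
The test is one-sided (over-representation) because the screen's
headline question is whether known splicing factors crowd the top of the
list; a background of $K = k = n$ is only consistent with an upper tail.
The background is the set of strains passing all filters for that
dataset, not the whole library. When several sets are tested, a
Bonferroni-adjusted p is reported alongside the raw value, the raw value
being primary. `candidate_report()` joins per-target calls, maximal d,
composite ranks and memberships, ordered by decreasing maximal d.

# The synthetic screen

`simulate_screen()` generates the complete object the pipeline consumes:
plate maps, long Cp tables, dilution-series points, and ground truth. Per
sample and target the true quantity is

$$q = A_t \cdot 2^{\beta} \cdot Y_s \cdot 2^{b_p}$$

where $A_t$ is the target's baseline abundance (references geometrically
spaced over a 300-fold span, anchored at 1 for the least abundant),
$\beta$ the strain's log2 spike effect (precursor targets only in
"splicing" mode; precursor plus total in "transcriptional" mode), $Y_s$ a
log-normal per-sample yield with log2 standard deviation $\sqrt{1.5}$
(matching the observed spread of $\log_2 C_{norm}$ in a real screen of
this design), and $b_p$ a per-plate batch offset. Technical replicates
multiply in mean-one log-normal noise with a chosen CV; Cp comes from the
target's standard curve; dropout replaces Cp with NA at a configured
rate. Everything is multiplicative/log-normal because QPCR errors are
multiplicative in quantity and all the pipeline's diagnostics live in
log2 space.

Defaults: 5500 strains, 2 biological × 2 technical replicates, technical
CV 0.05, dropout 0.002, plate offset sd 0.25 log2 units (a package
choice: real plate-to-plate drift is described only as "subtle"), curve
slopes drawn per target inside the 86–97% efficiency band, intercept 22
cycles (keeping every generated Cp positive across the abundance and
yield ranges). Strain-to-well assignment is deterministic row-major from
the seed, and a fixed seed reproduces the dataset byte for byte.

What the generator does *not* emulate: growth kinetics, structured
robotic liquid-handling errors, RNA degradation chemistry, primer-pair
cross-reactivity, or spatial plate gradients. Passing tests on synthetic
screens therefore validates the *arithmetic chain and its statistical
operating characteristics*, not the bench protocol; real-data pathologies
such as position effects would surface as CV or $C_{norm}$ filter
failures rather than being modeled.

# Numerical and boundary conventions

- Filter boundaries are strict on the failing side: CV of exactly 0.25
  passes; $\log_2 C_{norm}$ of exactly $-3$ passes.
- Even-count medians use the midpoint of the two central values.
- Hypergeometric tails are log-space sums with a per-value max shift;
  agreement with direct summation is at the 1e-14 level over all designs
  with $N \le 60$.
- Floating-point output is written with 17 significant digits so
  write–read round trips are lossless.
- Well labels are labels (A1–P24, zero-padded internally), never
  arithmetic indices.
- All randomness flows through explicit seeds; the exhaustive
  permutation path has none.

# Problem sizes used in validation

The test suite exercises the pipeline at sizes chosen to make every
statistical check sharp but quick: 2000-strain screens (2% spiked at +2
log2, technical CV 0.05, yield sd $\sqrt{1.5}$) over 10 seeds for
end-to-end recovery; 5000 samples for yield-variance recovery (3 seeds);
exhaustive hypergeometric cross-checks over every design with
$N \le 60$; and a 10,000-permutation sampled null against the 16-fold
exact enumeration. The acceptance script (`scripts/acceptance.R`) reruns
the same computations from scratch at the same sizes.

# Known limitations

- The deposited real-screen tables are not bundled; published SAM
  operating points (specific $\Delta$/FDR pairs and significant-strain
  counts) can only be checked by supplying those tables locally via
  `read_rel_table()`.
- The composite-constant aggregation (geometric mean) and the CV
  granularity are reasoned reconstructions of a protocol that admits
  several readings; both are configurable.
- The FDR-minimizing $\Delta$ rule shares basic SAM's known optimism at
  the selected threshold (see above); consumers wanting strict control
  should fix $\Delta$ a priori or apply the sweep table directly.
- With only 16 distinct permutations at 4 replicates, the FDR estimate is
  quantized; finer estimates require more replicates, not more sampling.
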