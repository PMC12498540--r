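---
title: "Quantifying rRNA 2'-O-methylation from fragment-end profiles: models and methods"
author: "riboMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rRNA 2'-O-methylation from fragment-end profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboMeth)
```

## The measurement model

A 2′-O-methyl group on the ribose of nucleotide *i* protects the
phosphodiester bond on its 3′ side from alkaline hydrolysis. When rRNA
is fragmented by controlled hydrolysis and the fragments are sequenced,
every cleavage of bond *i* leaves a fragment 3′ end at position *i* and
the next fragment's 5′ end at position *i + 1*. Methylation therefore
*depletes* read ends at the protected bond, in proportion to the
fraction of the rRNA population carrying the mark. That fraction — the
**methylation index** (MI) — is the estimand throughout this package:
MI = 1 is complete methylation, MI = 0.1 means 10 % of molecules are
methylated at the site.

### End counting and the bond coordinate

`countReadEnds()` tallies, per reference position, reads whose leftmost
aligned base starts there (5′ ends) and whose rightmost aligned base
stops there (3′ ends). Only mapped, primary, non-supplementary,
plus-strand alignments are counted: rRNA libraries are single-stranded,
so antisense alignments are artefacts and are only tallied in QC.
Ends are defined by the aligned reference span, so soft clipping never
moves an end — irrelevant for end-to-end aligners, but it makes the
behaviour defined for arbitrary input.

`combineEndCounts()` places both end classes on a common cleavage
coordinate. Because a cut at bond *i* produces a 3′ end at *i* and a 5′
end at *i + 1*, the 5′ counts are re-indexed down by one before
summation:

```
combined[i] = three_prime[i] + five_prime[i + 1],   i = 1 .. L-1
combined[L] = three_prime[L]
```

This is the only alignment of the two end classes onto one bond; the
mirrored convention (indexing each bond by its downstream nucleotide)
is available as `shiftDirection = "toward_end"` for comparison with
other code bases. 5′ ends at position 1 are natural transcript starts,
not hydrolysis evidence; they are excluded from `combined` and kept in
a separate slot. The transformation conserves counts:
`sum(combined) == sum(three_prime) + sum(five_prime[-1])`, a property
the test suite checks on random profiles.

### The score

For a catalogue site at position *i*,

$$\mathrm{MI}_i \;=\; 1 - \frac{n_i}{A_i}, \qquad
A_i = \frac{\sum_{d=1}^{k} w_d\,(c_{i-d} + c_{i+d})}{\sum w_d},$$

where $c$ is the combined profile, $n_i = c_i$, and the weights
$w_d = (k+1-d)/k$ decay linearly with distance (the "score C" family of
estimators: the site's count against a local expectation built from its
neighbourhood). The tunable parameters, all carried by `ScoreParams`:

| parameter          | default        | meaning                                    |
|--------------------|----------------|--------------------------------------------|
| `k`                | 6 positions    | neighbourhood half-width                   |
| `weightScheme`     | `linear_decay` | `w_d = (k+1-d)/k`, or `uniform`            |
| `minSiteCoverage`  | 100 counts     | minimum raw neighbour sum; below it, `NA`  |
| `clamp`            | `TRUE`         | restrict MI to [0, 1]                      |

The window size and weighting are deliberate design choices, not
constants dictated by the data: published score-C implementations vary
in both, so the package declares its defaults, records them in every
output header, and keeps them configurable. Three consequences of the
definition are enforced as tested invariants: MI is invariant to
uniform scaling of the profile (sequencing depth cancels), MI is
monotone non-increasing in the site's own count, and with clamping it
always lies in [0, 1].

Two deliberate missing-data rules: a site whose raw neighbour counts
fall below `minSiteCoverage`, or whose neighbourhood average is zero,
scores `NA` rather than a number — a low-coverage zero would otherwise
masquerade as "unmethylated". Windows are truncated at molecule ends
(no reflection or wrap-around): the simplest defensible edge rule, at
the cost of noisier averages within `k` positions of the ends.

### Replicate aggregation

Replicates are aggregated as the arithmetic mean of per-replicate MI
with SEM = sd/√n — the replicate, not the pooled read count, is the
unit of observation, matching how mean ± SEM panels are reported in
practice. A site missing in all replicates of a group is flagged and
excluded from contrasts; a site needs at least two non-missing values
per group to enter a test.

## Differential analysis

Pairwise contrasts use the unpaired two-tailed **equal-variance**
(pooled) t-test; multi-group trajectories use one-way ANOVA followed by
Tukey's multiple-comparison test, with the Tukey–Kramer harmonic-mean
form for unbalanced groups (replicate counts of 3 vs 4 are the norm in
the bundled dataset). Both are delegated to R's `t.test`, `aov` and
`TukeyHSD`; the package's own tests validate them against closed-form
and Monte-Carlo null-distribution oracles rather than trusting the
delegation blindly.

Classification of a significant site is purely directional: **hyper**
if the second group's mean exceeds the first's, **hypo** otherwise;
non-significant or untestable sites are **unchanged**. Significance is
an unadjusted per-site α = 0.05 — Tukey handles only the within-site
pairwise family — because the reference tables this package reproduces
use per-site p-values; a Benjamini–Hochberg switch exists
(`compareGroups(..., adjust = "BH")`) but defaults off, fidelity first.
A significant shift with a delta of exactly zero cannot be given a
direction and is classified unchanged with a warning; with continuous
MI this is practically unreachable.

Two operational definitions used throughout: a site is
**hypomethylated** in a group when its mean MI ≤ 0.9 (inclusive
boundary), and heatmap rows are split into **variable** (span of group
means > 0.05) versus **saturated** for display.

## The qPCR side

RTL-P exploits the same chemistry in reverse: at low dNTP
concentration, reverse transcriptase pauses at 2′-O-methylated riboses,
so an amplicon whose forward primer lies upstream of the site loses
template relative to one priming downstream. With
ΔΔCt = (Ct^up_low − Ct^down_low) − (Ct^up_high − Ct^down_high), the
score is

$$\mathrm{score} = 1 - 2^{-\Delta\Delta Ct},$$

clamped to [0, 1]. The model assumes 100 % amplification efficiency
(the base 2); an efficiency hook exists. The exact published form of
this score varies between laboratories, so the package treats it as a
declared, configurable model rather than a reproduction claim, and the
simulator inverts exactly this model so the round trip is testable.

Standard curves are least-squares fits of Ct against log10 dilution;
perfect doubling gives slope −1/log10 2 ≈ −3.3219 cycles per 10-fold
dilution. Copy numbers are *arbitrary*: the top standard is assigned a
nominal copy number (default 10⁶) and everything else follows from
inverting the line, with extrapolation beyond the fitted Ct range
flagged rather than refused. IP enrichment is the pellet/input ratio of
the target normalised to the same ratio of U6 snRNA.

## The simulator and what it does (not) emulate

`simulateEndCounts()` draws cleavage events over internal bonds with
probability ∝ `cleavage[i] · (1 − ρ · methylation[i])`, where ρ
(default 1) is the protection efficiency of a methyl group. The default
`"ends"` mode draws N events multinomially and emits each as a matched
3′/5′ end pair, so the combined profile reconstructs the cleavage draw
exactly and expected counts are analytic — this is the mode used for
estimator-recovery claims. The `"fragments"` mode samples cut *pairs*
with a 30–50 nt length window, emulating gel size selection; it
produces internally consistent SAM alignments and count tables and
stresses edge behaviour, at the cost of analytic expectations.

What the simulator does **not** model: sequencing error, adapter
read-through, base-quality structure, ligation and PCR bias, secondary
structure effects on hydrolysis (the `cleavage` vector can encode such
bias but defaults to uniform), and partial protection chemistry beyond
the single ρ parameter. Passing recovery tests on simulated data
therefore demonstrates the estimator's correctness under the stated
sampling model, not robustness to every real-library artefact.

`simulateMIMatrix()` generates replicate MI values around true group
means with clamped-Gaussian noise (a beta option with matched mean
exists for boundary-heavy truths, since clamping slightly biases means
near 0 or 1). `simulateRTLPCt()` and `simulateDilutionSeries()` invert
the qPCR models with Gaussian cycle noise. `writeFixtures()` emits a
complete miniature dataset — FASTA references, catalogue, SAM and count
tables for 2 molecules × 3 groups × 3 replicates, design file, Ct
tables, YAML truth manifest — byte-identical for a given seed. All
randomness flows through explicit seeds and leaks no RNG state.

## Numerical choices and problem sizes

* Coordinates are 1-based, closed, on the mature rRNA transcript
  everywhere (file headers say so); FASTA record ids map to molecule
  labels through an explicit configuration map, never substring
  matching.
* The packaged catalogue (42 sites on 18S, 64 on 28S) is the union of
  the positions in the bundled reference tables; users can supply their
  own TSV. p-values recorded there below print precision are stored at
  the censoring bound 1e-4 — they are only ever compared against
  α = 0.05.
* Estimator-recovery tests use one isolated site per 40-nt molecule at
  2×10⁵ events, giving each bond enough coverage that the
  |error| < 0.03 claim holds with wide margin; consistency is checked
  at 10³/10⁴/10⁵ events. Calibration tests use 1,000-site null
  matrices with σ = 0.05 and the 3/4/4 replicate structure of the
  bundled dataset. Monte-Carlo oracles for ANOVA and the studentized
  range use 10⁵ draws. These sizes keep the full suite under a minute
  per file while leaving the statistical margins comfortable.
* Monosome/polysome fractions need no special machinery: they are
  ordinary design groups (e.g. `ESC_WT_mono`), scored and contrasted
  like any other.

## Known limitations

* The score C constants (k, weights) affect absolute MI at sites whose
  neighbourhoods are themselves structured; cross-study comparison of
  absolute MI should fix these parameters, which is why they are
  recorded in output headers.
* `MI = 1 − n/A` is slightly biased when true cleavage propensity
  varies sharply within the window; the `cleavage` vector in the
  simulator exists precisely to probe this.
* The RTL-P score model assumes the downstream amplicon is unaffected
  by dNTP concentration; a site-specific efficiency correction is a
  hook, not a default.
* Hypomethylation calls at the MI ≤ 0.9 boundary are sensitive to the
  estimator's ~0.01–0.03 noise at realistic coverage; replicate
  aggregation is the mitigation, not a cure.
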