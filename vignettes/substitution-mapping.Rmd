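---
title: "Substitution mapping of volatile QTLs in a melon NIL panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution mapping of volatile QTLs in a melon NIL panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introqtl)
```

## The experimental design and its statistical model

A near-isogenic line (NIL) carries a single homozygous donor segment
(here from the Korean melon accession 'Shongwan Charmi', SC) in an
otherwise uniform recurrent background ('Piel de Sapo', PS). When a
panel of NILs carries overlapping segments of one chromosome region, a
trait difference between a NIL and PS places a QTL inside that NIL's
segment, and the *pattern* of which NILs do and do not differ localises
the QTL to the intersection of the affected segments minus the segments
of unaffected lines. That is substitution mapping: no likelihood model,
no LOD score — pure interval logic over marker-resolved segments.

The traits are relative abundances of fruit volatile organic compounds
(VOCs), expressed as percent of the per-sample total chromatographic
area. The panel is PS (n = 21 replicates) plus five NILs on chromosome 3
(SC3-5-7, n = 5; SC3-5-8 and SC3-5-12, n = 7; SC3-5-13 and SC3-5-14,
n = 9). Four NILs are climacteric (burst of respiration and ethylene at
ripening); SC3-5-7 and PS are not. The climacteric QTL *ETHQB3.5* lies
between markers CMPSNP374 and AI_14-F04 (25,197,968–26,434,021 bp,
1.24 Mb), and a VOC QTL whose interval overlaps that region is called
ethylene-dependent.

## Trait screening

Raw abundances are processed in a fixed order:

1. `normalize_relative()`: percent of per-sample total (compositional
   closure is therefore part of the measurement, see *Limitations*).
2. `substitute_zeros()`: zeros are detection-limit censoring, replaced
   by the minimum non-zero value of the whole matrix (one global
   constant; a per-trait variant exists but is not the default, since
   the single-constant reading is the literal protocol).
3. `log2_transform()`.
4. `anova_per_trait()` with pedigree (line) as the single fixed factor,
   `bh_adjust()` across traits, and retention at adjusted p < 0.05
   (strict inequality; ties at exactly 0.05 are excluded for
   determinism).
5. `dunnett_many_to_one()`: each NIL mean against PS, two-sided, pooled
   within-line variance with df = N − k. Adjusted p-values are tail
   probabilities of the maximum absolute component of the joint
   multivariate t of the contrast statistics (correlation
   `rho_ij = lambda_i lambda_j`, `lambda_i = sqrt(n_i/(n_i + n_PS))`),
   evaluated by quasi-Monte-Carlo (Genz–Bretz) with a fixed integration
   seed and absolute tolerance 1e-3. Reported p-values are therefore
   reproducible to that tolerance; the significance threshold 0.05 is
   never within 1e-3 of a decision boundary in the packaged analyses.
6. `significance_patterns()`: per trait, each NIL is scored +1
   (significantly above PS), −1 (below) or 0.

Outlier handling is reporting only (`flag_outliers()`, 1.5 IQR
box-whisker rule); nothing is removed automatically.

## The mapping rule

`consistent_bins()` works on *bins*, the intervals between adjacent
markers. A line's bin state is `SC` when both flanking calls are SC,
`PS` when both are PS, and `UNCERTAIN` when the flanks disagree (the
recombination breakpoint lies inside the bin) or a call is missing.

A bin is consistent with a significance pattern when

* every significant line is **certainly** SC there (`UNCERTAIN` is not
  evidence of presence), and
* no non-significant line is certainly SC there (`UNCERTAIN` is
  forgiven: only certain donor coverage excludes), and
* all significant lines share one sign.

The asymmetry is deliberate. A recombination gap is compatible with
either allele, so it cannot *support* a QTL claim for an affected line,
but neither can it *exclude* one for an unaffected line. It is also what
keeps the logic faithful to the panel's geometry: the SC3-5-7 breakpoint
lies in the CMPSNP374–ECM60c gap, so the region shared by all five NILs
ends at CMPSNP374, while the climacteric-specific region starts there —
the two must not bleed into each other, and with a symmetric rule they
would.

Two refinements, both exposed in `mapping_config()`:

* **Leniency.** SC3-5-13's climacteric behaviour is season-dependent, so
  its *failure* to reach significance is treated as non-informative —
  but only when every significant line in the pattern is climacteric.
  When the non-climacteric SC3-5-7 shows the effect, the trait is not a
  climacteric-association candidate and SC3-5-13's null result is
  ordinary exclusion evidence. The unconditional variant over-maps
  patterns of the form (+, +, +, 0, +) into the shared left segment.
* **Dominant direction** (class profile only). Compound classes
  aggregate member VOCs whose QTLs may pull in opposite directions, so a
  mixed-sign class pattern is retried once per sign with the
  opposite-signed lines excluded; it maps only if exactly one sign
  yields a non-empty bin set. Individual VOCs with mixed signs stay
  `NOT_INTERPRETABLE` — the package deliberately refuses to split one
  trait into two QTLs, since the panel cannot localise both.

`map_single_qtl()` then selects among the contiguous consistent runs:
the run overlapping the region of interest if any, else the largest
(ties: leftmost); the rest are kept as `alternates`. Colocalization
requires overlap of positive length — an interval that merely touches
the region at a shared marker does not colocalize, which is what places
QTLs "left of CMPSNP374" outside the ethylene region even though their
interval ends at its boundary marker. Traits with no significant line
are `NO_SIGNAL`; an empty bin set (or both signs mapping in fallback
mode) is `NOT_INTERPRETABLE`, scenario (iii).

## The genotype reconstruction

The published ideogram of the five NILs is graphical, without a printed
call matrix, so the packaged genotype fixture
(`genotypes_chr3_derived.tsv`, loaded by `melon_introgression_map()`) is
a constrained reconstruction, tagged *derived*: SC3-5-7 SC from the map
start through CMPSNP374, SC3-5-8 through MC215, SC3-5-12 from ECM208
through TJ10, SC3-5-13 and SC3-5-14 through AI_14-F04. These extents are
the simplest single-introgression assignment under which the mapping
rule reproduces the published per-trait outcomes — all 44 mapped QTLs
with their directions and ethylene labels, and none of the 66 unmapped
traits. Other reconstructions satisfying the same constraints may exist;
any of them would be observationally equivalent for this panel.

```{r fixture-run}
rp <- reproduce_paper()
rp$counts
```

## The synthetic-data generator

`simulate_dataset()` emulates the replicate-level data the study
measured but did not deposit. For sample *s* of line *L* and trait *t*:

raw_st = 2^( mu_t + beta_t I[state(L, b_t) = SC] + gamma_t f_gs + eps_st )

with `eps ~ N(0, sigma^2)`, per-sample latent block factors
`f ~ N(0, 1)`, censoring to zero below the `lod_q` quantile of the raw
values, then per-sample normalisation to percent. Defaults: the six-line
panel with the study's replicate counts, 161 traits, a quarter of them
carrying a planted QTL with `beta` = 2 log2 units and residual
`sigma` = 0.5, `lod_q` = 0.05, baseline log2 means N(0, 1.5²).

Two generator choices matter and are fixed by design:

* **Planted bins** are drawn only from bins certainly covered by at
  least one NIL segment. A QTL in the terminal TJ10–ECM125 bin, which no
  line covers with certainty, is invisible to this design by
  construction and would only dilute recovery scores with undetectable
  truths.
* **Planted traits are minor compounds** (baseline log2 mean N(−2, 1)).
  On the percent scale, strong planted up-effects on abundant traits
  inflate the affected lines' totals and push *every other* trait down
  in those lines — compositional closure. With planted effects on
  abundant traits that distortion reaches ~0.3 log2 per line and
  corrupts the sign patterns of null and planted traits alike, so the
  "true" QTL assignment stops being well-defined on the measured scale.
  Keeping planted effects on minor volatiles keeps closure second-order;
  it also mirrors the panel being emulated, where the large-fold mapped
  volatiles are minor esters and sulfur compounds while the dominant
  aldehyde/ketone background is comparatively stable.

What the generator does **not** emulate: season effects, correlated
replicate structure within plants, non-normal heavy-tailed measurement
error, and biosynthetic pathway constraints among traits. Passing
recovery tests therefore show that the pipeline inverts its own
generative assumptions at realistic signal-to-noise, not that the
published biological assignments are correct.

```{r recovery, eval = FALSE}
r <- simulate_and_recover(sim_config(seed = 1, n_traits = 200))
r$recovery
```

## Multivariate structure

`cna_groups()` links traits whose absolute Pearson correlation strictly
exceeds 0.7 and reports connected components, sorted by size.
`ward_hca()` clusters on `d = 1 − |r|` by default (sign-blind, matching
an absolute-correlation heatmap); `1 − r` and the squared-distance Ward
variant (ward.D2-style) are config options because the original
analysis does not state either choice — the defaults here are asserted
against this package's own oracles, not against the published figures.
Tie-breaking in the agglomeration follows `stats::hclust`; the
validation suite only uses continuous random instances where ties have
probability zero.

## Numerical conventions

* Zero within-group variance everywhere: F := 0, p := 1 (trait
  uninformative). Perfect separation with zero residual variance: p := 0.
* Dunnett tail probabilities: quasi-Monte-Carlo, fixed seed 20230113,
  absolute tolerance 1e-3, at most 50,000 integrand points.
* `interval_length_mb()` rounds half-up at the second decimal (plain
  `round()` would round half to even and miss printed values).
* BED export converts the package's 1-based closed intervals to 0-based
  half-open.
* All significance decisions use strict inequalities.

## Validation problem sizes

The test suite exercises: the full 110-trait fixture reconstruction;
Dunnett family-wise error on 2,000 simulated null datasets at the
study's replicate counts; Benjamini–Hochberg against a step-up oracle on
1,000 random vectors; the mapping kernel against an exhaustive
clause-by-clause oracle on 620 random map/pattern instances (up to 6
lines × 16 markers); parameter recovery on 32 simulated 200-trait
panels across effect sizes 0.5/1/2; and the network/clustering
operations against union-find, minimum-variance and pairwise-counting
oracles on several hundred random instances. These sizes were chosen so
each Monte-Carlo tolerance is a small multiple of its standard error.

## Known limitations

* One QTL per trait: genuinely polygenic traits surface as
  `NOT_INTERPRETABLE`, never as two intervals.
* The genotype fixture is a reconstruction (above); positions of mapped
  intervals inherit its marker resolution.
* Compositional closure is part of the measured scale; the package maps
  QTLs of *relative* abundances, which can differ from QTLs of absolute
  concentrations when totals shift strongly between lines.
* The engine has no "position in doubt" state; ambiguous runs are
  reported through `alternates` instead.
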