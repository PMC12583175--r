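---
title: "Diagnostic-ion screening of coumarins and cinnamic acids: methods and design"
author: "coumascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic-ion screening of coumarins and cinnamic acids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coumascreen)
```

## The problem

Untargeted positive-mode LC-MS/MS of coumarin-rich plant material yields
thousands of MS2 spectra, few of which match public spectral libraries.
Coumarins and cinnamic acids, however, fragment predictably: the
protonated molecule sheds small neutral moieties — CH3 (from methoxy
substituents), CHO, CO and CO2 (from the lactone/carboxyl), C2H2 and
H2O — in sequential, branching ladders. `coumascreen` turns that
chemistry into an automatic annotation workflow: match each node's
precursor against a curated in-house library, verify candidates by the
fraction of their expected characteristic ions actually observed,
explain unmatched precursors as library compounds plus common
modifications, group related nodes by molecular networking, and select
differential features across sample groups.

## Mass arithmetic

All masses are monoisotopic, computed from element counts (C = 12
exactly, H = 1.0078250319, O = 15.9949146221, N = 14.0030740052,
S = 31.97207069). The protonated adduct adds the proton mass
1.0072765 Da — not the hydrogen-atom mass — because library matching at
10 ppm resolves the ~0.55 mDa electron; at the 2-decimal display
precision used in reports the two conventions coincide. Displayed m/z
values are rounded half-up to 2 decimals, matching how such values are
reported; internal computation is always full precision.

Two tolerance levels are used throughout, and both matter:

* precursor level: 10 ppm (relative), for library matching and
  modification inference;
* fragment level: the wider of 20 ppm and 0.01 Da, mirroring 2-decimal
  fragment reporting; the absolute bound dominates below m/z 500.

`within_tolerance()` evaluates the relative window at the mean of the
two m/z values so the predicate is exactly symmetric.

## Fragment ladders and diagnostic scoring

```{r ladder}
iso_mh <- adduct_mz(monoisotopic_mass("C11H10O5"))  # isofraxidin
generate_ladder(iso_mh, c("CH3", "CHO", "CO2", "CO"))$display
generate_ladder(iso_mh, c("CH3", "CO2", "CH3", "C2H2"))$display
```

A candidate's *diagnostic-ion set* is built per compound, not from a
fixed global list: the class's branching loss sequences are applied to
the candidate's own `[M+H]+` and the unique rungs pooled. The coumarin
class uses four branches over the CH3/CHO/CO/CO2/C2H2 alphabet (13
unique rungs); cinnamic acids use H2O/CO branches (4 rungs), extended
by CH3 branches for methoxylated members (the 15 Da loss of
ferulic/sinapinic-type acids). A candidate is retained only when
strictly more than 60 % of its diagnostic ions have a matching peak —
the threshold is a strict inequality, so a score of exactly 0.6 fails.
The 13-rung coumarin set is deliberately deep: verification remains
robust when individual fragments drop below the noise floor (with 20 %
random peak loss, 8 of 13 rungs — still above threshold — survive with
probability ≈ 0.97).

Neutral-loss detection counts both precursor-to-fragment and
fragment-to-fragment differences, because the ladders are sequential: a
CO2 step may only be visible between two fragments. Class calls require
*all* of a class's gate losses (coumarin: CH3 and CO; cinnamic acid:
H2O and CO) and rank by supporting evidence; the typical intensity
ordering `[M+H-H2O]+ > [M+H-CO]+` of cinnamic acids is a soft,
rank-only feature. Class overlap is real — CH3/CO/CO2 losses are shared
with flavonoids — so multiple calls per node are reported rather than
suppressed.

One documented irregularity: three published scopoletin fragments
(133.03, 107.01, 81.00) sit ≈ 1.008 Da below the masses implied by
their own loss annotations, i.e. an extra hydrogen loss that is not
annotated. These ions are not used as anchor values. The ladder engine
accepts an explicit radical-H step
(`loss_catalog(include_radical_h = TRUE)`), off by default, which
reproduces them; no class rule relies on it.

## Screening pipeline and tiers

Per node: (1) precursor match at 10 ppm (isomers all returned);
(2) class calls from detected losses; (3) diagnostic scoring of every
library candidate; (4) if no candidate survives, modification
inference; (5) tier assignment:

* `library_confirmed` — a candidate passed the diagnostic score;
* `class_plus_modification` — a class was called and the precursor
  equals a class-consistent library base plus 1–2 catalog modifications
  (hexosylation +162.05282, methylation +14.01565, hydroxylation
  +15.99491, methoxylation +30.01057, acetylation +42.01057), with the
  base's own ladder verified in the spectrum;
* `class_only` — class evidence without a structural explanation;
* `unassigned` — everything else; degenerate spectra never error.

Modification combinations are capped at two steps to bound the
combinatorics (multisets, so "hexosylation+hexosylation" is allowed).
Nodes with two or more retained matches are flagged
`needs_manual_review` rather than auto-resolved — isomer discrimination
genuinely requires a human. The optional external-database resolver
slot for still-unexplained nodes is deliberately absent: the pipeline
performs no network calls.

## Coumarin dimers

Bicoumarin linkage is read from intensity dominance (> 50 % of total
ion current, a fixed operationalization of the qualitative "abundant
ions"): an ether-linked (C–O) dimer cleaves readily and shows a
continuous CH3/CH2/CO2 small-loss ladder from the precursor, while a
C–C-linked dimer resists cleavage and reproduces a single coumarin
unit's ladder. Spectra below the (configurable) m/z 300 dimer gate or
matching neither pattern return `undetermined`. The packaged formulas
for the chimsalicifoliusin dimers and arteminorin A are inferred from
their printed precursor masses and monomer compositions
(C21H16O9 → 413.09; C20H14O8 → 383.08) — they are stand-ins at the
mass-arithmetic level, which is all the engine uses.

## Molecular networking

`modified_cosine()` uses square-root intensity weighting and strict
one-to-one peak pairing; peaks match directly or offset by the
precursor difference, so a methylated analog aligns with its parent.
The pairing is solved exactly as a maximum-weight bipartite assignment
(via igraph) on the candidate-pair graph; a greedy mode exists as a
documented approximation. Edges require cosine > 0.6 (strict, "above
0.6") and ≥ 5 matched peaks (inclusive, "at least 5"); molecular
families are connected components, with singletons allowed. All
comparisons are node-vs-node — no consensus library spectra. Family
class labels are propagated with support counts, and mixed families
keep every label.

## Differential statistics

PCA and PLS-DA both operate on samples × features with unit-variance
scaling by default (the common metabolomics default; `pareto` and
`none` are available). PLS-DA is NIPALS PLS2 against a centered
one-hot group matrix, 2 components by default; VIP for feature *j* is
`sqrt(p * sum_a(w_ja^2 * SSY_a) / sum_a(SSY_a))`, whose mean square is
algebraically 1 — a property the test suite checks to 1e-9, and the
scores are cross-checked against an independent PLS-DA implementation.

The volcano stage computes fold change on arithmetic group means of
raw areas and p-values from a two-sided Welch t-test on log2 areas.
The named one-way ANOVA and the pooled t-test coincide for two groups;
Welch is the robust default and the comparisons are pairwise. No
multiple-testing correction is applied by default (the criterion is
raw p < 0.05); Benjamini–Hochberg is available via `p_adjust = "BH"`.
"FC ≥ 2" is inclusive and two-sided: `max(FC, 1/FC) >= 2` with the
direction from the ratio. When a table contains nonpositive areas,
half the smallest positive area is added throughout before ratios and
logs; clean tables are left untouched so exact planted ratios stay
exact. The differential-metabolite call is the intersection:
volcano-significant **and** VIP > 1 (strict).

Degenerate cases are handled, not hidden: constant matrices error
("no variance"), a both-groups-constant feature gets p = 1 when equal
and the smallest representable p when different, and zero-variance
features are dropped from scaled PCA with a warning.

## Synthetic data: what it emulates, what it does not

The generators close the loop between chemistry and screener.
`synth_spectrum()` realizes a compound's class ladder with branch-decay
intensities (earlier rungs more intense, `1000·0.8^(branch-1)·
0.6^(depth-1)`), uniform m/z jitter in ± ppm, independent per-rung
dropout, and uniform noise peaks over [50, precursor − 1] capped below
the 10th percentile of surviving signal intensities. Decoys are uniform
random peak lists. `synth_feature_table()` draws log-normal baselines
(meanlog log 1e5, sdlog 1), multiplies planted features by their fold
in the target group, and applies multiplicative log-normal noise
(sdlog = CV). Everything is integer-seeded; generators save and restore
the caller's RNG state.

The benchmark conditions are fixed: 50 planted compounds from a random
in-silico CHO library, 150 decoys, 5 ppm jitter, 20 % dropout for
screening (sensitivity ≥ 0.9, false-annotation rate ≤ 0.1 against
generator truth); 1000 features with 30 planted at 8× under 10 % CV
and n = 3 per group for the statistics (≥ 27 true, ≤ 3 false). Test
problem sizes (corpus sizes, trial counts such as the 1000-pair
assignment-oracle sweep) are chosen to exercise the combinatorics at
small n, where exhaustive oracles are feasible.

What passing these tests does **not** show: real spectra contain
isotope envelopes, multiply charged ions, chimeric co-isolation,
retention-time structure and instrument-specific noise, none of which
are simulated; real fold-change structure is not a clean two-group
plant. Corpus-level published counts (total annotated compounds,
fraction auto-annotated, per-pair differential counts) depend on raw
instrument data that is not public and are therefore out of scope.

## Pathway coverage

The coumarin biosynthetic route (phenylalanine/tyrosine →
cinnamic acids → umbelliferone/esculetin/scopoletin → scopolin,
fraxetin, isofraxidin, 6,7-dimethoxycoumarin) ships as a static
14-node DAG with enzyme-labelled edges (PAL, TAL, C4H, C3H, OMT, C2'H,
COSY, F6'H, 2GT, S8H) and an `authenticated` flag for steps usually
drawn dashed. Two encoding choices: the ferulic-acid → scopoletin step
lumps the CoA-ligation (3CL) into the F6'H edge rather than introduce
a feruloyl-CoA node; and the umbelliferone → esculetin hydroxylation,
whose enzyme is not in the legend, is carried by the hydroxylase label
F6'H with `authenticated = FALSE`. Coverage is exact set arithmetic
over canonicalized names with a synonym table ("isofraxin" =
"isofraxidin", "scoparone" = "6,7-dimethoxycoumarin"); no pathway
inference is attempted.

## Known limitations

* Element table covers C/H/N/O/S (an extension hook exists); halogens
  and phosphorus are out of scope for this compound space.
* Charge states > 1 and negative-mode adducts are not modeled.
* The screener's class rules are tuned to coumarins/cinnamic acids;
  flavonoids in the library are matched by precursor but have no
  dedicated ladder chemistry.
* The modified-cosine `O(n^2)` pair loop is intended for corpora of
  hundreds, not tens of thousands, of nodes.
* Dimer linkage calls are heuristics over intensity shares; they rank
  hypotheses, they do not prove bond connectivity.
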