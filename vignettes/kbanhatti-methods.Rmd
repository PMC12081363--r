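---
title: "K-Banhatti descriptors and polynomial QSPR models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{K-Banhatti descriptors and polynomial QSPR models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbanhatti)
```

## The model

A drug molecule is represented by its hydrogen-suppressed skeleton: a
simple undirected graph whose vertices are heavy atoms and whose edges
are bonds, with bond order ignored.  For a vertex $v$ write $d(v)$ for
its degree; for an edge $e = uv$ the *edge degree* is
$d(e) = d(u) + d(v) - 2$, the number of edges adjacent to $e$.  The five
K-Banhatti descriptors sum a function of $(d(v), d(e))$ over all
vertex--edge incidences $ve$ (each edge contributes two incidences):

$$
\begin{aligned}
B_1(G)  &= \sum_{ve} \bigl(d(v) + d(e)\bigr), &
B_2(G)  &= \sum_{ve} d(v)\,d(e), \\
HB_1(G) &= \sum_{ve} \bigl(d(v) + d(e)\bigr)^2, &
HB_2(G) &= \sum_{ve} \bigl(d(v)\,d(e)\bigr)^2, \\
Hb(G)   &= \sum_{ve} \frac{2}{d(v) + d(e)}.
\end{aligned}
$$

The summation-over-incidences reading is fixed by the worked reference
computations rather than the compact printed notation, which is
ambiguous about per-edge versus per-incidence terms; the arithmetic of
the worked examples disambiguates it.

Because every term depends only on the two endpoint degrees, the *edge
partition* -- the multiset of unordered endpoint-degree pairs $(a, b)$
with multiplicities $m(a,b)$ -- is a sufficient statistic.  With
$e = a + b - 2$, a class contributes $m(a,b)\,[(a+e) + (b+e)]$ to $B_1$
and analogously for the others.  The package computes descriptors
twice, by deliberately independent routes: class-wise sums over
`edge_partition()` and direct sums over `incidences()`
(`oracle_descriptors()`).  The two must agree exactly on the integer
descriptors and to $10^{-9}$ on $Hb$; this equivalence is asserted on
all packaged fixtures and hundreds of random graphs.

Edge degree 0 (a bond between two degree-1 atoms) is admitted: it
contributes 0 to $B_2$ and $HB_2$ and finite terms elsewhere, so no
special-casing is needed.  $Hb$ is accumulated in double precision with
no intermediate rounding; four-decimal presentation is formatting only.

## Packaged data and its quirks

The package ships the 20-drug anti-pneumonia panel: descriptor values
(thousands separators stripped on packaging), a property table with
five physicochemical properties -- enthalpy of vaporization En (kJ/mol),
molecular weight MW (g/mol), molar volume MV (cm³), flash point FP
(°C), molar refractivity MR (cm³) -- parsed from their printed
`value ± uncertainty` cells, and the four worked edge partitions.
Missing cells stay missing; nothing is imputed and no units are
converted.

Several quirks of the source tables are preserved and documented rather
than silently repaired:

* **Penicillin**: its property row holds a single value (344.390) under
  the En column with all other cells blank.  344 kJ/mol is implausible
  as an enthalpy of vaporization, and the value is close to a
  penicillin-salt molecular weight, so the row is treated as a
  data-entry misalignment and excluded from all property regressions by
  default (the descriptor row is kept).  This is the only *default*
  exclusion.
* **Carbapanem** (sic, as printed): MW is printed as 153.135 g/mol,
  chemically impossible for C18H29N3O5S.  The value is stored as
  printed; a toggle (`drop_carbapenem`) excludes the row.
* **Levaquin**: MR is printed as 91.1 ± 70.4 -- an uncertainty rivalling
  the value; a toggle (`drop_levaquin_mr`) blanks it.
* **Worked partitions**: the Cefuroxime class table has an odd total
  degree sum (155), so *no graph realizes it*; it exists only as a
  partition, and its product-form index sums to 467 where the source
  prints 466 (an arithmetic slip in the same table).  The Unasyn and
  Avibactam class tables are realizable but differ from the real
  molecular skeletons by one edge each; their packaged fixtures are
  therefore *synthetic realizations* of the class tables (constructed
  to match the published joint degree counts exactly, flagged
  `synthetic` in the JSON), while the other 18 fixtures encode the
  standard published structures.
* **Harmonic values**: exact class sums give 21.3524 (Linezolid) and
  14.0508 (Avibactam) against printed 21.364 and 14.06 -- roughly 0.01
  of accumulated rounding in the source; the package reports exact
  values.
* **Published model-quality grid**: the correlation table and the
  per-model R² listings are square-consistent ($r = \sqrt{R^2}$ within
  $10^{-3}$) in 95 of 96 printed cells; the cubic harmonic-index
  enthalpy cell (0.96497 vs $\sqrt{0.9019} = 0.9497$) carries a stray
  digit.

Every cleaning decision is data, not code: the exclusion list ships as
JSON with reasons, so alternate row sets can be swapped in for
sensitivity analysis.

## Regression models

For each descriptor $IN$ and property $W$ the package fits ordinary
least squares on the raw monomial basis
$W = \Phi_1 IN^d + \dots + \Phi_d IN + \beta$ for degrees $d = 1..4$
(linear, quadratic, cubic, biquadratic).  Descriptors are not centred
or standardized -- the published coefficient magnitudes are on the raw
scale -- and property uncertainties are ignored (ordinary, not weighted,
least squares; the source states no weighting scheme).  Model quality
is the unadjusted $R^2 = 1 - SS_{res}/SS_{tot}$ with $r = +\sqrt{R^2}$;
no information criteria or cross-validation, faithful to the protocol
being reproduced.  A fit needs at least $d + 2$ paired rows and a
non-degenerate design; grid cells that cannot be fitted are recorded
with a reason, never fatal.

Because the bases are nested, $R^2$ is non-decreasing in degree
cell-by-cell, and so is the mean $R^2$ per degree -- which is exactly
the linear < quadratic < cubic ≤ biquadratic reliability ordering the
grid reports.

### Row-set sensitivity

Under the default cleaning the recomputed grid does *not* reproduce
most published cell values: for example the linear MW~Hb fit gives
$R^2 = 0.827$ against a published 0.9627.  The discrepancies are
row-set artefacts, and `sweep_row_sets()` makes the search for the
published row sets explicit: it refits one cell under all exclusion
subsets of increasing size and reports the sets whose $R^2$ lands
within a tolerance of the target, smallest set first (deterministic,
exhaustive).  The findings, recomputed by `run_qspr()`'s report:

* dropping the implausible **Carbapanem** row reproduces the published
  molecular-weight fits (e.g. linear MW~Hb $R^2 = 0.9621$ vs 0.9627);
* dropping **Carbapanem + Levaquin's MR** reproduces the published
  molar-refractivity fits to four decimals (e.g. linear MR~B1
  $R^2 = 0.8964$);
* the published En, FP and MV fits are *not* recoverable by dropping
  up to a handful of rows with the printed property values, so those
  printed values cannot all derive from the printed table; for the
  quadratic En~B2 cell the sweep's closest printed-table row set (five
  exclusions) reaches $R^2 = 0.9376$ against a published 0.948.

The reproduction report states, for each matched column, the row set
used.  The internal-consistency check (square-root of recomputed $R^2$
against the published correlation grid, at $10^{-3}$) is asserted only
on cells whose $R^2$ is reproduced at its printed precision -- the
molecular-weight and molar-refractivity columns under the row sets
above.

## Synthetic data

`random_molecular_graph()` emulates drug-like skeletons: a random
spanning tree grown under a degree cap (default 4, heavy-atom valence),
then ring-closing edges between non-adjacent vertices with residual
degree, accepted with probability `ring_bias` and capped at
$\lfloor n/4 \rfloor$ so the cyclomatic number stays in the 2–5-ring
range typical of the panel.  Construction is spanning-tree-first, so
connectivity holds without rejection loops; a single integer seed
governs all randomness through an isolated RNG scope, leaving the
global random state untouched.

`synthetic_qspr_table()` plants a known polynomial of one descriptor
plus Gaussian noise, optionally masking a stated fraction of response
cells to emulate the property table's gaps.  What the generator does
*not* emulate: element identities, valence chemistry, realistic
property magnitudes, or correlated noise across properties.  Passing
tests on synthetic data therefore demonstrate algorithmic correctness
(descriptor computation, fitting, unbiased coefficient recovery), not
chemical validity of the QSPR models on real molecules.

Test and acceptance problem sizes were chosen to exercise the claims at
desk scale: oracle equivalence on all 20 fixtures plus 200 seeded
random graphs of 8–60 vertices; parameter recovery with 20 molecules
and 500 replicate refits at noise equal to 5% of the response range.

## Numerical choices and edge cases

* Integer descriptors are computed in integer/double arithmetic exactly;
  equality assertions are exact, $Hb$ comparisons use $10^{-9}$.
* `fit_polynomial()` computes $R^2$ directly from residuals, refuses
  fewer than $d + 2$ rows or a basis with fewer than $d + 1$ distinct
  descriptor values, and reports rank deficiency rather than silently
  dropping terms.
* Partition class keys are canonical ($a \le b$); querying $(b, a)$ is
  equivalent.  Coercion from published tables aggregates duplicate
  classes and rejects empty partitions.
* Drug-name joins are case-insensitive (the source tables spell at
  least one drug two ways).
* Ties in `best_models()` resolve to the first descriptor in column
  order; ties are not observed on the packaged data.

## Known limitations

* The 16 fixtures without published partitions are best-effort
  encodings of standard structures; they anchor validity and oracle
  tests, not published descriptor values (the packaged descriptor table
  is consumed directly for regressions).
* Only single-descriptor polynomial models are implemented -- no
  multivariate models, regularization, cross-validation or
  applicability-domain analysis, which the reproduced protocol also
  lacks.
* The row-set sweep is exhaustive and therefore combinatorial; it is
  intended for single cells at panel scale (tens of rows), not large
  datasets.
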