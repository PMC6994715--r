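---
title: "FUSIL binning and prioritisation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FUSIL binning and prioritisation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical procedures
it implements, the parameters that matter, the choices made where the
design was genuinely open, and what the synthetic-data tests do and do
not demonstrate about real data.

## 1. The viability model

A knockout line is produced from a heterozygote intercross, so under
Mendelian segregation a pup is homozygous null with probability 1/4.
With `n` genotyped pups and `k` live homozygotes the primary call is,
in decision order:

1. hemizygous lines are excluded (X-linked genes have no het×het
   cross to test);
2. if `n < 28`: the line is *viable* when `k >= 4` (at least 14% of a
   28-pup litter) and *insufficient* otherwise — a small litter can
   demonstrate survival but cannot demonstrate absence;
3. `k = 0` calls *lethal*;
4. `k/n < 0.125` together with a one-sided lower-tail exact binomial
   `P(X <= k; n, 0.25) < alpha` (default `alpha = 0.05`) calls
   *subviable*;
5. anything else is *viable*.

Two readings of the subviability rule are possible (fraction test only,
or fraction and significance); we require **both** criteria.  The
conjunction is conservative, reproduces the logic of the small-litter
exception, and uses a one-sided lower tail because subviability is a
one-directional deficit of homozygotes.  The exact binomial CDF comes
from `stats::pbinom`; nothing is approximated.

Per-line calls are resolved per gene: insufficient lines carry no
category and are dropped; any hemizygous line excludes the gene;
remaining substantive calls must be unanimous, otherwise the gene is
excluded as *conflicting*.  Treating insufficient lines as abstentions
(rather than viable votes) is deliberate: a small litter without
homozygotes is evidence of nothing.

### Windows of lethality

Embryonic stages E9.5, E12.5, E14.5/15.5 and E18.5 are scored for live
homozygotes (heartbeat at dissection).  A gene is *dead* at a stage
when zero live homozygotes were seen among at least 28 scored embryos
(the same minimum as the adult screen, reused deliberately), and
*alive* on any live homozygote.  The window is the interval between the
last alive stage and the first dead stage, and collapses to three
groups: before E9.5 → early; E9.5–E12.5 and E12.5–E14.5/15.5 → mid;
everything later, including lines still alive at E18.5 but lethal
preweaning, → late.  If the bounding stages are not adjacent (a stage
gap), more than one fine window is compatible with the data and the
gene is *unassigned*; we never interpolate.  Assignment is monotone:
additional survival at a later stage can only move the window later.

## 2. Essentiality and the −0.45 threshold

Per-gene essentiality is the arithmetic mean of CRISPR proliferation
scores across cell lines (lower = more essential); missing cells are
ignored, not imputed, since dropping a line changes the mean's variance
but not its target.  The essential/non-essential cut-off defaults to
−0.45 with the boundary on the essential side (`mean <= t`).

`select_threshold_f1()` re-derives a cut-off from data: every grid
value `t` predicts `essential iff mean <= t`, and the `t` maximising
`F1 = 2TP / (2TP + FP + FN)` against a reference labelling is chosen.
The default grid is −1.50 to 0.00 in steps of 0.01 — fine enough that
−0.45 is exactly representable, coarse enough that the search is
instantaneous.  F1 plateaus are common on well-separated data, so ties
are broken toward the grid value closest to the midpoint of the tied
run (lower index on an exact midpoint tie): deterministic, and central
in the plateau of equivalent cut-offs rather than at its arbitrary
edge.

## 3. FUSIL assignment

The five bins are the cross of the two axes: lethal × essential = CL,
lethal × non-essential = DL, subviable × non-essential = SV, viable ×
non-essential split by significant phenotypes into VP (≥ 1) and VN (0).
Subviable or viable genes scoring essential are set aside as
SV.outlier / V.outlier rather than forced into a bin — in practice
their means sit at or just below the threshold, and the synthetic
generator plants them there.  Viable genes with under 50% of their
phenotyping procedures completed cannot be split into VP/VN with any
confidence and are set aside as V.insuffProcedures; completeness is
computed as `procedures_done / procedures_total` against the total
scheduled procedures.

Cross-tabulation percentages are printed to two decimals with exact
halves rounded to even (base `round()`).  We verified both conventions
against the published table this layout mirrors: 318/320 = 99.375
prints as 99.38 *and* 2/320 = 0.625 prints as 0.62, which only
half-to-even reproduces.  Both halves are exactly representable in
binary, so the choice is not confounded by floating-point error.

## 4. Orthologue selection

Support for a human–mouse pair is the number of inference methods
(0–12) agreeing on it; tiers are 9–12 good, 5–8 moderate, 1–4 low.
The pipeline keeps pairs with support ≥ 5 and at least one
protein-coding member, then accepts a pair only when its support is the
**strict unique** maximum among surviving pairs of both its genes.
Ties for a maximum reject all tied pairs — this is how "filtering
duplicated maximum scores" is made precise — and guarantee the output
is a matching.  The alternative (accept ties arbitrarily) would make
the result depend on row order.

## 5. Enrichment statistics

Per bin and disease resource the 2×2 table is: `a` resource genes in
the bin, `b` genes annotated in **no** resource in the bin, `c`/`d` the
same outside the bin.  Genes annotated only in other resources are
excluded from that resource's table, so every comparison is
resource-vs-clean-background.  The universe is the five-bin set;
exclusion labels (outliers, V.insuffProcedures) are not part of any
comparison.

* Odds ratio: unconditional ML (Wald) `ad/bc`, CI
  `exp(log(OR) ± z · sqrt(1/a + 1/b + 1/c + 1/d))`.  Zero-cell tables
  return 0 or `Inf` with a `degenerate` flag and no CI; a
  Haldane-corrected (+0.5) variant is available behind the `haldane`
  argument but is off by default, because reporting a finite estimate
  from a degenerate table silently changes its meaning.
* Fisher's exact test: two-sided under the probability-ordering
  convention — the sum over all tables with the observed margins whose
  hypergeometric probability does not exceed the observed table's
  (with the standard `1 + 1e-7` relative tolerance for floating-point
  ties).  Conventions differ between implementations, which is why this
  one is stated; the suite cross-checks it against an independent
  implementation to 1e-12 on a thousand random tables.
* Benjamini–Hochberg correction is applied across the bins of each
  resource (the natural family here: one decision per bin per
  resource).  BH preserves the order of the p-values and never
  decreases them; it is *not* idempotent in general, and the tests
  assert the true properties only.
* Term over-representation is a one-sided upper-tail hypergeometric
  test per term against a reference universe, BH-corrected across
  terms — the generic core of GO/pathway analyses, with term→gene
  tables supplied as data.

## 6. Gene features

* **Recombination rates**: each map interval is assigned to the closest
  gene on its chromosome (distance 0 when overlapping), per-gene rate =
  unweighted mean of assigned interval rates.  Coordinates are 0-based
  half-open throughout.  Equidistant ties go to the gene with the lower
  start coordinate — some rule is required for determinism, and
  "upstream" is at least easy to state.  Interval–gene distances come
  from `GenomicRanges`; because its nearest-neighbour selection returns
  a single hit, ties are recovered by widening each interval by its
  nearest distance and filtering exact distances.
* **Expression tissues**: greedy decorrelation in input order — a
  tissue is retained iff its absolute Spearman rho with every
  already-retained tissue is ≤ 0.8.  The threshold is this package's
  choice (the upstream analysis did not print one); greedy-in-order is
  deterministic and keeps the first representative of each correlated
  block.  Constant columns have undefined rho and are retained with a
  warning rather than silently dropped.
* **Network statistics**: edges with combined score > 0.7 form an
  undirected simple graph (self-loops dropped with a warning).  Degree
  is the neighbour count; the topological coefficient follows the
  network-analyzer definition: for node *n* with `k_n >= 2` neighbours,
  `T_n` is the average of `J(n,m)/k_n` over all nodes *m* sharing at
  least one neighbour with *n*, where `J(n,m)` is the shared-neighbour
  count plus 1 if *n* and *m* interact directly; nodes with fewer than
  two neighbours get `T_n = 0`.  Computed from the sparse adjacency
  matrix (`S = A²`), and checked against a set-based oracle.
* **Paralogues**: a gene is paralogue-free when no partner reaches 30%
  amino-acid identity.  **Onset**: minimum over the fixed order
  antenatal < neonatal < … < elderly.  **Systems**: count of unique
  top-level phenotype terms.
* **Pairwise bin comparisons**: two-sided Wilcoxon rank-sum per bin
  pair, BH across the pairs of one feature.  The upstream analysis
  shows notched box plots without naming its test; the rank-sum test
  matches that display's medians-and-spread logic and needs no
  normality assumption.  Bins with fewer than 3 genes are skipped.

## 7. The prioritisation funnel

DL genes → absent from every disease resource → likely
haploinsufficient (`HI percentile < 10` OR `LOEUF < 0.35` OR
`pLI > 0.90`) → consortium evidence (Venn over 100KGP/DDD/CMG) → final
candidates (`in_100kgp AND (in_ddd OR in_cmg)`, variants absent from
gnomAD, `o/e missense < 0.8`).  A missing constraint score fails its
own clause but not the disjunction; a gene missing all three scores
cannot pass — no benefit of the doubt, since the filter's purpose is
positive evidence of intolerance.  In the shared-annotation comparison
(protein family / lowest-level pathway / direct interaction with known
monoallelic developmental-disorder genes) self-matches are excluded
when the query set overlaps the reference.

## 8. The synthetic-data generator

`fusil_sim_config()` defaults encode the study conditions: 5000 genes,
100 cell lines, class proportions near the real cross-tabulation
margins (CL 0.09, DL 0.17, SV 0.09, VP 0.42, VN 0.07, V.insuff 0.14,
outliers 0.01 each), homozygote rates 0 / U(0.01, 0.08) / 0.25 for
lethal / subviable / viable classes, litters of 28 + Poisson(20) pups
(with 2% of lines forced below 28 to exercise the insufficient-sample
path), essential and non-essential latent mean scores −1.0 and 0.0 with
between-gene sd 0.2 and per-cell-line sd 0.3, outlier classes planted
just below the −0.45 threshold, 20% baseline disease prevalence with a
true DL odds ratio of 2.6, 2% duplicated-maximum orthology edges, and
small hemizygous/conflicting plant rates (0.3% / 0.7%) matching the
order of magnitude seen in real screens.  Litter-size and
feature-distribution families (Beta/Normal/log-normal) are pragmatic
choices — only their ordering relative to the filter thresholds matters
for the tests.  All randomness flows from the single configured seed;
the same configuration reproduces byte-identical bundles, and the
writer records per-file checksums in a JSON manifest.

### What "borderline" means, and why

The generator's truth table carries an `is_borderline` flag computed
**ex ante** from latent parameters only: a gene is borderline when its
analytic probability of misclassification — combining the exact
binomial probabilities of a wrong viability call given its latent
homozygote rate and realized litter size with the normal probability of
its measured mean score crossing the threshold — exceeds 1%, or when it
was deliberately planted as an outlier, a duplicated orthologue, a
hemizygous or a conflicting line.  The 1% cut is self-consistent with
the 99% recovery target the end-to-end test asserts: a gene retained in
the denominator is, by construction, individually recoverable with
≥ 99% probability.

This definition matters because the confusion is *intrinsic to the
rules*, not an artefact of the implementation.  At the default litter
sizes (~48 pups) a truly Mendelian-viable gene is falsely called
subviable with probability ≈ 1.5% (the mass of the binomial lower tail
that passes both subviability criteria), and a subviable gene with a
homozygote rate near 0.01 produces zero homozygotes — a lethal call —
more often than not.  No classifier applying these rules can beat those
bounds, so the end-to-end recovery test conditions on the genes for
which the rules are informative, and the pipeline report prints the
unconditional recovery alongside it.  Planted true candidates are drawn
from DL genes clear of those boundaries, so funnel recall measures the
prioritisation logic rather than upstream stochastic dropout.

### What the generator does not emulate

Real litter and centre effects, allele-specific differences, genuine
score correlation structure across cell lines (scores are conditionally
independent given the gene mean), real ontology structure (term→gene
tables are flat), linkage between features (constraint scores,
expression and network degree are drawn independently given the class),
and the native file layouts of any external resource.  Passing tests
therefore demonstrate that the pipeline's logic is faithful to its
rules and recovers planted parameters — not that real data meet the
generator's assumptions.

## 9. Problem sizes and tolerances used by the test suite

The suite runs the viability caller against a brute-force oracle on the
full grid `n <= 60`; Fisher/BH against independent oracles on 1000
random tables (agreement to 1e-12); orthologue selection against
exhaustive evaluation on 1000 random bipartite instances up to 8×8;
threshold recovery over 50 replicates of 2000 genes (selected cut
within ±0.05 of −0.45); odds-ratio recovery over 200 replicates of
5000 genes (median within ±0.5 of 2.6, CI coverage ≥ 90%); and one
full 5000-gene, 100-cell-line pipeline run for end-to-end label
recovery.  These sizes keep the whole suite under a few minutes on a
single CPU while leaving each statistical assertion comfortable margins
under its null variance.

## 10. Known limitations

The subviability formulation (conjunction, one-sided lower tail) is a
documented reading, not a reproduction of any consortium's internal
pipeline; the completeness denominator is total scheduled procedures;
enrichment universes exclude the exclusion labels; and the funnel
abstracts consortium membership and gnomAD presence to per-gene
booleans — variant-level matching is out of scope.
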