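# fusil

Cross-species gene essentiality binning and disease-gene prioritisation.

Around a third of mammalian protein-coding genes are essential for life,
but "essential" means different things at different biological scales: a
gene can be required for the proliferation of a single cell, or
dispensable in cell culture yet indispensable for organism development.
`fusil` classifies genes along this full spectrum of intolerance to
loss of function (FUSIL) by combining two independent readouts:

* **mouse knockout viability** — counts of homozygous-null pups from
  heterozygote intercrosses, classified as *lethal* (no live
  homozygotes), *subviable* (< 12.5% homozygotes, i.e. less than half
  the Mendelian expectation of 25%, with a one-sided exact binomial
  *P* < 0.05) or *viable*, with a minimum of 28 genotyped pups (a
  smaller litter supports only a viable call, when ≥ 4 homozygotes are
  seen);
* **human cell-line essentiality** — the mean CRISPR-Cas9 proliferation
  score of each gene across cell lines, thresholded at −0.45 (the
  cut-off that maximises the F1 score against reference essentiality
  labellings; means at or below the threshold are essential).

Crossing the two axes yields five mutually exclusive bins:

| bin | mouse | human cells |
|-----|-------|-------------|
| CL  | lethal | essential — *cellular lethal* |
| DL  | lethal | non-essential — *developmental lethal* |
| SV  | subviable | non-essential |
| VP  | viable, ≥ 1 significant phenotype | non-essential |
| VN  | viable, no significant phenotype | non-essential |

plus exclusion labels for boundary cases (SV.outlier / V.outlier for
subviable/viable genes scoring just below the essentiality threshold,
and V.insuffProcedures for viable genes with under half of their
phenotyping procedures completed).

Around the core binning the package provides the supporting stages of
the analysis: one-to-one orthologue selection from multi-method support
counts (support ≥ 5 of 12 methods, at least one protein-coding member,
strict bidirectional unique maximum), windows-of-lethality assignment
from staged embryo scoring, per-bin disease-gene enrichment (Wald odds
ratio `ad/bc` with a log-scale normal-approximation CI, two-sided
Fisher exact *P*, Benjamini–Hochberg correction), gene-feature
summaries (recombination rates, expression tissue decorrelation,
network degree and topological coefficient, paralogues, age of onset,
affected physiological systems), and the staged prioritisation funnel
for developmental-disorder candidate genes (DL bin → not yet
disease-associated → likely haploinsufficient: HI percentile < 10 or
LOEUF < 0.35 or pLI > 0.90 → sequencing-consortium evidence → final
criteria: 100KGP and (DDD or CMG), variants absent from gnomAD,
o/e missense < 0.8).

A fully parameterised synthetic-data generator with latent ground truth
(`fusil_sim_config()` / `generate_dataset()`) emulates every input
table, so the whole pipeline is testable without any external download.

## Worked example

```r
library(fusil)
report <- run_fusil_pipeline(
  fusil_pipeline_config(simulate = fusil_sim_config(seed = 7)))
#> simulate: generating dataset (5000 genes, seed 7)
#> viability: 5000 genes called (1335 lethal, 455 subviable, 3111 viable)
#> orthology: 4912 of 5088 edges accepted as one-to-one
#> binning: CL=440 DL=871 SV=414 VP=1999 VN=346
#> prioritisation funnel: DL=871 -> DL_non_disease=557 ->
#>   constraint_filtered=418 -> any_consortium=83 -> final=24
#> truth: non-borderline recovery 0.9979 (n=1419), overall 0.9249
```

The log reads as the analysis funnel: of 5000 simulated genes, 1335 are
called lethal in the mouse; crossing with cell essentiality splits them
into 440 cellular-lethal and 871 developmental-lethal genes.  The DL
bin is then narrowed to 557 genes with no disease annotation, 418
passing the haploinsufficiency constraint filter, 83 with any
sequencing-consortium evidence and 24 final candidates.  The truth line
compares called bins against the generator's latent classes: 99.8% of
the genes whose latent parameters place them clear of the decision
boundaries are recovered exactly (92.5% of all genes — the remainder
sit inside the stochastic confusion bands discussed in the methods
vignette).

Per-bin disease enrichment from the same report (disease flags were
simulated with a true odds ratio of 2.6 for DL and baseline elsewhere):

```r
report$enrichment[report$enrichment$resource == "any",
                  c("bin", "a", "b", "or_hat", "ci_low", "ci_high")]
#>   bin   a    b or_hat ci_low ci_high
#> 1 CL   95  345  0.845  0.665   1.07
#> 2 DL  314  557  2.12   1.80    2.49
#> 3 SV   94  320  0.909  0.714   1.16
#> 4 VP  416 1583  0.690  0.597   0.798
#> 5 VN   68  278  0.747  0.567   0.983
```

(The full-pipeline DL estimate sits slightly below 2.6 because planted
disease-free candidate genes deplete the DL bin's prevalence; the
dedicated recovery experiment below isolates the estimator.)

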