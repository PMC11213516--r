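# methlink

Linking promoter CpG methylation to gene expression in two-group designs,
with the surrounding phenotype statistics of a cardiac knockout study:
differential methylation, differential expression, TSS-window integration,
an infarct-boundary roughness index, and metabolite/census panels — all
testable end to end on synthetic data with known ground truth.

## What it computes

**Differential methylation (per CpG).** Methylated counts *m* of *n* reads
are modelled as beta-binomial with group mean *p* and dispersion φ,
Var(*m*/*n*) = *p*(1−*p*)(1+(*n*−1)φ)/*n*. Each observation is transformed
with the arcsine link *y* = arcsin(2p̃−1), p̃ = (*m*+½)/(*n*+1), whose
delta-method variance (1+(*n*−1)φ)/*n* is free of *p*; a generalized
least-squares fit of intercept + group with those known weights gives the
group effect β̂, its standard error, and a Wald *z* test, with
Benjamini–Hochberg control across sites (DMC: *q* ≤ 0.05). A two-sample
Kolmogorov–Smirnov test reports the genome-wide methylation shift. A
numerical-ML beta-binomial likelihood-ratio test is included as an
independent cross-check.

**Differential expression (per gene).** Negative binomial log-linear model
with TMM-effective library-size offsets, dispersion from df-corrected
Pearson estimating equations with a lowess mean–dispersion trend, and a
1-df likelihood-ratio test of the group coefficient (DEG: *q* ≤ 0.05).

**Integration.** DMCs are linked to genes whose TSS ± 2 kb window contains
them; linked genes are intersected with DEGs; a gene survives the
anticorrelation filter if at least one linked CpG is ≥ 25 percentage
points more methylated in the gene's lower-expression group; survivors are
classified (down_hyper / up_hypo / down_hypo / up_hyper) and clustered
(k-means++ / Lloyd on z-scored log-CPM).

**Roughness index.** For a traced boundary polygon, the ratio of the
perimeter of the area-matched moment-based best-fit ellipse (Ramanujan II)
to the polygon perimeter: 1 for smooth ellipses, 2√π/4 ≈ 0.886 for a
square, lower for boundaries with finger-like projections. Slices are
averaged per animal before an unpaired t test.

**Phenotype panels.** Adenylate energy charge
([ATP]+½[ADP])/([ATP]+[ADP]+[AMP]); the 2-HG/α-KG, succinate/α-KG,
fumarate/α-KG and SAM/SAH methylation-potential ratios with Welch tests;
whole-organ cell-count extrapolation and the nucleation distribution.

**Synthetic study.** `sim_config()` + `simulate_study()` generate all
inputs (Bismark-style methylation counts, expression counts, annotation,
boundary tracings, metabolite/nucleotide panels) with planted,
ground-truthed effects; see the methods vignette for the generative models
and every default.

## Worked example

```r
library(methlink)

study <- simulate_study(sim_config(n_genes = 1000, seed = 42))
res <- run_pipeline(study)
print(res)
#> pipeline_result: KS D = 0.029 (p = 0.000395)
#> integration_report
#>   DMCs (q <= 0.05):            420
#>   TSS-proximal DMCs (+/-2000 bp): 296
#>   DEGs:                        110
#>   DEG/DMC overlap genes:       25
#>   filter survivors (>= 0.25):  23
#>   direction classes:  down_hyper=21, up_hypo=1, down_hypo=0, up_hyper=1
```

Of 10,000 simulated CpGs, 420 are called differentially methylated, 296 of
them within 2 kb of a TSS; 110 genes are differentially expressed; 25
genes are both, and 23 survive the 25% anticorrelation filter — almost all
of them hypermethylated-and-downregulated, as planted (20 coupled genes
were planted; here 19 are recovered plus 4 borderline false positives):

```r
coupled <- attr(study$meth$truth, "coupled_genes")
surv <- res$report$survivors$gene_id
c(precision = mean(surv %in% coupled), recall = mean(coupled %in% surv))
#> precision    recall
#> 0.826087     0.95
```

The boundary tracings separate cleanly (knockout boundaries are generated
with 12 lobes of amplitude 0.25, control with 0.05; within-group variation
is tiny by construction, hence the extreme t):

```r
ri_wt <- sapply(study$boundaries$WT, function(p) roughness_index(p)$value)
ri_ko <- sapply(study$boundaries$KO, function(p) roughness_index(p)$value)
compare_roughness(ri_wt, ri_ko,
                  animal_a = sapply(study$boundaries$WT, attr, "animal"),
                  animal_b = sapply(study$boundaries$KO, attr, "animal"))
#> roughness: WT 0.912 vs KO 0.455, p = 1.8e-19
```

and the nucleotide panel shows preserved energy charge (0.904 vs 0.863)
despite the planted 30% drop in absolute concentrations:

```r
nuc <- study$panels$nucleotides
tapply(energy_charge(nuc$ATP, nuc$ADP, nuc$AMP), nuc$group, mean)
#>    WT    KO
#> 0.904 0.863
```

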