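---
title: "Linking promoter CpG methylation to gene expression: models and design choices"
author: "methlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking promoter CpG methylation to gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`methlink` implements the statistical core of a two-group multi-omic analysis
of the kind used to study epigenetic reprogramming in knockout-versus-control
animal designs: per-CpG differential methylation from bisulfite counts,
negative binomial differential expression, linkage of the two through
transcription-start-site (TSS) windows with an anticorrelation filter, a
shape-descriptor index for infarct-boundary roughness, and closed-form
metabolite and cell-census statistics. Every stage is exercised on synthetic
data with known ground truth; nothing in the package depends on external
data.

# The differential methylation model

## Observable and model

For CpG site $i$, sample $j$, we observe methylated reads $m_{ij}$ out of
$n_{ij}$ total. Within a group, the per-sample methylation proportion is
modelled as beta-binomial: a latent proportion with mean $p$ and dispersion
$\varphi \in [0,1)$, parameterized so that

$$\mathrm{Var}(m_{ij}/n_{ij}) = p(1-p)\,\frac{1 + (n_{ij}-1)\varphi}{n_{ij}},$$

with $\varphi = 0$ degenerating to the binomial. The Beta parameters are
$a = p(1-\varphi)/\varphi$, $b = (1-p)(1-\varphi)/\varphi$.

## Arcsine link and GLS fit

Each observation is transformed with the variance-stabilizing arcsine link

$$y_{ij} = \arcsin\!\big(2\tilde p_{ij} - 1\big), \qquad
  \tilde p_{ij} = \frac{m_{ij} + 1/2}{n_{ij} + 1},$$

(the 1/2 is a continuity correction keeping boundary counts finite). The
delta method gives $\mathrm{Var}(y_{ij}) \approx (1 + (n_{ij}-1)\varphi)/n_{ij}$,
independent of $p$ — this single fact drives the whole fitting scheme: with
known weights $w_{ij} = n_{ij}/(1+(n_{ij}-1)\varphi)$, generalized least
squares on the design (intercept + group) reduces to the difference of
precision-weighted group means, its standard error
$\sqrt{1/\sum_{j\in\mathrm{ref}} w_{ij} + 1/\sum_{j\in\mathrm{alt}} w_{ij}}$
comes from the weights alone (no residual variance is estimated), and the
Wald $z = \hat\beta/\mathrm{SE}$ is referred to a standard normal. Because
the variance is *not* estimated from 6 residual degrees of freedom, the
normal reference (rather than a $t$) is the appropriate one; the calibration
tests confirm it.

## Dispersion estimation

A method-of-moments estimator equates the within-group squared deviations of
the sample proportions to their beta-binomial expectation,
$p(1-p)(1+(n_{ij}-1)\varphi)/n_{ij}$, pooled over both groups, floored at 0
and capped at 0.99.

At the study's design size (n = 4 per group) the per-site estimate is
essentially unidentifiable: its sampling noise exceeds typical values of
$\varphi$ by an order of magnitude, and summaries of the floored per-site
estimates (such as their median) are systematically biased low, which in
turn inflates the Wald statistic. The package therefore uses the
*genome-wide pooled* moment estimator — the ratio of the summed moment
numerators to the summed moment denominators across all non-degenerate
sites — for every site when either group has fewer than 6 samples. This
pooled estimator is nearly unbiased in simulation (0.053 recovered for a
true 0.05; 0.107 for 0.10), and with it the null rejection rate at
$p < 0.05$ sits at 0.04–0.05 for $\varphi \in \{0, 0.05, 0.1\}$. With 6 or
more samples per group the per-site estimate is informative and is used
unshrunk; this also makes the site ranking agree with a per-site
maximum-likelihood beta-binomial likelihood-ratio test (Spearman
$\ge 0.95$ at n = 8), which the test suite uses as an independent oracle.
At n = 4 the pooled design means the two tests can legitimately rank
borderline sites differently, so the oracle-equivalence check is run at
n = 8.

## Degenerate sites, filtering, multiplicity

Sites with methylation identically 0 (or identically 1) in every sample of
both groups carry no information on a group difference; they are flagged
`degenerate` and excluded from testing rather than assigned p = 1. The
default coverage filter requires `min_coverage = 5` reads in every sample.
Benjamini–Hochberg adjustment is applied over the testable sites and
"FDR $\le$ 0.05" is read inclusively ($q \le 0.05$). The genome-wide
methylation shift is tested by a two-sample Kolmogorov–Smirnov test on the
per-site group-mean methylation proportions.

Coordinates are 0-based half-open internally and 1-based at the
Bismark-format boundary. Symmetric CpG dyads (plus-strand site at position
$i$, minus-strand at $i+1$) are summed onto the plus strand before fitting.

# The differential expression model

Counts are modelled as negative binomial with log link,
$\log \mu_{gj} = \beta_{g0} + \beta_{g1}\,\mathrm{KO}_j + \log N_j$, where
$N_j$ is the TMM-effective library size. TMM here follows a fixed, fully
specified recipe: reference sample = the one whose 75th-percentile count
fraction is closest to the group mean; double trimming of 30% on each tail
of the log-ratios M and 5% on each tail of the abundances A; unweighted
mean of the kept M values; factors rescaled to geometric mean one.

Per-gene dispersion solves the Pearson estimating equation
$\sum_j (y_{gj}-\hat\mu_{gj})^2 / (\hat\mu_{gj} + \varphi\hat\mu_{gj}^2)
 = n - 2$, which charges the two fitted group means their degrees of
freedom and is mean-unbiased in simulation (0.050 recovered for a true
0.05, Poisson data recovered as $\approx 0$). A lowess trend over
log mean expression (computed with `iter = 0`: the local *mean* is the
unbiased plug-in target; robustness iterations would chase the median of
these strongly right-skewed estimates, which sits ~10% low) summarizes the
mean-dispersion relationship. In small designs (per-gene residual df < 10,
i.e. fewer than 12 samples) the trend is used as-is, because the per-gene
values carry more noise than signal and feeding that noise into the test
convexly inflates it; in larger designs each gene keeps 30% of its own
estimate. The cost of the pure trend is that genuinely outlying genes
(e.g. highly variable immune genes) are tested at the trend dispersion in
small designs — a known limitation shared by any heavily moderated
small-sample analysis.

Testing compares the full fit against the intercept-only fit by a
likelihood-ratio test on 1 df (both fitted by IRLS at the same fixed
dispersion), with BH adjustment. Under null simulations at the design size
(n = 4/4, 2,000 genes, dispersion 0.05) the rejection rate at $p<0.05$ is
0.045–0.056; planted two-fold-squared effects (log2FC = 2 at mean 200) are
recovered completely with mean |log2FC error| $\approx$ 0.19. Fold changes
are reported unshrunk; zero counts are handled by the IRLS working response,
not pseudo-counts.

# Methylation-expression integration

* **TSS windows**: symmetric $\pm$2 kb around each TSS, half-open, clipped
  at chromosome ends. The window is symmetric regardless of strand because
  the biology being captured (promoter-proximal regulatory methylation)
  does not specify a direction.
* **Linkage**: every (significant CpG, window) containment is a link; a CpG
  inside two overlapping windows links to both genes.
* **Overlap**: genes both differentially expressed and carrying at least one
  linked differentially methylated CpG (the Venn intersection).
* **Anticorrelation filter**: for each overlap gene, the *lower-expression
  group* is the group with the smaller TMM-normalized mean CPM for that
  gene; the gene passes if at least one linked CpG is more highly
  methylated in that group by $\ge$ 0.25 *absolute* on the
  methylation-proportion scale (inclusive). The absolute reading is chosen
  because methylation levels are compared as percentages; a relative
  ($\ge$1.25-fold) reading is exposed via `relative = TRUE`. The "any
  linked CpG" rule reflects that the filter operates per-CpG. Both choices
  are deliberately permissive individually and stringent jointly; the
  end-to-end test plants coupled genes and verifies precision and recall
  $\ge$ 0.9 of the survivor set.
* **Direction classes**: the sign of the expression change crossed with the
  sign of the strongest linked CpG's methylation change gives four classes
  (`down_hyper`, `up_hypo`, `down_hypo`, `up_hyper`); a zero methylation
  difference is tie-broken to hypo with a warning.
* **Clustering**: z-scored log-CPM of the survivors is clustered by
  Lloyd's k-means from k-means++ starts, best of 10 restarts, k = 2 by
  default (two groups, two dominant patterns), deterministic given a seed.

# The boundary roughness index

A traced infarct boundary is an ordered closed polygon in physical units.
Area and centroid come from the shoelace formulas; the second central
moments of the polygon *interior* come from exact Green's-theorem closed
forms (not vertex moments). The best-fit ellipse takes its orientation
$\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11}, \mu_{20}-\mu_{02})$ and axis
ratio from those moments (for a uniform ellipse the moment along the major
axis is $a^2/4$) and is then rescaled so its area equals the polygon area —
the "Fit Ellipse" convention of standard image-analysis software, which the
equal-area requirement dictates. The index is

$$\mathrm{RI} = \frac{P_{\mathrm{ellipse}}}{P_{\mathrm{polygon}}},$$

computed with Ramanujan's second approximation for the ellipse perimeter
(relative error below $10^{-6}$ for aspect ratios up to 20, guarded by a
quadrature oracle in the tests). Smooth elliptical tracings give 1; a
square gives $2\sqrt{\pi}/4 \approx 0.8862$; finger-like projections push
the index down. The index is invariant under rotation, translation and
uniform scaling, and strictly decreasing in the amplitude of the synthetic
lobe family $r(\theta) = R(1+\varepsilon\sin 12\theta)$.

Binary-mask input is supported by taking the 0.5-level isocontour of the
mask (sub-pixel marching squares), keeping the contour enclosing the
largest area, and simplifying it with a Douglas–Peucker tolerance of 0.5
pixels before measuring — raw pixelated contours would inflate the
perimeter by up to a factor $4/\pi$. The tolerance is configurable and
recorded on the returned polygon. Whether real tracings should be smoothed
before measurement is an open judgement call; the explicit, logged
tolerance is this package's answer.

Group comparison averages the 6–8 slice indices within each animal first
and applies an unpaired two-tailed Student t test to the animal means
(n = 4 animals per group in the emulated design).

# Phenotype statistics

* **Adenylate energy charge**: $([\mathrm{ATP}]+\tfrac12[\mathrm{ADP}]) /
  ([\mathrm{ATP}]+[\mathrm{ADP}]+[\mathrm{AMP}])$, on [0,1],
  scale-invariant.
* **Methylation-potential ratios**: 2-HG/α-KG, succinate/α-KG,
  fumarate/α-KG (inhibitors of α-ketoglutarate-dependent demethylases over
  their co-substrate) and SAM/SAH (methyl-donor potential), computed per
  sample on *raw* abundances and compared across groups with Welch's
  two-sample t test (Satterthwaite df). Median scaling (each metabolite to
  cross-sample median 1) is provided for display only; a test documents
  that ratios and median scaling do not commute. Ratios normalized to the
  reference-group mean are reported alongside the raw ones.
* **Census**: whole-organ counts extrapolate an aliquot count by its
  fraction; the nucleation distribution reports mono/bi/poly percentages
  and a nuclei total of $1\cdot\mathrm{mono} + 2\cdot\mathrm{bi} +
  k\cdot\mathrm{poly}$ with the polynucleated multiplicity $k$ defaulting
  to 3 (the smallest value consistent with "more than two"; configurable).

Welch's statistic is implemented in closed form rather than wrapped,
because the contract requires explicit zero-variance behaviour (p = 1 for
identical constant groups) where the standard implementation errors; the
standard implementation serves as the oracle in the tests.

# The synthetic study

The generator is a pure function of a single master seed (sub-seeds are
split deterministically per component) and its defaults *are* the emulated
study conditions:

| parameter | default | why |
|---|---|---|
| samples per group | 4 | animals per condition in the emulated design |
| coverage | NB(mean 30, shape 5), floor 1 | realistic RRBS depth variability |
| CpG placement | 60% in TSS±2 kb, 6 per window | guarantees linkable sites |
| baseline methylation | Beta(1.5,6) promoters, Beta(6,1.5) background | bimodal methylome |
| planted DMC effect | ±0.30 proportion, 80% hyper | matches the 0.25 filter scale; global upward shift |
| methylation dispersion φ | 0.01 | isogenic littermates; consistent with the stated power behaviour (recall ≥ 0.8 at coverage 30, n = 4/4) |
| expression means | lognormal(log 150, 1.2) | spans low to high expressors |
| planted log2FC | ±2, 10% of genes | clearly detectable at n = 4 |
| NB dispersion | 0.05 | typical for inbred-animal RNA-Seq |
| coupling | 20% of DEGs: ≥3 promoter CpGs at +0.30 and log2FC −2 | hypermethylation ↔ downregulation |
| metabolite noise | lognormal, CV 0.3 | scaled-intensity panels |
| boundaries | $R(1+\varepsilon\sin 12\theta)$, 400 vertices, jitter 0.002; ε = 0.05 (WT) / 0.25 (KO) | smooth vs finger-like peripheries |

Uncoupled planted DEGs are placed only on genes without planted promoter
CpGs, so coupling is unambiguous in the truth tables. Calibration
simulations (type-I checks) use a flat design instead — baseline uniform
on [0.1, 0.9] — because the operating range of the test is the informative
interior; the bimodal extremes of the study-like generator are largely
flagged degenerate and are tested separately.

What the generator does **not** emulate: restriction-fragment selection
geometry (MspI digestion), bisulfite-conversion errors, read-level data,
correlated methylation along the genome, batch structure, and
heterogeneous per-site dispersion. Passing tests therefore demonstrate the
statistical machinery under the model it assumes, not robustness to every
artefact of real libraries.

# Problem sizes and numerics

Operating-characteristic tests run at 2,000 sites/genes (type-I error
bands of ±0.015 at that size), effect recovery at coverage 100 with n = 8,
and the end-to-end study at 1,000 genes / ~10,000 CpGs — sizes at which the
whole suite completes in well under a minute while keeping Monte-Carlo
error far below the margins being tested. IRLS uses a convergence
tolerance of 1e-8 with 100 iterations and flags non-convergence per gene;
negative LR statistics beyond −1e-6 warn before clamping to 0; the
beta-binomial reference likelihood is maximized from two starts
(moment-based and high-dispersion) with L-BFGS-B on bounded parameters.

# Known limitations

Per-CpG testing only (no tiling, smoothing, or covariates); two-group
designs only; the anticorrelation filter's reading (absolute difference,
any linked CpG, per-gene lower-expression group) is one defensible
interpretation among several — alternatives are exposed as options but the
defaults are not claimed to match any particular published gene list; the
k of k-means and the polynucleated multiplicity are conventions, not
estimates.
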