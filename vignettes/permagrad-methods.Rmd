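---
title: "Statistical methods behind permagrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind permagrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permagrad)
```

permagrad implements the statistical workflow used to relate panarctic
permafrost metagenome abundance tables — KEGG-ortholog gene counts and
class-level taxonomic relative abundances — to environmental gradients
measured at nested sampling locations (continents containing regions
containing sites, with a handful of field replicates per site).  This
vignette explains each stage's model and assumptions, the tunable
parameters, the synthetic-data generator used to validate the pipeline, and
the numerical choices made where the methods literature leaves the design
open.

## Environmental covariates: transforms, EM imputation, PCA

Field campaigns rarely measure every variable at every core, so the twelve
continuous environmental variables (latitude, longitude, elevation, age,
depth, total C, total N, C/N, organic C, pH, ice content, EC) arrive with
missing cells.  Multivariate analyses that delete any incomplete sample
would discard much of the data, so missing cells are imputed under a
multivariate-normal model with an expectation-maximization (EM) algorithm.

`normalize_env()` prepares the variables for the Gaussian model: the
strictly positive, right-skewed quantities (age, depth, EC, ice content,
total C, total N, organic C) are log-transformed as `ln(x + c)` with `c`
half the smallest positive observed value (so zeros remain finite), and
every variable is standardized to mean 0, SD 1 on its observed cells.  All
transform parameters are recorded and exactly invertible.  Longitude is a
circular quantity treated as linear; panarctic sites do not wrap the
antimeridian in a way this analysis models, which is a documented caveat
rather than a modeling claim.

`em_impute()` is the classic EM for a multivariate normal with ignorable
missingness: the E-step fills each sample's missing block with its
conditional mean given the observed block and the current `(mu, Sigma)`,
accumulating the conditional covariance so the M-step update is exact and
the observed-data log-likelihood never decreases (checked at every
iteration).  Convergence is declared when the largest parameter change
falls below `tol` (default `1e-6`, a conventional EM tolerance) within
`max_iter` iterations (default 500; the pipeline driver allows more because
convergence slows when the number of samples per parameter is small).  A
non-positive-definite covariance update receives a `1e-8` ridge and is
logged.  A single conditional-mean completion is returned — the workflow
feeds one completed dataset to PCA and PERMANCOVA — rather than multiple
imputation, which would propagate uncertainty but produce a different,
non-reproducible downstream table each draw.

`pca_correlation()` eigendecomposes the Pearson correlation matrix of the
completed data (all variables on equal footing regardless of units).
Because eigenvectors are sign-ambiguous, each loading column is oriented so
its largest-magnitude variable loads positively — a deterministic
convention that makes outputs comparable across runs up to a global sign.
Scores are standardized to unit variance so that PC1/PC2 enter downstream
models as z-scores.

## Dissimilarity partitioning: nested PERMANCOVA

Gene tables are reduced with an abundance filter (keep a gene when strictly
more than `min_count` reads are seen in at least `min_fraction` of samples;
10 and 10% for the community-level analysis), converted to per-sample
relative abundances, square-root transformed to damp dominant genes, and
turned into a Bray–Curtis dissimilarity matrix
`d(i,j) = sum|x_i − x_j| / sum(x_i + x_j)`.

`permancova()` partitions the matrix by sequential (Type-I) sums of squares
over the ordered terms *covariate, continent, region(continent),
site(region), covariate × site(region)* using projection ("hat") matrices
applied to the Gower-centered inner-product matrix `G = −½ C D² C`, whose
trace equals the total sum of squares.  Percent variation is reported as
`100·SS/SS_total` from this sequential partition; "components of variation"
estimators used by some commercial software are not computed because their
exact definition is not recoverable, and SS proportions are unambiguous.

The design is mixed: continent is fixed; region within continent and site
within region are random.  Pseudo-F denominators follow the standard
expected-mean-square rules for a fixed factor above nested random factors —
continent over the region mean square, region over the site mean square,
site, covariates and interactions over the residual.  When a term
contributes no degrees of freedom (for example a single region per
continent) it is dropped with a message and the denominator chain collapses
to the next term down.

P-values come from permutation of residuals under the reduced model.  For
each term, `G` is residualized on all preceding terms and the residual
matrix is permuted at the exchangeable-unit level appropriate to the term:
samples freely for covariates, samples within regions for site-level terms,
whole sites within continents for the region term, and whole regions for
the continent term.  The full F-ratio (numerator and denominator mean
squares) is recomputed from each permuted matrix, and
`p = (1 + #{F* ≥ F}) / (B + 1)` with `B = 999` by default.  The covariate ×
site interaction uses globally centered covariate scores.  A priori trend
tests in latitude use `orthogonal_polynomials()` (classical orthonormal
contrasts up to cubic).

## Highly variable genes

The gene-level procedure asks which genes differ most often between pairs
of sites.  After a stricter filter (more than 100 reads in at least 10% of
samples), every unordered pair of *replicated* sites (at least 2 samples;
a dispersion cannot be estimated within a singleton site) is tested with a
negative-binomial Wald test, per gene:

* median-of-ratios size factors `s_j` (geometric-mean reference, rescaled
  to geometric mean 1; per-sample positive-gene fallback when no gene is
  positive everywhere);
* NB model `mu_gj = s_j q_g 2^(beta_g x_j)` with variance `mu + alpha mu²`;
* per-gene dispersion by method of moments on normalized counts pooled
  across the two sites, shrunk with weight 0.5 toward a fitted
  mean–dispersion trend `a0 + a1/mu`, floored at `1e-8`;
* `beta_g` (a log2 fold change) and its standard error by iteratively
  reweighted least squares, vectorized across genes; two-sided p-values
  from the normal reference, Benjamini–Hochberg adjusted within the pair.

This is deliberately a simplified DESeq2-style test: the downstream
statistic is a *count* of significant pairs per gene, which depends on the
ranking of genes far more than on exact per-test calibration.  The
trade-off is measurable: under a null with identical NB law at both sites,
the raw-p rejection rate at 0.05 is near 0.06 at 3–4 samples per site
(small-sample Wald inflation plus dispersion-estimation noise; even
oracle-dispersion Wald tests sit near 0.054 there), approaching the nominal
level as replication grows.  The BH-adjusted counting threshold the
selection actually uses is far less affected; the package asserts the
adjusted-scale calibration (fraction of significant gene–pair tests at
BH < 0.01 stays at or below 0.02 under the null) and the planted-gene
recovery properties instead of claiming exact raw-p calibration.

Counting uses BH-adjusted p < 0.01 by default (adjusted p-values are what
the multiple-testing correction leaves fit for thresholding); raw-p
counting is available behind `use_adjusted = FALSE`.  The top 5% of genes
by pair count are selected, with size `ceiling(0.05·G)` and deterministic
tie-breaks (larger total normalized abundance, then lexicographic id).
Selected genes are z-scaled across samples and clustered with Ward.D2 on
Euclidean distances; the tree is cut at 2 and each primary group cut at 2
again, labeling groups A1/A2/B1/B2.  The A/B labeling is cosmetic (larger
group is A, or the group carrying a supplied reference gene set).
Enrichment of annotation sets within each ward group uses the upper-tail
hypergeometric probability `P(X ≥ k)` with `N` the selected-gene universe,
`n` the group size, `K` the set size within the universe and `k` the
in-group set members, BH-adjusted across sets within a group.

## Sample clustering and environmental characterization

Samples are clustered on Johnson-normalized abundances of the selected
genes (and separately on taxa).  `johnson_transform()` fits the Johnson
S_U/S_B/S_L families by the percentile method over a small grid of
selection constants, adds a profile-likelihood-style S_L fit (threshold
chosen to maximize Shapiro–Wilk W) and the affine standardization as
candidates, and keeps the candidate maximizing W; with fewer than 20
observations a rank-based inverse-normal fallback is used.  Because the
affine candidate is always available and W is location-scale invariant, the
transform never worsens normality.

`kmeans_elbow()` standardizes features by the pooled within-cluster SD from
a pilot k-means at the midpoint k (a two-pass approximation of the JMP
"within cluster standard deviations" option, whose internals are not
published), then for each candidate k keeps the best of 50 k-means++
initializations by total within-cluster SS.  The chosen k maximizes the
second difference of the within-SS curve; when that curvature is less than
0.4 of the curve's total drop (single-cluster data measure at most ~0.3 on
this scale, clearly clustered data ~0.9) a no-pronounced-elbow warning is
emitted.  Clusters with four or fewer samples are flagged and excluded from
downstream comparisons.

Environmental characterization runs a one-way ANOVA of each biophysical
variable across retained clusters: Shapiro–Wilk on residuals, Johnson
normalization and refit when normality is rejected at 0.05, and
Tukey–Kramer HSD (valid under unequal group sizes) at family level 0.05
when the ANOVA is significant.  The same machinery powers the
Holocene-vs-Pleistocene age-class contrasts.

Agreement between the gene-based and taxa-based clusterings uses Cohen's
kappa.  Cluster labels are arbitrary, so the contingency table is first
aligned by the one-to-one label matching that maximizes the diagonal
(exhaustive for up to 7 clusters, greedy beyond), and
`kappa = (p_o − p_e)/(1 − p_e)` is computed on the aligned table with a
permutation p-value from label reshuffles.  The alignment step makes small
positive kappa values expected even for independent clusterings; the
permutation reference accounts for this.

## Taxonomy: diversity, the pH curve, and constrained ordination

Shannon diversity `H = −sum p_i ln p_i` (nats) is computed per sample at
the class level.  The diversity–pH relationship is fit as the centered
quadratic `H = b0 + b1·pH + b2·(pH − m)²` with `m` the mean pH of the
fitted samples — exactly the parameterization used by JMP-style reports, in
which `b2 < 0` indicates a unimodal curve.  Known outlier locations can be
excluded and the model refit.

Per-taxon regressions are simple OLS of relative abundance on each
environmental variable with BH adjustment across the full taxon × variable
family; untransformed relative abundances are the default, with a logit option
available for proportions near the boundary.

For constrained ordination the taxa table is Hellinger-transformed (square
roots of row-relative abundances, placing samples on the unit sphere so
linear methods behave), candidate predictors are pruned by iteratively
dropping the highest variance inflation factor until all VIFs are at most
10, and forward selection runs through vegan's `ordiR2step`: a candidate
enters when it maximizes adjusted R², passes a permutation entry test at
0.05, and keeps the running adjusted R² at or below the global
all-candidates adjusted R² (`R2scope`).  That global ceiling is vegan's
default and is kept as ours; note that when the extra candidates are pure
noise the ceiling sits at or below a single true predictor's own adjusted
R² about half the time and blocks entry — a property of the double-stopping
rule itself, which is why the selection-order validation in the test suite
disables the ceiling while the null entry-rate validation keeps it.
Selected predictors receive marginal `anova.cca` permutation tests with
FDR adjustment.

## The synthetic-data generator

`simulate_dataset()` emulates the data structure the analyses assume, and
its truth record (planted gene identities, site effects, pre-missingness
pH, site-level cluster labels) is written alongside the data but never read
by any analysis stage — an integration test re-runs the analysis from the
written tables with the truth file deleted and checks identical output.

* **Metadata**: site-level latents are multivariate normal under a
  block-correlation structure in which age, depth and pH are positively
  associated (mirroring the age-class confounding of field data: older
  permafrost is deeper and more alkaline), the C/N/organic-C block is
  tightly correlated, and latitude and elevation are mildly negatively
  related.  All samples of a site share the site latent plus small
  within-site noise (SD 0.2 on the latent scale).  Latents map to field
  units (ages log-normal in kyr, pH clamped to 3.5–9.5, positive
  percentages log-normal); `age_class` derives from age at the 11.7 kyr
  Holocene/Pleistocene boundary.  Missingness is applied completely at
  random — the mechanism the EM model assumes, which makes recovery
  testable.
* **Gene counts**: NB with variance `mu + alpha mu²` (matching the test's
  parameterization), per-gene dispersions gamma-distributed with mean 0.1,
  log-normal library sizes (median 2×10⁵), and log-normal baseline
  relative abundances.  Planted variable genes carry site-level log2
  effects: most follow a standardized random site pattern scaled by
  `effect_size` (default 2), and an archaea-like block (a third of the
  planted set) is strongly elevated only in high-pH, deep sites, giving
  sample clustering a recoverable structure and the enrichment stage a
  planted annotation signal.  Effects live at site level because the
  highly-variable-gene procedure contrasts sites.
* **Taxa**: per-sample Dirichlet compositions whose concentration is a
  quadratic in pH peaking at 7 (`max(0.5, 30 − 8(pH − 7)²)`), so expected
  Shannon diversity is unimodal with its maximum near neutral pH.

Defaults (3 × 2 × 2 sites, 4 samples/site, 300 genes with 15 planted, 25
classes, 10% missingness) were chosen once to resemble the shape of real
panarctic compilations at desk scale.  What passing tests on this generator shows is that the
pipeline recovers structure it is designed to detect under its own
assumptions; real metagenomes add compositional artifacts, annotation
error, uneven replication, spatial autocorrelation and non-Gaussian
environmental tails that the generator deliberately does not model.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-SD variables are an error
before EM; all-zero samples are errors in Bray–Curtis and Hellinger;
constant genes get an SD floor of `1e-12` before z-scaling; perfectly
separated ANOVA groups report `R² = 1` with an infinite F guard; zero
permutation-denominator mean squares report infinite pseudo-F at the
minimal attainable p.  Ties in the top-5% selection break deterministically.
All stochastic stages take explicit integer seeds and restore the caller's
RNG state, so pipeline outputs are byte-identical across reruns of the same
configuration.

The validation suite runs its simulations at deliberately modest sizes
chosen as the package's own desk-scale conditions: 100-replicate null
calibrations, 20-seed recovery averages, 99–199 permutations where the
permutation count is not itself the quantity under test, and a study-scale
integration run of 140 samples across 20 sites.  The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch at the
same sizes.
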