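---
title: "Mapping genetic brain-behavior covariance with twinmap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genetic brain-behavior covariance with twinmap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmap)
```

## The scientific problem

Psychiatric phenotypes such as depressive symptom frequency are heritable,
and so is cortical thickness — but heritability varies *within* anatomical
regions, so region-of-interest averages blur the genetic architecture.
twinmap estimates, at every vertex of a cortical surface mesh, how much of
the covariance between local cortical thickness and a behavioral phenotype
is attributable to shared additive-genetic influences versus shared
environmental influences, and turns the resulting statistical maps into
discrete, spatially contiguous regions suitable for downstream annotation
(conjunction across traits, split-half replication, expression clustering).

The design that makes this possible is the classical twin design:
monozygotic (MZ) co-twins share all their segregating genes, so their latent
additive-genetic scores correlate 1.0; dizygotic (DZ) co-twins share on
average half, so theirs correlate 0.5. Shared (common) environment C
correlates 1.0 within a pair regardless of zygosity, and non-shared
environment E is uncorrelated. The difference between MZ and DZ cross-twin
covariances therefore identifies the genetic part of any (co)variance.

## The bivariate Cholesky twin model

For two phenotypes per person (a vertex's thickness and a behavioral score),
each variance component's covariance matrix is parameterized as a lower
triangular path matrix times its transpose — the biometric Cholesky
decomposition — which keeps every component covariance positive
semidefinite by construction:

$$\Sigma_A = A A^\top,\quad \Sigma_C = C C^\top,\quad \Sigma_E = E E^\top,
\qquad A = \begin{pmatrix} a_{11} & 0 \\ a_{21} & a_{22} \end{pmatrix}.$$

The expected covariance of the stacked pair vector (twin 1's two variables,
then twin 2's) is

$$\Sigma_{pair} = \begin{pmatrix} W & X_f \\ X_f & W \end{pmatrix},\qquad
W = \Sigma_A + \Sigma_C + \Sigma_E,\qquad X_f = f\,\Sigma_A + \Sigma_C,$$

with the genetic cross-twin factor $f = 1$ (MZ) or $0.5$ (DZ). Derived
quantities:

- **genetic correlation** $r_G = a_{11}a_{21} / \sqrt{a_{11}^2
  (a_{21}^2 + a_{22}^2)}$, the correlation of the two traits' latent genetic
  components (the analogous formula on the E paths gives $r_E$);
- **bivariate heritability**, the product of the standardized paths
  $a_{11} \times a_{21}$: the portion of the phenotypic correlation carried
  by genes. It is signed, and together with the C and E analogues sums to
  the implied phenotypic correlation — this identity is enforced in the
  test suite at $10^{-6}$.

### Estimation

Models are fitted by full-information maximum likelihood (FIML): each
pair contributes the multivariate-normal log-density of its *observed*
sub-vector, so singletons (families where only one twin was assessed)
still inform means and variances, matching a missing-completely-at-random
deletion mechanism. Internally, pairs are grouped by zygosity and
missingness pattern and the likelihood is evaluated from per-group
sufficient statistics in compiled code, which is what makes $10^3$–$10^5$
per-vertex fits practical.

Numerical choices:

- Paths are unconstrained on the real line; after fitting, the sign of each
  component's diagonal is normalized nonnegative (a column sign flip leaves
  $AA^\top$ invariant). No boundary constraints are imposed on cross paths,
  which are interior parameters.
- Multi-start BFGS (default 5 starts; 2 for vertex loops, which are warm
  started) with a data-driven first start: the pooled within-twin
  covariance split across the model's components. Jittered restarts guard
  against local optima. Convergence tolerance is $10^{-12}$ relative on the
  log-likelihood; if every start fails the fit is flagged, never silently
  zeroed.
- A non-positive-definite implied covariance evaluates to $-\infty$
  (a rejected point), not an error.
- Degenerate inputs: a zero-variance vertex is marked invalid; a vertex
  *identical* to the behavioral trait makes the pair covariance singular and
  the boundary likelihood unbounded, so self-association should be probed
  with a near-duplicate (see the test suite).

### Nested tests, degrees of freedom, and fit indices

Significance of the genetic (or environmental) cross path uses the
chi-square difference test: $\chi^2 = 2(\ell_{full} - \ell_{reduced})$ on 1
df, with no boundary-mixture correction since a covariance cross path is an
interior parameter. (Variance-component comparisons with the same machinery
are conservative; we accept that.) The type-I error of this test is checked
by simulation against its nominal 5% level.

Means are equated across twin order and zygosity — one mean per variable —
so a bivariate AE model spends 6 paths + 2 means against the two-group
saturated model's $2\times(4 + 10) = 28$ statistics, giving 20 df. RMSEA
uses $n$ = number of families, the independent sampling units; published
twin analyses differ in this convention (some use individuals or apply
multigroup corrections), so RMSEA/TLI/CFI values from other software may
differ even at identical likelihoods. The baseline for TLI/CFI is the
independence model (diagonal E only, means and variances equated).

## Behavioral phenotype preparation

Likert scales are scored as the mean of answered items times the number of
items, provided at least 80% of items were answered (otherwise missing);
reverse-coded items are mapped $max + min - x$ first. Right-skewed symptom
scores are square-root transformed. Every analysis variable — each vertex
and each behavioral score — is residualized (OLS, intercept included) on
nuisance covariates, conventionally sex and mean cortical thickness, before
modeling; residualization is idempotent and exactly orthogonal to the
covariates. Behavioral scores are residualized once, on the pooled sample,
both for the behavioral-only model and for vertex mapping.

## Surface mapping and cluster-extent correction

`fit_vertexwise()` fits the bivariate model at every vertex with the vertex
as variable 1. Because cortical thickness often carries shared-environment
variance that psychometric scales do not, the default per-vertex
specification frees a C loading on the vertex only, fixing the C cross path
and the trait's C loading at zero.

Cluster extraction thresholds the per-vertex LR p-values at
$\alpha = 0.05$, splits the surviving vertices by the sign of the bivariate
heritability *before* connectivity (so each cluster is monotone in
direction), takes connected components under mesh edge adjacency, and
discards components smaller than a 20 mm spatial extent — twice a typical
10 mm surface smoothing kernel, which is the spatial scale below which
smoothed maps cannot carry independent signal. The 20 mm figure is a
length, so the default extent measure is the geodesic *diameter*: the
maximum pairwise shortest-path distance along mesh edges with Euclidean
edge weights. Exact polyhedral geodesics are not computed; at a 20 mm scale
on meshes with a few mm edge length, edge-graph distances overestimate true
geodesics by only a few percent and are orders of magnitude faster. A
surface-area mode (mm²) is available where an area criterion is preferred.
No further multiplicity correction is applied beyond the extent filter; the
split-half machinery below is the guard against overinterpretation.

Conjunction of two traits' maps intersects the vertex sets covered by each
trait's surviving clusters and re-partitions the intersection into
connected components; sign-discordant overlap is reported separately and
flagged rather than merged. Cluster centers of gravity are unweighted means
of member vertex coordinates in mm. Per-cluster genetic/environmental sign
concordance is reported because same-direction genetic and environmental
association is consistent with (not sufficient for) a causal account.

## Split-half replication

Families are partitioned at random with pairs kept intact. The default
mode draws exactly balanced halves (sizes differ by at most one); a
Bernoulli mode assigns each family independently, reproducing the slightly
unequal draws that occur in practice. Each half is analyzed with vertex
$\alpha = 0.05$ and the same 20 mm extent correction, and a full-sample
cluster is declared replicated only if it shares at least one vertex with a
same-sign surviving cluster in *both* halves — the full sample, being more
conservative, anchors the criterion. We require overlap and sign agreement
but no minimum overlap proportion, and we interpret the per-half
"minimum alpha" as the vertex-level threshold within each half rather than
a conjoint minimum statistic.

## Expression clustering and the elbow rule

`kmeans_elbow()` z-scores each gene's profile across regions (expression
images are typically renormalized before comparison, and profile *shape*
is what distinguishes over-, mixed-, and under-expression), then runs
k-means with restarts over a candidate range (default 1–8). The cluster
count is chosen at the elbow of the WSS curve, operationalized as the
maximum second difference of **log** WSS: on the log scale the criterion is
invariant to overall variance, and the curve's flattening after the true
cluster count is sharp even when two planted profiles lie close together —
a case where the raw second difference can tie the true count against one
fewer. When no candidate's log-curvature exceeds 0.1, the matrix is
declared structureless and $k = 1$ is returned (this also covers the
degenerate all-rows-identical matrix). Gene filtering removes an exclusion
list (e.g. the major histocompatibility complex, where long-range linkage
disequilibrium can fabricate associations) and genes without available
expression data, reporting the retained count.

## What the synthetic generator does and does not emulate

`simulate_twin_cohort()` mirrors the fitted model exactly: latent A drawn
with MZ/DZ cross-twin correlation 1.0/0.5, C shared, E independent,
phenotypes assembled through the Cholesky paths; co-twin deletion is
completely at random so FIML recovery tests are unconfounded by the
missingness mechanism. Planted brain-behavior covariance works through
cluster-level genetic factors: member vertices trade part of their genetic
path for a loading on the factor (total variance preserved), and the
behavioral trait loads on the same factor, so inside a planted cluster the
per-vertex bivariate model sees a genuine genetic cross path and outside it
sees none.

Defaults represent a moderately heritable cortical phenotype — per-vertex
variance shares A/C/E = 0.5/0.2/0.3 — and a behavioral trait with
heritability 0.40 and no shared environment. The behavioral *pair* of
traits used in two-trait simulations is generated from
`bivariate_ae_model()` with heritabilities 0.40 and 0.48 and correlations
$r_G = 0.40$, $r_E = 0.04$, values in the range reported for depressive
symptoms and callous-unemotional traits in young adults; note the estimated
$r_G$ and $r_E$ depend only on the generating correlations, not on the
heritability choice. The generator does **not** produce realistic cortical
folding, spatially autocorrelated noise fields, or smoothing-induced
dependence between neighboring vertices: passing tests demonstrate that the
estimator and the cluster machinery behave correctly under the model's own
assumptions, not that real cortical maps will show equally crisp cluster
boundaries.

## Problem sizes used in the shipped checks

The package's property checks run at sizes chosen to make Monte-Carlo noise
negligible relative to the tolerance being asserted: parameter recovery and
correlation recovery at 5,000 MZ + 5,000 DZ pairs; LR-test calibration over
1,000 null cohorts of 200 pairs; planted-cluster recovery on a 2,562-vertex
icosphere with 2,000 pairs; null-map calibration on a 642-vertex icosphere
with 500 pairs.

## Known limitations

- No dominance (ADE), sex-limitation/moderation, or ordinal liability
  models.
- Ordinary chi-square reference distributions for variance-component tests
  (conservative at boundary nulls).
- Geodesics are edge-graph approximations.
- Printed RMSEA/TLI/CFI conventions vary across software; only the
  likelihoods and degrees of freedom are convention-free.
- GIFTI support covers ASCII encoding only; MGH reading covers the common
  scalar-overlay layout.

## A minimal end-to-end example

```{r example, eval = FALSE}
mesh <- make_mesh("sphere", 642, scale_mm = 50)
patch <- geodesic_patch(mesh, 1, 20)
truth <- list(clusters = list(list(vertices = patch, loading = 0.55)),
              traits = list(list(name = "beh", a = sqrt(0.4),
                                 e = sqrt(0.6), cross = 0.5)))
s <- simulate_twin_cohort(mesh, truth, n_mz = 500, n_dz = 500, seed = 1)
map <- fit_vertexwise(s$thickness, s$behavior[, 1], s$pairing, seed = 1)
tab <- extract_clusters(map, mesh, alpha = 0.05, extent_mm = 20,
                        trait = "beh")
tab
```
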