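---
title: "Vertex-wise functional criticality: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-wise functional criticality: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vifc)
```

## The statistic and its dynamical rationale

Complex dynamical systems often announce an impending state transition
before it happens. Near a critical point, theory for dynamical network
biomarkers (DNBs) predicts that a *dominant group* of variables emerges
which simultaneously shows

1. sharply **rising correlation among its members**,
2. **falling correlation** between its members and the rest of the system,
3. sharply **rising variance** of its members.

`vifc` applies this idea vertex-wise to cortical surface fMRI. For a vertex
$i$ with BOLD series $x_i(t_1),\dots,x_i(t_N)$, let $I$ be its second-order
neighborhood cluster on the triangulated surface (all vertices within edge
graph distance 2, self excluded). The index of functional criticality is

$$
\mathrm{vIFC}(i) \;=\;
\frac{\mathrm{STD}(i)\,\cdot\,\langle \mathrm{PCC}_{ij}\rangle_{j \in I}}
     {\langle \mathrm{PCC}_{ik}\rangle_{k \notin I}},
$$

where $\mathrm{STD}(i)$ is the standard deviation of the series and
$\mathrm{PCC}$ is the Pearson correlation across time. Each of the three DNB
signatures pushes the ratio in the same direction, so a vertex inside a
group approaching criticality acquires a large index, while a typical vertex
does not. The three component maps (`std`, `corr_in`, `corr_out`) are always
returned alongside the ratio, since each carries interpretable signal of its
own.

### Assumptions

* The BOLD series are stationary over the scan and already preprocessed
  (nuisance-regressed, band-passed, surface-projected); the package starts
  from a dense vertices-by-timepoints matrix.
* "Local group" is taken literally as spatial neighborhood on the mesh: the
  local-information-transfer view that neighboring vertices tend to join the
  same dominant group. This follows the regional-homogeneity lineage of
  surface statistics, which motivates graph distance on the triangulation
  rather than a Euclidean radius.
* Correlations are pairwise Pearson coefficients, unshrunk.

## Estimation choices

**STD normalization.** `STD(i)` is the sample standard deviation
(denominator $N-1$). An unnormalized sum of squares would make the index
grow with scan length, which a per-subject "standard deviation" map is
clearly not meant to do.

**Signed vs absolute averaging.** The ratio as written averages raw signed
correlations; the DNB conditions are phrased in absolute value. Both are
implemented (`mode = "signed"` is the default, matching the formula and
enabling an exact $O(VN)$ denominator via
$\sum_k \mathrm{corr}(i,k) = z_i^\top \sum_k z_k /(N-1)$ on standardized
rows; `mode = "absolute"` uses a blocked $O(V^2N)$ sweep with bounded
memory). The two modes are not interchangeable in every regime: when the
outside field is genuinely uncorrelated with a vertex, the signed outside
mean is an average of $\sim V$ near-zero terms whose *sign* is essentially
random, so the signed ratio is sign-unstable even though its magnitude is
informative. Real cortical data carry broad shared fluctuations that keep
the signed denominator away from zero; our independent-background simulator
does not. Detection-performance validation therefore uses `absolute` mode,
which is the faithful reading of the DNB conditions; exactness of both code
paths is established separately against a naive double-loop reference.

**Degenerate inputs.** Constant series are flagged invalid and excluded from
every correlation average. Vertices with $|\mathrm{Corr_{out}}|$ at or below
the guard `epsilon` (default $10^{-6}$) get an *undefined* (NA) index rather
than a huge unstable ratio; undefined vertices are excluded from smoothing
sums, group models and cluster statistics rather than being zero-filled.
Whether the vertex itself joins $I$ is switchable (`include_self`, default
off): including it adds $\mathrm{corr}(i,i)=1$ to the numerator average and
biases it upward, but the flag allows sensitivity analyses.

**Medial wall.** Masked-out vertices carry no signal after surface
projection, so they are removed from the graph before neighborhoods are
built: they neither join $I$ nor the outside set, and they do not relay
adjacency. When both hemispheres are supplied
(`merge_hemispheres()`), the outside set spans the whole cortex; with a
single mesh it is restricted to that hemisphere. Both conventions are
available because published whole-cortex maps do not pin down the choice.

## Surface smoothing

Individual maps are smoothed along the surface with iterated
nearest-neighbor averaging,
$x_i \leftarrow (x_i + \sum_{j \in N_1(i)} x_j)/(1 + \deg i)$, the classic
mesh-based approximation to a geodesic Gaussian. The iteration count for a
requested FWHM (default 10 mm, the conventional kernel at ~4 mm vertex
spacing) is not taken from a fixed diffusion constant — that mapping is
mesh-dependent — but *calibrated on the mesh at hand*: a probe delta is
smoothed until its empirical full width at half maximum, measured along
edge-weighted graph distances, reaches the target. On a 4 mm mesh the
response widens by several millimetres per pass, so the achieved FWHM can
overshoot the target by a couple of millimetres; the calibration picks the
smallest count that reaches it. Missing vertices are excluded from both
numerator and denominator (renormalized averaging), which preserves
constants exactly and never bleeds artificial lows out of masked regions.
Each final map — the index and its three components — is smoothed
independently; the smoothed index is *not* recomputed from smoothed
components.

## Group inference

**Vertex-wise GLM.** Group comparisons use per-group intercepts and
per-group slopes for each covariate (age, sex, years of education) — the
"different offset, different slope" coding of surface group analyses. The
tested contrast is the difference of group intercepts with covariates
mean-centered across the two contrasted groups, i.e. the adjusted group
difference at the mean covariate profile; inference is an ordinary
two-sided t-test. Rank-deficient designs (a single-sex group, a constant
covariate) are refused with the offending columns named.

**FDR.** Vertex-wise p-values are corrected by Benjamini–Hochberg step-up.
The conventional level for signed maps, $\alpha = 0.05/2$, is interpreted as
a two-direction Bonferroni on top of BH and is simply passed as
`alpha = 0.025`. (Some toolchains apply BH per hemisphere; we apply it over
whatever vertex set is supplied, which is the more conservative joint
correction when hemispheres are merged.)

**Clusters and behavior.** Significant vertices are split into connected
components per contrast direction; each cluster reports its signed peak
$-\log_{10} p$, peak vertex, surface area (sum of one-third-incident
triangle areas, so areas partition the surface exactly) and vertex count,
sorted by peak magnitude with index-based tie-breaking for determinism.
Cluster-mean values are then related to behavioral scores (MMSE, AVLT,
MoCA) by partial correlation — residualize both on the covariates, correlate
residuals, $t$-based p with $n - q - 2$ degrees of freedom — Bonferroni
corrected across the clusters tested.

**Demographics tables.** When only per-group $(n, \text{mean}, \text{SD})$
summaries are available, `anova_from_summaries()` reconstructs the omnibus
one-way F exactly (between-SS from weighted means, within-SS
$\sum (n_g-1)\mathrm{SD}_g^2$); it is algebraically identical to raw-data
ANOVA on any moment-matched sample. It also offers the Welch
heteroscedastic form mirroring `stats::oneway.test(var.equal = FALSE)`:
published tables that pair ANOVAs with Dunnett's T3 post hoc switch to the
unequal-variance statistic for rows whose group SDs differ strongly
(cognitive scores with a several-fold SD range), and only the Welch form
reproduces such rows. Sex-by-group counts use the plain Pearson chi-square
without continuity correction.

## The synthetic stack

There is no public generative model for criticality in surface fMRI, so the
package defines the *simplest* latent system exhibiting all three DNB
signatures, documented as a stand-in rather than a claim about brain data:

* mesh: recursive icosphere subdivision; order 5 has 10,242 vertices,
  matching the standard fsaverage5 hemisphere, with default radius 100 mm
  for near-cortical (~3–4 mm) edge spacing;
* a shared latent AR(1) $u(t) = \rho\,u(t-1) + \varepsilon$ drives a
  connected patch (seed vertex plus graph-distance ball, default radius 2)
  with loading $\lambda$; every vertex adds independent background AR(1)
  noise with coefficient $\varphi$.

As $\rho \to 1$ the latent variance $\sigma^2/(1-\rho^2)$ diverges, so
within-patch correlation $\to \lambda^2\mathrm{Var}(u) /
(\lambda^2\mathrm{Var}(u) + \mathrm{Var}(b))$ rises toward 1, patch SD
rises, and patch–outside correlation stays near zero — conditions 1–3. The
default length of 235 timepoints mirrors a 478 s scan at TR = 2 s with four
equilibration volumes dropped; defaults $\rho = 0.95$, $\lambda = 1$,
$\varphi = 0.3$, $\sigma = 1$ put the patch deep in the critical regime
while keeping background series realistically autocorrelated.

What the simulator does **not** emulate: hemodynamic convolution,
physiological and motion artifacts, spatially correlated background noise,
distance-dependent connectivity, global signal, inter-subject anatomical
variability. Passing validation therefore demonstrates correctness of the
estimator and pipeline under the model's assumptions — not performance on
real cohort data.

The cohort simulator (`simulate_cohort()`) builds per-subject *maps* (not
series) as base + planted cluster effects + covariate slopes + iid noise,
with covariates echoing elderly-cohort ranges (age $\sim N(67, 8^2)$ years,
education $\sim N(11, 4.5^2)$ years, sex Bernoulli(0.4)), for testing the
GLM–FDR–cluster chain with known ground truth.

## Validation performed by the test-suite and acceptance script

All sizes below were chosen to give sharp checks at interactive runtimes.

* **Exactness**: both correlation paths, with and without masks and
  `include_self`, agree with a naive double-loop `cor()` reference to
  $10^{-10}$ on meshes up to 42 vertices; neighborhoods agree with an
  all-pairs shortest-path oracle on meshes up to 162 vertices.
* **Detection**: on an order-3 icosphere (642 vertices), $\rho = 0.95$,
  $N = 235$, the absolute-mode index separates patch from background with
  AUC averaged over 10 seeds of effectively 1.0 (the acceptance criterion is
  $\ge 0.9$), and the three DNB conditions hold in 10/10 seeds.
* **Calibration**: under a null cohort (500 replicates × 100 vertices) the
  vertex-wise GLM's type-I rate at $\alpha = 0.05$ stays inside the binomial
  95% interval; a 2-noise-SD planted effect (patch of 7 vertices,
  30 subjects/group) is recovered through FDR + clustering in 20/20 seeds.
* **Invariants**: scale equivariance of the index, BH monotonicity in
  $\alpha$, the smoothing maximum principle and exact constant preservation,
  Euler characteristic 2 at every icosphere order up to 5, and bit-identical
  reruns under fixed seeds.

## Known limitations

* Signed-mode indices are numerically fragile wherever the outside mean
  correlation is near zero; the `epsilon` guard reports such vertices as
  undefined instead of propagating unstable ratios, and `absolute` mode
  avoids the issue at quadratic cost.
* The smoothing calibration resolves FWHM only to roughly one averaging
  pass; sub-millimetre FWHM control on coarse meshes is not possible with
  this kernel family.
* Graph distance stands in for geodesic distance in both neighborhoods and
  FWHM measurement; on strongly anisotropic meshes the two diverge.
* Cluster inference is vertex-level FDR with descriptive cluster tables —
  no cluster-extent permutation inference.
* The GLM is per-vertex OLS: no spatial regularization, no mixed effects,
  no longitudinal structure.
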