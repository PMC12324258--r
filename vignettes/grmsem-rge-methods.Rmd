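---
title: "Modelling genomic and residual covariance with gene-environment correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genomic and residual covariance with gene-environment correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(latentgrm)
```

## The model

For k covariate-residualised, rank-normalised traits measured on n
unrelated individuals, `latentgrm` models the nk × nk covariance of
`vec(Y)` as a sum of Kronecker components keyed to two kernels: the
genetic relationship matrix `G` (genome-wide SNP relatedness, unit
diagonal after standardisation) and the identity (individual-specific
residuals):

$$\Sigma_V = (\Lambda_A \Phi_A \Lambda_A^\top) \otimes G +
             (\Lambda_E \Phi_E \Lambda_E^\top) \otimes I_n .$$

Latent factor variances are fixed to one, so all scale lives in the
loadings. The model family is encoded in the free-loading masks
(`make_structure()`): saturated Cholesky (lower-triangular k × k on both
sides; the descriptive baseline), Independent Pathway (nA and nE sparse
common factors plus diagonal trait-specific AS/ES factors), the IPC and
CIP hybrids, and bifactor variants used to test factorial independence.

### The gene-environment correlation extension

Freeing correlations between common genomic and residual factors
(`rge = TRUE`) adds the block `Phicov` between the two factor sets.
Specific factors never correlate across sides. A subtlety arises in the
implied covariance: the genomic factor scores live on the kernel `G`, the
residual ones on `I`, so their cross-covariance needs its own kernel. We
use the generative convention: a genomic factor score vector is
`G^{1/2} u` with `u` standard normal, residual scores are `v`, and
`cor(u, v)` holds the rGE parameters. The cross term is then

$$C_X \otimes G^{1/2}, \qquad
  C_X = \Lambda_A \Phi_{cov}^\top \Lambda_E^\top +
        \Lambda_E \Phi_{cov} \Lambda_A^\top,$$

which is symmetric and positive semi-definite for every admissible
correlation matrix. An alternative convention places one half of the
cross term under `⊗ G` and the other under `⊗ I`; for any GRM with
nonzero off-diagonal entries that matrix is asymmetric (the asymmetric
part is `M ⊗ (G − I)`), i.e. not a covariance, so it cannot define a
likelihood. It is retained in `implied_sigma(cross_kernel = "literal")`
for inspection — it errors on the asymmetry rather than symmetrising
silently — while every per-individual (diagonal-block) quantity,
in particular the variance arithmetic `V_j = a_j + e_j + 2c_j`, is
identical between the two conventions because `G` has unit diagonal.

Because `G ≈ I + E` with small off-diagonal `E`, the three kernels `G`,
`G^{1/2} ≈ I + E/2` and `I` are nearly collinear: rGE is identified
through the *structural restrictions* of the factor model (the cross
term must look like rank-one products of the A and E loading vectors),
not through raw kernel contrast. Identification is therefore weak when a
domain's genetic and residual loading vectors are nearly proportional,
and strongest in multi-domain models where they differ in shape — the
regime the data-driven pipeline targets. Users should expect wide rGE
sampling distributions at desk-scale n and rely on the
independence-vs-rGE comparison (`rge_evidence()`), which combines the
fit improvement (AIC, LRT) with Wald intervals for the rGE estimates.

## Likelihood evaluation

* **Rotated fast path** (complete data): with `G = U D U'` and
  `Ỹ = U'Y`, rows of `Ỹ` are independent with covariance
  `C_G d_i + C_X √d_i + C_I`, reducing one evaluation to n Cholesky
  factorisations of k × k matrices (compiled kernel in `src/`,
  O(n·k³)). GRMs built from in-sample allele frequencies are singular
  by construction (column centring), so the numerically-zero eigenvalue
  tail is clamped at zero.
* **Direct path** (any missingness): full-information subsetting of the
  dense nk × nk covariance — the likelihood of the observed subvector.
  Cost O((Σ observed)³); practical to roughly n·k ≈ 3000 observations.
  The default `path = "auto"` switches on any missing entry.
* The two paths agree to 1e-8 on complete data, which is a standing test
  (with and without rGE).

## Estimation

`grmsem_fit()` maximises the likelihood with a box-constrained
quasi-Newton optimiser (L-BFGS-B) and central-difference gradients.
Parameter scales: loadings are unconstrained (traits are standardised;
bounds ±25 are inert in practice); correlation-type parameters (factor
correlations, rGE) are optimised on an atanh scale capped at |tanh(4)| ≈
0.999 so the observed information remains usable when an estimate
approaches ±1; such boundary-adjacent parameters are flagged in the fit's
diagnostics rather than "corrected". Identification of signs is by
convention: Cholesky diagonals and specific loadings non-negative, each
common factor's largest loading positive (rGE rows/columns flip
accordingly); the likelihood is invariant, and the canonical
representative is unique.

Multi-start: the first start is data-informed (an even A/E split of the
regularised sample covariance, or a previous fit, e.g. the rGE model is
started from the independence IP fit, mirroring the stepwise design);
further restarts perturb it multiplicatively with N(1, 0.1²) noise, all
seeded. Convergence is declared when the optimiser reports success and
the projected gradient max-norm falls below `tol` (default 1e-3 — chosen
above the ~1e-6 noise floor of central differences at |LL| ≈ 1e4, so the
flag reflects the fit, not finite-difference noise; the default
`optim_factr = 1e2` resolves log-likelihoods to ~1e-7 relative).
Standard errors come from the numerical observed information at the
optimum; a near-singular information matrix (a flat direction, e.g. `G = I`
making A vs E non-identifiable, or a specific loading estimated at zero)
flags the fit and switches to a pseudo-inverse. Parameter points whose
implied covariance is not positive definite receive a large finite
penalty (the optimiser cannot digest infinities) and are thereby
rejected.

Missing data are never imputed: the phenotype transformation
(`double_residual_rank_transform()`: covariate OLS residuals →
inverse-normal ranks with the Blom offset 3/8, average ranks for ties →
re-residualisation to stop covariate effects re-entering) propagates the
missingness mask to the likelihood. Ties in heavily discrete
questionnaire scores yield tied normal scores; residuals from a
numerically perfect covariate fit are treated as all-tied.

## Model building

`run_grmsem_pipeline()` automates the stepwise design: fit the Cholesky
baseline; predict the genomic factor count from the Cholesky-derived
genetic correlation matrix (Kaiser criterion as primary; the Cattell
scree automated as the maximum-acceleration elbow — when the two
disagree, both candidate counts are fitted and adjudicated by AIC);
derive the loading pattern by ML EFA with promax rotation and salience
threshold 0.3; fit the IPC hybrid; repeat on its residual correlation
(factor count) and covariance (pattern) matrices to build the IP model;
run bifactor independence checks (reported, but not candidates for final
selection); extend the IP model with rGE parameters between structurally
matched factor pairs (matched by trait-set overlap; a full cross block is
available via `rge_pairs = "all"`), started from the IP estimates;
constrain specific loadings with |λ| < 0.05 to zero and refit. The final
model is the best by AIC among candidates with SRMR ≤ 0.08. Every
automatic choice is recorded in a replayable decision log. A fit whose
information matrix is merely near-singular does not halt the pipeline —
that is the situation the constraint step exists to resolve — whereas an
optimiser failure does.

Fit statistics follow the reporting conventions of this literature:
`AIC = −2LL + 2N_p`; `BIC = −2LL + N_p ln(N_ind)` with N the number of
individuals (not observations — the convention that reproduces the
published tables); LRT p-values are plain upper chi-square tails, except
the univariate h² = 0 boundary test which uses the 50:50 χ²₀/χ²₁
mixture; SRMR uses sample-standardised residuals over the lower triangle
including the diagonal. The phenotypic split-half stage (EFA on one
missingness-balanced half, CFA on the other) adds CFI/TLI/RMSEA from a
compact Wishart-ML confirmatory fitter written for this package.

## The synthetic-data generator

`simulate_genotypes()` draws unrelated individuals (Binomial(2, p)
dosages, MAF uniform in a range), `simulate_grm()` streams the same law
in marker blocks for large marker counts, and `simulate_phenotypes()`
draws phenotypes from exactly the model covariance — by default row-wise
in the eigenbasis of `G` (the same Gaussian law as a dense matrix
square root of `Σ_V`, at O(n·k³) instead of O((nk)³); the dense route is
kept for validation), then masks entries missing-completely-at-random.

`alspac_like_scenario()` is the calibrated preset: six traits, IP(2,2),
a cognitive/language domain and a social-difficulties domain with one
cross-loading trait, rGE = +0.89 and −0.62, published point estimates
for the loadings where available and round plausible values (annotated
`assumed`) elsewhere; specific residual loadings are solved so each
trait's implied variance is exactly 1, which puts SNP-h² in the
0.15–0.5 range and two genetic specific loadings below the 0.05
constraint threshold. Default missingness is 18% MCAR, the cohort
regime. What the generator does *not* emulate: linkage disequilibrium,
population structure or residual relatedness, non-Gaussian traits, and
informative missingness — passing tests demonstrate correctness of the
estimator under its own assumptions, not robustness to those
violations.

## Problem sizes used by the standing experiments

Chosen for one desk CPU: oracle equivalence on 100 instances (n ≤ 50,
k ≤ 4); scenario recovery at n = 2000 with a 5000-marker GRM shared
across 20 phenotype replicates (the Monte-Carlo variation of interest is
over phenotype draws; replicate fits use single data-informed starts and
a loosened optimiser tolerance, which affects speed, not the estimates);
null calibration of the rGE LRT over 200 replicates at n = 500, k = 4;
univariate h² recovery at n = 4000 with a 40,000-marker GRM, which puts
the GRM off-diagonal dispersion (≈ 0.005) and hence the h² standard
error (≈ 0.07) in the regime of cohort-scale GREML. Recovery experiments
run the scenario at `missing_rate = 0`: the rotated path needs complete
data, and dense full-information likelihoods at n = 2000, k = 6 are far
beyond desk scale; missing-data estimation is exercised separately at
small n through the direct path.

## Known limitations

* The dense missing-data path caps practical sample sizes at a few
  thousand observed entries; there is no sparse-GRM or AI-REML
  acceleration (ML only, by design — phenotypes are pre-residualised so
  no fixed effects enter the likelihood).
* rGE standard errors are boundary-skewed when the true correlation is
  near ±1; Wald intervals are reported but the LRT against independence
  is the more reliable evidence component.
* Factor correlations among common factors default to fixed zero
  (freeable via `corr_A`/`corr_E`), matching the independent-factor
  models this pipeline selects.
* The EFA stage inherits `stats::factanal`'s ML fitting; Heywood cases
  are handled by reducing the factor count, which is logged.
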