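---
title: "Screening soil bacteria for Striga-suppression candidates"
author: "StrigaSieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening soil bacteria for Striga-suppression candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StrigaSieve)
```

## The problem

*Striga hermonthica* is an obligate root parasite of cereals. Field soils can
suppress infection through their microbiome: microbes may degrade the
haustorium-inducing factors (HIFs — phenolics such as syringic and vanillic
acid that the host root exudes and that trigger formation of the parasite's
feeding organ), or induce root traits that impede penetration (cortical
aerenchyma, endodermal suberin). Given amplicon count tables from a
2 soils (natural / sterilized) x 2 Striga treatments (infected / control)
factorial sampled across soil/root compartments ("sub-categories") and
timepoints, plus per-plant trait measurements, StrigaSieve asks: *which
bacterial taxa are associated with the suppressive traits, over and above the
treatment effects themselves?*

The pipeline has four analytic stages.

## 1. Trait screen

Each trait at each timepoint is fit with the two-way ANOVA

$$\text{trait} = \text{Soil} + \text{Striga} + \text{Soil}{\times}\text{Striga},$$

(`twoWayAnova()`, sequential sums of squares on balanced data, hierarchical
type II otherwise). `classifyTrait()` labels the trait `soil_only` when the
Soil term is significant and the interaction is not — these are the traits
the microbiome changes *independently* of infection, and only they (plus the
Striga attachment count itself, which is the infection response) enter the
joint model. A significant interaction always takes precedence
(`interaction` label), because the soil effect is then not interpretable on
its own. The significance level defaults to $\alpha = 0.05$ and is
config-exposed.

## 2. Joint model and residual correlations

All retained responses — CLR-transformed taxa abundances and the screened
traits — are modeled jointly as a multivariate Gaussian regression

$$Y = XB + E,\qquad E_i \sim \mathcal N_q(0, \Sigma),$$

where $X$ is the treatment-coded design (reference cell
sterilized/control; columns intercept, soil\_natural, striga\_infected,
interaction). The scientific quantity is the **residual correlation**
$\mathrm{cov2cor}(\Sigma)$: association between a taxon and a trait that
remains after the modeled treatment effects are removed, the standard proxy
for a biotic interaction in joint attribute models.

Counts enter as centered log-ratios, $x_i = \ln\{(c_i + 0.5)/g(c+0.5)\}$,
rather than through censored-composition machinery: the CLR-Gaussian
approximation keeps both full conditionals conjugate, targets the same
residual-correlation estimand, and makes parameter recovery on synthetic
data well-posed. The pseudocount of 0.5 is the usual half-count convention.

`gibbsFit()` samples the posterior with an exact two-block Gibbs sweep:

* $\mathrm{vec}(B)\mid\Sigma \sim \mathcal N$ with precision
  $\Sigma^{-1}\!\otimes\!X^{\top}X + \tau I$ (ridge prior, $\tau = 10^{-3}$
  — essentially flat at the data scale, but proper);
* $\Sigma\mid B \sim \mathcal{IW}(\nu_0 + n,\; S_0 + E^{\top}E)$ with
  $\nu_0 = q + 2$ and $S_0 = I$, the weakest proper inverse-Wishart with an
  identity prior scale.

Defaults are 10,000 iterations, 2,000 burn-in, thinning 5 — enough for the
coefficients of a $q \le 100$ fit to stabilise; convergence is monitored by
Geweke z-scores on the residual log-determinant and ten distinct $\Sigma$
entries, warning (never erroring) at $|z| \ge 2$, a diagnostic with a ~5%
false-positive rate per chain. Residual correlations are the posterior mean
of the per-draw correlation conversion, so they are bounded entrywise by 1
by construction. Fits run independently per sub-category x timepoint.
`contrastH1H2()` reports the simple effects: the Striga effect within each
soil (H1) and the soil effect within each Striga treatment (H2), as
posterior means, 95% credible intervals and sign probabilities.

## 3. Candidate ranking

Residual correlations are turned into candidates by a fixed, deterministic
scheme (`rankTable()`, `selectCandidateGenera()`):

1. **Sign filter** — keep negative correlations for Striga attachments and
   the HIFs, positive for suberin and aerenchyma. Zeros are excluded: the
   filter is a strict inequality, since a zero correlation carries no
   directional evidence.
2. **Desirability ranks** — within each trait the most desirable taxon
   (lowest correlation for negative-desired traits, highest for
   positive-desired) receives the highest rank value $m$; ties get the
   average of the covered positions, with taxon id as a deterministic
   secondary order for output stability.
3. **Combined rank** — the Striga rank plus the focal-trait rank, restricted
   to taxa ranked in both, re-ranked so the largest sum gets the top value.
4. **Selection** — an OTU qualifies for a mechanism if its Striga
   correlation is below $-0.2$ *and* the mechanism correlation passes
   $\pm 0.2$ in its desirable direction; a genus is selected as soon as one
   member OTU qualifies, with mechanisms unioned across OTUs and
   sub-categories. Combined ranks are never merged across sub-categories —
   they are reported side by side.

The genus-level any-member rule reflects how candidate isolates are chosen
from culture collections, where taxonomic delineation is at genus level.

## 4. HIF degradation-product matching

Predicted microbial conversion products of the five HIFs (DMBQ, syringic
acid, vanillic acid, vanillin, acetosyringone) are matched against
untargeted LC-MS features on neutral monoisotopic mass within **25 ppm**
(inclusive boundary; many-to-many, every qualifying pair reported;
retention time carried but unused). Matched features are then screened for
differential abundance between soils: Welch t-test by default (a `student`
mode is available), Benjamini–Hochberg adjustment *across the matched
features only*, and the dual threshold adjusted $p < 0.05$ with
$|\log_2 \mathrm{FC}| > 1$. The fold-change offset $\epsilon$ is half the
smallest positive peak area in the table, a scale-respecting choice that
keeps ratios finite for absent features. Features are assumed
adduct-corrected upstream; matching is on neutral masses.

## The synthetic-data generator

`simulateDataset()` is first-class, tested code, not a fixture. It emulates
the study conditions: the full 2x2 factorial replicated in each
sub-category and timepoint (default 6 replicates per cell, matching the
phenotyping replication), latent Gaussian responses
$Z = XB + E,\ E \sim \mathcal N(0, \Sigma)$ with $\Sigma$ the identity
overwritten by the *planted* taxon–trait correlations (rejected with a
diagnostic if not positive definite), and a
logistic-normal-multinomial count layer: taxa latents are softmax-weighted
into multinomial reads at a default library size of 30,000. Defaults encode
the qualitative biology: natural soil lowers attachments and HIF exudation
and raises aerenchyma and suberin; infection raises attachments.

Soil sterilization is modeled as taxon dropout (default 30% of taxa zeroed
in sterilized samples) plus the configured mean shifts, reproducing the
lower alpha diversity of sterilized soil. Planted taxa are excluded from
the dropout set: a residual association is only estimable for a taxon
observed across the whole design, so dropping a planted taxon would make
recovery ill-posed by construction rather than informative.

All randomness flows from one integer master seed through a documented
splitting scheme (`subSeed(k) = (seed + 7919 k) mod (2^31 - 1)`; one
substream per sub-category x timepoint, a dedicated offset for the feature
table), so identical configs give byte-identical tables.

What the generator does **not** emulate: sequence-level error (chimeras,
amplification bias), overdispersion beyond the logistic-normal layer,
retention-time drift, adducts/isotopes in the feature table, and spatial or
temporal autocorrelation between sub-categories (bundles share taxa
identities but have independent noise). Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artefact of real amplicon or LC-MS data.

## Numerical choices and degenerate inputs

* CLR maps softmax latents back to (approximately) the latent scale, so
  planted latent correlations are recovered with only the mild attenuation
  induced by the multinomial layer and the CLR centering ($\approx$ 2–4% at
  25 taxa and a 30,000-read library).
* Correlation estimates at the validation sample sizes carry sampling noise
  of about $1/\sqrt{n - p}$; with $n = 48$ that is $\approx 0.15$ per
  entry, which is why recovery is assessed as MAE over planted entries and
  averaged over seeds.
* Zero-variance ANOVA cells error as "degenerate"; an empty cell falls back
  to main effects with a warning.
* Both-groups-constant t-tests return $p = 1$ at equal means and error at
  unequal means (a zero-variance difference is evidence, not a statistic).
* Zero cells in the suberization 2x2 get the Haldane–Anscombe 0.5
  correction before the odds ratio (the Fisher p uses the uncorrected
  table).
* Taxa filtering breaks abundance ties lexicographically by taxon id, and
  every ranking step has a stated tie rule, so the whole pipeline is a pure
  function of (data, config, seed): reruns are byte-identical.

## Validation problem sizes

The test suite validates the sampler and the end-to-end pipeline at sizes
chosen to give stable Monte-Carlo behaviour at desk scale: residual-
correlation recovery on 25 taxa + 5 traits at $n = 48$ (2 soils x 2
treatments x 12 replicates) over 10 seeds (MAE < 0.12); null calibration at
$n = 100$ with an identity covariance over 20 seeds (off-diagonal
$|r| > 0.2$ in $\le 5\%$ of entries — note this bound sits essentially at
the asymptotic value of the sampling distribution, $\Pr(|r| > 0.2) \approx
5\%$ at 96 residual df, so it is a sharp check of the absence of any
inflation, not a generous margin); planted-candidate recovery with 3
suppressive taxa among 50; and exact agreement of the ranking scheme with
an independent sort-based implementation on 100 random matrices. Chains in
these checks use 1,200–2,500 iterations, which for this fully conjugate
sampler mixes indistinguishably from the 10,000-iteration default.

## Known limitations

* The CLR-Gaussian treatment of counts ignores the mean–variance relation
  of low-abundance taxa; very sparse OTUs should be removed by
  `filterTaxa()` (default: present in ≥25% of samples, top 100 by mean
  relative abundance) before fitting.
* Residual correlation is association, not interaction: hub taxa,
  unmodeled environmental gradients and compositional closure can all
  induce it. The candidate set is a prioritisation for isolate testing, not
  an inference of mechanism.
* The inverse-Wishart prior shrinks all correlations mildly toward zero;
  at $n \ge 48$ this bias is below 0.02 and is dwarfed by sampling noise.
* With fewer than ~10 samples per design cell the H1/H2 credible intervals
  are wide and the screen's power is low; the generator's defaults are the
  smallest sizes at which the validation targets are stable.
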