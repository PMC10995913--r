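---
title: "Normative deviation modelling of regional brain atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative deviation modelling of regional brain atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normdev)
```

## The problem

Group-average comparisons of cortical thickness and subcortical volume ask
where patients differ *on average* from controls. In clinically
heterogeneous conditions — Parkinson's disease (PD) and dementia with Lewy
bodies (DLB) are the motivating examples — atrophy may be substantial in
every patient yet spatially inconsistent across patients, so group averages
wash it out. Normative modelling inverts the question: each region of each
individual is compared against the distribution of healthy controls of the
same age and sex, yielding a deviation z-score per region. Binarizing the
deviations gives a personal atrophy map; summing it gives a *total outlier
count*; comparing maps between individuals with the Hamming distance
quantifies how *dissimilar* two patients' atrophy patterns are.

`normdev` implements this pipeline end to end for the canonical feature set
of 169 regions: 148 Destrieux cortical-thickness regions (74 labels per
hemisphere) and a fixed convention of 21 `aseg` subcortical volumes
(10 bilateral structures plus the brain stem; the literature does not fix
this set, so the package documents its own and keeps it stable).

## The normative model

For one region with response $y$ (mm or mm$^3$), reference controls with
age $a$, sex $s \in \{0,1\}$ and site $k$:

1. **Standardize** $\tilde y = (y - \mu_y)/\sigma_y$.
2. **Warp** $t = \sinh(\delta \,\operatorname{asinh}(\tilde y) - \epsilon)$
   — the two-parameter sinh-arcsinh transform; $\epsilon$ absorbs residual
   skew, $\delta$ tail weight, $(\epsilon,\delta)=(0,1)$ is the identity.
   The warp is strictly increasing for every $\delta > 0$, so deviations
   keep their ordering.
3. **Bayesian linear regression** in warped space:
   $t = Xw + e$, $w \sim N(0, \alpha^{-1} I)$, $e \sim N(0, \beta^{-1} I)$,
   where the row of $X$ holds a clamped cubic B-spline basis over age
   (3 interior knots at reference-age quantiles), the sex indicator, an
   intercept, and fixed-effect dummy columns for the reference sites.

Hyperparameters $(\epsilon, \delta, \alpha, \beta)$ maximize the type-II
objective: the closed-form Gaussian BLR log evidence of the warped response
*plus* the log-Jacobian $\sum_i \log \frac{dt_i}{d\tilde y_i}$, which makes
evidences comparable across warp parameters. The search is bounded
L-BFGS-B from three fixed starting points with tolerance $10^{-6}$.

Two numerical points deserve emphasis:

* **Centring refinement.** The sinh-arcsinh family is not closed under
  translation of its input, so the *meaning* of $\epsilon$ depends on where
  the response is centred. The optimizer therefore refines the response
  centring (one extra location parameter, folded back into $\mu_y$ after
  fitting). The scale is deliberately *not* refined: freeing location and
  scale together creates a near-flat evidence ridge along which
  $(\epsilon, \delta)$ drift without distributional consequence — we
  measured skew estimates wandering by ±0.3 at $n = 2000$ with a free
  scale, versus ±0.02 with the centring-only refinement.
* **Redundant intercept.** The clamped spline basis forms a partition of
  unity, so the explicit intercept column makes $X$ rank-deficient. Under
  the Gaussian prior this is harmless (the null direction has prior
  precision $\alpha > 0$); the price is that individual basis weights are
  not interpretable one by one, and tests compare fitted mean *functions*
  rather than raw weights.

## Site transfer and z-scores

The fitted population model is frozen when moving to a new scanner/site.
From $m \geq 10$ target-site controls (a warning below 20) the package
stores warped-space residual corrections
$m_k = \operatorname{mean}(r_i)$ and
$s_k = \operatorname{sd}\!\big((r_i - m_k)/\sqrt{v_i}\big)$, where
$v_i = x_i^\top A^{-1} x_i + 1/\beta$ is the posterior-predictive variance.
The scale is computed on variance-standardized residuals (rather than as a
ratio of raw SDs) so that control z-scores at the site have unit variance
exactly, which is the purpose of the correction. Deviation z-scores are
then

$$z_{ir} = \frac{t_{ir} - x_i^\top w_r - m_{k(i),r}}{s_{k(i),r}\sqrt{v_{ir}}}.$$

Reference sites are self-calibrated at fit time through the identical
code path (site dummies zeroed, corrections from each site's own
controls), so prediction never branches on whether a site was seen during
fitting. Scoring a participant from an uncalibrated site is an explicit
error instructing recalibration, not a silent fallback. Ages outside the
spline support are clipped to it with a warning; clamped splines
extrapolate poorly and the package prefers a conservative boundary value.

## Deviation metrics

* **Outliers**: $z < -1.96$ (strictly; the lower 2.5% tail). Only the
  lower tail is flagged because the target phenomenon is atrophy; a
  two-tailed mode exists but is off by default. The alternate liberal
  threshold $-1.282$ (lower 10%) is wired in as a standard sensitivity
  rerun, and flagging is monotone in the threshold by construction.
* **Total outlier count** (0–169) and **mean regional z** per participant.
* **Regional outlier proportions** per group, exported as tables in
  canonical region order (surface rendering is out of scope).
* **Hamming dissimilarity**: pairwise within-group distances between
  binary outlier vectors (0–169), summarized per participant by the
  *median* of their $n-1$ distances — distance distributions are
  right-skewed, and the median over an even count is the mean of the two
  middle values. Cross-group distances are computable but not part of the
  default report.

## Group inference

Group differences in count and mean z, and clinical associations, use OLS
on `[intercept, predictor, age, sex]` with the Wald t test on the
predictor; contrasts are coded first-minus-reference (reference = the
second-listed group) so signs follow the usual reporting convention.
Regional outlier comparisons and Hamming-median comparisons use
Mann-Whitney U tests (U convention for the first sample, exact when the
samples are untied and $\binom{n_1+n_2}{n_1} \leq 20{,}000$, otherwise the
tie-corrected normal approximation with continuity correction), with
Benjamini-Hochberg FDR across the 169 regions. The composite cognitive
score averages subtest z-scores standardized against the control group;
participants missing all subtests are flagged missing rather than imputed.

Participants with extreme total outlier counts are flagged by a
reproducible far-outlier rule — count $> Q_3 + 3\,\mathrm{IQR}$ within
group — replacing the visual identification such studies typically use,
and every group comparison and association is rerun without them
(`*_sensitivity.csv`).

## The synthetic cohort generator

No patient data ship with the package; the generator produces cohorts with
the statistical structure the model assumes, plus known ground truth for
recovery testing:

* per-region lifespan trajectories: cubic polynomials in scaled age with
  coefficients drawn once per region from priors centred on age-related
  decline (the smooth-curve assumption without committing to any
  published spline shape);
* a single additive standardized sex offset (default 0.3 SD);
* additive per-site, per-region offsets $N(0, 0.2\,\mathrm{SD})$ — the
  additive-site assumption that recalibration corrects; no site × age
  interaction by default;
* skewed/heavy-tailed residuals: standard-normal draws passed through the
  inverse sinh-arcsinh warp, per-region $\epsilon \in [-0.3, 0.3]$ and
  $\delta \in [0.9, 1.2]$ by default. These are placeholders for plausible
  FreeSurfer residual behaviour, not estimates from any study's data;
* patient groups: each participant receives a random affected-region set
  (size ~ Poisson around the group burden; a `heterogeneity` knob in
  $[0,1]$ interpolates between one shared core set and fully independent
  sets) shifted down by the group effect size in residual-SD units;
* clinical scores (MoCA-like, a visuo-perception score, three cognitive
  subtests) that are linear-Gaussian in the participant's true injected
  burden, with group-specific loadings so that global cognition tracks
  burden in the DLB-like group and visuo-perception tracks burden in the
  PD-like groups.

The default study configuration (`default_study_config()`) mirrors the
motivating design: a 4-site reference cohort (default n = 1200 at package
scale; the null-calibration checks use n = 2000), two clinical sites
providing 50 and 100 recalibration controls, and groups PD-high (n = 62,
burden 2), PD-low (n = 34, burden 6) and DLB (n = 61, burden 14), all with
effect −2.5 SD. Group sizes follow the motivating cohort; burdens are set
so that expected counts are ordered PD-high < PD-low < DLB.

What passing tests on these data do **not** show: real residuals need not
be sinh-arcsinh; real site effects include multiplicative and
age-interacting components; real atrophy is spatially correlated rather
than an independent random subset of regions; and clinical scores have
floors, ceilings and integer supports. The generator validates the
machinery and its calibration, not the biology.

## Calibration behaviour and problem sizes

With the generator's defaults, fitting all 169 regions on a 2000-control
reference takes about a minute on one core; the full default pipeline runs
in 2–3 minutes. Scoring 1000 held-out null participants from a site
recalibrated with 100 controls yields a mean per-region outlier proportion
of ~2.5–2.8% at the −1.96 threshold across seeds. The slight excess over
the nominal 2.5% is the expected statistical floor of that design: the
site corrections estimated from 100 controls enter the tail probability
$\Phi(-1.96\,\hat s + \hat m)$ convexly, contributing ≈ +0.17 percentage
points in expectation, vanishing as the control pool grows.

## Known limitations

* One model per region: no spatial pooling or cross-region covariance.
* Recalibration adapts offset and scale only, never weights, warp or the
  noise precision — deliberate, so small control pools cannot corrupt the
  population model, but a site with genuinely different age dynamics will
  remain miscalibrated.
* Fixed-effect site dummies in the reference fit assume exchangeable
  additive site effects; hierarchical site models are out of scope.
* The spline basis clips, rather than extrapolates, outside the reference
  age range; participants far outside it get boundary-age predictions.
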