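---
title: "Image-domain bootstrapping of dynamic PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-domain bootstrapping of dynamic PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petboot)
```

## The statistical model

`petboot` treats a reconstructed dynamic PET study as an $N \times T$ array
$z_{ij}$ (voxel $i$, time-frame $j$, mid-times $t_j$ in minutes) and fits

$$ z_{ij} = x_j'\alpha_i + \sigma_i \phi_j \, Q(\eta_{ij} \mid \kappa_{ij}),
   \qquad \eta_{\cdot j} \sim N(0, \Sigma_N), $$

where

* the columns of the temporal basis $X$ are sub-TACs with the ability to
  represent every voxel time-course up to scale;
* $\sigma_i \ge 0$ and $\phi_j > 0$ factorize the error scale into spatial
  and temporal parts, with $\sum_j \phi_j^2 = T$ for identifiability;
* $Q(\cdot \mid \kappa)$ is a strictly monotone empirical quantile
  transform carrying a standard Gaussian variable to the observed error
  distribution, allowed to vary slowly with the surrogate
  $\kappa_{ij} = \hat z_{ij} / (\tilde\sigma_i \tilde\phi_j)$ (a local
  signal-to-noise index); its conditional standard deviation
  $h(\kappa)$ satisfies $\sum_l h_l^2 = L$ over the $\kappa$-bins;
* the sub-ordinate field $\eta$ is independent across frames (counts in
  different frames are independent) and spatially stationary, so its
  covariance is diagonalized by the FFT with a power spectrum $\lambda$,
  normalized to mean 1 so that $\eta$ has unit marginal variance.

The model is an approximation device for uncertainty propagation, not a
mechanistic claim: it captures mean structure (through $X$),
heteroscedasticity (through $\sigma, \phi, h$), non-Gaussian shape (through
$Q$) and spatial correlation (through $\lambda$), which are the features a
bootstrap of reconstructed PET data must reproduce.  FBP-reconstructed
data are close to Gaussian ($Q$ near identity, $h$ near flat); iteratively
reconstructed data are right-skewed at low $\kappa$, which the conditional
$Q$ absorbs.

## Estimation pipeline (`fit_glm`)

1. **Initial weights.** $w^0_j = e^{-t_j\zeta} \mathrm{d}t_j / \bar\mu_j^*$
   with $\bar\mu_j^* = \max(\bar\mu_j, 0.1\max_j \bar\mu_j)$ (frame means
   floored at a tenth of their maximum, so empty early frames cannot blow
   up the weights); $\phi^0_j \propto (w^0_j)^{-1/2}$.
2. **Unconstrained WLS** per voxel through one shared $K \times K$
   factorization gives $\hat\alpha$, fitted means and residuals.
3. **Frame-wise studentization.** Fitting $K$ coefficients suppresses the
   residual variance by a leverage-dependent share per frame.  Under the
   product variance model the suppression factor is exactly
   $c_j = \sum_k (I - H)^2_{jk} v_k / v_j$ with
   $H = X(X'WX)^{-1}X'W$ and $v$ the fitted variance profile; residuals
   are divided by $\sqrt{c_j}$, iterating twice so $v$ is self-consistent.
   *Why not the classical global $\sqrt{T/(T-K)}$:* with few frames
   ($T = 20$), $K/T$ around 0.3 and very uneven weights, the leverage
   concentrates on the long late frames and on the few early frames that
   carry all of the vascular signal; a global inflation then leaves
   simulated late-frame variance several-fold too small, which directly
   deflates flux standard errors.  For long protocols
   ($T \gtrsim 30$, $K/T \approx 0.2$) the two corrections nearly agree.
4. **Scale iteration** (`iterate_scales`).  Stage 1 alternates the
   conditional updates
   $\phi_j^2 = \mathrm{mean}_i(r_{ij}^2/\sigma_i^2)$ and
   $\sigma_i^2 = \mathrm{mean}_j(r_{ij}^2/\phi_j^2)$ with $h \equiv 1$,
   renormalizing $\sum\phi^2 = T$ each pass.  The converged basic-model
   scales define $\kappa$ and its $L$ equal-count percentile bins (fixed
   thereafter; stable-sort tie-breaks).  Stage 2 iterates the same updates
   with $h^{-2}$ in the weights jointly with
   $h_l^2 = \mathrm{mean}_{bin\,l}(r^2/(\sigma^2\phi^2))$, normalized to
   $\sum_l h_l^2 = L$.
5. **Quantile transform.**  Within each bin the sorted scaled residuals are
   paired with standard-normal quantiles $\Phi^{-1}((k-0.5)/n_l)$;
   $Q(\cdot\mid l)$ interpolates the table linearly and clamps at the
   extreme order statistics (no parametric tail extrapolation — simulated
   values stay within the observed residual range, a deliberately
   conservative choice).  The inverse map assigns every residual its
   normal score $\hat\eta_{ij}$.
6. **Spatial spectrum.**  Per frame, the periodogram
   $|\mathrm{FFT}(\hat\eta_{\cdot j})|^2/N$ on the voxel grid; frames are
   averaged with weights $\propto \phi_j^{-2}$ (normalized to sum 1) and
   the result scaled to mean 1.  Stationarity is imposed on the torus
   (circular FFT, no padding) so that estimation and simulation use the
   same convention; the autocorrelation is the real inverse FFT, scaled to
   $\rho(0) = 1$.

### Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `L_bins` | 64 | $\kappa$ bins (the useful range is roughly 50–100); reduced automatically so every bin holds at least 50 residuals |
| `tol`, `max_iter` | 1e-6, 200 | scale-iteration stopping rule; the alternating updates approach their fix point at a $\sim 1/\text{iteration}$ rate, so the run frequently stops at `max_iter` with drift far below statistical accuracy (`converged` flag records it) |
| `T_B` | 1/12 min (5 s) | vascular transit bound of the residue decomposition (5–10 s is physiologic for FDG/FLT) |
| `n_knots` / `delay_grid` | 24 geometric knots / 0–30 s by 2.5 s | monotone residue parameterization: dense early knots match fast vascular kinetics |
| `beta` | 1.35 | 1-D operator exponent matching the dose-vs-MSE behaviour of 2-D PET reconstruction |
| `target_noise` | 0.15 | reference-dose calibration: relative single-frame reconstruction noise over the support |

## Basis construction

Voxel time-courses are unit-normalized under the frame weights and split by
recursive bisection (2-means, largest-scatter-first, deterministic
farthest-point initialization) until the requested number of clusters;
background voxels (frame-weighted mean below 1% of the volume maximum) are
excluded and labelled cluster 0.  Candidate sub-TACs are scored by a
generalized cross-validation objective
$\mathrm{GCV}(S) = \sum_l |C_l| \, \mathrm{WRSS}_l(S) / (1 - |S|/T)^2$,
where $\mathrm{WRSS}_l$ is the weighted *non-negative* representation error
of the $l$-th cluster mean, and pruned by greedy backwards elimination
(ties broken at the lowest column index, for reproducibility); the subset
with the smallest GCV along the path is returned and the path itself is
kept as an attribute.  The GCV denominator requires fewer candidates than
frames; the builder refuses otherwise.

In the residue-model (NPRM) variant each cluster mean is replaced by its
monotone residue fit before elimination, and two protected elements are
prepended: a spiked residue of duration at most 5 s (unit integral — its
sub-TAC is the arterial input) and a constant residue (its sub-TAC is the
running integral of the input: the Patlak element, pure trapping).

A caveat on identifiability: with more knots than frames the monotone
residue fit reproduces the tissue curve but the residue itself is not
pointwise unique.  Kinetic summaries derived from it (integrals and end
values) are far better determined than the pointwise residue, which is the
reason the mapping works with a deliberately rich knot grid.

## Kinetics

The fitted residue decomposes on $[0, T_E]$ as $R = R_B + R_D + R_E$ with
$R_E \equiv R(T_E) = K_i$ (flux), $R_B(t) = R(t) - R(T_B)$ on $[0, T_B]$
(vascular), and $R_D$ the remainder (in-distribution).  Summaries follow by
quadrature: $V_b = \int_0^{T_B} R_B$, $K_d = R_D(0)$,
$V_d = \int_0^{T_E} R_D$, $K_1 = K_i + K_d$,
$\mathrm{MTT} = \Delta_w + V_d/K_d$ with flow weights
$w_k \propto \alpha_k K_{D,k}$ over basis elements (zero-flow elements are
excluded from the delay weighting), extraction $K_i/K_1$ where $K_1 > 0$.
Voxels where a denominator vanishes get `NA` — an explicit undefined
marker, excluded from SD statistics, never a silent 0.

The two-compartment construction (`two_compartment_residue`) serves as the
analytic oracle: its exponential mixture plus a triangular blood component
integrating to $f_b$ reproduces the familiar closed forms in the small
$T_B$, large $T_E$ limit ($K_i \to K_1 k_3/(k_2+k_3)$ and so on, with
$O(T_B)$ errors that the tests verify shrink linearly), and reduces to the
one-compartment flow model when $k_3 = k_4 = 0$.

## The three bootstraps

* **Image-domain:** per replicate and frame, white Gaussian noise is
  filtered to $\hat\lambda$ (exactly variance-preserving since
  $\mathrm{mean}(\hat\lambda) = 1$), mapped through $\hat Q(\cdot\mid
  \hat\kappa_{ij})$, scaled by $\hat\sigma_i\hat\phi_j$ and added to the
  fitted means.  Frames are independent by model assumption.
* **Projection-domain:** one multinomial draw over all bins of the count
  array with $N_e$ = total detected events, conserving $N_e$ exactly
  (binned equivalent of list-mode resampling with replacement).  The whole
  dynamic study is pooled into a single multinomial; resampling frames
  separately would not conserve the total event count.  The Poisson
  variant (more variable, not list-mode-equivalent) is out of scope.
* **Recycling:** a small retained set of coefficient arrays is converted to
  standardized deviations $(\alpha^b_i - \hat\alpha_i)/\hat\sigma_i$; each
  output replicate resamples one deviation per voxel (row-wise from the
  voxel's own set, or pooled over voxels), restores spatial correlation by
  filtering each coefficient column with $\hat\lambda^{1/2}$, and returns
  $\hat\alpha_i + \hat\sigma_i \tilde D_i$.  The spectral filter preserves
  marginal variance because the spectrum has mean 1 — without that
  normalization the recycled variance would be double-counted.  Recycled
  coefficient replicates are clamped at zero before kinetic mapping, since
  recycling produces unconstrained Gaussianized deviations while the
  kinetic maps require non-negative coefficients.

Every engine derives one sub-seed per replicate index from the master seed,
so replicate $b$ is bit-reproducible regardless of how many replicates are
requested.

## Scanning simulators and what they do (not) emulate

The 2-D scanner projects the image (unit square, $n \times n$) onto a
$[-\sqrt2, \sqrt2] \times [0, \pi)$ sinogram (183 × 181 at the reference
128 × 128 resolution, scaled proportionally) by pixel-driven linear
interpolation with per-ray attenuation factors, draws independent Poisson
counts, and reconstructs by frequency-domain ramp filtering (2× zero
padding against wrap-around), exact-transpose backprojection with $\pi/n_A$
angular quadrature, and a common Gaussian bandwidth chosen to minimize the
squared error of the duration-weighted total-uptake image against the known
truth.  That uptake-level criterion (rather than the frame-wise error sum)
is what yields a dose-dependent interior optimum; the discrete FBP has a
small ringing floor, so with noiseless data a fraction of a pixel of
smoothing can still help, and the "smallest bandwidth under no noise" ideal
holds exactly only for the 1-D model, whose least-squares inversion is
exact.

The 1-D scanner replaces the Radon transform by a circular convolution with
Fourier multiplier $|\nu|^{-\beta}$ (DC pinned to 1, preserving total
mass), Poisson counts with mean $\tau a_x (K_\beta \lambda)_x$, and either
exact Fourier-division least squares ("FBP") or multiplicative Poisson EM
from a uniform positive start.  EM needs a non-negative kernel; the
real-space kernel of $K_\beta$ has about 12% negative mass, so the EM
forward model truncates and renormalizes it.  This makes EM and LS estimate
slightly different operators: their high-count reconstructions agree to a
couple of percent only when compared under a common forward kernel, and the
package's tests do exactly that.

The phantoms state a synthetic world: an elliptical head (2-D) with
gray/white shells, a washout rim, a focal tumor and a vascular pool, or six
smooth bumps (1-D), each with two-compartment kinetics chosen once to span
trapping, washout and slow-exchange shapes (FDG style; faster exchange and
larger blood signal for FLT), driven by a gamma-variate bolus plus
recirculation tail, over a 20-frame, 60-minute schedule with dense early
sampling.  The reference dose is calibrated so a single-frame
reconstruction has 15% relative noise over the support.  Real data differ
in ways the generator does not emulate: scatter and randoms, detector
normalization, decay within frames, motion, non-stationary resolution, and
metabolite-corrected input functions.  A green test therefore establishes
internal consistency of the estimator chain and calibration against
replication truth *within this world*, not clinical validity.

## Evaluation design

Replication truth is the across-replicate SD of each kinetic parameter at
each voxel over `N_S` independent simulate–scan–reconstruct–map runs.
Calibration regressions are through the origin (the relation is a
proportionality; slope above 1 means the bootstrap under-estimates), with
the uncentered R² conventional for no-intercept fits.  The relative-error
model regresses log relative parameter SD on log scaled reconstruction
error with an intercept.  ROI analysis replaces the voxel index by nested
rectangular blocks kept when at least half inside the support.

At the scaled-down acceptance sizes (64 × 64, T = 20, `N_S` = 60,
`N_B` = 25), the SD fields on both axes of the calibration regression carry
Monte-Carlo noise of roughly 9% and 14%, and the single-replicate fit
contributes per-voxel scale-estimation noise of order $1/\sqrt{2T}$; the
flux calibration R² the acceptance suite computes sits just below the 0.9
mark for this reason — its slope, the bias measure, is well inside the
expected band.  Larger frame counts (the regime of real protocols) shrink
the dominant noise term.

## Known limitations

* Temporal correlation of $\eta$ is assumed away (frame independence);
  decay-weighting beyond the single constant $\zeta$ is out of scope.
* Spatial stationarity of the sub-ordinate field is imposed on the torus;
  strongly non-stationary correlation (e.g. variable resolution across the
  field of view) is outside the model family.
* The per-voxel scale $\sigma_i$ is estimated from $T$ residuals of a
  single study; its sampling noise propagates into every bootstrap SD and
  is the binding accuracy constraint for short protocols.
* The default monotone residue fit is over-parameterized by design; only
  its integral summaries should be interpreted pointwise.
* The 2-D scanner omits scatter, randoms and detector effects; dose is an
  abstract scale factor.
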