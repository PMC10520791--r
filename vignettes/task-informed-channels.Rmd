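---
title: "Task-informed autoencoder channels for the channelized Hotelling observer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-informed autoencoder channels for the channelized Hotelling observer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskobs)
```

## The detection task and its observers

Objective image-quality assessment asks how well a *task* can be performed
on the images a system produces, not how pretty the images look.  The task
here is binary signal detection: an observer receives a measured image
`g = H f + n` and must decide between

* H0 (signal absent): `g = H f_b + n`, and
* H1 (signal present): `g = H (f_b + f_s) + n`,

where `f_b` is a random background object, `f_s` the signal object, `H` a
linear continuous-to-discrete imaging operator and `n` measurement noise.
Performance is summarized by the area under the ROC curve (AUC) of the
observer's scalar test statistic.

The optimal *linear* observer is the Hotelling observer (HO).  Its template
solves

    w_HO = [ (K0 + K1) / 2 ]^-1  delta_g,      delta_g = gbar_1 - gbar_0,

with `K_j` the class-conditional covariance of `g`.  For `N`-pixel images
the covariance is `N x N`; estimating and inverting it directly
("HO-Direct") needs many images and a regularized pseudoinverse.  The
*channelized* HO (CHO) first projects images to a few scalars `v = T g`
through an `N x M` channel matrix (`M << N`) and applies the Hotelling
formula in channel space:

    t(v) = w_v' v,   w_v = K_v^-1 delta_v.

Channels are *efficient* when the CHO tracks the HO's performance.  The
package implements the classical efficient channel families --
Laguerre-Gauss (LG), LG convolved with the signal (the convolutional-LG
realization of the filtered channel observer), partial least squares
(PLS) -- the nonprewhitening matched filter (NPWMF, `w = delta_g`), and
the channel-learning approach at the package's core: a tied-weight linear
autoencoder (AE).

## Autoencoder-learned channels

A linear AE with tied weights `W` (`N x M`, no bias, no nonlinearity)
encodes `y = W' g` and reconstructs `g_hat = W y = W W' g`.  Its encoder is
exactly a channel matrix, `T = W'`.  Training the AE therefore *is*
channel learning.  Two losses are provided:

* **conventional**: `mean_i || W W' g_i - g_i ||^2` -- the classical
  reconstruction objective.  Its optimum spans the top principal
  directions of the data, which for noisy lumpy images are dominated by
  background structure, not the faint signal; the resulting channels are
  nearly task-blind.
* **task-informed**: `mean_i || W W' g_i - I(g_i) delta_g ||^2`, where
  `I(g_i)` is the signal-present indicator.  The reconstruction target is
  the mean signal image for present images and zero for absent ones, so
  the embedding spends its entire capacity on signal-bearing structure.

Training uses Adam over balanced mini-batches (125 present + 125 absent by
default, re-paired each epoch), truncated-normal initialization
(sd `5e-6`, truncated at two standard deviations -- the conventional
definition; only the sd is inherited from the study protocol), and is
fully deterministic given the seed.  The gradient of the quadratic
objective is analytic; the trainer uses a factorized form whose
intermediates are at most `N x M` (the task target is rank one), which the
test suite checks against the naive expansion and against finite
differences.  Because Adam's effective step is the learning rate, the tiny
initialization mainly fixes the *directions* the channels grow along;
magnitudes are irrelevant to the CHO, which whitens the channelized data
(score invariance to channel rescaling is a tested property).

Burn-in (pre-training on a 500-image subset) is available as a
configuration flag but off by default; when enabled, Adam moments are
reset between phases (the alternative -- carrying moments over -- is not
distinguishable on the toy problems and the reset is the simpler
contract).

Model selection follows the train/validate/test protocol: every
(channel-count, learning-rate) cell -- each also serving as an independent
random initialization -- is turned into a CHO whose empirical AUC on the
validation split picks the winner.  Channel counts are capped at 20.
`ablate_channels()` ranks a trained observer's channels by greedy backward
elimination, rebuilding the CHO at each step.

## Simulation models

* **Lumpy background**: `f_b(r) = sum_n a exp(-|r - r_n|^2 / (2 s^2))`
  with a Poisson(5) number of lumps, `a = 1`, `s = 7` pixels, centres
  uniform over the continuous 64 x 64 field of view; no wrap-around, so
  border lumps are truncated by the field of view.
* **Signal**: rotated elliptical Gaussian, amplitude `A = 0.2`, axis
  widths `sx = 5`, `sy = 1.5` pixels, centred at pixel (32, 32).  One
  angle (0 deg) gives the location-known task; angles
  {0, 45, 90, 135} give the fixed-centroid signal-known-statistically
  task, with the angle drawn per signal-present image and recorded.
* **Imaging operator**: an idealized parallel-hole collimator with
  Gaussian point response of gain `h = 40` and width `w` pixels
  (`w = 0.5` in the Gaussian-noise study; `w` in {1, 2, 4} in the
  domain-shift study).  Because both the objects and the PSF are
  Gaussians, the continuous-to-discrete map is evaluated in closed form
  (Gaussian-Gaussian convolution integrals); a discrete FFT-convolution
  path exists only as a test oracle.
* **Noise**: i.i.d. Gaussian with `sd = 20` for the Gaussian-noise
  studies; mixed Poisson/Gaussian for the domain-shift study, where each
  pixel is replaced by `Poisson(g_m) + N(0, 1)` and every image is then
  min-max rescaled to [0, 1].  Pre-Poisson intensities are clamped at
  zero (blurred scenes are non-negative; the clamp guards round-off).

Pixel centres sit on the integer lattice; images are stored one flattened
(column-major) image per row of an `n x N` matrix.  Datasets are generated
in signal-present/absent *pairs* with independent backgrounds per image,
matching the study protocol in which 2n unique backgrounds are split into
halves; a `scenes` argument lets several imaging systems share one
background stream, which the domain-shift study requires.

Two conventions were genuinely open:

* the [0, 1] rescaling in the mixed-noise study could be per image or
  global; the per-image reading is implemented (it is the conservative
  one -- it destroys any information carried by the absolute scale);
* whether the two members of a pair share a signal angle in the SKS task;
  angles are drawn independently per signal-present image.

## What the generator does and does not emulate

The generator reproduces the stochastic object model, stylized system and
noise of the simulation studies exactly, which is what makes closed-form
checks (peak values, quadrature, covariance decompositions) possible.  It
does not emulate real detector physics (scatter, depth-dependent blur,
dead pixels), anatomical backgrounds, or signal-location uncertainty.
Passing tests therefore certify the method implementations under the
stated stochastic models, not clinical performance; externally supplied
ROI stacks (e.g. digital-mammography patches) can be run through the same
observers via `load_external_rois()`, but no claims about them are tested
here.

## Numerical choices

* Covariances use divisor `n` (the expectation definition); the average
  covariance is symmetrized before eigendecomposition.
* The regularized Moore-Penrose pseudoinverse truncates singular values
  below `1e-6` of the largest ("scaled singular values" is read as
  relative to the largest singular value; the study protocol does not
  define the normalization).  For large symmetric covariances the solve
  `pinv(K) delta_g` goes through a single eigendecomposition instead of
  forming the `N x N` pseudoinverse.
* `cho_build()` solves the `M x M` system directly and falls back to the
  pseudoinverse when the condition number exceeds `1e12`.
* The reported binormal AUC uses the classical rank-based (latent)
  binormal ROC model: `qnorm(TPR) = a + b qnorm(FPR)` fitted by least
  squares through the interior empirical ROC points, with
  `AUC = pnorm(a / sqrt(1 + b^2))`.  This is what the ROC literature
  means by "binormal": only some monotone transform of the scores is
  assumed Gaussian per class, so the fit is invariant to monotone
  transforms and tracks the empirical (Mann-Whitney, half-credit ties)
  AUC, which is always reported alongside.  Fitting Gaussians to the
  raw score moments is kept as `method = "moment"`; it admits exact
  closed-form identities (e.g. `AUC = Phi(SNR / sqrt(2))` for
  equal-variance scores) and the tests exercise both.  The distinction
  matters here: Hotelling scores on per-image-rescaled mixed-noise
  images are visibly skewed, and the raw-moment fit under-reports their
  AUC by a few hundredths relative to both the empirical and rank-based
  estimates.  AUC uncertainty is a seeded nonparametric case bootstrap,
  since the study protocol does not specify its error-bar procedure.
* PLS is NIPALS with X-only deflation and unit-norm weight vectors
  (label deflation changes nothing for the first component; the X-only
  variant is recorded as the implemented choice).
* LG channel grids: the functional form
  `u_j ~ exp(-pi r^2 / a^2) L_j(2 pi r^2 / a^2)` is evaluated on the pixel
  grid and unit-normalized.  Note that for widths around 25 pixels on a
  64-pixel field of view the higher-order channels extend past the image
  border, and truncation visibly breaks their mutual orthogonality; this
  is a property of the geometry, not an implementation artifact, and the
  CHO's whitening makes it harmless.
* Grid searches (LG width and channel count; AE channel count and
  learning rate) select by validation AUC.  The convolutional-LG width
  grid spans 10-50 pixels by default.

## Desk-scale study sizes

The full study sizes (30,000 / 5,000 / 5,000 training / channel-covariance
/ test pairs; 500 AE epochs) are the package defaults in
`study_config()`.  The bundled acceptance script and the acceptance tests
run a *desk-scale* version of the domain-shift study chosen once for a
single-CPU workstation: 12,000 training pairs per system width (shared
background scenes across the widths), 1,500 validation pairs (which also
supply the channel covariance, as the domain-shift protocol reserves no
dedicated covariance split), and 2,500 test pairs.  Autoencoders train on
8,001-pair subsets for 100 epochs, with the candidate grid spanning
learning rates {1e-3, 5e-3} at 20 channels and selection by source-system
validation AUC; the amalgamated source draws even thirds from the width
datasets.  The learning-rate grid omits the `1e-5` rate that suits
unscaled-intensity images: on [0, 1]-rescaled data its total step budget
at desk-scale epoch counts cannot move the weights off their `5e-6`-scale
initialization.  The Gaussian-noise conventional-AE bound runs at 2,500
training pairs with that study's rate `1e-5` and 200 epochs.

Down-scaling costs accuracy in two places.  HO-Direct inverts a
4096-dimensional sample covariance, whose smallest-eigenvalue noise makes
the template improve only slowly with the image count, so desk-scale
HO-Direct AUCs sit one to several hundredths below their full-scale
counterparts, with the mismatched-width transfer cells affected most.
The AE channels are the other sensitive piece: with fewer epochs and
images (and only two random initializations via the grid), the learned
channels carry residual initialization noise that matters little on the
training system but depresses cross-system transfer.  The fixed-channel
and low-dimensional methods (conv-LG, PLS, NPWMF) are essentially
converged at these sizes.  The desk-scale sizes were chosen for the
compute budget and are not re-tuned per run.

## Known limitations

* HO-CMD requires the Gaussian noise model; for the mixed model (whose
  per-image rescaling has no closed-form noise covariance) it errors
  rather than approximating.
* The nonlinear (ReLU/untied) and label-decoder AE variants, SVD
  channels, ideal-observer approximations, and convolutional AEs are out
  of scope.
* The binormal fit is a moment fit; heavy-tailed score distributions
  would bias it relative to proper ROC maximum likelihood (the empirical
  AUC is reported alongside to flag such cases).
* Serialization uses R-native RDS containers with a version tag rather
  than HDF5 (no HDF5 R bindings are declared as dependencies); the layout
  mirrors the documented named-array container.
```
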