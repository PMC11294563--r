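---
title: "Modeling dimerization-driven cooperative membrane binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dimerization-driven cooperative membrane binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(par2coop)
```

## The problem

Peripheral membrane proteins that oligomerize can bind membranes
cooperatively: a dimer held by two membrane anchors dissociates far more
slowly than a monomer, so the effective affinity rises with concentration.
For the *C. elegans* polarity protein PAR-2 — which dimerizes through its
RING domain and binds the plasma membrane through basic–hydrophobic
motifs — this cooperativity amplifies posterior membrane accumulation
during polarization. `par2coop` implements the quantitative machinery for
studying this mechanism: an equilibrium thermodynamic model, its kinetic
extension, the cooperativity statistic used on rundown data, model
fitting, a SEC-MALS dimer model, and the image quantifier that produces
the membrane/cytoplasm measurements in the first place. Synthetic-data
generators stand in for embryo data throughout.

## The cooperativity score

For protein exchanging between cytoplasm ($c$) and membrane ($m$) with
binding/unbinding rates whose ratio varies as $\beta m^{\lambda}$ over the
observed range, the equilibrium relation is $m = \beta c^{\alpha}$ with
$\alpha = 1/(1-\lambda)$. We estimate $\alpha$ by OLS on
$\log_{10} m$ vs $\log_{10} c$ across embryos spanning a range of
expression (graded RNAi, "rundown"). $\alpha$ is dimensionless and
invariant to rescaling either axis, so raw-intensity data score
identically to calibrated data. Uncertainty comes from bootstrap
resampling of embryos (default 10,000 replicates, percentile 95% CIs).
Polarized and uniform embryos are pooled by default, matching how the
rundown panels treat them.

## Equilibrium model

Four species — cytoplasmic and membrane-bound monomers and dimers — with
the membrane treated as a slab of thickness $a$ (the protein diameter,
default 5 nm). Totals obey
$c_{\mathrm{tot}} = c_c + a\psi c_m$ (and $+\,a\phi c_n$ with an internal
membrane compartment), where $\psi$ is the membrane surface-to-volume
ratio. Equilibrium equates effective chemical potentials whose
concentration-dependent part is
$\ln c - \tfrac12 \ln D(c)$ with
$D(c) = 1 + 4c/K_D^{\dim} + \sqrt{1 + 8c/K_D^{\dim}}$; the reference
constants are compartment-independent and cancel.

Two implementation choices matter:

* **Reduced activity = monomer concentration.** We normalize the activity
  $c\,e^{-\frac12 \ln D(c)}$ by its dilute limit ($D(0)=2$), giving
  $c\sqrt{2/D(c)}$ — which is algebraically *identical* to the mass-action
  monomer concentration $c_1(c) = 2c/(1+\sqrt{1+8c/K})$. Equilibrium is
  then simply $c_1(c_c) = K_D^{\mathrm{mem}} c_1(c_m)$, and the activity
  inverts in closed form, $c = c_1 + 2c_1^2/K_D^{\dim}$. The
  normalization constant cancels in every equilibrium condition; tests
  verify the solver against a brute-force bisection on the raw chemical
  potentials.
* **Root finding.** Only the conservation law needs numerics: bracketed
  root finding on $\log_{10} c_c$ over
  $[\log_{10} c_{\mathrm{tot}} - 12,\ \log_{10} c_{\mathrm{tot}}]$
  (relative tolerance $10^{-10}$), guaranteed to converge because total
  bound protein is strictly increasing in $c_c$. `c_tot = 0` returns an
  all-zero state rather than erroring, which keeps parameter sweeps
  clean.
* **Numerical stability.** $c_1$ and $c_2$ use the forms
  $2c/(1+s)$ and $8c^2/(K(1+s)^2)$ with $s=\sqrt{1+8c/K}$; the textbook
  $\tfrac{K}{4}(s-1)$ form loses six digits of the mass-action invariant
  in the dilute regime.

Model cooperativity (`score_model()`) solves equilibria across a total
sweep of 20 log-spaced values from 27 to 0.27 nM
($\psi = 0.174\,\mu m^{-1}$) and regresses the log pairs. The landscape
over $(K_D^{\dim}, K_D^{\mathrm{mem}})$ is bounded by $1 \le \alpha \le 2$
for this two-state model and is unimodal in $K_D^{\dim}$: binding is
linear when dimerization is negligible *or* saturating, and cooperative
in between.

```{r landscape}
score_model(kd_dim = 1, kd_mem = 10^-2.43)      # dimerization off
score_model(kd_dim = 425e-9, kd_mem = 10^-2.43) # intermediate affinity
```

### Which surface ratio where

Two values of $\psi$ appear in different contexts and are deliberately
explicit parameters: cooperativity scoring uses
$\psi = 0.174\,\mu m^{-1}$ (whole plasma membrane), while the
three-compartment equilibrium and kinetic simulations use
$\psi = \phi = 0.087\,\mu m^{-1}$ (posterior-half availability). Defaults
follow the context; sweeps never silently switch.

## Fitting rundown data

Raw-unit datasets are first normalized: one multiplicative factor to both
channels so the reference subset (wild-type polarized) has a mean
cytoplasmic concentration of 10.4 nM, and the membrane channel divided by
$a$ to express per-area signal as slab molarity. The division-by-$a$
convention is a documented choice; the recovery experiments rely only on
internally consistent synthetic data, not on the absolute membrane scale.

`fit_joint()` minimizes summed squared residuals of
$\log_{10} c_m$ (data span about two decades, so log residuals weight the
cloud evenly) over per-genotype $K_D^{\dim}$ and one shared
$K_D^{\mathrm{mem}}$, by Nelder–Mead in log-parameter space from 8
deterministic quasi-random starts over
$K_D^{\dim} \in [1\,\mathrm{nM}, 100\,\mu\mathrm{M}]$,
$K_D^{\mathrm{mem}} \in [10^{-5}, 1]$; ties break toward the lowest
wild-type $K_D^{\dim}$ and all starts are reported. The wild-type
$K_D^{\dim}$ can be constrained to an independently measured value
(358 nM). Bootstrap refits resample embryos within genotype and compute
fold-changes within each replicate, so the fold-change CI respects the
correlation between the genotype estimates.

With the generator's study conditions (40 embryos/genotype, depletion
spanning 0.01–1 of baseline, 10% lognormal channel noise), recovery is
unbiased with median $|\log_{10}|$ error below 0.15 across a 100×-wide
affinity range; noiseless data are recovered exactly.

## Kinetic model and trapping

Transition-state theory gives
$k_{\mathrm{on}} = \tilde\Lambda/\sqrt{D(c_c)}$,
$k_{\mathrm{off},m} = \tilde\Lambda K_D^{\mathrm{mem}}/\sqrt{D(c_m)}$
(and likewise for internal membranes with $K_D^{\mathrm{int}}$). These
satisfy detailed balance against the equilibrium model identically —
tested to $10^{-10}$ over 1000 random parameter draws, the key
consistency check between the two modules. Here the *unnormalized*
$1/\sqrt{D}$ appears, exactly as in the calibration
$\tilde\Lambda = k_{\mathrm{off}}\sqrt{D(c_m)}/K_D^{\mathrm{mem}}$; any
common factor would cancel between on- and off-rates anyway.

```{r lambda}
calibrate_lambda(0.0073, 47.6e-6, 358e-9, 10^-2.43)
```

$\tilde\Lambda$ is a required argument, never a hidden default, because
two reference values coexist: the off-rate calibration gives 46.4 M/s
while the redistribution simulations use 4 M/s (`lambda_presets()`
provides both). Since $\tilde\Lambda$ only sets the global clock (the
trajectory under $2\tilde\Lambda$ is the trajectory under
$t \mapsto t/2$, an exact property test), the choice rescales time
without changing which states are visited.

Symmetry breaking is modeled as a parameter switch: equilibrate with
$K_D^{\mathrm{mem}} = 1$ (plasma membrane blocked by aPAR activity),
then drop $K_D^{\mathrm{mem}}$ at $t=0$ and integrate the
three-compartment ODEs (`deSolve::lsodar`, rtol $10^{-8}$, atol
$10^{-15}$ M, log-spaced output to $t_{\mathrm{end}} = 10^7$ s with a
root-function early exit once within $10^{-6}$ of the target
equilibrium). Stronger dimerization raises the equilibrium plasma
membrane fraction yet slows the approach so much that at ~600 s (the
NEBD landmark) the strong-dimer system still sits mostly on internal
membranes — kinetic trapping, the memory/responsiveness tradeoff.
Concentrations stay positive without log-space integration in every
regime exercised here; mass conservation along trajectories is tested at
integrator tolerance.

## SEC-MALS dimer model

A monomer–dimer mixture has weight-average molecular weight
$M_W = (n_m W_m^2 + n_d W_d^2)/(n_m W_m + n_d W_d)$ with molecule
numbers from the same mass-action partition ($W_m = 9.23474$ kDa for the
RING construct). $M_W$ depends on concentration only through
$c/K_D^{\dim}$ — an exact scale collapse, which is why a free
column-dilution factor is *off* by default in `fit_kdim()`: it is fully
confounded with $K_D^{\dim}$ except through curve shape, so fits report
input-concentration affinity unless the user opts in.

## The image quantifier

The forward model for a straightened cortex (50 pixels across the
membrane × arc length) is the tensor-product sum
$c_{\mathrm{cyt}} \otimes s_{\mathrm{cyt}} + c_{\mathrm{mem}} \otimes
s_{\mathrm{mem}}$, with $c_{\mathrm{cyt}}$ uniform per image. Training is
two-stage gradient descent (adaptive moments, learning rate 0.005,
convergence when the running best loss improves by less than $10^{-6}$
relatively over 100 iterations): first $s_{\mathrm{cyt}}$ on
cytoplasm-only images, then $s_{\mathrm{mem}}$ on polarized images with
$s_{\mathrm{cyt}}$ frozen — the along-arc contrast of polarized membranes
is what separates the two profiles, so contrast-free training sets are
rejected as unidentifiable. Profiles start from the conventional shapes
(error function and Gaussian, centre $H/2$, width 2 px) but are free to
become arbitrary, including asymmetric tails from out-of-focus membrane
signal.

Choices the underlying method leaves open, resolved here:

* **Scale degeneracy** between profiles and concentrations is broken by
  fixing the $s_{\mathrm{cyt}}$ interior plateau (mean of the 5 innermost
  pixels) to 1 and $\max(s_{\mathrm{mem}}) = 1$, so concentrations read
  in raw intensity units until `calibrate_units()` supplies the
  membrane-to-cytoplasm conversion
  $c = (C - C')/(\psi(M' - M))$ from an optogenetic redistribution pair.
* **Quantification is linear least squares.** With profiles fixed the
  problem is linear; the closed-form solution (membrane amplitudes
  profiled out per column, then one scalar for $c_{\mathrm{cyt}}$) is the
  default, and the gradient-descent path is retained and tested to agree
  to $10^{-6}$ — a live oracle for the optimizer used in training.
  Negative estimates are flagged, never clipped.
* **Geometry conventions.** Row 1 is extracellular, row $H$ interior; arc
  position 1 is the anterior pole and the posterior pole sits at $L/2$
  with wraparound. "Posterior-most 20%" means the 20% of arc centred on
  the posterior pole; the peak metric is the best mean over any 20%
  circular window; the local M:C profile uses an optional rolling mean
  (default width 21 px).

FRAP series are normalized control-ROI-first (cancelling shared drift
exactly), then rescaled between the 10-frame prebleach mean and the
designated first postbleach frame (~1 s after bleaching, to skip the fast
initial phase), giving 0 at that frame and 1 at full recovery.

## What the generators emulate — and what they do not

`gen_rundown()` draws per-embryo totals log-uniformly over 0.01–1 of an
undepleted baseline (60 nM, placing wild-type cytoplasm near 11 nM),
solves the equilibrium model, and applies independent multiplicative
lognormal noise (CV 10%) per channel — positive support matching the
log-space analysis. Images get additive Gaussian noise at 1% of the
cytoplasmic plateau; polarized membranes follow a smooth periodic step.
The study does not report its measurement noise magnitudes, so these
defaults are field-plausible choices fixed once, not calibrated to the
source data. Consequently, passing tests demonstrate correctness of the
estimators under known generative conditions — recovery, invariance,
coverage — not agreement with any embryo measurement; biological
features the generators omit (spatially varying cytoplasm,
autofluorescence, segmentation error, embryo-to-embryo parameter
variation) are exactly the features the real pipeline's upstream
corrections handle.

## Problem sizes and limitations

Routine runs use deliberately compact sizes — 20-point sweeps, 1000-draw
property tests, 40-embryo fits, 50×60–80 px images, bootstrap counts of
200–10,000 depending on stage — chosen so the full synthetic pipeline
completes in well under a minute while leaving every statistical check
comfortably powered. Known limitations: no spatial (reaction–diffusion)
dynamics and no symmetry-breaking mechanism — the equilibrium model
cannot polarize by construction, and the kinetic module models
polarization onset only as a membrane-availability switch; no
errors-in-variables regression (the score uses plain OLS, as the original
procedure does); the membrane-unit-to-slab-molarity mapping rests on the
division-by-$a$ convention; and the SEC-MALS fit takes no position on
column dilution.
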