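---
title: "memphys: models, synthetic world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memphys: models, synthetic world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memphys)
```

## Scope

`memphys` implements the computational chain of a multi-technique
membrane-biophysics study of a small amphipathic molecule in
phospholipid model membranes: DSC transition analysis and partial phase
diagrams, SAXD/WAXD mesophase indexing and Gaussian electron-density
model fitting, ³¹P powder-lineshape phase classification, NOESY
cross-relaxation depth localisation, and trajectory density/contact
analysis. Every stage is driven by a seeded synthetic-data generator
standing in for instrument data, which is what makes the chain testable
end to end. Running a molecular-dynamics engine, force-field topology
construction, raw FID processing and 2-D peak picking are out of scope:
the package starts from the *tables and traces* those tools produce.

## DSC

**Model.** Each endotherm is a two-state van't Hoff excess heat
capacity, $C_p^{xs}(T) = \Delta H\,\Delta H_{vH}/(RT^2)\cdot K/(1+K)^2$
with $K = \exp[-(\Delta H_{vH}/R)(1/T - 1/T_m)]$, $T$ in kelvin
internally and °C at every interface. This is the minimal model with the
right phenomenology: it integrates exactly to $\Delta H$ and its width
is set by the van't Hoff enthalpy (cooperativity), with
$\Delta H_{vH} \ge \Delta H$ enforced (a cooperative unit cannot be
smaller than one molecule). Default generator scenarios use
$\Delta H_{vH} = 600$–$800$ kcal/mol, giving the ~1 °C transition widths
typical of pure phospholipid MLVs at 1 °C/min.

**Baseline.** A low-order polynomial (linear by default) is fitted to
points *outside* user-declared exclusion windows and subtracted
everywhere, so inside a window the baseline is interpolated from the
flanks, never fitted to peak points. Windows covering more than 90% of
the grid are refused.

**Onset/end vs integration support.** Onset and end temperatures follow
the calorimetric convention: steepest leading/trailing tangents
intersected with the zero baseline. The enthalpy, however, is integrated
over a deterministic support of ±4 FWHM around the apex (clipped at
inter-peak minima), not between onset and end: for a two-state peak the
tangent intersections sit at ≈ ±3 on the logistic axis and strict
onset-to-end truncation loses ~9% of the area, which would be a
systematic bias far larger than the few-percent recovery the analysis
otherwise achieves. Beyond 4 FWHM the two-state tails are $e^{-14}$;
integrating the *raw* (unsmoothed) trace keeps the noise contribution
unbiased.

**Detection.** Peaks are local maxima of a lightly smoothed trace with
topographic prominence above 5× a robust noise estimate
(median-absolute-deviation of first differences), a threshold the
instrument data never specifies and which is therefore a config value.

**Phase diagrams.** Molar ratios $R{:}1$ become additive mole fraction
$x = 1/(1+R)$. Fluid immiscibility (the additive saturating the fluid
phase) appears as composition-independent boundaries; since the original
analyses eyeball this, a reproducible rule is used: the earliest
composition from which both onset and end stay within `plateau_tol`
(default 0.5 °C, the order of replicate scatter) *and* whose preceding
composition deviates by more than that. An everywhere-flat diagram is
reported as a plateau from the first composition; a strictly sloped one
is not a plateau.

## SAXD/WAXD

**Electron-density model.** The bilayer contrast profile is two positive
Gaussians at $\pm z_H$ (width $\sigma_H$, electron-dense headgroups)
plus one negative Gaussian at the centre (width $\sigma_C$, amplitude
ratio $\rho_r < 0$, the terminal-methyl trough). Its analytic Fourier
transform is the form factor; intensity is
$S(q)\,|F(q)|^2/q^2$ (powder Lorentz factor), $q = 2\pi s$,
$s = 2\sin\theta/\lambda$ — so lamellar Bragg orders sit at $s = h/d$
with **no** $2\pi$. All SAXD lengths are Å; trajectory lengths are nm,
converted only at reporting.

**Structure factor.** For $N$ correlated bilayers
$S = N + 2\sum_k (N-k)\cos(kqd)$, with modified-Caillé damping
$\exp[-(qd/2\pi)^2\eta\,\gamma_E]\,(\pi k)^{-(qd/2\pi)^2\eta}$ per term
when the bending-fluctuation parameter $\eta > 0$. Because a
monodisperse finite stack shows sinc²-type fringes that real MLV
samples never do (domain sizes are polydisperse), $S$ is averaged over a
uniform window of lamellae counts (±15% of $N$ by default). This
tapers the cosine coefficients, suppresses the fringes to below the
weakest Bragg order, and leaves the peak positions untouched. The exact
structure-factor parameterisation of the original global analysis
software is unpublished; this Caillé-type choice is a documented
stand-in with the same parameter meanings, and σ_H is kept free in the
fit because the bilayer-thickness formula requires it even though
structural tables typically print σ_C only.

**Amplitude ratio.** No printed value exists for the methyl-trough to
headgroup amplitude ratio; the default $\rho_r = -1$ (equal magnitude)
is a conventional starting point for PC bilayers and is a flagged
config value, not a fitted constant.

**Fit.** Nonlinear least squares over $(d, z_H, \sigma_H, \sigma_C,
\rho_r, \eta)$ with the linear scale profiled out analytically,
relative (1/I, floored) weighting so the first order does not drown the
rest, multi-start from perturbed initials, a small integer grid over
$N$ (the cosine sum needs integer $N$, so it is not a continuous
optimiser coordinate), and a smooth barrier keeping
$d_B = 2(z_H + 2\sigma_H) < d$ (a non-negative water layer). Derived
quantities are exact arithmetic: $d_{HH} = 2z_H$,
$d_B = 2(z_H+2\sigma_H)$, $d_w = d - d_B$, and $d_w + d_B = d$ holds
identically on every fit output.

**Indexing.** Greedy order assignment tests each peak's ratio against
the *previously assigned* peak, not against the first order: printed
gel-phase spacings deviate up to ~4.6% from integer ratios against the
first order but only ~2.6% between neighbours, and the acceptance
tolerance is 3%. The first peak may be assigned order 1–3 (series whose
first order fell outside the window still index); ties resolve toward
the smallest order sum, which is what makes the greedy result match an
exhaustive search over $h \in \{1..6\}$. Hexagonal indexing fits
$s_{hk} = \sqrt{h^2+hk+k^2}/d_{10}$ with peaks assigned to the
canonical first reflections (10), (11), (20), (21) *in order, without
skipping*: an H<sub>II</sub> claim rests on the $1 : 1/\sqrt3$ pair, so
a bare $1 : 1/2$ doublet scores badly against the hexagonal law and
falls to the lamellar assignment — the intended resolution of that
degeneracy.

**WAXD packing.** Sharp-vs-broad and singlet-vs-shoulder decisions use
config thresholds (FWHM in $s$ above 0.012 Å⁻¹ = fluid hump; a
two-Gaussian fit that improves RSS ≥ 5× with a ≥15% amplitude second
component ≥ 0.002 Å⁻¹ away = resolvable shoulder, i.e. the tilted-chain
gel packing). These encode the field's qualitative reading of
chain-packing reflections into reproducible rules.

## ³¹P lineshapes

The axially symmetric CSA powder pattern is built from the orientation
law $\delta(\theta) = \delta_{iso} - (\Delta\sigma/3)(3\cos^2\theta-1)$
averaged over a 1° grid with $\sin\theta$ weights, then convolved with
a Lorentzian of the stated line broadening (100 Hz default) and area
normalised. Two deliberate conventions:

* The powder span equals $|\Delta\sigma|$ exactly (edges at
  $\delta_{iso} + \Delta\sigma/3$ and $\delta_{iso} - 2\Delta\sigma/3$).
  A formulation with a $\Delta/2$ prefactor would span $3|\Delta|/2$
  and contradict the span the construction is meant to have.
* The sign is mapped so that the physical phosphodiester case
  ($\Delta\sigma < 0$ in bilayers) puts the intense perpendicular edge
  at high field (small ppm) with the parallel shoulder at low field —
  the classic bilayer signature. Fast lateral diffusion around
  H<sub>II</sub> cylinders averages the tensor to $-\Delta\sigma/2$:
  skew reverses and the span halves.

Classification uses the *sign of the lineshape skewness* about the
first moment rather than absolute edge positions, making it robust to
referencing offsets; two resolvable apex components (≥20% prominence,
≥5 ppm apart) signal phase coexistence; SNR below 5 flags the call
indeterminate. Note the classifier genuinely cannot distinguish a
hypothetical positive-Δσ lamellar pattern from a hexagonal one — they
are the same lineshape — so round-trip guarantees hold for the physical
negative-Δσ family. Edge positions are read at 5% fractional height;
because the Lorentzian tails push those crossings outward by an
*absolute* amount, span *ratios* are checked on lightly broadened
(20 Hz) patterns.

## NOESY localisation

Rates follow the single-mixing-time estimator
$\sigma_{ij} = A_{ij}/(A_{jj}\,t_m)$ — the only reading of the
published formula that yields s⁻¹ — normalised by the lipid group's
diagonal volume. This makes $\sigma$ exactly invariant to a global
volume rescale and reciprocal in $t_m$, both of which are tested as
identities. The location profile ranks lipid groups per ligand proton
by descending $\sigma$; ties break toward the polar interface and are
reported as tied. Numeric cross-relaxation values for the original
system were never printed, so only *rankings* are assertable against
the study's narrative.

## Trajectory analysis

Density profiles histogram group mass into uniform z-bins (the
requested 0.1 nm width is adjusted to tile the box exactly, which makes
mass conservation an identity, not an approximation) and convert
Da·nm⁻³ to kg·m⁻³. Contacts are *atom pairs* within the cutoff under
the 3-D minimum-image convention — the reproducible reading of
"number of contacts" between atom selections; whether the original
tool counted pairs or minimum-distance events is not resolvable, and
pair counting is verified exactly against a brute-force $O(N^2)$
oracle. Concordance between techniques is the Spearman correlation
between the NOESY rate ranking and the ranking by overlap integral
(integral of the pointwise minimum of unit-normalised profiles).

## The synthetic world, and what a green test establishes

One `depth_distribution` object drives both the NOESY volume generator
and the trajectory generator: each group is a Gaussian in z (bilayer
centre at 0). The reference distribution
(`popc_des_depth_distribution()`) places the seven canonical PC groups
from terminal methyl (0 nm) to choline gamma (2.0 nm) with the two
usable ligand proton groups centred at the C2/C3 depth (1.40/1.42 nm)
— the study's headline localisation — at reduced atom counts (a
~90-atom desk-scale stand-in for a 64-lipid leaflet). Cross-peak
volumes are mixing-time × proton-count × Gaussian-overlap with
multiplicative noise: a *monotone contact-to-volume map*, deliberately
not a relaxation-matrix simulation. Consequently a green round-trip
establishes that the analysis inverts the stated generative model — it
does not establish spin-diffusion robustness, instrument artefacts
beyond additive Gaussian noise, or force-field realism. The same
caveat applies to each stage: DSC traces are exact two-state peaks on a
linear baseline; SAXD patterns come from the same model family the fit
assumes (the round-trip validates the optimiser and parameterisation,
not the model's adequacy for real bilayers).

Seeds are mandatory arguments everywhere; there is no hidden global
RNG state (generators save and restore `.Random.seed`), and every
generator is bit-identical given its seed.

## Numerical choices and degenerate inputs

* Temperatures: °C at interfaces, kelvin inside; gas constant in
  kcal mol⁻¹ K⁻¹.
* Sub-grid peak positions by parabolic apex interpolation; FWHM by
  linear interpolation of half-height crossings.
* Robust noise: `mad(diff(y))/sqrt(2)` — insensitive to smooth signal.
* Indexing tolerance 3% (printed gel spacings deviate ~2–3% from exact
  ratios); classification requires the winning law to cover *all*
  picked peaks.
* Peak picking discards any maximum within 0.002 Å⁻¹ of a taller one
  (satellite exclusion), which removes residual stacking fringes.
* Degenerate inputs error early with typed conditions
  (`memphys_invalid_grid`, `memphys_negative_water`,
  `memphys_missing_diagonal`, `memphys_dependency_error`, …), and
  boundary cases (zero water layer, empty ligand list, windows covering
  the grid) are tests, not surprises.

## Known limitations

* The Caillé-type structure factor is a stand-in for the original
  (unpublished) global-analysis parameterisation; σ_H defaults cannot
  be checked against a printed value (structural tables imply
  σ_H = 3.0 Å via d_B but do not print it).
* The ³¹P simulator handles axially symmetric tensors only; no
  magic-angle-spinning sidebands.
* NOESY modelling is not a relaxation matrix; spin diffusion and
  overlapping resonances (the reason two ligand protons are absent from
  the original tables) are outside the model — absent columns are
  simply permitted.
* Trajectory I/O is restricted to multi-frame XYZ and a minimal GRO
  dialect; binary trajectory formats would need an external adapter.
* The "reversal effect" of boundary temperatures at low additive
  content is mentioned in the source narrative but never defined; no
  operation encodes it.
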