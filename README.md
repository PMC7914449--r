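# memphys

Membrane biophysics of lipid bilayers in R: differential scanning
calorimetry (DSC), small- and wide-angle X-ray diffraction (SAXD/WAXD),
³¹P-NMR powder lineshapes, ¹H-NOESY cross-relaxation localisation, and
trajectory density/contact analysis — with seeded synthetic-data
generators for every input type, so the whole chain is testable without
instrument data.

## Who this is for

Membrane biophysicists characterising how a small amphipathic molecule
(a drug, hormone, vitamin, …) perturbs phospholipid model membranes:
does it fluidise the bilayer, does it saturate (fluid immiscibility),
does it swell the interlamellar water layer, does it promote the
inverted-hexagonal (H<sub>II</sub>) phase, and *where* in the bilayer
does it sit?

## The models at the core

**DSC.** Endotherms are modelled as two-state van't Hoff excess heat
capacity peaks,

    Cp_xs(T) = ΔH·ΔH_vH / (R T²) · K/(1+K)²,   K = exp[−(ΔH_vH/R)(1/T − 1/Tm)]

which integrate exactly to ΔH. Onset/end temperatures come from the
calorimetric tangent-intersection convention; composition series are
folded into partial phase diagrams with a plateau detector for fluid
immiscibility.

**SAXD.** Multilamellar patterns are described by a symmetric
electron-density profile of two headgroup Gaussians at ±z<sub>H</sub>
(width σ<sub>H</sub>) and a negative terminal-methyl trough (width
σ<sub>C</sub>), with a Caillé-type structure factor for stacking
disorder, in the s = 2 sinθ/λ convention (Bragg orders at s = h/d).
Fitted parameters yield the headgroup peak–peak distance
d<sub>HH</sub> = 2z<sub>H</sub>, the bilayer thickness
d<sub>B</sub> = 2(z<sub>H</sub> + 2σ<sub>H</sub>) and the water layer
d<sub>w</sub> = d − d<sub>B</sub>. Lamellar indexing follows the
1 : 1/2 : 1/3 spacing law, H<sub>II</sub> indexing the 2-D hexagonal
1 : 1/√3 : 1/2 : 1/√7 law.

**³¹P-NMR.** Axially symmetric chemical-shift-anisotropy powder
patterns, δ(θ) = δ_iso − (Δσ/3)(3cos²θ − 1), with the H<sub>II</sub>
phase taking the motionally averaged anisotropy −Δσ/2 (skew reverses,
span halves). Phases are classified from the lineshape skew;
coexistence from resolvable apex components.

**NOESY.** Single-mixing-time cross-relaxation rates
σ<sub>ij</sub> = A<sub>ij</sub>/(A<sub>jj</sub>·t<sub>m</sub>) rank the
lipid segments a ligand proton touches, giving its modal depth in the
bilayer.

**Trajectories.** Per-group mass density profiles along the bilayer
normal (kg·m⁻³, terminal-methyl plane at z = 0) and atom-pair contact
counts within a cutoff (0.5 nm default) under the minimum-image
convention.

## Worked example

```r
library(memphys)

## a PE-like scan: gel-to-fluid at 35 degC, fluid-to-HII at 62 degC
p  <- thermogram_params(list(list(Tm = 35, dH = 7.1094, dH_vH = 600),
                             list(Tm = 62, dH = 0.5,    dH_vH = 800)),
                        baseline_slope = 0.002, baseline_intercept = 0.05,
                        noise_sd = 0.01, t_range = c(10, 70),
                        t_step = 0.05, seed = 7)
tg <- gen_thermogram(p)
find_transitions(subtract_baseline(tg, list(c(30, 40), c(58, 66))))
#> Tmax 35.00  onset 34.04  end 35.98  dH 7.106  fwhm 1.13
#> Tmax 62.01  onset 61.18  end 62.86  dH 0.502  fwhm 1.02
```

The two endotherms are recovered at their generating temperatures; the
main enthalpy (7.106 kcal/mol) reproduces the generator input 7.1094 to
0.05%.

```r
## a PC-like multilamellar pattern at d = 64 A and its model fit
pat <- gen_saxs_pattern(lamellar_model_params(64, 19.5, 3, 5.4),
                        seq(0.0075, 0.07, length.out = 600))
pick_peaks(pat)[, c("d", "height")]
#>        d    height
#> 63.98350 1841263.2      # order 1
#> 32.02017  510941.4      # order 2
#> 21.32352   17903.0      # order 3
fit_saxs(pat, lamellar_model_params(63, 20.2, 2.8, 5.8, -0.9, 20L, 0))
#> <lamellar_fit>
#>   d = 64.00 A, zH = 19.50 A, sigmaH = 3.00 A, sigmaC = 5.40 A
#>   dHH = 39.00 A, dB = 51.00 A, dw = 13.00 A (residual 9.2e-07)
```

The fit recovers the generating parameters and reports a 51.0 A bilayer
with a 13.0 A water layer — d<sub>w</sub> + d<sub>B</sub> = d holds
exactly on every fit.

A full simulated run (all stages plus a collated summary report):

```r
run_pipeline(list(seed = 11L, outdir = "memphys_run"))
```

or from the shell via the installed CLI script
(`system.file("cli/memphys", package = "memphys")`).

## Vignette

`vignettes/memphys-methods.Rmd` documents the models, the synthetic
world the generators state (and what a green test does *not*
establish), numerical choices, and known limitations.
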