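---
title: "Modelling a self-generated microfluidic drug-gradient spheroid screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a self-generated microfluidic drug-gradient spheroid screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradspheroid)
```

## The system being modelled

A pumpless microfluidic device screens drugs against arrays of multicellular
tumour spheroids. Spheroids sit in an 8 x 30 array of 150 um square
micro-wells at the bottom of a central channel. Two side channels run along
the array: drug solution is pipetted into the reservoirs of one side, plain
medium into the other, and the resulting hydrostatic pressure difference
drives a slow, symmetric cross-flow through arrays of high-resistance
connecting microchannels into the central channel and out through two
central reservoirs. Overflow ports in the central reservoirs clamp the
central fluid height, so the driving pressure decays only as slowly as the
side levels fall. The cross-flow carries compound over the array and, after
an establishment period, each *row* of wells sees a constant concentration
while concentration falls monotonically from the drug side (row 1) to the
medium side (row 8) -- one device therefore yields an 8-point
concentration-response curve.

Spheroid health is read out from images: the **shape factor**
$S_F = P^2 / (4 \pi A)$ (1 for a circular outline, rising as a spheroid
disaggregates and its boundary roughens) from daily brightfield frames, and
the end-point **viable fraction** $V_F = \mathrm{Area}_{FDA} /
\mathrm{Area}_{BF,\,pre-drug}$ from fluorescein-diacetate staining relative
to the brightfield area on the last day before drug incubation.

The package implements this whole chain as testable code: a hydraulic
network model of the device, a depth-averaged transport model of the
gradient, a ground-truthed synthetic image generator, the image analysis,
and the concentration-response statistics.

## Hydraulic network model

Open reservoirs are capacitors ($C = A/\rho g$), channels are resistors.
Rectangular-duct resistances use the exact Fourier series solution for
laminar flow,
$$R = \frac{12 \mu L}{w h^3}\Big[1 - \sum_{n\ \mathrm{odd}}
\frac{192\,h}{\pi^5 w\,n^5}\tanh\frac{n \pi w}{2h}\Big]^{-1},$$
rather than the common lubrication shortcut $12\mu L/(w h^3 (1-0.63 h/w))$:
the shortcut errs by ~14% for square cross-sections, while the truncated
series (25 odd terms, $n^{-5}$ convergence) is exact to numerical precision
at negligible cost, and the two agree in the shallow-channel limit that
dominates this device.

With four side reservoirs of capacitance $C_S$ discharging through a total
network resistance $R_T$ into height-clamped central reservoirs, the side
and central pressures follow

$$P(C_S) = \rho g\big(h_{S,in} - (h_{S,in} - h_{C,in})(1 -
e^{-t/(R_T 4 C_S)})\big), \qquad P(C_C) = \rho g\, h_{C,in}$$

with the overflow ports, and the corresponding two-exponential forms
without them, which equilibrate at the volume-weighted mean height
$(2A_S h_{S,in} + A_C h_{C,in})/(2A_S + A_C)$. The factor $4 C_S$ is the
parallel capacitance of the four side reservoirs. `simulate_network()`
integrates the per-reservoir volume balance directly (Heun stepping, 1 s
default step, automatic sub-stepping if a volume would go negative) on a
Kirchhoff conductance network, with the overflow port as a hard clamp:
excess central volume is routed to an `overflow_discharged` account. On the
symmetric six-reservoir topology the integration reproduces the closed
forms to well under 1%. Meniscus effects and evaporation are deliberately
outside the model -- they are exactly what the >10% reservoir-volume QC
rule (`qc_volume_check()`, strict inequality) screens for at the bench.

### Default geometry

The device concept fixes the well array (150 x 150 x 180 um wells, 35 um
side channels, 7 um connecting channels, 4/8 mm punched reservoirs) but not
the channel lengths, fill volumes or overflow height; those defaults were
set once, from the following sizing argument, and are ordinary config
parameters:

* side reservoirs: 8 mm diameter, 60 uL fill (initial height 1.19 mm);
* central reservoirs: 4 mm diameter with the overflow port at 0.15 mm, so
  the initial driving pressure is $\rho g \cdot 1.04\,\mathrm{mm} \approx
  10$ Pa;
* connecting arrays: 60 channels of 10 x 7 x 2000 um per side, giving
  $R_T \approx 7.4\times 10^{13}$ Pa s m$^{-3}$, a decay constant
  $R_T 4 C_S \approx 420$ h (the gradient-phase flow is quasi-steady over a
  day), and an initial cross-flow of $\approx 0.5$ uL/h;
* central flow layer 20 um deep, giving a transverse inflow velocity
  $v_s \approx 0.7$ um/s -- fast enough to sweep the channel width within
  the 1 h establishment window.

## Gradient transport model

The full 3D flow-and-transport problem is collapsed to a depth-averaged 2D
advection-diffusion equation over the central channel. The velocity field
is prescribed from the network flow $Q(t)$: transverse inflow enters
uniformly along both side walls and stagnates at the midline,
$v(y) = v_s(t)\,(1 - 2y/W)$, while the axial component grows linearly
towards the two outlets, $u(x) = (2 v_s/W)(x - L/2)$, with
$v_s(t) = Q(t)/(2 L h_c)$; the pair is exactly divergence-free, also
discretely. The side walls are Dirichlet rails (source concentration $c_0$
on the drug side, 0 on the medium side -- the connecting-channel arrays
continuously replenish both), and the short ends are advective outflow
boundaries.

The solver (`advection_diffusion_2d()`) is a conservative cell-centred
finite-volume scheme. Advection uses the hybrid face interpolation: central
differencing (second order) wherever the cell Peclet number $|u|\Delta/D$
is below 2, first-order upwinding beyond. At the default grid (20 um
transverse, 50 um axial) the device operates at cell Peclet < 1, so the
scheme is effectively central everywhere; a pure upwind scheme would add a
numerical diffusivity $u\Delta/2$ comparable to the smallest physical
diffusivities considered and visibly corrupt the low-diffusivity gradient
tails. Time stepping is explicit with a CFL safety factor of 0.4 on the
combined diffusive/advective limit; the effective step is reported in the
result. Closed-domain runs conserve mass to numerical precision (flux
form), fields respect the maximum principle, and the 1D steady profile
matches $c(x)/c_0 = (e^{Pe\,x/L} - 1)/(e^{Pe} - 1)$ to <1% for
$Pe \in \{0.1, 1, 10\}$.

Row summaries average the field over each well footprint with
cell-overlap weights (so results do not depend on how the grid aligns with
the wells), drop the first and last three columns (fringe region), and
report per-row means and within-row relative spreads. In this velocity
model the interior field is exactly axially uniform, so within-row spreads
after edge exclusion are at numerical-noise level; the real device's
residual spread comes from the discreteness of the connecting channels,
which the uniform-influx idealisation deliberately ignores.

### Diffusivities, and what "stable" means

Compound diffusivities come from the literature when known and otherwise
from a Stokes-Einstein-style power law $D = a\,\mathrm{MW}^{-1/3}$ with
$a = 5.2 \times 10^{-10}$, which places the screened panel (cisplatin 300
to docetaxel 808 g/mol) inside the $0.2$--$0.8\times 10^{-10}$ m$^2$/s
band used for the drug-transport simulations. The $-1/3$ exponent is the
hydrodynamic-radius scaling; it compresses the band relative to its
endpoints, which is acceptable because the band itself, not per-compound
precision, drives the protocol decisions.

Stability is operationalised as: after a 1 h establishment window, the
gradient is stable while row means remain strictly ordered *and* each row
mean stays within 10% of its establishment-snapshot value
(`stability_metrics()`). The establishment window and the 13 h protocol
(1 h establishment + 12 h incubation) are fixed by the assay design.

For the calcein validation configuration the package uses calcein's
literature aqueous diffusivity ($4.0\times 10^{-10}$ m$^2$/s). This choice
matters: at the MW-estimated $0.6\times 10^{-10}$ the transverse diffusion
time across the 1.6 mm channel is several hours, so no physically
reachable configuration of this device establishes the gradient within
1 h, whereas at the literature value the field settles well inside the
window and the simulated gradient then holds stable past 15 h with ~1%
row drift -- the observed device behaviour. The same analysis explains a
known, deliberate discrepancy: swept across the drug band
($0.2$--$0.8\times 10^{-10}$), the low-diffusivity endpoints are still
establishing at the 1 h snapshot, so their *per-row relative* 24 h drift
is far above the ~10% a full 3D model reports for the "gradient pattern"
change; the worst-case number the package reports is dominated by
late-establishing, near-zero far rows rather than by decay of an
established gradient. Normalising drift to the gradient amplitude instead
of each row's own mean would bring the figure down to the few-percent
range, but the per-row definition is kept because it is the stricter and
more interpretable criterion.

## Synthetic experiments

The generator fabricates everything the analysis consumes, with exact
ground truth:

* **Layouts** -- 8 x 30 x 150 um default (240 wells), 5 x 250 um variant
  for larger spheroids.
* **Seeding sizes** -- hydrostatic seeding loads fewer cells into wells far
  from the inlets, from *both* ends; diameters are Gaussian around a
  quadratic column profile (84 um at the ends, 64 um mid-array, sd 7 um,
  truncated at 30 um and 0.9x the well size), putting >90% of spheroids in
  the 50--100 um band.
* **Contours** -- star-convex perturbed circles
  $r(\theta) = R\,(1 + a f(\theta))$ with $f$ a seeded sum of Fourier modes
  (wavenumbers 2--7, $1/k$ decay, unit peak normalisation); polygon area
  and perimeter are exact ground truth for $S_F$ oracles.
* **Response** -- each well's effect is $e = c^{H}/(c^{H} + EC_{50,w}^{H})$
  with per-well $EC_{50,w}$ log-normally dispersed (CV 0.2) around the
  global truth and shifted so larger spheroids are somewhat more sensitive
  (the size dependence reported for cisplatin); effects ramp linearly over
  the 3 days following drug application. *Disaggregation* mode maps effect
  to boundary roughness plus a matching dead fraction (shape factor and
  viability move together); *shrinkage* mode maps it to radius loss with an
  intact contour (viability falls, shape factor stays flat) -- reproducing
  the two phenotypes that make the $S_F$/$V_F$ pair informative.
* **Rendering** -- 1 um/px crops; brightfield = dark disk on bright
  background, FDA = bright viable core scaled to the true viable area, PI =
  the dead rim, all with additive Gaussian noise (sd 0.03). Fluorescence
  channels exist on the final day only, matching end-point-only staining.

What the generator does *not* emulate: optics (PSF, vignetting, depth
effects), multicellular texture, dye kinetics, well-to-well optical
cross-talk, or real segmentation pathologies (debris, touching spheroids).
Passing tests therefore demonstrate correctness of the measurement and
inference chain on geometrically faithful inputs, not robustness to every
real-world imaging artefact.

## Image analysis choices

Segmentation is a global Otsu threshold (polarity-aware), hole filling,
largest connected component, with a minimum-area guard and a
minimum-contrast guard (Otsu always returns a split; thresholds that
merely bisect background noise are rejected as non-detections). The single
most consequential choice is the perimeter estimator: pixel-edge counting
overestimates perimeters by up to ~27% and would push a circle's $S_F$ to
~1.6, so contours are extracted sub-pixel -- the mask is Gaussian-smoothed
(sigma 1.5 px) and traced at the 0.5 level with marching squares
(`grDevices::contourLines`), and $S_F$ uses the shoelace area/perimeter of
that polygon. A rendered circle of radius 32 px measures $S_F \le 1.02$;
measured $S_F$ on rendered rough contours tracks the polygon oracle with
mean absolute error below 0.05.

Baselines for $V_F$ are fixed per well as the brightfield area on the last
imaged day before the drug day; FDA areas use the same segmentation on the
FDA channel (thresholded mask, not intensity-weighted). Size groups
(Group 1 = 0--75 um, Group 2 = 76--150 um, bounds inclusive) use the
baseline equivalent diameter $2\sqrt{A/\pi}$.

## Dose-response statistics

Each row contributes one point: mean, SEM ($sd/\sqrt{n}$, undefined for
$n = 1$) over retained spheroids. Curves are fitted with a four-parameter
logistic on $\log_{10}$ concentration via Levenberg-Marquardt
(`minpack.lm::nlsLM`), initialised from data quantiles, with the EC50
bounded to one decade beyond the tested range. Two guards refuse an EC50
rather than report a meaningless one: a flat-response guard (dynamic range
below twice the pooled SEM) and a bound-pinned guard (fitted EC50 at the
search boundary). SEMs are computed across spheroids within a device;
replicate devices, when present, should be aggregated a level up. No
multiple-testing machinery is included -- the package reports descriptive
fits and the $S_F$--$V_F$ Pearson correlation.

Parameter recovery under the defaults: over 20 seeded synthetic screens
(true EC50 100 uM, Hill 3, 24 spheroids/row), the median recovered-EC50
error is a few percent (the acceptance-style test bounds it at 15%), and
the disaggregation-mode $S_F$--$V_F$ correlation is $r \le -0.8$ while
shrinkage mode leaves $|r|$ small.

## Problem sizes and runtimes

The shipped tests and the acceptance script run the gradient twin at the
default grid (20 x 50 um; ~8,000 cells, explicit steps of ~0.5--2 s) for
horizons of 17--25 h of simulated time, the network model at 5--10 s
steps, and recovery studies over 20 seeds with 192 rendered wells each --
sized so the whole suite completes in tens of minutes on a single core
while keeping every quantitative claim at its stated tolerance.

## Known limitations

* The transport model is depth-averaged; wells are assumed
  concentration-equilibrated with the flow layer above them (vertical
  diffusion across 180 um takes minutes for the compounds considered).
* The uniform-influx idealisation removes the within-row fringe structure
  the edge-exclusion rule exists for; the rule is still applied, but its
  quantitative effect cannot be validated against this model.
* Reservoir depletion of compound is ignored (the cross-flow moves ~1% of
  a side reservoir per day).
* The MW-based diffusivity estimator is a band estimate, not a
  per-compound prediction; supply literature values via
  `compound(..., diffusion_coefficient = )` whenever they exist.
* Synthetic images are geometric, not photorealistic (see above).
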