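---
title: "A layered skin model for comparing gene-electrotransfer pulse protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A layered skin model for comparing gene-electrotransfer pulse protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinget)
```

## The problem

Gene electrotransfer (GET) to skin delivers plasmid DNA into cells by
electroporation: short high-voltage pulses applied through an electrode array
raise the local electric field above the threshold at which the cell membrane
becomes transiently permeable. Two competing requirements shape the design of
a pulse delivery protocol:

* **maximize the reversibly electroporated (RE) volume** — tissue exposed
  above the permeabilization threshold but below the lethal one, where cells
  take up DNA and survive;
* **minimize the irreversibly electroporated (IRE) volume** — tissue exposed
  above the lethal threshold, which counts as collateral damage.

`skinget` implements a stationary, sequential numerical model of skin
electroporation that lets these two volumes be computed for arbitrary
electrode-array commutation protocols, together with the protocol generators
themselves, device-envelope validation, and fluorescence-image quantification
of the resulting transfection.

## The tissue model

The skin is modeled as eight plane-parallel layers (stratum corneum,
epidermis, papillary dermis, upper vessel plexus, supply layer, deeper vessel
plexus, hypodermis, skeletal muscle), each with a diagonal, possibly
anisotropic conductivity tensor $\sigma_0 = \mathrm{diag}(\sigma_x, \sigma_y,
\sigma_z)$, an RE threshold $E_\mathrm{RE}$, an IRE threshold
$E_\mathrm{IRE}$, and a maximal conductivity increase factor
$f_\mathrm{max}$. `default_skin_stack()` carries the standard values; the
total stack depth is 27.35 mm. The stratum corneum dominates the problem: its
transverse conductivity is four orders of magnitude below the dermal layers,
and it is the layer whose conductivity rises up to 100-fold upon
electroporation.

### The conductivity law

Electroporation is modeled through a field-dependent conductivity: each
voxel's tensor is scaled by a sigmoid factor $f(E)$ rising from 1 around the
RE threshold to $f_\mathrm{max}$ at the IRE threshold. We use a logistic
curve centered at $E_\mathrm{mid} = (E_\mathrm{RE} + E_\mathrm{IRE})/2$ with
dimensionless steepness $k$ (default 10),

$$ f(E) = 1 + (f_\mathrm{max} - 1)\,
   \frac{L(E) - L(0)}{1 - L(0)}, \qquad
   L(E) = \frac{1}{1 + e^{-k (E - E_\mathrm{mid})/(E_\mathrm{IRE} -
   E_\mathrm{RE})}} . $$

The normalization by $L(0)$ is a deliberate design choice: a raw logistic
never quite reaches its plateaus, so $\sigma(0)$ would exceed $\sigma_0$ by
up to half a percent in the stratum corneum. The normalized form is
continuous, monotone, agrees with the raw logistic to $10^{-4}$ inside the
transition band, and satisfies the endpoint conditions $\sigma(0) = \sigma_0$
and $\sigma(E \to \infty) = f_\mathrm{max}\sigma_0$ exactly. The steepness
$k$ is not a measured tissue property; it controls how sharply the
conductivity transition is confined to the RE-to-IRE band and is exposed as
a parameter (`conductivity_law(steepness = )`).

The conductivity increase multiplies the whole (possibly anisotropic) tensor
by one scalar factor, since each layer carries a single maximal increase
value.

### Muscle anisotropy

Skeletal muscle electroporates more easily along its fibers: the RE threshold
is 80 V/cm for fields parallel to the fiber axis and 200 V/cm perpendicular
to it (the IRE threshold, 800 V/cm, is direction-independent as tabulated).
For intermediate angles $\theta$ between the field and the fiber axis we
interpolate elliptically,

$$ E_\mathrm{th}(\theta)^{-2} =
   \left(\frac{\cos\theta}{E_\parallel}\right)^2 +
   \left(\frac{\sin\theta}{E_\perp}\right)^2 , $$

the simplest smooth interpolation honoring both endpoints. The fiber axis is
taken along the direction of largest tabulated conductivity (y). Voxels with
zero field have no direction; they conservatively use the perpendicular
(higher) threshold, which only affects the degenerate zero-envelope case.

## Electrode arrays and protocols

Three applicator geometries are built by `build_array()`:

* `hex6` — six rod electrodes on a regular hexagon, opposite-center distance
  9 mm. The rod contact radius (1 mm) is derived from the two printed
  spacings: a regular hexagon with 9 mm diagonal has 4.5 mm sides, and a
  2.5 mm edge-to-edge gap between adjacent rods leaves a 2 mm rod diameter.
* `hex7` — the same hexagon plus a central electrode (classical applicator).
* `mea6` — the noninvasive multi-electrode array: a 3.5 mm hexagonal pin
  mesh. The pin contact radius is not tabulated; 0.35 mm is the package
  default and is configurable, and "3.5 mm apart" is read as center-to-center.

`generate_protocol()` produces the activation sequences: every pulsed pair
appears once in each polarity. The *classical* protocol pulses all 12
adjacent pairs of `hex7` (6 rim-rim + 6 rim-center; 24 steps), the
*alternative* protocol pulses the 6 rim pairs and then the 3 diagonals of
`hex6` (18 steps), and the MEA low-voltage protocol pulses the 6 rim pairs
(12 steps). Where the published step ordering diagrams leave room, we order
rim pairs counter-clockwise with immediate polarity reversal, then diagonals;
step order barely affects the stationary-sequential results (tested as a
property) but is preserved for protocol export. "Pulsing between two
opposite pairs of electrodes" admits two readings — single-electrode
diagonals or two-versus-two facing edges — both giving 6 diagonal steps; the
default is the simpler single-electrode reading and
`diagonal_mode = "paired"` selects the other.

Every step of both hexagonal protocols uses the same amplitude (560 V by
default). Whether the classical protocol should instead scale amplitude with
electrode distance is not settled; the amplitude is a config parameter, and
the comparison below holds for the common-amplitude reading.

## The field solver

For each activation step the stationary current-conservation equation
$\nabla\cdot(\sigma(|\mathbf E|)\nabla\varphi) = 0$ is solved on a structured
cell-centered finite-volume grid: uniform in x and y, graded in z so that
every layer interface is a grid line and the 20 µm stratum corneum is
resolved by at least two voxels. Face conductances use harmonic (series
half-cell) averaging, which is exact for layered media. Active electrodes are
Dirichlet contact discs on the skin surface (applied potential on the
boundary faces of the cells under the disc); all other outer boundaries are
insulating. Contact-gel and rod-penetration effects are not modeled.

Per-voxel fields are reconstructed flux-consistently: the current density
through each face divided by the adjacent cell's own conductivity gives that
cell's field at the face. This keeps the reconstruction exact across material
interfaces, where the field jumps but the normal current is continuous — a
face-gradient average would smear an O(1) error into every interface voxel.

The nonlinearity is resolved by damped Picard iteration within each step:
solve, recompute $|\mathbf E|$, update $\sigma$ toward
$\sigma(\max(E_\mathrm{env}, |\mathbf E|))$ with damping 0.5, repeat until
the largest relative change of $|\mathbf E|$ falls below $10^{-3}$ (default;
`solver_control()`). The damping is needed: the steep sigmoid makes undamped
iteration oscillate between the unelectroporated and electroporated branches.
The inner linear systems are symmetric positive definite and are solved by an
incomplete-Cholesky-preconditioned conjugate gradient implemented in compiled
code, warm-started across Picard iterations, to a $10^{-8}$ relative
residual — tight enough that the discrete current balance between source and
sink electrodes is conserved to well below 1%.

### Sequential electroporation memory

The protocol is modeled *sequentially*: after each step the per-voxel field
envelope $E_\mathrm{env} \leftarrow \max(E_\mathrm{env}, |\mathbf E|)$ is
updated and the conductivity persists at the envelope's value — a voxel
electroporated by any pulse stays electroporated for all later pulses. Within
a step the conductivity responds to the larger of the envelope and the
current field (self-consistency); across steps only the envelope persists.
The envelope direction at its maximum is stored for the muscle threshold.
Time-domain effects (membrane charging, pulse duration, repetition rate,
Joule heating) are outside the stationary model; pulse-train timing is
carried for protocol export and device validation only.

## Volume metrics

`classify_and_measure()` thresholds the final envelope voxel-wise: IRE where
$E_\mathrm{env} \ge E_\mathrm{IRE}$, RE where $E_\mathrm{th}(\theta) \le
E_\mathrm{env} < E_\mathrm{IRE}$. The headline RE volume excludes IRE voxels
(the two optimization criteria treat them as competing quantities); the
inclusive definition is reported alongside, since either could underlie a
published percentage. Comparisons use the classical protocol as baseline:

$$ \Delta_\mathrm{RE} = 100\,\frac{V_\mathrm{RE}^\mathrm{alt} -
   V_\mathrm{RE}^\mathrm{cls}}{V_\mathrm{RE}^\mathrm{cls}}, \qquad
   \Delta_\mathrm{IRE} = 100\,\frac{V_\mathrm{IRE}^\mathrm{cls} -
   V_\mathrm{IRE}^\mathrm{alt}}{V_\mathrm{IRE}^\mathrm{cls}} . $$

## Problem sizes and numerical choices

Grid presets (`build_grid(resolution = )`): `coarse` (31×31×25 ≈ 24k voxels)
for quick exploration and continuous testing, `default` (41×41×32 ≈ 54k) for
the reported comparisons, `fine` (61×61×46 ≈ 171k) for convergence checks.
These sizes are the package's choice of a resolution ladder for a desk-scale
reproduction; the published model does not disclose its mesh, domain extent,
or solver, so quantitative volume percentages carry a corresponding
uncertainty. Across the ladder, the IRE-volume reduction achieved by the
alternative protocol is robust in sign and brackets the published 15%
figure, and the absolute IRE volume changes by about 1% between the default
and fine grids. The RE comparison, by contrast, comes out in favor of the
*classical* protocol at every resolution when both protocols drive 560 V on
every step: the classical protocol's twelve extra center-rim steps add more
reversibly electroporated tissue than the alternative's six diagonal steps,
whose 560 V across the 9 mm diagonal produces only one to two hundred V/cm
at depth mid-array — below the 300 V/cm deep-layer RE threshold (a
spreading-resistance estimate for two 1 mm contacts gives the same order).
The published comparison reports the opposite sign (+8% for the
alternative); reproducing it may require the original model's mesh and
electrode-contact details, or a lower classical-protocol amplitude, which is
not stated. The amplitude is a config parameter so both readings can be
explored. The lateral domain extent (30 mm square for an 11 mm array) keeps
the boundary influence on the metrics below the percent level.

Degenerate inputs are handled explicitly: zero amplitude yields a zero
envelope and zero volumes; steps with no active electrode raise an error
(singular system); voxels whose disc electrode footprint is finer than the
grid fall back to the nearest surface cell so coarse grids remain usable.

## The synthetic-image generator

`synth_image()` emulates fluorescence stereomicroscope images of transfected
skin as Gaussian expression blobs over half-normal background noise,
deterministic under a seed. It reproduces what the quantification pipeline
(`quantify()`: thresholded area, mean intensity over the thresholded region,
and their product, the integrated density) consumes — not the optics of a
real stereomicroscope: no vignetting, no autofluorescence gradients, no
saturation. Passing tests therefore validate the arithmetic and its
invariants (threshold monotonicity, intensity-scale equivariance), not
biological image quality. The intensity threshold separating transfected
from non-transfected pixels is a user input applied identically to all
images of a comparison; no canonical value is assumed.

## Known limitations

* The model is stationary: pulse duration, repetition rate and number of
  pulses do not influence the computed volumes, only the field envelope of
  the activation pattern does.
* Electrode contact is ideal (equipotential discs); contact impedance enters
  only through the pre-pulse contact classifier, not the field solution.
* The conductivity-law steepness and the muscle-threshold interpolation are
  modeling choices, not measured properties; both are parameters.
* Reported volume percentages at desk-scale resolution are sensitive to the
  unpublished details of the original mesh and domain; treat them as
  order-of-magnitude reproductions anchored by the directional result.
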