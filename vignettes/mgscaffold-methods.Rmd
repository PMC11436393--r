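---
title: "Methods: synthetic micro-CT quantification of Mg scaffold degradation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic micro-CT quantification of Mg scaffold degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models, the
estimators, the numerical choices, and what the synthetic world does and
does not establish. Every empirical claim here is computed by the test
suite or the acceptance script; no numbers are asserted that the code does
not reproduce.

## 1. The degradation model

A magnesium strut corrodes by uniform recession of every exposed face at a
constant rate $k$ (mm/month per face). For a rectangular cross-section
$w \times h$ the remaining cross-sectional area fraction is

$$f(t) = \left(1 - \frac{2kt}{w}\right)_+ \left(1 - \frac{2kt}{h}\right)_+$$

and, because the strut is far longer than it is wide (end recession is
negligible), this is also the remaining **volume** fraction. For the square
strut ($w = h$) this collapses to $f(t) = (1 - t/T)^2$ with the complete
degradation period $T = w/(2k)$; the 50% period is
$t_{50} = T(1 - 1/\sqrt 2) \approx 0.293\,T$ in closed form. Scenario
curves are parameterized by the percent area loss at one month;
`k_from_loss_at_1M()` inverts $f(1)$ (closed form for the square, the
smaller quadratic root numerically for rectangles). `fit_T()` fits
$f(t) = \max(0, 1 - t/T)^2$ to observed ratios by bounded scalar least
squares (`stats::optimize` over $(10^{-6}, 50\,t_{\max})$, tolerance
$10^{-10}$).

Two fixed model-level facts serve as acceptance targets: with $T = 23.5$
months, $t_{50} = 6.88 \to 7$ months rounded; and among area losses of 5%,
7.5% and 10% at one month, the 7.5% scenario minimizes the squared
distance to the $T = 23.5$ curve at $t \in \{1, 6, 12, 18\}$. Note a
related ambiguity that the package deliberately exposes rather than
reconciles: the 7.5% scenario itself completes analytically at
$1/(1-\sqrt{0.925}) = 26.16$ months, not 23.5; `fit_T()` reports both the
fitted $T$ and the implied loss at one month so users see both numbers.

The time unit is the month throughout; no day-to-month conversion is
modelled (observations are supplied in months).

## 2. Scaffold geometry

`scaffold_design()` describes a stack of `n_rings` sinusoidal rings
(`crowns_per_ring` peaks each) joined by `links_between_rings` straight
axial links, on the cylinder of radius
$(D - \text{strut thickness})/2$. Only the diameter (2.5–3 mm), crown and
link counts (6/2), and strut thickness (110 µm, square) are published for
this class of device; ring pitch (default 1.5 mm) and crown amplitude
(default 0.45 mm) are free parameters chosen so a 3 mm device has ~10
rings over ~15 mm, typical coronary proportions. The defaults keep every
derived claim in the tests true (e.g. links, of length
$\text{pitch} - 2A$, remain longer than the crown amplitude). Alternate
rings are phase-shifted by half a crown so each link joins a crown apex to
the facing valley.

Segments — the unit of discontinuity accounting — are the crown limbs
(apex-to-valley arcs, two per crown) plus the links:
$n_\text{seg} = 2\,n_\text{rings} c + (n_\text{rings}-1)\,l$. The segment
graph is a single connected component for every valid design (property
test over randomized designs). Centerline lengths come from polyline
sampling (15 points per arc by default); the test suite checks them
against independent numeric arc-length integration of the sinusoid.

## 3. The voxel phantom

**Voxelization.** The rectangular cross-section (thickness radial, width
tangential) is swept along each segment centerline; a voxel is alloy iff
its center lies inside the sweep. The grid is voxel-centered, isotropic,
z along the vessel axis; default spacing 0.02 mm (5–6 voxels across a
110 µm strut; 0.01 mm for high-fidelity runs), with a hard floor of four
voxels per strut. The device is embedded in a coaxial tissue annulus
(default 0.3 mm inside to 0.45 mm outside the centerline radius);
background (lumen) elsewhere. The voxelized alloy volume matches the
analytic swept volume $\sum \ell_i\,w\,h$ within 10% (junction overlap and
voxel quantization account for the difference).

**Erosion.** A degradation state erodes all alloy within depth $d = kt$ of
the surface. Two estimators of "depth below the surface" are provided:

- `analytic` (default): the exact distance to the swept-rectangle boundary,
  computed from the known geometry. Eroding by $d$ then reproduces the
  continuum shrinkage of the cross-section by $d$ per face exactly, up to
  voxel-center quantization ($\pm$ half a voxel layer per face).
- `edt`: the voxel Euclidean distance transform from non-alloy voxels
  minus half a voxel. This is the generic method usable without geometry,
  but on tilted struts the staircase surface biases it by up to ~0.4
  voxel per face — enough to break the 3% end-to-end recovery requirement
  at 0.02 mm spacing, which is why it is not the default. (This is a
  deliberate deviation from the original design sketch, which prescribed
  the EDT; the implementation proved it too inaccurate at desk-scale
  resolution.)

Voxel-center quantization means the discrete remaining fraction is exact
when the erosion front falls midway between voxel layers and is off by at
most half a layer otherwise; the oracle-equivalence tests therefore
evaluate at depths commensurate with the grid, and the convergence
property (fraction $\to$ closed form as spacing $\to 0$) covers the rest.

**Product substitution.** Eroded alloy is reassigned to radiodense
Ca/P-salt-like product, radiolucent MgO-like product, or tissue (resorbed)
with configurable fractions (defaults 0.5 / 0.3 / remainder 0.2 — both
bright precipitates and darker substitution regions are seen
histologically at mid-degradation; where resorbed alloy goes at voxel
level is a modelling choice, not an observed fact). The draw is seeded and
constant over cubic blocks of `precipitate_size` (default 0.06 mm):
products form contiguous precipitates, not voxel-wise speckle. This
matters: iid speckle with the default fractions has mean grayvalue
$0.5 \cdot 230 + 0.3 \cdot 105 + 0.2 \cdot 60 \approx 158$,
indistinguishable from alloy (160) after any realistic point-spread
function, which would make the rendered shell look like intact metal.
Physical precipitates are larger than the PSF, and the generator follows
the physics. `precipitate_size: 0` restores iid draws.

**Fractures.** A cut segment loses its voxels *except* junction material
shared with an uncut segment. Removing the full swept volume would also
amputate the shared junctions of continuous neighbours and make them
spuriously discontinuous; with this rule the discontinuity ratio is
exactly `100 * cuts / segments` on noiseless phantoms, which is also how
the exactness criterion is defined. Fractures reassign to tissue (the
fragments' mass is not tracked), so cut schedules are not used when
validating volume-based $T$ recovery — a fracture does not remove mass in
reality, and mixing the two would break the volume law by construction.

**Rendering.** Class means $\to$ isotropic Gaussian PSF (sigma in voxels,
separable, truncated at $3\sigma$, border-renormalized) $\to$ additive
seeded Gaussian noise. The per-class spreads in the material model
describe expected histogram widths (used for initialization/assignment),
not injected noise, so `psf_sigma = 0, noise_sd = 0` reproduces class
means exactly. Beam hardening, ring artifacts, and scanner-specific
calibration are out of scope.

**I/O.** MetaImage (`.mhd` + little-endian raw; uint8 for labels, float32
default for grayscale, float64 on request) and multi-page uncompressed
float32 TIFF with spacing recorded in the image description. Both codecs
are implemented in the package because the pre-installed stack has no R
reader for either format. Round trips are exact for float32-representable
data; spacing survives to at least six decimals.

## 4. Remaining-volume estimation by histogram peak fitting

The reference pipeline estimated remaining volume "from histogram data
using a peak fitting program" without specifying the algorithm. Here:
equal-width histogram (default 128–256 bins) over a cylindrical region of
interest around the device, then a maximum-likelihood Gaussian mixture on
the binned counts (EM with Sheppard bin-variance correction and a half-bin
sd floor). `k = "auto"` selects 2–5 components by BIC. EM is multi-start
(quantile and equal-spaced initializations) because the alloy is a
percent-level fraction of any region of interest and quantile starts miss
it. Components closer than the unimodality limit ($|\Delta\mu| <
2\sigma_{\min}$) are merged — they are one peak that EM split — so a
single-class volume yields a single effective component. Components map to
material classes by proximity to the calibrated class means.

Volume attribution offers three estimators:

- `soft` — the alloy component's mixture weight times ROI volume. This is
  the design sketch's default, and it is accurate on sharp images, but
  under a 1-voxel PSF a 5-voxel strut is mostly partial-volume ramp: the
  fitted alloy peak captures only the interior plateau and the weight
  underestimates volume several-fold. The implementation kept the mode but
  demoted it from the pipeline default (a documented deviation).
- `threshold` — maximum-posterior classification of bins (hard threshold
  at the Gaussian intersections), then counting alloy bins.
- `midpoint` (pipeline default) — count bins between the tissue/alloy and
  alloy/dense midpoints, with the lower cut at the midpoint of the tissue
  level and the *fitted* alloy plateau. This is the classical half-maximum
  surface estimator: for symmetric blur the half-contrast crossing tracks
  the true surface while the strut is wider than ~2 PSF sigma, making the
  estimator nearly unbiased exactly where a volume measurement is
  meaningful, and degrading gracefully (undercounting) below resolution.

The denominator is always the analytic as-manufactured scaffold volume,
not a first-timepoint measurement. Only the metallic alloy class is
counted as "remaining"; whether radiolucent Mg products should also count
is unknowable from the source material — counting them would shift every
ratio up, and the class-resolved fit makes that variant a one-line change.

## 5. Integrity measurements

**Discontinuity.** The in-vivo analysis counted broken struts manually on
3D renderings; the algorithmic surrogate declares a designed segment
CONTINUOUS iff its endpoint nodes are joined by a 26-connected path of
mask voxels inside a capture tube of radius 1.5 strut widths around the
centerline (tolerant of partial-volume bloom, narrow enough not to bridge
across the lumen). The mask is alloy + dense product (visible strut
material), from labels directly or by maximum-posterior classification of
grayscale. Only full connectivity loss counts; a thinned but connected
strut is continuous (whether the manual analysis counted those is
unknown). The fragment count is the number of 26-connected components of
the whole mask.

**Inner area.** Slices every 3 mm (exactly `floor(3/spacing)` slices,
starting at the first occupied slice). On each slice the area is the
polygon through each strut component's innermost point (minimum radius
from the slice centroid), vertices sorted by angle; fewer than 3
components is unmeasurable — except when the mask encircles the centroid
(angular coverage $\ge 300^\circ$, e.g. an intact tube), where innermost
radii per 10° bin define the polygon. The original sketch had no
encircling-wall branch, but its own reference case (a thin-walled tube
whose area must match $\pi r^2$ within 5%) is a single connected
component; the branch resolves that contradiction. An 8-connected 2D /
26-connected 3D convention is used throughout, conventional for thin
structures.

## 6. Pipeline, reproducibility, and the synthetic world

`run_timecourse()` executes one schedule: per timepoint, build (possibly
dilated) geometry, voxelize, erode/substitute/cut, render, estimate the
remaining ratio (peak fitting by default, label counting with
`use_labels`), measure discontinuity and inner areas, then fit $T$ to the
pipeline's own ratio estimates. One master seed drives everything; per
timepoint seeds derive deterministically (`seed * 7919 + index * 104729`
mod $2^{31}-1$), the cut order is one seeded permutation (cuts accumulate
over time), and identical configs produce byte-identical JSON reports (no
timestamps). A failing timepoint is flagged and the run continues.

Default schedule times mirror the study design {1, 6, 12, 18, 26} months;
the default erosion programming uses the fitted $T = 23.5$.

What a green run establishes — and what it does not. The phantom captures
partial volume, noise, product attenuation contrast, fracture topology,
and outward remodeling (dilation), so it exercises estimator bias in the
regimes that matter. It does not capture beam hardening, scatter, motion,
registration error between serial scans, real corrosion morphology
(pitting, non-uniform fronts), or tissue heterogeneity; accuracy numbers
from the tests are therefore lower bounds on real-world error. End-to-end
recovery of the programmed $T$ is demonstrated at 0.02 mm spacing with a
1-voxel PSF and SNR 10 (within 15% via the grayscale path, 3% via the
label path) on a short 2-ring device — scaled down from a full device to
keep test runtimes in budget; nothing in the method depends on ring count.

## 7. Known limitations

- Erosion depth is quantized at half a voxel layer; sub-layer erosion
  steps (e.g. one month at 0.02 mm spacing) round to zero or one layer.
- The grayscale path loses the alloy peak once struts shrink below ~3
  voxels; late-stage ratios are under-detected rather than noisy.
- The discontinuity definition needs the design graph in the image frame;
  registration of real serial scans is not implemented.
- TIFF support is deliberately minimal (uncompressed little-endian
  baseline); MetaImage is the interchange format of record.
- Cut fragments vanish instead of displacing; fragment migration and
  embedding are not modelled.
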