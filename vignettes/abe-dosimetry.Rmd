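---
title: "Methods: boron-neutron D0 extraction, slide morphometry and ABE dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boron-neutron D0 extraction, slide morphometry and ABE dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abebnct)
```

This vignette is the package's own account of its models, the choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not demonstrate.

## 1. The survival model and the slope-subtraction extraction

Clonogenic survival after neutron irradiation is modelled as purely
exponential in the thermal neutron fluence $\varphi$ (n/cm²):

$$ SF(\varphi) = \exp(c - k\varphi). $$

No linear-quadratic term is fitted: for the high-LET products of the
$^{10}$B(n,$\alpha$)$^7$Li reaction and for the mixed beams considered
here, measured curves are log-linear over the fluence ranges of interest.
Two design decisions deserve emphasis:

* **The intercept $c$ is free**, not forced through $SF(0) = 1$. Control
  curves can be shouldered, and only *slopes* enter the extraction, so the
  intercept never contaminates $\varphi_0$. Forcing the origin would bias
  the slope whenever a shoulder exists.
* **The fit is unweighted OLS on the log scale.** Counting statistics would
  justify weights, but colony counts in the intended designs are large
  (hundreds to tens of thousands per dish), where weights change slopes
  negligibly; the unweighted log-linear fit is also the transparent reading
  of "a straight line on semi-log axes".

The beam-only control absorbs every non-capture dose component (thermal,
epithermal and fast neutron, $\gamma$): the boron-neutron effect is the
*difference of slopes*, $k_B = k_{total} - k_{beam}$, never a stepwise
decomposition of physical dose components. The 1/e fluence of the
subtracted line is $\varphi_0 = 1/k_B$, and

$$ D_0 = \varphi_0 \times 6.933\times10^{-14} \times [^{10}\mathrm{B}]\ \mathrm{(ppm)}, $$

where $6.933\times10^{-14}$ Gy·cm²/ppm is the thermal-neutron kerma
coefficient of the capture reaction (`boron_kerma_coefficient`), exposed as
an overridable argument for other beam spectra. If $k_B \le 0$ the package
refuses to report a $\varphi_0$: survival with boron that is not steeper
than the control means no detectable boron effect, not a negative dose.

Surviving fractions may be derived from colony counts as
`colonies / (plated × plating_efficiency)`; when the efficiency is not
given it is taken from the zero-fluence beam-only point. A point with zero
colonies is rejected outright (its log-survival is undefined) rather than
imputed.

Survival-curve points are stored sorted by fluence, which makes every
downstream result independent — bit for bit — of the order in which points
were supplied.

## 2. Morphometry and the stereological diameter chain

On an H&E-stained section the analysis region is chosen to avoid
interstitium; within it, eosin-pink pixels are classified as cytoplasm by
HSV hue, and the nuclear area is obtained by *subtraction* (region minus
cytoplasm), mirroring how the areas are measured with commercial image
analysers. Two indices follow:

* $X_{nc}$ — nuclear area fraction of the region. By the Delesse principle
  an area fraction on a random section estimates the volume fraction, so
  $X_{nc}$ is read as the N/C *volume* ratio.
* $X_{cs}$ — region area divided by the number of nuclei (μm² per cell).

Nuclei are counted as 8-connected components after a 1-px-radius
morphological opening and a minimum-area filter (default 4 μm²). The
opening affects *counting only*: areas remain pure colour-subtraction
measurements, which keeps $X_{nc}$ exactly invariant under integer
resampling of the raster. Border-touching nuclei are counted like any
other, since the index divides total area by total count with no edge
correction.

**Cell diameter.** A random plane through a sphere of radius $R$ shows a
profile of radius $\sqrt{R^2 - z^2}$; with the section offset $z$ uniform
on $[0, R]$, the mean profile radius is $\pi R/4$ and the mean profile
area is $\tfrac{2}{3}\pi R^2$ (both verified by the package's own
Monte-Carlo oracle, `simulate_random_sections()`). The default convention
treats $\sqrt{X_{cs}/\pi}$ as the mean profile radius and inverts the
correction:

$$ R = \frac{4}{\pi}\sqrt{\frac{X_{cs}}{\pi}}, \qquad d_{cell} = 2R. $$

This convention was selected because it reproduces the published reference
diameters for three of the five tumour lines exactly at printed precision
(SAS/neo 14.9 μm, SAS/mp53 15.9 μm, B16-BL6 20.4 μm) and a fourth (EL4,
12.4 vs 12.3 μm) within 0.1 μm. The SCCVII estimate (17.4 vs 18.5 μm,
about 6 %) deviates under this convention; the gap is unexplained and is
documented rather than absorbed by tuning. The convention is a named,
swappable strategy: `estimate_cell_diameter(..., convention =
"profile-area")` instead equates $X_{cs}$ with the mean profile area,
$R = \sqrt{3X_{cs}/(2\pi)}$.

**Nucleus diameter.** The area-derived $X_{nc}$ is taken as a volume
fraction and converted to a linear ratio by the cube root:
$d_{nuc} = d_{cell} \cdot X_{nc}^{1/3}$, which can never exceed the cell
diameter. The B16-BL6 N/C ratio is carried as 0.3 throughout.

## 3. The predictive regressions

* **BPA (intracellular carrier):** power law $D_0 = a X_{nc}^{b}$, fitted
  by OLS of $\ln D_0$ on $\ln X_{nc}$ over all five lines. $R^2$ is
  reported on the ln–ln fitting scale (the scale the fit minimises on),
  and the scale is recorded in the model metadata. On the packaged table
  this gives $a = 0.1341$, $b = -1.586$, $R^2 = 0.9721$.
* **BSH (extracellular carrier):** straight line $D_0 = \beta X_{cs} +
  \alpha$ with B16-BL6 excluded by a *named exclusion list* — never by
  automated outlier detection — because its BSH microdistribution deviates
  from the behaviour of the other four lines. This gives $\beta = 0.0122$,
  $\alpha = -0.1319$, $R^2 = 0.9795$; refitting with B16-BL6 included
  collapses $R^2$ below 0.3.

`compare_approximations()` refits the same pairs under linear,
exponential, logarithmic, power and quadratic forms and reports each
form's $R^2$ together with its prediction at a reference predictor value
(default $X_{nc} = 1$, a nucleus filling the cell). The power form is
preferred not only on $R^2$ but because the alternatives extrapolate to
negative or implausibly large $D_0$ at that limit; the comparison makes
that argument reproducible. The polynomial degree is 2 — higher degrees on
five points are exactly the over-fitting the comparison is meant to
expose. The BPA-versus-$X_{cs}$ linear relation can also be fitted, but it
carries no reference coefficients and is not used for prediction.

A linear-model prediction $D_0 \le 0$ (possible for very small $X_{cs}$)
is flagged out-of-validity: `predict_d0()` warns and attaches an
attribute, and the slide-to-ABE path turns it into an error rather than
reporting a negative dose.

## 4. ABE dose

The ABE factor of a tumour is $1/D_0$ (Gy/$D_0$; numerically per Gy,
treated as unitless since $D_0$ is itself in Gy — the package fixes this
convention explicitly since Gy/Gy bookkeeping is otherwise loose). The ABE
dose of a physical boron-neutron dose $D$ is $D/D_0$: the number of 1/e
reductions on the tumour's own survival curve, so the implied surviving
fraction is $\exp(-D/D_0)$. The identities
`abe_dose(k·D0, D0) = k` and `abe_dose(D, d) = −ln SF` for exponential
survival hold to numerical precision and are enforced by tests.

## 5. What the generators emulate — and what they do not

**Colony experiments** (`simulate_survival_experiment()`): expected
survival is exactly exponential; colony counts are Poisson with mean
`n_plated × plating_efficiency × SF` — the standard CFU noise model, with
no over-dispersion parameter in this version. The boron slope is derived
from the configured true $D_0$ in closed form, so extraction can be
validated against ground truth. Defaults are one beam-only and one
25-ppm-BPA curve at fluences 0–2×10¹¹ n/cm² (survival down to ~0.3 on the
boron arm), $10^5$ cells plated, plating efficiency 0.6, true
$D_0 = 0.35$ Gy, and a beam-only slope of $10^{-12}$ per n/cm² (a 1/e
fluence of $10^{12}$ n/cm², representative of mixed reactor beams). With
these defaults the mean recovered $D_0$ over 200 replicates sits within
5 % of truth. Real experiments add inter-dish variability, enzymatic
dissociation losses and fluence-measurement error, none of which are
modelled — passing recovery tests shows the estimator is correct under its
stated noise model, not that wet-lab data will be this clean.

**Tissue renders** (`generate_tissue_image()`): non-overlapping circular
cell profiles (gamma-distributed radii, default mean 7.5 μm, CV 0.15) with
concentric nuclei sized to the target area fraction, rasterized at 0.5
μm/px on a 512-px square with seeded per-cell colour jitter around
hematoxylin-purple and eosin-pink. The render *is* the section: no 3D
effects, no touching cells, no stain gradients, no chromatin texture, no
out-of-focus blur. It validates the segmentation arithmetic and the index
definitions, not robustness to real histology. Packing is random
sequential placement and refuses configurations beyond ~35–40 % area
fraction rather than looping forever — real confluent tumour sheets are
denser than this generator can produce.

**3D sectioning** (`simulate_sectioned_tissue()`): spheres with concentric
nuclear spheres of radius $r X_{nc}^{1/3}$ packed in a 120-μm box (default
120 cells, ~9 % volume fraction), cut by uniform random planes. A plane
cutting a cell misses its nucleus with probability $1 - X_{nc}^{1/3}$, so
the observed $X_{cs}$ (region area per *counted nucleus*) overestimates
the true mean cell cross-section per cell by a factor approaching
$X_{nc}^{-1/3}$ — about 1.5 at $X_{nc} = 0.3$ versus about 1.13 at 0.7.
This reproduces the documented direction of the low-N/C cell-size
overestimation; the package deliberately does not correct it, only
demonstrates it. The packing fraction does not enter this ratio, which is
why the modest density is acceptable.

All generators are seed-deterministic: identical configuration and seed
give identical bytes.

## 6. Numerical choices and degenerate inputs

* $R^2$ is computed directly as $1 - SS_{res}/SS_{tot}$ on the fitting
  scale; a zero-variance response is a degenerate perfect fit and reports
  $R^2 = 1$ (keeping the $[0,1]$ invariant) rather than NaN.
* Comparisons against published values round half away from zero to the
  printed decimals; all stored and serialized values keep full precision
  (17 significant digits in CSV/JSON output).
* Fewer than two distinct fluences, survival outside $(0,1]$, zero
  colonies, $k_B \le 0$, zero nuclei, non-positive $X_{cs}$, $X_{nc}$
  outside $(0,1]$ and negative doses are all classed errors
  (`abebnct_domain_error` / `abebnct_schema_error`); the CLI maps them to
  exit codes 3 and 2 respectively.
* Connected components use 8-connectivity; labeling is an iterated
  vectorized minimum-label propagation, cheap because nuclei are small.
* Raster convention: row-major, origin top-left, pixel-centre sampling at
  $(i - 0.5)\,\mathrm{mpp}$; masks are inclusive ($d^2 \le r^2$).

## 7. Problem sizes used by the tests and the acceptance script

Unit tests use reduced geometries (25–60 cells, 160–256 px rasters, 20–60
sections) chosen so each property is still sharply decided; the acceptance
script uses the full study conditions: 200 Poisson-replicate extractions at
$10^5$ cells plated, $10^6$ Monte-Carlo sphere sections, and 100 paired 3D
sections per N/C level.

## 8. Known limitations

* Purely exponential survival: shouldered (linear-quadratic) low-LET
  responses are out of scope by design.
* The colour segmenter is a two-band hue classifier sufficient for the
  generator and for clean H&E input; it is not a general nucleus
  segmenter and will mis-handle overlapping nuclei, necrosis or stain
  variation.
* The stereological convention assumes spherical cells sectioned uniformly
  at random; elongated or clustered cells violate it, and the SCCVII-size
  discrepancy shows real tissue can deviate by several percent.
* Predictions inherit the five-tumour fitting range ($X_{nc}$ 0.3–0.53,
  $X_{cs}$ 74–202 μm²); extrapolation beyond it is mechanically possible
  but scientifically unsupported, and the BSH line is invalid below
  $X_{cs} \approx 11$ μm² where it crosses zero.
* No uncertainty intervals on fitted coefficients are reported, and no
  physical beam-spectrum or microdosimetric modelling is attempted.
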