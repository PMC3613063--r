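---
title: "Automatic DSC-MR perfusion quantification: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic DSC-MR perfusion quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscquant)
```

# The quantification problem

Dynamic-susceptibility-contrast (DSC) MRI tracks a gadolinium bolus through
the brain as a transient T2\*-weighted signal drop. The standard
tracer-kinetic analysis yields *relative* cerebral blood volume and flow:
their scale depends on the arterial input function (AIF) partial-volume
content, scanner gain and the deconvolution settings, so values cannot be
compared across subjects or against PET/CT literature. In addition, vessel
voxels — with blood volume an order of magnitude above parenchyma — inflate
any region statistic that includes them.

`dscquant` implements an automatic chain that addresses both: it segments
normally perfused parenchyma without user interaction, derives two scaling
factors that put the relative maps on the literature scale, and removes
vessel voxels with dual absolute thresholds. This vignette documents the
model, every tunable parameter, the numerical conventions, and what the
built-in phantom validation does and does not establish.

# Signal model and concentration conversion

With echo time $TE$ and baseline $S_0$ (voxelwise mean of dynamics 6–10,
1-based), concentration is

$$C(t) = -\frac{k_1}{TE}\,\ln\frac{S(t)}{S_0}.$$

Conventions and choices:

* **Sign.** The log-ratio relation is often written without the minus sign,
  which makes the bolus passage negative. We use the negated form so
  concentrations are positive; every downstream operation (area sums,
  deconvolution, map maxima) assumes this.
* **$k_1 = 1$.** The proportionality constant cancels in the rCBV ratio and
  is absorbed by the scaling factors, so its value is immaterial.
* **Signal floor.** $S(t)$ is clamped at $\varepsilon S_0$ with
  $\varepsilon = 10^{-3}$ before the log (argument `epsilon` of
  `signalToConcentration()`); this bounds the concentration in noisy vessel
  voxels where the signal can touch zero, at $\ln(10^3)/TE \approx 173$
  arbitrary units for $TE = 40$ ms — far above any genuine bolus value but
  finite.
* **Index conventions.** All dynamic indices in this package are 1-based:
  baseline window `6:10`, bolus integration window `11:n` (clamped to the
  series length). Times in seconds are `(dynamic - 1) * TR`.

# Hemodynamic maps

**rCBV** is the windowed area ratio
$rCBV = (k_H/\rho)\sum_{11}^{70} C / \sum_{11}^{70} AIF$ with
$k_H/\rho = 0.705$ cc/g, the conventional composite of large-/small-vessel
hematocrit correction ($k_H = 0.73$) and brain density
($\rho = 1.04$ g/cc).

**rCBF** comes from inverting the convolution model
$C_{tissue}(t) = (\rho/k_H)\,AIF(t)\otimes[rCBF\cdot R(t)]$. The discrete
operator carries an explicit $TR$ factor, so results are invariant to
temporal resampling. Two variants:

* `sSVD`: lower-triangular Toeplitz matrix; assumes the tissue curve does
  not lead the AIF and underestimates flow when arrival is delayed.
* `cSVD`: circulant matrix of the AIF zero-padded by `padFactor` (default
  2); time-aliasing-free and insensitive to bolus delay.

Truncated SVD zeroes inverse weights of singular values below
`truncationFraction` of the largest. Defaults are the community-standard
0.20 (sSVD) and 0.10 (cSVD). Truncation is a bias/variance trade: at these
defaults a noise-free curve with the phantom's 4.8 s mean transit time is
recovered at about 0.78× (sSVD) and 0.68× (cSVD) of its generating residue
maximum. Three consequences worth stating explicitly:

1. The bias is a *global factor per method* for tissues sharing a residue
   shape, and the per-method scaling factor $SF_{CBF}$ divides it out —
   which is precisely why the method computes one $SF_{CBF}$ per
   deconvolution variant. Raw sSVD and cSVD maxima differ by ~13% at the
   defaults; the scaled maps agree to numerical precision on the phantom.
   Tests therefore assert method agreement on the *scaled* maps.
2. Validation tests that probe the inversion itself (residue recovery
   within 10%, the $k_H/\rho$ self-deconvolution constant) run at low
   truncation (0.05 and 0.01), which is the appropriate setting for
   noise-free data.
3. Delta-like residues (arterial voxels) are broadband and lose the most to
   truncation: vessel-class CBF is structurally under-recovered (~0.5× at
   the defaults). This is one reason the pipeline *segments and removes*
   vessels rather than quantifying them.

The maximum of the deconvolved curve is taken over the signed values;
residual negative map voxels are clamped to zero and counted in the map
metadata.

**TTP** is the time of the concentration maximum within the integration
window, on raw (unfitted) curves, first occurrence winning ties. Flat
curves (no positive value in the window) are assigned the window start and
flagged in `metadata$flat`; flagged voxels are excluded from the TTP median
below.

**MTT** is $CBV/CBF \times 60$ s, with voxels below a CBF floor (default
0.01 map units) set to zero and counted. After scaling, MTT is *recomputed*
from the scaled CBV and CBF maps rather than rescaled, since
$SF_{CBV} \ne SF_{CBF}$ in general.

# Automatic segmentation

* **Brain mask**: Otsu threshold on the first perfusion image (air vs
  tissue). Our Otsu implementation bins into 256 bins and returns the bin
  edge maximizing between-class variance; it is deterministic and
  translation-equivariant.
* **CSF mask**: Otsu threshold on the within-brain first-image/baseline
  ratio, whole-volume (a per-slice option was considered unnecessary: the
  T1-saturation contrast that separates CSF is not slice-dependent). CSF is
  the *high*-ratio class — its long T1 keeps the unsaturated first image
  disproportionately bright (`polarity` is configurable). Because a plain
  Otsu split always partitions, even a unimodal (CSF-free) distribution, we
  added a separability guard: the split is accepted only if Otsu's
  between-class/total variance ratio $\eta$ reaches `minSeparability`
  (default 0.75; a well-separated two-class mixture gives $\eta \to 1$, a
  single Gaussian about 0.64). Below it, the mask is empty with a warning.
* **Preliminary vessel mask**: voxels above twice the median rCBV *or*
  twice the median rCBF, medians taken over brain-minus-CSF voxels of the
  whole volume. The pipeline computes this mask from one configurable
  `primaryMethod` rCBF map (default sSVD) but records `2 × median(rCBF)`
  per method so the threshold comparison can be reported for both.
* **Normal parenchyma**: voxels with TTP in the inclusive window
  $[\mathrm{TTP}_{med} - w, \mathrm{TTP}_{med}]$, $w = 3$ s by default
  (`ttpWindow`). Inclusive bounds keep the median voxel itself. The median
  is computed after CSF and preliminary-vessel removal, excluding
  flat-curve voxels. The window's upper bound at the median is what makes
  the mask asymmetric in unilateral stenosis: delayed territory falls above
  the median and drops out.

# Scaling and vessel removal

The composite references are a 60/40 gray/white mixture of literature
values (GM 4 mL/100 g, 50 mL/100 g/min; WM 2, 25), giving 3.2 mL/100 g and
40 mL/100 g/min. All five constants are arguments of
`referenceConstants()`; the 60/40 assumption is not estimated from the
data, and the method is accordingly not applicable to global/diffuse
perfusion alterations. Scaling normalizes the normal-mask means to the
composite references *exactly* (an algebraic identity asserted in the
tests).

Final vessel removal applies strict inequalities CBV > 8 mL/100 g or
CBF > 100 mL/100 g/min, categorized (CBV-only / CBF-only / both). Dual
thresholds matter in pathology: impaired territory has raised CBV but
reduced CBF (caught by the CBV arm), normal territory the reverse, and
choroid-plexus-like tissue (high CBV, low CBF) appears in the CBV-only
category.

Hemispheric ROI statistics are reported under four cumulative conditions
(none / CSF removed / vessels removed / both), per hemisphere, split at the
in-plane midline of the brain bounding box (configurable, as is the slice
selection). CBV rows are repeated per method because the vessel mask
depends on the method's CBF map. The Mann-Whitney U test is implemented
from rank definitions with an exact permutation null for groups of up to 8
(valid under ties) and a tie-corrected, continuity-corrected normal
approximation beyond — keeping the statistical surface testable against
brute-force enumeration.

# The synthetic phantom

`buildPhantom()` generates a mirror-symmetric two-hemisphere grid (default
48×48×3, 70 dynamics, TR 1 s, TE 40 ms): a rectangular brain in a
background margin, a central CSF block, four small vessel blocks, and the
remaining parenchyma split WM-inside/GM-outside by distance rank with an
exact 60/40 GM/WM quota per hemisphere — so the normal mask matches the
scaling assumption by construction. Design choices:

* **Residue family**: mono-exponential $R(t) = e^{-t/MTT}$ (the pipeline
  estimates, never assumes, $R$; the generator needs *some* family and the
  exponential has an analytic MTT). The literature GM and WM values share
  MTT = 4.8 s, so GM/WM curves differ only in amplitude.
* **Discretization**: the discrete residue is cell-averaged over each TR
  interval, which makes the discrete curve area satisfy the central-volume
  theorem exactly; point sampling would inflate areas by ~10% at
  TR/MTT ≈ 0.21 and break the 1% area invariant the tests assert. The
  recoverable discrete residue maximum is then
  $(MTT/TR)(1 - e^{-TR/MTT}) \approx 0.90$ of CBF/60 at GM/WM parameters;
  recovery tests compare against this generating maximum.
* **Vessels carry the AIF** (`vesselCarriesAif = TRUE` by default): vessel
  voxels hold the amplitude-scaled undispersed arterial curve,
  $\kappa\,AIF(t)$ with $\kappa = CBV_{true}/(k_H/\rho)$, so automatic AIF
  selection has a correct target and tissue deconvolution is shape-unbiased.
  The implied vessel truth CBF is $CBV_{true}\cdot 60/TR$ (delta residue,
  MTT = TR). A convolution-based vessel model remains available.
* **T1 saturation** is a single multiplicative factor on dynamic 1 (CSF
  default 2.0, parenchyma 1.0) — exactly the feature the CSF stage
  consumes, with no Bloch simulation. The factor also leaves a negative
  $C(1)$ spike in CSF after log conversion, a realistic nuisance that the
  integration window excludes.
* **Noise**: Gaussian on signal, default SD 10 against baselines of
  700–1000 (baseline SNR ~10², typical of EPI perfusion), seeded and
  bit-reproducible. Rician noise is not simulated; at these SNRs the
  difference is negligible away from the background.
* **Impairment option**: `impairedDelay` (seconds; quantized to the dynamic
  grid) and `impairedCbfFactor` apply to the right hemisphere, emulating
  delayed/reduced collateral supply.

What the phantom does *not* emulate: contrast recirculation and leakage,
partial-volume mixing at class boundaries, motion, and k-space/EPI
artifacts. Consequently the pipeline's *clinical* scaling-factor range is
not expected to be reproduced — on the phantom the scaling factors absorb
the arbitrary AIF amplitude ($\kappa$) and the truncation factor, and their
numerical values are meaningless in themselves. Passing phantom tests
establish internal consistency (forward model inverted correctly,
segmentation rules implemented correctly, normalization exact), not
clinical accuracy.

# Validation summary and problem sizes

The test suite builds all fixtures in code on 32×32×1 grids with 70
dynamics (the layout scales; the defaults keep the suite under a few
seconds) and checks, among others: central-volume consistency within 1%;
brain/CSF/vessel segmentation exactly equal to truth on the separable
noise-free phantom and Jaccard > 0.95 under the default noise; GM/WM scaled
CBV/CBF within 15% of truth (measured: within ~2%) with the
VESSEL > GM > WM rank order preserved; ≥95% exclusion of 4-s-delayed voxels
from the normal mask with cSVD ≥ sSVD flow in delayed territory; and exact
agreement of the rank-sum test with exhaustive enumeration for all group
sizes up to 6. `scripts/acceptance.R` re-runs the main computations on the
default 48×48×3 phantom and writes the resulting quantities as JSON.

# Known limitations

* The 60/40 GM/WM reference mixture is assumed, not estimated; reference
  values are not age/sex-stratified, and the approach fails under global
  perfusion alteration.
* Vessel-class CBF is truncation-limited (see above); vessels are removed,
  not quantified.
* No leakage ($K_2$) or recirculation correction; no delay/dispersion
  correction beyond cSVD's delay insensitivity; no oscillation-index
  regularization.
* Automatic AIF selection is a simple composite score (early TTP, high
  peak, narrow first moment, equal thirds after z-scoring, top-10 average);
  it is deterministic and replaceable but less robust than
  independent-component approaches on clinical data.
* Whether the rCBF maximum should be taken over the signed or absolute
  deconvolved curve is not settled in the field; we use the signed curve,
  which is the conservative choice on real bolus shapes.
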