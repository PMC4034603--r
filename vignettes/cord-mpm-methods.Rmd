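---
title: "Quantitative multi-parameter mapping of the cervical cord: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative multi-parameter mapping of the cervical cord: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordmpm)
```

## The measurement problem

Multi-parameter mapping (MPM) estimates a set of quantitative MR parameters
— apparent proton density (APD), longitudinal relaxation time $T_1$,
magnetisation transfer saturation (MTsat), magnetisation transfer ratio
(MTR) and the apparent transverse relaxation rate $R_2^*$ — from three
multi-echo spoiled gradient-echo (FLASH) acquisitions with predominantly
PD, $T_1$ and MT weighting, plus an actual flip-angle imaging (AFI)
acquisition that maps the transmit field $f_T$ (actual/nominal flip angle,
in percent).

In the cervical spinal cord this is hard for two reasons: the structures of
interest (white-matter columns, the grey-matter butterfly) are only a few
millimetres across, and the three scans are acquired minutes apart, so
inter-scan motion of one or two voxels destroys any voxelwise combination
of the contrasts. The package therefore couples the parameter estimators to
a dedicated rigid co-registration pipeline, and ships a digital cord
phantom with known ground truth so that every stage can be validated
without access to scanner data.

## Signal model

The spoiled FLASH steady-state signal at echo time zero is, in the
rational small-angle approximation,

$$ S \;=\; A\,\alpha\,\frac{T_R R_1}{\alpha^2/2 + \delta + T_R R_1}, $$

where $A$ is the amplitude (APD before receive-field effects), $\alpha$ the
excitation flip angle in radians, $R_1 = 1/T_1$, and $\delta$ the
additional fractional saturation of the longitudinal magnetisation caused
by a single off-resonance MT pulse per TR ($\delta = 0$ for the PDw and T1w
contrasts). MTsat is reported as $100\,\delta$ in percent units. The exact
steady state (Ernst equation, extended with a once-per-TR saturation
factor $(1-\delta)$) is also implemented, as `flash_signal(mode = "exact")`;
it serves as the independent oracle for the approximation. At the
acquisition settings used here (6 and 20 degrees; TR 22–24 ms) the
approximation is accurate to 0.1–1%, and inverting exact-model signals with
the rational approximation biases $T_1$ by at most ~3% over 800–2500 ms
(about +1.3% at 1800 ms) — a property the test suite checks against
brute-force numerical inversion of the exact model.

Estimation proceeds in closed form:

* $R_2^*$: ordinary least squares of $\ln S$ against TE over the six PDw
  echoes (slope $=-R_2^*$). Unweighted, as is conventional; the estimator
  is scale-invariant and voxels with non-positive signal are masked rather
  than erroring.
* $T_1$ and APD: algebraic inversion of the rational approximation from
  the averaged PDw/T1w pair, with per-voxel effective angles
  $f_T\,\alpha_{\mathrm{nom}}$ when a B1 map is supplied.
* MTsat: $\delta = (A\,\alpha/S_{MT} - 1)\,T_R R_1 - \alpha^2/2$, inserting
  the estimated $A$ and $R_1$. Deliberately computed with the *nominal*
  angle: the MT pulse's own saturation scales as $f_T^2$ while the
  nominal-angle estimation bias scales as $1/f_T^2$, so transmit-field
  errors largely cancel — the key advantage of MTsat over MTR.
* MTR: $100\,(S_{PD}-S_{MT})/S_{PD}$ from the averaged volumes.

Two details matter for unbiased estimates and are on by default:

* **Echo-matched averaging.** The PDw series has six echoes but the T1w and
  MTw series five. If each contrast were averaged over all its own echoes,
  the averages would carry *different* $T_2^*$ weighting, and the $T_1$
  estimate — which is sensitive to the PDw/T1w signal ratio — would be
  biased by several percent. The averages that feed the $T_1$/APD/MTsat/MTR
  estimators therefore use the same echo positions (the first five) in
  every contrast, so the decay factor is common and cancels. $R_2^*$ still
  uses all six PDw echoes.
* **Decay compensation** (`t2star_compensation`). The echo average of a
  decaying signal is the TE = 0 amplitude times
  $\overline{e^{-R_2^* TE}}$. Dividing each average by this factor
  (computed per voxel from the fitted $R_2^*$ map) refers the amplitudes to
  TE = 0; without it APD absorbs an arbitrary ~0.8 decay factor. The factor
  is common to all three contrasts and cancels identically in $T_1$, MTsat
  and MTR.

## Registration pipeline

The four-step intra-subject pipeline operates on echo-averaged volumes:
(1) register the averaged PDw and T1w volumes to the averaged MTw volume;
(2) invert the registered T1w contrast (robust maximum minus intensity) so
CSF is bright, matching the other two; (3) average the three
intensity-normalised volumes into a fresh registration target; (4) register
the three *original* averaged volumes to that target. Because only the
step-4 transforms are applied to data used quantitatively (for $R_2^*$,
they are carried onto the individual PDw echoes), exactly one interpolation
pass touches any fitted image.

All registrations are rigid (6 degrees of freedom, rotations about the
volume centre in the order x, y, z) and maximise normalised mutual
information, $\mathrm{NMI} = (H(A)+H(B))/H(A,B)$, from a 64-bin joint
histogram over each image's robust (0.5–99.5 percentile) range. Numerical
choices that the near-cylindrical cord geometry forces:

* NMI is evaluated **over the field-of-view overlap only**, with a small
  penalty (0.2 per unit lost-overlap fraction). Including out-of-view
  zeros lets a sliding alignment *sharpen* the joint histogram spuriously;
  restricting to the overlap removes that, and the penalty breaks the
  plateau that remains when anatomy varies slowly along the slice axis.
* The optimiser is derivative-free: an exhaustive coarse grid over
  translations (±9 mm, NMI local maxima at grid-aligned shifts make pure
  descent unreliable), Nelder–Mead refinement with trilinear interpolation,
  then a refinement stage whose cost uses **windowed-sinc interpolation**,
  with 1-D sweeps over the weakly constrained parameters (slice-axis
  translation, all rotations, ±10 mm/deg) before a final simplex polish.
  Trilinear interpolation blurs the moving image enough to flatten the
  rotation basin of a near-cylindrical cord; the sinc-interpolated cost
  restores it. Final resampling always uses the Hann-windowed sinc kernel
  (7-voxel support per axis).
* Search is designed for misalignments within ±10 mm/±10 degrees, ample
  for inter-scan subject motion.

The B1 map is computed from the AFI pair via
$\cos\alpha = (rn-1)/(n-r)$, $r = S_2/S_1$, $n = T_{R2}/T_{R1}$, expressed
in percent of nominal, registered to the registered T1w volume with the
same NMI machinery, and smoothed with an 8-mm FWHM Gaussian (AFI is
acquired at low resolution; smoothing stabilises the correction; set
`b1_smoothing_fwhm_mm = 0` to disable).

## The digital cord phantom

`phantom_spec()` describes a synthetic subject; `simulate_subject()` and
`generate_cohort()` render it. The acquisition defaults are the protocol
the estimators are designed for: PDw TR 24.05 ms / 6° / six echoes equally
spaced over TE 3.0–18.55 ms; T1w TR 22 ms / 20° / five echoes; MTw five
echoes with a 4-ms Gaussian MT pulse (nominal 220°, 2 kHz off-resonance) —
its readout TR/flip default to the PDw values, a configurable choice since
MT-weighted readouts conventionally match the PD-weighted ones; AFI 60°
with TR pair 50/150 ms. Tissue values (amplitude, $T_1$, $\delta$,
$R_2^*$) default to healthy cervical-cord means for the dorsal and lateral
white-matter columns and grey matter; CSF values (A 8000 a.u., $T_1$
4300 ms, $\delta$ 0.001, $R_2^*$ 2 s$^{-1}$) are literature-plausible
configuration defaults.

The geometry is a stack of parametric cross-sections: an elliptical cord
(left–right semi-axis 6.5 mm, anterior–posterior aspect 0.8) inside an
elliptical CSF space, the white matter split into a dorsal sector (±60°
about the posterior axis) and mirror-image lateral columns, and a central
grey-matter butterfly (two elliptical ventral–dorsal lobes joined by a
commissural bridge). Two kinds of through-slice structure give the slab
the z-variation real cord images have: a smooth 6% cord-radius bulge
(the cervical enlargement) and an 8% periodic modulation of the CSF
boundary at 18-mm spacing (the scalloping of the subarachnoid space at
vertebral levels). Without them, slice-axis translation is fundamentally
unidentifiable to any overlap-based cost on a replicated cross-section.

Image formation is band-limited, as in a real k-space-truncated
acquisition: labels are rendered at 4× in-plane supersampling, blurred
with a Gaussian point-spread function (FWHM 0.8 mm), and box-downsampled
to 1×1×3 mm voxels. Each voxel's signal is then the partial-volume
fraction-weighted mixture of the pure tissue signals (each compartment
decaying at its own $R_2^*$). Hard-edged rendering
(`render = list(supersample = 1, psf_fwhm_mm = 0)`) is available but
produces aliased edges whose interpolation artefacts dominate sub-voxel
registration — piecewise-constant voxels are not what scanners produce.

The transmit field is an affine in-plane ramp (mean percent, percent/mm),
bounded to 70–130%. The effective per-voxel saturation scales as $f_T^2$
(MT pulse power follows the transmit field); the excitation angle scales
as $f_T$. Fuller MT-pulse physics (lineshape, direct saturation) is out of
scope — $\delta$ is the quantity the pipeline estimates.

Noise is Rician (magnitude of signal plus complex Gaussian), with
$\sigma$ defined as the mean noiseless white-matter first-echo signal
divided by the SNR — one unambiguous SNR reference. Inter-scan motion is a
per-contrast rigid transform applied by sinc resampling. A fixed seed
makes every output bit-reproducible.

For cohorts, each of the four tissue parameters is scaled per subject by a
normal multiplier with the configured coefficient of variation, shared
across tissues so that grey/white contrast is preserved — modelling
subject-level biological plus receive-field variation. Defaults
(A 10%, $T_1$ 7%, $\delta$ 8%, $R_2^*$ 7%) match the inter-subject
variability reported for healthy cords. Drawn $T_1$ below 100 ms would be
unphysical and is resampled with a message.

### What the phantom does and does not emulate

It emulates: the acquisition parameter dependence of the three contrasts,
partial-volume and band-limiting at acquisition resolution, transmit-field
inhomogeneity including its effect on MT saturation, Rician noise,
inter-scan rigid motion, and realistic through-slice anatomy. It does not
emulate: receive-coil sensitivity profiles (uncorrected in APD by design),
$B_0$ inhomogeneity and susceptibility-induced non-monoexponential decay,
flow and physiological motion within a scan, slab-profile effects, or
k-space/parallel-imaging artefacts. Tests passing on the phantom therefore
validate the *estimators and the pipeline plumbing*, not robustness to
every in-vivo confound.

## Region statistics

`roi_summary()` reports spatial mean, sample SD and voxel count per region
and parameter, using only valid (unmasked) voxels. Because partial-volume
edge voxels are tissue mixtures, region masks can be eroded in-plane
(8-neighbourhood, `roi_set(erode = 1)`), mirroring the standard practice of
placing manual ROIs away from boundaries; with the default geometry this
keeps every region non-empty while removing mixed voxels. Inter-subject
variability is summarised as the coefficient of variation
$100\,\mathrm{SD}/\mathrm{mean}$ (sample SD, $n-1$), and intra-subject
robustness as the same quantity computed from the two parameter estimates
obtained from odd-echo and even-echo subsets — for two values,
$100\,(|a-b|/\sqrt2)/\bar{x}$. Group contrasts use classical paired
t-tests, uncorrected, as is conventional for these within-subject
comparisons (a Bonferroni option exists). The intra-class correlation of
the odd/even pair defaults to the one-way form ICC(1,1) — odd and even
halves are not distinguishable "raters", so a rater effect is not
identifiable; the two-way absolute-agreement form ICC(A,1) is available
via `icc(model = "two_way")`.

## Problem sizes and reproducibility

The phantom's study conditions are a 64×64×30 grid at 1×1×3 mm — large
enough that the cord, CSF space and all four ROI regions are resolved,
and the full four-step registration pipeline runs in a few minutes on one
core. The test suite exercises: algebraic forward–inverse consistency to
numerical precision; the exact-model $T_1$ bias bound against a
brute-force oracle; MTsat-vs-MTR transmit-field robustness; the AFI round
trip of an injected 90–110% ramp; recovery of injected rigid motions
within 0.5 mm/0.5° and sub-half-millimetre residual misalignment after the
full pipeline; odd/even robustness below 0.5% on noiseless data and its
monotone degradation across SNR 50/25/12 (matched noise draws); and a
13-subject cohort in which an injected 7% MTR coefficient of variation is
recovered within its chi-square sampling interval and the grey/white MTsat
difference is detected by paired t-test. `scripts/acceptance.R` recomputes
these quantities from scratch under a caller-supplied seed.
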