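---
title: "Resting-state regional metrics, cluster-corrected group maps and striatal DAT quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{restmap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`restmap` re-implements, at desk scale, the analysis chain used in
resting-state fMRI studies of parkinsonism that ask which regional changes
are *common* to Parkinson's disease (PD) and drug-induced parkinsonism
(DIP), and whether those common changes track presynaptic dopaminergic
integrity measured by dopamine-transporter (DAT) imaging. This vignette is
the package's account of the models and the numerical choices behind them.
Every empirical statement here is computed by the test suite
(`tests/testthat/`) or the acceptance script (`scripts/acceptance.R`); the
analysis drivers under `analysis/` walk the same stages narratively.

## The measurement models

**Regional homogeneity (ReHo)** is Kendall's coefficient of concordance
between a voxel's time series and its 26 nearest neighbours. With $K$
series of $n$ timepoints, each series ranked (ascending, average ranks for
ties), $R_i$ the rank sum at timepoint $i$ and $\bar R$ its mean,

$$W \;=\; \frac{\sum_i R_i^2 - n \bar R^2}{K^2 (n^3 - n)/12} \in [0, 1],$$

with 1 meaning perfectly synchronised neighbourhoods. The implementation is
checked against an independently coded rank-variance form of Kendall's W on
a thousand random neighbourhoods to $10^{-10}$.

**ALFF** (amplitude of low-frequency fluctuation) is the mean of the
single-sided amplitude spectrum over 0.01–0.08 Hz. The spectrum convention
is fixed and documented because it is usually left implicit: for a series
of length $n$, amplitude$_k = 2\,|X_k|/n$ at interior bins and $|X_k|/n$ at
the Nyquist bin, DC excluded. Under this convention a unit-amplitude on-bin
sinusoid contributes exactly 1 to its bin, which makes the closed-form test
cases exact rather than approximate. **fALFF** is the ratio of the in-band
amplitude sum to the amplitude sum over the entire detectable range (first
positive bin through Nyquist); it is dimensionless in $[0,1]$, invariant to
rescaling the series, while ALFF scales linearly.

**SNBR** (specific-to-nonspecific binding ratio) divides every voxel of a
DAT uptake volume by the scalar mean uptake of occipital gray matter, with
the reference restricted to voxels whose GM partial-volume estimate exceeds
0.9 when a PVE map is available. Regional values are arithmetic means over
the five striatal subregions obtained from template mm coordinates: caudate
ventral ($z \le 0$) / dorsal ($z > 0$); putamen posterior ($y \le 0$) /
anterior ($y > 0$); anterior putamen ventral ($z \le -4$) / dorsal
($z > 0$). The anterior-putamen rules as printed leave $-4 < z \le 0$
uncovered; the package deliberately preserves that gap — those voxels stay
unassigned and their count is reported in the parcellation provenance —
rather than inventing an interpolation the rules do not state.

## Preprocessing and the order question

The temporal chain is: discard the first 3 volumes (165 acquired, 162
analysed at TR = 2 s), motion QC (exclude if any per-axis displacement
from the first volume exceeds 3 mm or 3°, strictly "more than" — exactly
3.0 passes), per-voxel linear detrending, nuisance regression on nine
regressors (six motion parameters, mean CSF, mean WM, global mean, plus an
intercept), ideal rectangular band-pass filtering, and 4-mm FWHM isotropic
Gaussian smoothing.

Source descriptions of this kind of pipeline typically list smoothing,
band-passing, detrending and regression in acquisition-tool order. Applied
literally before fALFF, a 0.01–0.08 Hz pre-filter makes the metric
degenerate: the in-band-to-total ratio of an already band-limited signal is
1 everywhere. The package therefore fixes a *metric-consistent* order as
the default:

* **ReHo branch** — detrend → band-pass → nuisance regression, never
  smoothed (ReHo images are not smoothed in this design). The nuisance
  regressors are band-passed identically to the data first, so regression
  cannot reintroduce frequencies the filter removed.
* **ALFF/fALFF branch** — detrend → nuisance regression → smoothing, with
  no temporal pre-filter; the band enters inside the ALFF/fALFF
  computation itself.

The literal listed order remains available (`order = "literal"` in
`preprocess_branch()`), for comparison rather than production use.

The band-pass filter is an ideal (rectangular spectral) filter — DFT bins
with folded frequency outside $[f_{lo}, f_{hi}]$ zeroed, band-inclusive at
both edges, DC always removed — rather than an IIR design. This matches
spectral-filtering practice in the field's toolchains and gives exact
testable band edges: an on-bin in-band tone passes unchanged to machine
precision and an on-bin out-of-band tone is rejected below $10^{-10}$
relative RMS.

"Maximal displacement" for motion QC is not defined precisely in most
pipeline descriptions (per-axis vs Euclidean; reference volume). The
package uses per-axis absolute deviation from the first volume; this is the
strictest common reading and the one under which the 3.0-vs-3.1 boundary
behaviour is unambiguous.

## Group statistics

Voxel-wise contrasts are two-group OLS fits with age, sex, years of
education and MMSE as nuisance covariates — the "pairwise t-test with
covariates" reading of an ANOVA contrast; variance is not pooled across the
third group. The t statistics are verified against an explicit
normal-equations solver.

Multiple comparisons are handled by Monte-Carlo cluster-extent correction,
the construction behind AFNI's cluster simulation: simulate Gaussian noise
on the analysis mask, smooth to the assumed smoothness, standardise,
threshold two-tailed at $p_{voxel} = 0.005$, and record the maximum
same-sign cluster size; the extent threshold $k_{crit}$ is the smallest
size whose null exceedance probability is at most $\alpha = 0.05/3$ (the
Bonferroni-style adjustment for three pairwise group comparisons). The
published value of 40 voxels for this kind of analysis belongs to an
MNI-sized grid and its smoothness; $k_{crit}$ is **always recomputed** for
the current mask and kernel, never hard-coded. By default the assumed
smoothness is the applied kernel FWHM (4 mm for the smoothed branch, 0 for
the unsmoothed ReHo branch); an estimated-smoothness input can be supplied
instead. Connectivity defaults to 26 (faces, edges, corners — AFNI's NN3),
with 6 and 18 available.

Because signed increases and decreases are both reported, thresholding is
two-tailed and clusters are sign-homogeneous: positive and negative
suprathreshold voxels are labelled separately. The **conjunction** of the
two patient-versus-control results keeps a voxel only if it survives in
both with the same sign, then re-labels the intersection into connected
components — the analogue of a table of "regions showing common change".
Empirically (acceptance suite), the corrected family-wise error of a null
contrast sits inside the 95% binomial interval of $\alpha$ over 300
simulated null cohorts, and at zero smoothness the extent threshold agrees
with an independent permutation oracle within one voxel.

## The synthetic cohort generator

No patient data accompany this package; the generator supplies cohorts
with known ground truth so each claim above is testable.

Each voxel's BOLD series is
`baseline + sqrt(rho) * s_region(t) + noise`, where `s_region` is a shared
low-frequency component built from a fixed bank of sinusoids (default 8)
with frequencies drawn uniformly in 0.01–0.08 Hz **once per region per
cohort** and phases drawn per subject, normalised so the component's
variance is independent of the bank size. Drawing the frequency bank at
cohort level is deliberate: per-subject frequency draws add spectral
sampling noise to subject-level ALFF that attenuates implanted cross-modal
correlations without adding realism to the quantity under test. Implanted
ALFF/fALFF effects scale the shared amplitude by $(1 + \text{effect
size})$ in affected groups; ReHo effects scale the synchrony weight the
same way. A linear drift and a motion-locked confound are added to every
brain voxel and are expected to be removed by detrending and regression.
Motion traces are slow random walks whose excursions stay far below the QC
limits; motion never corrupts the volumes themselves.

DAT volumes put `u_ref` mean uptake in all nonspecific tissue and
`u_ref * binding` in the striatum, where per-group binding ratios default
to 3.0 for controls and DIP and a reduced 2.2 (caudate) / 2.4 (putamen) /
1.5 (posterior putamen) profile for PD — the qualitative pattern that
separates degenerative from drug-induced parkinsonism. Cross-modal
correlations are induced by latent subject factors: each binding source
and effect region carries a standard-normal latent; a requested target
$\rho$ between quantities $a$ and $b$ replaces $b$'s latent with $\rho
\, z_a + \sqrt{1-\rho^2} \, z_b$. Binding and amplitude jitter are
lognormal in these latents (mean-corrected), keeping both positive.

Covariate tables echo the demography of a three-group parkinsonism cohort
of 68/69/70 subjects (ages near 69, DIP least educated, MMSE control >
PD > DIP, about a quarter to a third male); sex is a plain binary covariate
and education/MMSE truncated normals, since only their role as nuisance
covariates matters here. UPDRS side sums give PD a right-dominant
asymmetry tendency and DIP a more symmetric profile; scan-interval columns
feed the 61-day inclusion filter ("2 months or less" is fixed at 61 days,
overridable). Neuropsychological columns named in a correlation target are
driven by the shared latents; the rest are independent noise around
group-shifted means.

All randomness flows from one integer seed through counter-derived
substreams (per subject, per data stream), so any subject's data are
bit-reproducible independently of cohort size, and identical
specifications yield byte-identical outputs.

**What the generator does not emulate:** anatomy is boxes and ellipsoids
on a 24 × 28 × 24 grid at 3 mm (chosen so the full pipeline runs in
minutes while preserving all mm-coordinate logic); there is no k-space
physics, no motion-corrupted volumes, no spatial normalisation step (data
are born on the common grid), no spatially varying noise, and BOLD spectra
are sinusoid banks plus white noise rather than 1/f. Passing tests
therefore demonstrate the *correctness of the computations and the
calibration of the inference machinery under the stated model*, not
performance on real scanner data.

## Study-scale choices and problem sizes

The package's test and acceptance workloads use cohorts of 15 subjects per
group on the default grid (the full pipeline on such a cohort takes well
under a minute per branch), 2,000 Monte-Carlo iterations for the extent
threshold, 300 null cohorts for the family-wise-error check, and n = 59
single-group cohorts on a reduced 10 × 12 × 10 grid for correlation
recovery — 59 being the canonical size of an interval-filtered PD
correlation subsample. Effect sizes for implanted group differences are
calibration choices of this package (no published effect sizes exist for
the underlying contrasts): the reference recovery setting is an amplitude
scaling of 0.5 (a halved or 1.5× shared-component amplitude) at noise sd
0.5, where the conjunction recovers the implanted region with median Dice
well above 0.5 over seeds while null cohorts stay empty.

## Numerical conventions and degenerate inputs

* Ranks use average ranks for ties; the KCC denominator is the printed
  no-ties form. Negative floating error beyond $-10^{-12}$ is clamped to 0.
* A zero-variance series anywhere in a ReHo neighbourhood, or a
  neighbourhood with fewer than `k_min = 14` in-mask members (mask edges),
  makes the voxel *degenerate*: it receives 0 inside the mask and is
  counted in the per-subject QC record. The same policy (0 + QC count,
  never NaN in written maps) applies to fALFF's 0/0 voxels.
* `normalize_map` divides by the in-mask mean (giving mask mean 1) or
  z-scores within the mask; out-of-mask voxels are written as 0.
* Gaussian smoothing converts FWHM to per-axis voxel sigmas via
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})/\text{voxel size}$, truncates at
  $4\sigma$, normalises the kernel to unit mass, and offers mask-aware
  renormalisation (divide by the smoothed mask) against edge dilution.
* The "entire detectable frequency range" in fALFF excludes DC and
  includes the first positive bin through Nyquist; both edges of the pass
  band are inclusive. These conventions are configurable but fixed in all
  defaults.
* ROI means for the correlation analyses are taken from z-scored maps (the
  stated convention for the NP analysis; ambiguous for the DAT analysis) —
  a switch selects global-mean-divided maps instead.
* Interval filtering is inclusive (`<= 61` days); a 62-day subject is
  excluded. Correlation tables report uncorrected two-tailed P with 0.05 /
  0.01 flags, plus a Benjamini–Hochberg column as supplementary output
  that never drives the flags.

## Known limitations

Peak coordinates are reported in the template's own mm space; no Talairach
or MNI conversion is attempted. The smoothness fed to the null simulation
is the applied kernel width, not an estimate from residuals, so if a real
dataset's effective smoothness exceeded the kernel the correction would be
anticonservative — the estimated-smoothness option exists for that case.
Within-region signal sharing makes in-region voxels of one subject's map
correlated; the family-wise-error guarantee is calibrated against
independent smoothed-noise cohorts of matched kernel width. The
correlation recovery check uses a reduced grid and a single effect region;
it demonstrates the latent-coupling mechanism, not a whole-brain
simulation. Partial-volume handling is a single GM-PVE threshold on the
reference region; no partial-volume correction is applied to the striatal
signal itself.
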