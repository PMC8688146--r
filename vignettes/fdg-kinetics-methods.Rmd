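---
title: "Methods: voxel-wise FDG kinetics, paired statistics, photometry and overlap filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise FDG kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgkin)
```

This vignette is the package's account of its own methods: the models, the
choices that were genuinely open, the numerical tolerances, and what the
synthetic-data tests do and do not establish about real data.

## The kinetic model

Dynamic FDG uptake is modelled with the standard two-tissue-compartment
system: a free compartment exchanging with plasma at rates $k_1$
(ml cm$^{-3}$ min$^{-1}$, transport) and $k_2$ (min$^{-1}$, efflux), and a
phosphorylated compartment filled at $k_3$ and emptied at $k_4$
(min$^{-1}$). The total-tissue impulse response has the closed form

$$h(t) = B_1 e^{-\alpha_1 t} + B_2 e^{-\alpha_2 t}, \qquad
\alpha_{1,2} = \tfrac12\left[(k_2+k_3+k_4) \mp
\sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}\right],$$

with $B_1 + B_2 = k_1$, and the tissue curve is $C_T = h \otimes C_p$.
Numerical care points:

* $\alpha_1$ is computed as $k_2 k_4 / \alpha_2$ (product of roots), which
  is exact and avoids the subtractive cancellation of the textbook form as
  $k_4 \to 0$.
* When $|\alpha_2 - \alpha_1| < 10^{-10}$ min$^{-1}$ (a genuine repeated
  root, e.g. $k_3 = 0$, $k_2 = k_4$) the degenerate limit
  $h(t) = k_1 e^{-\alpha t}\,[1 + (k_3{+}k_4{-}\alpha)t]$ is used; the
  forward model then falls back to adaptive numerical convolution, which is
  rare enough not to matter for speed.
* Convolution is analytic for the parametric bolus input and uses exact
  exponential-kernel integration over piecewise-linear segments for sampled
  inputs, written in `expm1`-stable forms with series branches for nearly
  equal rates. Both routes agree with a stiff ODE integration of the
  compartment equations to better than $10^{-9}$ relative (tested at
  $10^{-5}$).
* A tissue blood-volume term is deliberately absent: the model is exactly
  the four-constant system, and the phantom's blood signal lives in a
  separate blood-pool region. (This is a modelling simplification; real
  tissue voxels carry a few percent blood signal.)

Emission frames measure mean activity over the frame, so all fitting
compares frame means with frame means. `frame_average()` integrates
adaptively (relative tolerance $10^{-10}$) and therefore conserves the time
integral of the curve by construction. The default schedule is the 45-min,
25-frame protocol (12×30 s, 3×60 s, 3×120 s, 7×240 s).

The derived transport statistic is $C_e/C_p = k_1/(k_2 + k_3/\mathrm{LC})$
with the lumped-constant-type factor LC defaulting to 0.26. The factor is
treated as a configurable scalar; nothing in the package depends on its
interpretation. $C_e/C_p$ is linear in $k_1$, so a fractional change in
transport maps one-to-one onto the statistic.

## Plasma input

Real studies measure the input in vivo; for simulation the package uses a
tri-exponential Feng-type bolus
$C_p(t) = (A_1 t - A_2 - A_3)e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} +
A_3 e^{-\lambda_3 t}$, chosen because it is smooth, nonnegative, zero at
$t=0$, peaks early (< 2 min), decays over the scan and integrates in closed
form. Default rates are the classic bolus values
($\lambda = 4.134, 0.119, 0.0104$ min$^{-1}$) with amplitudes scaled to
mouse-typical kBq ml$^{-1}$. This family is a stand-in: it claims no
fidelity to any particular measured input beyond those shape constraints.

## Image-derived input function

The blood pool is identified on the first frame, where blood is an order
of magnitude hotter than tissue: candidates above a quantile of the
positive first-frame values (default 0.95) — guarded by a
fraction-of-maximum floor (0.25) so ties in warm tissue cannot leak in —
are reduced to the 6-connected component containing the global maximum. An
explicit mask can always be supplied instead.

The IDIF is the per-frame mean over the mask at frame mid-times. Partial
volume is corrected as
$(\text{measured} - (1-\text{vf})\cdot\text{background})/\text{vf}$ with
vf = 0.6; the default background is zero, i.e. pure division by 0.6, which
is the correction as usually stated — the spill-in term exists as an
option because published descriptions are ambiguous on this point.
Negative corrected values are clamped to zero with a warning and counted
in provenance. Between samples the corrected input is interpolated
linearly through the origin; beyond the last sample a single-exponential
tail fitted to the final three samples extends it (the last frame mid-time
is 2 min before scan end, so the tail matters).

The phantom mixes blood-pool voxels at exactly the volume fraction the
correction assumes (0.6), so on noiseless data the extraction-correction
round trip is exact to machine precision — that is a designed identity,
not an empirical success; a mismatch knob (`vf_true`) exists for
sensitivity studies.

## Voxel fitting

Each masked voxel minimizes $\sum_i w_i\,(y_i - \hat C_i)^2$ with
$w_i = \Delta t_i$ (longer frames carry more counts; uniform and custom
weights are selectable). Two structural facts make whole-image fits cheap:

1. The model is linear in $k_1$, so $k_1$ is profiled out analytically
   (clamped to its bounds) and the search runs over $(k_2, k_3, k_4)$ only.
2. For a fixed input and schedule, the frame-averaged convolution
   $F(\alpha)$ of $e^{-\alpha t}$ with $C_p$ is a smooth function of one
   variable. It is precomputed on a dense grid (2000 log-spaced nodes plus
   $\alpha = 0$, Gauss–Legendre 10-point averaging per frame) and evaluated
   by cubic Hermite interpolation, reducing every objective evaluation to
   two interpolated rows. The interpolation error is ~$10^{-7}$ relative,
   far below the fit tolerances.

The bounded search is Nelder–Mead on a sigmoid transform of the boxes
$k_1 \in [0,2]$, $k_2, k_3 \in [0,2]$, $k_4 \in [0,0.2]$ (generous
physiological ranges; $k_4$ small because FDG dephosphorylation is slow),
with relative objective tolerance $10^{-8}$, at most 500 iterations per
start and one restart from the incumbent with a tighter simplex. Starts
are a fixed point $(0.1, 0.1, 0.05, 0.01)$ plus four seeded log-uniform
multistarts; ties are broken by lowest weighted residual sum of squares,
then lowest $k_4$. Non-convergence flags the voxel rather than raising an
error. $k_4$ is free by default (all four constants are reported);
`fit_config(fix_k4 = 0)` selects the irreversible variant.

On the noiseless default phantom every regional constant is recovered to
better than $10^{-5}$ absolute (tested at $10^{-3}$) and the $C_e/C_p$ map
to well under 1% — a self-consistency check that the estimator inverts its
own forward model. Under ~5% TAC noise the median $C_e/C_p$ error across a
144-voxel region is ~6% with ~1% bias. These numbers quantify estimator
noise, not model misspecification: real tissue is heterogeneous within
voxels, inputs carry delay and dispersion, and reconstructed noise is
correlated — none of which the phantom emulates.

## The phantom

`make_atlas()` grows 8 blob-like tissue regions (named after the brain
regions a paired insulin study reports: CP, BNST/LPO, MBH, PAG, ZI/aSNR,
pSNR, MV, SPV) plus a small blood pool in a 20×20×10 volume of
0.4×0.4×0.8 mm voxels — desk-scale, no anatomical realism claimed beyond
labelled contiguous regions. Regional constants spread over
$k_1 \in [0.08, 0.22]$, $k_2 \in [0.25, 0.45]$, $k_3 \in [0.04, 0.09]$,
$k_4 \in [0.004, 0.015]$, a plausible grey-matter-like range. The insulin
condition multiplies $k_1$ by 0.7 in the designated effect region (a 30%
transport suppression, the direction the cross-over design targets);
per-subject log-normal multipliers on $k_1$ (SD 0.1) create the
between-subject variance a paired design removes.

Noise is zero-mean Gaussian with per-frame SD $\sqrt{S_c\,C/\Delta t}$ —
the standard count-limited TAC surrogate; no projection-space effects,
scatter, attenuation or reconstruction correlations are simulated. Rather
than hard-coding $S_c$, `sc_for_cv()` derives it so the median per-frame
coefficient of variation of a mid-range tissue TAC equals the target (5%
by default), keeping "percent noise" well-defined across input scalings.
Simulated data are decay-corrected by construction (the model works in
concentration units throughout).

## Paired statistics

`paired_tmap()` computes the two-sided paired Student's t per voxel on
subject-wise saline−insulin differences of the $C_e/C_p$ maps
(df = n−1; voxels undefined for any subject are excluded; zero-variance
voxels get p = 1 when the mean difference is zero and the smallest
representable p, flagged, otherwise). No multiple-testing correction is
applied to the voxel map — the workflow reports raw p-maps and then
re-tests region-level VOIs, and readers should treat voxel-level
significances accordingly; an FDR adjustment can be applied downstream.
The compared scalar is $C_e/C_p$ by default; cumulative uptake is equally
computable from the fitted maps if a study prefers it.

VOIs are 6-connected components of $\{p < \alpha\}$ (default
$\alpha = 0.05$), split by effect direction, of at least 4 voxels, named
by the dominant overlapping atlas region. `voi_test()` then runs the
paired t-test on subject-level VOI means and reports the mean difference
and insulin/saline ratio. `resample_pmap()` trilinearly interpolates the
p-map onto a finer grid (default 0.1 mm) for presentation only — the
stored statistics are never altered, and p-values (not t) are
interpolated, matching how such maps are usually displayed.

Calibration is checked at map level: a null cohort built from a true map
plus independent Gaussian noise (the `simulate_paired_maps()` generator)
keeps the voxel-wise false-positive fraction within Monte-Carlo error of
$\alpha$, and swapping condition labels negates every t exactly. The
end-to-end check (phantom → IDIF → fit → statistics, n = 8 pairs, 5%
noise) recovers the planted 30% effect as a single VOI in the effect
region with the correct direction and no false-positive VOI at default
settings. With fits independent across voxels and regions, that
specificity is expected; spatially correlated reconstruction noise in
real data would make cluster-level false positives more likely than the
phantom suggests.

## Photometry

The fluorescence signal is the ratio of the calcium-dependent 465 nm
channel to the 405 nm isosbestic channel, so any multiplicative artefact
common to both channels — movement, slow drift, bleaching of the shared
path — cancels exactly; this is an algebraic identity, tested as one.
$F_0$ is the median of the pre-event baseline window (robust to up to 49%
outlier contamination), dF/F is $(F - F_0)/F_0 \times 100$ in percent, and
the response AUC is the trapezoidal integral over the post-event window in
%·min. The integration window is configurable and defaults to the full
20-min post-event recording (a 10-min baseline plus 20-min post recording
is the default simulated session); published AUC windows are often left
implicit, hence the explicit default. No photobleaching correction is
applied. The simulator runs at 20 Hz; the analysis is sampling-rate
agnostic. Per-channel (non-shared) noise does not cancel in the ratio —
the seeded tests show its effect on AUC is below 5% at 1% channel noise.

## Overlap filtering

The translatome filter chain operates on any DE table with columns
`gene_id`, `biotype`, `mean_tpm`, `log2fc`, `padj`; the DE statistics
themselves are upstream tools' business. Boundary conventions follow the
printed rules exactly: the expression pre-filter keeps protein-coding
genes with TPM ≥ 1 (inclusive); the enrichment gate is padj ≤ 0.05 AND
log2FC > 0 (inclusive p, strict sign); the common-DEG gate is padj < 0.05
in both comparisons (strict). "Commonly regulated" is interpreted as
concordant-sign significance in both comparisons — that is the reading
under which an up/down partition sums to the common total — and `NA`
adjusted p-values (as DESeq2 emits for filtered genes) count as not
significant. The synthetic generator plants exact counts (default
74 up / 50 down, of which 60 / 28 inside the enriched set) and the chain
reproduces them exactly with noise off; with noise on, spurious overlaps
become possible, as in real data.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline at the
study's paired size (n = 8 subjects, 16 dynamic scans) on the 20×20×10
phantom, the null calibration on ~2000 voxels, and the forward-model
oracle on 10 random parameter sets × 2 input curves — sizes chosen so the
whole suite completes in minutes on a single core while leaving every
statistical check adequately powered. Every stochastic stage takes an
explicit seed (stage seeds are derived from the global seed with fixed
offsets), RNG state is restored after each call, and repeated runs of
`run_all()` with one configuration produce byte-identical NIfTI outputs.

## Known limitations

* The phantom is a labelled-blob world: no anatomy, no partial-volume
  blur between tissue regions, no attenuation/scatter/reconstruction
  effects, no input-function delay or dispersion.
* The IDIF correction is exact on the phantom by construction; on real
  data the volume fraction is an approximation and the background term
  may matter.
* Voxel-wise p-maps are uncorrected for multiplicity by design of the
  mirrored workflow; inference should rest on the VOI-level re-tests.
* The Nelder–Mead search is local; multistarts make misconvergence rare
  on well-formed TACs but pathological voxels are flagged rather than
  rescued.
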