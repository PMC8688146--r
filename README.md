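# fdgkin

Voxel-wise two-tissue-compartment kinetic analysis of dynamic [18F]FDG PET
for small-animal cross-over studies, with an image-derived,
partial-volume-corrected input function and paired voxel statistics — plus
fibre-photometry dF/F processing and an overlap filter chain for
differential-expression tables.

## Who this is for

Preclinical imaging groups that scan the same animal under two conditions
(e.g. saline vs insulin), fit rate constants voxel by voxel, and ask where
in the brain glucose transport changed. Every pipeline stage is testable
without animal data: a phantom module simulates paired dynamic scans with
known regional kinetics, so parameter recovery, input-function inversion
and statistical calibration can all be checked against ground truth.

## The model

Tissue activity follows the two-tissue-compartment FDG model with rate
constants k1 (transport, ml·cm⁻³·min⁻¹), k2 (efflux), k3
(phosphorylation) and k4 (dephosphorylation, all min⁻¹). Its
unit-impulse response is the two-exponential

    h(t) = B1·exp(−α1·t) + B2·exp(−α2·t),
    α₁,₂ = [(k2+k3+k4) ∓ √((k2+k3+k4)² − 4·k2·k4)] / 2,
    B1 = k1·(k3+k4−α1)/(α2−α1),  B2 = k1·(α2−k3−k4)/(α2−α1),

and the tissue curve is the convolution C_T(t) = (h ⊗ C_p)(t) with the
plasma input C_p. The input is extracted from the blood pool of the image
itself (IDIF) and corrected for partial volume by a standardized volume
fraction of 0.6. Frames are compared as frame means (the quantity an
emission frame measures), weighted by frame duration in the per-voxel
nonlinear least-squares fit. The derived statistic

    Ce/Cp = k1 / (k2 + k3/0.26)

is a blood-glucose-insensitive surrogate for glucose transport; paired
two-sided t-tests on per-subject Ce/Cp maps give voxel-wise p-maps, from
which volumes of interest (VOIs) are defined and re-tested at region level.

## Worked example

```r
library(fdgkin)

run <- run_all(default_run_config(seed = 1))  # ~1 min on one core
run$voi_table
#>   name n_voxels      direction mean_saline mean_insulin     ratio        t df            p
#> 1  MBH       60 saline>insulin   0.2380738    0.1683478 0.7071244 18.08354  7 3.909921e-07
```

The default configuration simulates 8 subjects, each scanned under saline
and insulin (25 frames, 12×30 s + 3×60 s + 3×120 s + 7×240 s; 0.4×0.4×0.8 mm
voxels; ~5% TAC noise), with insulin reducing k1 — and therefore Ce/Cp —
by 30% in the mediobasal-hypothalamus-like region "MBH". The pipeline
locates the blood pool on the first frame, extracts and corrects the IDIF,
fits k1–k4 in every masked voxel, and tests the paired Ce/Cp maps. The VOI
table above shows it recovers exactly one significant region: MBH, lower
under insulin (direction `saline>insulin`), with an estimated Ce/Cp ratio
of 0.707 against the planted 0.7 and a region-level paired p of 4·10⁻⁷.
No spurious VOI appears elsewhere.

Single stages are exported too:

```r
cp    <- feng_plasma()                       # parametric bolus input
sched <- default_frame_schedule()
tac   <- forward_tac(kinetic_params(0.1, 0.2, 0.05, 0.005), cp,
                     frame_mid_s(sched))     # model tissue curve
fit   <- fit_voxel(frame_average(tac, sched), sched, cp)
ce_cp(fit$params)                            # transport ratio
```

A thin command-line front end with `simulate`, `fit`, `stats`,
`photometry`, `overlap` and `run-all` subcommands is installed at
`system.file("cli", "fdgkin.R", package = "fdgkin")`.

## Photometry and translatome overlap

`analyze_photometry()` implements the 465/405 nm isosbestic ratio signal,
the median pre-event baseline F0, dF/F in percent and the post-event AUC
in %·min; `simulate_trace()` generates two-channel traces with shared
multiplicative artefacts for testing. `overlap_pipeline()` chains the
expression pre-filter (protein-coding, TPM ≥ 1), the enrichment gate
(padj ≤ 0.05 and log2FC > 0), the concordant-sign common-DEG intersection
(padj < 0.05 in both comparisons) and the restriction to an enriched gene
set, reporting all counts.

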