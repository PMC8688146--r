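#' Dynamic PET image
#'
#' A 4D voxel-by-frame activity volume with its frame schedule and voxel
#' geometry. Activities are in kBq ml^-1.
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param schedule A [frame_schedule()] whose length matches the 4th axis.
#' @param voxel_dims mm triple (default 0.4 x 0.4 x 0.8).
#' @return A `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, voxel_dims = c(0.4, 0.4, 0.8)) {
  stopifnot(length(dim(data)) == 4L, inherits(schedule, "frame_schedule"),
            length(voxel_dims) == 3L, all(voxel_dims > 0))
  if (dim(data)[4] != nrow(schedule))
    stop("frame axis length (", dim(data)[4], ") does not match schedule (",
         nrow(schedule), " frames)")
  structure(list(data = data, schedule = schedule,
                 voxel_dims = as.numeric(voxel_dims)),
            class = "dynamic_image")
}

#' Ground-truth kinetics for the phantom
#'
#' Per-region rate constants for each condition of a paired cross-over
#' design (saline vs insulin). Conditions are identical except in the
#' designated effect regions, where insulin multiplies `k1` (and therefore
#' Ce/Cp, which is linear in `k1`) by `effect`. Holds the noise scale `Sc`
#' (kBq ml^-1 s; per-frame noise SD is `sqrt(Sc * C / dt)`), the true
#' blood-pool mixing fraction, and the SD of the per-subject multiplicative
#' random effect on `k1`.
#'
#' @param atlas A [region_atlas()].
#' @param effect_regions Character names of regions where insulin acts.
#' @param effect Multiplier applied to `k1` under insulin (default 0.7,
#'   a 30% transport reduction).
#' @param sc Noise scale; `NULL` derives it at simulation time via
#'   [sc_for_cv()] so that a mid-range tissue TAC has `target_cv` median
#'   relative noise.
#' @param target_cv Target median per-frame coefficient of variation used
#'   when `sc` is `NULL` (default 0.05).
#' @param vf_true Volume fraction mixing true blood activity into the
#'   blood-pool voxels (default 0.6, matching the correction the pipeline
#'   applies, so the correction is exact on the phantom).
#' @param blood_bg Background activity level mixed into blood-pool voxels
#'   (scalar or per-frame; default 0).
#' @param subject_sd Log-scale SD of the per-subject `k1` multiplier.
#' @param lc Lumped-constant-type factor for true Ce/Cp maps.
#' @return A `ground_truth` with a per-region, per-condition parameter table.
#' @export
ground_truth <- function(atlas, effect_regions = "MBH", effect = 0.7,
                         sc = NULL, target_cv = 0.05, vf_true = 0.6,
                         blood_bg = 0, subject_sd = 0.1, lc = 0.26) {
  stopifnot(inherits(atlas, "region_atlas"), effect > 0,
            vf_true > 0, vf_true <= 1)
  labs <- tissue_labels(atlas)
  nms <- atlas$names[as.character(labs)]
  if (length(effect_regions) && !all(effect_regions %in% nms))
    stop("effect region(s) not present in the atlas: ",
         paste(setdiff(effect_regions, nms), collapse = ", "))
  n <- length(labs)
  # deterministic, physiologically plausible grey-matter-like spread
  base <- data.frame(
    label = labs, region = nms,
    k1 = seq(0.08, 0.22, length.out = n),
    k2 = seq(0.25, 0.45, length.out = n),
    k3 = seq(0.04, 0.09, length.out = n),
    k4 = seq(0.004, 0.015, length.out = n),
    stringsAsFactors = FALSE)
  saline <- cbind(base, condition = "saline")
  insulin <- cbind(base, condition = "insulin")
  hit <- insulin$region %in% effect_regions
  insulin$k1[hit] <- insulin$k1[hit] * effect
  params <- rbind(saline, insulin)
  params$cecp <- ce_cp(params, lc = lc)
  structure(list(params = params, effect_regions = effect_regions,
                 effect = effect, sc = sc, target_cv = target_cv,
                 vf_true = vf_true, blood_bg = blood_bg,
                 subject_sd = subject_sd, lc = lc),
            class = "ground_truth")
}

#' Noise scale for a target TAC coefficient of variation
#'
#' The phantom noise model is zero-mean Gaussian with per-frame SD
#' `sqrt(Sc * C / dt)` (activity- and duration-scaled, the standard TAC
#' noise surrogate). This returns the `Sc` for which the median per-frame
#' relative noise of the median-uptake tissue region equals `cv`.
#'
#' @param truth A [ground_truth()].
#' @param plasma A `plasma_input`.
#' @param schedule A [frame_schedule()].
#' @param cv Target median coefficient of variation.
#' @return Scalar `Sc` in kBq ml^-1 s.
#' @export
sc_for_cv <- function(truth, plasma, schedule, cv = truth$target_cv) {
  par <- truth$params[truth$params$condition == "saline", ]
  ref <- par[order(par$k1), ][ceiling(nrow(par) / 2), ]
  kp <- kinetic_params(ref$k1, ref$k2, ref$k3, ref$k4)
  C <- frame_average(forward_tac_fun_(kp, plasma), schedule)
  dt <- frame_dur_s(schedule)
  keep <- C > max(C) * 0.05
  stats::median(cv^2 * C[keep] * dt[keep])
}

effective_sc_ <- function(truth, plasma, schedule) {
  truth$sc %||% sc_for_cv(truth, plasma, schedule)
}

truth_params_ <- function(truth, region, condition) {
  row <- truth$params[truth$params$region == region &
                        truth$params$condition == condition, ]
  if (nrow(row) != 1L)
    stop("no ground-truth parameters for region '", region,
         "' under condition '", condition, "'")
  kinetic_params(row$k1, row$k2, row$k3, row$k4)
}

#' True Ce/Cp map for one condition
#'
#' @param truth A [ground_truth()].
#' @param atlas The matching [region_atlas()].
#' @param condition `"saline"` or `"insulin"`.
#' @return 3D array; `NA` outside tissue regions.
#' @export
truth_cecp_map <- function(truth, atlas, condition) {
  out <- array(NA_real_, dim(atlas$labels))
  for (lab in tissue_labels(atlas)) {
    region <- atlas$names[[as.character(lab)]]
    row <- truth$params[truth$params$region == region &
                          truth$params$condition == condition, ]
    out[atlas$labels == lab] <- row$cecp
  }
  out
}

#' Paired cross-over study design
#'
#' @param n_subjects Number of subjects; each receives one saline and one
#'   insulin scan.
#' @param ids Optional subject identifiers.
#' @return A `study_design` data frame with a `subject` column.
#' @export
study_design <- function(n_subjects = 8L, ids = NULL) {
  stopifnot(n_subjects >= 1L)
  ids <- ids %||% sprintf("S%02d", seq_len(n_subjects))
  stopifnot(anyDuplicated(ids) == 0L)
  structure(data.frame(subject = ids, stringsAsFactors = FALSE),
            class = c("study_design", "data.frame"))
}

#' Simulate one dynamic scan
#'
#' Tissue voxels receive the frame-averaged two-tissue-compartment response
#' to the plasma input plus zero-mean Gaussian noise with per-frame SD
#' `sqrt(Sc * C / dt)`. Blood-pool voxels mix the frame-averaged true
#' plasma activity with the background level at the true volume fraction
#' (`vf * Cp + (1 - vf) * bg`), so image-derived input extraction followed
#' by the partial-volume correction recovers `Cp` exactly on a noiseless
#' phantom. Background voxels are zero. Deterministic given `seed`.
#'
#' @param atlas A [region_atlas()].
#' @param truth A [ground_truth()] covering every tissue region.
#' @param condition Condition label present in `truth`.
#' @param plasma A `plasma_input`.
#' @param schedule A [frame_schedule()].
#' @param seed Integer seed for the noise.
#' @param subject_effect Multiplier applied to every regional `k1` (the
#'   per-subject random effect; default 1).
#' @return A [dynamic_image()].
#' @export
simulate_subject_scan <- function(atlas, truth, condition, plasma, schedule,
                                  seed = 1L, subject_effect = 1) {
  stopifnot(inherits(atlas, "region_atlas"), inherits(truth, "ground_truth"),
            subject_effect > 0)
  if (!condition %in% truth$params$condition)
    stop("condition '", condition, "' not present in the ground truth")
  dims <- dim(atlas$labels)
  nf <- nrow(schedule)
  sc <- effective_sc_(truth, plasma, schedule)
  dt <- frame_dur_s(schedule)
  out <- array(0, c(dims, nf))
  vol <- prod(dims)

  with_seed_(seed, {
    for (lab in tissue_labels(atlas)) {
      region <- atlas$names[[as.character(lab)]]
      kp <- truth_params_(truth, region, condition)
      kp[["k1"]] <- kp[["k1"]] * subject_effect
      C <- frame_average(forward_tac_fun_(kp, plasma), schedule)
      vox <- region_voxels(atlas, lab)
      sd_f <- sqrt(sc * pmax(C, 0) / dt)
      for (j in seq_len(nf))
        out[vox + (j - 1L) * vol] <- C[j] +
          stats::rnorm(length(vox), 0, sd_f[j])
    }
    Cp <- frame_average(function(t) plasma_conc(plasma, t), schedule)
    bg <- rep_len(truth$blood_bg, nf)
    Cb <- truth$vf_true * Cp + (1 - truth$vf_true) * bg
    vox <- region_voxels(atlas, atlas$blood_label)
    sd_f <- sqrt(sc * pmax(Cb, 0) / dt)
    for (j in seq_len(nf))
      out[vox + (j - 1L) * vol] <- Cb[j] +
        stats::rnorm(length(vox), 0, sd_f[j])
  })
  dynamic_image(out, schedule, atlas$voxel_dims)
}

#' Simulate a paired cross-over cohort
#'
#' One saline and one insulin scan per subject. A per-subject multiplicative
#' random effect (log-normal, SD `truth$subject_sd`) scales `k1` identically
#' in both of that subject's scans; the two conditions otherwise differ only
#' through the effect regions and fresh noise. Also returns the true Ce/Cp
#' map per condition for recovery tests.
#'
#' @param design A [study_design()].
#' @param atlas,truth,plasma,schedule See [simulate_subject_scan()].
#' @param seed Integer seed; subject effects and per-scan noise seeds are
#'   drawn from it.
#' @return A `pet_cohort`: list with `scans` (named
#'   `"<subject>.<condition>"`), `design`, `subject_effects`, `truth_cecp`
#'   (list of saline/insulin 3D arrays), `atlas`, `schedule`.
#' @export
simulate_cohort <- function(design, atlas, truth, plasma, schedule,
                            seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  n <- nrow(design)
  conds <- c("saline", "insulin")
  draws <- with_seed_(seed, list(
    effects = exp(stats::rnorm(n, 0, truth$subject_sd)),
    scan_seeds = sample.int(.Machine$integer.max - 1L, 2L * n)))
  scans <- vector("list", 2L * n)
  nm <- character(2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (cond in conds) {
      k <- k + 1L
      scans[[k]] <- simulate_subject_scan(
        atlas, truth, cond, plasma, schedule,
        seed = draws$scan_seeds[k], subject_effect = draws$effects[i])
      nm[k] <- paste(design$subject[i], cond, sep = ".")
    }
  }
  names(scans) <- nm
  structure(list(
    scans = scans, design = design,
    subject_effects = stats::setNames(draws$effects, design$subject),
    truth_cecp = list(saline = truth_cecp_map(truth, atlas, "saline"),
                      insulin = truth_cecp_map(truth, atlas, "insulin")),
    atlas = atlas, schedule = schedule), class = "pet_cohort")
}
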