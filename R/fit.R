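#' Voxel-fit configuration
#'
#' Bounds, initialization, multistart and convergence settings for the
#' voxel-wise weighted nonlinear least-squares fit. Defaults: generous
#' physiological boxes (`k1 in [0, 2]` ml cm^-3 min^-1, `k2, k3 in [0, 2]`
#' min^-1, `k4 in [0, 0.2]` min^-1, small because FDG dephosphorylation is
#' slow), a fixed start at (0.1, 0.1, 0.05, 0.01) plus 4 seeded log-uniform
#' multistarts, frame-duration weights, relative objective tolerance 1e-8
#' and at most 500 iterations per start.
#'
#' @param lower,upper Bounds for (k1, k2, k3, k4).
#' @param init Fixed starting point (k1 is profiled analytically, so only
#'   the (k2, k3, k4) components steer the search).
#' @param multistart Number of additional seeded random starts.
#' @param weights `"duration"` (w_i = frame duration; longer frames weigh
#'   more), `"uniform"`, or a numeric vector per frame.
#' @param ftol Relative objective convergence tolerance.
#' @param maxit Maximum iterations per start.
#' @param fix_k4 Fix `k4` at this value instead of fitting it (`NULL` =
#'   free, the default; all four constants are reported).
#' @param mask_quantile Quantile used by [brain_mask()].
#' @param seed Seed for the multistart draws.
#' @param n_alpha,alpha_max Basis grid resolution, see [tac_basis()].
#' @param lc Lumped-constant-type factor for the Ce/Cp map.
#' @return A `fit_config` list.
#' @export
fit_config <- function(lower = c(0, 0, 0, 0), upper = c(2, 2, 2, 0.2),
                       init = c(0.1, 0.1, 0.05, 0.01), multistart = 4L,
                       weights = "duration", ftol = 1e-8, maxit = 500L,
                       fix_k4 = NULL, mask_quantile = 0.1, seed = 1L,
                       n_alpha = 2000L, alpha_max = NULL, lc = 0.26) {
  stopifnot(length(lower) == 4L, length(upper) == 4L, all(lower <= upper),
            length(init) == 4L, all(init >= lower), all(init <= upper),
            multistart >= 0L)
  alpha_max <- alpha_max %||% (sum(upper[2:4]) * 1.05)
  structure(list(lower = lower, upper = upper, init = init,
                 multistart = as.integer(multistart), weights = weights,
                 ftol = ftol, maxit = as.integer(maxit), fix_k4 = fix_k4,
                 mask_quantile = mask_quantile, seed = as.integer(seed),
                 n_alpha = as.integer(n_alpha), alpha_max = alpha_max,
                 lc = lc),
            class = "fit_config")
}

# (k2, k3, k4) starting points: the fixed init plus seeded log-uniform draws
fit_starts_ <- function(config) {
  lo <- pmax(config$lower[2:4], 1e-3)
  hi <- config$upper[2:4]
  fixed <- matrix(config$init[2:4], nrow = 1L)
  if (config$multistart == 0L) return(fixed)
  rand <- with_seed_(config$seed, {
    matrix(exp(stats::runif(3L * config$multistart, log(lo), log(hi))),
           ncol = 3L, byrow = TRUE)
  })
  rbind(fixed, rand)
}

fit_weights_ <- function(config, schedule) {
  if (is.numeric(config$weights)) {
    stopifnot(length(config$weights) == nrow(schedule))
    return(config$weights)
  }
  switch(config$weights,
         duration = s_to_min(frame_dur_s(schedule)),
         uniform = rep(1, nrow(schedule)),
         stop("unknown weight rule '", config$weights, "'"))
}

#' Brain mask from time-integrated activity
#'
#' Voxels whose time-integrated activity exceeds half the
#' `threshold_quantile` quantile of the nonzero integrals (a permissive cut
#' that keeps all tissue on the phantom while rejecting empty background).
#' An optional blood-pool mask is excluded.
#'
#' @param image A [dynamic_image()].
#' @param threshold_quantile Quantile in (0, 1), default 0.1.
#' @param exclude Optional logical mask to remove (e.g. the blood pool).
#' @return Logical 3D mask.
#' @export
brain_mask <- function(image, threshold_quantile = 0.1, exclude = NULL) {
  stopifnot(inherits(image, "dynamic_image"))
  dt <- frame_dur_s(image$schedule)
  d <- dim(image$data)
  integral <- array(as.vector(matrix(image$data, ncol = d[4]) %*% dt), d[1:3])
  pos <- integral[integral > 0]
  if (length(pos) == 0L) stop("image has no activity; empty brain mask")
  cut <- stats::quantile(pos, threshold_quantile, names = FALSE) / 2
  mask <- integral >= cut
  if (!is.null(exclude)) mask <- mask & !exclude
  if (!any(mask)) stop("brain mask is empty")
  mask
}

#' Fit one time-activity curve
#'
#' Weighted nonlinear least squares for the two-tissue-compartment model:
#' minimizes `sum_i w_i (tac_i - model_i)^2` over bounded (k1..k4), with
#' `w_i` the frame durations by default. The model is linear in `k1`, which
#' is profiled analytically; the remaining parameters are searched by
#' multistart Nelder-Mead. Non-convergence is flagged, never an exception.
#'
#' @param tac Per-frame activities (kBq ml^-1).
#' @param schedule A [frame_schedule()].
#' @param plasma A `plasma_input` covering the schedule.
#' @param config A [fit_config()].
#' @param basis Optional precomputed [tac_basis()] (built if missing).
#' @return A list with `params` ([kinetic_params()]), `cecp`, `wrss`,
#'   `converged`, and `start_wrss` (objective at each multistart
#'   initialization, for diagnostics).
#' @export
fit_voxel <- function(tac, schedule, plasma, config = fit_config(),
                      basis = NULL) {
  stopifnot(is.numeric(tac), length(tac) == nrow(schedule),
            all(is.finite(tac)))
  basis <- basis %||% tac_basis(plasma, schedule, config$n_alpha,
                                config$alpha_max)
  w <- fit_weights_(config, schedule)
  starts <- fit_starts_(config)
  fk4 <- if (is.null(config$fix_k4)) -1 else config$fix_k4
  res <- cpp_fit_tacs(matrix(tac, nrow = 1L), w, basis$alpha, basis$F,
                      basis$D, config$lower, config$upper, starts,
                      config$ftol, config$maxit, fk4)
  start_wrss <- apply(starts, 1L, function(s) {
    k4 <- if (is.null(config$fix_k4)) s[3] else config$fix_k4
    m <- basis_model_frames_(c(1, s[1], s[2], k4), basis)
    den <- sum(w * m^2)
    k1 <- if (den > 0) min(max(sum(w * m * tac) / den, config$lower[1]),
                           config$upper[1]) else 0
    sum(w * (tac - k1 * m)^2)
  })
  params <- kinetic_params(res[1, 1], res[1, 2], res[1, 3], res[1, 4])
  list(params = params,
       cecp = suppressWarnings(ce_cp(params, config$lc)),
       wrss = res[1, 5], converged = res[1, 6] == 1,
       start_wrss = start_wrss)
}

#' Parametric map container
#'
#' Per-voxel fitted constants plus derived Ce/Cp, weighted residual sum of
#' squares and a convergence flag; voxels outside the mask are `NA`.
#' Created by [fit_image()].
#'
#' @name parametric_map
NULL

#' Fit every masked voxel of a dynamic image
#'
#' Applies [fit_voxel()] over the brain mask and assembles parametric maps
#' of k1..k4, Ce/Cp (via [ce_cp()]), WRSS and convergence. Unmasked voxels
#' are `NA`.
#'
#' @param image A [dynamic_image()].
#' @param plasma A `plasma_input` covering the schedule (sampled inputs are
#'   made continuous with [as_continuous()]).
#' @param config A [fit_config()].
#' @param mask Optional logical mask; default [brain_mask()].
#' @param exclude Optional mask removed from the default brain mask
#'   (typically the blood pool).
#' @param verbose Print progress.
#' @return A `parametric_map`: list of 3D arrays `k1`, `k2`, `k3`, `k4`,
#'   `cecp`, `wrss`, `converged`, plus `mask`, `voxel_dims`, `config`.
#' @export
fit_image <- function(image, plasma, config = fit_config(), mask = NULL,
                      exclude = NULL, verbose = FALSE) {
  stopifnot(inherits(image, "dynamic_image"))
  sched <- image$schedule
  if (inherits(plasma, "plasma_sampled")) {
    if (max(plasma$time_s) < max(frame_mid_s(sched)) - 1e-6)
      stop("plasma input does not cover the frame schedule")
    plasma <- as_continuous(plasma)
  }
  mask <- mask %||% brain_mask(image, config$mask_quantile, exclude = exclude)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty fit mask")
  d <- dim(image$data)
  tacs <- matrix(image$data, ncol = d[4])[idx, , drop = FALSE]
  if (any(!is.finite(tacs))) stop("non-finite activities inside the mask")
  basis <- tac_basis(plasma, sched, config$n_alpha, config$alpha_max)
  w <- fit_weights_(config, sched)
  starts <- fit_starts_(config)
  fk4 <- if (is.null(config$fix_k4)) -1 else config$fix_k4
  if (verbose)
    message("fitting ", length(idx), " voxels (",
            nrow(starts), " starts each)")
  res <- cpp_fit_tacs(tacs, w, basis$alpha, basis$F, basis$D,
                      config$lower, config$upper, starts,
                      config$ftol, config$maxit, fk4)
  blank <- array(NA_real_, d[1:3])
  put <- function(col) { a <- blank; a[idx] <- res[, col]; a }
  converged <- array(FALSE, d[1:3])
  converged[idx] <- res[, 6] == 1
  cecp <- blank
  kc <- list(k1 = res[, 1], k2 = res[, 2], k3 = res[, 3])
  cecp[idx] <- ifelse(res[, 6] == 1,
                      suppressWarnings(ce_cp(kc, config$lc)), NA_real_)
  n_nc <- sum(res[, 6] != 1)
  if (verbose && n_nc > 0)
    message(n_nc, " voxel(s) did not converge")
  structure(list(k1 = put(1), k2 = put(2), k3 = put(3), k4 = put(4),
                 cecp = cecp, wrss = put(5), converged = converged,
                 mask = mask, voxel_dims = image$voxel_dims,
                 n_nonconverged = n_nc, config = config),
            class = "parametric_map")
}
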