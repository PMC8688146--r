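#' Two-tissue-compartment rate constants
#'
#' Rate constants of the irreversible-plus-dephosphorylation FDG model:
#' `k1` (transport, ml cm^-3 min^-1), `k2` (efflux, min^-1), `k3`
#' (phosphorylation, min^-1), `k4` (dephosphorylation, min^-1).
#'
#' @param k1,k2,k3,k4 Nonnegative scalars.
#' @return A named numeric vector of class `kinetic_params`.
#' @export
kinetic_params <- function(k1, k2, k3, k4 = 0) {
  k <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(k)) || any(k < 0))
    stop("rate constants must be finite and nonnegative")
  structure(k, class = "kinetic_params")
}

#' Impulse response of the two-tissue-compartment model
#'
#' Closed-form solution of the compartment ODEs for a unit-impulse plasma
#' input. The total-tissue response is
#' \deqn{h(t) = B_1 e^{-\alpha_1 t} + B_2 e^{-\alpha_2 t}} with
#' \deqn{\alpha_{1,2} = \frac{(k_2+k_3+k_4) \mp
#'   \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4}}{2}}
#' \deqn{B_1 = k_1 \frac{k_3+k_4-\alpha_1}{\alpha_2-\alpha_1},\qquad
#'   B_2 = k_1 \frac{\alpha_2-k_3-k_4}{\alpha_2-\alpha_1}.}
#' \eqn{\alpha_1} is computed as \eqn{k_2 k_4/\alpha_2} (product of roots),
#' which is stable as \eqn{k_4 \to 0}. When \eqn{|\alpha_2-\alpha_1| <
#' 10^{-10}} min^-1 the repeated-root limit
#' \eqn{h(t) = k_1 e^{-\alpha t}(1 + (k_3+k_4-\alpha)t)} is used.
#'
#' @param params A [kinetic_params()].
#' @return A list with `B1`, `B2`, `alpha1`, `alpha2` (min^-1),
#'   `degenerate`, and the input `params`.
#' @examples
#' impulse_response(kinetic_params(0.1, 0.2, 0.05, 0))
#' @export
impulse_response <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  k1 <- params[["k1"]]; k2 <- params[["k2"]]
  k3 <- params[["k3"]]; k4 <- params[["k4"]]
  S <- k2 + k3 + k4
  disc <- max(S^2 - 4 * k2 * k4, 0)
  sq <- sqrt(disc)
  a2 <- (S + sq) / 2
  a1 <- if (a2 > 0) k2 * k4 / a2 else 0
  degenerate <- (a2 - a1) < 1e-10
  if (degenerate) {
    a <- (a1 + a2) / 2
    return(structure(list(B1 = NA_real_, B2 = NA_real_, alpha1 = a,
                          alpha2 = a, degenerate = TRUE, params = params),
                     class = "impulse_response"))
  }
  B1 <- k1 * (k3 + k4 - a1) / (a2 - a1)
  B2 <- k1 * (a2 - k3 - k4) / (a2 - a1)
  structure(list(B1 = B1, B2 = B2, alpha1 = a1, alpha2 = a2,
                 degenerate = FALSE, params = params),
            class = "impulse_response")
}

#' @rdname impulse_response
#' @param ir An `impulse_response`.
#' @param t_min Times in minutes.
#' @export
eval_impulse <- function(ir, t_min) {
  k <- ir$params
  if (ir$degenerate) {
    a <- ir$alpha1
    k[["k1"]] * exp(-a * t_min) * (1 + (k[["k3"]] + k[["k4"]] - a) * t_min)
  } else {
    ir$B1 * exp(-ir$alpha1 * t_min) + ir$B2 * exp(-ir$alpha2 * t_min)
  }
}

# ---- exponential-kernel convolutions (time in minutes) ----

# conv of e^(-alpha t) with e^(-lam t): (e^(-lam t) - e^(-alpha t))/(alpha-lam)
conv_ee_ <- function(alpha, lam, t) {
  x <- alpha - lam
  if (abs(x) < 1e-12) return(t * exp(-alpha * t))
  exp(-alpha * t) * expm1(x * t) / x
}

# conv of e^(-alpha t) with t e^(-lam t)
conv_te_ <- function(alpha, lam, t) {
  x <- lam - alpha
  u <- x * t
  small <- abs(u) < 1e-3
  out <- numeric(length(t))
  if (any(!small)) {
    ts <- t[!small]
    out[!small] <- (exp(-alpha * ts) - (1 + x * ts) * exp(-lam * ts)) / x^2
  }
  if (any(small)) { # series in u = (lam-alpha) t, avoids cancellation
    ts <- t[small]; us <- u[small]
    out[small] <- exp(-alpha * ts) * ts^2 * (0.5 - us / 3 + us^2 / 8)
  }
  out
}

# conv of e^(-alpha t) with a Feng bolus, unit amplitude on the kernel
conv_exp_feng_ <- function(alpha, t_min, p) {
  p$A1 * conv_te_(alpha, p$l1, t_min) -
    (p$A2 + p$A3) * conv_ee_(alpha, p$l1, t_min) +
    p$A2 * conv_ee_(alpha, p$l2, t_min) +
    p$A3 * conv_ee_(alpha, p$l3, t_min)
}

# conv of e^(-alpha t) with a piecewise-linear sampled input
# (exact per-segment integration; exponential tail beyond the last knot)
conv_exp_plin_ <- function(alpha, t_min, knots_min, vals, tail_lambda_min) {
  stopifnot(length(knots_min) == length(vals))
  if (knots_min[1] > 0) { # implicit origin anchor
    knots_min <- c(0, knots_min)
    vals <- c(0, vals)
  }
  nk <- length(knots_min)
  out <- numeric(length(t_min))
  g_ <- function(u) { # e^u * u - expm1(u), series for small u
    small <- abs(u) < 1e-4
    r <- numeric(length(u))
    r[!small] <- exp(u[!small]) * u[!small] - expm1(u[!small])
    r[small] <- u[small]^2 / 2 + u[small]^3 / 3
    r
  }
  for (i in seq_len(nk - 1L)) {
    a <- knots_min[i]; b <- knots_min[i + 1L]
    va <- vals[i]; m <- (vals[i + 1L] - va) / (b - a)
    act <- t_min > a
    if (!any(act)) next
    tt <- t_min[act]
    be <- pmin(b, tt)
    d <- be - a
    if (alpha > 0) {
      Ea <- exp(-alpha * (tt - a))
      u <- alpha * d
      seg <- va * Ea * expm1(u) / alpha + m * Ea * g_(u) / alpha^2
    } else {
      seg <- va * d + m * d^2 / 2
    }
    out[act] <- out[act] + seg
  }
  tm <- knots_min[nk]; vm <- vals[nk]
  act <- t_min > tm
  if (any(act) && vm > 0) {
    u <- t_min[act] - tm
    out[act] <- out[act] + vapply(u, function(uu)
      conv_ee_(alpha, tail_lambda_min, uu), numeric(1)) * vm
  }
  out
}

#' Tissue time-activity curve (forward model)
#'
#' Convolves the two-tissue-compartment impulse response with a plasma
#' input: \eqn{C_T(t) = (h \otimes C_p)(t)}. The convolution is analytic
#' for the parametric bolus family and uses exact exponential-kernel
#' integration over piecewise-linear segments for sampled inputs; the rare
#' repeated-root branch falls back to adaptive numerical convolution.
#'
#' @param params A [kinetic_params()].
#' @param plasma A `plasma_input`.
#' @param times_s Evaluation times (seconds), >= 0.
#' @return A `tissue_curve`: data frame with `time_s`, `value` (kBq ml^-1).
#' @export
forward_tac <- function(params, plasma, times_s) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(plasma, "plasma_input"))
  if (any(times_s < -1e-9)) stop("times must be nonnegative")
  t_min <- s_to_min(pmax(times_s, 0))
  ir <- impulse_response(params)
  if (params[["k1"]] == 0) {
    v <- numeric(length(times_s))
  } else if (ir$degenerate) {
    v <- vapply(t_min, function(tt) {
      if (tt == 0) return(0)
      stats::integrate(function(s)
        eval_impulse(ir, tt - s) * plasma_conc(plasma, min_to_s(s)),
        0, tt, rel.tol = 1e-10, subdivisions = 500L)$value
    }, numeric(1))
  } else if (inherits(plasma, "plasma_feng")) {
    v <- ir$B1 * conv_exp_feng_(ir$alpha1, t_min, plasma) +
      ir$B2 * conv_exp_feng_(ir$alpha2, t_min, plasma)
  } else if (inherits(plasma, "plasma_sampled")) {
    km <- s_to_min(plasma$time_s)
    v <- ir$B1 * conv_exp_plin_(ir$alpha1, t_min, km, plasma$conc,
                                plasma$tail_lambda_min) +
      ir$B2 * conv_exp_plin_(ir$alpha2, t_min, km, plasma$conc,
                             plasma$tail_lambda_min)
  } else {
    stop("unsupported plasma input class")
  }
  structure(data.frame(time_s = times_s, value = v),
            class = c("tissue_curve", "data.frame"))
}

# continuous-time forward model as a function of seconds (internal)
forward_tac_fun_ <- function(params, plasma) {
  function(t_s) forward_tac(params, plasma, t_s)$value
}

#' Frame-average a continuous curve
#'
#' Per-frame mean concentration \eqn{(1/\Delta t)\int_{t_0}^{t_1} C(t)dt},
#' the quantity an emission frame measures. Accepts a vectorized function of
#' time in seconds or a `tissue_curve` (interpolated linearly). Frame
#' averaging conserves the time integral: `sum(value * dur) = integral`.
#'
#' @param curve Function of seconds, or a `tissue_curve`.
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of per-frame mean activities.
#' @export
frame_average <- function(curve, schedule) UseMethod("frame_average")

#' @export
frame_average.function <- function(curve, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  mapply(function(s, e) {
    stats::integrate(curve, s, e, rel.tol = 1e-10,
                     subdivisions = 1000L)$value / (e - s)
  }, schedule$frame_start_s, schedule$frame_end_s)
}

#' @export
frame_average.tissue_curve <- function(curve, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  rng <- range(curve$time_s)
  if (min(schedule$frame_start_s) < rng[1] - 1e-9 ||
      max(schedule$frame_end_s) > rng[2] + 1e-9)
    stop("schedule extends beyond the support of the curve")
  f <- stats::approxfun(curve$time_s, curve$value, rule = 2)
  frame_average.function(f, schedule)
}

#' Glucose-transport ratio Ce/Cp
#'
#' The ratio of tissue to plasma glucose concentration derived from the
#' fitted rate constants, \deqn{C_e/C_p = \frac{k_1}{k_2 + k_3/LC}} with
#' the lumped-constant-type factor `lc` defaulting to 0.26. Used as a
#' blood-glucose-insensitive surrogate for glucose transport. Voxels with a
#' nonpositive denominator return `NA` (flagged, not an error).
#'
#' @param params A [kinetic_params()], or a list/data frame with elements
#'   `k1`, `k2`, `k3` (vectorized).
#' @param lc Positive dimensionless factor dividing `k3` (default 0.26).
#' @return Dimensionless ratio(s); `NA` where undefined.
#' @examples
#' ce_cp(kinetic_params(0.1, 0.2, 0.052)) # 0.25
#' @export
ce_cp <- function(params, lc = 0.26) {
  stopifnot(is.numeric(lc), length(lc) == 1L, lc > 0)
  if (inherits(params, "kinetic_params")) {
    k1 <- params[["k1"]]; k2 <- params[["k2"]]; k3 <- params[["k3"]]
  } else {
    k1 <- params$k1; k2 <- params$k2; k3 <- params$k3
  }
  den <- k2 + k3 / lc
  out <- ifelse(is.finite(den) & den > 0, k1 / den, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " voxel(s) with undefined Ce/Cp (zero denominator)")
  out
}
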