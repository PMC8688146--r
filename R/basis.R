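# Frame-averaged exponential-convolution basis.
#
# The 2TCM tissue model is k1 * (B1u * F(alpha1) + B2u * F(alpha2)) where
# F(alpha) is the frame-averaged convolution of exp(-alpha t) with the
# plasma input and B1u, B2u are the unit-k1 amplitudes. Precomputing F on a
# dense alpha grid (exact convolution, Gauss-Legendre 10-point averaging per
# frame) reduces every objective evaluation during voxel fitting to two
# cubic-Hermite interpolations, which is what makes whole-image fits cheap.

#' Precompute the fitting basis for a plasma input and schedule
#'
#' @param plasma A `plasma_input` (parametric or sampled).
#' @param schedule A [frame_schedule()].
#' @param n_alpha Number of decay-rate grid nodes (0 plus a log-spaced grid).
#' @param alpha_max Largest decay rate covered (min^-1); must exceed
#'   `k2 + k3 + k4` at the fit bounds.
#' @return A `tac_basis` used by [fit_voxel()] and [fit_image()].
#' @export
tac_basis <- function(plasma, schedule, n_alpha = 2000L, alpha_max = 4.5) {
  stopifnot(inherits(plasma, "plasma_input"),
            inherits(schedule, "frame_schedule"), n_alpha >= 50L)
  nf <- nrow(schedule)
  # Gauss-Legendre nodes/weights per frame (minutes)
  nodes <- matrix(0, 10L, nf)
  wts <- matrix(0, 10L, nf)
  for (j in seq_len(nf)) {
    gl <- pracma::gaussLegendre(10L, s_to_min(schedule$frame_start_s[j]),
                                s_to_min(schedule$frame_end_s[j]))
    nodes[, j] <- gl$x
    wts[, j] <- gl$w / s_to_min(frame_dur_s(schedule)[j]) # mean, not integral
  }
  tt <- as.vector(nodes)
  alpha <- c(0, exp(seq(log(1e-4), log(alpha_max), length.out = n_alpha - 1L)))
  conv <- matrix(0, n_alpha, length(tt))
  if (inherits(plasma, "plasma_feng")) {
    for (i in seq_len(n_alpha))
      conv[i, ] <- conv_exp_feng_(alpha[i], tt, plasma)
  } else if (inherits(plasma, "plasma_sampled")) {
    km <- s_to_min(plasma$time_s)
    for (i in seq_len(n_alpha))
      conv[i, ] <- conv_exp_plin_(alpha[i], tt, km, plasma$conc,
                                  plasma$tail_lambda_min)
  } else stop("unsupported plasma input class")
  # frame means: weight matrix is block diagonal over frames
  W <- matrix(0, length(tt), nf)
  for (j in seq_len(nf)) W[(j - 1L) * 10L + 1:10, j] <- wts[, j]
  Fm <- conv %*% W
  # d F / d alpha on the nonuniform grid (3-point weighted differences)
  D <- Fm
  h <- diff(alpha)
  for (i in seq_len(n_alpha)) {
    if (i == 1L) D[i, ] <- (Fm[2L, ] - Fm[1L, ]) / h[1L]
    else if (i == n_alpha)
      D[i, ] <- (Fm[i, ] - Fm[i - 1L, ]) / h[i - 1L]
    else D[i, ] <- ((Fm[i + 1L, ] - Fm[i, ]) / h[i] * h[i - 1L] +
                      (Fm[i, ] - Fm[i - 1L, ]) / h[i - 1L] * h[i]) /
        (h[i - 1L] + h[i])
  }
  structure(list(alpha = alpha, F = Fm, D = D, schedule = schedule),
            class = "tac_basis")
}

# model frame vector for given kinetic parameters via the basis (C++ kernel)
basis_model_frames_ <- function(params, basis) {
  cpp_model_frames(as.numeric(params), basis$alpha, basis$F, basis$D)
}
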