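# Independent ODE oracle for the two-tissue-compartment model: direct stiff
# integration of the compartment equations, evaluated at arbitrary times.
ode_tac_oracle <- function(params, plasma, times_s, rtol = 1e-10) {
  rhs <- function(t_min, y, p) {
    Cp <- plasma_conc(plasma, t_min * 60)
    list(c(params[["k1"]] * Cp -
             (params[["k2"]] + params[["k3"]]) * y[1] + params[["k4"]] * y[2],
           params[["k3"]] * y[1] - params[["k4"]] * y[2]))
  }
  out <- deSolve::ode(c(0, 0), c(0, times_s / 60), rhs, NULL,
                      method = "lsoda", rtol = rtol, atol = 1e-12)
  rowSums(out[-1, 2:3, drop = FALSE])
}

# small shared phantom pieces (built once per test run)
tiny_atlas <- function(seed = 1L) make_atlas(c(20L, 20L, 10L), 8L, seed = seed)

# single-region atlas with >= 100 voxels for noise studies
block_atlas <- function() {
  labs <- array(0L, c(8L, 8L, 6L))
  labs[2:7, 2:7, 2:5] <- 1L
  labs[1L, 1L, 1:2] <- 2L
  region_atlas(labs, c(`1` = "MBH", `2` = "blood_pool"), blood_label = 2L)
}
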