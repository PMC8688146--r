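test_that("impulse response matches the closed form for k4 = 0", {
  ir <- impulse_response(kinetic_params(0.1, 0.2, 0.05, 0))
  expect_equal(ir$alpha1, 0)
  expect_equal(ir$alpha2, 0.25)
  # B1 = k1 k3/(k2+k3), B2 = k1 k2/(k2+k3) by hand algebra
  expect_equal(ir$B1, 0.02)
  expect_equal(ir$B2, 0.08)
  expect_equal(ir$B1 + ir$B2, 0.1)
})

test_that("no influx means a zero response", {
  ir <- impulse_response(kinetic_params(0, 0.3, 0.1, 0.01))
  expect_equal(ir$B1, 0)
  expect_equal(ir$B2, 0)
  tac <- forward_tac(kinetic_params(0, 0.3, 0.1, 0.01), feng_plasma(),
                     c(0, 60, 600))
  expect_equal(tac$value, c(0, 0, 0))
})

test_that("analytic convolution matches ODE integration for random draws", {
  skip_if_not_installed("deSolve")
  cp <- feng_plasma()
  sp <- as_continuous(sampled_plasma(
    frame_mid_s(default_frame_schedule()),
    plasma_conc(cp, frame_mid_s(default_frame_schedule()))))
  tmid <- frame_mid_s(default_frame_schedule())
  set.seed(7)
  for (i in 1:10) {
    kp <- kinetic_params(runif(1, 0.05, 0.3), runif(1, 0.1, 0.6),
                         runif(1, 0.02, 0.15), runif(1, 0, 0.04))
    for (plasma in list(cp, sp)) {
      a <- forward_tac(kp, plasma, tmid)$value
      b <- ode_tac_oracle(kp, plasma, tmid)
      expect_lt(max(abs(a - b)) / max(abs(b)), 1e-5)
    }
  }
})

test_that("nonnegative parameters and input give nonnegative output", {
  cp <- feng_plasma()
  set.seed(11)
  for (i in 1:5) {
    kp <- kinetic_params(runif(1, 0, 0.5), runif(1, 0, 1),
                         runif(1, 0, 0.3), runif(1, 0, 0.1))
    v <- forward_tac(kp, cp, seq(0, 2580, by = 120))$value
    expect_true(all(v >= -1e-12))
  }
})

test_that("outputs are continuous as k4 approaches zero", {
  cp <- feng_plasma()
  tt <- frame_mid_s(default_frame_schedule())
  a <- forward_tac(kinetic_params(0.1, 0.3, 0.05, 0), cp, tt)$value
  b <- forward_tac(kinetic_params(0.1, 0.3, 0.05, 1e-11), cp, tt)$value
  expect_lt(max(abs(a - b)) / max(a), 1e-8)
})

test_that("repeated-root branch agrees with the nearby two-root form", {
  # k3 = 0, k2 = k4 gives a genuine repeated root
  cp <- feng_plasma()
  tt <- c(60, 300, 1200, 2400)
  deg <- forward_tac(kinetic_params(0.1, 0.2, 0, 0.2), cp, tt)$value
  near <- forward_tac(kinetic_params(0.1, 0.2, 1e-7, 0.2), cp, tt)$value
  expect_lt(max(abs(deg - near)) / max(deg), 1e-5)
})

test_that("constant input gives the Patlak asymptotic slope", {
  const <- sampled_plasma(c(0, 10000), c(1, 1))
  kp <- kinetic_params(0.1, 0.2, 0.05, 0)
  tt <- c(3000, 6000) # late, transients gone
  v <- forward_tac(kp, const, tt)$value
  slope <- diff(v) / diff(tt / 60)
  expect_lt(abs(slope - 0.02), 1e-4) # k1 k3/(k2+k3) = 0.02 per min
})

test_that("frame averaging reproduces constants and linear ramps", {
  sched <- default_frame_schedule()
  expect_equal(frame_average(function(t) rep(3.5, length(t)), sched),
               rep(3.5, 25))
  one <- frame_schedule(0, 30)
  expect_equal(frame_average(function(t) t, one), 15)
})

test_that("frame averaging conserves the time integral", {
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  f <- function(t) plasma_conc(cp, t)
  fa <- frame_average(f, sched)
  total <- stats::integrate(f, 0, 2580, rel.tol = 1e-11,
                            subdivisions = 1000L)$value
  expect_lt(abs(sum(fa * frame_dur_s(sched)) - total) / total, 1e-8)
})

test_that("frame averaging rejects schedules beyond the curve support", {
  curve <- forward_tac(kinetic_params(0.1, 0.2, 0.05), feng_plasma(),
                       seq(0, 1200, by = 30))
  expect_error(frame_average(curve, default_frame_schedule()), "support")
})

test_that("ce_cp follows the transport formula and is linear in k1", {
  expect_equal(ce_cp(kinetic_params(0.1, 0.2, 0)), 0.5)
  expect_equal(ce_cp(kinetic_params(0.1, 0.2, 0.052)), 0.25)
  base <- ce_cp(kinetic_params(0.07, 0.31, 0.06, 0.01))
  expect_equal(ce_cp(kinetic_params(0.14, 0.31, 0.06, 0.01)), 2 * base)
})

test_that("ce_cp flags a zero denominator instead of crashing", {
  expect_warning(out <- ce_cp(kinetic_params(0.1, 0, 0)), "undefined")
  expect_true(is.na(out))
  expect_warning(v <- ce_cp(list(k1 = c(0.1, 0.2), k2 = c(0, 0.2),
                                 k3 = c(0, 0.052))), "undefined")
  expect_equal(v, c(NA, 0.5))
})

test_that("default schedule is 25 frames totalling 2580 s", {
  fs <- default_frame_schedule()
  expect_equal(nrow(fs), 25L)
  expect_equal(sum(frame_dur_s(fs)), 2580)
  expect_equal(frame_dur_s(fs), rep(c(30, 60, 120, 240), c(12, 3, 3, 7)))
})

test_that("invalid schedules are rejected", {
  expect_error(frame_schedule(c(0, 20), c(30, 50)), "contiguous")
  expect_error(frame_schedule(c(0, 30), c(30, 30)), "start < end")
})
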