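test_that("brain mask keeps tissue and drops background on the phantom", {
  at <- tiny_atlas()
  truth <- ground_truth(at, sc = 0)
  img <- simulate_subject_scan(at, truth, "saline", feng_plasma(),
                               default_frame_schedule(), seed = 1)
  blood <- at$labels == at$blood_label
  mask <- brain_mask(img, exclude = blood)
  tissue <- at$labels > 0 & !blood
  expect_true(all(which(tissue) %in% which(mask)))
  expect_equal(sum(mask & at$labels == 0), 0L)
  expect_error(brain_mask(dynamic_image(array(0, c(4, 4, 4, 25)),
                                        default_frame_schedule())),
               "no activity")
})

test_that("noiseless voxel fits recover the generating parameters", {
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  basis <- tac_basis(cp, sched)
  for (kp in list(kinetic_params(0.1, 0.2, 0.05, 0.005),
                  kinetic_params(0.2, 0.4, 0.08, 0.015))) {
    tac <- frame_average(fdgkin:::forward_tac_fun_(kp, cp), sched)
    fit <- fit_voxel(tac, sched, cp, fit_config(), basis = basis)
    expect_true(fit$converged)
    expect_lt(max(abs(as.numeric(fit$params) - as.numeric(kp))), 1e-3)
    expect_equal(fit$cecp, ce_cp(kp), tolerance = 1e-4)
  }
})

test_that("an all-zero TAC fits to k1 = 0 and is flagged converged", {
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  fit <- fit_voxel(rep(0, 25), sched, cp, fit_config())
  expect_lte(fit$params[["k1"]], 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$wrss, 0)
})

test_that("fits are scale-equivariant in joint TAC/plasma scaling", {
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  kp <- kinetic_params(0.12, 0.3, 0.06, 0.01)
  tac <- frame_average(fdgkin:::forward_tac_fun_(kp, cp), sched)
  set.seed(3)
  tac <- tac * (1 + rnorm(25, 0, 0.05))
  f1 <- fit_voxel(tac, sched, cp, fit_config())
  cp10 <- feng_plasma(A1 = 8000, A2 = 219, A3 = 208)
  f2 <- fit_voxel(tac * 10, sched, cp10, fit_config())
  expect_equal(as.numeric(f1$params), as.numeric(f2$params),
               tolerance = 1e-6)
})

test_that("returned WRSS never exceeds any multistart initialization", {
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  kp <- kinetic_params(0.15, 0.35, 0.07, 0.01)
  base <- frame_average(fdgkin:::forward_tac_fun_(kp, cp), sched)
  set.seed(5)
  for (i in 1:5) {
    tac <- base * (1 + rnorm(25, 0, 0.08))
    fit <- fit_voxel(tac, sched, cp, fit_config())
    expect_true(all(fit$wrss <= fit$start_wrss + 1e-9))
  }
})

test_that("fits are deterministic given the config seed", {
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  kp <- kinetic_params(0.15, 0.35, 0.07, 0.01)
  set.seed(9)
  tac <- frame_average(fdgkin:::forward_tac_fun_(kp, cp), sched) *
    (1 + rnorm(25, 0, 0.05))
  f1 <- fit_voxel(tac, sched, cp, fit_config(seed = 4))
  f2 <- fit_voxel(tac, sched, cp, fit_config(seed = 4))
  expect_identical(f1$params, f2$params)
})

test_that("k4 can be fixed at zero (irreversible variant)", {
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  kp <- kinetic_params(0.1, 0.25, 0.06, 0)
  tac <- frame_average(fdgkin:::forward_tac_fun_(kp, cp), sched)
  fit <- fit_voxel(tac, sched, cp, fit_config(fix_k4 = 0))
  expect_equal(fit$params[["k4"]], 0)
  expect_lt(max(abs(as.numeric(fit$params) - as.numeric(kp))), 1e-3)
})

test_that("fit_image recovers the regional truth on a noiseless phantom", {
  at <- tiny_atlas()
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  truth <- ground_truth(at, sc = 0)
  img <- simulate_subject_scan(at, truth, "saline", cp, sched, seed = 1)
  pm <- fit_image(img, cp, fit_config(),
                  exclude = at$labels == at$blood_label)
  expect_equal(pm$n_nonconverged, 0L)
  worst_k <- 0
  worst_cecp <- 0
  for (lab in tissue_labels(at)) {
    region <- at$names[[as.character(lab)]]
    row <- truth$params[truth$params$region == region &
                          truth$params$condition == "saline", ]
    vox <- region_voxels(at, lab)
    for (kk in c("k1", "k2", "k3", "k4"))
      worst_k <- max(worst_k, max(abs(pm[[kk]][vox] - row[[kk]])))
    worst_cecp <- max(worst_cecp,
                      max(abs(pm$cecp[vox] - row$cecp) / row$cecp))
  }
  expect_lt(worst_k, 1e-3)
  expect_lt(worst_cecp, 0.01)
  # bookkeeping: defined Ce/Cp voxels = mask size minus non-converged
  expect_equal(sum(!is.na(pm$cecp)), sum(pm$mask) - pm$n_nonconverged)
})

test_that("under ~5% TAC noise the Ce/Cp error stays controlled", {
  at <- block_atlas() # one region, 144 voxels
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  truth <- ground_truth(at, target_cv = 0.05)
  img <- simulate_subject_scan(at, truth, "saline", cp, sched, seed = 21)
  pm <- fit_image(img, cp, fit_config(), exclude = at$labels == 2L)
  vox <- region_voxels(at, 1L)
  truthc <- truth$params$cecp[truth$params$condition == "saline" &
                                truth$params$region == "MBH"]
  rel <- abs(pm$cecp[vox] - truthc) / truthc
  expect_gte(sum(!is.na(rel)), 100)
  expect_lt(median(rel, na.rm = TRUE), 0.10)
  bias <- (mean(pm$cecp[vox], na.rm = TRUE) - truthc) / truthc
  expect_lt(abs(bias), 0.05)
})

test_that("noisy brain masks still capture nearly all tissue", {
  at <- tiny_atlas()
  truth <- ground_truth(at, target_cv = 0.05)
  img <- simulate_subject_scan(at, truth, "saline", feng_plasma(),
                               default_frame_schedule(), seed = 13)
  blood <- at$labels == at$blood_label
  mask <- brain_mask(img, exclude = blood)
  tissue <- which(at$labels > 0 & !blood)
  expect_gte(mean(tissue %in% which(mask)), 0.95)
})
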