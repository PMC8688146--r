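test_that("make_atlas honours the construction contract", {
  at <- tiny_atlas()
  sizes <- table(at$labels[at$labels > 0])
  expect_length(sizes, 9L) # 8 tissue + blood pool
  expect_true(all(sizes >= 8L))
  expect_equal(at$names[[as.character(at$blood_label)]], "blood_pool")
  expect_true("MBH" %in% at$names)
})

test_that("make_atlas is deterministic given its seed", {
  expect_identical(make_atlas(c(20, 20, 10), 8, seed = 1)$labels,
                   make_atlas(c(20, 20, 10), 8, seed = 1)$labels)
  expect_false(identical(make_atlas(c(20, 20, 10), 8, seed = 1)$labels,
                         make_atlas(c(20, 20, 10), 8, seed = 2)$labels))
})

test_that("infeasible packings raise a sizing error", {
  expect_error(make_atlas(c(2, 2, 1), 8), "too small")
})

test_that("atlas regions are 6-connected blobs", {
  at <- tiny_atlas()
  for (lab in c(tissue_labels(at), at$blood_label)) {
    m <- at$labels == lab
    comp <- fdgkin:::label_components_(m)
    expect_equal(max(comp), 1L)
  }
})

test_that("noiseless tissue equals the deterministic forward model", {
  at <- tiny_atlas()
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  truth <- ground_truth(at, sc = 0)
  img <- simulate_subject_scan(at, truth, "saline", cp, sched, seed = 1)
  vol <- prod(dim(at$labels))
  lab <- tissue_labels(at)[3]
  region <- at$names[[as.character(lab)]]
  kp <- fdgkin:::truth_params_(truth, region, "saline")
  ref <- frame_average(fdgkin:::forward_tac_fun_(kp, cp), sched)
  v <- region_voxels(at, lab)[1]
  tac <- img$data[v + (seq_len(25) - 1L) * vol]
  expect_identical(as.numeric(tac), as.numeric(ref)) # bit-for-bit
})

test_that("zero k1 with zero noise produces an all-zero tissue region", {
  at <- block_atlas()
  truth <- ground_truth(at, sc = 0)
  truth$params$k1 <- 0
  img <- simulate_subject_scan(at, truth, "saline", feng_plasma(),
                               default_frame_schedule(), seed = 1)
  expect_true(all(img$data[region_voxels(at, 1L) +
                             rep((0:24) * prod(dim(at$labels)),
                                 each = length(region_voxels(at, 1L)))] == 0))
})

test_that("blood-pool voxels are the stated partial-volume mixture", {
  at <- tiny_atlas()
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  truth <- ground_truth(at, sc = 0, blood_bg = 0)
  img <- simulate_subject_scan(at, truth, "saline", cp, sched, seed = 1)
  cpf <- frame_average(function(t) plasma_conc(cp, t), sched)
  vol <- prod(dim(at$labels))
  v <- region_voxels(at, at$blood_label)[1]
  bl <- img$data[v + (seq_len(25) - 1L) * vol]
  expect_equal(as.numeric(bl), 0.6 * cpf, tolerance = 1e-12)
})

test_that("scans are deterministic given the seed and condition exists", {
  at <- block_atlas()
  truth <- ground_truth(at)
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  a <- simulate_subject_scan(at, truth, "saline", cp, sched, seed = 3)
  b <- simulate_subject_scan(at, truth, "saline", cp, sched, seed = 3)
  expect_identical(a$data, b$data)
  expect_error(simulate_subject_scan(at, truth, "ketamine", cp, sched),
               "not present")
})

test_that("per-frame noise variance scales as Sc * C / dt", {
  labs <- array(0L, c(12, 12, 12))
  labs[2:11, 2:11, 2:11] <- 1L # 1000 replicate voxels
  labs[1, 1, 1:3] <- 2L
  at <- region_atlas(labs, c(`1` = "MBH", `2` = "blood_pool"), 2L)
  truth <- ground_truth(at, target_cv = 0.05)
  cp <- feng_plasma()
  sched <- default_frame_schedule()
  sc <- sc_for_cv(truth, cp, sched)
  truth$sc <- sc
  img <- simulate_subject_scan(at, truth, "saline", cp, sched, seed = 7)
  kp <- fdgkin:::truth_params_(truth, "MBH", "saline")
  C <- frame_average(fdgkin:::forward_tac_fun_(kp, cp), sched)
  dt <- frame_dur_s(sched)
  vox <- region_voxels(at, 1L)
  vol <- prod(dim(labs))
  for (j in c(5L, 15L, 25L)) {
    emp <- stats::var(img$data[vox + (j - 1L) * vol])
    expect_equal(emp, sc * C[j] / dt[j], tolerance = 0.1)
  }
})

test_that("cohorts pair scans and carry exact truth maps", {
  at <- tiny_atlas()
  truth <- ground_truth(at, effect_regions = "MBH", effect = 0.7, sc = 0)
  cohort <- simulate_cohort(study_design(4L), at, truth, feng_plasma(),
                            default_frame_schedule(), seed = 5)
  expect_length(cohort$scans, 8L) # 4 subjects x 2 conditions
  expect_setequal(names(cohort$scans),
                  as.vector(outer(sprintf("S%02d", 1:4),
                                  c("saline", "insulin"), paste, sep = ".")))
  mbh <- at$labels == as.integer(names(which(at$names == "MBH")))
  ratio <- cohort$truth_cecp$insulin[mbh] / cohort$truth_cecp$saline[mbh]
  expect_equal(unique(ratio), 0.7) # Ce/Cp linear in k1
  other <- at$labels > 0 & at$labels != at$blood_label & !mbh
  expect_equal(cohort$truth_cecp$insulin[other],
               cohort$truth_cecp$saline[other])
})

test_that("a unit effect multiplier gives a null cohort truth", {
  at <- block_atlas()
  truth <- ground_truth(at, effect_regions = "MBH", effect = 1)
  expect_identical(truth_cecp_map(truth, at, "saline"),
                   truth_cecp_map(truth, at, "insulin"))
})
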