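const_mapset <- function(diffs, dims = c(2, 2, 2)) {
  sal <- lapply(diffs, function(x) array(x, dims))
  ins <- lapply(diffs, function(x) array(0, dims))
  paired_map_set(sal, ins)
}

test_that("identical condition maps give t = 0, p = 1 everywhere", {
  m <- array(runif(27, 0.1, 0.5), c(3, 3, 3))
  ms <- paired_map_set(list(m, m, m, m), list(m, m, m, m))
  pm <- paired_tmap(ms)
  expect_true(all(pm$t == 0))
  expect_true(all(pm$p == 1))
})

test_that("the voxel t matches the reference paired t-test", {
  d <- c(2, 0, 2, 0)
  pm <- paired_tmap(const_mapset(d))
  ref <- t.test(d)
  expect_equal(pm$t[1, 1, 1], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pm$p[1, 1, 1], ref$p.value, tolerance = 1e-12)
  expect_equal(pm$df, 3L)
  # textbook values
  expect_equal(pm$t[1, 1, 1], 1.732051, tolerance = 1e-6)
  expect_equal(pm$p[1, 1, 1], 0.1816901, tolerance = 1e-6)
})

test_that("zero-variance voxels follow the degenerate conventions", {
  pm <- paired_tmap(const_mapset(c(0.1, 0.1, 0.1, 0.1)))
  expect_true(all(pm$flagged))
  expect_equal(pm$p[1, 1, 1], .Machine$double.xmin)
  pm0 <- paired_tmap(const_mapset(c(0, 0, 0, 0)))
  expect_true(all(pm0$t == 0) && all(pm0$p == 1))
})

test_that("null cohorts are calibrated at alpha = 0.05", {
  truth <- array(0.3, c(13, 13, 12)) # ~2000 voxels
  maps <- simulate_paired_maps(truth, n_subjects = 8L, cv = 0.05, seed = 11)
  pm <- paired_tmap(maps)
  fpr <- mean(pm$p[pm$defined] < 0.05)
  expect_gte(fpr, 0.03)
  expect_lte(fpr, 0.07)
})

test_that("swapping condition labels negates t and preserves p", {
  truth <- array(0.3, c(8, 8, 8))
  maps <- simulate_paired_maps(truth, n_subjects = 6L, cv = 0.05, seed = 3)
  pm <- paired_tmap(maps)
  sw <- paired_tmap(paired_map_set(maps$insulin, maps$saline))
  expect_identical(pm$t, -sw$t)
  expect_identical(pm$p, sw$p)
})

test_that("voxels undefined for any subject are excluded", {
  m <- array(0.3, c(2, 2, 2))
  sal <- list(m, m, m)
  sal[[2]][1, 1, 1] <- NA
  pm <- paired_tmap(paired_map_set(sal, list(m, m, m)))
  expect_false(pm$defined[1, 1, 1])
  expect_true(is.na(pm$p[1, 1, 1]))
  expect_true(all(pm$defined[-1]))
})

test_that("define_vois returns nothing on a flat map and one VOI on a cube", {
  m <- array(0.3, c(6, 6, 6))
  maps <- simulate_paired_maps(m, n_subjects = 4L, cv = 0.05, seed = 5)
  pm <- paired_tmap(maps)
  pm$p[] <- 1
  expect_length(define_vois(pm), 0L)
  pm$p[2:4, 2:4, 2:4] <- 1e-4
  pm$sign[2:4, 2:4, 2:4] <- 1
  vois <- define_vois(pm)
  expect_length(vois, 1L)
  expect_setequal(vois[[1]]$voxels, which(pm$p < 0.05))
  expect_equal(vois[[1]]$direction, "saline>insulin")
  expect_equal(vois[[1]]$n_voxels, 27L)
})

test_that("components below min_voxels or of mixed sign are split off", {
  m <- array(0.3, c(8, 8, 4))
  maps <- simulate_paired_maps(m, n_subjects = 4L, cv = 0.05, seed = 6)
  pm <- paired_tmap(maps)
  pm$p[] <- 1
  pm$p[2:3, 2:3, 2] <- 1e-3 # 4 voxels, direction +
  pm$sign[2:3, 2:3, 2] <- 1
  pm$p[6, 6, 3] <- 1e-3 # single voxel, below min size
  pm$sign[6, 6, 3] <- -1
  vois <- define_vois(pm, min_voxels = 4L)
  expect_length(vois, 1L)
  expect_equal(vois[[1]]$n_voxels, 4L)
})

test_that("voi_test reports paired statistics and effect sizes", {
  dims <- c(4, 4, 2)
  set.seed(8)
  sal <- lapply(1:6, function(i) array(rnorm(32, 0.30, 0.01), dims))
  ins <- lapply(1:6, function(i) array(rnorm(32, 0.21, 0.01), dims))
  maps <- paired_map_set(sal, ins)
  voi <- structure(list(voxels = 1:32, name = "MBH",
                        direction = "saline>insulin", n_voxels = 32L,
                        min_p = NA, dims = dims), class = "voi")
  res <- voi_test(voi, maps)
  expect_lt(res$p, 0.05)
  expect_equal(res$ratio, 0.7, tolerance = 0.05)
  expect_equal(res$df, 5L)
  # identical conditions: t = 0, p = 1
  same <- paired_map_set(sal, sal)
  res0 <- voi_test(voi, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_true(res0$flagged)
})

test_that("resampling at the source spacing is the identity", {
  m <- array(runif(60, 0.01, 1), c(5, 4, 3))
  pm <- list(p = m, defined = array(TRUE, dim(m)), dims = dim(m),
             voxel_dims = c(0.4, 0.4, 0.8))
  class(pm) <- "p_value_map"
  rs <- resample_pmap(pm, target_spacing = c(0.4, 0.4, 0.8))
  expect_equal(rs$p, m)
  expect_true(rs$presentation_only)
})

test_that("resampling interpolates linearly between voxel centres", {
  m <- array(0.3, c(4, 4, 4))
  m[1, 1, 1] <- 0.2
  m[2, 1, 1] <- 0.4
  pm <- list(p = m, dims = dim(m), voxel_dims = c(1, 1, 1))
  class(pm) <- "p_value_map"
  rs <- resample_pmap(pm, target_spacing = c(0.5, 1, 1))
  # target centres at x = 0.75 and 1.25 straddle the source centres
  # (0.5, 1.5); 0.75 -> 0.25 of the way from 0.2 to 0.4
  expect_equal(rs$p[2, 1, 1], 0.25)
  expect_equal(rs$p[3, 1, 1], 0.35)
  # constant region stays constant
  expect_true(all(abs(rs$p[, 3, 3] - 0.3) < 1e-12))
  expect_error(resample_pmap(pm, c(10, 10, 10)), "extent")
})
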