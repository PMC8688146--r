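#' Paired map set
#'
#' Congruent per-subject Ce/Cp maps under the two conditions of a
#' cross-over design.
#'
#' @param saline,insulin Named lists of 3D arrays (one per subject, same
#'   order and geometry).
#' @param voxel_dims mm triple.
#' @return A `paired_map_set`.
#' @export
paired_map_set <- function(saline, insulin, voxel_dims = c(0.4, 0.4, 0.8)) {
  stopifnot(length(saline) == length(insulin), length(saline) >= 1L)
  d <- dim(saline[[1]])
  ok <- vapply(c(saline, insulin),
               function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("all maps must be congruent (same dimensions)")
  subjects <- names(saline) %||% sprintf("S%02d", seq_along(saline))
  structure(list(saline = saline, insulin = insulin, subjects = subjects,
                 dims = d, voxel_dims = as.numeric(voxel_dims)),
            class = "paired_map_set")
}

#' Build a paired map set from per-scan parametric maps
#'
#' @param maps Named list of [fit_image()] results, names
#'   `"<subject>.<condition>"` as produced by [simulate_cohort()].
#' @param what Which map to compare (default `"cecp"`).
#' @return A [paired_map_set()].
#' @export
mapset_from_fits <- function(maps, what = "cecp") {
  nm <- names(maps)
  subj <- unique(sub("\\.(saline|insulin)$", "", nm))
  pick <- function(cond) {
    out <- lapply(subj, function(s) maps[[paste(s, cond, sep = ".")]][[what]])
    stats::setNames(out, subj)
  }
  vd <- maps[[1]]$voxel_dims %||% c(0.4, 0.4, 0.8)
  paired_map_set(pick("saline"), pick("insulin"), voxel_dims = vd)
}

#' Voxel-wise paired t-map
#'
#' Two-sided paired Student's t-test per voxel on the subject-wise
#' differences (saline - insulin). Voxels where any subject is undefined
#' (`NA`) are excluded. Zero-variance voxels: t = 0, p = 1 when the mean
#' difference is also zero; otherwise p is set to the smallest representable
#' double and the voxel is flagged.
#'
#' @param maps A [paired_map_set()] with at least 3 subjects.
#' @return A `p_value_map`: list of 3D arrays `t`, `p`, `sign` (+1 where
#'   saline > insulin), `defined`, `flagged`, plus `df` and geometry.
#' @export
paired_tmap <- function(maps) {
  stopifnot(inherits(maps, "paired_map_set"))
  n <- length(maps$subjects)
  if (n < 3L) stop("paired t-map needs at least 3 subjects")
  V <- prod(maps$dims)
  D <- matrix(NA_real_, n, V)
  for (i in seq_len(n))
    D[i, ] <- as.vector(maps$saline[[i]]) - as.vector(maps$insulin[[i]])
  defined <- colSums(is.na(D)) == 0L
  md <- colMeans(D)
  sdd <- sqrt(colSums(sweep(D, 2L, md)^2) / (n - 1L))
  tt <- rep(NA_real_, V)
  pp <- rep(NA_real_, V)
  flag <- rep(FALSE, V)
  ok <- defined & sdd > 0
  tt[ok] <- md[ok] / (sdd[ok] / sqrt(n))
  pp[ok] <- 2 * stats::pt(-abs(tt[ok]), df = n - 1L)
  degen <- defined & sdd == 0
  if (any(degen)) {
    zm <- degen & md == 0
    nz <- degen & md != 0
    tt[zm] <- 0; pp[zm] <- 1
    tt[nz] <- sign(md[nz]) * Inf
    pp[nz] <- .Machine$double.xmin
    flag[nz] <- TRUE
  }
  shape <- function(x) array(x, maps$dims)
  structure(list(t = shape(tt), p = shape(pp),
                 sign = shape(ifelse(defined, sign(md), NA_real_)),
                 defined = shape(defined), flagged = shape(flag),
                 df = n - 1L, dims = maps$dims,
                 voxel_dims = maps$voxel_dims),
            class = "p_value_map")
}

#' Define volumes of interest from a p-value map
#'
#' Connected components (6-neighbour) of `{p < alpha}`, split by direction
#' sign, with at least `min_voxels` voxels; each VOI is named after the
#' dominant overlapping atlas region when an atlas is supplied.
#'
#' @param pmap A [paired_tmap()] result.
#' @param alpha Significance threshold in (0, 1), default 0.05.
#' @param min_voxels Minimum component size, default 4.
#' @param atlas Optional [region_atlas()] for naming.
#' @return List of `voi` objects (possibly empty): each has `voxels`
#'   (linear indices), `name`, `direction` (`"saline>insulin"` or
#'   `"insulin>saline"`), `n_voxels`, `min_p`.
#' @export
define_vois <- function(pmap, alpha = 0.05, min_voxels = 4L, atlas = NULL) {
  stopifnot(inherits(pmap, "p_value_map"), alpha > 0, alpha < 1)
  out <- list()
  for (s in c(1, -1)) {
    sel <- pmap$defined & !is.na(pmap$p) & pmap$p < alpha &
      !is.na(pmap$sign) & pmap$sign == s
    if (!any(sel)) next
    comp <- label_components_(sel)
    for (id in setdiff(unique(as.vector(comp)), 0L)) {
      vox <- which(comp == id)
      if (length(vox) < min_voxels) next
      name <- sprintf("voi_%s_%d", if (s > 0) "dec" else "inc", id)
      if (!is.null(atlas)) {
        labs <- atlas$labels[vox]
        labs <- labs[labs != 0L]
        if (length(labs) > 0L) {
          dom <- as.integer(names(which.max(table(labs))))
          name <- atlas$names[[as.character(dom)]]
        }
      }
      out[[length(out) + 1L]] <- structure(
        list(voxels = vox, name = name,
             direction = if (s > 0) "saline>insulin" else "insulin>saline",
             n_voxels = length(vox), min_p = min(pmap$p[vox]),
             dims = pmap$dims),
        class = "voi")
    }
  }
  out
}

#' Region-level follow-up test for a VOI
#'
#' Subject-level mean Ce/Cp over the VOI per condition, then a paired
#' two-sided t-test on those means, with effect sizes (mean difference and
#' insulin/saline ratio). Subjects whose VOI voxels are all undefined are
#' dropped with a warning (degrees of freedom adjusted).
#'
#' @param voi A `voi` from [define_vois()].
#' @param maps The [paired_map_set()] the p-map came from.
#' @return A list with `name`, `n_voxels`, `direction`, `n_subjects`,
#'   `mean_saline`, `mean_insulin`, `mean_diff`, `ratio`, `t`, `df`, `p`,
#'   `flagged`.
#' @export
voi_test <- function(voi, maps) {
  stopifnot(inherits(voi, "voi"), inherits(maps, "paired_map_set"))
  if (length(voi$voxels) == 0L) stop("empty VOI")
  ms <- vapply(maps$saline, function(m) mean(m[voi$voxels], na.rm = TRUE),
               numeric(1))
  mi <- vapply(maps$insulin, function(m) mean(m[voi$voxels], na.rm = TRUE),
               numeric(1))
  keep <- is.finite(ms) & is.finite(mi)
  if (!all(keep))
    warning(sum(!keep), " subject(s) with fully undefined VOI dropped")
  ms <- ms[keep]; mi <- mi[keep]
  n <- length(ms)
  if (n < 2L) stop("fewer than 2 usable subjects in VOI test")
  d <- ms - mi
  flagged <- FALSE
  if (stats::sd(d) == 0) {
    flagged <- TRUE
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pp <- if (mean(d) == 0) 1 else .Machine$double.xmin
  } else {
    ht <- stats::t.test(ms, mi, paired = TRUE)
    tt <- unname(ht$statistic)
    pp <- ht$p.value
  }
  list(name = voi$name, n_voxels = voi$n_voxels, direction = voi$direction,
       n_subjects = n, mean_saline = mean(ms), mean_insulin = mean(mi),
       mean_diff = mean(d), ratio = mean(mi) / mean(ms),
       t = tt, df = n - 1L, p = pp, flagged = flagged)
}

#' Resample a p-value map for presentation
#'
#' Trilinear interpolation of the voxel-wise p values onto a finer grid
#' (presentation only: the source statistics are not altered, and the
#' returned object carries a `presentation_only` note).
#'
#' @param pmap A [paired_tmap()] result.
#' @param target_spacing mm triple, e.g. `c(0.1, 0.1, 0.1)`.
#' @return List with the resampled `p` array, `spacing`, and provenance note.
#' @export
resample_pmap <- function(pmap, target_spacing = c(0.1, 0.1, 0.1)) {
  stopifnot(inherits(pmap, "p_value_map"), length(target_spacing) == 3L,
            all(target_spacing > 0))
  extent <- pmap$dims * pmap$voxel_dims
  if (any(target_spacing > extent))
    stop("target spacing exceeds the volume extent")
  p_res <- trilinear_resample_(pmap$p, pmap$voxel_dims, target_spacing)
  list(p = p_res, spacing = target_spacing,
       source_spacing = pmap$voxel_dims,
       presentation_only = TRUE)
}

# vectorized trilinear resampling; voxel centre of index i is (i - 0.5) * dx
trilinear_resample_ <- function(arr, src_dx, tgt_dx) {
  d <- dim(arr)
  nt <- pmax(1L, as.integer(floor(d * src_dx / tgt_dx)))
  g <- lapply(1:3, function(ax) {
    x <- (seq_len(nt[ax]) - 0.5) * tgt_dx[ax]
    u <- x / src_dx[ax] + 0.5 # fractional 1-based source index
    pmin(pmax(u, 1), d[ax])
  })
  gr <- expand.grid(u1 = g[[1]], u2 = g[[2]], u3 = g[[3]])
  i0 <- lapply(1:3, function(ax) pmin(floor(gr[[ax]]), d[ax] - 1L))
  fr <- lapply(1:3, function(ax) gr[[ax]] - i0[[ax]])
  acc <- 0
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    wgt <- (if (c1) fr[[1]] else 1 - fr[[1]]) *
      (if (c2) fr[[2]] else 1 - fr[[2]]) *
      (if (c3) fr[[3]] else 1 - fr[[3]])
    idx <- (i0[[1]] + c1) + d[1] * (i0[[2]] + c2 - 1L) +
      d[1] * d[2] * (i0[[3]] + c3 - 1L)
    acc <- acc + wgt * arr[idx]
  }
  array(acc, nt)
}

#' Map-level paired cohort simulation
#'
#' Generates a [paired_map_set()] directly from true Ce/Cp maps by adding
#' independent zero-mean Gaussian noise with SD `cv * |true|` per voxel and
#' scan. This is the light-weight generator used for statistical
#' calibration (type-I error, label-swap symmetry) where the estimation
#' noise of a full voxel fit is not the object under test.
#'
#' @param true_saline,true_insulin 3D arrays (`NA` = undefined voxel);
#'   identical arrays give a null cohort.
#' @param n_subjects Number of paired subjects.
#' @param cv Relative noise SD (default 0.05).
#' @param seed Integer seed.
#' @return A [paired_map_set()].
#' @export
simulate_paired_maps <- function(true_saline, true_insulin = true_saline,
                                 n_subjects = 8L, cv = 0.05, seed = 1L) {
  stopifnot(identical(dim(true_saline), dim(true_insulin)), n_subjects >= 3L)
  with_seed_(seed, {
    noisy <- function(truth) {
      sd <- cv * abs(truth)
      out <- truth + stats::rnorm(length(truth), 0, ifelse(is.na(sd), 0, sd))
      array(out, dim(truth))
    }
    sal <- lapply(seq_len(n_subjects), function(i) noisy(true_saline))
    ins <- lapply(seq_len(n_subjects), function(i) noisy(true_insulin))
    names(sal) <- names(ins) <- sprintf("S%02d", seq_len(n_subjects))
    paired_map_set(sal, ins)
  })
}

#' VOI summary table
#'
#' @param vois List from [define_vois()].
#' @param maps The [paired_map_set()].
#' @return Data frame with one row per VOI (name, n_voxels, direction,
#'   means, t, df, p).
#' @export
voi_table <- function(vois, maps) {
  if (length(vois) == 0L)
    return(data.frame(name = character(), n_voxels = integer(),
                      direction = character(), mean_saline = numeric(),
                      mean_insulin = numeric(), ratio = numeric(),
                      t = numeric(), df = integer(), p = numeric()))
  rows <- lapply(vois, function(v) {
    s <- voi_test(v, maps)
    data.frame(name = s$name, n_voxels = s$n_voxels,
               direction = s$direction, mean_saline = s$mean_saline,
               mean_insulin = s$mean_insulin, ratio = s$ratio,
               t = s$t, df = s$df, p = s$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
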