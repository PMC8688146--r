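#' Region atlas
#'
#' A labelled 3D volume: integer labels (0 = background) with a name per
#' label, exactly one label designated as the blood pool, and voxel
#' dimensions in mm.
#'
#' @param labels 3D integer array (0 = background).
#' @param names Named character vector mapping label (as character) to
#'   region name; must include every nonzero label in `labels`.
#' @param blood_label Integer label of the blood-pool region.
#' @param voxel_dims mm triple, default `c(0.4, 0.4, 0.8)`.
#' @return A `region_atlas`.
#' @export
region_atlas <- function(labels, names, blood_label,
                         voxel_dims = c(0.4, 0.4, 0.8)) {
  stopifnot(length(dim(labels)) == 3L, is.numeric(voxel_dims),
            length(voxel_dims) == 3L, all(voxel_dims > 0))
  labels <- array(as.integer(labels), dim(labels))
  used <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!all(as.character(used) %in% base::names(names)))
    stop("every nonzero label must have a name")
  blood_label <- as.integer(blood_label)
  if (!blood_label %in% used)
    stop("blood_label must be a label present in the volume")
  structure(list(labels = labels, names = names,
                 blood_label = blood_label,
                 voxel_dims = as.numeric(voxel_dims)),
            class = "region_atlas")
}

#' @rdname region_atlas
#' @param atlas A `region_atlas`.
#' @export
tissue_labels <- function(atlas) {
  used <- setdiff(sort(unique(as.vector(atlas$labels))), 0L)
  setdiff(used, atlas$blood_label)
}

#' @rdname region_atlas
#' @param label Integer region label.
#' @export
region_voxels <- function(atlas, label) which(atlas$labels == label)

# region abbreviations used for the default phantom labels
default_region_names_ <- c("CP", "BNST/LPO", "MBH", "PAG", "ZI/aSNR",
                           "pSNR", "MV", "SPV")

#' Synthetic labelled atlas
#'
#' Deterministically (given `seed`) places `n_regions` contiguous blob-like
#' tissue regions plus a small blood-pool region in a background volume, by
#' seeding well-separated voxels and growing them with a multi-source
#' breadth-first fill. Region names default to mouse-brain abbreviations
#' (CP, BNST/LPO, MBH, ...).
#'
#' @param dims Voxel-count triple, each >= 4.
#' @param n_regions Number of tissue regions (>= 2).
#' @param seed Integer seed.
#' @param region_size Target voxels per tissue region (default scales with
#'   the volume, at least 8).
#' @param blood_size Target blood-pool voxels.
#' @param voxel_dims mm triple.
#' @param names Region names (length `n_regions`).
#' @return A [region_atlas()] whose blood-pool label is `n_regions + 1`,
#'   named `"blood_pool"`.
#' @examples
#' at <- make_atlas(c(20, 20, 10), n_regions = 8, seed = 1)
#' table(at$labels)[-1]
#' @export
make_atlas <- function(dims = c(20L, 20L, 10L), n_regions = 8L, seed = 1L,
                       region_size = NULL, blood_size = 12L,
                       voxel_dims = c(0.4, 0.4, 0.8), names = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, n_regions >= 2L)
  n_blobs <- n_regions + 1L
  if (any(dims < 4L) || prod(dims) < 18L * n_blobs)
    stop("volume too small to place ", n_regions, " regions plus a blood pool")
  region_size <- region_size %||%
    max(8L, as.integer(round(0.12 * prod(dims) / n_regions)))
  if (is.null(names)) {
    names <- if (n_regions <= length(default_region_names_))
      default_region_names_[seq_len(n_regions)]
    else c(default_region_names_,
           paste0("R", seq(length(default_region_names_) + 1L, n_regions)))
  }
  stopifnot(length(names) == n_regions)
  targets <- c(rep(region_size, n_regions), blood_size)

  lab <- with_seed_(seed, {
    seeds <- place_seeds_(dims, n_blobs)
    grow_blobs_(dims, seeds, targets)
  })
  counts <- tabulate(lab, nbins = n_blobs)
  if (any(counts < 8L))
    stop("could not grow every region to at least 8 voxels; enlarge dims")
  region_atlas(lab, stats::setNames(c(names, "blood_pool"),
                                    as.character(seq_len(n_blobs))),
               blood_label = n_blobs, voxel_dims = voxel_dims)
}

# pick n well-separated seed voxels (rejection with relaxing separation)
place_seeds_ <- function(dims, n) {
  minsep <- 0.7 * (prod(dims) / n)^(1 / 3)
  coords <- NULL
  for (attempt in 1:6) {
    coords <- matrix(numeric(0), ncol = 3)
    cand <- sample.int(prod(dims))
    for (v in cand) {
      xyz <- arrayInd(v, dims)
      if (any(xyz == 1L) || any(xyz == dims)) next # keep off the faces
      if (nrow(coords) == 0L ||
          min(sqrt(rowSums(sweep(coords, 2, as.numeric(xyz))^2))) >= minsep) {
        coords <- rbind(coords, as.numeric(xyz))
        if (nrow(coords) == n) break
      }
    }
    if (nrow(coords) == n) break
    minsep <- minsep * 0.8
  }
  if (nrow(coords) < n)
    stop("volume too small to place ", n, " separated regions")
  coords
}

# multi-source BFS growth to target sizes; regions claim frontier voxels in
# seeded random order each round, so blobs stay compact and disjoint
grow_blobs_ <- function(dims, seeds, targets) {
  lab <- array(0L, dims)
  n <- nrow(seeds)
  frontier <- vector("list", n)
  size <- integer(n)
  lin <- function(xyz) xyz[1] + dims[1] * (xyz[2] - 1L) + prod(dims[1:2]) * (xyz[3] - 1L)
  for (r in seq_len(n)) {
    v <- lin(as.integer(seeds[r, ]))
    lab[v] <- r
    size[r] <- 1L
    frontier[[r]] <- neighbours_(v, dims)
  }
  repeat {
    active <- which(size < targets & lengths(frontier) > 0L)
    if (length(active) == 0L) break
    for (r in sample(active)) {
      if (size[r] >= targets[r]) next
      fr <- frontier[[r]]
      claimed <- FALSE
      while (length(fr) > 0L) {
        v <- fr[[1L]]
        fr <- fr[-1L]
        if (lab[v] == 0L) {
          lab[v] <- r
          size[r] <- size[r] + 1L
          fr <- c(fr, neighbours_(v, dims)[lab[neighbours_(v, dims)] == 0L])
          claimed <- TRUE
          break
        }
      }
      frontier[[r]] <- fr
      if (!claimed && length(fr) == 0L) frontier[[r]] <- integer(0)
    }
  }
  lab
}

# linear indices of valid 6-neighbours
neighbours_ <- function(v, dims) {
  ai <- arrayInd(v, dims)
  out <- integer(0)
  for (ax in 1:3) {
    for (dd in c(-1L, 1L)) {
      nb <- ai
      nb[ax] <- nb[ax] + dd
      if (nb[ax] < 1L || nb[ax] > dims[ax]) next
      out <- c(out, nb[1L] + dims[1L] * (nb[2L] - 1L) +
                 prod(dims[1:2]) * (nb[3L] - 1L))
    }
  }
  out
}
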