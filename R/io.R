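#' Write / read a dynamic image as NIfTI-1 plus a schedule TSV
#'
#' The 4D activity volume is stored as double-precision NIfTI-1 with the
#' voxel dimensions in the header; the frame schedule travels in a sidecar
#' TSV (columns `frame_start_s`, `frame_end_s`).
#'
#' @param image A [dynamic_image()].
#' @param path_image NIfTI path (`.nii` / `.nii.gz`).
#' @param path_schedule TSV path.
#' @export
write_dynamic_image <- function(image, path_image, path_schedule) {
  stopifnot(inherits(image, "dynamic_image"))
  nii <- RNifti::asNifti(image$data)
  RNifti::pixdim(nii) <- c(image$voxel_dims, 1)
  RNifti::writeNifti(nii, path_image, datatype = "double")
  write_frame_schedule(image$schedule, path_schedule)
  invisible(path_image)
}

#' @rdname write_dynamic_image
#' @return `read_dynamic_image()` returns a [dynamic_image()].
#' @export
read_dynamic_image <- function(path_image, path_schedule) {
  nii <- RNifti::readNifti(path_image)
  arr <- plain_array_(nii)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D dynamic image, got ", length(dim(arr)), "D")
  sched <- read_frame_schedule(path_schedule)
  if (dim(arr)[4] != nrow(sched))
    stop("image has ", dim(arr)[4], " frames but the schedule lists ",
         nrow(sched))
  vd <- RNifti::pixdim(nii)[1:3]
  dynamic_image(arr, sched, voxel_dims = vd)
}

#' Write an atlas as NIfTI-1 plus a JSON name map
#'
#' @param atlas A [region_atlas()].
#' @param path_labels NIfTI path for the integer label volume.
#' @param path_names JSON path for the label-name map (includes the
#'   blood-pool label).
#' @export
write_atlas <- function(atlas, path_labels, path_names) {
  nii <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(nii) <- atlas$voxel_dims
  RNifti::writeNifti(nii, path_labels, datatype = "int16")
  jsonlite::write_json(list(names = as.list(atlas$names),
                            blood_label = atlas$blood_label),
                       path_names, auto_unbox = TRUE, pretty = TRUE)
  invisible(path_labels)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path_labels, path_names) {
  nii <- RNifti::readNifti(path_labels)
  meta <- jsonlite::read_json(path_names)
  region_atlas(plain_array_(nii), unlist(meta$names),
               blood_label = meta$blood_label,
               voxel_dims = RNifti::pixdim(nii)[1:3])
}

#' Write parametric maps
#'
#' One 3D double-precision NIfTI-1 per quantity (k1, k2, k3, k4, cecp,
#' wrss; undefined voxels as NaN), the mask as uint8, and a provenance JSON
#' with the fit configuration alongside.
#'
#' @param pmap A [fit_image()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param provenance Optional extra provenance fields (list).
#' @return The directory, invisibly.
#' @export
write_parametric_maps <- function(pmap, dir, prefix = "fit",
                                  provenance = list()) {
  stopifnot(inherits(pmap, "parametric_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- pmap$voxel_dims
  for (q in c("k1", "k2", "k3", "k4", "cecp", "wrss")) {
    a <- pmap[[q]]
    a[is.na(a)] <- NaN # undefined voxels stored as NaN by convention
    nii <- RNifti::asNifti(a)
    RNifti::pixdim(nii) <- pd
    RNifti::writeNifti(nii, file.path(dir, paste0(prefix, "_", q, ".nii.gz")),
                       datatype = "double")
  }
  mask <- RNifti::asNifti(array(as.integer(pmap$mask), dim(pmap$mask)))
  RNifti::pixdim(mask) <- pd
  RNifti::writeNifti(mask, file.path(dir, paste0(prefix, "_mask.nii.gz")),
                     datatype = "uint8")
  prov <- c(list(package = "fdgkin",
                 version = as.character(utils::packageVersion("fdgkin")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 config = pmap$config[setdiff(names(pmap$config), "")],
                 config_digest = config_digest_(pmap$config),
                 n_nonconverged = pmap$n_nonconverged),
            provenance)
  jsonlite::write_json(prov, file.path(dir, paste0(prefix, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Read one parametric map volume
#'
#' @param path NIfTI path written by [write_parametric_maps()].
#' @return 3D array.
#' @export
read_map <- function(path) plain_array_(RNifti::readNifti(path))

# strip NIfTI attributes down to a plain numeric array
plain_array_ <- function(nii) {
  arr <- as.array(nii)
  array(as.vector(arr), dim(arr))
}

# md5 digest of an R object via its canonical JSON serialization
config_digest_ <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

#' Write a 3D map as NIfTI-1
#'
#' @param arr 3D array.
#' @param path Output path.
#' @param voxel_dims mm triple.
#' @export
write_map <- function(arr, path, voxel_dims = c(0.4, 0.4, 0.8)) {
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- voxel_dims
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}
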