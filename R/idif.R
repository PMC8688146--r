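#' Locate the blood pool on the first frame
#'
#' The arterial blood pool is the hottest structure on the earliest frame of
#' a dynamic FDG scan. The mask is the connected component (6-neighbour)
#' containing the first-frame maximum among voxels above a quantile
#' threshold of the positive first-frame values. A fraction-of-maximum
#' guard (`min_frac`) keeps the candidate set from leaking into tissue,
#' which at the first frame is far colder than blood.
#'
#' @param image A [dynamic_image()] with at least one frame.
#' @param quantile Threshold quantile of positive first-frame voxel values
#'   (default 0.95).
#' @param min_frac Candidates must also exceed this fraction of the
#'   first-frame maximum (default 0.25).
#' @return Logical 3D mask.
#' @export
locate_blood_pool <- function(image, quantile = 0.95, min_frac = 0.25) {
  stopifnot(inherits(image, "dynamic_image"))
  f1 <- image$data[, , , 1, drop = TRUE]
  pos <- f1[f1 > 0]
  if (length(pos) == 0L)
    stop("no positive voxels in the first frame; cannot locate blood pool")
  thr <- max(stats::quantile(pos, quantile, names = FALSE),
             min_frac * max(f1))
  cand <- f1 >= thr
  if (!any(cand)) stop("no voxel exceeds the blood-pool threshold")
  comp <- label_components_(cand)
  comp == comp[which.max(f1)]
}

#' Extract an image-derived input function
#'
#' Per-frame mean activity over the mask voxels, timestamped at frame
#' mid-times. The result is uncorrected for partial volume; see
#' [pvc_correct()].
#'
#' @param image A [dynamic_image()].
#' @param mask Logical 3D mask (non-empty, congruent with the image).
#' @return A [sampled_plasma()] with attribute `pv_corrected = FALSE`.
#' @export
extract_idif <- function(image, mask) {
  stopifnot(inherits(image, "dynamic_image"))
  if (!identical(dim(mask), dim(image$data)[1:3]))
    stop("mask geometry does not match the image")
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty blood-pool mask")
  nf <- nrow(image$schedule)
  vol <- prod(dim(image$data)[1:3])
  vals <- vapply(seq_len(nf), function(j)
    mean(image$data[idx + (j - 1L) * vol]), numeric(1))
  out <- sampled_plasma(frame_mid_s(image$schedule), pmax(vals, 0))
  attr(out, "pv_corrected") <- FALSE
  attr(out, "raw_negative") <- sum(vals < 0)
  out
}

#' Partial-volume correction of an IDIF
#'
#' Inverts the mixing of blood activity with surrounding background at a
#' standardized volume fraction: `corrected = (measured - (1 - vf) *
#' background) / vf`. With the default `background = 0` this is division by
#' `vf` (0.6), matching the standardized-volume-fraction correction as
#' usually stated; the spill-in term is available as an option. Corrected
#' values below zero are clamped to zero with a warning.
#'
#' @param idif A [sampled_plasma()] from [extract_idif()].
#' @param vf Volume fraction in (0, 1], default 0.6.
#' @param background Background activity (scalar or per-sample), default 0.
#' @return A corrected [sampled_plasma()] with attribute
#'   `pv_corrected = TRUE` and `n_clamped`.
#' @export
pvc_correct <- function(idif, vf = 0.6, background = 0) {
  stopifnot(inherits(idif, "plasma_sampled"), vf > 0, vf <= 1)
  bg <- rep_len(background, length(idif$conc))
  corrected <- (idif$conc - (1 - vf) * bg) / vf
  n_clamped <- sum(corrected < -1e-12)
  if (n_clamped > 0)
    warning(n_clamped, " corrected IDIF value(s) below zero; clamped")
  out <- sampled_plasma(idif$time_s, pmax(corrected, 0))
  attr(out, "pv_corrected") <- TRUE
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Write / read an IDIF as CSV
#'
#' Columns: `time_s`, `uncorrected_kBq_ml`, `corrected_kBq_ml`.
#' @param uncorrected,corrected [sampled_plasma()] objects on the same grid.
#' @param path File path.
#' @export
write_idif_csv <- function(uncorrected, corrected, path) {
  stopifnot(identical(uncorrected$time_s, corrected$time_s))
  utils::write.csv(data.frame(time_s = uncorrected$time_s,
                              uncorrected_kBq_ml = uncorrected$conc,
                              corrected_kBq_ml = corrected$conc),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_idif_csv
#' @return `read_idif_csv()` returns a list with elements `uncorrected` and
#'   `corrected`.
#' @export
read_idif_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("time_s", "uncorrected_kBq_ml", "corrected_kBq_ml")
  if (!all(need %in% names(tab))) stop("malformed IDIF CSV")
  list(uncorrected = sampled_plasma(tab$time_s, tab$uncorrected_kBq_ml),
       corrected = sampled_plasma(tab$time_s, tab$corrected_kBq_ml))
}
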