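#' Emission frame schedule
#'
#' An ordered set of contiguous, non-overlapping emission time frames into
#' which continuous tracer activity is histogrammed. Times are in seconds
#' from injection.
#'
#' @param start_s,end_s Numeric vectors of frame start/end times (seconds).
#' @return A `frame_schedule`: a data frame with columns `frame_start_s`
#'   and `frame_end_s`.
#' @examples
#' fs <- default_frame_schedule()
#' nrow(fs)            # 25
#' sum(frame_dur_s(fs))  # 2580 s
#' @export
frame_schedule <- function(start_s, end_s) {
  stopifnot(is.numeric(start_s), is.numeric(end_s),
            length(start_s) == length(end_s), length(start_s) >= 1L)
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)))
    stop("frame times must be finite")
  if (any(end_s <= start_s))
    stop("every frame must satisfy start < end")
  if (is.unsorted(start_s, strictly = TRUE))
    stop("frames must be in increasing time order")
  if (length(start_s) > 1L &&
      any(abs(start_s[-1] - end_s[-length(end_s)]) > 1e-9))
    stop("frames must be contiguous and non-overlapping")
  out <- data.frame(frame_start_s = as.numeric(start_s),
                    frame_end_s = as.numeric(end_s))
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Default 45-minute 25-frame schedule
#'
#' Twelve 30-s frames, three 60-s frames, three 120-s frames and seven
#' 240-s frames (2580 s total), the standard dynamic FDG acquisition this
#' package targets.
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- rep(c(30, 60, 120, 240), c(12L, 3L, 3L, 7L))
  ends <- cumsum(dur)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

#' @rdname frame_schedule
#' @param schedule A `frame_schedule`.
#' @export
frame_mid_s <- function(schedule) {
  (schedule$frame_start_s + schedule$frame_end_s) / 2
}

#' @rdname frame_schedule
#' @export
frame_dur_s <- function(schedule) {
  schedule$frame_end_s - schedule$frame_start_s
}

#' Read / write a frame schedule as TSV
#'
#' The sidecar format is a two-column tab-separated table with header
#' `frame_start_s`, `frame_end_s`.
#' @param path File path.
#' @return `read_frame_schedule()` returns a [frame_schedule()].
#' @export
read_frame_schedule <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("frame_start_s", "frame_end_s")
  if (!all(need %in% names(tab)))
    stop("schedule TSV must have columns frame_start_s and frame_end_s")
  frame_schedule(tab$frame_start_s, tab$frame_end_s)
}

#' @rdname read_frame_schedule
#' @param schedule A [frame_schedule()].
#' @export
write_frame_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
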