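#' Calibrated time-lapse movie
#'
#' Container for a fluorescence time-lapse recording: a `T x Y x X` array
#' (or `T x Z x Y x X` before z-averaging) of grey-level intensities plus the
#' acquisition calibration (frame period in seconds, pixel size in um/px).
#'
#' @param data numeric array, `T x Y x X` or `T x Z x Y x X`, finite and >= 0.
#' @param frame_period_s frame period in seconds (0.25 Hz acquisition = 4 s).
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param channel free-text channel label.
#' @return an object of class `ca_movie`.
#' @export
ca_movie <- function(data, frame_period_s = 4, pixel_size_um = 1,
                     channel = "GCaMP") {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a T x Y x X or T x Z x Y x X array")
  if (!all(is.finite(data))) stop("movie intensities must be finite")
  if (min(data) < 0) stop("movie intensities must be >= 0")
  structure(list(data = data, frame_period_s = frame_period_s,
                 pixel_size_um = pixel_size_um, channel = channel),
            class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$data)
  axes <- if (length(d) == 4L) "T x Z x Y x X" else "T x Y x X"
  cat(sprintf("<ca_movie> %s: %s | %.3g s/frame, %.3g um/px, channel %s\n",
              axes, paste(d, collapse = " x "), x$frame_period_s,
              x$pixel_size_um, x$channel))
  invisible(x)
}

n_frames <- function(movie) dim(movie$data)[1]

has_z <- function(movie) length(dim(movie$data)) == 4L

frame_dims <- function(movie) {
  d <- dim(movie$data)
  d[(length(d) - 1L):length(d)]
}

#' Stimulus protocol
#'
#' Ordered, labelled stimulation windows of a calcium-imaging run. The
#' standard run applies the three TRP-channel agonist windows in the fixed
#' order M3 (pregnenolone sulfate + CIM0216), A1 (mustard oil), V1
#' (capsaicin), followed by the depolarising high-potassium window K used for
#' excitability verification and amplitude normalisation.
#'
#' @param label character vector of stimulus labels (subset of M3, A1, V1, K
#'   in that order; K last when present).
#' @param start_frame,end_frame integer vectors of window bounds (inclusive,
#'   1-based frames).
#' @param pre_frames number of pre-stimulus frames used as the per-stimulus
#'   baseline window (default 10); at least 3.
#' @param recovery_gap frames after the previous window's end excluded from
#'   the next baseline (wash-out guard, default 2).
#' @param agonist optional free-text agonist metadata per window.
#' @return an object of class `stim_protocol` (a data frame).
#' @export
stim_protocol <- function(label, start_frame, end_frame,
                          pre_frames = 10L, recovery_gap = 2L,
                          agonist = NULL) {
  label <- as.character(label)
  canonical <- c("M3", "A1", "V1", "K")
  if (!all(label %in% canonical))
    stop("labels must be among ", paste(canonical, collapse = ", "))
  if (!identical(label, canonical[canonical %in% label]))
    stop("stimuli must follow the fixed order M3, A1, V1, K")
  if (anyDuplicated(label)) stop("duplicate stimulus labels")
  start_frame <- as.integer(start_frame); end_frame <- as.integer(end_frame)
  if (any(end_frame < start_frame)) stop("window end before start")
  if (any(start_frame[-1] <= end_frame[-length(end_frame)]))
    stop("stimulus windows must be non-overlapping and ordered")
  if (pre_frames < 3L) stop("pre-stimulus window must be >= 3 frames")
  p <- data.frame(label = label, start_frame = start_frame,
                  end_frame = end_frame, stringsAsFactors = FALSE)
  if (!is.null(agonist)) p$agonist <- as.character(agonist)
  attr(p, "pre_frames") <- as.integer(pre_frames)
  attr(p, "recovery_gap") <- as.integer(recovery_gap)
  class(p) <- c("stim_protocol", "data.frame")
  p
}

#' Default four-stimulus protocol
#'
#' A compact M3 / A1 / V1 / K protocol: a pre-stimulus baseline, 6-frame
#' agonist windows separated by wash-out gaps, the K window last.
#'
#' @param baseline_frames frames before the first stimulus (default 14).
#' @param stim_frames frames per stimulus window (default 6).
#' @param gap_frames wash-out frames between windows (default 10).
#' @param pre_frames baseline frames per stimulus (default 10).
#' @return a [stim_protocol()].
#' @export
default_protocol <- function(baseline_frames = 14L, stim_frames = 6L,
                             gap_frames = 10L, pre_frames = 10L) {
  starts <- baseline_frames + 1L +
    (0:3) * (stim_frames + gap_frames)
  stim_protocol(c("M3", "A1", "V1", "K"), starts,
                starts + stim_frames - 1L, pre_frames = pre_frames)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>\n")
  print.data.frame(x)
  cat(sprintf("pre_frames: %d, recovery_gap: %d\n",
              attr(x, "pre_frames"), attr(x, "recovery_gap")))
  invisible(x)
}

protocol_end <- function(protocol) max(protocol$end_frame)

first_onset <- function(protocol) min(protocol$start_frame)

## per-stimulus baseline frames: the frames between the previous window's end
## (plus the recovery gap) and the current onset, truncated to the trailing
## `pre_frames`
pre_window_frames <- function(protocol, i) {
  pre_frames <- attr(protocol, "pre_frames")
  gap <- attr(protocol, "recovery_gap")
  lo <- if (i == 1L) 1L else protocol$end_frame[i - 1L] + gap + 1L
  hi <- protocol$start_frame[i] - 1L
  if (hi - lo + 1L < 3L)
    stop("fewer than 3 baseline frames before stimulus ", protocol$label[i])
  frames <- lo:hi
  if (length(frames) > pre_frames)
    frames <- frames[(length(frames) - pre_frames + 1L):length(frames)]
  frames
}

stim_window_frames <- function(protocol, i)
  protocol$start_frame[i]:protocol$end_frame[i]
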