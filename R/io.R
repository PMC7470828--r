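#' Write a movie as multi-page TIFF with a JSON metadata sidecar
#'
#' Frames (z-planes flattened page-wise for 4-D stacks) are stored as
#' 32-bit float pages scaled to [0, 1]; the scale, axis layout and
#' calibration go to `<path>.json` so the round trip is lossless to float
#' precision.
#'
#' @param movie a [ca_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$data)
  scale <- max(movie$data, 1e-12)
  pages <- if (length(d) == 4L) {
    unlist(lapply(seq_len(d[1]), function(t)
      lapply(seq_len(d[2]), function(z) movie$data[t, z, , ] / scale)),
      recursive = FALSE)
  } else {
    lapply(seq_len(d[1]), function(t) movie$data[t, , ] / scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(dims = d, scale = scale,
               frame_period_s = movie$frame_period_s,
               pixel_size_um = movie$pixel_size_um, channel = movie$channel)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path (expects the `.json` sidecar next to it).
#' @return a [ca_movie()].
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  data <- array(0, d)
  if (length(d) == 4L) {
    k <- 0L
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
      k <- k + 1L
      data[t, z, , ] <- pages[[k]] * meta$scale
    }
  } else {
    for (t in seq_len(d[1])) data[t, , ] <- pages[[t]] * meta$scale
  }
  ca_movie(data, meta$frame_period_s, meta$pixel_size_um, meta$channel)
}

#' Write / read a 16-bit label mask TIFF
#'
#' Labels up to 65535 survive the round trip exactly.
#'
#' @param label Y x X integer matrix.
#' @param path file path.
#' @return `path` invisibly / the label matrix.
#' @export
write_mask_tiff <- function(label, path) {
  if (max(label) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(label / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read a stimulus protocol as YAML
#'
#' @param protocol a [stim_protocol()].
#' @param path YAML path.
#' @return `path` invisibly / a [stim_protocol()].
#' @export
write_protocol_yaml <- function(protocol, path) {
  obj <- list(pre_frames = attr(protocol, "pre_frames"),
              recovery_gap = attr(protocol, "recovery_gap"),
              windows = lapply(seq_len(nrow(protocol)), function(i) {
                w <- list(label = protocol$label[i],
                          start_frame = protocol$start_frame[i],
                          end_frame = protocol$end_frame[i])
                if (!is.null(protocol$agonist)) w$agonist <- protocol$agonist[i]
                w
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  w <- obj$windows
  stim_protocol(vapply(w, `[[`, "", "label"),
                vapply(w, `[[`, 1, "start_frame"),
                vapply(w, `[[`, 1, "end_frame"),
                pre_frames = obj$pre_frames,
                recovery_gap = obj$recovery_gap,
                agonist = if (!is.null(w[[1]]$agonist))
                  vapply(w, `[[`, "", "agonist") else NULL)
}

#' Write a ground-truth sidecar as JSON
#'
#' Serialises a `calcium_truth`, `skin_truth` or `rnascope_truth` (label
#' images included as nested arrays) so generated datasets are
#' self-describing on disk.
#'
#' @param truth a truth object.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- unclass(truth)
  obj$.class <- class(truth)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Write / read a background model as JSON
#'
#' @param model a [fit_background()] model.
#' @param path JSON path.
#' @return `path` invisibly / a `background_model` (mask omitted on disk;
#'   re-evaluation via [predict.background_model()] only needs the
#'   coefficients, degree and field size).
#' @export
write_background_json <- function(model, path) {
  jsonlite::write_json(list(coefficients = as.list(model$coefficients),
                            degree = model$degree, dims = model$dims,
                            n_mask_px = sum(model$mask)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_background_json
#' @export
read_background_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(obj$coefficients),
                 degree = obj$degree, dims = as.integer(obj$dims),
                 mask = NULL),
            class = "background_model")
}
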