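#' Z-average a z-stack movie
#'
#' Collapses a `T x Z x Y x X` recording to `T x Y x X` by averaging over
#' the z planes, the first step applied to spinning-disk stacks.
#'
#' @param movie a [ca_movie()].
#' @param allow_projected if `TRUE`, a movie without a Z axis is returned
#'   unchanged; otherwise the missing axis is an error.
#' @return a `T x Y x X` [ca_movie()] with calibration preserved.
#' @export
z_project <- function(movie, allow_projected = TRUE) {
  if (!has_z(movie)) {
    if (allow_projected) return(movie)
    stop("movie has no Z axis to project")
  }
  d <- dim(movie$data)
  out <- array(0, d[c(1, 3, 4)])
  for (t in seq_len(d[1]))
    out[t, , ] <- colMeans(array(movie$data[t, , , ], d[2:4]), dims = 1)
  ca_movie(out, movie$frame_period_s, movie$pixel_size_um, movie$channel)
}

#' Pre-stimulus reference image
#'
#' Temporal mean of the first `n_frames` frames, taken before any stimulus,
#' used both as the registration template and as the baseline F0.
#'
#' @param movie a z-projected [ca_movie()].
#' @param n_frames frames to average (default 10).
#' @param protocol optional [stim_protocol()]; when given, `n_frames` must
#'   not reach into the first stimulus window.
#' @return Y x X matrix with attribute `n_frames_averaged`.
#' @export
make_reference <- function(movie, n_frames = 10L, protocol = NULL) {
  if (has_z(movie)) stop("z-project the movie first")
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L || n_frames > n_frames(movie))
    stop("n_frames out of range")
  if (!is.null(protocol) && n_frames >= first_onset(protocol))
    stop("reference frames reach into the first stimulus window")
  ref <- colMeans(array(movie$data[seq_len(n_frames), , ],
                        c(n_frames, frame_dims(movie))), dims = 1)
  attr(ref, "n_frames_averaged") <- n_frames
  ref
}

## integer-shift estimate maximising circular cross-correlation (FFT)
xcorr_shift <- function(frame, reference) {
  f <- frame - mean(frame)
  r <- reference - mean(reference)
  if (all(f == 0) || all(r == 0)) return(c(NA_integer_, NA_integer_))
  cc <- Re(stats::fft(stats::fft(r) * Conj(stats::fft(f)), inverse = TRUE))
  k <- which.max(cc) - 1L
  ny <- nrow(frame); nx <- ncol(frame)
  dy <- k %% ny; dx <- k %/% ny
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  ## cc[dy,dx] peaks where frame shifted by (dy,dx) matches the reference,
  ## i.e. the frame is displaced by (-dy,-dx) relative to it
  c(-dy, -dx)
}

#' Correct translational drift against a reference image
#'
#' Estimates an integer (dy, dx) shift per frame by FFT cross-correlation
#' with the reference and shifts each frame back, replicating edge values
#' for pixels entering the field.
#'
#' @param movie a z-projected [ca_movie()].
#' @param reference Y x X reference image from [make_reference()].
#' @param max_shift optional cap on the absolute shift (px); larger
#'   estimates are clamped with a warning.
#' @return list with `movie` (registered), `shifts` (`T x 2` matrix of the
#'   estimated frame displacements), and `degenerate` (logical per frame:
#'   constant frames get zero shift with a warning).
#' @export
register_translation <- function(movie, reference, max_shift = NULL) {
  if (has_z(movie)) stop("z-project the movie first")
  if (!identical(dim(reference), frame_dims(movie)))
    stop("reference dimensions do not match the movie frames")
  T <- n_frames(movie)
  shifts <- matrix(0L, T, 2, dimnames = list(NULL, c("dy", "dx")))
  degenerate <- logical(T)
  out <- movie$data
  for (t in seq_len(T)) {
    s <- xcorr_shift(movie$data[t, , ], reference)
    if (anyNA(s)) {
      degenerate[t] <- TRUE
      s <- c(0L, 0L)
    }
    if (!is.null(max_shift) && any(abs(s) > max_shift)) {
      warning("frame ", t, ": estimated shift exceeds max_shift, clamped")
      s <- pmin(pmax(s, -max_shift), max_shift)
    }
    shifts[t, ] <- s
    if (any(s != 0L)) out[t, , ] <- shift_matrix(movie$data[t, , ],
                                                 -s[1], -s[2])
  }
  if (any(degenerate))
    warning(sum(degenerate), " constant frame(s): zero shift assumed")
  list(movie = ca_movie(out, movie$frame_period_s, movie$pixel_size_um,
                        movie$channel),
       shifts = shifts, degenerate = degenerate)
}

#' Temporal coefficient-of-variation map
#'
#' Per-pixel SD over time divided by mean over time (population SD). Pixels
#' whose temporal mean is at or below `eps` get CV 0 and are flagged.
#'
#' @param movie a z-projected [ca_movie()].
#' @param eps mean guard; default `1e-6 * max(movie)` (scale-free).
#' @return Y x X matrix with attribute `flagged` (logical matrix of guarded
#'   pixels).
#' @export
temporal_cv_map <- function(movie, eps = NULL) {
  if (has_z(movie)) stop("z-project the movie first")
  eps <- eps %||% (1e-6 * max(movie$data))
  d <- frame_dims(movie)
  T <- n_frames(movie)
  flat <- matrix(aperm(movie$data, c(2, 3, 1)), prod(d), T)
  mu <- rowMeans(flat)
  sd_t <- sqrt(rowMeans(flat^2) - mu^2)
  sd_t[sd_t < 0 | is.nan(sd_t)] <- 0
  cv <- ifelse(mu > eps, sd_t / mu, 0)
  flagged <- matrix(mu <= eps, d[1], d[2])
  cv <- matrix(cv, d[1], d[2])
  attr(cv, "flagged") <- flagged
  cv
}

#' Non-responsive pixel mask by Otsu thresholding of the CV map
#'
#' Pixels whose temporal CV falls below the Otsu threshold (256 equal-width
#' bins, ties toward the lower threshold) are non-responsive; the polynomial
#' background surface is fitted only to these.
#'
#' @param cv_map output of [temporal_cv_map()].
#' @param n_bins histogram bins (default 256).
#' @return logical Y x X mask (`TRUE` = non-responsive) with attribute
#'   `threshold`. A constant CV map yields an all-`TRUE` mask with a warning.
#' @export
nonresponsive_mask <- function(cv_map, n_bins = 256L) {
  if (!all(is.finite(cv_map))) stop("CV map must be finite")
  thr <- suppressWarnings(otsu_threshold(cv_map, n_bins))
  if (is.na(thr)) {
    warning("constant CV map: entire image marked non-responsive")
    mask <- matrix(TRUE, nrow(cv_map), ncol(cv_map))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  mask <- cv_map < thr
  attr(mask, "threshold") <- thr
  mask
}

poly_terms <- function(degree) {
  ij <- expand.grid(i = 0:degree, j = 0:degree)
  ij[ij$i + ij$j <= degree, , drop = FALSE]
}

poly_design <- function(ys, xs, degree) {
  ## coordinates scaled to [-1, 1] for conditioning; the span of all
  ## monomials x^i y^j (i + j <= degree) is unchanged by the affine map
  tm <- poly_terms(degree)
  X <- matrix(0, length(ys), nrow(tm))
  for (k in seq_len(nrow(tm))) X[, k] <- xs^tm$i[k] * ys^tm$j[k]
  colnames(X) <- sprintf("x%d.y%d", tm$i, tm$j)
  X
}

scale_coords <- function(idx, n) if (n > 1L) 2 * (idx - 1) / (n - 1) - 1 else 0

#' Fit a polynomial background surface to non-responsive pixels
#'
#' Least-squares fit of a bivariate polynomial of total degree `degree`
#' (all monomials `x^i y^j`, `i + j <= degree`; 15 terms at degree 4) to the
#' mask-true pixels of a time-averaged image. The surface is fitted once to
#' the temporal mean and subtracted from every frame: the mask is defined by
#' temporal statistics, so the model is temporal by construction, and
#' per-frame fits would absorb stimulus signal.
#'
#' @param image Y x X time-averaged (or reference) image.
#' @param mask logical Y x X, `TRUE` where the fit may use pixels.
#' @param degree total polynomial degree (default 4).
#' @return an object of class `background_model` with the coefficients, the
#'   degree, the image dimensions and the mask.
#' @export
fit_background <- function(image, mask, degree = 4L) {
  stopifnot(identical(dim(image), dim(mask)))
  n_terms <- nrow(poly_terms(degree))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < n_terms)
    stop("mask has ", nrow(idx), " pixels; need at least ", n_terms)
  ys <- scale_coords(idx[, 1], nrow(image))
  xs <- scale_coords(idx[, 2], ncol(image))
  X <- poly_design(ys, xs, degree)
  qrX <- qr(X)
  if (qrX$rank < n_terms)
    stop("rank-deficient background design: mask pixels are degenerate ",
         "(e.g. confined to a line)")
  beta <- qr.coef(qrX, image[mask])
  structure(list(coefficients = beta, degree = degree,
                 dims = dim(image), mask = mask),
            class = "background_model")
}

#' Evaluate a fitted background surface
#'
#' @param object a `background_model`.
#' @param ... unused.
#' @return Y x X matrix of the fitted surface.
#' @export
predict.background_model <- function(object, ...) {
  ny <- object$dims[1]; nx <- object$dims[2]
  idx <- as.matrix(expand.grid(y = seq_len(ny), x = seq_len(nx)))
  X <- poly_design(scale_coords(idx[, 1], ny), scale_coords(idx[, 2], nx),
                   object$degree)
  matrix(X %*% object$coefficients, ny, nx)
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> total degree %d (%d terms), %d x %d field, %d mask pixels\n",
              x$degree, length(x$coefficients), x$dims[1], x$dims[2],
              sum(x$mask)))
  invisible(x)
}

#' Subtract a fitted background surface from every frame
#'
#' @param movie a z-projected [ca_movie()].
#' @param model a [fit_background()] model.
#' @return the background-subtracted [ca_movie()], clamped at 0.
#' @export
subtract_background <- function(movie, model) {
  surf <- predict(model)
  out <- movie$data
  for (t in seq_len(n_frames(movie)))
    out[t, , ] <- pmax(movie$data[t, , ] - surf, 0)
  ca_movie(out, movie$frame_period_s, movie$pixel_size_um, movie$channel)
}

#' Normalise a movie to its baseline fluorescence
#'
#' Converts raw fluorescence to F/F0 or dF/F0 = (F - F0) / F0 against a
#' per-pixel baseline (normally the pre-stimulus reference image). Pixels
#' with F0 at or below `eps` are excluded (set `NA`) and flagged.
#'
#' @param movie a z-projected [ca_movie()].
#' @param f0 Y x X baseline image.
#' @param mode `"dff"` (default) or `"f_f0"`.
#' @param eps baseline guard; default `1e-6 * max(f0)`.
#' @return a [ca_movie()] of normalised values with attribute `excluded`
#'   (logical Y x X).
#' @export
normalize_movie <- function(movie, f0, mode = c("dff", "f_f0"), eps = NULL) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(f0), frame_dims(movie)))
  eps <- eps %||% (1e-6 * max(f0))
  if (all(f0 <= eps)) stop("baseline is zero everywhere")
  excluded <- f0 <= eps
  out <- movie$data
  safe <- ifelse(excluded, NA_real_, f0)
  for (t in seq_len(n_frames(movie))) {
    r <- movie$data[t, , ] / safe
    out[t, , ] <- if (mode == "dff") r - 1 else r
  }
  m <- structure(list(data = out, frame_period_s = movie$frame_period_s,
                      pixel_size_um = movie$pixel_size_um,
                      channel = paste0(movie$channel, " (", mode, ")")),
                 class = "ca_movie")
  attr(m, "excluded") <- excluded
  m
}

#' Full preprocessing pipeline
#'
#' Z-average, build the pre-stimulus reference, correct translational drift,
#' compute the temporal-CV non-responsive mask, fit and subtract the
#' polynomial background surface, and normalise to the (background-
#' corrected) reference baseline.
#'
#' @param movie a raw [ca_movie()] (with or without a Z axis).
#' @param protocol a [stim_protocol()] (guards the reference window).
#' @param ref_frames reference frames to average (default 10).
#' @param degree background polynomial total degree (default 4).
#' @param register correct drift (default `TRUE`).
#' @param background fit/subtract the background surface (default `TRUE`;
#'   the in-situ DRG branch may disable it).
#' @param mode normalisation mode passed to [normalize_movie()].
#' @return list with `dff` (normalised [ca_movie()]), `corrected` (the
#'   registered, background-subtracted movie), `reference`, `shifts`,
#'   `cv_map`, `mask`, and `background_model` (NULL when disabled).
#' @export
preprocess_movie <- function(movie, protocol, ref_frames = 10L, degree = 4L,
                             register = TRUE, background = TRUE,
                             mode = "dff") {
  m <- z_project(movie)
  ref <- make_reference(m, ref_frames, protocol)
  shifts <- NULL
  if (register) {
    reg <- register_translation(m, ref)
    m <- reg$movie
    shifts <- reg$shifts
    ref <- make_reference(m, ref_frames, protocol)
  }
  cv <- temporal_cv_map(m)
  mask <- nonresponsive_mask(cv)
  bg_model <- NULL
  if (background) {
    tmean <- colMeans(aperm(m$data, c(1, 2, 3)), dims = 1)
    bg_model <- fit_background(tmean, mask, degree)
    m <- subtract_background(m, bg_model)
    ref <- make_reference(m, ref_frames, protocol)
  }
  dff <- normalize_movie(m, ref, mode = mode)
  list(dff = dff, corrected = m, reference = ref, shifts = shifts,
       cv_map = cv, mask = mask, background_model = bg_model)
}
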