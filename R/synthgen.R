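#' Ground truth for a synthetic calcium-imaging movie
#'
#' Describes a field of GCaMP-expressing somata with programmed responses:
#' which channels (M3, A1, V1) each cell functionally expresses, the response
#' amplitude per stimulus in multiples of the baseline noise SD, whether the
#' cell responds to the depolarising K+ stimulus, its retrograde-label (WGA)
#' status, per-frame translational drift, a smooth polynomial background
#' field, and the noise model.
#'
#' @param cell_positions n x 2 matrix of (y, x) centres in pixels.
#' @param cell_radius_px soma radius in pixels (> 0).
#' @param expressed list (length n) of character vectors, subsets of
#'   `c("M3","A1","V1")`.
#' @param amplitude_sd response amplitude in units of the baseline noise SD
#'   (scalar, or n-vector per cell); >= 0.
#' @param k_responsive logical n-vector: responds to high K+.
#' @param wga_labeled logical n-vector: retrogradely labelled.
#' @param drift_path `T x 2` matrix of per-frame (dy, dx) shifts in pixels,
#'   or NULL for no drift.
#' @param background_coeffs named numeric vector of bivariate polynomial
#'   coefficients (names like `"x2.y1"` meaning `x^2 * y^1` on coordinates
#'   scaled to `[-1, 1]`), total degree <= 4; default none (flat field).
#' @param noise_sd additive Gaussian noise SD in grey levels (default 2).
#' @param baseline_level resting fluorescence in grey levels (default 100).
#' @param resting_contrast static grey-level elevation of cell pixels above
#'   the surrounding field (GCaMP somata are visible at rest; default 20,
#'   i.e. 10x the default noise SD, giving the registration and blob stages
#'   a structural SNR of 10).
#' @return an object of class `calcium_truth`.
#' @export
calcium_truth <- function(cell_positions, cell_radius_px = 6,
                          expressed, amplitude_sd = 10,
                          k_responsive = TRUE, wga_labeled = FALSE,
                          drift_path = NULL, background_coeffs = numeric(0),
                          noise_sd = 2, baseline_level = 100,
                          resting_contrast = 20) {
  cell_positions <- as.matrix(cell_positions)
  n <- nrow(cell_positions)
  if (ncol(cell_positions) != 2L) stop("cell_positions must be n x 2 (y, x)")
  if (cell_radius_px <= 0) stop("cell_radius_px must be positive")
  if (length(expressed) != n) stop("`expressed` must have one entry per cell")
  lapply(expressed, function(e) {
    if (!all(e %in% c("M3", "A1", "V1")))
      stop("expressed channels must be subsets of {M3, A1, V1}")
  })
  amplitude_sd <- rep_len(amplitude_sd, n)
  if (any(amplitude_sd < 0)) stop("response amplitudes must be >= 0")
  k_responsive <- rep_len(as.logical(k_responsive), n)
  wga_labeled <- rep_len(as.logical(wga_labeled), n)
  ## cells must be disjoint
  if (n > 1L) {
    d <- as.matrix(stats::dist(cell_positions))
    diag(d) <- Inf
    if (min(d) <= 2 * cell_radius_px)
      stop("overlapping cells: minimum centre distance ",
           sprintf("%.2f", min(d)), " <= 2 * radius")
  }
  structure(list(cell_positions = cell_positions,
                 cell_radius_px = cell_radius_px,
                 expressed = expressed, amplitude_sd = amplitude_sd,
                 k_responsive = k_responsive, wga_labeled = wga_labeled,
                 drift_path = drift_path,
                 background_coeffs = background_coeffs,
                 noise_sd = noise_sd, baseline_level = baseline_level,
                 resting_contrast = resting_contrast),
            class = "calcium_truth")
}

## evaluate a named coefficient vector ("xi.yj" on [-1,1]-scaled coords)
eval_poly_field <- function(coeffs, ny, nx) {
  field <- matrix(0, ny, nx)
  if (length(coeffs) == 0L) return(field)
  xs <- if (nx > 1L) seq(-1, 1, length.out = nx) else 0
  ys <- if (ny > 1L) seq(-1, 1, length.out = ny) else 0
  for (nm in names(coeffs)) {
    ij <- as.integer(strsplit(sub("x([0-9]+)\\.y([0-9]+)", "\\1 \\2", nm),
                              " ")[[1]])
    field <- field + coeffs[[nm]] * outer(ys^ij[2], xs^ij[1])
  }
  field
}

## step-up / exponential-decay transient kernel over T frames
transient_kernel <- function(T, start_frame, tau = 8) {
  k <- numeric(T)
  t <- start_frame:T
  k[t] <- exp(-(t - start_frame) / tau)
  k
}

## per-cell temporal signal (grey levels) given truth and protocol
truth_cell_traces <- function(truth, protocol, T, tau = 8) {
  n <- nrow(truth$cell_positions)
  traces <- matrix(0, n, T)
  for (i in seq_len(nrow(protocol))) {
    lab <- protocol$label[i]
    kern <- transient_kernel(T, protocol$start_frame[i], tau)
    amp <- vapply(seq_len(n), function(c) {
      on <- if (lab == "K") truth$k_responsive[c]
            else lab %in% truth$expressed[[c]]
      if (on) truth$amplitude_sd[c] * truth$noise_sd else 0
    }, numeric(1))
    traces <- traces + outer(amp, kern)
  }
  traces
}

## static scene: baseline + background field, cell discs flagged separately
truth_scene <- function(truth, ny, nx) {
  bg <- truth$baseline_level + eval_poly_field(truth$background_coeffs, ny, nx)
  if (min(bg) <= 0)
    stop("background field must be strictly positive over the image")
  cell_label <- matrix(0L, ny, nx)
  for (c in seq_len(nrow(truth$cell_positions))) {
    px <- disc_pixels(truth$cell_positions[c, 1], truth$cell_positions[c, 2],
                      truth$cell_radius_px, ny, nx)
    cell_label[cbind(px$y, px$x)] <- c
  }
  bg <- bg + (truth$resting_contrast %||% 0) * (cell_label > 0L)
  list(bg = bg, cell_label = cell_label)
}

#' Generate a synthetic DRG soma movie with ground truth
#'
#' Renders each frame as baseline + polynomial background + per-cell
#' stimulus-locked transients (instant rise, exponential decay with time
#' constant `tau` frames), translates the whole scene along the programmed
#' drift path, and adds Gaussian noise. Emits a co-registered WGA channel in
#' which labelled cells sit `wga_contrast` background-SDs above the WGA
#' background mean.
#'
#' @param truth a [calcium_truth()].
#' @param protocol a [stim_protocol()].
#' @param shape `c(T, Y, X)` movie dimensions.
#' @param seed integer RNG seed; identical seed and truth give bit-identical
#'   output.
#' @param tau transient decay time constant in frames (default 8, i.e. 32 s
#'   at 0.25 Hz).
#' @param z_planes if > 1, emit a `T x Z x Y x X` stack whose planes share
#'   the scene with independent noise.
#' @param frame_period_s,pixel_size_um calibration stored in the movie.
#' @param wga_contrast labelled-cell WGA intensity in background-SD units
#'   (default 10, unambiguous under the 5xSD classifier; lower it for
#'   borderline stress tests).
#' @param noise one of `"gaussian"` (default) or `"poisson"`.
#' @return a list with elements `movie` ([ca_movie()]), `wga` (Y x X WGA
#'   channel image), `truth` (the input truth with `drift_path` filled in),
#'   and `cell_label` (Y x X ground-truth label image, pre-drift).
#' @export
gen_soma_movie <- function(truth, protocol, shape, seed, tau = 8,
                           z_planes = 1L, frame_period_s = 4,
                           pixel_size_um = 1, wga_contrast = 10,
                           noise = c("gaussian", "poisson")) {
  noise <- match.arg(noise)
  stopifnot(length(shape) == 3L)
  T <- shape[1]; ny <- shape[2]; nx <- shape[3]
  if (protocol_end(protocol) > T)
    stop("protocol windows do not fit within T = ", T, " frames")
  drift <- truth$drift_path %||% matrix(0L, T, 2)
  if (nrow(drift) != T) stop("drift_path must have one row per frame")
  if (max(abs(drift[, 1])) + truth$cell_radius_px >= ny ||
      max(abs(drift[, 2])) + truth$cell_radius_px >= nx)
    stop("drift too large: a cell would leave the field")
  scene <- truth_scene(truth, ny, nx)
  traces <- truth_cell_traces(truth, protocol, T, tau)
  with_seed(seed, {
    mk_frame <- function(t) {
      f <- scene$bg
      on <- scene$cell_label > 0L
      f[on] <- f[on] + traces[scene$cell_label[on], t]
      shift_matrix(f, drift[t, 1], drift[t, 2])
    }
    if (z_planes > 1L) {
      data <- array(0, c(T, z_planes, ny, nx))
      for (t in seq_len(T)) {
        f <- mk_frame(t)
        for (z in seq_len(z_planes))
          data[t, z, , ] <- add_noise(f, truth$noise_sd, noise)
      }
    } else {
      data <- array(0, c(T, ny, nx))
      for (t in seq_len(T)) data[t, , ] <- add_noise(mk_frame(t),
                                                     truth$noise_sd, noise)
    }
    wga_bg_mean <- 50; wga_bg_sd <- 5
    wga <- matrix(stats::rnorm(ny * nx, wga_bg_mean, wga_bg_sd), ny, nx)
    lab <- scene$cell_label > 0L &
      truth$wga_labeled[pmax(scene$cell_label, 1L)]
    wga[lab] <- wga[lab] + wga_contrast * wga_bg_sd
    wga <- pmax(wga, 0)
    truth$drift_path <- drift
    list(movie = ca_movie(data, frame_period_s, pixel_size_um),
         wga = wga, truth = truth, cell_label = scene$cell_label)
  })
}

add_noise <- function(frame, noise_sd, model) {
  if (model == "poisson") {
    ## shot-like: variance scaled so a flat region at the baseline has the
    ## requested SD
    gain <- noise_sd^2 / mean(frame)
    matrix(stats::rpois(length(frame), frame / gain) * gain,
           nrow(frame), ncol(frame))
  } else {
    pmax(frame + matrix(stats::rnorm(length(frame), 0, noise_sd),
                        nrow(frame), ncol(frame)), 0)
  }
}

#' Ground truth for a synthetic skin-nerve movie
#'
#' Nerve-ending branches are thin random-walk polylines (width 1-3 px) whose
#' member pixels share one temporal trace (perfectly correlated within a
#' branch). Branch fields mirror [calcium_truth()] per branch.
#'
#' @param shape `c(Y, X)` field size.
#' @param n_branches number of branches.
#' @param expressed list of character vectors per branch.
#' @param amplitude_sd amplitude per branch in noise-SD units.
#' @param k_responsive,wga_labeled logical per branch.
#' @param length_px random-walk length in steps (default 60).
#' @param width_px branch width in pixels, 1-3 (default 2).
#' @param seed RNG seed for the geometry.
#' @param background_coeffs,noise_sd,baseline_level,resting_contrast as in
#'   [calcium_truth()].
#' @return an object of class `skin_truth` containing `branch_label`
#'   (Y x X ground-truth label image) and the programmed responses.
#' @export
skin_truth <- function(shape, n_branches, expressed, amplitude_sd = 10,
                       k_responsive = TRUE, wga_labeled = FALSE,
                       length_px = 60, width_px = 2, seed = 1,
                       background_coeffs = numeric(0), noise_sd = 2,
                       baseline_level = 100, resting_contrast = 20) {
  ny <- shape[1]; nx <- shape[2]
  if (length(expressed) != n_branches)
    stop("`expressed` must have one entry per branch")
  if (width_px < 1 || width_px > 3) stop("branch width must be 1-3 px")
  amplitude_sd <- rep_len(amplitude_sd, n_branches)
  if (any(amplitude_sd < 0)) stop("response amplitudes must be >= 0")
  k_responsive <- rep_len(as.logical(k_responsive), n_branches)
  wga_labeled <- rep_len(as.logical(wga_labeled), n_branches)
  label <- with_seed(seed, {
    lab <- matrix(0L, ny, nx)
    margin <- 4L
    for (b in seq_len(n_branches)) {
      placed <- FALSE
      for (attempt in 1:50) {
        y <- stats::runif(1, margin, ny - margin)
        x <- stats::runif(1, margin, nx - margin)
        theta <- stats::runif(1, 0, 2 * pi)
        pts <- matrix(0, length_px, 2)
        for (s in seq_len(length_px)) {
          theta <- theta + stats::rnorm(1, 0, 0.25)
          y <- min(max(y + sin(theta), margin), ny - margin)
          x <- min(max(x + cos(theta), margin), nx - margin)
          pts[s, ] <- c(y, x)
        }
        px <- unique(do.call(rbind, lapply(seq_len(length_px), function(s)
          as.matrix(disc_pixels(pts[s, 1], pts[s, 2], width_px / 2 + 0.5,
                                ny, nx)))))
        ## keep branches separated (1-px clearance) so ground-truth regions
        ## stay disjoint and never merge under 8-connectivity
        clear <- TRUE
        for (dy in -1:1) {
          for (dx in -1:1) {
            yy <- pmin(pmax(px[, 1] + dy, 1L), ny)
            xx <- pmin(pmax(px[, 2] + dx, 1L), nx)
            if (any(lab[cbind(yy, xx)] != 0L)) { clear <- FALSE; break }
          }
          if (!clear) break
        }
        if (clear) {
          lab[px] <- b
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place branch ", b, " without overlap")
    }
    lab
  })
  structure(list(branch_label = label, n_branches = n_branches,
                 expressed = expressed, amplitude_sd = amplitude_sd,
                 k_responsive = k_responsive, wga_labeled = wga_labeled,
                 background_coeffs = background_coeffs, noise_sd = noise_sd,
                 baseline_level = baseline_level,
                 resting_contrast = resting_contrast),
            class = "skin_truth")
}

#' Generate a synthetic skin-nerve movie with ground truth
#'
#' As [gen_soma_movie()], but fluorescence sources are the branch polylines
#' of a [skin_truth()]: all pixels of a branch follow one shared trace, so
#' within-branch temporal correlation is 1 before noise.
#'
#' @param truth a [skin_truth()].
#' @param protocol a [stim_protocol()].
#' @param shape `c(T, Y, X)`; Y, X must match the truth's field.
#' @param seed RNG seed for noise.
#' @param tau,frame_period_s,pixel_size_um as in [gen_soma_movie()].
#' @return list with `movie`, `truth`, and `branch_label`.
#' @export
gen_skin_movie <- function(truth, protocol, shape, seed, tau = 8,
                           frame_period_s = 4, pixel_size_um = 1) {
  T <- shape[1]; ny <- shape[2]; nx <- shape[3]
  stopifnot(all(dim(truth$branch_label) == c(ny, nx)))
  if (protocol_end(protocol) > T)
    stop("protocol windows do not fit within T = ", T, " frames")
  bg <- truth$baseline_level + eval_poly_field(truth$background_coeffs, ny, nx)
  if (min(bg) <= 0) stop("background field must be strictly positive")
  bg <- bg + (truth$resting_contrast %||% 0) * (truth$branch_label > 0L)
  fake <- list(cell_positions = matrix(0, truth$n_branches, 2),
               expressed = truth$expressed, amplitude_sd = truth$amplitude_sd,
               k_responsive = truth$k_responsive, noise_sd = truth$noise_sd)
  traces <- truth_cell_traces(fake, protocol, T, tau)
  with_seed(seed, {
    data <- array(0, c(T, ny, nx))
    on <- truth$branch_label > 0L
    for (t in seq_len(T)) {
      f <- bg
      f[on] <- f[on] + traces[truth$branch_label[on], t]
      data[t, , ] <- add_noise(f, truth$noise_sd, "gaussian")
    }
    list(movie = ca_movie(data, frame_period_s, pixel_size_um),
         truth = truth, branch_label = truth$branch_label)
  })
}

#' Ground truth for a synthetic RNAscope slide
#'
#' @param cell_masks Y x X integer label image of cell segments (0 =
#'   background), e.g. from [make_cell_grid()].
#' @param dots_per_cell non-negative integer per cell.
#' @param cluster_fraction proportion of each cell's dots emitted inside
#'   clusters (default 0.2).
#' @param single_dot_intensity integrated grey-level intensity of one dot
#'   (default 1000).
#' @param single_dot_diameter_um dot diameter in um (default 0.8).
#' @param wga_labeled logical per cell.
#' @return an object of class `rnascope_truth`.
#' @export
rnascope_truth <- function(cell_masks, dots_per_cell, cluster_fraction = 0.2,
                           single_dot_intensity = 1000,
                           single_dot_diameter_um = 0.8,
                           wga_labeled = FALSE) {
  n <- max(cell_masks)
  dots_per_cell <- rep_len(as.integer(dots_per_cell), n)
  if (any(dots_per_cell < 0)) stop("dot counts must be non-negative")
  if (cluster_fraction < 0 || cluster_fraction > 1)
    stop("cluster_fraction must be in [0, 1]")
  structure(list(cell_masks = cell_masks, dots_per_cell = dots_per_cell,
                 cluster_fraction = cluster_fraction,
                 single_dot_intensity = single_dot_intensity,
                 single_dot_diameter_um = single_dot_diameter_um,
                 wga_labeled = rep_len(as.logical(wga_labeled), n)),
            class = "rnascope_truth")
}

#' Lay out a grid of disc-shaped cell masks
#'
#' @param n_cells number of cells.
#' @param cell_radius_px disc radius in pixels.
#' @param spacing_px centre-to-centre spacing (default `3 * radius`).
#' @return Y x X integer label image sized to fit the grid.
#' @export
make_cell_grid <- function(n_cells, cell_radius_px = 12,
                           spacing_px = 3 * cell_radius_px) {
  ncol_g <- ceiling(sqrt(n_cells))
  nrow_g <- ceiling(n_cells / ncol_g)
  ny <- as.integer(nrow_g * spacing_px)
  nx <- as.integer(ncol_g * spacing_px)
  lab <- matrix(0L, ny, nx)
  for (i in seq_len(n_cells)) {
    r <- (i - 1) %/% ncol_g; c <- (i - 1) %% ncol_g
    cy <- r * spacing_px + spacing_px / 2
    cx <- c * spacing_px + spacing_px / 2
    px <- disc_pixels(cy, cx, cell_radius_px, ny, nx)
    lab[cbind(px$y, px$x)] <- i
  }
  lab
}

## render an isotropic Gaussian spot of given integrated intensity
render_spot <- function(img, cy, cx, sigma, integrated) {
  r <- ceiling(4 * sigma)
  ny <- nrow(img); nx <- ncol(img)
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  g <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  patch <- exp(-g / (2 * sigma^2))
  patch <- patch * (integrated / (2 * pi * sigma^2))
  img[ys, xs] <- img[ys, xs] + patch
  img
}

#' Generate a synthetic RNAscope slide with ground truth
#'
#' Emits a probe channel containing Gaussian dots of the stated diameter. A
#' `cluster_fraction` of each cell's dots are merged into clusters of 2-4
#' members, rendered as one wider blob (member dots overlapping beyond
#' resolution) whose integrated intensity is the sum of its members
#' (count x single-dot intensity before noise). A smooth linear background gradient and optional
#' Gaussian noise are added. WGA and DAPI channels are emitted consistently
#' with the truth.
#'
#' @param truth an [rnascope_truth()].
#' @param pixel_size_um pixel size; `single_dot_diameter_um / pixel_size_um`
#'   must be >= 2 px.
#' @param seed RNG seed.
#' @param noise_sd additive noise SD in grey levels (0 = noise-free).
#' @param background_peak amplitude of the smooth background gradient.
#' @param wga_contrast labelled-cell WGA contrast in background-SD units.
#' @return list with `probe`, `wga`, `dapi` (Y x X images), `truth`, and
#'   `spots` (data frame of every emitted object: cell, y, x, members,
#'   is_cluster).
#' @export
gen_rnascope_image <- function(truth, pixel_size_um = 0.2, seed = 1,
                               noise_sd = 0, background_peak = 20,
                               wga_contrast = 10) {
  d_px <- truth$single_dot_diameter_um / pixel_size_um
  if (d_px < 2) stop("dot diameter must be >= 2 px at this pixel size")
  sigma <- d_px / (2 * sqrt(2))
  lab <- truth$cell_masks
  ny <- nrow(lab); nx <- ncol(lab)
  n_cells <- max(lab)
  with_seed(seed, {
    probe <- matrix(0, ny, nx)
    spots <- list()
    for (cell in seq_len(n_cells)) {
      idx <- which(lab == cell, arr.ind = TRUE)
      if (nrow(idx) == 0L && truth$dots_per_cell[cell] > 0L)
        stop("dots requested for cell ", cell, " with empty mask")
      n_dots <- truth$dots_per_cell[cell]
      if (n_dots == 0L) next
      n_clustered <- round(truth$cluster_fraction * n_dots)
      ## group clustered dots into clumps of 2-4 members
      remaining <- n_clustered
      clumps <- integer(0)
      while (remaining >= 2L) {
        k <- min(remaining, sample(2:4, 1))
        if (remaining - k == 1L) k <- remaining   # no stranded member
        clumps <- c(clumps, k)
        remaining <- remaining - k
      }
      n_single <- n_dots - sum(clumps)
      ## dot centres inside the mask; distinct objects (singles, clumps)
      ## separated by >= 2.5 dot diameters so they segment individually
      placed <- matrix(numeric(0), 0, 2)
      pick <- function() {
        for (a in 1:100) {
          cand <- idx[sample.int(nrow(idx), 1L), ]
          if (nrow(placed) == 0L ||
              min((placed[, 1] - cand[1])^2 +
                    (placed[, 2] - cand[2])^2) >= (2.5 * d_px)^2) break
        }
        placed <<- rbind(placed, cand)
        cand
      }
      for (s in seq_len(n_single)) {
        p <- pick()
        probe <- render_spot(probe, p[1], p[2], sigma,
                             truth$single_dot_intensity)
        spots[[length(spots) + 1L]] <- data.frame(
          cell = cell, y = p[1], x = p[2], members = 1L, is_cluster = FALSE)
      }
      for (k in clumps) {
        p <- pick()
        ## a k-dot aggregate: one blob, wider than a single (its member
        ## dots overlap beyond resolution), integrating to k x unit
        probe <- render_spot(probe, p[1], p[2], sigma * 1.3 * sqrt(k),
                             k * truth$single_dot_intensity)
        spots[[length(spots) + 1L]] <- data.frame(
          cell = cell, y = p[1], x = p[2], members = k, is_cluster = TRUE)
      }
    }
    xs <- seq(0, 1, length.out = nx); ys <- seq(0, 1, length.out = ny)
    probe <- probe + background_peak * outer(ys, xs, function(y, x)
      (x + y) / 2)
    if (noise_sd > 0)
      probe <- pmax(probe + matrix(stats::rnorm(ny * nx, 0, noise_sd),
                                   ny, nx), 0)
    wga_bg_mean <- 50; wga_bg_sd <- 5
    wga <- matrix(stats::rnorm(ny * nx, wga_bg_mean, wga_bg_sd), ny, nx)
    labl <- lab > 0L & truth$wga_labeled[pmax(lab, 1L)]
    wga[labl] <- wga[labl] + wga_contrast * wga_bg_sd
    dapi <- 10 + 90 * (lab > 0L)
    spots <- if (length(spots)) do.call(rbind, spots) else
      data.frame(cell = integer(0), y = numeric(0), x = numeric(0),
                 members = integer(0), is_cluster = logical(0))
    list(probe = probe, wga = pmax(wga, 0), dapi = dapi, truth = truth,
         spots = spots)
  })
}
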