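#' ROI set
#'
#' Labelled, pairwise-disjoint connected pixel regions with per-ROI mean
#' traces and retrograde-label status.
#'
#' @param label Y x X integer label image (0 = background).
#' @param traces `n_roi x T` matrix of per-ROI pixel-mean traces.
#' @param pixel_size_um pixel size (areas are `n_px * pixel_size_um^2`).
#' @param mode provenance string (`"import"`, `"soma"`, `"skin"`).
#' @return an object of class `roi_set`: the label image plus a data frame
#'   `table` with columns id, n_px, area_um2, wga_status, wga_margin.
#' @export
roi_set <- function(label, traces, pixel_size_um = 1, mode = "import") {
  ids <- sort(unique(label[label > 0L]))
  if (length(ids) && !identical(as.integer(ids), seq_along(ids)))
    label <- relabel_consecutive(label)
  ids <- seq_len(max(0L, max(label)))
  n_px <- tabulate(label[label > 0L], nbins = length(ids))
  tab <- data.frame(id = ids, n_px = n_px,
                    area_um2 = n_px * pixel_size_um^2,
                    wga_status = rep(NA_character_, length(ids)),
                    wga_margin = rep(NA_real_, length(ids)))
  structure(list(label = label, traces = traces, table = tab,
                 pixel_size_um = pixel_size_um, mode = mode),
            class = "roi_set")
}

relabel_consecutive <- function(label) {
  ids <- sort(unique(label[label > 0L]))
  out <- label
  for (k in seq_along(ids)) out[label == ids[k]] <- k
  out
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI(s), mode %s, %d x %d field\n",
              nrow(x$table), x$mode, nrow(x$label), ncol(x$label)))
  invisible(x)
}

n_rois <- function(rois) nrow(rois$table)

#' Per-ROI pixel-mean traces from a movie
#'
#' @param label Y x X integer label image.
#' @param movie a z-projected [ca_movie()] (or a raw `T x Y x X` array).
#' @return `n_roi x T` matrix.
#' @export
roi_traces <- function(label, movie) {
  data <- if (inherits(movie, "ca_movie")) movie$data else movie
  T <- dim(data)[1]
  ids <- seq_len(max(0L, max(label)))
  tr <- matrix(NA_real_, length(ids), T)
  flat <- matrix(aperm(data, c(2, 3, 1)), ncol = T)
  for (k in ids) {
    px <- which(label == k)
    if (length(px))
      tr[k, ] <- colMeans(flat[px, , drop = FALSE], na.rm = TRUE)
  }
  tr
}

#' Detect soma ROIs (import a mask or automatic blob detection)
#'
#' In import mode a user-supplied label mask is adopted verbatim (matching
#' manual/visual soma identification). In auto mode bright disc-like blobs
#' are found on the reference image by band-pass (difference of Gaussians)
#' filtering, Otsu thresholding, watershed splitting of touching somata, and
#' a diameter filter.
#'
#' @param movie a preprocessed [ca_movie()] used for the traces.
#' @param reference Y x X image for detection (auto mode).
#' @param mask user label image (import mode).
#' @param soma_diameter_px expected soma diameter range, `c(min, max)`.
#' @param pixel_size_um pixel size for areas.
#' @return a [roi_set()] (empty, with a warning, when the mask has no
#'   labels or nothing is detected).
#' @export
detect_soma_rois <- function(movie, reference = NULL, mask = NULL,
                             soma_diameter_px = c(6, 30),
                             pixel_size_um = 1) {
  if (!is.null(mask)) {
    if (max(mask) == 0L) warning("empty mask: no ROIs")
    lab <- relabel_consecutive(mask)
    return(roi_set(lab, roi_traces(lab, movie), pixel_size_um, "import"))
  }
  if (is.null(reference)) stop("auto mode needs a reference image")
  s_small <- soma_diameter_px[1] / 4
  s_large <- soma_diameter_px[2] / 2
  img <- EBImage::as.Image(reference / max(reference))
  bp <- EBImage::gblur(img, s_small) - EBImage::gblur(img, s_large)
  bpm <- EBImage::imageData(bp)
  thr <- otsu_threshold(bpm)
  bin <- bpm > thr
  dm <- EBImage::distmap(EBImage::as.Image(bin))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  ## diameter filter
  a_min <- pi * (soma_diameter_px[1] / 2)^2 / 2
  a_max <- pi * (soma_diameter_px[2] / 2)^2 * 2
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < a_min | sizes > a_max)
  lab[lab %in% drop] <- 0L
  lab <- relabel_consecutive(lab)
  if (max(lab) == 0L) warning("no somata detected")
  roi_set(lab, roi_traces(lab, movie), pixel_size_um, "soma")
}

## standardise pixel traces (zero mean, unit norm); rows = pixels
standardize_rows <- function(m) {
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- Inf
  m / nrm
}

#' Detect contiguous regions of temporally correlated activity
#'
#' Deterministic seed-and-grow segmentation of a dF/F0 movie into contiguous
#' regions whose pixels share one temporal signal (the contract of
#' correlation-based source extraction, applied to cutaneous nerve-ending
#' branches). Seeds are active pixels (temporal SD above an Otsu threshold,
#' or the responsive complement of the preprocessing CV mask when
#' `active_mask` is given) whose mean Pearson correlation with their active
#' 8-neighbours exceeds `min_corr`; restricting the mean to active
#' neighbours keeps thin (1-3 px) branches seedable, since their border
#' pixels always abut uncorrelated background. Regions grow, from the
#' strongest seed first, by adding frontier pixels whose correlation with
#' the region's mean trace is at least `min_corr`; regions smaller than
#' `min_size_px` are discarded.
#'
#' @param dff_movie a normalised [ca_movie()] (or `T x Y x X` array).
#' @param min_corr Pearson correlation threshold (default 0.8).
#' @param min_size_px minimum region size (default 10).
#' @param max_gap growth neighbourhood radius beyond 8-connectivity
#'   (default 0: strict 8-neighbours).
#' @param pixel_size_um pixel size for areas.
#' @param active_mask optional logical Y x X mask of temporally active
#'   pixels (e.g. the negation of [nonresponsive_mask()] computed on the
#'   corrected movie, whose CV is well-defined); default: SD of the dF/F0
#'   traces thresholded by Otsu.
#' @return a [roi_set()] (possibly empty).
#' @export
detect_correlated_rois <- function(dff_movie, min_corr = 0.8,
                                   min_size_px = 10L, max_gap = 0L,
                                   pixel_size_um = 1, active_mask = NULL) {
  data <- if (inherits(dff_movie, "ca_movie")) dff_movie$data else dff_movie
  T <- dim(data)[1]; ny <- dim(data)[2]; nx <- dim(data)[3]
  flat <- matrix(aperm(data, c(2, 3, 1)), ny * nx, T)
  flat[!is.finite(flat)] <- 0
  if (is.null(active_mask)) {
    sd_map <- matrix(sqrt(rowMeans(flat^2) - rowMeans(flat)^2), ny, nx)
    sd_map[is.nan(sd_map)] <- 0
    sd_thr <- suppressWarnings(otsu_threshold(sd_map))
    active_mask <- if (is.na(sd_thr)) matrix(FALSE, ny, nx) else
      sd_map > sd_thr
  }
  stopifnot(all(dim(active_mask) == c(ny, nx)))
  z <- standardize_rows(flat)
  ## mean correlation with active in-field neighbours, via shifted inner
  ## products of the standardised traces
  corr_sum <- matrix(0, ny, nx)
  corr_n <- matrix(0, ny, nx)
  zm <- array(z, c(ny, nx, T))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- seq_len(ny); xs <- seq_len(nx)
    oy <- ys + dy; ox <- xs + dx
    keep_y <- oy >= 1 & oy <= ny; keep_x <- ox >= 1 & ox <= nx
    a <- zm[ys[keep_y], xs[keep_x], , drop = FALSE]
    b <- zm[oy[keep_y], ox[keep_x], , drop = FALSE]
    act <- active_mask[oy[keep_y], ox[keep_x]]
    cc <- rowSums(a * b, dims = 2) * act
    corr_sum[ys[keep_y], xs[keep_x]] <-
      corr_sum[ys[keep_y], xs[keep_x]] + cc
    corr_n[ys[keep_y], xs[keep_x]] <-
      corr_n[ys[keep_y], xs[keep_x]] + act
  }
  ncorr <- ifelse(corr_n >= 2, corr_sum / pmax(corr_n, 1), -Inf)
  seeds <- which(ncorr > min_corr & active_mask)
  label <- matrix(0L, ny, nx)
  if (length(seeds) == 0L)
    return(roi_set(label, matrix(numeric(0), 0, T), pixel_size_um, "skin"))
  ## strongest seed first; ties by index -> deterministic
  seeds <- seeds[order(-ncorr[seeds], seeds)]
  reach <- 1L + as.integer(max_gap)
  offs <- as.matrix(expand.grid(dy = -reach:reach, dx = -reach:reach))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  next_id <- 0L
  for (s in seeds) {
    if (label[s] != 0L) next
    region <- s
    sum_trace <- flat[s, ]
    frontier_of <- function(px) {
      y <- ((px - 1L) %% ny) + 1L
      x <- ((px - 1L) %/% ny) + 1L
      yr <- outer(y, offs[, 1], `+`); xr <- outer(x, offs[, 2], `+`)
      valid <- as.vector(yr >= 1L & yr <= ny & xr >= 1L & xr <= nx)
      unique(as.vector(yr + (xr - 1L) * ny)[valid])
    }
    repeat {
      cand <- setdiff(frontier_of(region), region)
      cand <- cand[label[cand] == 0L]
      if (length(cand) == 0L) break
      mu <- sum_trace / length(region)
      mu_c <- mu - mean(mu)
      nrm <- sqrt(sum(mu_c^2))
      if (nrm == 0) break
      cors <- as.vector(z[cand, , drop = FALSE] %*% (mu_c / nrm))
      add <- cand[cors >= min_corr]
      if (length(add) == 0L) break
      region <- c(region, add)
      sum_trace <- sum_trace + colSums(flat[add, , drop = FALSE])
    }
    if (length(region) >= min_size_px) {
      next_id <- next_id + 1L
      label[region] <- next_id
    }
  }
  ## enforce connected-component ROIs (growth with max_gap can bridge)
  if (next_id > 0L) {
    comp <- EBImage::imageData(EBImage::bwlabel(
      EBImage::as.Image(label > 0L)))
    sizes <- tabulate(comp[comp > 0L])
    keep <- which(sizes >= min_size_px)
    out <- matrix(0L, ny, nx)
    for (k in seq_along(keep)) out[comp == keep[k]] <- k
    label <- out
  }
  tr <- if (max(label) > 0L) roi_traces(label, data) else
    matrix(numeric(0), 0, T)
  roi_set(label, tr, pixel_size_um, "skin")
}

#' Classify ROIs as retrogradely labelled (WGA+) or not
#'
#' An ROI is WGA-positive iff its mean intensity in the WGA channel strictly
#' exceeds the background mean plus `k` background SDs ("exceeded five times
#' the standard deviation of the background fluorescence"). Background
#' pixels default to everything outside all ROIs after a 3-px dilation.
#'
#' @param rois a [roi_set()].
#' @param wga_image Y x X co-registered WGA channel image.
#' @param background_region optional logical Y x X mask of background
#'   pixels; default as above.
#' @param k SD multiplier (default 5).
#' @param dilate_px dilation radius excluded around ROIs when deriving the
#'   default background (default 3).
#' @return the [roi_set()] with `wga_status` (`"positive"`/`"negative"`)
#'   and `wga_margin` (mean intensity minus threshold) filled in.
#' @export
classify_wga <- function(rois, wga_image, background_region = NULL, k = 5,
                         dilate_px = 3L) {
  stopifnot(identical(dim(wga_image), dim(rois$label)))
  if (is.null(background_region)) {
    inroi <- rois$label > 0L
    if (any(inroi)) {
      brush <- EBImage::makeBrush(2L * dilate_px + 1L, "disc")
      dil <- EBImage::imageData(EBImage::dilate(EBImage::as.Image(inroi),
                                                brush)) > 0
    } else dil <- inroi
    background_region <- !dil
  }
  if (!any(background_region)) stop("empty background region")
  bg <- wga_image[background_region]
  thr <- mean(bg) + k * stats::sd(bg)
  for (i in seq_len(n_rois(rois))) {
    m <- mean(wga_image[rois$label == rois$table$id[i]])
    rois$table$wga_status[i] <- if (m > thr) "positive" else "negative"
    rois$table$wga_margin[i] <- m - thr
  }
  attr(rois$table, "wga_threshold") <- thr
  rois
}
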