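#' Rolling-ball background subtraction
#'
#' Morphological background flattening: the background is estimated as the
#' grayscale opening of the image with a disc structuring element of the
#' given radius and subtracted (white top-hat), so structures smaller than
#' the element (RNAscope dots) are preserved while smooth shading is
#' removed. Output is clamped at 0.
#'
#' @param image Y x X numeric image.
#' @param radius_um ball radius in micrometres (1 um in the standard
#'   protocol).
#' @param pixel_size_um pixel size; `radius_um / pixel_size_um` must be
#'   >= 1 px.
#' @return background-subtracted Y x X image (attribute `background` holds
#'   the estimated surface).
#' @export
rolling_ball <- function(image, radius_um, pixel_size_um, smooth = TRUE) {
  r_px <- radius_um / pixel_size_um
  if (r_px < 1) stop("rolling-ball radius must be >= 1 px")
  size <- 2L * as.integer(ceiling(r_px)) + 1L
  brush <- EBImage::makeBrush(size, "disc")
  rng <- range(image)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  img01 <- (image - rng[1]) / scale
  bg01 <- EBImage::imageData(EBImage::opening(EBImage::as.Image(img01),
                                              brush))
  ## the shading being removed is smooth by assumption; median-filtering
  ## the raw opening rejects its residual local lift under compact bright
  ## objects (which would bite into spot intensities) while tracking a
  ## smooth gradient without lag
  if (smooth)
    bg01 <- EBImage::imageData(EBImage::medianFilter(
      EBImage::as.Image(pmin(pmax(bg01, 0), 1)), 2L * as.integer(ceiling(r_px))))
  bg <- bg01 * scale + rng[1]
  out <- pmax(image - bg, 0)
  attr(out, "background") <- bg
  out
}

## Laplacian-of-Gaussian kernel (negated: positive response at bright blobs)
log_kernel <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  g <- outer((-r:r)^2, (-r:r)^2, `+`)
  k <- (g / sigma^2 - 2) * exp(-g / (2 * sigma^2))
  -(k - mean(k))
}

#' Detect RNAscope spots and flag clusters
#'
#' Scale-matched blob detection on a background-subtracted probe image:
#' Laplacian-of-Gaussian filtering at `sigma = diameter / (2 * sqrt(2))`,
#' local maxima above `min_prominence`, then segmentation of the supporting
#' connected components. Each component containing at least one maximum is
#' one spot; its integrated intensity is the sum of the component's
#' (background-subtracted) pixels, so single-dot and cluster intensities are
#' measured on the same footing and their ratio is meaningful. The
#' equivalent diameter is twice the intensity-weighted RMS radius about the
#' centroid: for an isolated Gaussian dot of nominal diameter d this equals
#' d up to tail truncation, independent of brightness, while merged dots
#' acquire extra spread from their centre offsets; a spot is flagged
#' `is_cluster` when its equivalent diameter exceeds `cluster_factor` times
#' the single-dot diameter, or when its component carries two or more
#' scale-matched intensity maxima (overlapping dots that remain individually
#' resolved).
#'
#' @param image background-subtracted Y x X probe image.
#' @param diameter_um nominal single-dot diameter (default 0.8 um).
#' @param pixel_size_um pixel size in um/px.
#' @param min_prominence absolute intensity threshold for maxima and
#'   segmentation; default `max(0.1 * max(image), 5 * sigma_noise)` with the
#'   noise scale estimated by the median absolute deviation.
#' @param cluster_factor equivalent-diameter multiple above which a spot is
#'   a cluster (default 1.5).
#' @return a `spot_list` data frame: y, x (intensity-weighted centroid),
#'   integrated, area_px, eq_diameter_um, is_cluster.
#' @export
detect_spots <- function(image, diameter_um = 0.8, pixel_size_um,
                         min_prominence = NULL, cluster_factor = 1.5) {
  d_px <- diameter_um / pixel_size_um
  sigma <- d_px / (2 * sqrt(2))
  min_prominence <- min_prominence %||%
    max(0.1 * max(image), 5 * stats::mad(image))
  ## reject sub-resolution noise blips: a real dot covers at least a
  ## quarter of the nominal disc
  min_area <- max(2L, as.integer(round(0.25 * pi * (d_px / 2)^2)))
  empty <- data.frame(y = numeric(0), x = numeric(0),
                      integrated = numeric(0), area_px = integer(0),
                      eq_diameter_um = numeric(0), is_cluster = logical(0))
  class(empty) <- c("spot_list", "data.frame")
  if (max(image) <= 0) return(empty)
  resp <- EBImage::imageData(EBImage::filter2(EBImage::as.Image(image),
                                              log_kernel(sigma)))
  ## local maxima of the LoG response over intensity-eligible pixels
  mx <- resp
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    mx <- pmax(mx, shift_matrix(resp, dy, dx))
  }
  maxima <- which(resp >= mx & image > min_prominence)
  if (length(maxima) == 0L) return(empty)
  seg <- EBImage::imageData(EBImage::bwlabel(
    EBImage::as.Image(image > min_prominence)))
  keep <- sort(unique(seg[maxima]))
  keep <- keep[keep > 0L]
  if (length(keep)) {
    sizes <- tabulate(seg[seg > 0L])
    keep <- keep[sizes[keep] >= min_area]
  }
  if (length(keep) == 0L) return(empty)
  n_max <- tabulate(seg[maxima], nbins = max(seg))
  rows <- lapply(keep, function(k) {
    px <- which(seg == k, arr.ind = TRUE)
    w <- image[seg == k]
    cy <- sum(px[, 1] * w) / sum(w)
    cx <- sum(px[, 2] * w) / sum(w)
    ## truncation-corrected RMS diameter: segmentation cuts the Gaussian
    ## tail at the threshold, shrinking the raw RMS radius by a known
    ## factor g(u) with u = log(peak / threshold)
    u <- max(log(max(w) / min_prominence), 0.2)
    g_u <- (1 - (1 + u) * exp(-u)) / (1 - exp(-u))
    rms2 <- sum(w * ((px[, 1] - cy)^2 + (px[, 2] - cx)^2)) / sum(w)
    eq_d_px <- 2 * sqrt(rms2 / g_u)
    data.frame(y = cy, x = cx,
               integrated = sum(w), area_px = nrow(px),
               eq_diameter_um = eq_d_px * pixel_size_um,
               is_cluster = eq_d_px > cluster_factor * d_px ||
                 n_max[k] >= 2L)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spot_list", "data.frame")
  out
}

#' Per-slide single-dot reference intensity
#'
#' Mean integrated intensity of the non-cluster spots of one slide (never
#' pooled across slides). At least 5 singles are required; otherwise the
#' cluster correction is impossible and an error is raised.
#'
#' @param spots a `spot_list` from [detect_spots()].
#' @param min_singles minimum number of single dots (default 5).
#' @return the reference intensity (scalar).
#' @export
single_dot_intensity <- function(spots, min_singles = 5L) {
  singles <- spots$integrated[!spots$is_cluster]
  if (length(singles) < min_singles)
    stop("only ", length(singles), " single dots on this slide; ",
         "need >= ", min_singles, " for cluster correction")
  mean(singles)
}

#' Convert a cluster intensity to an equivalent dot count
#'
#' The theoretical number of dots in a cluster is the ratio of the cluster's
#' integrated intensity to the slide's average single-dot intensity, rounded
#' to the nearest integer with a minimum of 1.
#'
#' @param cluster_intensity integrated intensity (vectorised).
#' @param ref_intensity single-dot reference intensity (> 0).
#' @return integer equivalent dot count(s).
#' @export
cluster_to_dots <- function(cluster_intensity, ref_intensity) {
  if (any(cluster_intensity <= 0) || ref_intensity <= 0)
    stop("intensities must be positive")
  pmax(1L, as.integer(round(cluster_intensity / ref_intensity)))
}

#' Count corrected RNAscope dots per cell
#'
#' Assigns each spot to the cell whose mask contains its centroid pixel
#' (rounded to the nearest pixel centre); spots outside all masks go to a
#' background bin. Per cell, `dots_total` = singles + the sum of cluster
#' equivalent counts, and the cell is positive iff `dots_total >=
#' pos_threshold`.
#'
#' @param cell_masks Y x X integer label image (0 = background).
#' @param spots a `spot_list`.
#' @param ref_intensity single-dot reference from [single_dot_intensity()];
#'   `NA` leaves clusters uncorrected (counted as 1) with a flag.
#' @param pos_threshold positivity threshold in dots (default 5).
#' @param pixel_size_um pixel size for cell areas.
#' @return data frame of class `cell_dot_record`: cell_id, area_um2,
#'   n_single_dots, n_cluster_equivalents, dots_total, positive,
#'   wga_status (NA here; see [classify_wga()]), corrected. Attribute
#'   `background_spots` reports spots outside all masks.
#' @export
count_dots_per_cell <- function(cell_masks, spots, ref_intensity,
                                pos_threshold = 5L, pixel_size_um = 1) {
  n_cells <- max(cell_masks)
  ny <- nrow(cell_masks); nx <- ncol(cell_masks)
  corrected <- is.finite(ref_intensity)
  cell_of <- if (nrow(spots)) {
    iy <- pmin(pmax(as.integer(round(spots$y)), 1L), ny)
    ix <- pmin(pmax(as.integer(round(spots$x)), 1L), nx)
    cell_masks[cbind(iy, ix)]
  } else integer(0)
  equiv <- if (nrow(spots)) {
    ifelse(spots$is_cluster,
           if (corrected) cluster_to_dots(spots$integrated, ref_intensity)
           else 1L,
           1L)
  } else integer(0)
  rec <- do.call(rbind, lapply(seq_len(n_cells), function(cid) {
    in_cell <- which(cell_of == cid)
    singles <- sum(!spots$is_cluster[in_cell])
    clust_eq <- sum(equiv[in_cell][spots$is_cluster[in_cell]])
    total <- singles + clust_eq
    data.frame(cell_id = cid,
               area_um2 = sum(cell_masks == cid) * pixel_size_um^2,
               n_single_dots = singles, n_cluster_equivalents = clust_eq,
               dots_total = total, positive = total >= pos_threshold,
               wga_status = NA_character_, corrected = corrected)
  }))
  attr(rec, "background_spots") <- sum(cell_of == 0L)
  class(rec) <- c("cell_dot_record", "data.frame")
  rec
}

#' Per-animal fraction of RNAscope-positive cells
#'
#' @param records a `cell_dot_record` data frame (rows may pool animals).
#' @param animal factor per cell (one level per animal/section).
#' @param group optional higher-level factor per cell (e.g. side x WGA);
#'   summaries are computed within each group over its animals.
#' @return list: `per_animal` (data frame group, animal, n, n_positive,
#'   fraction) and `summary` (group, mean, sem, n_animals). Empty groups
#'   are flagged.
#' @export
fraction_positive <- function(records, animal, group = NULL) {
  animal <- factor(rep_len(animal, nrow(records)))
  group <- if (is.null(group)) factor(rep("all", nrow(records))) else
    factor(rep_len(group, nrow(records)))
  per <- do.call(rbind, lapply(split(seq_len(nrow(records)),
                                     list(group, animal), drop = TRUE),
                               function(i) {
    data.frame(group = as.character(group[i][1]),
               animal = as.character(animal[i][1]),
               n = length(i), n_positive = sum(records$positive[i]),
               fraction = mean(records$positive[i]))
  }))
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, per$group), function(d) {
    data.frame(group = d$group[1], mean = mean(d$fraction),
               sem = stats::sd(d$fraction) / sqrt(nrow(d)),
               n_animals = nrow(d))
  }))
  rownames(summ) <- NULL
  list(per_animal = per, summary = summ)
}

#' Full RNAscope quantification of one slide
#'
#' Rolling-ball background subtraction, spot detection, per-slide single-dot
#' reference, cluster correction, per-cell counting and positivity, and
#' optional WGA classification of the cell masks.
#'
#' @param probe Y x X probe-channel image.
#' @param cell_masks Y x X label image of manually segmented cells.
#' @param pixel_size_um pixel size in um/px.
#' @param wga optional co-registered WGA channel image.
#' @param radius_um rolling-ball radius (default 1).
#' @param spot_um spot-detection diameter (default 0.8).
#' @param pos_threshold positivity threshold (default 5 dots).
#' @param min_prominence see [detect_spots()].
#' @return list: `records` (`cell_dot_record`), `spots`, `ref_intensity`,
#'   `background` subtracted image.
#' @export
quantify_rnascope <- function(probe, cell_masks, pixel_size_um, wga = NULL,
                              radius_um = 1, spot_um = 0.8,
                              pos_threshold = 5L, min_prominence = NULL) {
  sub <- rolling_ball(probe, radius_um, pixel_size_um)
  spots <- detect_spots(sub, spot_um, pixel_size_um, min_prominence)
  ref <- tryCatch(single_dot_intensity(spots), error = function(e) {
    warning(conditionMessage(e), "; cells reported uncorrected")
    NA_real_
  })
  rec <- count_dots_per_cell(cell_masks, spots, ref, pos_threshold,
                             pixel_size_um)
  if (!is.null(wga)) {
    rs <- roi_set(cell_masks, matrix(0, max(cell_masks), 1), pixel_size_um)
    rs <- classify_wga(rs, wga)
    rec$wga_status <- rs$table$wga_status[match(rec$cell_id, rs$table$id)]
  }
  list(records = rec, spots = spots, ref_intensity = ref, corrected = sub)
}
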