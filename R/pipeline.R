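#' Analyse a DRG soma movie end to end
#'
#' Preprocess (z-average, register, background-correct, normalise), adopt
#' or detect soma ROIs, classify WGA status, call responses under the dual
#' criterion, apply the high-K+ exclusion and the K+ normalisation, and
#' derive co-expression classes.
#'
#' @param movie a raw [ca_movie()].
#' @param protocol a [stim_protocol()].
#' @param wga_image optional co-registered WGA channel.
#' @param roi_masks optional label image of visually identified somata
#'   (import mode); otherwise automatic blob detection is used.
#' @param peak_mult responder peak criterion multiplier (default 5).
#' @param background fit/subtract the polynomial background (default TRUE).
#' @param ... passed to [preprocess_movie()].
#' @return list: `rois`, `table` (K-excluded, K-normalised
#'   [response_table()]), `classes`, `pre` (preprocessing products).
#' @export
analyze_drg_movie <- function(movie, protocol, wga_image = NULL,
                              roi_masks = NULL, peak_mult = 5,
                              background = TRUE, ...) {
  pre <- preprocess_movie(movie, protocol, background = background, ...)
  rois <- detect_soma_rois(pre$dff, reference = pre$reference,
                           mask = roi_masks,
                           pixel_size_um = movie$pixel_size_um)
  if (!is.null(wga_image)) rois <- classify_wga(rois, wga_image)
  tab <- response_table(rois, protocol, movie$frame_period_s, peak_mult)
  tab <- apply_k_exclusion(tab)
  tab <- normalize_to_k(tab)
  cls <- coexpression_classes(tab)
  list(rois = rois, table = tab, classes = cls, pre = pre)
}

#' Analyse a skin-nerve movie end to end
#'
#' Preprocess, detect correlated-activity ROIs, call responses, and report
#' responsive-area fractions. The high-K+ exclusion and K+ normalisation
#' are not applied: skin endings do not always show robust K+ responses.
#'
#' @param movie a raw [ca_movie()].
#' @param protocol a [stim_protocol()].
#' @param min_corr,min_size_px see [detect_correlated_rois()].
#' @param peak_mult responder criterion multiplier (default 5).
#' @param ... passed to [preprocess_movie()].
#' @return list: `rois`, `table`, `areas` (from [responsive_area()]),
#'   `pre`.
#' @export
analyze_skin_movie <- function(movie, protocol, min_corr = 0.8,
                               min_size_px = 10L, peak_mult = 5, ...) {
  pre <- preprocess_movie(movie, protocol, ...)
  rois <- detect_correlated_rois(pre$dff, min_corr, min_size_px,
                                 pixel_size_um = movie$pixel_size_um)
  if (n_rois(rois) == 0L)
    return(list(rois = rois, table = NULL, areas = NULL, pre = pre))
  tab <- response_table(rois, protocol, movie$frame_period_s, peak_mult)
  areas <- responsive_area(rois, tab)
  list(rois = rois, table = tab, areas = areas, pre = pre)
}

#' Simulate and analyse an ipsi/contra cohort of DRG movies
#'
#' Generates one small soma movie per virtual animal and side with a
#' programmed M3-responder fraction (enriched ipsilaterally), runs the full
#' DRG pipeline on each using the ground-truth soma masks (import mode,
#' mirroring visual identification), and estimates the ipsi/contra ratio of
#' M3-responder fractions with a percentile-bootstrap CI over cells.
#'
#' @param n_animals virtual animals per side (default 6).
#' @param cells_per_animal somata per movie (default 32; a desk-scale
#'   stand-in for the hundreds of neurons scored per ganglion in practice).
#' @param frac_ipsi,frac_contra programmed M3-responder fractions
#'   (defaults 0.5 and 0.25: a 2.0x enrichment).
#' @param seed cohort RNG seed.
#' @param shape per-animal movie dimensions `c(T, Y, X)`.
#' @param amplitude_sd transient amplitude in noise-SD units (default 10).
#' @param n_boot bootstrap resamples for the ratio CI (default 10000).
#' @return list: `comparison` ([bootstrap_ratio_ci()] result on the
#'   per-cell responder indicators, cell-level resampling), `per_animal`
#'   (data frame side, animal, n, fraction), `truth_ratio` (programmed
#'   enrichment).
#' @export
simulate_cohort <- function(n_animals = 6L, cells_per_animal = 32L,
                            frac_ipsi = 0.5, frac_contra = 0.25,
                            seed = 1L, shape = c(64L, 80L, 80L),
                            amplitude_sd = 10, n_boot = 10000L) {
  protocol <- default_protocol(baseline_frames = 12L, stim_frames = 5L,
                               gap_frames = 8L)
  stopifnot(protocol_end(protocol) <= shape[1])
  per_animal <- list()
  resp <- list(ipsi = logical(0), contra = logical(0))
  for (side in c("ipsi", "contra")) {
    frac <- if (side == "ipsi") frac_ipsi else frac_contra
    for (a in seq_len(n_animals)) {
      s <- seed * 10000L + a * 10L + (side == "ipsi")
      sim <- with_seed(s, {
        n_m3 <- stats::rbinom(1, cells_per_animal, frac)
        expressed <- c(replicate(n_m3, "M3", simplify = FALSE),
                       replicate(cells_per_animal - n_m3, character(0),
                                 simplify = FALSE))
        expressed <- sample(expressed)
        pos <- grid_positions(cells_per_animal, shape[2], shape[3],
                              radius = 4)
        truth <- calcium_truth(pos, cell_radius_px = 4,
                               expressed = expressed,
                               amplitude_sd = amplitude_sd,
                               k_responsive = TRUE)
        gen_soma_movie(truth, protocol, shape, seed = s + 1L)
      })
      res <- analyze_drg_movie(sim$movie, protocol,
                               roi_masks = sim$cell_label,
                               background = FALSE, register = FALSE)
      m3 <- res$table[res$table$stimulus == "M3" & !res$table$excluded, ]
      resp[[side]] <- c(resp[[side]], m3$is_responder)
      per_animal[[length(per_animal) + 1L]] <-
        data.frame(side = side, animal = a, n = nrow(m3),
                   fraction = mean(m3$is_responder))
    }
  }
  cmp <- bootstrap_ratio_ci(as.numeric(resp$ipsi), as.numeric(resp$contra),
                            n_boot = n_boot, seed = seed)
  list(comparison = cmp, per_animal = do.call(rbind, per_animal),
       truth_ratio = frac_ipsi / frac_contra)
}

## non-overlapping grid of soma centres inside a ny x nx field
grid_positions <- function(n, ny, nx, radius) {
  spacing <- 2 * radius + 3
  ncol_g <- max(1L, (nx - 2 * radius) %/% spacing)
  pos <- t(vapply(seq_len(n) - 1L, function(i) {
    c(radius + 2 + (i %/% ncol_g) * spacing,
      radius + 2 + (i %% ncol_g) * spacing)
  }, numeric(2)))
  if (max(pos[, 1]) + radius >= ny || max(pos[, 2]) + radius >= nx)
    stop("too many cells for the field")
  pos
}
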