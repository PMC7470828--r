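#' Dual-criterion responder call for one trace and one stimulus
#'
#' A trace responds to a stimulus iff both criteria hold: (1) the peak of
#' the baseline-subtracted dF/F0 during the stimulation window strictly
#' exceeds `peak_mult` times the SD of the pre-stimulus window, and (2) the
#' peak of the first derivative dF/dt during stimulation strictly exceeds
#' the SD of dF/dt over the pre-stimulus window. A degenerate pre-stimulus
#' SD of 0 is replaced by a small guard and flagged.
#'
#' @param trace numeric dF/F0 (or F/F0) trace per frame.
#' @param stim_window integer frames of the stimulation window.
#' @param pre_window integer frames of the pre-stimulus baseline window;
#'   must precede the stimulus; both windows >= 3 frames.
#' @param frame_period_s frame period in seconds (scales dF/dt; cancels
#'   between the two sides of criterion 2 but is applied for reportable
#'   units).
#' @param peak_mult SD multiplier of criterion 1 (default 5).
#' @param deriv_mult SD multiplier of criterion 2 (default 1).
#' @param baseline_subtract subtract the pre-window mean before the peak
#'   test (default `TRUE`); set `FALSE` to test the raw F/F0 peak.
#' @return list: `is_responder`, `peak_dff` (peak of the baseline-
#'   subtracted trace over the stimulus window), `peak_margin`,
#'   `deriv_margin` (criterion excesses in SD units), `degenerate`.
#' @export
call_response <- function(trace, stim_window, pre_window,
                          frame_period_s = 4, peak_mult = 5,
                          deriv_mult = 1, baseline_subtract = TRUE) {
  if (length(stim_window) < 3L || length(pre_window) < 3L)
    stop("stimulus and pre-stimulus windows must each span >= 3 frames")
  if (max(pre_window) >= min(stim_window))
    stop("pre-stimulus window must precede the stimulation window")
  pre <- trace[pre_window]
  stim <- trace[stim_window]
  degenerate <- FALSE
  eps <- 1e-6 * max(abs(trace), 1e-12)
  base <- mean(pre)
  sd_pre <- stats::sd(pre)
  if (sd_pre == 0) { sd_pre <- eps; degenerate <- TRUE }
  peak_dff <- max(stim - base)
  peak_stat <- if (baseline_subtract) peak_dff else max(stim)
  crit1 <- peak_stat > peak_mult * sd_pre
  ## first derivative: include the rise into the first stimulus frame
  didx <- (min(stim_window) - 1L):(max(stim_window) - 1L)
  didx <- didx[didx >= 1L & didx < length(trace)]
  dstim <- (trace[didx + 1L] - trace[didx]) / frame_period_s
  dpre <- diff(pre) / frame_period_s
  sd_dpre <- stats::sd(dpre)
  if (sd_dpre == 0) { sd_dpre <- eps; degenerate <- TRUE }
  crit2 <- max(dstim) > deriv_mult * sd_dpre
  list(is_responder = crit1 && crit2, peak_dff = peak_dff,
       peak_margin = peak_stat / sd_pre - peak_mult,
       deriv_margin = max(dstim) / sd_dpre - deriv_mult,
       degenerate = degenerate)
}

#' Build the per-ROI, per-stimulus response table
#'
#' Applies [call_response()] to every ROI trace and every protocol window.
#' The per-stimulus baseline window is the stretch between the previous
#' window's end (plus the recovery gap) and the current onset, truncated to
#' the protocol's `pre_frames`.
#'
#' @param traces `n_roi x T` matrix (dF/F0), or a [roi_set()].
#' @param protocol a [stim_protocol()].
#' @param frame_period_s frame period in seconds.
#' @param peak_mult,deriv_mult,baseline_subtract see [call_response()].
#' @return a `response_table`: data frame with one row per ROI x stimulus
#'   (columns roi, stimulus, is_responder, peak_dff, peak_margin,
#'   deriv_margin, degenerate) plus per-ROI columns added by the downstream
#'   steps.
#' @export
response_table <- function(traces, protocol, frame_period_s = 4,
                           peak_mult = 5, deriv_mult = 1,
                           baseline_subtract = TRUE) {
  if (inherits(traces, "roi_set")) traces <- traces$traces
  n <- nrow(traces)
  rows <- vector("list", n * nrow(protocol))
  r <- 0L
  for (i in seq_len(nrow(protocol))) {
    sw <- stim_window_frames(protocol, i)
    pw <- pre_window_frames(protocol, i)
    for (j in seq_len(n)) {
      cr <- call_response(traces[j, ], sw, pw, frame_period_s, peak_mult,
                          deriv_mult, baseline_subtract)
      r <- r + 1L
      rows[[r]] <- data.frame(roi = j, stimulus = protocol$label[i],
                              is_responder = cr$is_responder,
                              peak_dff = cr$peak_dff,
                              peak_margin = cr$peak_margin,
                              deriv_margin = cr$deriv_margin,
                              degenerate = cr$degenerate)
    }
  }
  tab <- do.call(rbind, rows)
  tab$excluded <- FALSE
  tab$peak_dff_norm <- NA_real_
  class(tab) <- c("response_table", "data.frame")
  attr(tab, "k_applied") <- FALSE
  tab
}

#' @export
print.response_table <- function(x, ...) {
  n <- length(unique(x$roi))
  cat(sprintf("<response_table> %d ROI(s) x %d stimuli; K+ exclusion %s\n",
              n, length(unique(x$stimulus)),
              if (isTRUE(attr(x, "k_applied"))) "applied" else "not applied"))
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("...", nrow(x) - 12, "more rows\n")
  invisible(x)
}

#' Exclude ROIs that do not respond to the high-K+ stimulus
#'
#' Cells that did not respond to the depolarising high-K+ window are not
#' excitable under the assay's criterion and are removed from all further
#' analysis: every row of such an ROI is flagged `excluded`.
#'
#' @param table a [response_table()].
#' @return the table with `excluded` set; attribute `k_applied` is `TRUE`.
#' @export
apply_k_exclusion <- function(table) {
  if (!"K" %in% table$stimulus)
    stop("no high-K+ stimulus in the table")
  k_ok <- table$roi[table$stimulus == "K" & table$is_responder]
  table$excluded <- !(table$roi %in% k_ok)
  attr(table, "k_applied") <- TRUE
  table
}

#' Normalise peak amplitudes to the high-K+ response
#'
#' `peak_dff_norm = peak_dff(stimulus) / peak_dff(K)` per ROI, defined only
#' for non-excluded ROIs (apply [apply_k_exclusion()] first).
#'
#' @param table a K-excluded [response_table()].
#' @return the table with `peak_dff_norm` filled for non-excluded rows.
#' @export
normalize_to_k <- function(table) {
  if (!isTRUE(attr(table, "k_applied")))
    stop("apply the high-K+ exclusion before normalising")
  kpk <- table[table$stimulus == "K", c("roi", "peak_dff")]
  kmap <- stats::setNames(kpk$peak_dff, kpk$roi)
  live <- !table$excluded
  if (any(kmap[as.character(table$roi[live])] <= 0))
    stop("non-excluded ROI with non-positive K+ peak: inconsistent table")
  table$peak_dff_norm[live] <-
    table$peak_dff[live] / kmap[as.character(table$roi[live])]
  table
}

#' Functional co-expression class per ROI
#'
#' The class of an ROI is the set of agonists (among M3, A1, V1) it
#' responds to; with three channels there are 8 classes including the empty
#' set. Excluded ROIs get `NA`.
#'
#' @param table a [response_table()] (K+ exclusion applied for DRG mode).
#' @param group optional factor per ROI (e.g. side x WGA status) for class
#'   frequency tables.
#' @return list: `class` (named character per ROI, e.g. `"M3+V1"`, `""`
#'   for no responses) and `frequencies` (per-group class proportions when
#'   `group` is given, otherwise overall).
#' @export
coexpression_classes <- function(table, group = NULL) {
  rois <- sort(unique(table$roi))
  cls <- vapply(rois, function(r) {
    rows <- table[table$roi == r & table$stimulus %in% c("M3", "A1", "V1"), ]
    if (any(rows$excluded)) return(NA_character_)
    paste(c("M3", "A1", "V1")[c("M3", "A1", "V1") %in%
                                rows$stimulus[rows$is_responder]],
          collapse = "+")
  }, character(1))
  names(cls) <- rois
  all_classes <- c("", "M3", "A1", "V1", "M3+A1", "M3+V1", "A1+V1",
                   "M3+A1+V1")
  freq_of <- function(v) {
    v <- v[!is.na(v)]
    tab <- table(factor(v, levels = all_classes))
    if (length(v)) as.numeric(tab) / length(v) else rep(NA_real_, 8)
  }
  if (is.null(group)) {
    freqs <- stats::setNames(freq_of(cls), all_classes)
  } else {
    group <- as_group_factor(group, length(rois))
    freqs <- t(vapply(split(cls, group), freq_of, numeric(8)))
    colnames(freqs) <- all_classes
  }
  list(class = cls, frequencies = freqs)
}

#' Fraction of responding ROIs per stimulus and group
#'
#' `responders / non-excluded` within each group; per-animal values are the
#' inputs to the ANOVA stage.
#'
#' @param table a [response_table()].
#' @param group factor per ROI (e.g. animal, or side x WGA); default one
#'   group.
#' @return data frame with columns group, stimulus, n, n_responders,
#'   fraction. Empty groups yield `NA` fractions with a flag column.
#' @export
responder_fraction <- function(table, group = NULL) {
  rois <- sort(unique(table$roi))
  group <- if (is.null(group)) factor(rep("all", length(rois))) else
    as_group_factor(group, length(rois))
  out <- list()
  for (g in levels(group)) {
    g_rois <- rois[group == g]
    for (s in unique(table$stimulus)) {
      rows <- table[table$roi %in% g_rois & table$stimulus == s &
                      !table$excluded, ]
      n <- nrow(rows)
      out[[length(out) + 1L]] <- data.frame(
        group = g, stimulus = s, n = n,
        n_responders = sum(rows$is_responder),
        fraction = if (n > 0) sum(rows$is_responder) / n else NA_real_,
        empty = n == 0)
    }
  }
  do.call(rbind, out)
}

#' Responsive area fractions (skin mode)
#'
#' Total area of ROIs responding to each agonist (and to each exact
#' co-expression class), normalised to the total imaged area. The high-K+
#' exclusion is not applied in skin mode: nerve endings do not always show
#' robust K+ responses even when they respond to agonists.
#'
#' @param rois a [roi_set()] in skin mode.
#' @param table the matching [response_table()].
#' @param imaged_area_px total imaged area in pixels (defaults to the full
#'   label-image field).
#' @return list: `per_stimulus` (data frame stimulus, area_px, fraction)
#'   and `per_class` (data frame class, area_px, fraction over exact
#'   classes of the agonist stimuli).
#' @export
responsive_area <- function(rois, table, imaged_area_px = NULL) {
  imaged_area_px <- imaged_area_px %||% length(rois$label)
  areas <- stats::setNames(rois$table$n_px, rois$table$id)
  stims <- intersect(c("M3", "A1", "V1", "K"), unique(table$stimulus))
  per_stim <- do.call(rbind, lapply(stims, function(s) {
    resp <- table$roi[table$stimulus == s & table$is_responder]
    a <- sum(areas[as.character(resp)])
    data.frame(stimulus = s, area_px = a, fraction = a / imaged_area_px)
  }))
  cls <- coexpression_classes(table)$class
  per_class <- do.call(rbind, lapply(unique(cls[!is.na(cls)]), function(cl) {
    r <- names(cls)[!is.na(cls) & cls == cl]
    a <- sum(areas[r])
    data.frame(class = cl, area_px = a, fraction = a / imaged_area_px)
  }))
  list(per_stimulus = per_stim, per_class = per_class)
}
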