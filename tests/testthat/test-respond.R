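test_that("dual responder criterion behaves at the programmed extremes", {
  T <- 70; stim <- 31:36; pre <- 21:30
  # step of 10 sigma at onset -> responder, peak within 10% of 10 sigma
  set.seed(5)
  hits <- 0; peaks <- numeric(200)
  for (i in 1:200) {
    trc <- step_trace(T, 31, amp_sd = 10, noise_sd = 1)
    cr <- call_response(trc, stim, pre)
    hits <- hits + cr$is_responder
    peaks[i] <- cr$peak_dff
  }
  expect_gte(hits / 200, 0.95)
  expect_lt(abs(mean(peaks) - 10) / 10, 0.10)
  # slow ramp whose per-frame increment stays below the pre-stimulus dF/dt
  # SD: criterion 2 rejects even though the peak criterion passes
  wiggle <- 0.5 * (-1)^(1:30)          # baseline alternation: sd(pre) ~ 0.5,
  ramp <- 0.6 * (1:40)                 # sd(diff(pre)) ~ 1.05 > slope 0.6
  cr_ramp <- call_response(c(wiggle, ramp), stim, pre)
  expect_false(cr_ramp$is_responder)
  expect_gt(cr_ramp$peak_margin, 0)   # peak criterion alone would pass
  # degenerate zero-SD baseline flagged
  flatstep <- c(rep(1, 30), rep(2, 40))
  cr_flat <- call_response(flatstep, stim, pre)
  expect_true(cr_flat$degenerate)
  # window preconditions
  expect_error(call_response(rnorm(70), 31:36, 29:31), "precede")
  expect_error(call_response(rnorm(70), 31:32, 21:30), ">= 3 frames")
})

test_that("null traces stay below a 5% false-positive rate", {
  set.seed(11)
  fp <- 0
  for (i in 1:1000) {
    trc <- rnorm(70)
    fp <- fp + call_response(trc, 31:36, 21:30)$is_responder
  }
  expect_lte(fp / 1000, 0.05)
})

test_that("raising either criterion multiplier is monotone", {
  set.seed(19)
  for (i in 1:50) {
    trc <- step_trace(70, 31, amp_sd = runif(1, 0, 8))
    r5 <- call_response(trc, 31:36, 21:30, peak_mult = 5)
    r6 <- call_response(trc, 31:36, 21:30, peak_mult = 6)
    expect_true(r5$is_responder || !r6$is_responder)
    d1 <- call_response(trc, 31:36, 21:30, deriv_mult = 1)
    d2 <- call_response(trc, 31:36, 21:30, deriv_mult = 2)
    expect_true(d1$is_responder || !d2$is_responder)
  }
})

test_that("K+ exclusion removes non-excitable ROIs everywhere downstream", {
  p <- test_protocol()
  n <- 10
  k_ok <- rep(c(TRUE, FALSE), c(7, 3))
  tr <- uniform_truth(n, channels = "M3", k_responsive = k_ok)
  sim <- gen_soma_movie(tr, p, c(70, 64, 64), seed = 23)
  pre <- preprocess_movie(sim$movie, p, register = FALSE,
                          background = FALSE)
  tab <- response_table(roi_traces(sim$cell_label, pre$dff), p)
  tab <- apply_k_exclusion(tab)
  # concordance with programmed excitability at 10 x SD contrast
  excl <- vapply(1:10, function(r) any(tab$excluded[tab$roi == r]),
                 logical(1))
  expect_identical(excl, !k_ok)
  # excluded ROIs appear in no downstream summary
  frac <- responder_fraction(tab)
  expect_equal(unique(frac$n), 7)
  cls <- coexpression_classes(tab)
  expect_true(all(is.na(cls$class[!k_ok])))
  tab <- normalize_to_k(tab)
  expect_true(all(is.na(tab$peak_dff_norm[tab$excluded])))
  expect_true(all(is.finite(tab$peak_dff_norm[!tab$excluded])))
  # all-responsive table passes through unchanged
  tr2 <- uniform_truth(4, channels = "M3")
  sim2 <- gen_soma_movie(tr2, p, c(70, 64, 64), seed = 24)
  pre2 <- preprocess_movie(sim2$movie, p, register = FALSE,
                           background = FALSE)
  tab2 <- apply_k_exclusion(
    response_table(roi_traces(sim2$cell_label, pre2$dff), p))
  expect_false(any(tab2$excluded))
})

test_that("K+ normalisation is the exact peak ratio", {
  p <- test_protocol()
  tab <- data.frame(roi = rep(1:2, each = 4),
                    stimulus = rep(c("M3", "A1", "V1", "K"), 2),
                    is_responder = TRUE,
                    peak_dff = c(2, 1, 0.5, 2, 0.5, 0.2, 1, 2),
                    peak_margin = 1, deriv_margin = 1, degenerate = FALSE)
  tab$excluded <- FALSE; tab$peak_dff_norm <- NA_real_
  class(tab) <- c("response_table", "data.frame")
  attr(tab, "k_applied") <- FALSE
  expect_error(normalize_to_k(tab), "exclusion")
  attr(tab, "k_applied") <- TRUE
  out <- normalize_to_k(tab)
  # peak M3 = peak K -> 1; 0.5 / 2 -> 0.25; brute-force ratio for the rest
  expect_equal(out$peak_dff_norm[out$roi == 1],
               c(2, 1, 0.5, 2) / 2)
  expect_equal(out$peak_dff_norm[out$roi == 2 & out$stimulus == "M3"], 0.25)
  # non-positive K peak on a live ROI is an inconsistency
  bad <- tab; bad$peak_dff[bad$roi == 2 & bad$stimulus == "K"] <- 0
  expect_error(normalize_to_k(bad), "inconsistent")
})

test_that("co-expression classes match programmed channel mixtures", {
  p <- test_protocol()
  mix <- list("M3", c("M3", "V1"), c("M3", "A1", "V1"), character(0))
  tr <- calcium_truth(test_positions(8, 96, 96), 4,
                      expressed = rep(mix, 2))
  sim <- gen_soma_movie(tr, p, c(70, 96, 96), seed = 31)
  pre <- preprocess_movie(sim$movie, p, register = FALSE,
                          background = FALSE)
  tab <- apply_k_exclusion(
    response_table(roi_traces(sim$cell_label, pre$dff), p))
  cls <- coexpression_classes(tab)
  expect_identical(unname(cls$class),
                   rep(c("M3", "M3+V1", "M3+A1+V1", ""), 2))
  expect_equal(sum(cls$frequencies), 1)
  # per-group frequencies also sum to 1
  cls2 <- coexpression_classes(tab, group = rep(c("a", "b"), 4))
  expect_equal(unname(rowSums(cls2$frequencies)), c(1, 1))
})

test_that("responder fractions and responsive areas are exact ratios", {
  p <- test_protocol()
  # 5 of 20 responders -> 0.25 (constructed table)
  tab <- data.frame(roi = rep(1:20, each = 1), stimulus = "M3",
                    is_responder = rep(c(TRUE, FALSE), c(5, 15)),
                    peak_dff = 1, peak_margin = 0, deriv_margin = 0,
                    degenerate = FALSE, excluded = FALSE,
                    peak_dff_norm = NA_real_)
  class(tab) <- c("response_table", "data.frame")
  fr <- responder_fraction(tab)
  expect_equal(fr$fraction, 0.25)
  # empty group flagged
  fr2 <- responder_fraction(tab, group = factor(rep("a", 20),
                                                levels = c("a", "b")))
  expect_true(fr2$empty[fr2$group == "b"])
  expect_true(is.na(fr2$fraction[fr2$group == "b"]))
  # one 500-px ROI responding in a 50,000-px field -> fraction 0.01
  lab <- matrix(0L, 250, 200)
  lab[1:25, 1:20] <- 1L
  rs <- roi_set(lab, matrix(0, 1, 10), mode = "skin")
  tab1 <- tab[1, ]; tab1$roi <- 1L
  class(tab1) <- c("response_table", "data.frame")
  ra <- responsive_area(rs, tab1)
  expect_equal(ra$per_stimulus$fraction[ra$per_stimulus$stimulus == "M3"],
               0.01)
  # no responders -> 0
  tab1$is_responder <- FALSE
  expect_equal(responsive_area(rs, tab1)$per_stimulus$fraction, 0)
})
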