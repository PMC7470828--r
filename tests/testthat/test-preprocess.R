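test_that("z-projection and reference match brute-force means", {
  set.seed(10)
  data <- array(runif(6 * 3 * 8 * 9), c(6, 3, 8, 9))
  m <- ca_movie(data)
  zp <- z_project(m)
  # oracle: naive per-pixel loop
  for (t in c(1, 4)) for (y in c(2, 7)) for (x in c(3, 9))
    expect_equal(zp$data[t, y, x], mean(data[t, , y, x]), tolerance = 1e-12)
  # z-planes identical -> output equals any single plane
  d2 <- array(rep(data[, 1, , ], 3), c(6, 8, 9, 3))
  m2 <- ca_movie(aperm(d2, c(1, 4, 2, 3)))
  expect_equal(z_project(m2)$data, data[, 1, , ] * 1, tolerance = 1e-12)
  # projecting a projected movie is the identity (flag) or an error
  expect_identical(z_project(zp), zp)
  expect_error(z_project(zp, allow_projected = FALSE), "no Z axis")

  ref <- make_reference(zp, 4)
  for (y in c(1, 8)) for (x in c(2, 5))
    expect_equal(ref[y, x], mean(zp$data[1:4, y, x]), tolerance = 1e-12)
  # frames valued t at a pixel -> mean 5.5 over the first 10
  tv <- array(rep(1:10, 4), c(10, 2, 2))
  expect_equal(make_reference(ca_movie(tv), 10)[1, 1], 5.5)
  # reference must not reach into the first stimulus
  expect_error(make_reference(zp, 4, stim_protocol("M3", 3, 8)), "stimulus")
})

test_that("registration recovers programmed integer shifts exactly", {
  p <- test_protocol()
  T <- 70
  set.seed(33)
  drift <- cbind(c(rep(0L, 10), sample(-5:5, T - 10, TRUE)),
                 c(rep(0L, 10), sample(-5:5, T - 10, TRUE)))
  tr <- uniform_truth(6, drift_path = drift, noise_sd = 2,
                      resting_contrast = 20)  # structural SNR 10
  sim <- gen_soma_movie(tr, p, c(T, 64, 64), seed = 8)
  reg <- register_translation(sim$movie, make_reference(sim$movie, 10))
  expect_identical(unname(reg$shifts), unname(drift))
  # registering the registered movie changes nothing (idempotence)
  reg2 <- register_translation(reg$movie, make_reference(reg$movie, 10))
  expect_true(all(abs(reg2$shifts) < 0.5))
  # zero-drift movie -> all shifts zero
  tr0 <- uniform_truth(6)
  sim0 <- gen_soma_movie(tr0, p, c(T, 64, 64), seed = 8)
  reg0 <- register_translation(sim0$movie, make_reference(sim0$movie, 10))
  expect_true(all(reg0$shifts == 0L))
  # degenerate constant frames -> zero shift with warning
  flat <- ca_movie(array(5, c(4, 8, 8)))
  expect_warning(rf <- register_translation(flat, matrix(5, 8, 8)),
                 "constant")
  expect_true(all(rf$shifts == 0L))
})

test_that("temporal CV map matches brute force and is scale-invariant", {
  set.seed(4)
  data <- array(runif(20 * 6 * 7, 1, 2), c(20, 6, 7))
  m <- ca_movie(data)
  cv <- temporal_cv_map(m)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  for (y in c(1, 6)) for (x in c(2, 7))
    expect_equal(cv[y, x], pop_sd(data[, y, x]) / mean(data[, y, x]),
                 tolerance = 1e-10)
  # pixel alternating 1,3: population SD 1, mean 2 -> CV 1/2
  alt <- ca_movie(array(rep(c(1, 3), each = 1, times = 10), c(20, 1, 1)))
  expect_equal(temporal_cv_map(alt)[1, 1], 0.5)
  # constant pixel -> CV 0
  expect_equal(temporal_cv_map(ca_movie(array(7, c(5, 2, 2))))[1, 1], 0)
  # multiplicative rescaling leaves CV (and the Otsu mask) unchanged
  cv2 <- temporal_cv_map(ca_movie(data * 37.5))
  expect_equal(cv, cv2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Otsu mask separates a two-valued CV map at an interior threshold", {
  set.seed(6)
  cvv <- matrix(0.01, 30, 30)
  hot <- sample(900, 90)
  cvv[hot] <- 0.5
  mask <- nonresponsive_mask(cvv)
  thr <- attr(mask, "threshold")
  # oracle: exhaustive search over all 256 bin edges
  edges <- seq(0.01, 0.5, length.out = 257)
  bcv <- sapply(edges[2:256], function(e) {
    lo <- cvv[cvv < e]; hi <- cvv[cvv >= e]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  })
  expect_equal(thr, edges[which.max(bcv) + 1])
  expect_gt(thr, 0.01); expect_lt(thr, 0.5)
  expect_identical(unname(mask[hot]), rep(FALSE, 90))
  expect_true(all(mask[-hot]))
  # all-constant movie -> everything non-responsive, with warning
  expect_warning(m0 <- nonresponsive_mask(matrix(0.3, 5, 5)), "constant")
  expect_true(all(m0))
})

test_that("background fit recovers polynomial surfaces", {
  # reference itself a degree-4 polynomial, full mask -> exact recovery
  coeffs <- c(x0.y0 = 50, x1.y0 = 10, x0.y2 = -6, x2.y2 = 4, x4.y0 = 3)
  surf <- 0 + calciscope:::eval_poly_field(coeffs, 48, 52)
  full <- matrix(TRUE, 48, 52)
  bm <- fit_background(surf, full, 4)
  expect_lt(max(abs(predict(bm) - surf)), 1e-6 * diff(range(surf)))
  # constant image -> constant surface, residual 0
  bmc <- fit_background(matrix(3, 20, 20), matrix(TRUE, 20, 20))
  expect_equal(predict(bmc), matrix(3, 20, 20), tolerance = 1e-9)
  # degree-2 background + bright cells excluded by the mask: recovered
  # within noise, and cell dF/F transients preserved after subtraction
  p <- test_protocol()
  coef2 <- c(x0.y0 = 30, x1.y0 = 8, x0.y1 = -5, x1.y1 = 4)
  tr <- uniform_truth(5, channels = "M3", background_coeffs = coef2,
                      noise_sd = 1)
  sim <- gen_soma_movie(tr, p, c(70, 64, 64), seed = 14)
  tmean <- colMeans(sim$movie$data, dims = 1)
  mask <- sim$cell_label == 0
  bm2 <- fit_background(tmean, mask, 4)
  truth_surf <- 100 + calciscope:::eval_poly_field(coef2, 64, 64)
  expect_lt(max(abs(predict(bm2) - truth_surf)), 3 * 1)
  # peak dF of cell mean trace before vs after subtraction within 5%
  sub <- subtract_background(sim$movie, bm2)
  peak_df <- function(mv) {
    trc <- roi_traces(sim$cell_label, mv)[1, ]
    max(trc[15:20]) - mean(trc[5:14])
  }
  expect_lt(abs(peak_df(sub) - peak_df(sim$movie)) / peak_df(sim$movie),
            0.05)
  # degenerate masks rejected
  line_mask <- matrix(FALSE, 30, 30); line_mask[15, ] <- TRUE
  expect_error(fit_background(matrix(1, 30, 30), line_mask, 4), "rank")
  tiny <- matrix(FALSE, 30, 30); tiny[1:10] <- TRUE
  expect_error(fit_background(matrix(1, 30, 30), tiny, 4), "at least 15")
})

test_that("normalisation yields exact ratios and guards zero baselines", {
  set.seed(9)
  data <- array(runif(12 * 5 * 5, 10, 20), c(12, 5, 5))
  m <- ca_movie(data)
  f0 <- matrix(10, 5, 5)
  dff <- normalize_movie(m, f0)
  for (t in c(1, 12)) expect_equal(dff$data[t, , ], data[t, , ] / 10 - 1,
                                   tolerance = 1e-12)
  # F == F0 -> 0; F = 2 F0 -> 1
  expect_equal(normalize_movie(ca_movie(array(10, c(3, 2, 2))),
                               matrix(10, 2, 2))$data[1, 1, 1], 0)
  expect_equal(normalize_movie(ca_movie(array(20, c(3, 2, 2))),
                               matrix(10, 2, 2))$data[2, 1, 1], 1)
  ff0 <- normalize_movie(m, f0, mode = "f_f0")
  expect_equal(ff0$data[1, , ], data[1, , ] / 10, tolerance = 1e-12)
  expect_error(normalize_movie(m, matrix(0, 5, 5)), "zero")
  # partial zero baseline: excluded and flagged, rest intact
  f0z <- f0; f0z[1, 1] <- 0
  dz <- normalize_movie(m, f0z)
  expect_true(attr(dz, "excluded")[1, 1])
  expect_true(all(is.na(dz$data[, 1, 1])))
  expect_equal(dz$data[3, 2, 2], data[3, 2, 2] / 10 - 1)
})
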