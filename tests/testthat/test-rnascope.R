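test_that("rolling ball removes smooth shading and keeps small spots", {
  # constant image -> all zeros
  expect_equal(rolling_ball(matrix(7, 40, 40), 1, 0.2),
               matrix(0, 40, 40), ignore_attr = TRUE)
  # smooth gradient + compact spots: gradient removed, spots preserved
  ny <- nx <- 80
  grad <- 50 * outer(seq(0, 1, length.out = ny), seq(0, 1, length.out = nx),
                     function(y, x) (x + y) / 2)
  spots <- matrix(0, ny, nx)
  tr <- rnascope_truth(make_cell_grid(1, 30), 1)
  for (c in list(c(20, 20), c(60, 40), c(30, 65)))
    spots <- calciscope:::render_spot(spots, c[1], c[2],
                                      sigma = 1.4, integrated = 1000)
  out <- rolling_ball(grad + spots, radius_um = 1, pixel_size_um = 0.2)
  fg <- spots >= 1e-3
  expect_lt(max(out[!fg]) / max(grad), 0.05)          # gradient removed
  expect_lt(abs(sum(out[fg]) - sum(spots)) / sum(spots), 0.10)  # spots kept
  # radius below 1 px rejected
  expect_error(rolling_ball(grad, 0.1, 0.2), ">= 1 px")
})

test_that("spot detection finds singles, localises them, flags clusters", {
  expect_equal(nrow(detect_spots(matrix(0, 50, 50), 0.8, 0.2)), 0)
  # 20 non-overlapping singles, SNR 10
  masks <- make_cell_grid(4, cell_radius_px = 20)
  tr <- rnascope_truth(masks, dots_per_cell = 5, cluster_fraction = 0)
  img <- gen_rnascope_image(tr, pixel_size_um = 0.2, seed = 13,
                            noise_sd = 2)  # peak/noise ~ 40/2
  sub <- rolling_ball(img$probe, 1, 0.2)
  sp <- detect_spots(sub, 0.8, 0.2)
  expect_true(abs(nrow(sp) - 20) <= 1)
  expect_false(any(sp$is_cluster))
  # localisation error < 1 px against generated positions
  for (i in seq_len(nrow(img$spots))) {
    d <- sqrt((sp$y - img$spots$y[i])^2 + (sp$x - img$spots$x[i])^2)
    expect_lt(min(d), 1)
  }
  # a 3-member cluster becomes one object flagged is_cluster
  tr3 <- rnascope_truth(masks, dots_per_cell = c(3, 0, 0, 0),
                        cluster_fraction = 1)
  img3 <- gen_rnascope_image(tr3, pixel_size_um = 0.2, seed = 3)
  sp3 <- detect_spots(rolling_ball(img3$probe, 1, 0.2), 0.8, 0.2)
  expect_equal(nrow(sp3), 1)
  expect_true(sp3$is_cluster)
  # cluster flagging is monotone in the diameter factor
  n_cl <- vapply(c(1.2, 1.5, 3), function(f)
    sum(detect_spots(sub, 0.8, 0.2, cluster_factor = f)$is_cluster),
    numeric(1))
  expect_true(all(diff(n_cl) <= 0))
})

test_that("single-dot reference and cluster conversion follow the ratio rule", {
  sp <- data.frame(y = 1:3, x = 1:3, integrated = c(900, 1000, 1100),
                   area_px = 5, eq_diameter_um = 0.8,
                   is_cluster = FALSE)
  expect_error(single_dot_intensity(sp), "5")
  sp5 <- rbind(sp, sp[1:2, ])
  expect_equal(single_dot_intensity(sp5), mean(c(900, 1000, 1100, 900, 1000)))
  all_cl <- transform(sp5, is_cluster = TRUE)
  expect_error(single_dot_intensity(all_cl), "single dots")
  # ratio and rounding rules
  expect_equal(cluster_to_dots(3000, 1000), 3L)
  expect_equal(cluster_to_dots(1499, 1000), 1L)
  expect_equal(cluster_to_dots(1501, 1000), 2L)
  expect_equal(cluster_to_dots(100, 1000), 1L)   # minimum 1
  expect_error(cluster_to_dots(-5, 1000), "positive")
  expect_error(cluster_to_dots(500, 0), "positive")
})

test_that("per-cell counting applies the positivity threshold exactly", {
  masks <- matrix(0L, 40, 80)
  masks[5:35, 5:35] <- 1L
  masks[5:35, 45:75] <- 2L
  mk <- function(n, y0, x0, cluster = FALSE, intensity = 1000)
    data.frame(y = y0 + seq_len(n), x = x0 + seq_len(n),
               integrated = intensity, area_px = 5, eq_diameter_um = 0.8,
               is_cluster = cluster)
  # cell 1: 4 singles -> negative; cell 2: 2 singles + a 4-equivalent
  # cluster -> 6 dots, positive
  spots <- rbind(mk(4, 10, 10), mk(2, 10, 50),
                 mk(1, 25, 60, cluster = TRUE, intensity = 4000),
                 mk(1, 1, 1))   # outside both masks -> background bin
  rec <- count_dots_per_cell(masks, spots, ref_intensity = 1000)
  expect_equal(rec$dots_total, c(4, 6))
  expect_identical(rec$positive, c(FALSE, TRUE))
  expect_equal(rec$n_cluster_equivalents, c(0, 4))
  expect_equal(attr(rec, "background_spots"), 1)
  # raising the threshold never increases the positive fraction
  pos_at <- vapply(4:8, function(thr)
    mean(count_dots_per_cell(masks, spots, 1000, thr)$positive), numeric(1))
  expect_true(all(diff(pos_at) <= 0))
})

test_that("counts are invariant to probe-channel rescaling and conserve signal", {
  masks <- make_cell_grid(16, cell_radius_px = 25, spacing_px = 55)
  set.seed(2); dots <- rpois(16, 8)
  tr <- rnascope_truth(masks, dots, cluster_fraction = 0.2)
  img <- gen_rnascope_image(tr, pixel_size_um = 0.2, seed = 4, noise_sd = 0)
  q1 <- quantify_rnascope(img$probe, masks, 0.2)
  q2 <- quantify_rnascope(img$probe * 7.3, masks, 0.2)
  expect_identical(q1$records$dots_total, q2$records$dots_total)
  # cluster correction conserves total signal within 10% (noise-free)
  tot_est <- sum(q1$records$dots_total) * q1$ref_intensity
  tot_obs <- sum(q1$spots$integrated)
  expect_lt(abs(tot_est - tot_obs) / tot_obs, 0.10)
})

test_that("noise-free boundary cells split 4 vs 5 dots into neg vs pos", {
  masks <- make_cell_grid(2, cell_radius_px = 20)
  tr <- rnascope_truth(masks, dots_per_cell = c(4, 5), cluster_fraction = 0)
  img <- gen_rnascope_image(tr, pixel_size_um = 0.2, seed = 6, noise_sd = 0)
  q <- quantify_rnascope(img$probe, masks, 0.2)
  expect_equal(q$records$dots_total, c(4, 5))
  expect_identical(q$records$positive, c(FALSE, TRUE))
})

test_that("per-animal positive fractions aggregate with mean and SEM", {
  rec <- data.frame(cell_id = 1:20, area_um2 = 1, n_single_dots = 5,
                    n_cluster_equivalents = 0, dots_total = 5,
                    positive = rep(c(TRUE, FALSE), c(7, 3)),
                    wga_status = NA, corrected = TRUE)
  fp <- fraction_positive(rec[1:10, ], animal = rep("m1", 10))
  expect_equal(fp$per_animal$fraction, 0.7)
  # two animals at 0.6 and 0.8 -> mean 0.7, SEM 0.1
  rec$positive <- c(rep(c(TRUE, FALSE), c(6, 4)), rep(c(TRUE, FALSE), c(8, 2)))
  fp2 <- fraction_positive(rec, animal = rep(c("m1", "m2"), each = 10))
  expect_equal(sort(fp2$per_animal$fraction), c(0.6, 0.8))
  expect_equal(fp2$summary$mean, 0.7)
  expect_equal(fp2$summary$sem, 0.1)
})
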