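test_that("identity pairs give zero velocity and constructed shifts are recovered", {
  tex <- gen_texture(1, c(128, 128), correlation_length = 4)
  f0 <- piv_pair(tex, tex, 32, 16, dt = 1)
  expect_true(all(f0$valid))
  expect_lt(max(abs(c(f0$vx_um_s, f0$vy_um_s))), 1e-6)

  # +3 px integer shift along x (periodic texture, exact)
  f3 <- piv_pair(tex, tex[, c(126:128, 1:125)], 32, 16, dt = 1, px_size = 1)
  expect_lt(max(abs(f3$vx_um_s - 3)), 0.1)
  expect_lt(max(abs(f3$vy_um_s)), 0.1)

  # subpixel Fourier shift recovered to <= 0.1 px
  f5 <- piv_pair(tex, fourier_shift(tex, 0.5, 0), 32, 16, dt = 1)
  expect_lt(max(abs(f5$vx_um_s - 0.5)), 0.1)
  expect_lt(max(abs(f5$vy_um_s)), 0.1)
})

test_that("piv velocities scale with dt and px_size", {
  tex <- gen_texture(2, c(96, 96), correlation_length = 4)
  sh <- tex[, c(95:96, 1:94)]     # 2 px
  f <- piv_pair(tex, sh, 32, 16, dt = 4, px_size = 0.5)
  expect_equal(mean(f$vx_um_s[f$valid]), 2 * 0.5 / 4, tolerance = 0.05)
})

test_that("piv is translation-equivariant", {
  tex <- gen_texture(3, c(128, 128), correlation_length = 4)
  base <- fourier_shift(tex, 1.2, -0.7)
  f1 <- piv_pair(tex, base, 32, 16, dt = 1)
  f2 <- piv_pair(tex, fourier_shift(base, 2, 1), 32, 16, dt = 1)
  expect_lt(max(abs((f2$vx_um_s - f1$vx_um_s) - 2)), 0.1)
  expect_lt(max(abs((f2$vy_um_s - f1$vy_um_s) - 1)), 0.1)
})

test_that("rotating both frames by 90 degrees rotates the vectors", {
  tex <- gen_texture(4, c(96, 96), correlation_length = 4)
  shifted <- fourier_shift(tex, 2, 1)
  # quarter-turn in array coords: new[i, j] = old[n + 1 - j, i], which maps
  # a displacement (dx, dy) to (-dy, dx)
  rot <- function(m) t(m)[, rev(seq_len(nrow(m)))]
  fr <- piv_pair(rot(tex), rot(shifted), 32, 16, dt = 1)
  expect_equal(mean(fr$vx_um_s[fr$valid]), -1, tolerance = 0.1)
  expect_equal(mean(fr$vy_um_s[fr$valid]), 2, tolerance = 0.1)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(piv_pair(matrix(0, 8, 8), matrix(0, 8, 8), 32, 16, dt = 1),
               "smaller than one")
  expect_error(piv_pair(matrix(0, 64, 64), matrix(0, 32, 32), 32, 16, dt = 1),
               "identical dimensions")
  expect_error(piv_pair(matrix(0, 64, 64), matrix(0, 64, 64), 32, 33, dt = 1),
               "overlap_px")
  flat <- piv_pair(matrix(1, 64, 64), matrix(1, 64, 64), 32, 16, dt = 1)
  expect_false(any(flat$valid))
  expect_error(mean_speed(flat), "no valid")
})

test_that("mean speed averages magnitudes over valid nodes only", {
  expect_equal(mean_speed(make_piv_field(0, 0)), 0)
  expect_equal(mean_speed(make_piv_field(3, 4)), 5)
  f <- make_piv_field(0, 0, nx = 2, ny = 2)
  f$vx_um_s <- c(1, 0, 1, 0); f$vy_um_s <- c(0, 1, 0, 1)
  expect_equal(mean_speed(f), 1)
  f$valid <- c(TRUE, TRUE, FALSE, FALSE)
  f$vx_um_s[3:4] <- 100
  expect_equal(mean_speed(f), 1)   # invalid nodes excluded, not zero-filled
})

test_that("normalized median filtering replaces spikes and spares structure", {
  tex <- gen_texture(1, c(128, 128), correlation_length = 4)
  f <- piv_pair(tex, tex[, c(127:128, 1:126)], 32, 16, dt = 1)
  f$vx_um_s[25] <- f$vx_um_s[25] * 10
  ff <- filter_outliers(f, threshold = 2)
  expect_true(ff$replaced[25])
  expect_equal(sum(ff$replaced), 1L)
  expect_equal(ff$vx_um_s[25], 2, tolerance = 0.05)

  # uniform field untouched
  u <- make_piv_field(2, 0)
  expect_false(any(filter_outliers(u)$replaced))

  # i.i.d. noise: modest replacement rate at the default threshold
  g <- make_piv_field(0, 0, nx = 12, ny = 12)
  set.seed(11)
  g$vx_um_s <- rnorm(144); g$vy_um_s <- rnorm(144)
  expect_lte(mean(filter_outliers(g, threshold = 2)$replaced), 0.10)
})

test_that("speed traces reflect programmed flows and schedules", {
  tex <- gen_texture(5, c(160, 160), correlation_length = 4)
  lit <- always_on()
  seq_static <- render_sequence(tex, flow_spec("uniform", speed = 0), lit,
                                n_frames = 4, dt = 1, noise_sd = 0, seed = 1)
  st0 <- speed_trace(seq_static, lit)
  expect_lt(max(st0$speed_um_s), 1e-6)

  seq2 <- render_sequence(tex, flow_spec("uniform", speed = 2), lit,
                          n_frames = 8, dt = 1, noise_sd = 0.02, seed = 2)
  st2 <- speed_trace(seq2, lit)
  expect_equal(mean(st2$speed_um_s), 2, tolerance = 0.05)
  expect_equal(st2$time_s[1], 0.5)   # pair midpoint timestamps

  # alternating dark/light: on-episode speeds dominate
  cyc <- illumination_schedule(0, 6, 1)
  seq3 <- render_sequence(tex, flow_spec("uniform", speed = 2), cyc,
                          n_frames = 13, dt = 1, noise_sd = 0.02, seed = 3)
  st3 <- speed_trace(seq3, cyc)
  on_mean <- mean(st3$speed_um_s[st3$intensity_uW_mm2 > 0])
  off_mean <- mean(st3$speed_um_s[st3$intensity_uW_mm2 == 0])
  expect_gt(on_mean, 5 * off_mean)

  # time reversal preserves speed magnitudes
  rev_seq <- image_sequence(seq2[, , rev(seq_len(dim(seq2)[3]))],
                            px_size = 1, dt = 1)
  st_rev <- speed_trace(rev_seq, lit)
  expect_equal(rev(st_rev$speed_um_s), st2$speed_um_s, tolerance = 0.02)
})

test_that("field correlation behaves as a Pearson coefficient", {
  tex <- gen_texture(6, c(128, 128), correlation_length = 4)
  f <- piv_pair(tex, fourier_shift(tex, 1.5, 0.5), 32, 16, dt = 1)
  expect_equal(field_correlation(f, f), 1)
  neg <- f; neg$vx_um_s <- -f$vx_um_s; neg$vy_um_s <- -f$vy_um_s
  expect_equal(field_correlation(f, neg), -1)

  # independently seeded random fields decorrelate
  a <- make_piv_field(0, 0, nx = 11, ny = 11)
  b <- a
  set.seed(21); a$vx_um_s <- rnorm(121); a$vy_um_s <- rnorm(121)
  set.seed(22); b$vx_um_s <- rnorm(121); b$vy_um_s <- rnorm(121)
  expect_lt(abs(field_correlation(a, b)), 0.2)

  small <- make_piv_field(1, 0, nx = 3, ny = 3, step = 10)
  expect_error(field_correlation(f, small), "different grids")
})
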