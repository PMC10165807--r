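test_that("generators are bit-reproducible for a fixed seed", {
  expect_identical(gen_texture(3, c(64, 64)), gen_texture(3, c(64, 64)))
  s <- always_on()
  expect_identical(
    gen_speed_trace(1.2, 8, 13, 0, s, noise_sd = 0.1, seed = 4, span = c(0, 50)),
    gen_speed_trace(1.2, 8, 13, 0, s, noise_sd = 0.1, seed = 4, span = c(0, 50)))
  tex <- gen_texture(1, c(48, 48))
  expect_identical(
    render_sequence(tex, flow_spec("uniform", speed = 1), s, 3, 1,
                    noise_sd = 0.01, seed = 9),
    render_sequence(tex, flow_spec("uniform", speed = 1), s, 3, 1,
                    noise_sd = 0.01, seed = 9))
  geo <- tibble::tibble(L_um = c(50, 100), W_um = c(50, 100), H_um = 100)
  expect_identical(gen_threshold_dataset(1, geo, 0.05, seed = 2),
                   gen_threshold_dataset(1, geo, 0.05, seed = 2))
})

test_that("textures carry the programmed director orientation", {
  tex0 <- gen_texture(1, c(256, 256), orientation = 0, correlation_length = 4)
  expect_true(all(tex0 >= 0 & tex0 <= 1))
  expect_lt(abs(modal_angle(orientation_field(tex0, 1, 4))), 0.035)

  tex45 <- gen_texture(2, c(256, 256), orientation = pi / 4,
                       correlation_length = 4)
  expect_equal(modal_angle(orientation_field(tex45, 1, 4)), pi / 4,
               tolerance = 0.035 / (pi / 4))

  expect_error(gen_texture(1, c(64, 64), correlation_length = 0.5),
               "correlation_length")
})

test_that("rendering is gated by the illumination schedule", {
  tex <- gen_texture(4, c(64, 64), correlation_length = 4)
  dark <- illumination_schedule(0, 100, 0)
  noise_sd <- 0.01
  seq_dark <- render_sequence(tex, flow_spec("uniform", speed = 2), dark,
                              n_frames = 4, dt = 1, noise_sd = noise_sd,
                              seed = 5)
  for (k in 2:4) {
    expect_lte(mean(abs(seq_dark[, , k] - seq_dark[, , 1])), 3 * noise_sd)
  }

  still <- render_sequence(tex, flow_spec("uniform", speed = 0), always_on(),
                           n_frames = 3, dt = 1, noise_sd = noise_sd, seed = 6)
  expect_lte(max(abs(still[, , 2] - tex)), 5 * noise_sd)

  # uniform 1 um/s, dt = 1 s, 1 um/px: consecutive frames cross-correlate at
  # a 1 px lag (plain FFT correlation as the oracle)
  lit <- render_sequence(tex, flow_spec("uniform", speed = 1), always_on(),
                         n_frames = 3, dt = 1, noise_sd = 0, seed = 7)
  a <- lit[, , 1] - mean(lit[, , 1]); b <- lit[, , 2] - mean(lit[, , 2])
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  expect_equal(unname(pk[1]), 1L)   # no y lag
  expect_equal(unname(pk[2]), 2L)   # +1 px in x
})

test_that("rendering rejects regions outside the frame", {
  tex <- gen_texture(1, c(32, 32))
  bad <- illumination_schedule(0, 10, 1, region = rect_region(20, 0, 64, 10))
  expect_error(render_sequence(tex, flow_spec("uniform"), bad, 2, 1, seed = 1),
               "outside the frame")
})

test_that("noiseless speed traces follow the switching kinetics exactly", {
  vmax <- 1.2; tau_on <- 8; tau_off <- 13; dark <- 0.05
  s <- illumination_schedule(c(100, 700), c(400, 1000), intensity = 1)
  tr <- gen_speed_trace(vmax, tau_on, tau_off, dark, s, dt = 1,
                        span = c(100, 1200))
  on1 <- tr$time_s >= 100 & tr$time_s < 400
  tp <- tr$time_s[on1] - 100
  expect_equal(tr$speed_um_s[on1],
               dark + (vmax - dark) * (1 - exp(-tp / tau_on)),
               tolerance = 1e-10)
  off1 <- tr$time_s >= 400 & tr$time_s < 700
  v_de <- dark + (vmax - dark) * (1 - exp(-300 / tau_on))
  tq <- tr$time_s[off1] - 400
  expect_equal(tr$speed_um_s[off1],
               dark + (v_de - dark) * 2 / (1 + exp(tq / tau_off)),
               tolerance = 1e-10)
  # half-rise at t' = tau_on * ln 2
  t_half <- 100 + tau_on * log(2)
  tr2 <- gen_speed_trace(vmax, tau_on, tau_off, dark, s, dt = t_half - 100,
                         span = c(100, 400))
  expect_equal(tr2$speed_um_s[2], dark + (vmax - dark) / 2, tolerance = 1e-10)
  # asymptote
  expect_equal(tr$speed_um_s[tr$time_s == 400], vmax, tolerance = 1e-10)
  expect_error(gen_speed_trace(0.5, 8, 13, 0.6, s), "exceed")
})

test_that("noiseless angle traces follow the relaxation model exactly", {
  gd <- 0.002; tau <- 17; r <- 17
  s <- illumination_schedule(0, 300, 1)
  tr <- gen_angle_trace(gd, tau, r, schedule = s, dt = 1, span = c(0, 600))
  # linear growth: 0.6 rad over a 300 s on-episode
  expect_equal(tr$angle_rad[tr$time_s == 300], 0.6, tolerance = 1e-10)
  # off-interval follows the two-term decay with C = angle at deactivation
  off <- tr$time_s >= 300
  tq <- tr$time_s[off] - 300
  expect_equal(tr$angle_rad[off],
               exp(-tq / tau) * gd * tq + 0.6 * exp(-tq / r),
               tolerance = 1e-10)
  # value at deactivation equals C; decays to zero at long times
  s_off <- illumination_schedule(0, 1, 0)
  tr2 <- gen_angle_trace(gd, tau, r, C = 0.2, schedule = s_off, dt = 50,
                         span = c(0, 2000))
  expect_equal(tr2$angle_rad[1], 0.2, tolerance = 1e-10)
  expect_lt(tr2$angle_rad[nrow(tr2)], 1e-8)
})

test_that("threshold datasets satisfy the confinement model", {
  geoC <- tibble::tibble(L_um = c(50, 100, 150, 200, 250, 300, 400, 500),
                         W_um = c(50, 100, 150, 200, 250, 300, 400, 500),
                         H_um = 100)
  d0 <- gen_threshold_dataset(1.17, geoC, rel_noise = 0)
  expect_equal(d0$I_threshold,
               1.17 * alpha_eff(d0$L_um, d0$W_um, d0$H_um), tolerance = 1e-12)
  fit <- fit_activity_coefficient(d0)
  expect_equal(unname(fit$params["a"]), 1.17, tolerance = 1e-6)

  # saturated branch: I* independent of L when 1/L^2 < 1/W^2 + 1/H^2
  geo_sat <- tibble::tibble(L_um = c(300, 400, 500, 600), W_um = 200,
                            H_um = 100)
  d_sat <- gen_threshold_dataset(2, geo_sat, rel_noise = 0)
  expect_equal(diff(range(d_sat$I_threshold)), 0, tolerance = 1e-12)

  # hand evaluation: L = W = H = 100 um sits on the saturated branch
  d1 <- gen_threshold_dataset(1.17, tibble::tibble(L_um = 100, W_um = 100,
                                                   H_um = 100), 0)
  expect_equal(d1$I_threshold, 1.17 * 4 * pi^2 * 2e-4, tolerance = 1e-12)

  expect_error(gen_threshold_dataset(-1, geoC), "a")
  expect_error(
    gen_threshold_dataset(1, tibble::tibble(L_um = -5, W_um = 1, H_um = 1)),
    "dimensions")
})

test_that("accumulated displacement can relax after deactivation", {
  tex <- gen_texture(7, c(96, 96), correlation_length = 4)
  s <- illumination_schedule(0, 200, 1)
  fl <- flow_spec("bend_mode", growth = 0.002, wavevector = 2 * pi / 48)
  seq <- render_sequence(tex, fl, s, n_frames = 9, dt = 50, noise_sd = 0,
                         seed = 3, relax_r = 60)
  tr <- angle_trace(seq, theta0 = 0, schedule = s)
  base <- tr$angle_rad[1]
  peak <- max(tr$angle_rad)
  final <- tr$angle_rad[nrow(tr)]
  expect_gt(peak, base + 0.1)              # grows while lit
  expect_lt(final, base + 0.02)            # relaxes back near baseline
})
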