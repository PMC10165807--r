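# displacement series built from programmed per-node velocities
programmed_fields <- function(fun, n_steps, nx = 9, ny = 9, step = 16) {
  lapply(seq_len(n_steps), function(k) {
    f <- make_piv_field(0, 0, nx = nx, ny = ny, step = step)
    v <- fun(f$x_um, f$y_um, k)
    f$vx_um_s <- v$vx; f$vy_um_s <- v$vy
    f
  })
}

test_that("displacement accumulates Eulerian increments from zero", {
  flds <- programmed_fields(function(x, y, k) list(vx = rep(1, length(x)),
                                                   vy = rep(0, length(x))), 10)
  disp <- accumulate_displacement(flds, dt = 1)
  expect_equal(disp$ux_um[disp$time_s == 0], rep(0, 81))
  expect_equal(disp$ux_um[disp$time_s == 10], rep(10, 81))
  expect_equal(max(abs(disp$uy_um)), 0)

  z <- programmed_fields(function(x, y, k) list(vx = rep(0, length(x)),
                                                vy = rep(0, length(x))), 5)
  dz <- accumulate_displacement(z, dt = 2)
  expect_equal(max(abs(c(dz$ux_um, dz$uy_um))), 0)

  # linearly growing speed integrates to a quadratic (within one step)
  lin <- programmed_fields(function(x, y, k) list(vx = rep(k, length(x)),
                                                  vy = rep(0, length(x))), 10)
  dl <- accumulate_displacement(lin, dt = 1)
  u_end <- dl$ux_um[dl$time_s == 10][1]
  expect_equal(u_end, 55)                      # sum of 1..10
  expect_lt(abs(u_end - 10^2 / 2), 10)         # trapezoid within one step

  # invalid nodes contribute zero increments and are counted
  flds[[3]]$valid[5] <- FALSE
  d2 <- accumulate_displacement(flds, dt = 1)
  expect_equal(d2$ux_um[d2$time_s == 10][5], 9)
  expect_equal(d2$n_missing[d2$time_s == 10][5], 1L)
})

test_that("strain traces recover affine gradients and ignore rigid motion", {
  reg <- rect_region(0, 0, 160, 160)
  rigid <- programmed_fields(function(x, y, k) list(vx = rep(0.7, length(x)),
                                                    vy = rep(-0.3, length(x))), 6)
  st <- strain_trace(accumulate_displacement(rigid, dt = 1), reg, erode_um = 0)
  expect_lt(max(abs(c(st$gamma_xx, st$gamma_yy))), 1e-12)

  ext_x <- programmed_fields(function(x, y, k) list(vx = 0.001 * x,
                                                    vy = rep(0, length(x))), 10)
  stx <- strain_trace(accumulate_displacement(ext_x, dt = 1), reg, erode_um = 0)
  expect_equal(stx$gamma_xx[stx$time_s == 10], 0.01, tolerance = 1e-10)
  expect_equal(stx$gamma_yy[stx$time_s == 10], 0, tolerance = 1e-12)

  ext_y <- programmed_fields(function(x, y, k) list(vx = rep(0, length(x)),
                                                    vy = 0.002 * y), 10)
  sty <- strain_trace(accumulate_displacement(ext_y, dt = 1), reg, erode_um = 0)
  expect_equal(sty$gamma_yy[sty$time_s == 10], 0.02, tolerance = 1e-10)

  # net transverse strain is invariant to a global translation
  shifted <- lapply(ext_y, function(f) { f$uy_offset <- NULL
    f$vx_um_s <- f$vx_um_s + 5; f$vy_um_s <- f$vy_um_s + 3; f })
  sts <- strain_trace(accumulate_displacement(shifted, dt = 1), reg,
                      erode_um = 0)
  expect_equal(sts$gamma_yy, sty$gamma_yy, tolerance = 1e-12)

  expect_error(strain_trace(accumulate_displacement(ext_y, dt = 1),
                            rect_region(0, 0, 20, 20), erode_um = 0),
               "3x3")
})

test_that("piv-derived strain matches a programmed affine deformation", {
  tex <- gen_texture(4, c(192, 192), correlation_length = 4)
  reg <- rect_region(16, 16, 160, 160)
  schd <- illumination_schedule(0, 1e6, 1, region = reg)
  fl <- flow_spec("extension", rate = 0.002, origin = c(96, 96))
  seq <- render_sequence(tex, fl, schd, n_frames = 11, dt = 2,
                         noise_sd = 0.005, seed = 5)
  fields <- lapply(1:10, function(k) {
    filter_outliers(piv_pair(seq[, , k], seq[, , k + 1], 32, 16, dt = 2))
  })
  disp <- accumulate_displacement(fields, dt = 2)
  st <- strain_trace(disp, reg)
  expect_equal(st$gamma_xx[nrow(st)], 0.002 * 20, tolerance = 0.02)
  expect_lt(abs(st$gamma_yy[nrow(st)]), 0.002)
})

test_that("region fluorescence traces normalize to the first frame", {
  tex <- gen_texture(2, c(96, 96), correlation_length = 4)
  reg <- rect_region(16, 16, 64, 64)
  static <- image_sequence(replicate(4, tex), px_size = 1, dt = 1)
  tr <- region_intensity_trace(static, reg)
  expect_equal(tr$intensity_rel, rep(1, 4))

  # linear bleach to half
  bleach <- image_sequence(
    lapply(seq(1, 0.5, length.out = 5), function(s) s * tex),
    px_size = 1, dt = 1)
  trb <- region_intensity_trace(bleach, reg)
  expect_equal(trb$intensity_rel[5], 0.5, tolerance = 1e-10)

  # sustained outflow drains the region when inflowing material is dim
  schd <- illumination_schedule(0, 1e6, 1, region = reg)
  adv <- render_sequence(tex, flow_spec("uniform", speed = 2), schd,
                         n_frames = 6, dt = 2, noise_sd = 0, seed = 3,
                         background_dim = 0.2)
  tra <- region_intensity_trace(adv, reg)
  expect_true(all(diff(tra$intensity_rel) <= 1e-3))
  expect_lt(tra$intensity_rel[6], 0.9)
})

test_that("regimes classify by transverse then extensional strain", {
  t10 <- tibble::tibble(time_s = 0:10)
  quiescent <- dplyr::mutate(t10, gamma_xx = 0, gamma_yy = -1e-4 * time_s)
  expect_equal(as.character(classify_regime(quiescent)), "quiescent")

  sliding <- dplyr::mutate(t10, gamma_xx = 0.03 * time_s,
                           gamma_yy = -1e-4 * time_s)
  expect_equal(as.character(classify_regime(sliding)), "sliding")

  buckling <- dplyr::mutate(t10, gamma_xx = 0, gamma_yy = 0.002 * time_s)
  expect_equal(as.character(classify_regime(buckling)), "buckling")
  expect_equal(attr(classify_regime(buckling), "dgamma_yy"), 0.02)
})

test_that("threshold intensity is the first to exceed the strain criterion", {
  res <- tibble::tibble(intensity_uW_mm2 = c(0.1, 0.2, 0.4, 0.8),
                        dgamma_yy = c(0.001, 0.003, 0.008, 0.02))
  expect_equal(as.numeric(threshold_intensity(res)), 0.4)

  below <- res; below$dgamma_yy <- rep(0.001, 4)
  out <- threshold_intensity(below)
  expect_true(is.na(out))
  expect_false(attr(out, "reached"))

  first <- res; first$dgamma_yy <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(as.numeric(threshold_intensity(first)), 0.1)

  unsorted <- res[c(3, 1, 2, 4), ]
  expect_error(threshold_intensity(unsorted), "sorted")
})
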