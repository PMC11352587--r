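test_that("Michelson contrast handles the display luminances and edge cases", {
  expect_equal(michelson_contrast(22, 7), 15 / 29, tolerance = 1e-12)
  expect_equal(michelson_contrast(13, 13), 0)
  expect_equal(michelson_contrast(40, 0), 1)
  expect_error(michelson_contrast(5, 7), "l_max >= l_min")
  expect_error(michelson_contrast(0, 0), "both")
})

test_that("contrast rendering interpolates from background to the full map", {
  px <- matrix(c(0L, 1L, NA, 1L), 2, 2) # black, white, background, white
  sk <- structure(list(pixels = px, retained_count = 3L), class = "sketch")
  lum <- luminance_map() # 7 / 22 / 12 cd/m^2
  r0 <- render_at_contrast(sk, 0, lum)
  expect_true(all(r0 == 12))
  r1 <- render_at_contrast(sk, 1, lum)
  expect_equal(r1[1, 1], 7)
  expect_equal(r1[2, 1], 22)
  expect_equal(r1[1, 2], 12)
  rh <- render_at_contrast(sk, 0.5, lum)
  expect_equal(rh[2, 1], 17) # white at half contrast: 12 + 0.5 * (22 - 12)
  expect_error(render_at_contrast(sk, 1.2, lum), "\\[0, 1\\]")
})

test_that("rendering is affine in contrast and monotone in rendered contrast", {
  px <- matrix(c(0L, 1L), 1, 2)
  lum <- luminance_map()
  cs <- seq(0, 1, by = 0.25)
  white <- vapply(cs, function(cc) render_at_contrast(px, cc, lum)[1, 2], 1)
  black <- vapply(cs, function(cc) render_at_contrast(px, cc, lum)[1, 1], 1)
  expect_equal(diff(white), rep(0.25 * (22 - 12), 4), tolerance = 1e-12)
  expect_equal(diff(black), rep(0.25 * (7 - 12), 4), tolerance = 1e-12)
  mich <- michelson_contrast(white, black)
  expect_true(all(diff(mich) > 0))
})

test_that("Gabor frame stacks have the right count, period and determinism", {
  spec <- gabor_spec(noise_sigma = 0, contrast = 0.5)
  fs <- make_gabor_frames(spec, duration = 25, frame_rate = 120,
                          direction = "right", noise_seed = 7)
  expect_length(fs$frames, 3) # 25 ms at 120 Hz
  # 10 Hz drift at 120 Hz: 30 deg of phase per frame, 12-frame period
  long <- make_gabor_frames(spec, duration = 200, frame_rate = 120,
                            direction = "right", noise_seed = 7)
  expect_equal(long$frames[[13]], long$frames[[1]], tolerance = 1e-9)
  expect_gt(max(abs(long$frames[[2]] - long$frames[[1]])), 1)
  # half a cycle inverts the carrier about the background
  expect_equal(long$frames[[7]] - 127, -(long$frames[[1]] - 127),
               tolerance = 1e-9)
  # static direction freezes the phase
  none <- make_gabor_frames(spec, 50, 120, direction = "none", noise_seed = 7)
  expect_equal(none$frames[[4]], none$frames[[1]], tolerance = 1e-12)
})

test_that("Gabor noise is static across frames and zero-contrast frames are pure noise", {
  spec <- gabor_spec(noise_sigma = 20, contrast = 0)
  fs <- make_gabor_frames(spec, 50, 120, direction = "right", noise_seed = 3)
  for (k in 2:length(fs$frames)) {
    expect_equal(fs$frames[[k]], fs$frames[[1]], tolerance = 1e-12)
  }
  fs2 <- make_gabor_frames(spec, 50, 120, direction = "right", noise_seed = 3)
  expect_identical(fs, fs2)
  expect_true(all(fs$frames[[1]] >= 0 & fs$frames[[1]] <= 255))
})

test_that("flicker frames alternate as a square wave with 6-frame half periods", {
  spec <- flicker_spec() # 22 / 7 cd/m^2 at 10 Hz
  fs <- make_flicker_frames(spec, duration = 100, frame_rate = 120)
  lev <- vapply(fs$frames, function(f) f[1, 1], 1)
  expect_equal(lev[1:6], rep(22, 6))
  expect_equal(lev[7:12], rep(7, 6))
  full <- make_flicker_frames(spec, duration = 2000, frame_rate = 120)
  expect_length(full$frames, 240)
  expect_warning(make_flicker_frames(flicker_spec(alternation_freq = 7), 100),
                 "rounding")
  const <- make_flicker_frames(flicker_spec(l_high = 12, l_low = 12), 50)
  expect_true(all(vapply(const$frames, function(f) f[1, 1], 1) == 12))
})

test_that("masks are seed-reproducible uniform pixel fields", {
  m1 <- make_mask(64, 64, seed = 9)
  m2 <- make_mask(64, 64, seed = 9)
  expect_identical(m1, m2)
  m3 <- make_mask(64, 64, seed = 10)
  expect_gt(sum(m1 != m3), 0)
  big <- make_mask(256, 256, seed = 1)
  expect_true(all(big >= 0 & big <= 255))
  expect_gt(mean(big), 115)
  expect_lt(mean(big), 140)
})
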