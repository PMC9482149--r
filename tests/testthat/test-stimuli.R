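test_that("Michelson contrast reproduces the printed stimulus labels", {
  expect_equal(contrast_label(220, 255), 0.07)
  expect_equal(contrast_label(210, 255), 0.10)
  expect_equal(michelson_contrast(255, 255), 0)
  expect_equal(michelson_contrast(0, 255), 1)
  expect_equal(michelson_contrast(0, 0), 0)  # degenerate black-on-black
  # the nine-loom series is strictly decreasing from 1.00 to 0.05
  labels <- contrast_label(contrast_series_bytes(), 255)
  expect_equal(labels, c(1.00, 0.67, 0.44, 0.26, 0.19, 0.12, 0.10, 0.07, 0.05))
  expect_true(all(diff(michelson_contrast(contrast_series_bytes(), 255)) < 0))
})

test_that("Michelson contrast is symmetric, bounded and monotone in the object byte", {
  for (g in c(0.8, 1, 2.2)) {
    d <- display_model(g)
    b1 <- c(0, 17, 120, 255); b2 <- c(255, 40, 0, 10)
    expect_equal(michelson_contrast(b1, b2, d), michelson_contrast(b2, b1, d))
    cc <- michelson_contrast(0:255, 255, d)
    expect_true(all(cc >= 0 & cc <= 1))
  }
  cc <- michelson_contrast(0:254, 255)
  expect_true(all(diff(cc) < 0))
})

test_that("isoluminant grey calibration matches linear and non-linear displays", {
  expect_equal(isoluminant_grey(0, 255), 127)  # tie 127/128 broken downward
  expect_equal(isoluminant_grey(100, 100), 100)
  # the study's grey of 153 implies a display gamma of ~1.357
  gamma <- log(0.5) / log(153 / 255)
  expect_equal(isoluminant_grey(0, 255, display_model(gamma)), 153)
})

test_that("loom frames start empty, end at alpha_max, and only ever grow", {
  cfg <- test_cfg()
  spec <- loom_spec(0, 255, expansion_profile("linear", duration_s = 5,
                                              alpha_max_deg = 30,
                                              frame_rate = 12))
  f0 <- render_loom_frame(spec, cfg, 0)
  expect_true(all(f0 == 255))
  fT <- render_loom_frame(spec, cfg, 5)
  # disc diameter in px within 2 px of the physical width of alpha_max
  diam_px <- max(colSums(fT == 0))
  expect_equal(diam_px, physical_width(30, cfg) / cfg$pixel_pitch_mm,
               tolerance = 2 / diam_px)
  frames <- render_sequence(spec, cfg)
  counts <- vapply(frames, function(f) sum(f == 0), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("a disc larger than the frame is clipped with a warning", {
  cfg <- viewing_config(frame_width_px = 40, frame_height_px = 40)
  spec <- loom_spec(0, 255, expansion_profile("linear", duration_s = 5))
  expect_warning(f <- render_loom_frame(spec, cfg, 5), "clipped")
  expect_true(all(f == 0))
})

test_that("checkerboard frames are balanced, sized correctly, and isoluminant under the calibrated grey", {
  # frame of exactly 12 x 12 checks so the checkerboard is perfectly balanced
  cfg <- viewing_config(frame_width_px = 132, frame_height_px = 132)
  spec <- checker_loom_spec(3.2, profile = expansion_profile(
    "linear", duration_s = 5, alpha_max_deg = 30, frame_rate = 6))
  f0 <- render_checker_frame(spec, cfg, 0)
  # 3.2 deg at 50 mm / 0.25 mm px pitch -> 11 px checks, white at top-left
  expect_equal(f0[1, 1], 255)
  expect_equal(rle(f0[1, ] == 255)$lengths[1], 11)
  expect_equal(sum(f0 == 0), sum(f0 == 255))
  # isoluminance: mean mapped luminance invariant in t to < 0.5%
  frames <- render_sequence(spec, cfg)
  lum <- vapply(frames, frame_mean_luminance, numeric(1))
  expect_lt(max(abs(lum - lum[1])) / lum[1], 0.005)
  # unrenderable check widths are refused
  expect_error(
    render_checker_frame(checker_loom_spec(0.05), cfg, 0), "pixel")
})

test_that("PNG frame sequences round-trip byte-exact with zero-padded names", {
  cfg <- viewing_config(frame_width_px = 32, frame_height_px = 32)
  spec <- checker_loom_spec(3.2, profile = expansion_profile(
    "linear", duration_s = 1, alpha_max_deg = 20, frame_rate = 4))
  frames <- render_sequence(spec, cfg)
  dir <- withr::local_tempdir()
  paths <- write_frame_sequence(frames, dir)
  expect_equal(basename(paths[1]), "frame_0000.png")
  expect_length(paths, length(frames))
  for (i in seq_along(paths))
    expect_identical(unclass(read_frame(paths[i]))[, ],
                     unclass(frames[[i]])[, ])
  expect_length(write_frame_sequence(list(), dir), 0)
})
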