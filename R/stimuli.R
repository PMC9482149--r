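#' Display model mapping byte values to relative luminance
#'
#' Maps an 8-bit pixel value b to relative luminance `L = (b/255)^gamma`.
#' The default `gamma = 1` treats byte values as linear luminance, which is
#' the only display model that reproduces the study's printed contrast labels
#' (0.07 for byte 220 on 255, 0.10 for byte 210). The grey value 153 used on
#' the checkerboard background implies the physical monitor was non-linear
#' (gamma close to 1.36), so gamma is exposed as configuration.
#'
#' @param gamma Positive exponent (default 1).
#' @return An object of class `display_model`.
#' @export
display_model <- function(gamma = 1) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  structure(list(gamma = gamma, max_byte = 255L), class = "display_model")
}

#' Relative luminance of a byte value
#'
#' @param byte Pixel byte value(s) in 0..255.
#' @param display A [display_model()].
#' @return Relative luminance in `[0, 1]`.
#' @export
byte_luminance <- function(byte, display = display_model()) {
  stopifnot(inherits(display, "display_model"))
  if (any(byte < 0) || any(byte > 255)) stop("byte outside 0..255", call. = FALSE)
  (byte / 255)^display$gamma
}

#' Michelson contrast between two byte values
#'
#' `C = (Lmax - Lmin) / (Lmax + Lmin)` on display-mapped luminances.
#' Symmetric in its two byte arguments and bounded in `[0, 1]`. Both bytes
#' zero is the degenerate black-on-black case, defined as contrast 0.
#' Values are returned unrounded; the study labels stimuli with the 2-decimal
#' rounding applied by [contrast_label()].
#'
#' @param object_byte,background_byte Byte values in 0..255.
#' @param display A [display_model()].
#' @return Michelson contrast, dimensionless.
#' @examples
#' michelson_contrast(220, 255)  # 0.0737 -> labelled 0.07
#' @export
michelson_contrast <- function(object_byte, background_byte,
                               display = display_model()) {
  l1 <- byte_luminance(object_byte, display)
  l2 <- byte_luminance(background_byte, display)
  lo <- pmin(l1, l2); hi <- pmax(l1, l2)
  ifelse(hi + lo == 0, 0, (hi - lo) / (hi + lo))
}

#' Two-decimal Michelson contrast label
#'
#' @inheritParams michelson_contrast
#' @return Contrast rounded to 2 decimals, the convention used to label
#'   stimuli in reports and figures.
#' @export
contrast_label <- function(object_byte, background_byte,
                           display = display_model()) {
  round(michelson_contrast(object_byte, background_byte, display), 2)
}

#' Byte value isoluminant with a checkerboard
#'
#' Returns the byte `g` whose display-mapped luminance is closest to the mean
#' luminance of the black and white checks, i.e. the grey that makes the
#' expanding disc invisible to an eye that cannot resolve the checks. Ties
#' are broken toward the lower byte. Under a linear display this is 127 for
#' a 0/255 checkerboard; the study's grey of 153 corresponds to a display
#' gamma of about 1.357.
#'
#' @param black_byte,white_byte Check byte values, `black_byte <= white_byte`.
#' @param display A [display_model()].
#' @return Integer byte in 0..255.
#' @examples
#' isoluminant_grey(0, 255)                        # 127 (linear display)
#' isoluminant_grey(0, 255, display_model(1.357))  # 153
#' @export
isoluminant_grey <- function(black_byte, white_byte,
                             display = display_model()) {
  if (black_byte > white_byte) stop("black_byte must be <= white_byte", call. = FALSE)
  target <- mean(byte_luminance(c(black_byte, white_byte), display))
  err <- abs(byte_luminance(0:255, display) - target)
  # which.min returns the first (lowest-byte) minimiser: the stated tie rule
  as.integer(which.min(err) - 1L)
}

#' Specification of a plain loom stimulus
#'
#' A disc of `object_byte` expanding on a uniform `background_byte` field,
#' following `profile`; used in the contrast-sensitivity experiment (white
#' background 255, object bytes 0..230). Carries its Michelson-contrast label.
#'
#' @param object_byte,background_byte Byte values in 0..255.
#' @param profile An [expansion_profile()]; defaults to the 10-s exponential
#'   loom of the contrast experiment.
#' @param display A [display_model()] used to compute the contrast label.
#' @return An object of class `loom_spec`.
#' @export
loom_spec <- function(object_byte, background_byte = 255,
                      profile = expansion_profile("exponential"),
                      display = display_model()) {
  stopifnot(inherits(profile, "expansion_profile"))
  if (any(c(object_byte, background_byte) < 0) ||
      any(c(object_byte, background_byte) > 255))
    stop("byte values must be in 0..255", call. = FALSE)
  structure(
    list(object_byte = as.integer(object_byte),
         background_byte = as.integer(background_byte),
         profile = profile,
         contrast = michelson_contrast(object_byte, background_byte, display),
         contrast_label = contrast_label(object_byte, background_byte, display)),
    class = "loom_spec")
}

#' Specification of an isoluminant checkerboard loom stimulus
#'
#' A grey disc expanding over a black-and-white checkerboard; used in the
#' spatial-resolution experiment (check widths 0.3-3.2 deg, grey byte 153 on
#' the study monitor). If `grey_byte` is omitted it is calibrated with
#' [isoluminant_grey()] for the given display model.
#'
#' @param check_width_deg Angular width of one check in degrees (> 0).
#' @param black_byte,white_byte Check bytes (defaults 0 and 255).
#' @param grey_byte Disc byte; default calibrated to isoluminance.
#' @param profile An [expansion_profile()]; defaults to the 5-s linear loom
#'   of the resolution experiment.
#' @param display A [display_model()].
#' @return An object of class `checker_loom_spec`.
#' @export
checker_loom_spec <- function(check_width_deg, black_byte = 0L,
                              white_byte = 255L, grey_byte = NULL,
                              profile = expansion_profile("linear"),
                              display = display_model()) {
  stopifnot(inherits(profile, "expansion_profile"))
  if (check_width_deg <= 0) stop("check_width_deg must be > 0", call. = FALSE)
  if (is.null(grey_byte)) grey_byte <- isoluminant_grey(black_byte, white_byte, display)
  if (!(black_byte < grey_byte && grey_byte < white_byte))
    stop("need black_byte < grey_byte < white_byte", call. = FALSE)
  structure(
    list(check_width_deg = check_width_deg,
         black_byte = as.integer(black_byte),
         white_byte = as.integer(white_byte),
         grey_byte = as.integer(grey_byte),
         profile = profile),
    class = "checker_loom_spec")
}

# integer pixel radius of the disc at time t; >= 1 px once expansion starts
disc_radius_px <- function(profile, cfg, t) {
  physical_width(alpha_at(profile, t), cfg) / 2 / cfg$pixel_pitch_mm
}

# logical disc mask centred on the frame
disc_mask <- function(cfg, radius_px) {
  cx <- (cfg$frame_width_px + 1) / 2
  cy <- (cfg$frame_height_px + 1) / 2
  col <- matrix(seq_len(cfg$frame_width_px), cfg$frame_height_px,
                cfg$frame_width_px, byrow = TRUE)
  row <- matrix(seq_len(cfg$frame_height_px), cfg$frame_height_px,
                cfg$frame_width_px)
  (col - cx)^2 + (row - cy)^2 <= radius_px^2
}

#' Render one frame of a plain loom
#'
#' Fills the frame with the background byte and overlays the centred disc at
#' the angular size given by the profile at time `t`. A disc larger than the
#' frame is clipped (the frame becomes fully object-coloured) with a warning.
#'
#' @param spec A [loom_spec()].
#' @param cfg A [viewing_config()].
#' @param t Time in seconds within the profile duration.
#' @return Integer matrix (rows = frame height) of byte values, class `frame`.
#' @export
render_loom_frame <- function(spec, cfg, t) {
  stopifnot(inherits(spec, "loom_spec"), inherits(cfg, "viewing_config"))
  r <- disc_radius_px(spec$profile, cfg, t)
  half <- min(cfg$frame_width_px, cfg$frame_height_px) / 2
  if (r > half)
    warning("disc exceeds frame at t = ", signif(t, 4), "; clipped", call. = FALSE)
  f <- matrix(spec$background_byte, cfg$frame_height_px, cfg$frame_width_px)
  f[disc_mask(cfg, r)] <- spec$object_byte
  structure(f, class = c("frame", "matrix"))
}

#' Render one frame of an isoluminant checkerboard loom
#'
#' The background is an alternating checkerboard anchored at the frame's
#' top-left corner (top-left check white); the calibrated grey disc is
#' overlaid centred as in [render_loom_frame()]. A check narrower than one
#' pixel cannot be rendered and is a configuration error.
#'
#' @param spec A [checker_loom_spec()].
#' @param cfg A [viewing_config()].
#' @param t Time in seconds within the profile duration.
#' @return Integer matrix of byte values, class `frame`.
#' @export
render_checker_frame <- function(spec, cfg, t) {
  stopifnot(inherits(spec, "checker_loom_spec"), inherits(cfg, "viewing_config"))
  check_px <- round(physical_width(spec$check_width_deg, cfg) / cfg$pixel_pitch_mm)
  if (check_px < 1)
    stop("check width ", spec$check_width_deg,
         " deg is below one pixel at this geometry", call. = FALSE)
  row_band <- (seq_len(cfg$frame_height_px) - 1) %/% check_px
  col_band <- (seq_len(cfg$frame_width_px) - 1) %/% check_px
  white <- outer(row_band, col_band, function(r, c) (r + c) %% 2 == 0)
  f <- matrix(spec$black_byte, cfg$frame_height_px, cfg$frame_width_px)
  f[white] <- spec$white_byte
  f[disc_mask(cfg, disc_radius_px(spec$profile, cfg, t))] <- spec$grey_byte
  structure(f, class = c("frame", "matrix"))
}

#' Render a full frame sequence
#'
#' Renders frames at the profile's frame rate from t = 0 to the stimulus
#' duration inclusive.
#'
#' @param spec A [loom_spec()] or [checker_loom_spec()].
#' @param cfg A [viewing_config()].
#' @return List of frames.
#' @export
render_sequence <- function(spec, cfg) {
  profile <- spec$profile
  times <- seq(0, profile$duration_s, by = 1 / profile$frame_rate)
  render <- if (inherits(spec, "loom_spec")) render_loom_frame else render_checker_frame
  lapply(times, function(t) render(spec, cfg, t))
}

#' Write frames as numbered 8-bit greyscale PNG files
#'
#' Files are named `frame_0000.png`, `frame_0001.png`, ... under `dir`
#' (created if needed). The round trip through [read_frame()] is byte-exact.
#' An empty sequence writes nothing and succeeds.
#'
#' @param frames List of byte matrices as returned by the renderers.
#' @param dir Output directory.
#' @return Invisibly, the vector of file paths written.
#' @export
write_frame_sequence <- function(frames, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir, call. = FALSE)
  paths <- character(0)
  for (i in seq_along(frames)) {
    p <- file.path(dir, sprintf("frame_%04d.png", i - 1))
    png::writePNG(unclass(frames[[i]]) / 255, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read one greyscale PNG frame back as a byte matrix
#'
#' @param path PNG file path.
#' @return Integer matrix of byte values.
#' @export
read_frame <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  structure(matrix(as.integer(round(x * 255)), nrow(x), ncol(x)),
            class = c("frame", "matrix"))
}

#' Mean display-mapped luminance of a frame
#'
#' Used to verify the isoluminance contract: with a calibrated grey disc the
#' mean luminance of a checkerboard-loom frame is invariant in time to well
#' under 0.5%.
#'
#' @param frame Byte matrix.
#' @param display A [display_model()].
#' @return Mean relative luminance.
#' @export
frame_mean_luminance <- function(frame, display = display_model()) {
  mean(byte_luminance(as.numeric(frame), display))
}

#' Object byte values of the contrast-sensitivity loom series
#'
#' The nine object byte values presented against a 255 background, giving
#' Michelson contrast labels 1.00 down to 0.05 under the linear display.
#'
#' @return Integer vector of length 9.
#' @export
contrast_series_bytes <- function() {
  c(0L, 50L, 100L, 150L, 175L, 200L, 210L, 220L, 230L)
}

#' Check-width series of the spatial-resolution experiment
#'
#' Eight angular check widths spanning 0.3-3.2 deg in near-geometric steps,
#' including the 0.53 deg level at which the acuity threshold sits.
#'
#' @return Numeric vector of length 8, degrees.
#' @export
check_width_series <- function() {
  c(0.3, 0.4, 0.53, 0.8, 1.1, 1.6, 2.2, 3.2)
}
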