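#' Viewing geometry of the experimental display
#'
#' Records the physical geometry that maps on-screen millimetres and pixels to
#' visual angle at the animal's eye: the distance from the eye to the monitor,
#' the pixel pitch of the panel, the frame size in pixels, and (for record
#' keeping only) the radius of the cylindrical experimental container. The
#' container curvature blurs and shrinks the image in the curved plane, so
#' behavioural resolution measured through it is a limiting value; no optical
#' model of the vessel is applied.
#'
#' @param viewing_distance_mm Distance from eye to screen in mm (default 50,
#'   i.e. the 5 cm used in the behavioural setup).
#' @param pixel_pitch_mm Physical width of one pixel in mm (default 0.25, a
#'   typical ~100 dpi LCD panel; the study monitor's pitch is not reported, so
#'   absolute pixel sizes are configuration-dependent).
#' @param frame_width_px,frame_height_px Frame dimensions in pixels.
#' @param container_radius_mm Radius of the cylindrical vessel in mm (default
#'   60, i.e. the 12 cm diameter container); recorded, not modelled.
#' @return An object of class `viewing_config`.
#' @examples
#' cfg <- viewing_config()
#' angular_size(100, cfg)   # 90 deg at 50 mm
#' @export
viewing_config <- function(viewing_distance_mm = 50, pixel_pitch_mm = 0.25,
                           frame_width_px = 400, frame_height_px = 400,
                           container_radius_mm = 60) {
  if (!is.numeric(viewing_distance_mm) || viewing_distance_mm <= 0)
    stop("viewing_distance_mm must be > 0", call. = FALSE)
  if (!is.numeric(pixel_pitch_mm) || pixel_pitch_mm <= 0)
    stop("pixel_pitch_mm must be > 0", call. = FALSE)
  frame_width_px <- as.integer(frame_width_px)
  frame_height_px <- as.integer(frame_height_px)
  if (frame_width_px < 1L || frame_height_px < 1L)
    stop("frame dimensions must be >= 1 pixel", call. = FALSE)
  structure(
    list(viewing_distance_mm = viewing_distance_mm,
         pixel_pitch_mm = pixel_pitch_mm,
         frame_width_px = frame_width_px,
         frame_height_px = frame_height_px,
         container_radius_mm = container_radius_mm),
    class = "viewing_config")
}

#' Visual angle subtended by a physical width
#'
#' Standard flat-screen visual-angle geometry: an object of width `w` centred
#' on the line of sight at distance `D` subtends `2 * atan(w / (2 * D))`.
#'
#' @param physical_width_mm Object width in mm (>= 0); vectorised.
#' @param cfg A [viewing_config()].
#' @return Angular size in degrees.
#' @seealso [physical_width()], its exact inverse.
#' @export
angular_size <- function(physical_width_mm, cfg = viewing_config()) {
  stopifnot(inherits(cfg, "viewing_config"))
  if (any(physical_width_mm < 0)) stop("physical width must be >= 0", call. = FALSE)
  2 * atan(physical_width_mm / (2 * cfg$viewing_distance_mm)) * 180 / pi
}

#' On-screen width of a given visual angle
#'
#' Inverse of [angular_size()]: `w = 2 * D * tan(angle / 2)`. Angles of 180
#' degrees or more cannot be produced on a flat screen.
#'
#' @param angle_deg Angular size in degrees, `0 <= angle < 180`; vectorised.
#' @param cfg A [viewing_config()].
#' @return Physical width in mm.
#' @export
physical_width <- function(angle_deg, cfg = viewing_config()) {
  stopifnot(inherits(cfg, "viewing_config"))
  if (any(angle_deg < 0) || any(angle_deg >= 180))
    stop("angle must be in [0, 180) degrees", call. = FALSE)
  2 * cfg$viewing_distance_mm * tan(angle_deg / 2 * pi / 180)
}

#' Angular size of one pixel
#'
#' Convenience for the smallest renderable object, used as the default seed
#' size of the exponential expansion profile.
#'
#' @param cfg A [viewing_config()].
#' @return Angular size of one pixel in degrees.
#' @export
pixel_angle <- function(cfg = viewing_config()) {
  angular_size(cfg$pixel_pitch_mm, cfg)
}

#' Angular expansion profile of a looming stimulus
#'
#' Describes how the angular size of the expanding circle grows with time.
#' Two shapes are supported, following the two behavioural paradigms:
#' `"exponential"` (contrast-sensitivity experiment; angular size grows as
#' `alpha_start * exp(gamma * t)` over 10 s) and `"linear"`
#' (spatial-resolution experiment; angular size grows as `alpha_max * t / T`
#' over 5 s). Both reach `alpha_max` (83 deg) exactly at `t = T`.
#'
#' The exponential profile cannot start at 0 deg; `alpha_start` defaults to
#' the angular size of one pixel at the default viewing geometry (~0.29 deg),
#' the smallest renderable object.
#'
#' @param shape `"exponential"` or `"linear"`.
#' @param duration_s Stimulus duration T in seconds. Defaults to 10 for the
#'   exponential profile and 5 for the linear one.
#' @param alpha_max_deg Final angular size in degrees (default 83).
#' @param alpha_start_deg Seed angular size for the exponential profile
#'   (ignored by the linear profile's trajectory, retained for record).
#' @param frame_rate Frames per second for rendering (default 60).
#' @return An object of class `expansion_profile`.
#' @examples
#' p <- expansion_profile("exponential", alpha_start_deg = 0.1)
#' alpha_at(p, 5)   # geometric mean of 0.1 and 83
#' @export
expansion_profile <- function(shape = c("exponential", "linear"),
                              duration_s = NULL, alpha_max_deg = 83,
                              alpha_start_deg = NULL, frame_rate = 60) {
  shape <- match.arg(shape)
  if (is.null(duration_s)) duration_s <- if (shape == "exponential") 10 else 5
  if (is.null(alpha_start_deg)) alpha_start_deg <- pixel_angle(viewing_config())
  if (duration_s <= 0) stop("duration must be > 0", call. = FALSE)
  if (alpha_start_deg <= 0 || alpha_start_deg > alpha_max_deg || alpha_max_deg > 180)
    stop("need 0 < alpha_start <= alpha_max <= 180", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be > 0", call. = FALSE)
  structure(
    list(shape = shape, duration_s = duration_s,
         alpha_max_deg = alpha_max_deg, alpha_start_deg = alpha_start_deg,
         frame_rate = frame_rate),
    class = "expansion_profile")
}

#' Angular size of the stimulus at time t
#'
#' Linear shape: `alpha(t) = alpha_max * t / T`. Exponential shape:
#' `alpha(t) = alpha_start * exp(gamma * t)` with
#' `gamma = log(alpha_max / alpha_start) / T`, so that `alpha(T) = alpha_max`
#' in both cases. A degenerate exponential profile with
#' `alpha_start == alpha_max` is the constant `alpha_max`.
#'
#' @param profile An [expansion_profile()].
#' @param t Time in seconds, within `[0, T]`; vectorised.
#' @return Angular size in degrees.
#' @export
alpha_at <- function(profile, t) {
  stopifnot(inherits(profile, "expansion_profile"))
  if (any(t < 0) || any(t > profile$duration_s))
    stop("t outside [0, duration]", call. = FALSE)
  if (profile$shape == "linear") {
    profile$alpha_max_deg * t / profile$duration_s
  } else {
    g <- log(profile$alpha_max_deg / profile$alpha_start_deg) / profile$duration_s
    profile$alpha_start_deg * exp(g * t)
  }
}

#' Time at which the stimulus reaches a given angular size
#'
#' Exact inverse of [alpha_at()], used to re-express behavioural event times
#' as stimulus angular sizes (and vice versa when simulating trials).
#'
#' @param profile An [expansion_profile()].
#' @param angle_deg Target angular size in degrees; must lie within the
#'   profile's attainable range (`[0, alpha_max]` linear;
#'   `[alpha_start, alpha_max]` exponential); vectorised.
#' @return Time in seconds.
#' @export
time_to_reach <- function(profile, angle_deg) {
  stopifnot(inherits(profile, "expansion_profile"))
  if (profile$shape == "linear") {
    if (any(angle_deg < 0) || any(angle_deg > profile$alpha_max_deg))
      stop("angle outside [0, alpha_max]", call. = FALSE)
    profile$duration_s * angle_deg / profile$alpha_max_deg
  } else {
    if (any(angle_deg < profile$alpha_start_deg) ||
        any(angle_deg > profile$alpha_max_deg))
      stop("angle outside [alpha_start, alpha_max]", call. = FALSE)
    g <- log(profile$alpha_max_deg / profile$alpha_start_deg) / profile$duration_s
    if (g == 0) return(rep(0, length(angle_deg)))  # degenerate constant profile
    log(angle_deg / profile$alpha_start_deg) / g
  }
}
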