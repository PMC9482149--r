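#' Anatomical measurements of a camera-type eye
#'
#' Container for the micrometre-scale measurements from which acuity and
#' sensitivity are estimated. Defaults are the study eye: rhabdom-centre
#' separation s = 6.5 um, focal length f = 720 um, aperture A = 630 um,
#' rhabdom diameter d = 6.6 um, rhabdom length x = 70.9 um, absorption
#' coefficient k = 0.0067 per um (the lobster-rhabdom value conventionally
#' used for invertebrate photoreceptors). If a lens radius `r_um` is given,
#' the focal length follows the strombid convention f = 2r; supplying both
#' with `f != 2r` draws a warning.
#'
#' @param s_um Rhabdom-centre separation (um).
#' @param f_um Focal length (um); derived as `2 * r_um` when omitted.
#' @param A_um Aperture diameter (um).
#' @param d_um Rhabdom diameter (um).
#' @param x_um Rhabdom length (um).
#' @param k_per_um Absorption coefficient (um^-1).
#' @param r_um Optional lens radius (um).
#' @return An object of class `eye_anatomy`.
#' @export
eye_anatomy <- function(s_um = 6.5, f_um = NULL, A_um = 630, d_um = 6.6,
                        x_um = 70.9, k_per_um = 0.0067, r_um = NULL) {
  if (is.null(f_um)) {
    if (is.null(r_um)) f_um <- 720 else f_um <- 2 * r_um
  } else if (!is.null(r_um) && !isTRUE(all.equal(f_um, 2 * r_um))) {
    warning("focal length differs from 2 * lens radius (f = 2r convention)",
            call. = FALSE)
  }
  vals <- c(s = s_um, f = f_um, A = A_um, d = d_um, x = x_um, k = k_per_um)
  if (any(vals <= 0)) stop("all anatomical quantities must be > 0", call. = FALSE)
  structure(list(s_um = s_um, f_um = f_um, A_um = A_um, d_um = d_um,
                 x_um = x_um, k_per_um = k_per_um, r_um = r_um),
            class = "eye_anatomy")
}

#' Inter-receptor angle
#'
#' The angle between the viewing directions of adjacent photoreceptors,
#' `delta_phi = s / f` radians (small-angle form; at these magnitudes the
#' arctangent differs by under 1e-4 deg), converted to degrees. Warns when
#' `s / f > 0.1` rad, where the small-angle form degrades.
#'
#' @param s_um Rhabdom-centre separation (um), or an [eye_anatomy()].
#' @param f_um Focal length (um); ignored when `s_um` is an `eye_anatomy`.
#' @return Inter-receptor angle in degrees.
#' @examples
#' inter_receptor_angle(6.5, 720)   # 0.517 deg -> reported as 0.52
#' @export
inter_receptor_angle <- function(s_um, f_um = NULL) {
  if (inherits(s_um, "eye_anatomy")) {
    f_um <- s_um$f_um; s_um <- s_um$s_um
  }
  if (s_um < 0 || f_um <= 0) stop("need s >= 0 and f > 0", call. = FALSE)
  if (s_um / f_um > 0.1)
    warning("s/f exceeds 0.1 rad; small-angle form is inaccurate", call. = FALSE)
  s_um / f_um * 180 / pi
}

#' Anatomical angular resolution
#'
#' Twice the inter-receptor angle: the finest grating period the receptor
#' mosaic can sample (one receptor per light and dark bar).
#'
#' @inheritParams inter_receptor_angle
#' @return Angular resolution `2 * delta_phi` in degrees, unrounded.
#' @seealso [report_optical_estimates()] for the reporting convention.
#' @export
anatomical_resolution <- function(s_um, f_um = NULL) {
  2 * inter_receptor_angle(s_um, f_um)
}

#' Optical sensitivity of the eye
#'
#' Land's sensitivity for an extended source:
#' `S = (pi/4)^2 * A^2 * (d/f)^2 * (1 - exp(-k * x))`, in um^2 sr --
#' aperture area times the solid angle seen by one rhabdom times the fraction
#' of entering photons absorbed along the rhabdom length.
#'
#' @param anatomy An [eye_anatomy()].
#' @return Sensitivity S in um^2 sr.
#' @examples
#' optical_sensitivity(eye_anatomy())  # 7.78 um^2 sr for the study eye
#' @export
optical_sensitivity <- function(anatomy = eye_anatomy()) {
  stopifnot(inherits(anatomy, "eye_anatomy"))
  (pi / 4)^2 * anatomy$A_um^2 * (anatomy$d_um / anatomy$f_um)^2 *
    (1 - exp(-anatomy$k_per_um * anatomy$x_um))
}

#' Derived optical estimates for an eye
#'
#' @param anatomy An [eye_anatomy()].
#' @return List of class `optical_estimates` with unrounded `delta_phi_deg`,
#'   `resolution_deg` (= 2 * delta_phi) and `S_um2_sr`.
#' @export
optical_estimates <- function(anatomy = eye_anatomy()) {
  dphi <- inter_receptor_angle(anatomy)
  structure(list(delta_phi_deg = dphi,
                 resolution_deg = 2 * dphi,
                 S_um2_sr = optical_sensitivity(anatomy)),
            class = "optical_estimates")
}

#' Optical estimates with the study's reporting conventions
#'
#' Angles are reported to 2 decimals and the resolution as twice the
#' *rounded* inter-receptor angle (so a 0.52-deg inter-receptor angle is
#' reported as a 1.04-deg resolution), matching how such estimates are
#' conventionally printed; sensitivity to 2 decimals.
#'
#' @param anatomy An [eye_anatomy()].
#' @param digits Rounding for angles and S (default 2).
#' @return Data frame with columns `quantity`, `value`, `units`.
#' @export
report_optical_estimates <- function(anatomy = eye_anatomy(), digits = 2) {
  dphi <- round(inter_receptor_angle(anatomy), digits)
  data.frame(
    quantity = c("inter_receptor_angle", "angular_resolution",
                 "optical_sensitivity"),
    value = c(dphi, 2 * dphi, round(optical_sensitivity(anatomy), digits)),
    units = c("deg", "deg", "um^2 sr"),
    stringsAsFactors = FALSE)
}

#' Retinal cell-count sample
#'
#' Cell counts within a sectioned patch of retina, with the sampled and total
#' retinal areas needed to extrapolate a per-eye census. The default sampled
#' area is 2048 um^2 (a 204.8 um block-face width by a 10 um run depth of one
#' hundred 100-nm sections) and the default total retinal area 1.7 mm^2.
#' Note the sampled area is stored in um^2: the study's printed
#' "2.048 x 10^3 mm^2" is dimensionally inconsistent with its own
#' extrapolation and must be read as 2.048 x 10^-3 mm^2.
#'
#' @param counts Named non-negative integer vector of cell counts per class
#'   (e.g. SPC, PRC_I..PRC_IV, GC), or a single total count.
#' @param sampled_area_um2 Sectioned area in um^2 (> 0).
#' @param total_area_mm2 Total retinal area in mm^2 (> 0).
#' @param grain Rounding grain for per-eye totals in cells (default 100).
#' @return An object of class `retina_sample`.
#' @export
retina_sample <- function(counts, sampled_area_um2 = 204.8 * 10,
                          total_area_mm2 = 1.7, grain = 100) {
  if (sampled_area_um2 <= 0 || total_area_mm2 <= 0)
    stop("areas must be > 0", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(counts = counts, sampled_area_um2 = sampled_area_um2,
                 total_area_mm2 = total_area_mm2, grain = grain),
            class = "retina_sample")
}

#' Extrapolate a sampled cell count to a per-eye total
#'
#' `total = count * (total_area / sampled_area)`, rounded to the configured
#' grain (nearest 100 cells by default). The 189 cells of the study sample
#' extrapolate to 156,900, i.e. the printed 1.57e5 retinal cells per eye.
#'
#' @param sample A [retina_sample()].
#' @param class One class name, or `"all"` (default) for the summed count.
#' @param rounded Apply the grain rounding (default TRUE).
#' @return Estimated cells per eye.
#' @export
extrapolate_total <- function(sample, class = "all", rounded = TRUE) {
  stopifnot(inherits(sample, "retina_sample"))
  count <- if (identical(class, "all")) sum(sample$counts)
           else sample$counts[[class]]
  est <- count * (sample$total_area_mm2 * 1e6 / sample$sampled_area_um2)
  if (rounded) round(est / sample$grain) * sample$grain else est
}

#' Areal cell density of a sample
#'
#' @param sample A [retina_sample()].
#' @param class One class name or `"all"`.
#' @return Cells per mm^2, unrounded.
#' @export
cell_density <- function(sample, class = "all") {
  stopifnot(inherits(sample, "retina_sample"))
  count <- if (identical(class, "all")) sum(sample$counts)
           else sample$counts[[class]]
  count / (sample$sampled_area_um2 / 1e6)
}

#' Per-eye total from an areal density
#'
#' `total = density * area`, reported to 3 significant figures: the route by
#' which the 23,400 per mm^2 density of the main photoreceptor class gives
#' 3.98e4 cells per eye over 1.7 mm^2.
#'
#' @param density_per_mm2 Cells per mm^2 (>= 0).
#' @param total_area_mm2 Retinal area in mm^2 (> 0).
#' @return Cells per eye, 3 significant figures.
#' @export
total_from_density <- function(density_per_mm2, total_area_mm2 = 1.7) {
  if (density_per_mm2 < 0 || total_area_mm2 <= 0)
    stop("need density >= 0 and area > 0", call. = FALSE)
  signif(density_per_mm2 * total_area_mm2, 3)
}

# signed FFT frequency magnitudes in cycles per sample
fft_freq <- function(n) {
  k <- 0:(n - 1)
  pmin(k, n - k) / n
}

#' Acuity-limited blurring of an image
#'
#' Low-pass filters a luminance image through the modulation transfer
#' function `MTF(nu) = exp(-3.56 * (mra * nu)^2)` with `nu` in cycles per
#' degree, the Gaussian MTF whose amplitude falls to about 2.8% at the
#' minimum resolvable angle's spatial frequency `nu = 1/mra`. This renders a
#' scene as it appears to an eye of the given acuity. Filtering is done in
#' the Fourier domain with periodic boundaries; mean luminance is preserved
#' exactly (MTF(0) = 1) and image variance never increases.
#'
#' @param image Numeric matrix of luminances (any linear scale).
#' @param mra_deg Minimum resolvable angle in degrees (> 0).
#' @param pixels_per_degree Angular sampling of the image (px/deg, > 0).
#' @return Blurred matrix, same dimensions.
#' @export
acuity_blur <- function(image, mra_deg, pixels_per_degree) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite numeric matrix", call. = FALSE)
  if (mra_deg <= 0) stop("mra_deg must be > 0", call. = FALSE)
  if (pixels_per_degree <= 0) stop("pixels_per_degree must be > 0", call. = FALSE)
  fy <- fft_freq(nrow(image)) * pixels_per_degree  # cycles/deg
  fx <- fft_freq(ncol(image)) * pixels_per_degree
  nu2 <- outer(fy^2, fx^2, "+")
  mtf <- exp(-3.56 * mra_deg^2 * nu2)
  Re(stats::fft(stats::fft(image) * mtf, inverse = TRUE)) / length(image)
}
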