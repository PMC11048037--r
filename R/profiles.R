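#' Observer profile: age and iris pigmentation
#'
#' Bundles the two observer-dependent terms of the CIE disability-glare
#' equation: age `A` in years and the iris pigmentation coefficient `p`
#' (0 very dark, 0.5 dark, 1.0 light, 1.2 very light eyes).
#'
#' @param age Observer age in years (> 0; the age factor is calibrated for
#'   19--75 and clamps outside that range with a warning).
#' @param pigmentation Iris pigmentation coefficient in `[0, 1.2]`.
#' @return An object of class `observer_profile`.
#' @examples
#' observer_profile(30, 0.5)
#' @export
observer_profile <- function(age = 30, pigmentation = 0.5) {
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0) {
    abort("`age` must be a single positive number.")
  }
  if (!is.numeric(pigmentation) || length(pigmentation) != 1L ||
      pigmentation < 0 || pigmentation > 1.2) {
    abort("`pigmentation` must lie in [0, 1.2].")
  }
  structure(list(age = age, pigmentation = pigmentation),
            class = "observer_profile")
}

#' Scene conditions: ambient luminance, target contrast and size
#'
#' @param ambient_luminance Background (adaptation) luminance `L_b` in cd/m²;
#'   must be positive.
#' @param target_contrast Intrinsic target contrast `C_orig` in `(0, 1]`,
#'   the contrast of the target in the absence of any laser field.
#' @param target_size_deg Full angular subtense of the target in degrees.
#' @return An object of class `scene_conditions`.
#' @examples
#' scene_conditions(13.14, 0.89, 2.75)
#' @export
scene_conditions <- function(ambient_luminance, target_contrast,
                             target_size_deg) {
  if (ambient_luminance <= 0) abort("`ambient_luminance` must be > 0.")
  if (target_contrast <= 0 || target_contrast > 1) {
    abort("`target_contrast` must lie in (0, 1].")
  }
  if (target_size_deg <= 0) abort("`target_size_deg` must be > 0.")
  structure(list(ambient_luminance = ambient_luminance,
                 target_contrast = target_contrast,
                 target_size_deg = target_size_deg),
            class = "scene_conditions")
}

#' Laser exposure at the eye plane
#'
#' @param wavelength_nm Laser wavelength in nm, within the photopic band
#'   380--780 nm.
#' @param eye_irradiance Radiant power density at the cornea in mW/cm².
#' @param incidence_angle_deg Angle between the laser source and the line of
#'   sight, degrees (> 0).
#' @return An object of class `laser_exposure`.
#' @export
laser_exposure <- function(wavelength_nm = 532, eye_irradiance = 0,
                           incidence_angle_deg = 0.5) {
  if (wavelength_nm < 380 || wavelength_nm > 780) {
    abort("`wavelength_nm` must lie in [380, 780] (photopic band).")
  }
  if (eye_irradiance < 0) abort("`eye_irradiance` must be >= 0.")
  if (incidence_angle_deg <= 0) abort("`incidence_angle_deg` must be > 0.")
  structure(list(wavelength_nm = wavelength_nm,
                 eye_irradiance = eye_irradiance,
                 incidence_angle_deg = incidence_angle_deg),
            class = "laser_exposure")
}

#' Laser source description
#'
#' Far-field source model: a circular top-hat beam of diameter
#' `d0 + divergence * distance`.
#'
#' @param power_mW Average output power, mW.
#' @param divergence_mrad Full-angle beam divergence, mrad.
#' @param initial_beam_diameter_m Exit beam diameter `d0` in metres
#'   (default 0).
#' @param distance_m Propagation distance to the eye in metres.
#' @param wavelength_nm Centre wavelength in nm.
#' @return An object of class `laser_source`.
#' @examples
#' laser_source(100, 1.5, distance_m = 300)
#' @export
laser_source <- function(power_mW = 100, divergence_mrad = 1.5,
                         initial_beam_diameter_m = 0, distance_m = 100,
                         wavelength_nm = 532) {
  if (power_mW <= 0) abort("`power_mW` must be > 0.")
  if (divergence_mrad <= 0) abort("`divergence_mrad` must be > 0.")
  if (initial_beam_diameter_m < 0) abort("`initial_beam_diameter_m` must be >= 0.")
  if (distance_m < 0) abort("`distance_m` must be >= 0.")
  structure(list(power_mW = power_mW, divergence_mrad = divergence_mrad,
                 initial_beam_diameter_m = initial_beam_diameter_m,
                 distance_m = distance_m, wavelength_nm = wavelength_nm),
            class = "laser_source")
}

# CIE 1924 photopic luminous efficiency V(lambda), 380-780 nm at 5 nm steps.
cie_photopic_table <- function() {
  tibble::tibble(
    wavelength_nm = seq(380, 780, by = 5),
    efficiency = c(
      0.000039, 0.000064, 0.000120, 0.000217, 0.000396, 0.000640, 0.001210,
      0.002180, 0.004000, 0.007300, 0.011600, 0.016840, 0.023000, 0.029800,
      0.038000, 0.048000, 0.060000, 0.073900, 0.090980, 0.112600, 0.139020,
      0.169300, 0.208020, 0.258600, 0.323000, 0.407300, 0.503000, 0.608200,
      0.710000, 0.793200, 0.862000, 0.914850, 0.954000, 0.980300, 0.994950,
      1.000000, 0.995000, 0.978600, 0.952000, 0.915400, 0.870000, 0.816300,
      0.757000, 0.694900, 0.631000, 0.566800, 0.503000, 0.441200, 0.381000,
      0.321000, 0.265000, 0.217000, 0.175000, 0.138200, 0.107000, 0.081600,
      0.061000, 0.044580, 0.032000, 0.023200, 0.017000, 0.011920, 0.008210,
      0.005723, 0.004102, 0.002929, 0.002091, 0.001484, 0.001047, 0.000740,
      0.000520, 0.000361, 0.000249, 0.000172, 0.000120, 0.0000848, 0.0000600,
      0.0000424, 0.0000300, 0.0000212, 0.0000150
    )
  )
}

#' Photopic luminous efficiency V(lambda)
#'
#' Linear interpolation of the CIE 1924 photopic efficiency table
#' (380--780 nm, 5 nm resolution). `V(555) = 1` by definition.
#'
#' @param wavelength_nm Wavelength(s) in nm.
#' @return Dimensionless efficiency in `[0, 1]`.
#' @examples
#' photopic_efficiency(555)
#' photopic_efficiency(532)
#' @export
photopic_efficiency <- function(wavelength_nm) {
  tab <- cie_photopic_table()
  if (any(wavelength_nm < 380 | wavelength_nm > 780)) {
    abort("wavelength outside the photopic table support [380, 780] nm.")
  }
  approx(tab$wavelength_nm, tab$efficiency, xout = wavelength_nm)$y
}

#' Glare-model calibration constants
#'
#' Holds the empirical calibration of the veiling-luminance model:
#' `s1 = 0.9147`, `t1 = 0.1775` (background-luminance scaling of the veil),
#' the luminous efficacy constant `C = 683` lm/W, and the photopic
#' efficiency function. The threshold-contrast calibration functions
#' `sqrt_phi(L_b)` and `sqrt_l(L_b)` (Adrian-style visibility functions;
#' see [threshold_contrast()]) are pluggable here.
#'
#' @param s1,t1 Veil calibration coefficients.
#' @param luminous_efficacy_constant lm/W conversion constant (683).
#' @param photopic Function mapping wavelength (nm) to V(lambda).
#' @param sqrt_phi,sqrt_l Functions of background luminance (cd/m²) used by
#'   the threshold-contrast model; defaults are the Adrian (1989)
#'   small-target visibility functions.
#' @return An object of class `glare_calibration`.
#' @export
glare_calibration <- function(s1 = 0.9147, t1 = 0.1775,
                              luminous_efficacy_constant = 683,
                              photopic = photopic_efficiency,
                              sqrt_phi = adrian_sqrt_phi,
                              sqrt_l = adrian_sqrt_l) {
  if (s1 <= 0) abort("`s1` must be > 0.")
  if (t1 <= 0 || t1 >= 1) abort("`t1` must lie in (0, 1).")
  if (luminous_efficacy_constant != 683) {
    abort("`luminous_efficacy_constant` is fixed at 683 lm/W.")
  }
  structure(list(s1 = s1, t1 = t1,
                 luminous_efficacy_constant = luminous_efficacy_constant,
                 photopic = photopic, sqrt_phi = sqrt_phi, sqrt_l = sqrt_l),
            class = "glare_calibration")
}

#' @export
print.observer_profile <- function(x, ...) {
  cat(sprintf("<observer_profile> age %g y, pigmentation %g\n",
              x$age, x$pigmentation))
  invisible(x)
}

#' @export
print.scene_conditions <- function(x, ...) {
  cat(sprintf(
    "<scene_conditions> L_b %g cd/m2, C_orig %g, target %g deg\n",
    x$ambient_luminance, x$target_contrast, x$target_size_deg))
  invisible(x)
}

#' @export
print.laser_source <- function(x, ...) {
  cat(sprintf(
    "<laser_source> %g mW @ %g nm, %g mrad, d0 %g m, L %g m\n",
    x$power_mW, x$wavelength_nm, x$divergence_mrad,
    x$initial_beam_diameter_m, x$distance_m))
  invisible(x)
}
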