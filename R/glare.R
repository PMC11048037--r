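#' CIE disability-glare function
#'
#' Angular kernel of the CIE general disability-glare equation: veiling
#' luminance per unit corneal illuminance as a function of glare angle
#' `theta` (degrees), observer age `A` and iris pigmentation `p`:
#' \deqn{g(\theta, A, p) = 10/\theta^3 +
#'   \left[5/\theta^2 + 0.1 p/\theta\right]\left[1 + (A/62.5)^4\right] +
#'   0.0025 p.}
#'
#' @param theta_deg Glare angle(s) in degrees; must be > 0.
#' @param observer An [observer_profile()].
#' @return Glare kernel value(s), sr^-1 by CIE convention (treated as
#'   dimensionless here); strictly decreasing in `theta_deg`.
#' @examples
#' glare_function(1, observer_profile(30, 0.5))
#' @export
glare_function <- function(theta_deg, observer = observer_profile()) {
  if (any(!is.finite(theta_deg)) || any(theta_deg <= 0)) {
    abort("`theta_deg` must be positive.")
  }
  A <- observer$age
  p <- observer$pigmentation
  10 / theta_deg^3 +
    (5 / theta_deg^2 + 0.1 * p / theta_deg) * (1 + (A / 62.5)^4) +
    0.0025 * p
}

#' Age factor of the threshold-contrast model
#'
#' Two-branch quadratic age factor: `(A-19)^2/2160 + 0.99` up to age 64 and
#' `(A-56.6)^2/116.3 + 1.43` above. Ages outside 19--75 are clamped to the
#' calibrated range with a warning.
#'
#' @param age Age(s) in years.
#' @return Dimensionless age factor, >= 0.99.
#' @examples
#' age_factor(30)
#' age_factor(70)
#' @export
age_factor <- function(age) {
  clamped <- pmin(pmax(age, 19), 75)
  if (any(clamped != age)) {
    warn("age outside the calibrated range [19, 75]; clamped.")
  }
  ifelse(clamped <= 64,
         (clamped - 19)^2 / 2160 + 0.99,
         (clamped - 56.6)^2 / 116.3 + 1.43)
}

#' Adrian visibility calibration functions
#'
#' Luminance-dependent terms of the small-target visibility threshold model
#' (Adrian 1989): `adrian_sqrt_phi` is the square root of the luminous-flux
#' term Phi and `adrian_sqrt_l` the square root of the luminance term, each
#' defined piecewise over three adaptation-luminance regimes (below
#' 0.00418 cd/m², 0.00418--0.6 cd/m², and photopic above 0.6 cd/m²). The
#' branches join continuously to within ~2%.
#'
#' @param lb Background luminance(s), cd/m² (> 0).
#' @return Calibration value(s) used by [threshold_contrast()].
#' @export
adrian_sqrt_phi <- function(lb) {
  if (any(lb <= 0)) abort("background luminance must be > 0.")
  x <- log10(lb)
  ifelse(lb >= 0.6,
         log10(4.1925 * lb^0.1556) + 0.1684 * lb^0.5867,
         ifelse(lb >= 0.00418,
                10^(-0.072 + 0.3372 * x + 0.0866 * x^2),
                10^(0.028 + 0.173 * x)))
}

#' @rdname adrian_sqrt_phi
#' @export
adrian_sqrt_l <- function(lb) {
  if (any(lb <= 0)) abort("background luminance must be > 0.")
  x <- log10(lb)
  ifelse(lb >= 0.6,
         0.05946 * lb^0.466,
         ifelse(lb >= 0.00418,
                10^(-1.256 + 0.319 * x),
                10^(-0.891 + 0.5275 * x + 0.0227 * x^2)))
}

#' Visual (photometric) corneal illuminance
#'
#' Converts the radiometric eye-plane irradiance to photometric illuminance:
#' `E_v = 683 * V(lambda) * E_e` with `E_e` in W/m² (the exposure stores
#' mW/cm²; 1 mW/cm² = 10 W/m²).
#'
#' @param exposure A [laser_exposure()].
#' @param calib A [glare_calibration()].
#' @return Illuminance in lm/m² (lux).
#' @examples
#' visual_corneal_illuminance(laser_exposure(555, eye_irradiance = 0.1))
#' @export
visual_corneal_illuminance <- function(exposure, calib = glare_calibration()) {
  e_wm2 <- exposure$eye_irradiance * 10
  calib$luminous_efficacy_constant * calib$photopic(exposure$wavelength_nm) *
    e_wm2
}

#' Veiling luminance produced by a glare source
#'
#' Equivalent veiling luminance superimposed on the retinal image by
#' intraocular scattering of the laser:
#' `L_v = S1 * L_b^T1 * g(theta, A, p) * E_v`, where `E_v` is the visual
#' corneal illuminance and `S1 = 0.9147`, `T1 = 0.1775` calibrate the
#' background-luminance dependence.
#'
#' @param theta_deg Glare angle(s), degrees.
#' @param observer An [observer_profile()].
#' @param scene A [scene_conditions()].
#' @param exposure A [laser_exposure()].
#' @param calib A [glare_calibration()].
#' @return Veiling luminance in cd/m²; linear in eye irradiance and
#'   decreasing in `theta_deg`.
#' @export
veiling_luminance <- function(theta_deg, observer, scene, exposure,
                              calib = glare_calibration()) {
  calib$s1 * scene$ambient_luminance^calib$t1 *
    glare_function(theta_deg, observer) *
    visual_corneal_illuminance(exposure, calib)
}

#' Threshold contrast for target detection
#'
#' Minimum contrast the eye needs to detect a target of angular size `a`
#' (degrees) against background luminance `L_b`:
#' `C_thr = Omega(L_b, a) * AF(A)` with
#' `Omega = 2.6 * (sqrt_phi(L_b)/(60 a) + sqrt_l(L_b))^2 / L_b`
#' (the `60 a` converts the subtense to arcminutes). The calibration
#' functions default to the Adrian visibility functions and can be replaced
#' through [glare_calibration()].
#'
#' @inheritParams veiling_luminance
#' @return Dimensionless threshold contrast; decreasing in target size,
#'   increasing in the age factor.
#' @examples
#' threshold_contrast(scene_conditions(13.14, 0.89, 2.75), observer_profile(30, 0.5))
#' @export
threshold_contrast <- function(scene, observer = observer_profile(),
                               calib = glare_calibration()) {
  a <- scene$target_size_deg
  if (a <= 0) abort("target angular size must be > 0.")
  lb <- scene$ambient_luminance
  omega <- 2.6 * (calib$sqrt_phi(lb) / (60 * a) + calib$sqrt_l(lb))^2 / lb
  omega * age_factor(observer$age)
}

#' Effective target contrast under a veiling luminance
#'
#' Standard veiling-glare contrast reduction:
#' `C_w = C_orig * L_b / (L_b + L_v)`.
#'
#' @param scene A [scene_conditions()].
#' @param veiling Veiling luminance(s) `L_v`, cd/m² (>= 0).
#' @return Effective contrast, equal to `C_orig` when `L_v = 0` and
#'   strictly decreasing in `L_v`.
#' @export
effective_contrast <- function(scene, veiling) {
  if (any(veiling < 0)) abort("`veiling` must be >= 0.")
  scene$target_contrast * scene$ambient_luminance /
    (scene$ambient_luminance + veiling)
}

masked_at <- function(theta_deg, observer, scene, exposure, calib) {
  lv <- veiling_luminance(theta_deg, observer, scene, exposure, calib)
  effective_contrast(scene, lv) < threshold_contrast(scene, observer, calib)
}

#' Dazzle (target occlusion) angle
#'
#' The largest glare angle `U` at which the veiling luminance pushes the
#' target's effective contrast below the detection threshold, i.e. the
#' angular extent of the region around the laser within which the target is
#' masked. Solved by bisection on `[0.01, 90]` degrees; the veil is strictly
#' decreasing in angle, so the masked region is the interval `(0, U)` and
#' the root is unique.
#'
#' @inheritParams veiling_luminance
#' @param tol Bisection tolerance in degrees.
#' @return Dazzle angle in degrees; 0 when no angle is masked (e.g. zero
#'   irradiance), 90 with a warning when even the largest angle is masked.
#' @export
dazzle_angle <- function(observer, scene, exposure,
                         calib = glare_calibration(), tol = 1e-4) {
  if (exposure$eye_irradiance < 0) abort("eye irradiance must be >= 0.")
  if (exposure$eye_irradiance == 0) return(0)
  lo <- 0.01
  hi <- 90
  if (!masked_at(lo, observer, scene, exposure, calib)) return(0)
  if (masked_at(hi, observer, scene, exposure, calib)) {
    warn("target masked even at 90 deg; returning the upper bracket bound.")
    return(hi)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (masked_at(mid, observer, scene, exposure, calib)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Maximum dazzle exposure (MDE)
#'
#' The eye irradiance at which the dazzle extent just reaches angle
#' `theta_deg`: closed-form inversion of the masking criterion, the `E`
#' such that `L_v(theta, E) = L_b * (C_orig / C_thr - 1)`.
#'
#' @param theta_deg Reference glare angle, degrees (> 0).
#' @inheritParams veiling_luminance
#' @param wavelength_nm Laser wavelength for the photometric conversion.
#' @return MDE in mW/cm²; strictly increasing in `theta_deg`.
#' @export
mde <- function(theta_deg, observer, scene, calib = glare_calibration(),
                wavelength_nm = 532) {
  if (any(theta_deg <= 0)) abort("`theta_deg` must be > 0.")
  cthr <- threshold_contrast(scene, observer, calib)
  if (cthr >= scene$target_contrast) {
    abort("degenerate scene: target below detection threshold even unlit.")
  }
  lv_needed <- scene$ambient_luminance * (scene$target_contrast / cthr - 1)
  per_unit <- calib$s1 * scene$ambient_luminance^calib$t1 *
    glare_function(theta_deg, observer) *
    calib$luminous_efficacy_constant * calib$photopic(wavelength_nm) * 10
  lv_needed / per_unit
}

#' Eye-plane irradiance of a diverging beam
#'
#' Far-field top-hat model: the power spread uniformly over a disc of
#' diameter `d0 + divergence * distance`.
#'
#' @param source A [laser_source()].
#' @param distance_m Optional override of the source distance, m (> 0).
#' @return Irradiance at the eye in mW/cm²; strictly decreasing in distance.
#' @examples
#' eye_irradiance_at_distance(laser_source(100, 1.5, distance_m = 300))
#' @export
eye_irradiance_at_distance <- function(source, distance_m = source$distance_m) {
  if (any(distance_m <= 0)) abort("`distance_m` must be > 0.")
  diam_m <- source$initial_beam_diameter_m +
    source$divergence_mrad * 1e-3 * distance_m
  if (any(diam_m <= 0)) abort("zero beam area: check divergence and d0.")
  p_w <- source$power_mW * 1e-3
  irr_wm2 <- p_w / (pi / 4 * diam_m^2)
  irr_wm2 / 10
}

#' Maximum permissible exposure, visible CW, aversion response
#'
#' IEC-style MPE for continuous-wave visible lasers under the
#' aversion-response assumption: `18 * t^0.75 / t` W/m² for exposure
#' durations `0 < t <= 10` s (about 25.5 W/m² at the 0.25 s blink-reflex
#' time). Pulsed regimes and retinal thermal limits are out of scope; refer
#' to the full laser-safety standard for those.
#'
#' @param exposure_time_s Exposure duration in seconds, in (0, 10].
#' @return MPE in W/m².
#' @examples
#' mpe_visible_cw()          # 0.25 s aversion response
#' @export
mpe_visible_cw <- function(exposure_time_s = 0.25) {
  if (any(exposure_time_s <= 0 | exposure_time_s > 10)) {
    abort(paste("unsupported regime: only visible CW exposures of 0-10 s",
                "are implemented; consult the laser-safety standard."))
  }
  18 * exposure_time_s^0.75 / exposure_time_s
}

#' Nominal ocular hazard distance (NOHD)
#'
#' Distance at which the beam irradiance falls to the MPE:
#' `(sqrt(4 P / (pi * MPE)) - d0) / divergence`.
#'
#' @param source A [laser_source()].
#' @param mpe_wm2 MPE in W/m² (> 0).
#' @return NOHD in metres; 0 when the beam is below the MPE already at the
#'   exit aperture.
#' @examples
#' nohd(laser_source(100, 1.5))   # ~47.1 m
#' @export
nohd <- function(source, mpe_wm2 = mpe_visible_cw()) {
  if (mpe_wm2 <= 0) abort("`mpe_wm2` must be > 0.")
  p_w <- source$power_mW * 1e-3
  d_mpe <- sqrt(4 * p_w / (pi * mpe_wm2))
  dist <- (d_mpe - source$initial_beam_diameter_m) /
    (source$divergence_mrad * 1e-3)
  max(dist, 0)
}

#' Nominal ocular dazzle distance (NODD)
#'
#' Distance at which the beam irradiance falls to the maximum dazzle
#' exposure at a reference angle (default: the target's angular
#' half-extent). Beyond this distance the dazzle criterion at that angle is
#' no longer met.
#'
#' @param source A [laser_source()].
#' @inheritParams veiling_luminance
#' @param reference_angle_deg Angle at which the MDE is evaluated; defaults
#'   to half the target subtense.
#' @return NODD in metres; 0 when the criterion is never met (including a
#'   vanishing-power source).
#' @export
nodd <- function(source, observer, scene, calib = glare_calibration(),
                 reference_angle_deg = scene$target_size_deg / 2) {
  e_mde <- mde(reference_angle_deg, observer, scene, calib,
               wavelength_nm = source$wavelength_nm)
  if (!is.finite(e_mde) || e_mde <= 0) return(0)
  e_mde_wm2 <- e_mde * 10
  p_w <- source$power_mW * 1e-3
  d_mde <- sqrt(4 * p_w / (pi * e_mde_wm2))
  dist <- (d_mde - source$initial_beam_diameter_m) /
    (source$divergence_mrad * 1e-3)
  max(dist, 0)
}
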