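# Synthetic normative waveform templates.
#
# Each joint-angle waveform is a truncated Fourier series on cycle phase
# phi in [0,1): theta(phi) = a0 + sum_k a_k cos(2 pi k phi) + b_k sin(2 pi
# k phi), K = 6 harmonics (the top two zero by design so the waveforms stay
# well inside the passband of the kinematic-curve smoothing). The shapes
# are idealized smooth versions of healthy walking kinematics -- stance
# flexion wave and swing peak for the knee, reciprocal flexion/extension
# for the hip, dorsiflexion ramp and push-off plantarflexion for the ankle
# -- designed for peak calibratability, and are synthetic: they are not
# measurements of any cohort.

template_coefs <- list(
  knee_angle = list(a0 = 23.7947,
    a = c(-6.5068, -9.6634, -1.1575, -0.1323, 0, 0),
    b = c(-21.2831, 11.7681, 1.3813, 0.1143, 0, 0)),
  hip_flexion = list(a0 = 9.5171,
    a = c(20.4357, -1.8116, -0.0275, -0.1229, 0, 0),
    b = c(-7.8622, -1.4123, -0.0194, 0.0230, 0, 0)),
  hip_adduction = list(a0 = 0.9268,
    a = c(0.9455, -0.4565, -0.3518, -0.0442, 0, 0),
    b = c(5.6602, -0.6223, 0.0509, 0.0095, 0, 0)),
  hip_rotation = list(a0 = -2.1373,
    a = c(1.4945, -1.2723, -0.0718, 0.0029, 0, 0),
    b = c(3.8402, -0.3829, 0.0111, -0.0040, 0, 0)),
  ankle_angle = list(a0 = -0.6374,
    a = c(-0.7251, 1.6130, -0.8084, 0.3523, 0, 0),
    b = c(6.8168, -9.1838, 0.2357, -0.3343, 0, 0)),
  subtalar_angle = list(a0 = -1.4891,
    a = c(-1.6504, 1.4794, 0.5061, 0.1102, 0, 0),
    b = c(-5.6003, 0.0643, -0.0495, 0.0077, 0, 0)),
  pelvis_tilt = list(a0 = -4,
    a = c(0, 0.9855, 0, 0, 0, 0),
    b = c(0, 0, 0, 0, 0, 0)),
  pelvis_list = list(a0 = 0.1655,
    a = c(0.0495, 0.6746, 0.0758, 0.0121, 0, 0),
    b = c(-3.4022, 0.6667, -0.0005, -0.0168, 0, 0)),
  pelvis_rotation = list(a0 = -0.2568,
    a = c(3.7419, 0.3885, 0.0543, 0.0423, 0, 0),
    b = c(-1.1786, 0.5102, 0.0180, 0.0043, 0, 0))
)

new_template <- function(dof, a0, a, b) {
  structure(list(dof = dof, a0 = a0, a = a, b = b),
            class = "waveform_template")
}

#' Bundled synthetic waveform templates
#'
#' Returns the package's synthetic normative joint-angle waveform templates,
#' one [waveform_template] per degree-of-freedom family (`knee_angle`,
#' `hip_flexion`, `hip_adduction`, `hip_rotation`, `ankle_angle`,
#' `subtalar_angle`, `pelvis_tilt`, `pelvis_list`, `pelvis_rotation`).
#'
#' @return Named list of `waveform_template` objects.
#' @export
gait_templates <- function() {
  purrr::imap(template_coefs, function(co, nm)
    new_template(nm, co$a0, co$a, co$b))
}

#' Evaluate a waveform template at cycle phases
#'
#' @param template A `waveform_template`.
#' @param phase Cycle phases (any real; evaluated modulo 1).
#' @return Angles in degrees.
#' @export
eval_template <- function(template, phase) {
  y <- rep(template$a0, length(phase))
  for (k in seq_along(template$a)) {
    if (template$a[k] != 0) y <- y + template$a[k] * cos(2 * pi * k * phase)
    if (template$b[k] != 0) y <- y + template$b[k] * sin(2 * pi * k * phase)
  }
  y
}

#' Extrema of a waveform template
#'
#' Locates the global maximum and minimum of the periodic waveform by a
#' dense grid scan refined with golden-section optimization, accurate to
#' well below 1e-6 degrees.
#'
#' @param template A `waveform_template`.
#' @return Named numeric `c(min = ..., max = ...)`.
#' @export
template_extrema <- function(template) {
  g <- seq(0, 1, length.out = 2049)[-2049]
  y <- eval_template(template, g)
  refine <- function(i, maximum) {
    lo <- g[i] - 1 / 2048
    hi <- g[i] + 1 / 2048
    opt <- stats::optimize(function(p) eval_template(template, p),
                           c(lo, hi), maximum = maximum, tol = 1e-12)
    opt$objective
  }
  c(min = min(refine(which.min(y), FALSE), min(y)),
    max = max(refine(which.max(y), TRUE), max(y)))
}

#' Calibrate a template to target extrema
#'
#' Applies the affine transform (gain and offset) that maps the template's
#' global extrema onto the requested targets, so that per-participant peak
#' angles can be imposed exactly on the synthetic waveforms. With only
#' `target_max` given the template is shifted (gain 1), which is how single
#' peak targets (pelvis) are imposed.
#'
#' @param template A `waveform_template`.
#' @param target_max Desired curve maximum, degrees.
#' @param target_min Desired curve minimum, degrees, or `NULL` for an
#'   offset-only shift.
#' @return Calibrated `waveform_template` whose extrema equal the targets
#'   to within 1e-6 degrees.
#' @export
calibrate_template <- function(template, target_max, target_min = NULL) {
  ex <- template_extrema(template)
  if (is.null(target_min)) {
    out <- template
    out$a0 <- template$a0 + (target_max - ex["max"])
    return(out)
  }
  assert_that(target_max > target_min,
              "target_max (%.3f) must exceed target_min (%.3f)",
              target_max, target_min)
  gain <- (target_max - target_min) / (ex["max"] - ex["min"])
  out <- template
  out$a0 <- unname(target_min + gain * (template$a0 - ex["min"]))
  out$a <- template$a * gain
  out$b <- template$b * gain
  out
}

#' @export
print.waveform_template <- function(x, ...) {
  ex <- template_extrema(x)
  cat(sprintf("<waveform_template> %s: K = %d, range [%.2f, %.2f] deg\n",
              x$dof, length(x$a), ex["min"], ex["max"]))
  invisible(x)
}
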