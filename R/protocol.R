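#' Define a continuous-wave saturation protocol
#'
#' Describes the saturation applied before each CEST readout: a
#' CW-equivalent amplitude, a total saturation duration, and the list of
#' saturation frequency offsets at which volumes were (or are to be)
#' acquired. Offsets are in ppm relative to the water resonance; the
#' Larmor frequency sets the ppm to rad/s conversion.
#'
#' @param b1 CW-equivalent saturation amplitude in microtesla.
#' @param t_sat Total saturation duration in seconds.
#' @param offsets Numeric vector of saturation offsets in ppm, in
#'   acquisition order (this order must match the 4th dimension of any 4D
#'   data the protocol is paired with).
#' @param larmor Water Larmor frequency in MHz. Default 127.74 MHz (3 T).
#' @param reference_offset Offset treated as the unsaturated reference,
#'   ppm. Default 300.
#' @return An object of class `"cest_protocol"`.
#' @examples
#' default_protocol()
#' @export
saturation_protocol <- function(b1, t_sat, offsets, larmor = 127.74,
                                reference_offset = 300) {
  if (!is.finite(b1) || b1 < 0) stop("b1 must be >= 0")
  if (!is.finite(t_sat) || t_sat <= 0) stop("t_sat must be > 0")
  if (length(offsets) < 1L || !all(is.finite(offsets)))
    stop("offsets must be a non-empty finite numeric vector")
  if (!is.finite(larmor) || larmor <= 0) stop("larmor must be > 0")
  structure(list(b1 = b1, t_sat = t_sat, offsets = as.numeric(offsets),
                 larmor = larmor, reference_offset = reference_offset),
            class = "cest_protocol")
}

#' @export
print.cest_protocol <- function(x, ...) {
  cat(sprintf(
    "<cest_protocol> b1=%.3g uT, t_sat=%g s, %d offsets [%g, %g] ppm, %g MHz\n",
    x$b1, x$t_sat, length(x$offsets), min(x$offsets), max(x$offsets),
    x$larmor))
  invisible(x)
}

#' Default acquisition protocol
#'
#' The default saturation scheme: 32 offsets evenly spaced from -4.5 to
#' +4.5 ppm plus an unsaturated reference at 300 ppm, CW-equivalent B1 of
#' 0.55 uT, 2 s total saturation (50 pulse cycles of 40 ms), at 3 T.
#'
#' @return A [saturation_protocol()] object.
#' @export
default_protocol <- function() {
  saturation_protocol(b1 = 0.55, t_sat = 2.0,
                      offsets = c(seq(-4.5, 4.5, length.out = 32), 300),
                      larmor = 127.74, reference_offset = 300)
}

#' Describe a pulsed saturation train
#'
#' Records the pulsed preparation actually played out on the scanner so
#' that its power-equivalent CW amplitude can be computed with
#' [cw_equivalent_b1()]. The pulse amplitude is fixed implicitly by the
#' flip angle (the integral of gamma * B1(t) over one pulse equals the
#' flip angle).
#'
#' @param n_pulses Number of pulses.
#' @param flip_angle Flip angle per pulse, degrees.
#' @param pulse_duration Duration of each pulse, seconds.
#' @param inter_pulse_delay Gap between pulses, seconds.
#' @param shape `"rectangular"` or `"gaussian"`.
#' @param gaussian_truncation For Gaussian pulses: the fraction of the peak
#'   amplitude at which the pulse is truncated at its edges. Required when
#'   `shape = "gaussian"`.
#' @return An object of class `"pulse_train"`.
#' @examples
#' # 50 Gaussian pulses, 184 degrees, 20 ms pulse / 20 ms delay
#' tr <- pulse_train(50, 184, 0.02, 0.02, "gaussian", gaussian_truncation = 0.01)
#' cw_equivalent_b1(tr)
#' @export
pulse_train <- function(n_pulses, flip_angle, pulse_duration,
                        inter_pulse_delay = 0,
                        shape = c("rectangular", "gaussian"),
                        gaussian_truncation = NULL) {
  shape <- match.arg(shape)
  if (n_pulses < 1L) stop("n_pulses must be >= 1")
  if (flip_angle < 0) stop("flip_angle must be >= 0")
  if (pulse_duration <= 0) stop("pulse_duration must be > 0")
  if (inter_pulse_delay < 0) stop("inter_pulse_delay must be >= 0")
  if (shape == "gaussian") {
    if (is.null(gaussian_truncation))
      stop("gaussian shape requires 'gaussian_truncation'")
    if (gaussian_truncation <= 0 || gaussian_truncation >= 1)
      stop("gaussian_truncation must be in (0, 1)")
  }
  structure(list(n_pulses = as.integer(n_pulses), flip_angle = flip_angle,
                 pulse_duration = pulse_duration,
                 inter_pulse_delay = inter_pulse_delay, shape = shape,
                 gaussian_truncation = gaussian_truncation),
            class = "pulse_train")
}

# gamma for 1H: rad s^-1 T^-1
GAMMA_H <- 2.675221874e8

#' Power-equivalent CW amplitude of a pulsed saturation train
#'
#' Converts a pulsed preparation to the continuous-wave amplitude with the
#' same mean saturation power, `sqrt(mean(B1(t)^2))`, where the peak
#' amplitude of each pulse is set by its flip angle. By default the mean is
#' taken over the full pulse-plus-delay cycle; `average = "pulse"` averages
#' over the pulse only.
#'
#' @param train A [pulse_train()].
#' @param average `"cycle"` (default) or `"pulse"`: the window over which
#'   the mean square amplitude is taken.
#' @return CW-equivalent amplitude in microtesla.
#' @examples
#' # rectangular 180 degrees, 20 ms pulse + 20 ms delay -> 0.415 uT
#' cw_equivalent_b1(pulse_train(50, 180, 0.02, 0.02, "rectangular"))
#' @export
cw_equivalent_b1 <- function(train, average = c("cycle", "pulse")) {
  stopifnot(inherits(train, "pulse_train"))
  average <- match.arg(average)
  if (train$flip_angle == 0) return(0)
  flip_rad <- train$flip_angle * pi / 180
  tp <- train$pulse_duration
  t_cycle <- tp + train$inter_pulse_delay

  if (train$shape == "rectangular") {
    b1_peak <- flip_rad / (GAMMA_H * tp)          # tesla
    int_b1sq <- b1_peak^2 * tp
  } else {
    # truncated Gaussian: B1(t) = peak * exp(-t^2 / (2 sigma^2)) on
    # [-tp/2, tp/2], with B1(+-tp/2) = truncation * peak
    cfrac <- train$gaussian_truncation
    sigma <- tp / (2 * sqrt(2 * log(1 / cfrac)))
    area1 <- sigma * sqrt(2 * pi) * erf(tp / (2 * sqrt(2) * sigma))
    b1_peak <- flip_rad / (GAMMA_H * area1)
    int_b1sq <- b1_peak^2 * sigma * sqrt(pi) * erf(tp / (2 * sigma))
  }
  window <- if (average == "cycle") t_cycle else tp
  sqrt(int_b1sq / window) * 1e6                    # tesla -> microtesla
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
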