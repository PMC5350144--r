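#' Stimulation protocols
#'
#' `step_protocol()` describes a square current step; `zap_protocol()` a ZAP
#' chirp `A * sin(B * t^2)` whose instantaneous frequency sweeps linearly from
#' 0 to `f_max`; `vclamp_protocol()` a somatic voltage-clamp step from rest.
#'
#' @param amplitude step amplitude, pA.
#' @param onset,offset step onset/offset, ms.
#' @param total total simulated time, ms (defaults to `offset + 100`).
#' @param injection_site compartment label receiving the current.
#' @return an object of class `grc_protocol`.
#' @export
step_protocol <- function(amplitude, onset = 100, offset = onset + 2000,
                          total = offset + 100, injection_site = "soma") {
  stopifnot(offset > onset, total >= offset)
  structure(list(kind = "step", amplitude = amplitude, onset = onset,
                 offset = offset, total = total,
                 injection_site = injection_site),
            class = "grc_protocol")
}

#' @rdname step_protocol
#' @param A ZAP amplitude, pA.
#' @param f_max top of the swept band, Hz (sweep starts at 0 Hz).
#' @param duration chirp duration, ms.
#' @param offset_pA tonic current added to the chirp, pA.
#' @export
zap_protocol <- function(A = 10, f_max = 10, duration = 30000,
                         offset_pA = 0, injection_site = "soma") {
  stopifnot(duration > 0, f_max > 0)
  # instantaneous frequency f(t) = B*t/pi (B in rad/s^2) reaches f_max at the
  # end of the sweep
  B <- pi * f_max / (duration / 1000)
  structure(list(kind = "zap", A = A, B = B, f_max = f_max,
                 duration = duration, total = duration,
                 offset_pA = offset_pA, injection_site = injection_site),
            class = "grc_protocol")
}

#' @rdname step_protocol
#' @param dv clamp step relative to rest, mV.
#' @param duration clamp-step duration, ms.
#' @param baseline pre-step clamp-at-rest duration, ms.
#' @export
vclamp_protocol <- function(dv = -10, duration = 100, baseline = 100,
                            injection_site = "soma") {
  structure(list(kind = "vclamp", dv = dv, duration = duration,
                 baseline = baseline, total = baseline + duration,
                 injection_site = injection_site),
            class = "grc_protocol")
}

#' ZAP current waveform
#'
#' `I(t) = A * sin(B * t^2)` with `t` in seconds and `B` in rad/s^2; the
#' instantaneous frequency is `B*t/pi` Hz, a linear sweep. Zero crossings sit
#' at `t_k = sqrt(k*pi/B)`.
#'
#' @param A amplitude, pA.
#' @param B sweep coefficient, rad/s^2.
#' @param t time grid, ms.
#' @return current values, pA.
#' @export
zap_current <- function(A, B, t) {
  if (any(t < 0)) stop("negative time in ZAP waveform")
  ts <- t / 1000
  A * sin(B * ts^2)
}
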