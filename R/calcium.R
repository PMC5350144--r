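#' Calcium shell pool
#'
#' First-order submembrane calcium dynamics:
#' `d[Ca]/dt = -I_Ca / (2*F*d) - beta * ([Ca] - [Ca]_rest)`
#' with `I_Ca` the calcium current density (mA/cm^2, outward positive), `d`
#' the shell depth and `beta` the decay rate constant ("Calc"). The calcium
#' reversal potential is recomputed from the pool as the two-concentration
#' Nernst equilibrium with z = 2.
#'
#' @param cai intracellular concentration, mM.
#' @param carest resting concentration, mM.
#' @param cao extracellular concentration, mM.
#' @param beta decay rate constant, 1/ms.
#' @param depth shell depth, um.
#' @param temp_C temperature, degrees C.
#' @param floor lowest admissible concentration, mM (guards the log in the
#'   Nernst potential).
#' @return object of class `grc_capool`.
#' @examples
#' p <- calcium_pool()
#' calcium_reversal(p)  # ~129.3 mV
#' @export
calcium_pool <- function(cai = 1e-4, carest = 1e-4, cao = 2,
                         beta = 1.5, depth = 0.2, temp_C = 30,
                         floor = 1e-6) {
  stopifnot(cai > 0, carest > 0, cao > 0, beta > 0, depth > 0, floor > 0)
  structure(list(cai = cai, carest = carest, cao = cao, beta = beta,
                 depth = depth, temp_C = temp_C, floor = floor),
            class = "grc_capool")
}

#' @rdname calcium_pool
#' @param pool a [calcium_pool()].
#' @param i_ca calcium current density, mA/cm^2 (outward positive; inward
#'   calcium current is negative and raises `[Ca]i`).
#' @param dt time step, ms (> 0).
#' @return the updated pool. The update is the exact solution of the linear
#'   shell equation over `dt` for constant `i_ca`; if the concentration would
#'   fall below `floor` it is clamped there with a warning.
#' @export
update_calcium <- function(pool, i_ca, dt) {
  stopifnot(inherits(pool, "grc_capool"), dt > 0)
  depth_cm <- pool$depth * 1e-4
  influx <- -i_ca / (2 * .FARADAY * depth_cm)  # mM/ms
  css <- pool$carest + influx / pool$beta
  cai <- css + (pool$cai - css) * exp(-pool$beta * dt)
  if (cai < pool$floor) {
    warning("calcium concentration clamped at floor")
    cai <- pool$floor
  }
  pool$cai <- cai
  pool
}

#' @rdname calcium_pool
#' @return `calcium_reversal`: the calcium equilibrium potential, mV.
#' @export
calcium_reversal <- function(pool) {
  stopifnot(inherits(pool, "grc_capool"))
  if (pool$cai <= 0 || pool$cao <= 0) stop("concentrations must be positive")
  tk <- pool$temp_C + .KELVIN0
  1000 * .GASCONST * tk / (2 * .FARADAY) * log(pool$cao / pool$cai)
}
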