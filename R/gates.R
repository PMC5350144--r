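#' Hodgkin-Huxley gate specifications
#'
#' A gate is one activation/inactivation particle of an ionic channel. Its
#' voltage dependence is given either as alpha/beta rate functions or as a
#' steady-state sigmoid plus a bell-shaped time constant. All kinetics are
#' taken as already normalized to 30 degrees C; no Q10 scaling is applied at
#' run time.
#'
#' Rate functional forms (`form`):
#' \describe{
#'   \item{`"exp"`}{`A * exp((V - V0)/K)`}
#'   \item{`"sigmoid"`}{`A / (1 + exp((V - V0)/K))`}
#'   \item{`"linoid"`}{`A * (V - V0) / (exp((V - V0)/K) - 1)` (limit `A*K` at `V = V0`)}
#' }
#'
#' @param name gate label.
#' @param p integer exponent (>= 1) of the gating particle.
#' @param alpha,beta lists `list(form, A, V0, K)` describing the opening and
#'   closing rate functions (1/ms, mV).
#' @return An object of class `grc_gate`.
#' @examples
#' g <- gate_ab("m", 3,
#'   alpha = list(form = "linoid", A = -0.1, V0 = -40, K = -10),
#'   beta  = list(form = "exp",    A = 4,    V0 = -65, K = -18))
#' gate_steady_state(g, -40)
#' @export
gate_ab <- function(name, p, alpha, beta) {
  stopifnot(p >= 1, p == round(p))
  enc <- c(1, p,
           .rate_form_id(alpha$form), alpha$A, alpha$V0, alpha$K,
           .rate_form_id(beta$form), beta$A, beta$V0, beta$K)
  structure(list(name = name, p = as.integer(p), kind = "ab",
                 alpha = alpha, beta = beta, enc = enc),
            class = "grc_gate")
}

.rate_form_id <- function(form) {
  switch(match.arg(form, c("exp", "sigmoid", "linoid")),
         exp = 1, sigmoid = 2, linoid = 3)
}

#' @rdname gate_ab
#' @param vhalf,k half-activation voltage (mV) and slope (mV) of the
#'   steady-state sigmoid `1/(1 + exp(-(V - vhalf)/k))`; `k < 0` gives a gate
#'   that closes with depolarization (inactivation or inward rectification).
#' @param tau_min,tau_amp,vt,k1,k2 parameters of the bell-shaped time constant
#'   `tau_min + tau_amp / (exp((V - vt)/k1) + exp(-(V - vt)/k2))` (ms, mV).
#' @export
gate_inf_tau <- function(name, p, vhalf, k, tau_min, tau_amp, vt, k1, k2) {
  stopifnot(p >= 1, p == round(p), tau_min > 0 || tau_amp > 0)
  enc <- c(2, p, vhalf, k, tau_min, tau_amp, vt, k1, k2)
  structure(list(name = name, p = as.integer(p), kind = "inf_tau",
                 vhalf = vhalf, k = k, tau_min = tau_min, tau_amp = tau_amp,
                 vt = vt, k1 = k1, k2 = k2, enc = enc),
            class = "grc_gate")
}

#' @rdname gate_ab
#' @param Aa,Ba,Ka,Ab,Bb,Kb calcium-and-voltage dependent rate parameters:
#'   `alpha = Aa / (1 + Ka*exp(-V/Ba)/ca)`, `beta = Ab / (1 + ca/(Kb*exp(-V/Bb)))`
#'   with `ca` the intracellular calcium concentration (mM).
#' @export
gate_kca <- function(name, p, Aa, Ba, Ka, Ab, Bb, Kb) {
  stopifnot(p >= 1, p == round(p))
  enc <- c(3, p, Aa, Ba, Ka, Ab, Bb, Kb)
  structure(list(name = name, p = as.integer(p), kind = "kca",
                 Aa = Aa, Ba = Ba, Ka = Ka, Ab = Ab, Bb = Bb, Kb = Kb,
                 enc = enc, ca_dependent = TRUE),
            class = "grc_gate")
}

#' Steady state and time constant of a gate
#'
#' Evaluates `m_inf(V) = alpha/(alpha + beta)` and `tau(V) = 1/(alpha + beta)`
#' (or the direct `m_inf`/`tau` parameterization) at the given voltages.
#'
#' @param gate a [gate_ab()]/[gate_inf_tau()]/[gate_kca()] object.
#' @param v membrane potential(s), mV; must be finite.
#' @param ca intracellular calcium (mM), used only by calcium-dependent gates.
#' @return list with numeric vectors `minf` (in `[0, 1]`) and `tau` (ms, > 0).
#' @export
gate_steady_state <- function(gate, v, ca = 1e-4) {
  stopifnot(inherits(gate, "grc_gate"))
  if (!all(is.finite(v))) stop("membrane potential must be finite")
  cpp_gate_minf_tau(gate$enc, as.numeric(v), ca)
}

#' Ionic channel specification (HH form)
#'
#' One conductance of the membrane equation: ohmic current
#' `I = Gmax * prod(m_k^p_k) * (V - Erev)`, outward positive.
#'
#' @param name channel label (e.g. `"Na"`, `"Kir"`, `"Lkg1"`).
#' @param gates list of [gate_ab()]-type gates (may be empty, e.g. leak).
#' @param gmax maximum specific conductance, mS/cm^2 (>= 0).
#' @param erev reversal potential, mV; use `erev = "ca"` for the dynamic
#'   calcium reversal (recomputed from the calcium pool during simulation).
#' @param compartment placement label.
#' @param carries_ca logical; does this channel's current feed the calcium pool.
#' @return object of class `grc_channel`.
#' @export
channel_spec <- function(name, gates = list(), gmax, erev,
                         compartment = "soma", carries_ca = FALSE) {
  stopifnot(is.numeric(gmax), gmax >= 0)
  erev_ca <- identical(erev, "ca")
  if (!erev_ca) stopifnot(is.numeric(erev), is.finite(erev))
  structure(list(name = name, gates = gates, gmax = gmax,
                 erev = if (erev_ca) NA_real_ else erev, erev_ca = erev_ca,
                 compartment = compartment,
                 carries_ca = carries_ca || erev_ca, markov = NULL),
            class = "grc_channel")
}

#' Current density through an HH channel
#'
#' @param spec a [channel_spec()].
#' @param gate_states numeric vector of gate activations, one per gate, each
#'   in `[0, 1]`.
#' @param v membrane potential, mV.
#' @param eca calcium reversal (mV) for channels with dynamic reversal.
#' @return current density in mA/cm^2, outward positive.
#' @export
channel_current <- function(spec, gate_states = numeric(0), v, eca = NULL) {
  stopifnot(inherits(spec, "grc_channel"))
  if (length(gate_states) != length(spec$gates))
    stop("need one gate state per gate")
  if (length(gate_states) && (any(gate_states < 0) || any(gate_states > 1)))
    stop("gate states must lie in [0, 1]")
  e <- if (spec$erev_ca) {
    if (is.null(eca)) stop("channel has dynamic calcium reversal; supply eca")
    eca
  } else spec$erev
  gp <- 1
  for (i in seq_along(spec$gates)) gp <- gp * gate_states[i]^spec$gates[[i]]$p
  # mS/cm^2 * mV = 1e-3 mA/cm^2
  spec$gmax * gp * (v - e) * 1e-3
}

#' 13-state Markov sodium channel (resurgent gating)
#'
#' Continuous-time Markov scheme with five closed states (C1-C5), an open
#' state (O), an open-blocked state (OB) and six inactivated states (I1-I6).
#' Activation steps in the closed chain carry statistical factors 4a..1a
#' (backward 1b..4b); opening/closing C5<->O use rates gamma/delta; open-channel
#' block O<->OB uses epsilon and the voltage-dependent unblock zeta; the
#' inactivation chain mirrors the closed chain scaled by allosteric factors
#' `a = (Oon/Con)^(1/4)` and `b = (Ooff/Coff)^(1/4)`.
#'
#' @param alpha0,va forward activation rate `alpha0*exp(V/va)` (1/ms, mV).
#' @param beta0,vb backward rate `beta0*exp(-V/vb)`.
#' @param gamma,delta opening and closing rates (1/ms).
#' @param epsilon block rate (1/ms); `zeta0,vz` unblock rate `zeta0*exp(-V/vz)`.
#' @param Con,Coff,Oon,Ooff closed-state and open-state inactivation rates (1/ms).
#' @param scale overall rate multiplier (temperature normalization).
#' @return numeric parameter vector of class `grc_markov`.
#' @export
markov_na_params <- function(alpha0 = 353.91, va = 13.99,
                             beta0 = 1.272, vb = 13.99,
                             gamma = 150, delta = 40,
                             epsilon = 1.75, zeta0 = 0.03, vz = 25,
                             Con = 0.005, Coff = 0.5,
                             Oon = 0.75, Ooff = 0.005,
                             scale = 1.5) {
  structure(c(alpha0, va, beta0, vb, gamma, delta, epsilon, zeta0, vz,
              Con, Coff, Oon, Ooff, scale),
            names = c("alpha0", "va", "beta0", "vb", "gamma", "delta",
                      "epsilon", "zeta0", "vz", "Con", "Coff", "Oon", "Ooff",
                      "scale"),
            class = "grc_markov")
}

#' @rdname markov_na_params
#' @param gmax maximum conductance, mS/cm^2.
#' @param erev sodium reversal potential, mV.
#' @param compartment placement label.
#' @param params a [markov_na_params()] vector.
#' @export
markov_channel_spec <- function(name = "Na", gmax, erev = 87.39,
                                compartment = "AIS",
                                params = markov_na_params()) {
  ch <- channel_spec(name, gates = list(), gmax = gmax, erev = erev,
                     compartment = compartment)
  ch$markov <- params
  ch
}

#' State labels of the 13-state sodium scheme
#' @export
markov_state_labels <- function() {
  c(paste0("C", 1:5), "O", "OB", paste0("I", 1:6))
}

#' Generator matrix of the Markov sodium scheme
#'
#' @param params a [markov_na_params()] vector.
#' @param v membrane potential, mV.
#' @return 13 x 13 generator matrix `Q` (rows sum to zero); the occupancy
#'   evolves as `dP/dt = t(Q) %*% P`.
#' @export
markov_q <- function(params, v) {
  q <- cpp_markov_q(unclass(params), v)
  dimnames(q) <- list(markov_state_labels(), markov_state_labels())
  q
}

#' Advance a Markov occupancy distribution by one time step
#'
#' Implicit (backward-Euler) update of the master equation
#' `dP/dt = t(Q(V)) P`. The update conserves total occupancy exactly and
#' preserves non-negativity for any step size.
#'
#' @param params a [markov_na_params()] vector.
#' @param occupancy probability vector over the 13 states (sums to 1).
#' @param v membrane potential, mV.
#' @param dt time step, ms (> 0).
#' @return updated occupancy vector; the open fraction is component `"O"`.
#' @export
markov_step <- function(params, occupancy, v, dt) {
  stopifnot(dt > 0)
  if (abs(sum(occupancy) - 1) > 1e-6)
    stop("occupancy must sum to 1")
  out <- cpp_markov_step(unclass(params), occupancy, v, dt)
  if (any(out < -1e-9))
    stop("integration step produced negative occupancy; reduce dt")
  names(out) <- markov_state_labels()
  out
}
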