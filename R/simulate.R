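#' Simulate a granule-cell model under a protocol
#'
#' Integrates the membrane equation
#' `dV/dt = -1/Cm * (sum_i g_i (V - E_i) + I_axial - I_inj)` for every
#' compartment, together with the gate, Markov-occupancy and calcium states,
#' using a staggered theta-method (Crank-Nicolson voltage solve on the
#' compartment tree, Rush-Larsen exponential gate updates, implicit Markov
#' updates). Before the protocol starts the model is initialized at `v_init`
#' (gates at steady state) and settled for `settle` ms with no input, so every
#' protocol starts from the model's own resting state.
#'
#' @param model a [granule_model()].
#' @param protocol a [step_protocol()], [zap_protocol()] or
#'   [vclamp_protocol()].
#' @param record compartment labels to record (default: soma; `"all"` records
#'   every compartment).
#' @param dt integration step, ms. Traces are recorded on a uniform
#'   `record_dt` grid (defaults to `dt`).
#' @param record_dt recording resolution, ms (multiple of `dt`).
#' @param settle settling pre-run duration, ms.
#' @param theta implicitness of the voltage update (0.5 = Crank-Nicolson,
#'   1 = backward Euler).
#' @param record_ca,record_currents also record calcium concentrations and
#'   per-channel currents (nA).
#' @return object of class `grc_trace`: list with `time` (ms), `v` (matrix,
#'   one column per recorded compartment), optional `ca` and `currents`,
#'   `i_clamp` (nA, voltage-clamp protocols), `v_rest` (voltage at the end of
#'   settling), `dt`, and the protocol.
#' @export
simulate_model <- function(model, protocol, record = "soma", dt = 0.025,
                           record_dt = dt, settle = 500, theta = 0.5,
                           record_ca = FALSE, record_currents = FALSE) {
  stopifnot(inherits(model, "grc_model"), inherits(protocol, "grc_protocol"))
  cm <- .compile_model(model)
  labels <- cm$labels
  if (identical(record, "all")) record <- labels
  rec_idx <- match(record, labels)
  if (anyNA(rec_idx)) stop("unknown compartment(s): ",
                           paste(record[is.na(rec_idx)], collapse = ", "))
  inj_idx <- match(protocol$injection_site, labels)
  if (is.na(inj_idx)) stop("unknown injection site: ", protocol$injection_site)
  if (round(record_dt / dt) != record_dt / dt)
    record_dt <- dt * max(1, round(record_dt / dt))

  nsteps <- round(protocol$total / dt)
  control <- list(dt = dt, theta = theta, settle_ms = settle,
                  t_stop = protocol$total, record_dt = record_dt,
                  record_comps = as.integer(rec_idx - 1L),
                  record_ca = record_ca, record_currents = record_currents,
                  inj_comp = as.integer(inj_idx - 1L),
                  stim_mode = 0L, stim_onset = 0, stim_offset = 0,
                  stim_amp_na = 0, stim_vec = numeric(0),
                  clamp_comp = -1L, clamp_v = numeric(0))

  v_rest <- NULL
  if (protocol$kind == "step") {
    control$stim_mode <- 1L
    control$stim_onset <- protocol$onset
    control$stim_offset <- protocol$offset
    control$stim_amp_na <- protocol$amplitude / 1000
  } else if (protocol$kind == "zap") {
    tm <- (seq_len(nsteps) - 0.5) * dt
    control$stim_mode <- 2L
    control$stim_vec <- (zap_current(protocol$A, protocol$B, tm) +
                           protocol$offset_pA) / 1000
  } else if (protocol$kind == "vclamp") {
    # find rest first, then clamp at rest and rest+dv
    v_rest <- .resting_v(model, cm, dt, settle, theta)
    control$clamp_comp <- as.integer(inj_idx - 1L)
    nb <- round(protocol$baseline / dt)
    control$clamp_v <- c(rep(v_rest, nb), rep(v_rest + protocol$dv, nsteps - nb))
  }

  out <- cpp_simulate(cm, control)
  v <- out$v
  colnames(v) <- labels[rec_idx]
  res <- list(time = out$time, v = v, dt = record_dt, protocol = protocol,
              v_rest = if (is.null(v_rest)) v[1, 1] else v_rest,
              occ_err_max = out$occ_err_max)
  if (record_ca && length(cm$pool_labels)) {
    colnames(out$ca) <- cm$pool_labels
    res$ca <- out$ca
  }
  if (record_currents) {
    colnames(out$currents) <- vapply(cm$channels, function(ch)
      paste(ch$gene, ch$label, sep = "@"), character(1))
    res$currents <- out$currents
  }
  if (protocol$kind == "vclamp") res$i_clamp <- out$i_clamp
  structure(res, class = "grc_trace")
}

# resting potential: settle, then read the voltage with no input
.resting_v <- function(model, cm = .compile_model(model), dt = 0.025,
                       settle = 500, theta = 0.5) {
  control <- list(dt = dt, theta = theta, settle_ms = settle, t_stop = dt,
                  record_dt = dt, record_comps = 0L,
                  record_ca = FALSE, record_currents = FALSE,
                  inj_comp = 0L, stim_mode = 0L, stim_onset = 0,
                  stim_offset = 0, stim_amp_na = 0, stim_vec = numeric(0),
                  clamp_comp = -1L, clamp_v = numeric(0))
  cpp_simulate(cm, control)$v[1, 1]
}

#' @export
print.grc_trace <- function(x, ...) {
  cat(sprintf("granule-cell trace: %s protocol, %.0f ms, %d compartment(s) at dt = %g ms\n",
              x$protocol$kind, max(x$time), ncol(x$v), x$dt))
  invisible(x)
}

#' @export
as.data.frame.grc_trace <- function(x, ...) {
  data.frame(time = x$time, x$v, check.names = FALSE)
}
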