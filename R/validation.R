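#' Frequency-current curve
#'
#' Simulates a series of current steps, extracts the mean firing frequency and
#' the delay to first spike per amplitude, and fits a least-squares line of
#' frequency against current over the spiking amplitudes.
#'
#' @param model a [granule_model()].
#' @param amplitudes sorted step amplitudes, pA.
#' @param duration step duration, ms.
#' @param dt integrator step, ms.
#' @return list of class `grc_fi`: `curve` (data.frame amplitude, frequency,
#'   delay, n_spikes), `slope` (spikes s^-1 / pA; `NA` if nothing fires) and
#'   `empty` flag.
#' @export
fi_curve <- function(model, amplitudes = seq(10, 34, by = 6), duration = 2000,
                     dt = 0.025) {
  stopifnot(!is.unsorted(amplitudes))
  rows <- lapply(amplitudes, function(a) {
    tr <- simulate_model(model, step_protocol(a, onset = 100,
                                              offset = 100 + duration,
                                              total = 100 + duration), dt = dt)
    sp <- detect_spikes(tr)
    f <- extract_features(tr, spikes = sp)
    data.frame(amplitude = a, frequency = f[["mean_frequency"]],
               delay = f[["time_to_first_spike"]], n_spikes = nrow(sp))
  })
  curve <- do.call(rbind, rows)
  spk <- !is.na(curve$frequency) & curve$n_spikes >= 2
  slope <- if (sum(spk) >= 2)
    unname(coef(lm(frequency ~ amplitude, data = curve[spk, ]))[2]) else NA_real_
  structure(list(curve = curve, slope = slope, empty = !any(spk)),
            class = "grc_fi")
}

#' Fit the f/I slope from an amplitude/frequency table
#'
#' Least-squares slope of frequency (Hz) against current (pA), in
#' spikes s^-1 per pA.
#'
#' @param amplitude,frequency numeric vectors.
#' @export
fi_slope <- function(amplitude, frequency) {
  unname(coef(lm(frequency ~ amplitude))[2])
}

#' Rheobase: minimal step current that elicits a spike
#'
#' Bisection between `lo` and `hi` to within `tol` pA.
#'
#' @param model a [granule_model()].
#' @param lo,hi bracketing amplitudes, pA.
#' @param tol resolution, pA.
#' @param duration test-step duration, ms.
#' @param dt integrator step, ms.
#' @return rheobase estimate, pA (upper end of the final bracket).
#' @export
rheobase <- function(model, lo = 0, hi = 30, tol = 0.5, duration = 1000,
                     dt = 0.025) {
  fires <- function(a) {
    tr <- simulate_model(model, step_protocol(a, onset = 100,
                                              offset = 100 + duration,
                                              total = 100 + duration), dt = dt)
    nrow(detect_spikes(tr)) > 0
  }
  if (!fires(hi)) return(NA_real_)
  if (fires(lo)) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Inward rectification under negative current steps
#'
#' Simulates hyperpolarizing steps and reports, per amplitude, the peak and
#' steady-state voltage deflection, plus a rectification index: the chord
#' conductance at the largest step divided by the chord conductance at the
#' smallest. An index above 1 is the signature of an inward rectifier that
#' opens with hyperpolarization; a passive membrane gives exactly 1.
#'
#' @param model a [granule_model()].
#' @param amplitudes negative step amplitudes, pA.
#' @param duration step duration, ms.
#' @param dt integrator step, ms.
#' @return list of class `grc_rectification`: `table` (amplitude, v_peak,
#'   v_ss, chord_uS), `index`, `anomaly` (TRUE if a spike occurred).
#' @export
inward_rectification <- function(model, amplitudes = c(-3, -6, -9),
                                 duration = 500, dt = 0.025) {
  stopifnot(all(amplitudes < 0) || any(amplitudes == 0))
  amplitudes <- sort(amplitudes, decreasing = TRUE) # small to large |amp|
  anomaly <- FALSE
  rows <- lapply(amplitudes, function(a) {
    tr <- simulate_model(model, step_protocol(a, onset = 100,
                                              offset = 100 + duration,
                                              total = 100 + duration + 100),
                         dt = dt)
    if (nrow(detect_spikes(tr)) > 0) anomaly <<- TRUE
    v <- tr$v[, 1]
    t <- tr$time
    rest <- mean(v[t < 100])
    instep <- t > 100 & t <= 100 + duration
    vpeak <- min(v[instep])
    ss <- t > 100 + 0.8 * duration & t <= 100 + duration
    vss <- mean(v[ss])
    chord <- if (a == 0) NA_real_ else (a / 1000) / (vss - rest)  # uS
    data.frame(amplitude = a, v_rest = rest, v_peak = vpeak, v_ss = vss,
               chord_uS = chord)
  })
  tab <- do.call(rbind, rows)
  nz <- tab$amplitude != 0
  index <- tab$chord_uS[which.max(abs(tab$amplitude))] /
    tab$chord_uS[nz][which.min(abs(tab$amplitude[nz]))]
  structure(list(table = tab, index = unname(index), anomaly = anomaly),
            class = "grc_rectification")
}

#' ZAP resonance analysis
#'
#' Applies a 0-to-`f_max` Hz ZAP chirp (amplitude `A`) on top of a tonic
#' offset just above rheobase, detects spikes, computes the instantaneous
#' frequency of every adjacent spike pair, assigns each pair to the ZAP cycle
#' containing its midpoint, and averages per cycle. The resonance peak is the
#' cycle (input) frequency with the largest mean output frequency.
#'
#' @param model a [granule_model()].
#' @param A ZAP amplitude, pA.
#' @param f_max swept band top, Hz.
#' @param duration sweep duration, ms.
#' @param offset_pA tonic offset, pA; `"auto"` = rheobase + 2 pA.
#' @param dt integrator step, ms.
#' @param use_isi if `TRUE` average the raw ISI per cycle instead of the
#'   instantaneous frequency.
#' @param min_pairs cycles with fewer spike pairs than this are excluded from
#'   the peak search (their per-cycle means are degenerate).
#' @return list of class `grc_resonance`: `curve` (cycle, f_in, f_out,
#'   isi_ms, n_pairs), `peak_hz`, `no_resonance` flag.
#' @export
zap_resonance <- function(model, A = 10, f_max = 10, duration = 30000,
                          offset_pA = "auto", dt = 0.025, use_isi = FALSE,
                          min_pairs = 3) {
  if (identical(offset_pA, "auto")) {
    rb <- rheobase(model)
    if (is.na(rb)) stop("model does not fire; cannot place ZAP offset")
    offset_pA <- rb + 2
  }
  prot <- zap_protocol(A = A, f_max = f_max, duration = duration,
                       offset_pA = offset_pA)
  tr <- simulate_model(model, prot, dt = dt)
  sp <- detect_spikes(tr)
  if (nrow(sp) < 2)
    return(structure(list(curve = NULL, peak_hz = NA_real_,
                          no_resonance = TRUE, offset_pA = offset_pA),
                     class = "grc_resonance"))
  B <- prot$B
  # cycle boundaries: zero crossings t_k = sqrt(k*pi/B) (seconds -> ms)
  ncyc <- floor(B * (duration / 1000)^2 / pi / 2)
  bounds <- sqrt(seq(0, 2 * ncyc, by = 2) * pi / B) * 1000
  mids <- (sp$peak_time[-1] + sp$peak_time[-nrow(sp)]) / 2
  isi <- diff(sp$peak_time)
  cyc <- findInterval(mids, bounds, rightmost.closed = TRUE)
  keep <- cyc >= 1 & cyc <= ncyc
  agg_f <- tapply(1000 / isi[keep], cyc[keep], mean)
  agg_i <- tapply(isi[keep], cyc[keep], mean)
  cyc_id <- as.integer(names(agg_f))
  # cycle input frequency: instantaneous sweep frequency at the cycle center
  tc <- (bounds[cyc_id] + bounds[cyc_id + 1]) / 2 / 1000
  f_in <- B * tc / pi
  curve <- data.frame(cycle = cyc_id, f_in = f_in,
                      f_out = as.numeric(agg_f), isi_ms = as.numeric(agg_i),
                      n_pairs = as.integer(table(cyc[keep])[as.character(cyc_id)]))
  # cycles with too few spike pairs give degenerate per-cycle means
  well <- curve[curve$n_pairs >= min_pairs, ]
  if (!nrow(well)) well <- curve
  peak <- if (use_isi) well$f_in[which.min(well$isi_ms)]
          else well$f_in[which.max(well$f_out)]
  structure(list(curve = curve, peak_hz = unname(peak), no_resonance = FALSE,
                 offset_pA = offset_pA),
            class = "grc_resonance")
}

#' Near-threshold subthreshold oscillations
#'
#' Holds the model just below rheobase (default 1 pA below) for several
#' seconds and estimates the dominant frequency of the detrended subthreshold
#' voltage: mean-removed, Hann-windowed, zero-padded FFT; the reported peak is
#' the largest spectral component above `f_lo` Hz.
#'
#' @param model a [granule_model()].
#' @param hold holding current, pA, or `"auto"` (rheobase - 1 pA).
#' @param duration holding duration, ms.
#' @param discard initial transient discarded from the spectrum, ms.
#' @param f_lo lower edge of the searched band, Hz.
#' @param dt integrator step, ms.
#' @return list of class `grc_oscillation`: `freq_hz`, `amplitude_mv`
#'   (peak-to-peak of the analysed segment), `spectrum` (data.frame), `hold`.
#' @export
near_threshold_oscillations <- function(model, hold = "auto", duration = 5000,
                                        discard = 1000, f_lo = 1, dt = 0.025) {
  if (identical(hold, "auto")) {
    rb <- rheobase(model)
    if (is.na(rb)) stop("model does not fire; rheobase undefined")
    hold <- rb - 1
  }
  for (try_i in 1:3) {
    tr <- simulate_model(model, step_protocol(hold, onset = 100,
                                              offset = 100 + duration,
                                              total = 100 + duration), dt = dt)
    if (nrow(detect_spikes(tr)) == 0) break
    hold <- hold - 1   # spiking at holding current: retry one step lower
  }
  t <- tr$time
  v <- tr$v[, 1]
  w <- t > 100 + discard & t <= 100 + duration
  x <- v[w]
  x <- x - mean(x)
  n <- length(x)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  xw <- x * hann
  nfft <- nextn(4 * n, 2)
  sp <- abs(fft(c(xw, rep(0, nfft - n))))[seq_len(nfft %/% 2)]
  fs <- 1000 / dt  # Hz
  fgrid <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  band <- fgrid >= f_lo & fgrid <= 25
  pk <- which.max(sp[band])
  spectrum <- data.frame(freq = fgrid[band], power = sp[band]^2)
  structure(list(freq_hz = fgrid[band][pk],
                 amplitude_mv = diff(range(x)),
                 spectrum = spectrum, hold = hold),
            class = "grc_oscillation")
}

#' Action-potential propagation metrics (multi-compartment model)
#'
#' Drives the cell with a somatic step, localizes the peak time of one action
#' potential in every compartment (parabolic sub-sample refinement), and
#' reports conduction speed along the axon (distance between two axonal
#' recording sites over their peak-time difference) and the back-propagation
#' delay between the axon initial segment and the dendrites.
#'
#' @param model a multi-compartment [granule_model()].
#' @param amplitude somatic step, pA.
#' @param spike which action potential to analyse (1 = first).
#' @param sites axonal recording sites (compartment labels) for the speed
#'   estimate; defaults to two proximal sites spanning the first third of the
#'   axon (the actively conducting wavefront region; the sealed distal end is
#'   near-isopotential and would bias the estimate).
#' @param dt integrator step, ms.
#' @return list of class `grc_propagation`: `peaks` (label, position_um,
#'   peak_time), `speed_mm_ms` (Inf flagged degenerate), `backprop_delay_ms`,
#'   `ais_first` (logical).
#' @export
conduction_metrics <- function(model, amplitude = 16, spike = 2,
                               sites = NULL, dt = 0.0125) {
  if (model$mode != "multi") stop("conduction metrics need the multi-compartment model")
  n_axon <- model$n_axon
  if (is.null(sites))
    sites <- sprintf("axon%02d", c(1, max(2, round(n_axon / 3))))
  tr <- simulate_model(model, step_protocol(amplitude, onset = 100,
                                            offset = 600, total = 650),
                       record = "all", dt = dt)
  sp_soma <- detect_spikes(tr, compartment = "soma")
  if (nrow(sp_soma) < spike) {
    if (nrow(sp_soma) == 0) stop("no spike at the requested amplitude")
    spike <- nrow(sp_soma)
  }
  t0 <- sp_soma$peak_time[spike]
  labels <- colnames(tr$v)
  peak_of <- function(lab) {
    v <- tr$v[, lab]
    w <- which(tr$time > t0 - 1.5 & tr$time < t0 + 1.5)
    if (!length(w)) stop("no spike window at site ", lab)
    k <- w[which.max(v[w])]
    if (v[k] < -20) stop("no action potential detected at site ", lab)
    pt <- tr$time[k]
    if (k > 1 && k < length(v)) {
      den <- v[k - 1] - 2 * v[k] + v[k + 1]
      if (den < 0) pt <- tr$time[k] + 0.5 * (v[k - 1] - v[k + 1]) / den * dt
    }
    pt
  }
  pos <- setNames(model$compartments$position, model$compartments$label)
  peaks <- data.frame(label = labels, position_um = pos[labels],
                      peak_time = vapply(labels, peak_of, numeric(1)),
                      row.names = NULL)
  dist_um <- abs(pos[sites[2]] - pos[sites[1]])
  dt_pk <- peaks$peak_time[peaks$label == sites[2]] -
    peaks$peak_time[peaks$label == sites[1]]
  speed <- if (dt_pk == 0) Inf else (dist_um / 1000) / dt_pk  # mm/ms
  t_ais <- peaks$peak_time[peaks$label == "AIS"]
  t_dend <- mean(peaks$peak_time[grepl("^dend", peaks$label)])
  structure(list(peaks = peaks, speed_mm_ms = unname(speed),
                 backprop_delay_ms = unname(abs(t_dend - t_ais)),
                 ais_first = t_ais <= min(peaks$peak_time) + 1e-9,
                 degenerate = !is.finite(speed), sites = sites),
            class = "grc_propagation")
}

#' Deviation of conductances from a reference
#'
#' Per-gene percent deviation `|G - G_ref| / G_ref * 100`, averaged first over
#' individuals and then over genes.
#'
#' @param population genome matrix (rows = individuals) or a single named
#'   vector.
#' @param reference named reference vector (e.g. range midpoints or a known
#'   ground truth).
#' @return list of class `grc_deviation`: `per_gene` (mean % per gene),
#'   `per_individual` (mean % per row), `mean` (grand mean %).
#' @export
gmax_deviation <- function(population, reference) {
  G <- if (is.null(dim(population))) matrix(population, nrow = 1,
                                            dimnames = list(NULL, names(population)))
       else as.matrix(population)
  genes <- colnames(G)
  if (is.null(genes) || !all(genes %in% names(reference)))
    stop("population and reference must share conductance names")
  ref <- reference[genes]
  dev <- 100 * abs(sweep(G, 2, ref) ) / matrix(abs(ref), nrow(G), length(ref),
                                               byrow = TRUE)
  structure(list(per_gene = colMeans(dev), per_individual = rowMeans(dev),
                 mean = mean(colMeans(dev))),
            class = "grc_deviation")
}

#' Input resistance from a voltage-clamp step
#'
#' Clamps the soma at rest, applies a `dv` step for `duration` ms and computes
#' the input resistance from the steady-state change in clamp current.
#'
#' @param model a [granule_model()].
#' @param dv clamp step, mV.
#' @param duration step duration, ms.
#' @param dt integrator step, ms.
#' @return input resistance, GOhm.
#' @export
input_resistance <- function(model, dv = -10, duration = 100, dt = 0.025) {
  prot <- vclamp_protocol(dv = dv, duration = duration, baseline = duration)
  tr <- simulate_model(model, prot, dt = dt)
  t <- tr$time
  i <- tr$i_clamp
  base <- mean(i[t > 0.8 * duration & t <= duration])
  ss <- mean(i[t > duration + 0.8 * duration & t <= 2 * duration])
  di <- ss - base                       # nA
  if (!is.finite(di) || di == 0) stop("voltage clamp did not converge")
  (dv / di) / 1000                      # mV/nA = MOhm -> /1000 GOhm
}
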