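#' Detect action potentials in a voltage trace
#'
#' Spikes are upward crossings of `threshold` separated by at least
#' `refractory` ms; each spike's peak is localized between the upward and the
#' following downward crossing. For every spike a per-spike threshold voltage
#' is found as the voltage at which dV/dt first exceeds `dvdt_threshold`
#' before the peak (used as the baseline for width measures).
#'
#' @param trace a `grc_trace` (or a list with uniform `time` and a voltage
#'   vector/matrix `v`).
#' @param threshold detection threshold, mV.
#' @param refractory minimal spike separation, ms.
#' @param compartment column of `v` to analyse.
#' @param dvdt_threshold rate-of-rise criterion for the per-spike threshold,
#'   mV/ms.
#' @return object of class `grc_spikes`: data.frame with `peak_time`,
#'   `peak_v`, `threshold_time`, `threshold_v`.
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 1,
                          compartment = 1, dvdt_threshold = 20) {
  t <- trace$time
  v <- trace$v
  if (is.matrix(v)) v <- v[, compartment]
  dtv <- diff(t)
  if (length(dtv) < 2) stop("trace too short")
  if (max(abs(dtv - dtv[1])) > 1e-9 * dtv[1] + 1e-12)
    stop("spike detection requires a uniform time grid")
  dt <- dtv[1]

  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  rows <- vector("list", length(up))
  nrow_out <- 0L
  last_peak <- -Inf
  fast <- c(-Inf, diff(v) / dt)   # dV/dt at each sample (backward difference)
  for (i in up) {
    j <- i + 1
    while (j < length(v) && v[j + 1] >= threshold) j <- j + 1
    seg <- (i + 1):j
    k <- seg[which.max(v[seg])]
    if (t[k] - last_peak < refractory) next
    last_peak <- t[k]
    # parabolic refinement of the peak
    pt <- t[k]; pv <- v[k]
    if (k > 1 && k < length(v)) {
      den <- v[k - 1] - 2 * v[k] + v[k + 1]
      if (den < 0) {
        sh <- 0.5 * (v[k - 1] - v[k + 1]) / den
        pt <- t[k] + sh * dt
        pv <- v[k] - 0.25 * (v[k - 1] - v[k + 1]) * sh
      }
    }
    # per-spike threshold: first dV/dt crossing of dvdt_threshold before peak
    lo <- max(2, k - round(5 / dt))
    hit <- which(fast[lo:k] >= dvdt_threshold)
    th_t <- NA_real_; th_v <- NA_real_
    if (length(hit)) {
      m <- lo + hit[1] - 1
      th_t <- t[m]; th_v <- v[m]
    }
    nrow_out <- nrow_out + 1L
    rows[[nrow_out]] <- c(pt, pv, th_t, th_v)
  }
  peaks <- if (nrow_out) {
    out <- do.call(rbind, rows[seq_len(nrow_out)])
    data.frame(peak_time = out[, 1], peak_v = out[, 2],
               threshold_time = out[, 3], threshold_v = out[, 4])
  } else {
    data.frame(peak_time = numeric(0), peak_v = numeric(0),
               threshold_time = numeric(0), threshold_v = numeric(0))
  }
  structure(peaks, class = c("grc_spikes", "data.frame"))
}

#' Names of the ten template features
#' @export
feature_names <- function() {
  c("resting_voltage", "AP_height", "AP_width", "AP_half_width",
    "AHP_depth", "AHP_depth_slow", "time_to_first_spike",
    "mean_frequency", "adaptation_index", "ISI_CV")
}

#' Extract the ten template features from a trace
#'
#' Feature definitions: resting voltage = mean pre-stimulus voltage;
#' AP height = absolute peak voltage; AP width = time above the per-spike
#' threshold voltage; AP half-width = width at half amplitude between the
#' per-spike threshold voltage and the peak; AHP depth = minimum voltage in
#' the 5 ms after each peak (absolute mV); slow AHP depth = minimum voltage
#' between neighboring spikes excluding the first 5 ms; time to first spike =
#' first peak minus stimulus onset; mean frequency = spike count over the
#' onset-to-last-spike interval (Hz); adaptation index = mean of
#' `(ISI_{k+1} - ISI_k)/(ISI_{k+1} + ISI_k)`; ISI CV = sd(ISI)/mean(ISI)
#' (sample sd). Per-spike quantities are averaged over spikes. Features that
#' need spikes (or >= 2/3 spikes) are `NA` when undefined.
#'
#' @param trace a `grc_trace`.
#' @param spikes optional precomputed [detect_spikes()] result.
#' @param stim_onset,stim_offset stimulus window, ms (defaults from a step
#'   protocol attached to the trace).
#' @param compartment voltage column to analyse.
#' @inheritParams detect_spikes
#' @return named numeric vector over [feature_names()].
#' @export
extract_features <- function(trace, spikes = NULL, stim_onset = NULL,
                             stim_offset = NULL, compartment = 1,
                             threshold = -20, refractory = 1,
                             dvdt_threshold = 20) {
  if (is.null(stim_onset) && inherits(trace$protocol, "grc_protocol")) {
    stim_onset <- trace$protocol$onset
    stim_offset <- trace$protocol$offset
  }
  if (is.null(stim_onset)) stop("stimulus window unknown")
  t <- trace$time
  v <- trace$v
  if (is.matrix(v)) v <- v[, compartment]
  if (is.null(spikes))
    spikes <- detect_spikes(trace, threshold, refractory, compartment,
                            dvdt_threshold)
  dt <- t[2] - t[1]
  f <- setNames(rep(NA_real_, 10), feature_names())

  pre <- t < stim_onset
  f["resting_voltage"] <- if (any(pre)) mean(v[pre]) else v[1]

  n <- nrow(spikes)
  if (n >= 1) {
    f["AP_height"] <- mean(spikes$peak_v)
    f["time_to_first_spike"] <- spikes$peak_time[1] - stim_onset
    if (spikes$peak_time[n] > stim_onset)
      f["mean_frequency"] <- n / (spikes$peak_time[n] - stim_onset) * 1000

    N <- length(v)
    # local index window around [a, b] (pads 2 samples; mask applied on the
    # short slice so the semantics match a full-vector mask exactly)
    win_min <- function(a, b, left_open = TRUE, right_open = FALSE) {
      rng <- max(1, floor(a / dt)):min(N, ceiling(b / dt) + 2)
      tt <- t[rng]
      w <- (if (left_open) tt > a else tt >= a) &
        (if (right_open) tt < b else tt <= b)
      if (any(w)) min(v[rng][w]) else NA_real_
    }
    widths <- half_widths <- ahp <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      thv <- spikes$threshold_v[k]
      pk_i <- min(N, max(1, round(spikes$peak_time[k] / dt) + 1))
      if (!is.na(thv)) {
        i0 <- pk_i
        while (i0 > 1 && v[i0 - 1] >= thv && t[pk_i] - t[i0 - 1] < 5) i0 <- i0 - 1
        i1 <- pk_i
        while (i1 < N && v[i1 + 1] >= thv && t[i1 + 1] - t[pk_i] < 5) i1 <- i1 + 1
        widths[k] <- .cross_width(t, v, i0, i1, pk_i, thv)
        hv <- thv + 0.5 * (spikes$peak_v[k] - thv)
        j0 <- pk_i; while (j0 > i0 && v[j0 - 1] >= hv) j0 <- j0 - 1
        j1 <- pk_i; while (j1 < i1 && v[j1 + 1] >= hv) j1 <- j1 + 1
        half_widths[k] <- .cross_width(t, v, j0, j1, pk_i, hv)
      }
      # fast AHP: minimum within 5 ms after the peak
      ahp[k] <- win_min(spikes$peak_time[k], spikes$peak_time[k] + 5)
    }
    f["AP_width"] <- mean(widths, na.rm = TRUE)
    f["AP_half_width"] <- mean(half_widths, na.rm = TRUE)
    f["AHP_depth"] <- mean(ahp, na.rm = TRUE)
  }
  if (n >= 2) {
    N <- length(v)
    win_min2 <- function(a, b) {
      rng <- max(1, floor(a / dt)):min(N, ceiling(b / dt) + 2)
      tt <- t[rng]
      w <- tt > a & tt < b
      if (any(w)) min(v[rng][w]) else NA_real_
    }
    slow <- vapply(seq_len(n - 1), function(k)
      win_min2(spikes$peak_time[k] + 5, spikes$peak_time[k + 1]), numeric(1))
    f["AHP_depth_slow"] <- mean(slow, na.rm = TRUE)
    isi <- diff(spikes$peak_time)
    if (length(isi) >= 2) {
      f["ISI_CV"] <- sd(isi) / mean(isi)
      r <- diff(isi) / (isi[-1] + isi[-length(isi)])
      f["adaptation_index"] <- mean(r)
    }
  }
  f
}

# linear-interpolated width of the region above level `lev` around the peak
.cross_width <- function(t, v, i0, i1, pk, lev) {
  tl <- t[i0]
  if (i0 > 1 && v[i0 - 1] < lev)
    tl <- t[i0 - 1] + (lev - v[i0 - 1]) / (v[i0] - v[i0 - 1]) * (t[i0] - t[i0 - 1])
  tr <- t[i1]
  if (i1 < length(v) && v[i1 + 1] < lev)
    tr <- t[i1] + (v[i1] - lev) / (v[i1] - v[i1 + 1]) * (t[i1 + 1] - t[i1])
  tr - tl
}

#' Score model features against a template
#'
#' Each objective is a z-like distance `|feature - mean| / sd` for one
#' (feature, stimulus) pair. Features that are undefined in the model trace
#' (e.g. no spikes) receive the penalty score, so non-spiking individuals rank
#' behind any spiking one.
#'
#' @param features named list: one feature vector (from [extract_features()])
#'   per stimulus amplitude, names = amplitudes in pA.
#' @param template a template data.frame as returned by [read_templates()] or
#'   [reference_templates()] (columns `feature`, `stim_pA`, `mean`, `sd`).
#' @param penalty score assigned to missing features.
#' @return named numeric vector of objectives (`feature@stim`).
#' @export
objective_scores <- function(features, template, penalty = 250) {
  stopifnot(all(c("feature", "stim_pA", "mean", "sd") %in% names(template)))
  if (any(template$sd <= 0)) stop("template sds must be positive")
  out <- numeric(0)
  for (s in names(features)) {
    fs <- features[[s]]
    tm <- template[template$stim_pA == as.numeric(s), ]
    for (r in seq_len(nrow(tm))) {
      val <- fs[[tm$feature[r]]]
      z <- if (is.null(val) || is.na(val)) penalty
           else abs(val - tm$mean[r]) / tm$sd[r]
      out[paste0(tm$feature[r], "@", s)] <- z
    }
  }
  out
}

#' Feature templates: read, write, and the shipped reference table
#'
#' Templates are CSV tables with one row per (feature, stimulus): columns
#' `feature`, `stim_pA`, `mean`, `sd`.
#'
#' @param which `"exp"` for the experimental columns of the shipped reference
#'   table, `"model"` for its published-model columns.
#' @return a data.frame of class `grc_template`.
#' @export
reference_templates <- function(which = c("exp", "model")) {
  which <- match.arg(which)
  tab <- read.csv(.extdata("reference-features.csv"), stringsAsFactors = FALSE)
  out <- data.frame(feature = tab$feature, stim_pA = tab$stim_pA,
                    mean = tab[[paste0(which, "_mean")]],
                    sd = tab[[paste0(which, "_sd")]],
                    stringsAsFactors = FALSE)
  structure(out, class = c("grc_template", "data.frame"))
}

#' @rdname reference_templates
#' @param path CSV file path.
#' @export
read_templates <- function(path) {
  tm <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("feature", "stim_pA", "mean", "sd") %in% names(tm)))
  structure(tm, class = c("grc_template", "data.frame"))
}

#' @rdname reference_templates
#' @param template template data.frame.
#' @export
write_templates <- function(template, path) {
  write.csv(as.data.frame(template)[, c("feature", "stim_pA", "mean", "sd")],
            path, row.names = FALSE)
  invisible(path)
}
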