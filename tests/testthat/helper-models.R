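# shared fixtures: models, synthetic traces, independent oracles

# leak-only (passive) conductance vectors
passive_gmax <- function(mode = "mono") {
  rng <- parameter_ranges(mode)
  g <- setNames(rep(0, nrow(rng)), rng$gene)
  g[grep("^Lkg", names(g))] <- (rng$lo[grep("^Lkg", rng$gene)] +
                                  rng$hi[grep("^Lkg", rng$gene)]) / 2
  g
}

passive_mono <- function() granule_model("mono", gmax = passive_gmax("mono"))
passive_multi <- function() granule_model("multi", gmax = passive_gmax("multi"))

reference_mono <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- granule_model("mono")
    val
  }
})

reference_multi <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- granule_model("multi")
    val
  }
})

# synthetic voltage trace with Gaussian spikes at known peak times
synth_trace <- function(peak_times, dt = 0.025, total = NULL, base = -65,
                        amp = 90, width = 0.25, onset = 100) {
  if (is.null(total)) total <- max(peak_times) + 50
  t <- seq(0, total, by = dt)
  v <- rep(base, length(t))
  for (pk in peak_times) v <- v + amp * exp(-((t - pk) / width)^2 / 2)
  structure(list(time = t, v = matrix(v, dimnames = list(NULL, "soma")),
                 dt = dt,
                 protocol = step_protocol(10, onset = onset, offset = total,
                                          total = total)),
            class = "grc_trace")
}

# random spike-train trace under a fixed seed
random_synth_trace <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1)
  isis <- runif(n, 6, 40)
  peaks <- 120 + cumsum(isis)
  synth_trace(peaks, base = runif(1, -75, -60), amp = runif(1, 70, 105),
              width = runif(1, 0.2, 0.4))
}

# ---------------------------------------------------------------------------
# independent reference implementation of the ten features (same definitions,
# separately coded: vectorized crossings instead of the package's scan loops)
ref_features <- function(t, v, onset, threshold = -20, refractory = 1,
                         dvdt_threshold = 20) {
  dt <- t[2] - t[1]
  f <- setNames(rep(NA_real_, 10), c(
    "resting_voltage", "AP_height", "AP_width", "AP_half_width", "AHP_depth",
    "AHP_depth_slow", "time_to_first_spike", "mean_frequency",
    "adaptation_index", "ISI_CV"))
  f["resting_voltage"] <- mean(v[t < onset])

  up <- which(diff(v >= threshold) == 1) + 1
  down <- which(diff(v >= threshold) == -1)
  peaks <- c(); peak_v <- c(); thr_v <- c()
  for (u in up) {
    d <- down[down >= u][1]
    if (is.na(d)) d <- length(v)
    k <- (u:d)[which.max(v[u:d])]
    pt <- t[k]; pv <- v[k]
    den <- v[k - 1] - 2 * v[k] + v[k + 1]
    if (den < 0) {
      sh <- 0.5 * (v[k - 1] - v[k + 1]) / den
      pt <- t[k] + sh * dt
      pv <- v[k] - 0.25 * (v[k - 1] - v[k + 1]) * sh
    }
    if (length(peaks) && pt - peaks[length(peaks)] < refractory) next
    dv <- c(NA, diff(v)) / dt
    win <- max(2, k - round(5 / dt)):k
    hit <- win[which(dv[win] >= dvdt_threshold)[1]]
    peaks <- c(peaks, pt); peak_v <- c(peak_v, pv)
    thr_v <- c(thr_v, if (is.na(hit)) NA else v[hit])
  }
  n <- length(peaks)
  if (n >= 1) {
    f["AP_height"] <- mean(peak_v)
    f["time_to_first_spike"] <- peaks[1] - onset
    if (peaks[n] > onset) f["mean_frequency"] <- 1000 * n / (peaks[n] - onset)
    w <- hw <- ahp <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      pk_i <- which.min(abs(t - peaks[k]))
      if (!is.na(thr_v[k])) {
        w[k] <- crossing_width(t, v, pk_i, thr_v[k])
        hw[k] <- crossing_width(t, v, pk_i, thr_v[k] + (peak_v[k] - thr_v[k]) / 2)
      }
      m <- v[t > peaks[k] & t <= peaks[k] + 5]
      if (length(m)) ahp[k] <- min(m)
    }
    f["AP_width"] <- mean(w, na.rm = TRUE)
    f["AP_half_width"] <- mean(hw, na.rm = TRUE)
    f["AHP_depth"] <- mean(ahp, na.rm = TRUE)
  }
  if (n >= 2) {
    sl <- vapply(seq_len(n - 1), function(k) {
      m <- v[t > peaks[k] + 5 & t < peaks[k + 1]]
      if (length(m)) min(m) else NA_real_
    }, numeric(1))
    f["AHP_depth_slow"] <- mean(sl, na.rm = TRUE)
    isi <- diff(peaks)
    if (length(isi) >= 2) {
      f["ISI_CV"] <- sd(isi) / mean(isi)
      f["adaptation_index"] <- mean(diff(isi) / (isi[-1] + isi[-length(isi)]))
    }
  }
  f
}

# interpolated width of the contiguous region above `lev` around index pk_i,
# bounded to +-5 ms (mirrors the package definition)
crossing_width <- function(t, v, pk_i, lev) {
  dt <- t[2] - t[1]
  lim <- round(5 / dt)
  i0 <- pk_i
  while (i0 > 1 && v[i0 - 1] >= lev && pk_i - (i0 - 1) <= lim) i0 <- i0 - 1
  i1 <- pk_i
  while (i1 < length(v) && v[i1 + 1] >= lev && (i1 + 1) - pk_i <= lim) i1 <- i1 + 1
  tl <- t[i0]
  if (i0 > 1 && v[i0 - 1] < lev)
    tl <- t[i0 - 1] + (lev - v[i0 - 1]) / (v[i0] - v[i0 - 1]) * dt
  tr <- t[i1]
  if (i1 < length(v) && v[i1 + 1] < lev)
    tr <- t[i1] + (v[i1] - lev) / (v[i1] - v[i1 + 1]) * dt
  tr - tl
}

# ---------------------------------------------------------------------------
# brute-force IBEA oracle (direct transcription of the fitness definition)
bf_ibea_fitness <- function(obj, kappa = 0.05) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n == 1) return(0)
  lo <- apply(obj, 2, min); hi <- apply(obj, 2, max)
  rng <- ifelse(hi - lo == 0, 1, hi - lo)
  z <- sweep(sweep(obj, 2, lo), 2, rng, "/")
  I <- matrix(0, n, n)
  for (a in 1:n) for (b in 1:n) if (a != b) I[a, b] <- max(z[a, ] - z[b, ])
  cmax <- max(abs(I))
  if (cmax == 0) return(rep(0, n))
  f <- numeric(n)
  for (x in 1:n) for (y in 1:n) if (y != x)
    f[x] <- f[x] - exp(-I[y, x] / (cmax * kappa))
  f
}

# removal loop re-derived from the definition: indicator and scaling fixed on
# the full population, survivor fitness recomputed from scratch each round
bf_environmental_selection <- function(obj, n_keep, kappa = 0.05) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  lo <- apply(obj, 2, min); hi <- apply(obj, 2, max)
  rng <- ifelse(hi - lo == 0, 1, hi - lo)
  z <- sweep(sweep(obj, 2, lo), 2, rng, "/")
  I <- matrix(0, n, n)
  for (a in 1:n) for (b in 1:n) if (a != b) I[a, b] <- max(z[a, ] - z[b, ])
  cmax <- max(abs(I))
  E <- if (cmax == 0) matrix(1, n, n) else exp(-I / (cmax * kappa))
  diag(E) <- 0
  alive <- seq_len(n)
  while (length(alive) > n_keep) {
    f <- vapply(alive, function(x) -sum(E[setdiff(alive, x), x]), numeric(1))
    drop <- max(which(f == min(f)))
    alive <- alive[-drop]
  }
  alive
}

# ---------------------------------------------------------------------------
# pure-R right-hand side of the mono-compartment ODE system, built from the
# same channel specs; integrated with deSolve as an independent solver oracle
mono_rhs_system <- function(model, inj_nA, onset = 100) {
  kin <- model$kinetics
  tab <- model$channels
  area <- model$compartments$area_um2 * 1e-8
  C <- 1e3 * area
  gates <- list(); gmaxu <- c(); erevs <- c()
  for (r in seq_len(nrow(tab))) {
    kc <- kin$channels[[tab$kinetics[r]]]
    gmaxu[r] <- tab$density[r] * area * 1e3
    erevs[r] <- ifelse(tab$erev[r] == "ca", NA, as.numeric(tab$erev[r]))
    gates[[r]] <- kc$gates
  }
  calc <- model$calcium
  tk <- kin$temp_C + 273.15
  rhs <- function(t, y, parms) {
    V <- y[1]; ca <- y[2]
    eca <- 1000 * 8.314462618 * tk / (2 * 96485.33212) * log(calc$cao / ca)
    idx <- 3; Itot <- 0; ica <- 0
    dy <- numeric(length(y))
    for (r in seq_along(gates)) {
      gp <- 1
      for (g in gates[[r]]) {
        ss <- gate_steady_state(g, V, ca)
        dy[idx] <- (ss$minf - y[idx]) / ss$tau
        gp <- gp * y[idx]^g$p
        idx <- idx + 1
      }
      E <- if (is.na(erevs[r])) eca else erevs[r]
      I <- gmaxu[r] * gp * (V - E)
      if (is.na(erevs[r])) ica <- ica + I
      Itot <- Itot + I
    }
    dy[1] <- (-Itot + if (t >= onset) inj_nA else 0) / C
    ica_d <- ica * 1e-6 / area
    dy[2] <- -ica_d / (2 * 96485.33212 * calc$depth * 1e-4) -
      calc$beta * (ca - calc$carest)
    list(dy)
  }
  y0 <- c(V = model$v_init, ca = calc$carest)
  for (r in seq_along(gates)) for (g in gates[[r]])
    y0 <- c(y0, gate_steady_state(g, model$v_init, calc$carest)$minf)
  names(y0) <- c("V", "ca", paste0("g", seq_len(length(y0) - 2)))
  list(rhs = rhs, y0 = y0)
}
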