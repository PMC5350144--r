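#' Assemble a granule-cell model
#'
#' Builds the simulatable cell: compartments (geometry, passive properties),
#' channel placement with maximum conductances, and calcium pools.
#'
#' The mono-compartment model is a sphere of radius 9.76 um carrying the full
#' channel complement. The multi-compartment model has four dendrites
#' (15 x 0.75 um), a cylindrical soma (5.8 um diameter, 5.6 um length), an
#' axon initial segment (2.5 x 1.5 um) and a 70 x 0.3 um ascending axon split
#' into `n_axon` uniform segments; sodium channels live only on AIS and axon
#' (as a 13-state Markov scheme), Kir/Kslow/KA on the soma, KCa/Ca-HVA on the
#' dendrites and leak everywhere.
#'
#' @param mode `"mono"` or `"multi"`.
#' @param gmax named numeric vector of maximum conductances (mS/cm^2) keyed by
#'   gene name (see [parameter_ranges()]); missing entries default to the
#'   midpoint of the admissible range. May include `"Calc"`, the calcium-decay
#'   rate (1/ms).
#' @param kinetics a [kinetics_set()] (or its name).
#' @param n_axon number of axonal segments (multi mode).
#' @param ra axial resistivity, Ohm cm.
#' @param cm specific membrane capacitance, uF/cm^2.
#' @param v_init initialization voltage, mV (gates start at steady state here;
#'   a settling pre-run precedes every protocol).
#' @return an object of class `grc_model`.
#' @examples
#' m <- granule_model("mono")
#' m$compartments$area_um2  # ~1197 um^2
#' @export
granule_model <- function(mode = c("mono", "multi"), gmax = NULL,
                          kinetics = kinetics_set(), n_axon = 15,
                          ra = 100, cm = 1, v_init = NULL) {
  mode <- match.arg(mode)
  if (is.character(kinetics)) kinetics <- kinetics_set(kinetics)
  stopifnot(inherits(kinetics, "grc_kinetics"))
  if (is.null(v_init)) v_init <- if (mode == "mono") -65 else -76

  if (mode == "mono") {
    comps <- data.frame(
      label = "soma", kind = "sphere", diam = 2 * 9.76, length = NA_real_,
      parent = NA_integer_, position = 0, stringsAsFactors = FALSE)
  } else {
    geo <- granule_geometry_table()
    g <- function(s, f) geo[[f]][geo$section == s]
    seg_len <- g("axon", "length_um") / n_axon
    comps <- data.frame(
      label = c("soma", paste0("dend", 1:4), "AIS",
                sprintf("axon%02d", seq_len(n_axon))),
      kind = "cylinder",
      diam = c(g("soma", "diameter_um"), rep(g("dendrite", "diameter_um"), 4),
               g("AIS", "diameter_um"), rep(g("axon", "diameter_um"), n_axon)),
      length = c(g("soma", "length_um"), rep(g("dendrite", "length_um"), 4),
                 g("AIS", "length_um"), rep(seg_len, n_axon)),
      parent = c(NA, rep(1L, 4), 1L, 6L, 6L + seq_len(n_axon - 1)),
      stringsAsFactors = FALSE)
    # distance from the soma edge along the axonal path (compartment centers)
    pos <- numeric(nrow(comps))
    pos[6] <- g("AIS", "length_um") / 2
    pos[7:(6 + n_axon)] <- g("AIS", "length_um") +
      (seq_len(n_axon) - 0.5) * seg_len
    comps$position <- pos
  }
  comps$area_um2 <- ifelse(comps$kind == "sphere",
                           pi * comps$diam^2,            # 4*pi*r^2
                           pi * comps$diam * comps$length)

  tab <- granule_channel_table(mode)
  tab$gene <- ifelse(duplicated(tab$channel) | duplicated(tab$channel, fromLast = TRUE),
                     paste(tab$channel, tab$compartment, sep = "."), tab$channel)
  tab$density <- (tab$lo + tab$hi) / 2

  calcium <- kinetics$calcium
  if (mode == "multi" && !is.null(calcium$beta_multi))
    calcium$beta <- calcium$beta_multi
  if (!is.null(gmax)) {
    bad <- setdiff(names(gmax), c(tab$gene, "Calc"))
    if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
    hit <- intersect(names(gmax), tab$gene)
    tab$density[match(hit, tab$gene)] <- as.numeric(gmax[hit])
    if ("Calc" %in% names(gmax)) calcium$beta <- as.numeric(gmax[["Calc"]])
  }
  if (any(tab$density < 0)) stop("maximum conductances must be >= 0")
  missing_kin <- setdiff(tab$kinetics, names(kinetics$channels))
  if (length(missing_kin))
    stop("kinetics set lacks channel(s): ", paste(missing_kin, collapse = ", "))

  structure(list(mode = mode, compartments = comps, channels = tab,
                 kinetics = kinetics, calcium = calcium, ra = ra, cm = cm,
                 n_axon = if (mode == "multi") n_axon else 0L,
                 v_init = v_init),
            class = "grc_model")
}

#' @export
print.grc_model <- function(x, ...) {
  cat(sprintf("granule-cell model (%s): %d compartment(s), %d conductance gene(s)\n",
              x$mode, nrow(x$compartments), nrow(x$channels)))
  cat(sprintf("kinetics set: %s; Ra = %g Ohm cm; Cm = %g uF/cm^2; v_init = %g mV\n",
              x$kinetics$name, x$ra, x$cm, x$v_init))
  invisible(x)
}

#' Build a model from a configuration list or YAML file
#'
#' Configuration schema: `mode` (`"mono"`/`"multi"`), optional `gmax` (named
#' list of maximum conductances, mS/cm^2), `kinetics` (set name or path),
#' `n_axon`, `ra`, `cm`, `v_init`.
#'
#' @param config a list or path to a YAML file.
#' @return a [granule_model()].
#' @export
build_model <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("mode", "gmax", "kinetics", "n_axon", "ra", "cm", "v_init")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (is.null(config$mode)) stop("config must name a mode")
  args <- config
  if (!is.null(args$gmax)) args$gmax <- unlist(args$gmax)
  if (is.null(args$kinetics)) args$kinetics <- kinetics_set()
  do.call(granule_model, args)
}

#' Axial coupling conductance between adjacent compartments
#'
#' Series resistance of the two half-cylinders,
#' `R = sum_i 4 * Ra * (L_i/2) / (pi * d_i^2)`, returned as a conductance.
#'
#' @param c1,c2 lists (or single data.frame rows) with fields `diam` and
#'   `length` in um.
#' @param ra axial resistivity, Ohm cm.
#' @return conductance in uS; symmetric in its compartment arguments.
#' @examples
#' cyl <- list(diam = 1, length = 10)
#' 1 / axial_conductance(cyl, cyl, 100) # ~0.01273 MOhm^-1 => 12.73 MOhm
#' @export
axial_conductance <- function(c1, c2, ra = 100) {
  half_r <- function(cc) {
    d <- cc$diam * 1e-4; l <- cc$length * 1e-4  # cm
    if (is.na(d) || d <= 0) stop("compartment needs a positive diameter")
    if (is.na(l) || l <= 0) stop("compartment needs a positive length")
    4 * ra * (l / 2) / (pi * d^2)               # Ohm
  }
  r <- half_r(c1) + half_r(c2)
  1e6 / r                                        # uS
}

# ---------------------------------------------------------------------------
# compile a grc_model into the integrator's flat representation

.compile_model <- function(model) {
  stopifnot(inherits(model, "grc_model"))
  comps <- model$compartments
  n <- nrow(comps)
  area_cm2 <- comps$area_um2 * 1e-8
  cm_nf <- model$cm * area_cm2 * 1e3   # uF/cm^2 * cm^2 = uF -> nF
  ga <- numeric(n)
  if (n > 1) {
    for (i in 2:n) {
      p <- comps$parent[i]
      ga[i] <- axial_conductance(comps[i, ], comps[p, ], model$ra)
    }
  }
  # soma treated as cylinder for coupling in multi mode (already is); for the
  # mono sphere there is nothing to couple.

  kin <- model$kinetics$channels
  chans <- list()
  pool_comps <- integer(0)
  comp_idx <- function(pattern) {
    hit <- switch(pattern,
      soma = which(comps$label == "soma"),
      dendrite = grep("^dend", comps$label),
      AIS = which(comps$label == "AIS"),
      axon = grep("^axon", comps$label),
      which(comps$label == pattern))
    if (!length(hit)) stop("channel placed on undefined compartment: ", pattern)
    hit
  }
  for (r in seq_len(nrow(model$channels))) {
    row <- model$channels[r, ]
    kc <- kin[[row$kinetics]]
    erev_ca <- identical(row$erev, "ca")
    for (ci in comp_idx(row$compartment)) {
      ch <- list(comp = ci - 1L,
                 gbar_us = row$density * area_cm2[ci] * 1e3,
                 erev = if (erev_ca) 0 else as.numeric(row$erev),
                 erev_ca = erev_ca,
                 carries_ca = isTRUE(kc$carries_ca) || erev_ca,
                 gates = if (identical(kc$kind, "hh"))
                   lapply(kc$gates, `[[`, "enc") else list(),
                 markov = if (identical(kc$kind, "markov"))
                   unclass(kc$params) else NULL,
                 gene = row$gene, name = row$channel,
                 label = comps$label[ci])
      if (ch$carries_ca) pool_comps <- union(pool_comps, ci)
      chans[[length(chans) + 1L]] <- ch
    }
  }
  capools <- NULL
  if (length(pool_comps)) {
    calc <- model$calcium
    capools <- lapply(sort(pool_comps), function(ci)
      list(comp = ci - 1L, cao = calc$cao, carest = calc$carest,
           beta = calc$beta, depth_um = calc$depth, floor = calc$floor,
           temp_K = model$kinetics$temp_C + .KELVIN0))
  }
  list(parent = as.integer(ifelse(is.na(comps$parent), -1L, comps$parent - 1L)),
       cm_nf = cm_nf, ga_us = ga, area_cm2 = area_cm2,
       v_init = model$v_init, channels = chans, capools = capools,
       labels = comps$label,
       pool_labels = comps$label[sort(pool_comps)])
}
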