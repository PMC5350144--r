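#' Load a kinetics set
#'
#' A kinetics set is a versioned configuration file that fully determines the
#' gating kinetics of the channel complement (functional forms and rate
#' constants, normalized to 30 degrees C) plus the calcium-pool parameters.
#' The package ships the set `"grc2017"`.
#'
#' @param name set name or a path to a YAML file with the same schema.
#' @return a list of class `grc_kinetics` with elements `name`, `temp_C`,
#'   `calcium` and `channels` (a named list; each channel has `kind`
#'   `"hh"`/`"markov"` and either a list of `grc_gate`s or Markov parameters).
#' @export
kinetics_set <- function(name = "grc2017") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("kinetics-", name, ".yaml"), package = "grcopt")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown kinetics set: ", name)
  raw <- yaml::read_yaml(path)
  chans <- lapply(names(raw$channels), function(nm) {
    ch <- raw$channels[[nm]]
    if (identical(ch$kind, "markov")) {
      list(kind = "markov", params = do.call(markov_na_params, ch$params))
    } else {
      gates <- lapply(ch$gates, .parse_gate)
      list(kind = "hh", gates = gates,
           carries_ca = isTRUE(ch$carries_ca))
    }
  })
  names(chans) <- names(raw$channels)
  structure(list(name = raw$name, temp_C = raw$temp_C,
                 calcium = raw$calcium, channels = chans),
            class = "grc_kinetics")
}

.parse_gate <- function(g) {
  switch(g$kind,
    inf_tau = gate_inf_tau(g$name, g$p, g$vhalf, g$k, g$tau_min, g$tau_amp,
                           g$vt, g$k1, g$k2),
    ab = gate_ab(g$name, g$p,
                 alpha = list(form = g$alpha$form, A = g$alpha$A,
                              V0 = g$alpha$V0, K = g$alpha$K),
                 beta = list(form = g$beta$form, A = g$beta$A,
                             V0 = g$beta$V0, K = g$beta$K)),
    kca = gate_kca(g$name, g$p, g$Aa, g$Ba, g$Ka, g$Ab, g$Bb, g$Kb),
    stop("unknown gate kind: ", g$kind))
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "grcopt")
  if (!nzchar(path)) stop("missing shipped data file: ", file)
  path
}

#' Shipped granule-cell reference tables
#'
#' `granule_channel_table()` returns the channel complement of the mono- or
#' multi-compartment granule-cell model: placement, admissible maximum-
#' conductance range (mS/cm^2) and reversal potential (mV; `"ca"` marks the
#' dynamic calcium reversal). `granule_geometry_table()` returns the
#' multi-compartment morphology (um).
#'
#' @param mode `"mono"` or `"multi"`.
#' @return a data.frame.
#' @export
granule_channel_table <- function(mode = c("mono", "multi")) {
  mode <- match.arg(mode)
  read.csv(.extdata(paste0(mode, "-channels.csv")),
           stringsAsFactors = FALSE, colClasses = c(erev = "character"))
}

#' @rdname granule_channel_table
#' @export
granule_geometry_table <- function() {
  read.csv(.extdata("multi-geometry.csv"), stringsAsFactors = FALSE)
}
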