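#' Sample a ground-truth conductance vector
#'
#' Draws a maximum-conductance vector uniformly inside the admissible ranges
#' with a safety margin (default 5% of the range width per gene, so recovery
#' is never a boundary artifact) and, optionally, rejects candidates whose
#' model fails the three-step spiking validity criterion.
#'
#' @param ranges a [parameter_ranges()] table.
#' @param seed RNG seed.
#' @param margin fraction of the range width kept clear at both ends.
#' @param mode model mode used for the validity check.
#' @param kinetics kinetics set for the validity check.
#' @param validate require spikes at all `stimuli`.
#' @param stimuli validity-test amplitudes, pA.
#' @param trace_ms validity-test stimulus duration, ms.
#' @param max_tries resampling budget.
#' @return object of class `grc_ground_truth`: list with `gmax` (named
#'   vector), `seed`, `mode`.
#' @export
sample_ground_truth <- function(ranges, seed = 1, margin = 0.05,
                                mode = "mono", kinetics = kinetics_set(),
                                validate = TRUE, stimuli = c(10, 16, 22),
                                trace_ms = 1500, max_tries = 100) {
  stopifnot(all(ranges$lo < ranges$hi), margin >= 0, margin < 0.5)
  set.seed(seed)
  w <- ranges$hi - ranges$lo
  lo <- ranges$lo + margin * w
  hi <- ranges$hi - margin * w
  for (i in seq_len(max_tries)) {
    g <- setNames(runif(nrow(ranges), lo, hi), ranges$gene)
    if (!validate) return(structure(list(gmax = g, seed = seed, mode = mode),
                                    class = "grc_ground_truth"))
    m <- granule_model(mode, gmax = g, kinetics = kinetics)
    ok <- TRUE
    for (amp in stimuli) {
      tr <- try(simulate_model(m, step_protocol(amp, onset = 100,
                                                offset = 100 + trace_ms,
                                                total = 100 + trace_ms)),
                silent = TRUE)
      # valid ground truths must spike at every test step with every
      # template feature defined (otherwise no template can be built)
      if (inherits(tr, "try-error") || anyNA(extract_features(tr))) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(structure(list(gmax = g, seed = seed, mode = mode),
                             class = "grc_ground_truth"))
  }
  stop("no valid ground truth found in ", max_tries,
       " tries; inspect the parameter ranges")
}

#' Build feature templates from a ground truth
#'
#' Simulates the ground-truth model at the template stimuli, extracts the ten
#' features, and uses them as template means; sds are taken from the shipped
#' reference table (or a configured fraction of each mean). In `"gaussian"`
#' mode the means additionally receive Gaussian noise with those sds,
#' emulating experimental scatter; `"none"` (the default) keeps the means
#' noise-free so the sds act only as objective normalizers.
#'
#' @param gt a [sample_ground_truth()] result.
#' @param noise `"none"` or `"gaussian"`.
#' @param sds `"reference"` (shipped experimental sds) or a numeric fraction of
#'   the mean.
#' @param stimuli template stimuli, pA.
#' @param trace_ms stimulus duration used for feature extraction, ms.
#' @param kinetics kinetics set.
#' @param seed RNG seed for the noise realization.
#' @param dt integrator step, ms.
#' @return template data.frame of class `grc_template` (attributes carry the
#'   noise-free feature values).
#' @export
make_templates <- function(gt, noise = c("none", "gaussian"), sds = "reference",
                           stimuli = c(10, 16, 22), trace_ms = 2000,
                           kinetics = kinetics_set(), seed = 1, dt = 0.025) {
  noise <- match.arg(noise)
  stopifnot(inherits(gt, "grc_ground_truth"))
  m <- granule_model(gt$mode, gmax = gt$gmax, kinetics = kinetics)
  ref <- reference_templates("exp")
  rows <- list()
  for (amp in stimuli) {
    tr <- simulate_model(m, step_protocol(amp, onset = 100,
                                          offset = 100 + trace_ms,
                                          total = 100 + trace_ms), dt = dt)
    f <- extract_features(tr)
    if (anyNA(f))
      stop("ground-truth model has undefined feature(s) at ", amp,
           " pA; re-sample the ground truth")
    sd_vec <- if (identical(sds, "reference")) {
      rr <- ref[ref$stim_pA == amp, ]
      setNames(rr$sd, rr$feature)[names(f)]
    } else pmax(abs(f) * sds, 1e-6)
    rows[[as.character(amp)]] <- data.frame(feature = names(f), stim_pA = amp,
                                            mean = unname(f),
                                            sd = unname(sd_vec))
  }
  tmpl <- do.call(rbind, c(rows, make.row.names = FALSE))
  truth <- tmpl$mean
  if (noise == "gaussian") {
    set.seed(seed)
    tmpl$mean <- tmpl$mean + rnorm(nrow(tmpl), 0, tmpl$sd)
  }
  structure(tmpl, class = c("grc_template", "data.frame"),
            noise = noise, truth_means = truth, gt_seed = gt$seed)
}

#' Parameter-recovery experiment
#'
#' Runs the IBEA optimization against templates generated from a known
#' ground-truth conductance vector and reports how closely the conductances
#' are re-found: per-gene percent errors of the best valid individual and of
#' the final population.
#'
#' @param gt a [sample_ground_truth()] result.
#' @param config an [opt_config()].
#' @param templates optional precomputed [make_templates()] result.
#' @param kinetics kinetics set.
#' @param noise template noise mode (when templates are built here).
#' @return list of class `grc_recovery`: `best` (genome), `best_deviation`
#'   (a [gmax_deviation()] for the best valid individual), `population_deviation`,
#'   `valid_fraction`, `failed` flag, `opt` (the raw optimization result).
#' @export
parameter_recovery <- function(gt, config, templates = NULL,
                               kinetics = kinetics_set(), noise = "none") {
  stopifnot(inherits(gt, "grc_ground_truth"))
  if (is.null(templates))
    templates <- make_templates(gt, noise = noise, stimuli = config$stimuli,
                                trace_ms = config$trace_ms,
                                kinetics = kinetics, seed = gt$seed,
                                dt = config$dt)
  model <- granule_model(gt$mode, kinetics = kinetics)
  ranges <- parameter_ranges(gt$mode)
  ranges <- ranges[ranges$gene %in% names(gt$gmax), , drop = FALSE]
  opt <- run_optimization(model, templates, config, ranges = ranges)
  fv <- filter_valid(opt, model, stimuli = config$stimuli,
                     trace_ms = config$trace_ms, dt = config$dt)
  if (!any(fv$valid)) {
    return(structure(list(failed = TRUE, valid_fraction = 0, opt = opt,
                          gt = gt),
                     class = "grc_recovery"))
  }
  sums <- rowSums(opt$objectives[fv$valid, , drop = FALSE])
  bestG <- fv$population[which.min(sums), ]
  structure(list(
    failed = FALSE,
    best = bestG,
    best_deviation = gmax_deviation(bestG, gt$gmax),
    population_deviation = gmax_deviation(fv$population, gt$gmax),
    valid_fraction = fv$fraction,
    opt = opt, gt = gt),
    class = "grc_recovery")
}
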