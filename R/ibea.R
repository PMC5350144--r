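#' Additive epsilon indicator
#'
#' Smallest translation `eps` such that `a - eps` weakly dominates `b`
#' (minimization): `eps = max_i (a_i - b_i)`. Negative iff `a` dominates `b`.
#'
#' @param a,b objective vectors of equal length.
#' @return scalar indicator value.
#' @export
epsilon_indicator <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors differ in length")
  max(a - b)
}

# objectives normalized to [0, 1] per dimension over the population;
# degenerate (constant) dimensions map to 0
.normalize_objectives <- function(obj) {
  lo <- apply(obj, 2, min)
  hi <- apply(obj, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  sweep(sweep(obj, 2, lo), 2, rng, "/")
}

# pairwise additive-epsilon matrix: I[y, x] = epsilon_indicator(obj[y,], obj[x,])
.indicator_matrix <- function(objn) {
  n <- nrow(objn)
  I <- matrix(0, n, n)
  for (y in seq_len(n)) for (x in seq_len(n))
    if (x != y) I[y, x] <- max(objn[y, ] - objn[x, ])
  I
}

#' IBEA fitness of a population
#'
#' `F(x) = sum_{y != x} -exp(-I(y, x) / (c * kappa))` with `I` the additive
#' epsilon indicator on objectives normalized to `[0, 1]` per dimension and
#' `c = max |I|` over all pairs. Larger fitness is better (individuals that
#' few others nearly-dominate lose little). A population of one has fitness 0.
#'
#' @param obj numeric matrix, one row of (minimized) objectives per individual.
#' @param kappa indicator scaling factor (> 0).
#' @return numeric fitness vector.
#' @export
ibea_fitness <- function(obj, kappa = 0.05) {
  stopifnot(kappa > 0)
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n == 1) return(0)
  I <- .indicator_matrix(.normalize_objectives(obj))
  cmax <- max(abs(I))
  if (cmax == 0) return(rep(0, n))
  E <- exp(-I / (cmax * kappa))
  diag(E) <- 0
  -colSums(E)
}

#' Environmental selection (iterated worst-removal)
#'
#' Repeatedly removes the individual with the worst IBEA fitness and adds the
#' removed individual's indicator contribution back to the survivors' fitness,
#' until `n_keep` remain. Fitness ties are broken by stable population index
#' (the later individual is removed, so earlier individuals are retained).
#'
#' @inheritParams ibea_fitness
#' @param n_keep survivors to retain.
#' @return integer vector: indices of the retained individuals (ascending).
#' @export
environmental_selection <- function(obj, n_keep, kappa = 0.05) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  stopifnot(n >= n_keep)
  if (n == n_keep) return(seq_len(n))
  I <- .indicator_matrix(.normalize_objectives(obj))
  cmax <- max(abs(I))
  E <- if (cmax == 0) matrix(1, n, n) else exp(-I / (cmax * kappa))
  diag(E) <- 0
  fit <- -colSums(E)
  alive <- rep(TRUE, n)
  for (drop in seq_len(n - n_keep)) {
    cand <- which(alive)
    fc <- fit[cand]
    # ties broken by stable population index: the later individual is removed
    worst <- cand[max(which(fc == min(fc)))]
    alive[worst] <- FALSE
    fit <- fit + E[worst, ]               # remove its contribution to others
  }
  which(alive)
}

#' Parameter ranges of the optimized conductances
#'
#' One row per gene: name, placement, admissible `[lo, hi]` (mS/cm^2) taken
#' from the shipped channel tables. Optionally appends the calcium-decay gene
#' `"Calc"` (1/ms).
#'
#' @param mode `"mono"` or `"multi"`.
#' @param include_calc also optimize the calcium decay rate.
#' @return data.frame of class `grc_ranges` with columns `gene`,
#'   `compartment`, `lo`, `hi`.
#' @export
parameter_ranges <- function(mode = c("mono", "multi"), include_calc = FALSE) {
  mode <- match.arg(mode)
  tab <- granule_channel_table(mode)
  gene <- ifelse(duplicated(tab$channel) | duplicated(tab$channel, fromLast = TRUE),
                 paste(tab$channel, tab$compartment, sep = "."), tab$channel)
  out <- data.frame(gene = gene, compartment = tab$compartment,
                    lo = tab$lo, hi = tab$hi, stringsAsFactors = FALSE)
  if (include_calc) {
    beta0 <- if (identical(mode, "multi")) 0.1 else 1.5
    out <- rbind(out, data.frame(gene = "Calc", compartment = "soma",
                                 lo = 0.8 * beta0, hi = 1.2 * beta0))
  }
  stopifnot(all(out$lo < out$hi))
  structure(out, class = c("grc_ranges", "data.frame"))
}

#' Optimization configuration
#'
#' Defaults follow the published protocol: population 150 (mono) or 200
#' (multi), 50 generations per cycle, 10 cycles, individual mutation and
#' recombination probabilities 0.5, per-gene swap probability 0.25, objectives
#' built from the 10/16/22 pA steps.
#'
#' @param population even population size.
#' @param generations generations per cycle.
#' @param cycles number of optimization cycles; between cycles the parameter
#'   range is reset around the best decile and the population re-seeded.
#' @param p_mut,p_recomb individual mutation/recombination probabilities.
#' @param p_swap per-gene swap probability within recombination.
#' @param eta polynomial-mutation distribution index.
#' @param kappa IBEA indicator scaling.
#' @param stimuli step amplitudes (pA) used for the objectives.
#' @param trace_ms stimulus duration per evaluation, ms.
#' @param dt,settle integrator step and settling time, ms.
#' @param seed RNG seed (every run is reproducible from it).
#' @return list of class `grc_opt_config`.
#' @export
opt_config <- function(population = 150, generations = 50, cycles = 10,
                       p_mut = 0.5, p_recomb = 0.5, p_swap = 0.25,
                       eta = 20, kappa = 0.05, stimuli = c(10, 16, 22),
                       trace_ms = 2000, dt = 0.025, settle = 500, seed = 1) {
  stopifnot(population >= 2, population %% 2 == 0,
            all(c(p_mut, p_recomb, p_swap) >= 0),
            all(c(p_mut, p_recomb, p_swap) <= 1))
  structure(list(population = population, generations = generations,
                 cycles = cycles, p_mut = p_mut, p_recomb = p_recomb,
                 p_swap = p_swap, eta = eta, kappa = kappa, stimuli = stimuli,
                 trace_ms = trace_ms, dt = dt, settle = settle, seed = seed),
            class = "grc_opt_config")
}

#' Binary-tournament mating selection
#' @param fitness fitness vector (larger is better).
#' @param n number of parents to draw (with replacement).
#' @return integer indices of the selected parents.
#' @export
binary_tournament <- function(fitness, n) {
  i <- sample.int(length(fitness), n, replace = TRUE)
  j <- sample.int(length(fitness), n, replace = TRUE)
  ifelse(fitness[i] >= fitness[j], i, j)
}

#' Variation: recombination and polynomial mutation
#'
#' Parents are paired (1-2, 3-4, ...). With probability `p_recomb` a pair
#' exchanges each gene with probability `p_swap`; with probability `p_mut`
#' an offspring undergoes bounded polynomial mutation on every gene.
#' Offspring are clipped to the admissible ranges.
#'
#' @param parents numeric matrix of parent genomes (rows).
#' @param ranges a [parameter_ranges()] table.
#' @inheritParams opt_config
#' @return matrix of offspring, same shape as `parents`.
#' @export
vary <- function(parents, ranges, p_mut = 0.5, p_recomb = 0.5, p_swap = 0.25,
                 eta = 20) {
  off <- as.matrix(parents)
  n <- nrow(off); ng <- ncol(off)
  lo <- ranges$lo; hi <- ranges$hi
  for (k in seq_len(floor(n / 2))) {
    i <- 2 * k - 1; j <- 2 * k
    if (runif(1) < p_recomb) {
      swap <- runif(ng) < p_swap
      tmp <- off[i, swap]
      off[i, swap] <- off[j, swap]
      off[j, swap] <- tmp
    }
  }
  for (i in seq_len(n)) {
    if (runif(1) < p_mut) {
      for (g in seq_len(ng)) {
        w <- hi[g] - lo[g]
        if (w <= 0) next
        u <- runif(1)
        d <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
             else 1 - (2 * (1 - u))^(1 / (eta + 1))
        off[i, g] <- off[i, g] + d * w
      }
    }
  }
  off <- pmin(pmax(off, matrix(lo, n, ng, byrow = TRUE)),
              matrix(hi, n, ng, byrow = TRUE))
  off
}

# evaluate a genome matrix: simulate the stimuli, extract features, score.
# `cache` is an environment keyed by the genome so clones are not re-simulated.
.evaluate_genomes <- function(G, model, template, config, cache = NULL,
                              objective_fun = NULL) {
  n <- nrow(G)
  first <- NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    key <- paste(signif(G[i, ], 12), collapse = ",")
    if (!is.null(cache) && !is.null(cache[[key]])) {
      rows[[i]] <- cache[[key]]
    } else {
      val <- if (!is.null(objective_fun)) objective_fun(G[i, ])
             else .objectives_for_genome(G[i, ], model, template, config)
      rows[[i]] <- val
      if (!is.null(cache)) cache[[key]] <- val
    }
    if (is.null(first)) first <- rows[[i]]
  }
  do.call(rbind, rows)
}

.objectives_for_genome <- function(g, model, template, config) {
  m <- granule_model(model$mode, gmax = g, kinetics = model$kinetics,
                     n_axon = max(model$n_axon, 1L),
                     ra = model$ra, cm = model$cm, v_init = model$v_init)
  feats <- list()
  for (amp in config$stimuli) {
    tr <- try(simulate_model(m, step_protocol(amp, onset = 100,
                                              offset = 100 + config$trace_ms,
                                              total = 100 + config$trace_ms),
                             dt = config$dt, settle = config$settle),
              silent = TRUE)
    feats[[as.character(amp)]] <-
      if (inherits(tr, "try-error")) setNames(rep(NA_real_, 10), feature_names())
      else extract_features(tr)
  }
  objective_scores(feats, template)
}

#' Run the IBEA conductance optimization
#'
#' Evolves populations of maximum-conductance vectors against a feature
#' template. Each cycle runs `generations` generations of: IBEA fitness,
#' binary-tournament mating, recombination/mutation, evaluation of the
#' offspring, and environmental selection on the merged population. Between
#' cycles the admissible range of each gene is reset to the span of the top
#' decile of the final generation (widened by 10%, clipped to the initial
#' envelope) and the population is re-seeded inside the new range around the
#' carried-over best decile. Failed simulations score the penalty objective;
#' they never abort the run. Fully reproducible from `config$seed`.
#'
#' @param model a [granule_model()] whose mode/kinetics define the search.
#' @param template objective template ([reference_templates()] layout).
#' @param config an [opt_config()].
#' @param ranges optional [parameter_ranges()] override.
#' @param objective_fun optional replacement objective `function(genome)`
#'   returning the objective vector (used for algorithm tests on analytic
#'   problems).
#' @param verbose print per-generation progress.
#' @return object of class `grc_opt`: list with `population` (genome matrix of
#'   the final generation), `objectives`, `fitness`, `history` (per cycle:
#'   best/mean objective sum per generation), `ranges`, `config`,
#'   `evaluations`.
#' @export
run_optimization <- function(model, template, config = opt_config(),
                             ranges = NULL, objective_fun = NULL,
                             verbose = FALSE) {
  if (is.null(ranges)) ranges <- parameter_ranges(model$mode)
  ng <- nrow(ranges)
  init_env <- ranges
  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  npop <- config$population

  sample_pop <- function(rng, n) {
    G <- matrix(runif(n * ng, rep(rng$lo, each = n), rep(rng$hi, each = n)),
                nrow = n)
    colnames(G) <- rng$gene
    G
  }

  G <- sample_pop(ranges, npop)
  history <- list()
  obj <- NULL
  for (cyc in seq_len(config$cycles)) {
    if (cyc > 1) {
      # range reset around the top decile, then re-seed
      k <- max(2L, ceiling(npop * 0.10))
      top <- order(rowSums(obj))[seq_len(k)]
      topG <- G[top, , drop = FALSE]
      lo <- apply(topG, 2, min); hi <- apply(topG, 2, max)
      pad <- 0.10 * (init_env$hi - init_env$lo)
      ranges$lo <- pmax(init_env$lo, lo - pad)
      ranges$hi <- pmin(init_env$hi, hi + pad)
      G <- rbind(topG, sample_pop(ranges, npop - k))
      colnames(G) <- ranges$gene
    }
    obj <- .evaluate_genomes(G, model, template, config, cache, objective_fun)
    evals <- evals + nrow(G)
    curve_best <- curve_mean <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      fit <- ibea_fitness(obj, config$kappa)
      par_idx <- binary_tournament(fit, npop)
      off <- vary(G[par_idx, , drop = FALSE], ranges,
                  p_mut = config$p_mut, p_recomb = config$p_recomb,
                  p_swap = config$p_swap, eta = config$eta)
      obj_off <- .evaluate_genomes(off, model, template, config, cache,
                                   objective_fun)
      evals <- evals + nrow(off)
      Gall <- rbind(G, off)
      objall <- rbind(obj, obj_off)
      keep <- environmental_selection(objall, npop, config$kappa)
      G <- Gall[keep, , drop = FALSE]
      obj <- objall[keep, , drop = FALSE]
      sums <- rowSums(obj)
      curve_best[gen] <- min(sums)
      curve_mean[gen] <- mean(sums)
      if (verbose)
        message(sprintf("cycle %d gen %d: best %.3f mean %.3f",
                        cyc, gen, curve_best[gen], curve_mean[gen]))
    }
    history[[cyc]] <- data.frame(cycle = cyc,
                                 generation = seq_len(config$generations),
                                 best = curve_best, mean = curve_mean)
  }
  fit <- ibea_fitness(obj, config$kappa)
  structure(list(population = G, objectives = obj, fitness = fit,
                 history = do.call(rbind, history), ranges = ranges,
                 init_ranges = init_env, config = config,
                 evaluations = evals),
            class = "grc_opt")
}

#' Filter biologically valid individuals
#'
#' Retains individuals that fire at least one action potential at every test
#' amplitude (the validity criterion: models that never spike are not granule
#' cells).
#'
#' @param population genome matrix (or a `grc_opt` result).
#' @param model template [granule_model()] providing mode and kinetics.
#' @param stimuli test amplitudes, pA.
#' @param trace_ms stimulus duration, ms.
#' @param dt integrator step, ms.
#' @return list with `valid` (logical vector), `fraction`, and `population`
#'   (the valid genomes).
#' @export
filter_valid <- function(population, model, stimuli = c(10, 16, 22),
                         trace_ms = 2000, dt = 0.025) {
  G <- if (inherits(population, "grc_opt")) population$population
       else as.matrix(population)
  ok <- logical(nrow(G))
  for (i in seq_len(nrow(G))) {
    m <- granule_model(model$mode, gmax = G[i, ], kinetics = model$kinetics,
                       n_axon = max(model$n_axon, 1L), ra = model$ra,
                       cm = model$cm, v_init = model$v_init)
    good <- TRUE
    for (amp in stimuli) {
      tr <- try(simulate_model(m, step_protocol(amp, onset = 100,
                                                offset = 100 + trace_ms,
                                                total = 100 + trace_ms),
                               dt = dt), silent = TRUE)
      if (inherits(tr, "try-error") ||
          nrow(detect_spikes(tr)) == 0) { good <- FALSE; break }
    }
    ok[i] <- good
  }
  list(valid = ok, fraction = mean(ok), population = G[ok, , drop = FALSE])
}
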