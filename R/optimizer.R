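#' Electrophysiological feature targets for conductance optimization
#'
#' Experimental means and SEMs of the features used as optimization
#' objectives: pacemaker rate, step-evoked firing rates (+4, +16 pA), sag
#' amplitude at -16 pA, spike amplitude and half-width, the rebound
#' first-spike delay and first ISI after hyperpolarization, and the
#' passive input resistance. The step-rate
#' targets at +4 and +16 pA are derived from the pacemaker rate and the
#' f-I slope of the validated model (2.13 Hz/pA).
#'
#' @return Data frame with columns `feature`, `mean`, `sem`.
#' @export
sc_feature_targets <- function() {
  data.frame(
    feature = c("freq_0", "freq_4", "freq_16", "sag", "amplitude",
                "half_width", "rebound_delay", "rebound_isi", "r_input"),
    mean = c(24.2, 32.7, 58.3, 10.3, 37.3, 1.0, 17.2, 20.1, 0.75),
    sem = c(2.1, 3.0, 4.4, 2.0, 5.2, 0.2, 2.3, 1.0, 0.06))
}

#' Parameter space of the 36 free conductances
#'
#' @param center optional named vector to center the bounds on (defaults to
#'   the layout's `default` column).
#' @param spread multiplicative half-range: bounds are
#'   `center/spread .. center*spread`.
#' @return Data frame with `name`, `low`, `high`, `center` (S/cm2).
#' @export
parameter_space <- function(center = NULL, spread = 10) {
  lay <- conductance_layout()
  ctr <- if (is.null(center)) setNames(lay$default, rownames(lay))
         else center[rownames(lay)]
  data.frame(name = rownames(lay), low = ctr / spread, high = ctr * spread,
             center = ctr, row.names = rownames(lay))
}

#' Evaluate one conductance genome against the feature targets
#'
#' Runs the standard battery (spontaneous, +4, +16, -16 pA; 2-s steps) on
#' the model carrying `genome` and returns the SEM-normalized error for
#' every target feature. Integration failures yield the penalty score on
#' every objective.
#'
#' @param genome named conductance vector (the 36 slots, S/cm2).
#' @param model a `cmodel` whose conductances are replaced by `genome`.
#' @param targets a [sc_feature_targets()] data frame.
#' @param penalty fitness assigned on failure / missing features.
#' @param pre,post settle time before and padding after each step (ms).
#' @return Named numeric vector of objective values (>= 0).
#' @export
evaluate_genome <- function(genome, model, targets = sc_feature_targets(),
                            penalty = 250, pre = 600, post = 600) {
  m <- set_conductances(model, genome)
  vals <- tryCatch({
    f0 <- .step_features(run_protocol(m, step_protocol(0, dur = 2000,
                                                       pre = pre, post = 0)),
                         pre, 2000, 0)
    f4 <- .step_features(run_protocol(m, step_protocol(4, dur = 2000,
                                                       pre = pre, post = 0)),
                         pre, 2000, 4)
    f16 <- .step_features(run_protocol(m, step_protocol(16, dur = 2000,
                                                        pre = pre, post = 0)),
                          pre, 2000, 16)
    fm <- .step_features(run_protocol(m, step_protocol(-16, dur = 2000,
                                                       pre = pre, post = post)),
                         pre, 2000, -16)
    list(freq_0 = f0$ap_freq, freq_4 = f4$ap_freq, freq_16 = f16$ap_freq,
         sag = fm$sag_mV,
         amplitude = if (is.null(f0$amplitude)) NA else f0$amplitude,
         half_width = if (is.null(f0$half_width)) NA else f0$half_width,
         rebound_delay = fm$first_spike_delay_ms,
         rebound_isi = fm$first_isi_ms,
         r_input = input_resistance(m, settle = 1000, dur = 1000))
  }, error = function(e) NULL)
  if (is.null(vals))
    return(setNames(rep(penalty, nrow(targets)), targets$feature))
  fitness(vals, targets, penalty = penalty)
}

# additive epsilon indicator I(a dominates-by b): smallest shift making a
# weakly dominate b (on normalized objectives)
.eps_indicator <- function(fa, fb) max(fa - fb)

# IBEA fitness of each individual from the pairwise indicator matrix
.ibea_fitness <- function(fits, kappa = 0.05) {
  n <- nrow(fits)
  rng <- apply(fits, 2, function(x) diff(range(x)))
  rng[rng == 0] <- 1
  norm <- sweep(fits, 2, apply(fits, 2, min))
  norm <- sweep(norm, 2, rng, "/")
  ind <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) ind[i, j] <- .eps_indicator(norm[i, ], norm[j, ])
  c_abs <- max(abs(ind)); if (c_abs == 0) c_abs <- 1
  f <- numeric(n)
  for (i in seq_len(n))
    f[i] <- sum(-exp(-ind[-i, i] / (kappa * c_abs)))
  f
}

# non-dominated filter
.pareto_front <- function(fits) {
  n <- nrow(fits)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !keep[i]) next
    if (all(fits[j, ] <= fits[i, ]) && any(fits[j, ] < fits[i, ]))
      keep[i] <- FALSE
  }
  keep
}

#' Indicator-based evolutionary optimization (IBEA)
#'
#' Generic multi-objective minimizer using the additive-epsilon indicator:
#' binary-tournament mating on the indicator fitness, blend crossover and
#' lognormal (or gaussian) mutation, and indicator-based environmental
#' selection of the merged parent+offspring pool.
#'
#' @param objective function(genome) -> numeric vector of objectives
#'   (minimized).
#' @param lower,upper bounds (vectors of equal length).
#' @param pop_size population size (>= 2).
#' @param generations number of generations (>= 1).
#' @param seed random seed.
#' @param kappa IBEA scaling constant.
#' @param p_mut per-gene mutation probability.
#' @param sigma_mut mutation width (log units when `log_space`).
#' @param init optional list of genomes to seed into the first population.
#' @param log_space search in log-parameter space (for strictly positive
#'   parameters such as conductances).
#' @param checkpoint_dir if given, the population and fitness matrix are
#'   written there as JSON after every generation.
#' @param verbose print per-generation progress.
#' @return List with `archive` (non-dominated `genomes` + `fitness`),
#'   `hof` (lowest sum-of-objectives individual), `history`,
#'   `evaluations`, `seed`.
#' @export
ibea_optimize <- function(objective, lower, upper, pop_size = 20,
                          generations = 10, seed = 1, kappa = 0.05,
                          p_mut = 0.25, sigma_mut = 0.25, init = NULL,
                          log_space = TRUE, checkpoint_dir = NULL,
                          verbose = FALSE) {
  stopifnot(pop_size >= 2, generations >= 1, length(lower) == length(upper),
            all(upper > lower))
  set.seed(seed)
  d <- length(lower)
  enc <- if (log_space) log else identity
  dec <- if (log_space) exp else identity
  llo <- enc(lower); lhi <- enc(upper)
  rand_genome <- function() dec(llo + runif(d) * (lhi - llo))
  clip <- function(g) pmin(pmax(g, lower), upper)

  pop <- lapply(seq_len(pop_size), function(i) rand_genome())
  if (!is.null(init))
    for (i in seq_along(init)) if (i <= pop_size) pop[[i]] <- clip(init[[i]])
  evals <- 0
  eval_all <- function(genomes) {
    out <- lapply(genomes, function(g) { evals <<- evals + 1; objective(g) })
    do.call(rbind, out)
  }
  fits <- eval_all(pop)

  history <- data.frame(generation = integer(0), best_sum = numeric(0),
                        mean_sum = numeric(0), front_size = integer(0))
  best_sum <- Inf; hof <- NULL
  record_hof <- function(gen) {
    sums <- rowSums(fits)
    if (min(sums) < best_sum) {
      best_sum <<- min(sums)
      hof <<- list(genome = pop[[which.min(sums)]],
                   fitness = fits[which.min(sums), ],
                   sum = best_sum, generation = gen)
    }
  }
  record_hof(0)

  for (gen in seq_len(generations)) {
    fit_i <- .ibea_fitness(fits, kappa)
    tour <- function() {
      a <- sample.int(pop_size, 1); b <- sample.int(pop_size, 1)
      if (fit_i[a] >= fit_i[b]) a else b
    }
    children <- lapply(seq_len(pop_size), function(k) {
      pa <- enc(pop[[tour()]]); pb <- enc(pop[[tour()]])
      w <- runif(d, -0.1, 1.1)               # blend crossover
      child <- w * pa + (1 - w) * pb
      mut <- runif(d) < p_mut
      child[mut] <- child[mut] + rnorm(sum(mut), 0, sigma_mut)
      clip(dec(child))
    })
    cfits <- eval_all(children)
    pool <- c(pop, children)
    pfits <- rbind(fits, cfits)
    while (length(pool) > pop_size) {
      f <- .ibea_fitness(pfits, kappa)
      worst <- which.min(f)
      pool <- pool[-worst]
      pfits <- pfits[-worst, , drop = FALSE]
    }
    pop <- pool; fits <- pfits
    record_hof(gen)
    sums <- rowSums(fits)
    front <- .pareto_front(fits)
    history <- rbind(history, data.frame(
      generation = gen, best_sum = min(sums), mean_sum = mean(sums),
      front_size = sum(front)))
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(
        list(generation = gen, seed = seed, population = pop,
             fitness = fits, best_sum = best_sum),
        file.path(checkpoint_dir, sprintf("generation_%03d.json", gen)),
        auto_unbox = TRUE, digits = NA)
    }
    if (verbose)
      message(sprintf("gen %d: best %.2f mean %.2f front %d",
                      gen, min(sums), mean(sums), sum(front)))
  }
  front <- .pareto_front(fits)
  list(archive = list(genomes = pop[front],
                      fitness = fits[front, , drop = FALSE]),
       hof = hof, history = history, evaluations = evals, seed = seed)
}

#' Multi-objective evolutionary optimization of the 36 conductances
#'
#' Runs [ibea_optimize()] over the conductance space against the
#' electrophysiological feature targets; one individual of the initial
#' population starts at the space center (the package reference values).
#'
#' @param model a `cmodel` providing morphology and fixed parameters.
#' @param space a [parameter_space()].
#' @param targets a [sc_feature_targets()] data frame.
#' @param pop_size population size (spec default 100; desk preset 20).
#' @param generations generation count (spec default 50; desk preset 10).
#' @param seed random seed (reproducible).
#' @param seed_center start one individual at the space center.
#' @param ... further arguments for [ibea_optimize()].
#' @return See [ibea_optimize()]; genomes carry the 36 slot names.
#' @export
optimize_conductances <- function(model, space = parameter_space(),
                                  targets = sc_feature_targets(),
                                  pop_size = 20, generations = 10, seed = 1,
                                  seed_center = TRUE, ...) {
  name_g <- function(g) setNames(g, space$name)
  res <- ibea_optimize(
    objective = function(g) evaluate_genome(name_g(g), model, targets),
    lower = space$low, upper = space$high,
    pop_size = pop_size, generations = generations, seed = seed,
    init = if (seed_center) list(space$center) else NULL, ...)
  res$archive$genomes <- lapply(res$archive$genomes, name_g)
  res$hof$genome <- name_g(res$hof$genome)
  res
}

#' Select the best model per morphology from optimization results
#'
#' Picks, for each optimization result, the archive individual with the
#' lowest weighted (SEM-normalized) total error; ties are broken by the
#' lower total conductance.
#'
#' @param results list of [optimize_conductances()] results (one per
#'   morphology).
#' @return List of named conductance vectors.
#' @export
select_best <- function(results) {
  lapply(results, function(r) {
    sums <- rowSums(r$archive$fitness)
    best <- which(sums == min(sums))
    if (length(best) > 1) {
      tot <- vapply(r$archive$genomes[best], sum, 1.0)
      best <- best[which.min(tot)]
    }
    r$archive$genomes[[best]]
  })
}
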