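#' Configuration for the CPG parameter search
#'
#' Box-constrained genetic-algorithm search for oscillator parameters whose
#' simulated rhythm matches a target frequency. Default bounds bracket the
#' reference parameter set: tau1, tau2 in [0.01, 1] s, beta in [0.5, 20],
#' mu12/mu21 in [1, 10], c in [1, 100].
#'
#' @param target_freq Desired oscillation frequency in Hz (> 0).
#' @param bounds Named list of `c(low, high)` pairs for `tau1, tau2, beta,
#'   mu21, mu12, c`.
#' @param population_size,generations GA budget.
#' @param mutation_rate,crossover_rate Per-gene mutation and per-pair
#'   crossover probabilities, in \[0, 1\].
#' @param seed Integer seed; the whole search is deterministic given it.
#' @param stability_penalty Fitness penalty added when a candidate fails
#'   the empirical stability check (or blows up).
#' @param sim_dt,sim_duration Screening-resolution simulation settings used
#'   inside the fitness function; the returned winner is re-verified at
#'   1 ms.
#' @return A `cpg_search_config` list.
#' @export
cpg_search_config <- function(target_freq = 2.5,
                              bounds = list(tau1 = c(0.01, 1.0),
                                            tau2 = c(0.01, 1.0),
                                            beta = c(0.5, 20),
                                            mu21 = c(1, 10),
                                            mu12 = c(1, 10),
                                            c = c(1, 100)),
                              population_size = 50, generations = 40,
                              mutation_rate = 0.2, crossover_rate = 0.9,
                              seed = 1, stability_penalty = 100,
                              sim_dt = 0.002, sim_duration = 6) {
  if (target_freq <= 0) stop("cpg_search_config: target_freq must be > 0")
  needed <- c("tau1", "tau2", "beta", "mu21", "mu12", "c")
  if (!setequal(names(bounds), needed))
    stop("cpg_search_config: bounds must name exactly: ",
         paste(needed, collapse = ", "))
  bounds <- bounds[needed]
  for (nm in needed) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] > b[2])
      stop("cpg_search_config: bounds for '", nm, "' must be (low <= high)")
  }
  if (mutation_rate < 0 || mutation_rate > 1 ||
      crossover_rate < 0 || crossover_rate > 1)
    stop("cpg_search_config: rates must lie in [0, 1]")
  if (population_size < 4) stop("cpg_search_config: population_size >= 4")
  structure(list(target_freq = target_freq, bounds = bounds,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 seed = as.integer(seed),
                 stability_penalty = stability_penalty,
                 sim_dt = sim_dt, sim_duration = sim_duration),
            class = "cpg_search_config")
}

params_from_vector <- function(v) {
  cpg_params(tau1 = v[1], tau2 = v[2], beta = v[3],
             mu21 = v[4], mu12 = v[5], c = v[6])
}

#' Fitness of a CPG parameter set for a target frequency
#'
#' Absolute deviation of the simulated oscillation frequency from the
#' target, plus `stability_penalty` when the empirical stability check
#' fails. Simulation blow-ups are penalized, never raised. Lower is better.
#'
#' @param params A [cpg_params()].
#' @param target_freq Target frequency in Hz.
#' @param stability_penalty Penalty added on instability or blow-up.
#' @param dt,duration Simulation resolution used for scoring.
#' @return A single finite score (lower is better).
#' @export
cpg_fitness <- function(params, target_freq, stability_penalty = 100,
                        dt = 0.002, duration = 6) {
  dt <- min(dt, params$tau1 / 10)
  tr <- tryCatch(cpg_simulate(params, duration = duration, dt = dt),
                 error = function(e) NULL)
  if (is.null(tr)) return(stability_penalty + target_freq)
  f <- estimate_frequency(tr, discard = duration / 3)
  score <- abs(f - target_freq)
  # non-decay check on the trailing thirds, as in check_stability
  t_end <- tr$t[nrow(tr)]
  w <- duration / 3
  amp_last <- peak_to_peak(tr$y_out[tr$t >= t_end - w])
  amp_prev <- peak_to_peak(tr$y_out[tr$t >= t_end - 2 * w & tr$t < t_end - w])
  if (f <= 0 || amp_last <= 1e-3 || amp_last < 0.95 * amp_prev)
    score <- score + stability_penalty
  score
}

#' Genetic-algorithm search for CPG parameters
#'
#' Real-coded GA with tournament selection (size 3), uniform crossover,
#' Gaussian mutation with sd equal to 10\% of each bound range (clamped to
#' the box), and elitism of one. The best individual is re-scored at 1 ms
#' resolution before being returned. Deterministic given `config$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param config A [cpg_search_config()].
#' @return A `cpg_search` list: `best` ([cpg_params()]), `fitness` (score of
#'   the winner at screening resolution), `verified_freq` (frequency of the
#'   winner re-simulated at 1 ms), and `history` (data frame of per-
#'   generation best/mean fitness).
#' @export
cpg_search <- function(config) {
  stopifnot(inherits(config, "cpg_search_config"))
  lo <- vapply(config$bounds, `[`, numeric(1), 1)
  hi <- vapply(config$bounds, `[`, numeric(1), 2)
  npar <- length(lo)
  pop_n <- config$population_size
  score_one <- function(v)
    cpg_fitness(params_from_vector(v), config$target_freq,
                config$stability_penalty, config$sim_dt, config$sim_duration)

  run <- function() {
    pop <- matrix(stats::runif(pop_n * npar, rep(lo, each = pop_n),
                               rep(hi, each = pop_n)), nrow = pop_n)
    fit <- apply(pop, 1, score_one)
    if (all(fit >= config$stability_penalty) &&
        config$generations == 0L)
      stop("cpg_search: no feasible individual in the initial population; ",
           "widen the bounds")
    history <- data.frame(generation = integer(0), best = numeric(0),
                          mean = numeric(0))
    mut_sd <- 0.1 * (hi - lo)
    for (gen in seq_len(config$generations)) {
      elite_i <- which.min(fit)
      newpop <- matrix(NA_real_, pop_n, npar)
      newpop[1, ] <- pop[elite_i, ]
      i <- 2L
      while (i <= pop_n) {
        # tournament selection, size 3
        pick <- function() {
          cand <- sample.int(pop_n, 3)
          cand[which.min(fit[cand])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (stats::runif(1) < config$crossover_rate) {
          mask <- stats::runif(npar) < 0.5
          ch1 <- ifelse(mask, p1, p2)
          ch2 <- ifelse(mask, p2, p1)
        } else {
          ch1 <- p1; ch2 <- p2
        }
        for (ch in list(ch1, ch2)) {
          if (i > pop_n) break
          mut <- stats::runif(npar) < config$mutation_rate
          ch[mut] <- ch[mut] + stats::rnorm(sum(mut), 0, mut_sd[mut])
          newpop[i, ] <- pmin(pmax(ch, lo), hi)
          i <- i + 1L
        }
      }
      pop <- newpop
      fit <- apply(pop, 1, score_one)
      # elitism guarantees monotone best-so-far
      history <- rbind(history,
                       data.frame(generation = gen, best = min(fit),
                                  mean = mean(fit)))
    }
    if (all(fit >= config$stability_penalty))
      stop("cpg_search: every individual is infeasible (unstable); ",
           "widen the bounds")
    best_i <- which.min(fit)
    list(best = pop[best_i, ], fitness = fit[best_i], history = history)
  }
  res <- with_seed(config$seed, run())
  best <- params_from_vector(res$best)
  vtr <- cpg_simulate(best, duration = max(10, config$sim_duration),
                      dt = min(0.001, best$tau1 / 10))
  structure(list(best = best, fitness = res$fitness,
                 verified_freq = estimate_frequency(vtr, discard = 2),
                 history = res$history, config = config),
            class = "cpg_search")
}

#' @export
print.cpg_search <- function(x, ...) {
  cat(sprintf("CPG parameter search: target %.3g Hz -> achieved %.3g Hz\n",
              x$config$target_freq, x$verified_freq))
  cat(sprintf("  screening fitness %.4g after %d generations\n",
              x$fitness, nrow(x$history)))
  print(x$best)
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
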