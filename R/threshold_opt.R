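#' Optimiser configuration for peak-threshold tuning
#'
#' The peak threshold is encoded as a single real in \[`lower`, `upper`\]
#' (default \[2.0, 3.5\] g, the plausible wrist-worn range). The genetic
#' algorithm uses a population of 10 evolved for 10 generations with convex
#' crossover (probability 0.8, mate by binary tournament, offspring replaces
#' its parent only when fitter) and Gaussian mutation (probability 0.2,
#' unconditional replacement). Simulated annealing cools geometrically from
#' `T0` = 1.0 to `T_min` = 0.1 with `alpha` = 0.9 and 5 proposals per
#' temperature, accepting worse neighbours with probability
#' `exp((f(y) - f(x)) / T)`.
#'
#' Crossover and mutation are scheduled as one exclusive draw per individual
#' per generation (crossover with probability `p_crossover`, otherwise
#' mutation with probability `p_mutation`), so a run costs exactly
#' `pop_size * (generations + 1)` fitness evaluations at the default setting.
#'
#' @param lower,upper search range in g.
#' @param pop_size,generations GA population size and generation count.
#' @param p_crossover,p_mutation GA operator probabilities; their sum must
#'   not exceed 1 under the exclusive schedule.
#' @param T0,T_min,alpha,iters_per_T SA temperature schedule.
#' @param mutation_sigma standard deviation (g) of the Gaussian perturbation
#'   used by GA mutation and the SA neighbourhood. Default 0.05 g, about 3%
#'   of the search range.
#' @return an object of class `opt_config`.
#' @export
opt_config <- function(lower = 2.0, upper = 3.5,
                       pop_size = 10, generations = 10,
                       p_crossover = 0.8, p_mutation = 0.2,
                       T0 = 1.0, T_min = 0.1, alpha = 0.9, iters_per_T = 5,
                       mutation_sigma = 0.05) {
  if (lower >= upper) stop("lower must be below upper")
  if (p_crossover < 0 || p_mutation < 0 || p_crossover + p_mutation > 1 + 1e-12)
    stop("operator probabilities must be non-negative and sum to at most 1")
  if (!(T0 > T_min && T_min > 0)) stop("need T0 > T_min > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (pop_size < 1 || generations < 0 || iters_per_T < 1)
    stop("invalid population / iteration counts")
  if (mutation_sigma <= 0) stop("mutation_sigma must be positive")
  structure(list(lower = lower, upper = upper, pop_size = pop_size,
                 generations = generations, p_crossover = p_crossover,
                 p_mutation = p_mutation, T0 = T0, T_min = T_min,
                 alpha = alpha, iters_per_T = iters_per_T,
                 mutation_sigma = mutation_sigma),
            class = "opt_config")
}

#' Recording-level detection fitness
#'
#' Classifies each recording FALL when [detect_peaks()] at the candidate
#' threshold finds at least one peak, tallies the recording-level confusion
#' counts against the labels, and returns the geometric mean
#' `sqrt(Se * Sp)`, with the convention that a zero denominator (no FALL or
#' no NOT_FALL recordings) yields 0.
#'
#' @param threshold candidate peak threshold in g.
#' @param recordings list of labelled [accel_ts] with magnitude present.
#' @param quiet_ms quiet period passed to the detector.
#' @return the geometric-mean fitness in \[0, 1\].
#' @export
detection_fitness <- function(threshold, recordings, quiet_ms = 2500) {
  if (length(recordings) == 0L) stop("no recordings to evaluate")
  cfg <- peak_config(th1 = threshold, quiet_ms = quiet_ms)
  detected <- vapply(recordings,
                     function(r) length(detect_peaks(r, cfg)) > 0L, logical(1))
  truth <- vapply(recordings, function(r) r$label, character(1))
  if (anyNA(truth)) stop("all recordings must carry a FALL/NOT_FALL label")
  tp <- sum(detected & truth == "FALL")
  fn <- sum(!detected & truth == "FALL")
  fp <- sum(detected & truth == "NOT_FALL")
  tn <- sum(!detected & truth == "NOT_FALL")
  se <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  sp <- if (tn + fp == 0L) 0 else tn / (tn + fp)
  sqrt(se * sp)
}

new_opt_result <- function(algorithm, evals, seed) {
  # ties on the (often flat) fitness plateau are resolved toward the lowest
  # threshold: among equally fit candidates the most sensitive one is kept,
  # since an undetected fall is the costly error
  best_fit <- max(evals$fitness)
  structure(list(algorithm = algorithm,
                 best_threshold = min(evals$threshold[evals$fitness == best_fit]),
                 best_fitness = best_fit,
                 n_evaluations = nrow(evals),
                 evaluations = evals, seed = seed),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> %s: best threshold %.5f g, fitness %.4f (%d evaluations)\n",
              x$algorithm, x$best_threshold, x$best_fitness, x$n_evaluations))
  invisible(x)
}

#' Tune the peak threshold with a genetic algorithm
#'
#' Real-coded GA on the single peak-threshold gene. The population is
#' initialised uniformly in the search range; each generation every
#' individual undergoes, via one exclusive operator draw, either convex
#' crossover with a binary-tournament mate (offspring `l*x + (1-l)*mate`,
#' `l ~ U(0,1)`, replacing the parent only when fitter) or Gaussian mutation
#' (clamped to the range, replacing unconditionally — the returned optimum is
#' therefore the best threshold ever evaluated, not the final population
#' best).
#'
#' @param recordings list of labelled [accel_ts].
#' @param config an [opt_config].
#' @param seed integer seed; runs are reproducible.
#' @param quiet_ms quiet period for the detector.
#' @return an `opt_result`: `best_threshold`, `best_fitness`, the full
#'   evaluation trace and the evaluation count.
#' @export
optimize_ga <- function(recordings, config = opt_config(), seed = 1L,
                        quiet_ms = 2500) {
  stopifnot(inherits(config, "opt_config"))
  f <- function(th) detection_fitness(th, recordings, quiet_ms)
  clamp <- function(x) pmin(pmax(x, config$lower), config$upper)
  with_seed(seed, {
    evals <- list()
    note <- function(th, fit) evals[[length(evals) + 1L]] <<- c(th, fit)
    pop <- stats::runif(config$pop_size, config$lower, config$upper)
    fit <- vapply(pop, f, numeric(1))
    for (i in seq_along(pop)) note(pop[i], fit[i])
    for (gen in seq_len(config$generations)) {
      for (i in seq_len(config$pop_size)) {
        u <- stats::runif(1)
        if (u < config$p_crossover) {
          cand <- sample.int(config$pop_size, 2L, replace = TRUE)
          mate <- cand[which.max(fit[cand])]          # binary tournament
          lam <- stats::runif(1)
          child <- lam * pop[i] + (1 - lam) * pop[mate]
          fc <- f(child); note(child, fc)
          if (fc > fit[i]) { pop[i] <- child; fit[i] <- fc }
        } else if (u < config$p_crossover + config$p_mutation) {
          mut <- clamp(pop[i] + stats::rnorm(1, 0, config$mutation_sigma))
          fm <- f(mut); note(mut, fm)
          pop[i] <- mut; fit[i] <- fm                  # unconditional
        }
      }
    }
    ev <- do.call(rbind, evals)
    new_opt_result("GA", data.frame(threshold = ev[, 1L], fitness = ev[, 2L]),
                   seed)
  })
}

#' Tune the peak threshold with simulated annealing
#'
#' Single-solution search: start from a uniform random threshold, propose
#' Gaussian neighbours (clamped to the range), accept improvements always and
#' deteriorations with probability `exp((f(y) - f(x)) / T)`. The temperature
#' starts at `T0` and is multiplied by `alpha` after `iters_per_T` proposals
#' until it drops below `T_min`. Best-ever bookkeeping, as for the GA.
#'
#' @inheritParams optimize_ga
#' @return an `opt_result`.
#' @export
optimize_sa <- function(recordings, config = opt_config(), seed = 1L,
                        quiet_ms = 2500) {
  stopifnot(inherits(config, "opt_config"))
  f <- function(th) detection_fitness(th, recordings, quiet_ms)
  clamp <- function(x) pmin(pmax(x, config$lower), config$upper)
  with_seed(seed, {
    evals <- list()
    note <- function(th, fit) evals[[length(evals) + 1L]] <<- c(th, fit)
    x <- stats::runif(1, config$lower, config$upper)
    fx <- f(x); note(x, fx)
    temp <- config$T0
    while (temp >= config$T_min * (1 - 1e-9)) {
      for (it in seq_len(config$iters_per_T)) {
        y <- clamp(x + stats::rnorm(1, 0, config$mutation_sigma))
        fy <- f(y); note(y, fy)
        if (fy >= fx || stats::runif(1) < exp((fy - fx) / temp)) {
          x <- y; fx <- fy
        }
      }
      temp <- temp * config$alpha
    }
    ev <- do.call(rbind, evals)
    new_opt_result("SA", data.frame(threshold = ev[, 1L], fitness = ev[, 2L]),
                   seed)
  })
}

#' Repeated threshold-tuning runs with median reporting
#'
#' Runs the chosen metaheuristic `runs` times with consecutive seeds and
#' reports the per-run best thresholds and fitnesses together with their
#' medians, the headline statistic for repeated stochastic tuning runs.
#'
#' @param recordings list of labelled [accel_ts].
#' @param algorithm `"SA"` or `"GA"`.
#' @param runs number of independent runs (default 10).
#' @param seed base seed; run `i` uses `seed + i - 1`.
#' @param config an [opt_config].
#' @param quiet_ms quiet period for the detector.
#' @return list with `runs` (data.frame of seed, best_threshold,
#'   best_fitness, n_evaluations), `median_threshold`, `median_fitness` and
#'   `results` (the individual `opt_result` objects).
#' @export
tune_threshold <- function(recordings, algorithm = c("SA", "GA"), runs = 10,
                           seed = 1L, config = opt_config(), quiet_ms = 2500) {
  algorithm <- match.arg(algorithm)
  opt <- if (algorithm == "GA") optimize_ga else optimize_sa
  results <- lapply(seq_len(runs), function(i)
    opt(recordings, config, seed = seed + i - 1L, quiet_ms = quiet_ms))
  tab <- data.frame(
    seed = seed + seq_len(runs) - 1L,
    best_threshold = vapply(results, `[[`, numeric(1), "best_threshold"),
    best_fitness = vapply(results, `[[`, numeric(1), "best_fitness"),
    n_evaluations = vapply(results, `[[`, numeric(1), "n_evaluations"))
  list(runs = tab,
       median_threshold = stats::median(tab$best_threshold),
       median_fitness = stats::median(tab$best_fitness),
       results = results)
}
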