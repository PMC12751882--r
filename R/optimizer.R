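#' Differential-evolution control parameters
#'
#' Classical DE/rand/1/bin settings: population size NP, mutation factor F,
#' crossover rate CR, generation cap Gmax, and a convergence threshold
#' epsilon applied to the improvement of the best fitness over a 10-generation
#' window. Defaults are the standard settings used to fit the attenuation
#' coefficients (NP = 50, F = 0.6, CR = 0.9, Gmax = 100, eps = 1e-6) with
#' both coefficients searched in [1, 3]: below 1 would amplify rather than
#' attenuate, and 3 comfortably brackets the plausible optima.
#'
#' @param np Population size (>= 4; mutation needs three distinct partners).
#' @param f Mutation factor (> 0).
#' @param cr Crossover rate in (0, 1].
#' @param gmax Maximum number of generations.
#' @param eps Convergence threshold on best-fitness improvement.
#' @param bounds Two-column matrix (`lower`, `upper`), one row per searched
#'   dimension; lower bounds must be >= 1.
#' @param seed Optional RNG seed for a fully reproducible run.
#' @param window Convergence window in generations (default 10).
#' @return An object of class `de_config`.
#' @export
de_config <- function(np = 50, f = 0.6, cr = 0.9, gmax = 100, eps = 1e-6,
                      bounds = cbind(lower = c(1, 1), upper = c(3, 3)),
                      seed = NULL, window = 10) {
  if (np < 4) stop("np must be >= 4 (mutation draws three distinct members)")
  if (f <= 0) stop("f must be > 0")
  if (cr <= 0 || cr > 1) stop("cr must be in (0, 1]")
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2 || any(bounds[, 1] >= bounds[, 2])) {
    stop("bounds must be a two-column (lower < upper) matrix")
  }
  if (any(bounds[, 1] < 1)) stop("lower bounds must be >= 1")
  structure(list(np = as.integer(np), f = f, cr = cr,
                 gmax = as.integer(gmax), eps = eps, bounds = bounds,
                 seed = seed, window = as.integer(window)),
            class = "de_config")
}

#' Maximize a fitness function by differential evolution (DE/rand/1/bin)
#'
#' Uniform random initialization within bounds; mutation
#' `v = x_r1 + F (x_r2 - x_r3)` with three distinct members other than the
#' target; binomial crossover at rate CR with one forced dimension;
#' out-of-bounds components clipped to the bounds; greedy selection with ties
#' keeping the incumbent (fitness plateaus are common when the objective is
#' an accuracy on few pairs). Stops at Gmax generations or as soon as the
#' best fitness improved by less than `eps` over the last `window`
#' generations.
#'
#' @param fn Fitness function taking a numeric parameter vector, returning a
#'   scalar to maximize.
#' @param config A [de_config()] object.
#' @return An object of class `de_result`: list with `best_params`,
#'   `best_fitness`, `history` (data frame `generation`, `best`, `mean`),
#'   `generations_run`, `converged`.
#' @examples
#' fn <- function(p) -(p[1] - 1.5)^2 - (p[2] - 1.1)^2
#' res <- de_optimize(fn, de_config(np = 20, gmax = 60, seed = 1))
#' res$best_params
#' @export
de_optimize <- function(fn, config = de_config()) {
  stopifnot(inherits(config, "de_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  lo <- config$bounds[, 1]
  hi <- config$bounds[, 2]
  d <- length(lo)
  np <- config$np

  pop <- t(replicate(np, lo + runif(d) * (hi - lo)))
  if (d == 1) pop <- matrix(pop, ncol = 1)
  fit <- apply(pop, 1, fn)

  best_hist <- numeric(0)
  mean_hist <- numeric(0)
  converged <- FALSE
  g <- 0L
  while (g < config$gmax) {
    g <- g + 1L
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3)
      v <- pop[r[1], ] + config$f * (pop[r[2], ] - pop[r[3], ])
      jrand <- sample.int(d, 1)
      cross <- runif(d) < config$cr
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      u <- pmin(pmax(u, lo), hi)
      fu <- fn(u)
      if (fu > fit[i]) {          # ties keep the incumbent
        pop[i, ] <- u
        fit[i] <- fu
      }
    }
    best_hist[g] <- max(fit)
    mean_hist[g] <- mean(fit)
    if (g > config$window &&
        best_hist[g] - best_hist[g - config$window] < config$eps) {
      converged <- TRUE
      break
    }
  }

  b <- which.max(fit)
  structure(list(
    best_params = pop[b, ],
    best_fitness = fit[b],
    history = data.frame(generation = seq_len(g), best = best_hist,
                         mean = mean_hist),
    generations_run = g,
    converged = converged
  ), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("DE result: best fitness ", format(x$best_fitness), " at (",
      paste(sprintf("%.4f", x$best_params), collapse = ", "), ") after ",
      x$generations_run, " generations",
      if (x$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

# Cached training-accuracy evaluator over (delta_pos, delta_neg). Path
# spectra per drug and the shortest-path matrix depend only on topology, so
# they are computed once; each candidate then only re-derives the node sets
# and averages precomputed distances.
make_delta_evaluator <- function(train, network, profiles, hop_max = 2) {
  stopifnot(all(c("drug_a", "drug_b", "label") %in% names(train)),
            nrow(train) >= 1)
  drugs <- unique(c(train$drug_a, train$drug_b))
  missing <- setdiff(drugs, names(profiles))
  if (length(missing)) {
    stop("no drug profile for: ", paste(utils::head(missing, 3),
                                        collapse = ", "))
  }
  spectra <- lapply(profiles[drugs], path_spectrum, network = network,
                    hop_max = hop_max)
  reach <- unique(unlist(lapply(spectra, function(s) rownames(s$pos))))
  D <- if (length(reach)) {
    igraph::distances(as_igraph(network), v = reach, to = reach,
                      mode = "out")
  } else matrix(numeric(0), 0, 0)

  function(par) {
    dp <- par[1]
    dn <- par[2]
    ia <- lapply(spectra, ia_from_spectrum, delta_pos = dp, delta_neg = dn)
    correct <- vapply(seq_len(nrow(train)), function(i) {
      sa <- ia[[train$drug_a[i]]]
      sb <- ia[[train$drug_b[i]]]
      Ip <- names(sa)[sa > 0]; Im <- names(sa)[sa < 0]
      Jp <- names(sb)[sb > 0]; Jm <- names(sb)[sb < 0]
      qd <- function(I, J) {
        if (!length(I) || !length(J)) return(NA_real_)
        set_distance(NULL, I, J, dist_matrix = D)
      }
      rel <- relative_distances(qd(Ip, Jp), qd(Im, Jm), qd(Ip, Jm),
                                qd(Im, Jp))
      classify_combination(rel$d_plus, rel$d_minus) == train$label[i]
    }, logical(1))
    mean(correct)     # indeterminate calls never match a label: counted wrong
  }
}

#' Fit the attenuation coefficients by differential evolution
#'
#' Maximizes the training classification accuracy of the synergy/antagonism
#' call over labeled drug pairs as a function of (`delta_pos`, `delta_neg`),
#' using [de_optimize()]. Indeterminate calls count as errors.
#'
#' @param train Data frame with columns `drug_a`, `drug_b`, `label`
#'   (`synergism`/`antagonism`); non-empty.
#' @param network A `regnet` object.
#' @param profiles Named list of `drug_profile` objects covering every drug
#'   in `train`.
#' @param config A [de_config()] object.
#' @param hop_max Propagation hop cap (default 2).
#' @return A `de_result` whose `best_params` element is an
#'   [attenuation_params()] object; the raw parameter vector is kept in
#'   `best_par`.
#' @export
optimize_delta <- function(train, network, profiles, config = de_config(),
                           hop_max = 2) {
  fitness <- make_delta_evaluator(train, network, profiles, hop_max)
  res <- de_optimize(fitness, config)
  res$best_par <- res$best_params
  res$best_params <- attenuation_params(res$best_par[1], res$best_par[2],
                                        hop_max)
  res
}

#' Exhaustive grid search over the attenuation coefficients
#'
#' Evaluates the training accuracy at every (`delta_pos`, `delta_neg`) grid
#' point; the argmax is reported with ties broken toward smaller
#' (`delta_pos`, `delta_neg`) lexicographically. Fitness is order-free in the
#' training records.
#'
#' @param train,network,profiles As in [optimize_delta()].
#' @param grid_pos,grid_neg Numeric vectors of candidate coefficient values
#'   (non-empty).
#' @param hop_max Propagation hop cap (default 2).
#' @return List with `surface` (data frame `delta_pos`, `delta_neg`,
#'   `accuracy`), `best_params` ([attenuation_params()]), `best_accuracy`.
#' @export
grid_search_delta <- function(train, network, profiles,
                              grid_pos = seq(1, 3, by = 0.1),
                              grid_neg = seq(1, 3, by = 0.1),
                              hop_max = 2) {
  stopifnot(length(grid_pos) >= 1, length(grid_neg) >= 1)
  fitness <- make_delta_evaluator(train, network, profiles, hop_max)
  surface <- expand.grid(delta_pos = sort(grid_pos),
                         delta_neg = sort(grid_neg))
  surface <- surface[order(surface$delta_pos, surface$delta_neg), ]
  rownames(surface) <- NULL
  surface$accuracy <- vapply(seq_len(nrow(surface)), function(i) {
    fitness(c(surface$delta_pos[i], surface$delta_neg[i]))
  }, numeric(1))
  best <- which(surface$accuracy == max(surface$accuracy))[1]
  list(surface = surface,
       best_params = attenuation_params(surface$delta_pos[best],
                                        surface$delta_neg[best], hop_max),
       best_accuracy = surface$accuracy[best])
}
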