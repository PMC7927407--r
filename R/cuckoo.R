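#' Cuckoo Search configuration
#'
#' Defaults follow the published tuning setup: 40 nests, step size 1,
#' 500 generations, and box bounds k1, k3 in (0,100), b1, b2 in (0,1),
#' alpha in (0,5) for the five searched ranking parameters. The
#' abandonment probability `pa = 0.25` and Levy exponent `lambda = 1.5`
#' are the standard settings of the origin method.
#'
#' @param n Number of nests (>= 2).
#' @param step_size Step size T (> 0).
#' @param max_generation Generation cap.
#' @param pa Abandonment probability in (0,1).
#' @param lambda Levy exponent in (1,3].
#' @param lower,upper Per-dimension bounds (named vectors).
#' @param seed Random seed (integer) or NULL.
#' @return Object of class `cs_config`.
#' @export
cs_config <- function(n = 40, step_size = 1, max_generation = 500,
                      pa = 0.25, lambda = 1.5,
                      lower = c(k1 = 1e-6, k3 = 1e-6, b1 = 0, b2 = 0,
                                alpha = 0),
                      upper = c(k1 = 100, k3 = 100, b1 = 1, b2 = 1,
                                alpha = 5),
                      seed = NULL) {
  stopifnot(n >= 2, step_size > 0, max_generation >= 1,
            pa > 0, pa < 1, lambda > 1, lambda <= 3,
            length(lower) == length(upper))
  if (any(lower >= upper)) stop("infeasible bounds: lower >= upper")
  structure(list(n = n, step_size = step_size,
                 max_generation = max_generation, pa = pa, lambda = lambda,
                 lower = lower, upper = upper, seed = seed),
            class = "cs_config")
}

#' Heavy-tailed Levy-flight displacement
#'
#' Draws a `dimension`-long vector by the Mantegna construction with
#' stable index `beta = lambda - 1`, so that step lengths have the
#' power-law tail `p(s) ~ |s|^(-lambda)`. Deterministic under a fixed
#' RNG state.
#'
#' @param dimension Number of components (0 gives an empty vector).
#' @param lambda Levy exponent in (1,3].
#' @return Numeric vector of displacements.
#' @export
levy_step <- function(dimension, lambda = 1.5) {
  if (lambda <= 1 || lambda > 3) stop("lambda must be in (1, 3]")
  if (dimension == 0) return(numeric())
  beta <- lambda - 1
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(dimension, sd = sigma_u)
  v <- stats::rnorm(dimension)
  u / abs(v)^(1 / beta)
}

#' Propose a new nest position by Levy flight
#'
#' Applies the position update `X + T (*) Levy(lambda)` pointwise, with
#' the displacement modulated by `0.05 (X - X_best)` in the manner of
#' the origin method's reference implementation (steps shrink
#' automatically as a nest approaches the incumbent best, enabling fine
#' convergence), and clamps the result to the bounds.
#'
#' @param position Current position (within bounds).
#' @param best_position Incumbent best position.
#' @param config A [cs_config()].
#' @return New position vector (within bounds).
#' @export
cs_propose <- function(position, best_position, config) {
  step <- levy_step(length(position), config$lambda)
  new <- position + config$step_size * 0.05 * step *
    (position - best_position)
  pmin(pmax(new, config$lower), config$upper)
}

#' Abandon nests with probability Pa
#'
#' Every nest except the incumbent best is replaced, with probability
#' `pa`, by a fresh uniform draw within the bounds; the nest count is
#' unchanged and the best nest is always handed down. [cs_optimize()]
#' treats the returned positions as candidates and keeps each only when
#' fitter than the nest it replaces.
#'
#' @param positions Matrix of nest positions (rows = nests).
#' @param best_row Row index of the best nest.
#' @param config A [cs_config()].
#' @return List with the new `positions` matrix and logical `replaced`.
#' @export
cs_abandon <- function(positions, best_row, config) {
  n <- nrow(positions); d <- ncol(positions)
  replace <- stats::runif(n) < config$pa
  replace[best_row] <- FALSE
  for (i in which(replace)) {
    positions[i, ] <- config$lower +
      stats::runif(d) * (config$upper - config$lower)
  }
  list(positions = positions, replaced = replace)
}

#' Maximize an objective by Cuckoo Search
#'
#' Population metaheuristic with Levy-flight proposals and abandonment
#' of poor nests with probability `pa`. Selection is elitist throughout,
#' as in the origin method's reference implementation: each cuckoo egg
#' replaces its host nest only when fitter, and an abandonment draw
#' (fresh uniform position from [cs_abandon()]) is likewise accepted
#' only when fitter than the nest it would replace. The best-so-far
#' fitness trace is monotonically non-decreasing and the whole run is
#' reproducible under a fixed seed. Objective evaluations are cached by
#' parameter vector (quantized at 1e-9) since the objective is
#' deterministic.
#'
#' @param fn Objective function of a numeric parameter vector, to be
#'   maximized.
#' @param config A [cs_config()].
#' @return List with `best_par`, `best_value`, `trace` (data frame:
#'   generation, best_fitness) and `n_evals`.
#' @export
cs_optimize <- function(fn, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- length(config$lower)
  n <- config$n
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  eval_fn <- function(x) {
    key <- paste(sprintf("%.9e", round(x / 1e-9) * 1e-9), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- fn(x)
    evals <<- evals + 1L
    cache[[key]] <- v
    v
  }

  positions <- matrix(stats::runif(n * d), nrow = n) *
    rep(config$upper - config$lower, each = n) +
    rep(config$lower, each = n)
  colnames(positions) <- names(config$lower)
  fitness <- apply(positions, 1, eval_fn)
  best_row <- which.max(fitness)
  best_par <- positions[best_row, ]
  best_val <- fitness[best_row]
  trace <- numeric(config$max_generation)

  for (t in seq_len(config$max_generation)) {
    # one cuckoo egg per nest: Levy proposal, kept only if fitter
    for (i in seq_len(n)) {
      egg <- cs_propose(positions[i, ], best_par, config)
      f_egg <- eval_fn(egg)
      if (f_egg > fitness[i]) {
        positions[i, ] <- egg
        fitness[i] <- f_egg
      }
    }
    # abandonment: fresh uniform draws, accepted only when fitter
    best_row <- which.max(fitness)
    ab <- cs_abandon(positions, best_row, config)
    for (i in which(ab$replaced)) {
      f_new <- eval_fn(ab$positions[i, ])
      if (f_new > fitness[i]) {
        positions[i, ] <- ab$positions[i, ]
        fitness[i] <- f_new
      }
    }

    best_row <- which.max(fitness)
    if (fitness[best_row] > best_val) {
      best_val <- fitness[best_row]
      best_par <- positions[best_row, ]
    }
    trace[t] <- best_val
  }
  list(best_par = best_par, best_value = best_val,
       trace = data.frame(generation = seq_len(config$max_generation),
                          best_fitness = trace),
       n_evals = evals)
}

#' Retrieval objective: average P@10 plus average nDCG
#'
#' Builds a closure over precomputed per-topic profiles so that each
#' evaluation at new parameters is a vectorized re-ranking plus metric
#' computation. The value lies in \[0, 2\].
#'
#' @param index A [build_index()] object.
#' @param queries List of [build_expanded_query()] objects.
#' @param qrels A [read_qrels()] object.
#' @param mode Co-word mode.
#' @param top_k Run depth (default 1000).
#' @return Function of a parameter vector `c(k1, k3, b1, b2, alpha)`.
#' @export
retrieval_objective <- function(index, queries, qrels, mode = "cross",
                                top_k = 1000) {
  profiles <- lapply(queries, query_profile, index = index, mode = mode)
  names(profiles) <- vapply(queries, `[[`, character(1), "topic_id")
  topics <- qrels_topics(qrels)
  grades_by_topic <- lapply(topics, function(t) qrels_grades(qrels, t))
  names(grades_by_topic) <- topics
  ideal_dcg <- vapply(topics, function(t) {
    g <- sort(grades_by_topic[[t]], decreasing = TRUE)
    g <- g[seq_len(min(top_k, length(g)))]
    if (length(g) == 0 || all(g == 0)) return(0)
    sum(g / log(seq_along(g) + 1))
  }, numeric(1))

  function(par) {
    params <- model_params(k1 = max(par[1], 1e-9), k3 = max(par[2], 1e-9),
                           b1 = par[3], b2 = par[4], alpha = par[5])
    p10 <- numeric(length(topics)); ndcg <- numeric(length(topics))
    for (ti in seq_along(topics)) {
      t <- topics[ti]
      prof <- profiles[[t]]
      if (is.null(prof)) next
      scores <- profile_scores(prof, params)
      ord <- order(-scores, prof$doc_ids)
      docs <- prof$doc_ids[ord[seq_len(min(top_k, length(ord)))]]
      g <- grades_by_topic[[t]][docs]
      g[is.na(g)] <- 0
      p10[ti] <- sum(g[seq_len(min(10, length(g)))] > 0) / 10
      if (ideal_dcg[ti] > 0)
        ndcg[ti] <- sum(g / log(seq_along(g) + 1)) / ideal_dcg[ti]
    }
    mean(p10) + mean(ndcg)
  }
}

#' Tune the ranking parameters by Cuckoo Search
#'
#' Runs [cs_optimize()] on the [retrieval_objective()] over the
#' five-dimensional space (k1, k3, b1, b2, alpha); k2 is fixed at 1 and
#' excluded from the search.
#'
#' @inheritParams retrieval_objective
#' @param config A [cs_config()].
#' @return List with `params` (a [model_params()]), `objective`,
#'   `trace` and `n_evals`.
#' @export
optimize_params <- function(index, queries, qrels, config = cs_config(),
                            mode = "cross", top_k = 1000) {
  obj <- retrieval_objective(index, queries, qrels, mode, top_k)
  res <- cs_optimize(obj, config)
  p <- res$best_par
  list(params = model_params(k1 = max(p[["k1"]], 1e-9),
                             k3 = max(p[["k3"]], 1e-9),
                             b1 = p[["b1"]], b2 = p[["b2"]],
                             alpha = p[["alpha"]]),
       objective = res$best_value, trace = res$trace, n_evals = res$n_evals)
}
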