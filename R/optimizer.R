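#' Define a box-bounded continuous search space
#'
#' A search space is the axis-aligned box `[lower, upper]` in `dim`
#' dimensions over which the metaheuristic operates.
#'
#' @param dim Number of decision variables (positive integer).
#' @param lower,upper Numeric scalars or length-`dim` vectors of bounds;
#'   scalars are recycled. `lower < upper` elementwise.
#' @return An object of class `"search_space"` with fields `dim`, `lower`,
#'   `upper`.
#' @examples
#' search_space(5, -0.5, 0.5)
#' @export
search_space <- function(dim, lower, upper) {
  stopifnot(length(dim) == 1, dim >= 1, dim == as.integer(dim))
  dim <- as.integer(dim)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("bounds must be finite")
  if (!all(lower < upper))
    stop("every lower bound must be strictly below its upper bound")
  structure(list(dim = dim, lower = lower, upper = upper),
            class = "search_space")
}

#' Strategy parameters for the adaptive metaheuristic
#'
#' Collects the tunables governing adaptive strategy selection and the
#' mutation operator.
#'
#' @param maxg Iteration budget (positive integer).
#' @param base_prob Floor of the adaptive selection probability; default 0.3.
#' @param exponent_g Exponent `g` of the selection schedule; default 1.
#' @param mutation_one_prob Per-dimension probability that the mutation mask
#'   is 1 (dimension redrawn); default 0.6.
#' @param seed Integer seed controlling every random draw of a run.
#' @return An object of class `"strategy_params"`.
#' @export
strategy_params <- function(maxg, base_prob = 0.3, exponent_g = 1,
                            mutation_one_prob = 0.6, seed = 1L) {
  stopifnot(maxg >= 0, maxg == as.integer(maxg),
            base_prob > 0, base_prob < 1,
            mutation_one_prob >= 0, mutation_one_prob <= 1)
  structure(list(maxg = as.integer(maxg), base_prob = base_prob,
                 exponent_g = exponent_g,
                 mutation_one_prob = mutation_one_prob,
                 seed = as.integer(seed)),
            class = "strategy_params")
}

clip_box <- function(x, space) pmin(pmax(x, space$lower), space$upper)

eval_objective <- function(objective, x, who) {
  f <- objective(x)
  if (length(f) != 1 || !is.finite(f))
    stop("objective returned a non-finite value for ", who)
  as.numeric(f)
}

#' Initialize the population
#'
#' Draws `n` individuals i.i.d. uniformly over the box, with zero velocities
#' and personal memories equal to the starting positions, and records the
#' elitist global best. Evaluation order (and therefore the random stream)
#' follows population index order.
#'
#' @param space A [search_space()].
#' @param n Population size, at least 2.
#' @param objective Function mapping a length-`dim` vector to a finite
#'   scalar; maximized.
#' @param params A [strategy_params()]. `params$seed` seeds the run unless
#'   the caller has already seeded the session (`seed = FALSE` draws from the
#'   current stream).
#' @param seed_rng Set to `FALSE` to consume the session RNG stream instead
#'   of seeding from `params$seed`.
#' @return An optimizer state: list with `population` (list of individuals,
#'   each holding `position`, `velocity`, `memory_position`,
#'   `memory_fitness`, `fitness`), `global_best`, `iteration`, `history`,
#'   `n_evals`, plus the `space`, `params` used.
#' @export
init_population <- function(space, n, objective, params, seed_rng = TRUE) {
  stopifnot(inherits(space, "search_space"), n >= 2)
  if (seed_rng) set.seed(params$seed)
  pop <- vector("list", n)
  for (i in seq_len(n)) {
    x <- space$lower + stats::runif(space$dim) * (space$upper - space$lower)
    f <- eval_objective(objective, x, paste0("individual ", i))
    pop[[i]] <- list(position = x, velocity = numeric(space$dim),
                     memory_position = x, memory_fitness = f, fitness = f)
  }
  fits <- vapply(pop, `[[`, numeric(1), "fitness")
  b <- which.max(fits)
  state <- list(population = pop,
                global_best = list(position = pop[[b]]$position,
                                   fitness = fits[b]),
                iteration = 0L,
                history = list(),
                n_evals = n,
                space = space, params = params)
  class(state) <- "afoa_state"
  state
}

#' Oscillation perturbation terms for movement strategy I
#'
#' Computes the adaptive change amount `lambda`, the oscillation step `v`
#' and the perturbation `beta` used by the two-probe local search around the
#' incumbent best. `lambda_d = exp(-0.25 * Ub_d * (t - 0.3*maxg) / maxg) *
#' r_d` with `r_d ~ U(0,1)`, so early iterations (t < 0.3*maxg) allow
#' amplitudes above 1 (wide search) that decay as t grows;
#' `v = lambda^0.8 * (lambda/4) * (Ub - Lb)`; `beta = Ub * q * lambda` with
#' the binary `q` equal to 0 with probability 0.5.
#'
#' @param t Current iteration, in `[1, maxg]`.
#' @param space A [search_space()].
#' @param params A [strategy_params()].
#' @return List with vectors `lam`, `v`, `beta` and the scalar `q`.
#' @export
compute_perturbation <- function(t, space, params) {
  if (t < 1 || t > params$maxg) stop("t must lie in [1, maxg]")
  r <- stats::runif(space$dim)
  lam <- exp(-0.25 * space$upper * (t - 0.3 * params$maxg) / params$maxg) * r
  v <- lam^0.8 * (lam / 4) * (space$upper - space$lower)
  q <- if (stats::runif(1) < 0.5) 0 else 1
  beta <- space$upper * q * lam
  list(lam = lam, v = v, beta = beta, q = q)
}

#' Guidance coefficient from the distance between two positions
#'
#' `a = exp(-d / (2 * dim^0.8))` where `d` is the Euclidean distance between
#' `p` and `q`; equal positions give `a = 1` and `a` decays with distance,
#' damped by dimension.
#'
#' @param p,q Numeric vectors of length `dim`.
#' @param dim Dimensionality used for the damping term.
#' @return List with `a` and `d`.
#' @export
guidance_coefficient <- function(p, q, dim) {
  if (length(p) != dim || length(q) != dim)
    stop("guidance_coefficient: dimension mismatch")
  d <- sqrt(sum((p - q)^2))
  list(a = exp(-d / (2 * dim^0.8)), d = d)
}

#' Two-probe oscillation local search (movement strategy I)
#'
#' Probes `X_b + v + beta` and `X_b - v - beta` (clipped to the box) around
#' the incumbent best, evaluates both (exactly two objective calls), and
#' adopts the better probe as the working position. The elitist archive in
#' the caller retains the previous best if both probes are worse.
#'
#' @param state An optimizer state.
#' @param objective Objective function (maximized).
#' @param pert Perturbation terms from [compute_perturbation()].
#' @return List with `position`, `fitness` of the winning probe and
#'   `n_evals = 2`.
#' @export
strategy_one <- function(state, objective, pert) {
  xb <- state$global_best$position
  xp <- clip_box(xb + pert$v + pert$beta, state$space)
  xm <- clip_box(xb - pert$v - pert$beta, state$space)
  fp <- eval_objective(objective, xp, "strategy I probe (+)")
  fm <- eval_objective(objective, xm, "strategy I probe (-)")
  if (fp >= fm) list(position = xp, fitness = fp, n_evals = 2L)
  else          list(position = xm, fitness = fm, n_evals = 2L)
}

#' Simplified movement around the best (movement strategy II)
#'
#' Picks two distinct random individuals; if their memories differ the new
#' position is `X_b + a * rand(1,D) * (Xm_r1 - Xm_r2)` with the guidance
#' coefficient `a` computed from the memory distance, otherwise
#' `X_b + 0.25 * rand(1,D) * (Ub - Lb)`. The result is clipped to the box.
#'
#' @param state An optimizer state with population size >= 2.
#' @return New position vector for the dispatching individual.
#' @export
strategy_two <- function(state) {
  n <- length(state$population)
  if (n < 2) stop("strategy II needs a population of at least 2")
  idx <- sample.int(n, 2)
  m1 <- state$population[[idx[1]]]$memory_position
  m2 <- state$population[[idx[2]]]$memory_position
  xb <- state$global_best$position
  r <- stats::runif(state$space$dim)
  if (any(m1 != m2)) {
    a <- guidance_coefficient(m1, m2, state$space$dim)$a
    x <- xb + a * r * (m1 - m2)
  } else {
    x <- xb + 0.25 * r * (state$space$upper - state$space$lower)
  }
  clip_box(x, state$space)
}

#' Velocity-guided global move (movement strategy III)
#'
#' Updates individual `i`'s velocity toward a randomly chosen other
#' individual and toward its own memory,
#' `A_i <- rand*A_i + a1*rand*(X_r - X_i) + a2*rand*(Xm_i - X_i)`,
#' with guidance coefficients from the respective distances, then moves
#' `X_i <- X_i + A_i` (clipped).
#'
#' @param i Index of the moving individual.
#' @param state An optimizer state with population size >= 2.
#' @return List with `position` and `velocity`.
#' @export
strategy_three <- function(i, state) {
  n <- length(state$population)
  if (n < 2) stop("strategy III needs a population of at least 2")
  ind <- state$population[[i]]
  r_idx <- sample.int(n - 1, 1)
  if (r_idx >= i) r_idx <- r_idx + 1  # exclude self
  xr <- state$population[[r_idx]]$position
  m <- state$space$dim
  a1 <- guidance_coefficient(xr, ind$position, m)$a
  a2 <- guidance_coefficient(ind$memory_position, ind$position, m)$a
  vel <- stats::runif(m) * ind$velocity +
    a1 * stats::runif(m) * (xr - ind$position) +
    a2 * stats::runif(m) * (ind$memory_position - ind$position)
  list(position = clip_box(ind$position + vel, state$space), velocity = vel)
}

#' Random mutation operation
#'
#' Draws a per-dimension binary mask (1 with probability
#' `mutation_one_prob`, default 0.6) and redraws the masked dimensions
#' uniformly inside the box; unmasked dimensions are returned bit-identical.
#'
#' @param position Numeric vector of length `dim`.
#' @param space A [search_space()].
#' @param params A [strategy_params()].
#' @return Mutated position vector.
#' @export
mutate_position <- function(position, space, params) {
  stopifnot(length(position) == space$dim)
  mask <- stats::runif(space$dim) < params$mutation_one_prob
  if (any(mask)) {
    position[mask] <- space$lower[mask] +
      stats::runif(sum(mask)) * (space$upper - space$lower)[mask]
  }
  position
}

#' Adaptive selection probability
#'
#' `Pr(ti) = min(1, base_prob + (ti/maxg)^(2g))`: starts at the floor
#' (default 0.3) and grows monotonically to 1 as the iteration counter
#' approaches the budget, so the probability of the exploratory simplified
#' strategy II (chosen with probability `1 - Pr`) decays over the run.
#'
#' @param ti Current iteration in `[0, maxg]`.
#' @param params A [strategy_params()].
#' @return Scalar probability in `[base_prob, 1]`.
#' @export
selection_probability <- function(ti, params) {
  if (params$maxg == 0) stop("maxg must be positive")
  min(1, params$base_prob + (ti / params$maxg)^(2 * params$exponent_g))
}

#' Dispatch one of the four update strategies
#'
#' Draws `u1 ~ U(0,1)`: if `u1 >= Pr(ti)` strategy II is chosen (so
#' `P(II) = 1 - Pr(ti)`, high early and zero once `Pr` saturates at 1);
#' otherwise a second uniform draw picks I, III or the mutation with equal
#' probability.
#'
#' @param ti Current iteration.
#' @param params A [strategy_params()].
#' @return One of `"I"`, `"II"`, `"III"`, `"MUTATE"`.
#' @export
select_strategy <- function(ti, params) {
  pr <- selection_probability(ti, params)
  if (stats::runif(1) >= pr) return("II")
  u2 <- stats::runif(1)
  if (u2 < 1 / 3) "I" else if (u2 < 2 / 3) "III" else "MUTATE"
}

update_individual <- function(state, i, position, fitness,
                              velocity = NULL) {
  ind <- state$population[[i]]
  ind$position <- position
  ind$fitness <- fitness
  if (!is.null(velocity)) ind$velocity <- velocity
  if (fitness > ind$memory_fitness) {
    ind$memory_fitness <- fitness
    ind$memory_position <- position
  }
  state$population[[i]] <- ind
  if (fitness > state$global_best$fitness)
    state$global_best <- list(position = position, fitness = fitness)
  state
}

#' Advance the optimizer by one iteration
#'
#' For each individual in index order the adaptive dispatch selects one of
#' the four updates; new positions are evaluated, personal memories are
#' updated when improved, and the elitist global best never degrades. The
#' history gains one record (iteration, best fitness, strategy usage counts,
#' cumulative evaluation count).
#'
#' @param state An optimizer state from [init_population()].
#' @param objective Objective function (maximized).
#' @return The advanced state.
#' @export
afoa_step <- function(state, objective) {
  t <- state$iteration + 1L
  params <- state$params
  counts <- c(I = 0L, II = 0L, III = 0L, MUTATE = 0L)
  for (i in seq_along(state$population)) {
    s <- select_strategy(t, params)
    counts[s] <- counts[s] + 1L
    if (s == "I") {
      pert <- compute_perturbation(t, state$space, params)
      probe <- strategy_one(state, objective, pert)
      state$n_evals <- state$n_evals + probe$n_evals
      state <- update_individual(state, i, probe$position, probe$fitness)
    } else if (s == "II") {
      x <- strategy_two(state)
      f <- eval_objective(objective, x, paste0("individual ", i))
      state$n_evals <- state$n_evals + 1L
      state <- update_individual(state, i, x, f)
    } else if (s == "III") {
      mv <- strategy_three(i, state)
      f <- eval_objective(objective, mv$position, paste0("individual ", i))
      state$n_evals <- state$n_evals + 1L
      state <- update_individual(state, i, mv$position, f, mv$velocity)
    } else {
      x <- mutate_position(state$population[[i]]$position, state$space,
                           params)
      f <- eval_objective(objective, x, paste0("individual ", i))
      state$n_evals <- state$n_evals + 1L
      state <- update_individual(state, i, x, f)
    }
  }
  state$iteration <- t
  state$history[[t]] <- list(iteration = t,
                             best_fitness = state$global_best$fitness,
                             strategy_counts = as.list(counts),
                             n_evals = state$n_evals)
  state
}

#' Run the metaheuristic
#'
#' Initializes a population and advances `maxg` iterations, returning the
#' elitist best. Identical `(seed, configuration)` pairs give bit-identical
#' histories. Maximization is canonical; set `minimize = TRUE` to negate the
#' objective at the boundary (reported fitness is then the minimized value).
#'
#' @param objective Scalar objective over the box.
#' @param space A [search_space()].
#' @param n Population size.
#' @param maxg Iteration budget.
#' @param params Optional [strategy_params()]; defaults to
#'   `strategy_params(maxg, seed = seed)`.
#' @param seed Integer seed (used when `params` is NULL).
#' @param minimize Minimize instead of maximize.
#' @return List with `best_position`, `best_fitness`, `history`, `n_evals`
#'   and the final `state`.
#' @examples
#' res <- afoa_run(function(x) -sum(x^2), search_space(3, -0.5, 0.5),
#'                 n = 6, maxg = 20, seed = 1)
#' res$best_fitness
#' @export
afoa_run <- function(objective, space, n, maxg, params = NULL, seed = 1L,
                     minimize = FALSE) {
  if (is.null(params)) params <- strategy_params(maxg, seed = seed)
  obj <- if (minimize) function(x) -objective(x) else objective
  state <- init_population(space, n, obj, params)
  g <- 0L
  while (g < maxg) {
    state <- afoa_step(state, obj)
    g <- g + 1L
  }
  bf <- state$global_best$fitness
  list(best_position = state$global_best$position,
       best_fitness = if (minimize) -bf else bf,
       history = state$history,
       n_evals = state$n_evals,
       state = state)
}

#' Benchmark the optimizer against seed-matched random search
#'
#' Runs the metaheuristic on a standard test function over `[-0.5, 0.5]^dim`
#' for several seeds and, for each seed, a uniform random search consuming
#' the same number of objective evaluations.
#'
#' @param fun One of `"sphere"`, `"rastrigin"`, `"rosenbrock"` (all
#'   minimized; reported fitness is the maximized negative).
#' @param dim,n,maxg Problem dimension, population size, iteration budget.
#' @param seeds Integer vector of seeds.
#' @return Data frame with one row per seed: best fitness of the
#'   metaheuristic, of random search, and the evaluation budget.
#' @export
benchmark_optimizer <- function(fun = c("sphere", "rastrigin", "rosenbrock"),
                                dim = 5, n = 8, maxg = 50,
                                seeds = 1:10) {
  fun <- match.arg(fun)
  f <- switch(fun,
    sphere = function(x) -sum(x^2),
    rastrigin = function(x) -(10 * length(x) +
                              sum(x^2 - 10 * cos(2 * pi * x))),
    rosenbrock = function(x) -sum(100 * (x[-1] - x[-length(x)]^2)^2 +
                                  (1 - x[-length(x)])^2))
  space <- search_space(dim, -0.5, 0.5)
  rows <- lapply(seeds, function(s) {
    res <- afoa_run(f, space, n = n, maxg = maxg, seed = s)
    set.seed(s + 10^6)
    rbest <- -Inf
    for (k in seq_len(res$n_evals)) {
      x <- space$lower + stats::runif(dim) * (space$upper - space$lower)
      rbest <- max(rbest, f(x))
    }
    data.frame(seed = s, afoa_best = res$best_fitness,
               random_best = rbest, n_evals = res$n_evals)
  })
  do.call(rbind, rows)
}
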