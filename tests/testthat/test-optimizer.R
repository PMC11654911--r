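test_that("initialization samples inside the box and records the elitist best", {
  space <- search_space(3, -0.5, 0.5)
  params <- strategy_params(10, seed = 7)
  st <- init_population(space, 2, function(x) 7, params)
  pos <- do.call(rbind, lapply(st$population, `[[`, "position"))
  expect_true(all(pos >= -0.5 & pos <= 0.5))
  expect_identical(st$global_best$fitness, 7)

  # brute-force oracle: replay the same seeded uniform draws
  sphere <- function(x) -sum(x^2)
  space5 <- search_space(5, -0.5, 0.5)
  st <- init_population(space5, 8, sphere, strategy_params(10, seed = 11))
  set.seed(11)
  fits <- replicate(8, sphere(-0.5 + stats::runif(5)))
  expect_equal(st$global_best$fitness, max(fits))
  expect_equal(vapply(st$population, `[[`, numeric(1), "fitness"),
               as.numeric(fits))
})

test_that("initialization rejects non-finite objectives with the index", {
  space <- search_space(2, -1, 1)
  bad <- function(x) if (x[1] > -2) NaN else 0
  expect_error(init_population(space, 3, bad, strategy_params(5, seed = 1)),
               "individual 1")
})

test_that("perturbation terms follow the adaptive oscillation schedule", {
  space <- search_space(4, -0.5, 0.5)
  params <- strategy_params(100, seed = 3)
  # replay the RNG to predict r and q
  set.seed(5)
  p <- compute_perturbation(30, space, params)  # t = 0.3 * maxg
  set.seed(5)
  r <- stats::runif(4)
  q <- if (stats::runif(1) < 0.5) 0 else 1
  expect_equal(p$lam, r)  # exponent vanishes at t = 0.3 maxg
  expect_equal(p$v, r^0.8 * (r / 4) * 1)
  expect_identical(p$q, q)
  if (q == 0) expect_equal(p$beta, rep(0, 4))
  else expect_equal(p$beta, 0.5 * r)

  # monotone decay: same r (same seed), larger t gives smaller lambda
  set.seed(9); early <- compute_perturbation(5, space, params)
  set.seed(9); late <- compute_perturbation(95, space, params)
  expect_true(all(late$lam <= early$lam))

  # q = 0 happens and then beta is exactly zero
  set.seed(1)
  qs <- replicate(50, {
    pp <- compute_perturbation(10, space, params)
    if (pp$q == 0) expect_identical(pp$beta, rep(0, 4))
    pp$q
  })
  expect_true(any(qs == 0) && any(qs == 1))
  expect_error(compute_perturbation(0, space, params), "t must")
})

test_that("guidance coefficient is 1 at zero distance and decays", {
  expect_equal(guidance_coefficient(c(1, 2), c(1, 2), 2)$a, 1)
  g <- guidance_coefficient(0, 2, 1)
  expect_equal(g$d, 2)
  expect_equal(g$a, exp(-1))
  a1 <- guidance_coefficient(rep(0, 3), rep(0.1, 3), 3)$a
  a2 <- guidance_coefficient(rep(0, 3), rep(0.4, 3), 3)$a
  expect_gt(a1, a2)
  expect_error(guidance_coefficient(1:2, 1:3, 3), "dimension")
})

test_that("strategy I adopts the better of its two probes", {
  space <- search_space(1, -0.5, 0.5)
  params <- strategy_params(10, seed = 1)
  f <- function(x) -(x - 0.2)^2
  st <- init_population(space, 2, f, params)
  st$global_best <- list(position = 0, fitness = f(0))
  pert <- list(lam = 1, v = 0.25, beta = 0, q = 0)
  probe <- strategy_one(st, f, pert)
  expect_equal(probe$position, 0.25)       # f(0.25) beats f(-0.25)
  expect_equal(probe$fitness, -0.0025)
  expect_identical(probe$n_evals, 2L)
  # zero perturbation leaves the best where it is
  probe0 <- strategy_one(st, f, list(lam = 0, v = 0, beta = 0, q = 0))
  expect_equal(probe0$position, 0)
})

test_that("strategy II stays inside the box and uses the else-branch step", {
  space <- search_space(3, -0.5, 0.5)
  params <- strategy_params(10, seed = 1)
  st <- init_population(space, 4, function(x) sum(x), params)
  for (k in 1:20) expect_true(all(abs(strategy_two(st)) <= 0.5))
  # identical memories: step is X_b + 0.25 * r * (Ub - Lb), r >= 0
  same <- rep(0.1, 3)
  for (i in 1:4) st$population[[i]]$memory_position <- same
  st$global_best$position <- rep(-0.2, 3)
  for (k in 1:10) {
    x <- strategy_two(st)
    expect_true(all(x >= -0.2 - 1e-12 & x <= -0.2 + 0.25 + 1e-12))
  }
  st$population <- st$population[1]
  expect_error(strategy_two(st), "at least 2")
})

test_that("strategy III is stationary when all guidance terms vanish", {
  space <- search_space(3, -0.5, 0.5)
  params <- strategy_params(10, seed = 2)
  st <- init_population(space, 3, function(x) 0, params)
  same <- rep(0.1, 3)
  for (i in 1:3) {
    st$population[[i]]$position <- same
    st$population[[i]]$memory_position <- same
    st$population[[i]]$velocity <- rep(0, 3)
  }
  mv <- strategy_three(1, st)
  expect_equal(mv$position, same)
  expect_equal(mv$velocity, rep(0, 3))
  # any inputs: clipped into the box
  st$population[[2]]$position <- rep(0.5, 3)
  st$population[[2]]$velocity <- rep(5, 3)
  for (k in 1:10) {
    mv <- strategy_three(2, st)
    expect_true(all(mv$position >= -0.5 & mv$position <= 0.5))
  }
})

test_that("mutation redraws masked dimensions only, at the configured rate", {
  m <- 10000L
  space <- search_space(m, -0.5, 0.5)
  params <- strategy_params(10, mutation_one_prob = 0.6, seed = 1)
  x <- rep(0.123, m)
  set.seed(77)
  y <- mutate_position(x, space, params)
  changed <- y != x
  expect_gt(mean(changed), 0.57)
  expect_lt(mean(changed), 0.63)
  expect_identical(y[!changed], x[!changed])  # bit-exact locality
  expect_true(all(y >= -0.5 & y <= 0.5))
  # prob 0: identity; prob 1: all redrawn (almost surely all differ)
  p0 <- strategy_params(10, mutation_one_prob = 0, seed = 1)
  expect_identical(mutate_position(x, space, p0), x)
  p1 <- strategy_params(10, mutation_one_prob = 1, seed = 1)
  expect_true(all(mutate_position(x, space, p1) != x))
})

test_that("selection probability starts at the floor and saturates at 1", {
  params <- strategy_params(100, seed = 1)
  expect_equal(selection_probability(0, params), 0.3)
  expect_equal(selection_probability(100, params), 1)
  pr <- vapply(0:100, selection_probability, numeric(1), params = params)
  expect_true(all(diff(pr) >= 0))
  expect_error(selection_probability(1, strategy_params(0, seed = 1)),
               "positive")
})

test_that("strategy dispatch frequencies match the adaptive rule", {
  params <- strategy_params(100, seed = 1)
  set.seed(123)
  draws <- replicate(1e5, select_strategy(0, params))
  expect_equal(mean(draws == "II"), 0.7, tolerance = 0.015)
  others <- table(draws[draws != "II"]) / sum(draws != "II")
  expect_true(all(abs(others - 1 / 3) < 0.02))
  draws_late <- replicate(1e3, select_strategy(100, params))
  expect_false(any(draws_late == "II"))  # Pr capped at 1
})

test_that("stepping preserves bounds, elitism and memory soundness", {
  space <- search_space(5, -0.5, 0.5)
  params <- strategy_params(20, seed = 4)
  sphere <- function(x) -sum(x^2)
  st <- init_population(space, 6, sphere, params)
  best_seq <- st$global_best$fitness
  for (t in 1:20) {
    st <- afoa_step(st, sphere)
    best_seq <- c(best_seq, st$global_best$fitness)
    for (ind in st$population) {
      expect_true(all(ind$position >= -0.5 & ind$position <= 0.5))
      expect_gte(ind$memory_fitness, ind$fitness)
      expect_equal(ind$memory_fitness, sphere(ind$memory_position))
    }
  }
  expect_true(all(diff(best_seq) >= 0))          # elitism
  expect_length(st$history, 20)
  expect_equal(st$history[[20]]$best_fitness, st$global_best$fitness)
  # constant objective: best never moves
  stc <- init_population(space, 4, function(x) 1, params)
  for (t in 1:5) stc <- afoa_step(stc, function(x) 1)
  expect_identical(stc$global_best$fitness, 1)
})

test_that("runs are deterministic under a fixed seed and maxg = 0 returns the initial best", {
  space <- search_space(4, -0.5, 0.5)
  sphere <- function(x) -sum(x^2)
  r0 <- afoa_run(sphere, space, n = 5, maxg = 0, seed = 3)
  set.seed(3)
  init_best <- max(replicate(5, sphere(-0.5 + stats::runif(4))))
  expect_equal(r0$best_fitness, init_best)
  r1 <- afoa_run(sphere, space, n = 5, maxg = 15, seed = 9)
  r2 <- afoa_run(sphere, space, n = 5, maxg = 15, seed = 9)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_position, r2$best_position)
  expect_gte(r1$best_fitness, r0$best_fitness - 1e-12)
  # minimization wrapper returns the minimized value
  rm <- afoa_run(function(x) sum(x^2), space, n = 5, maxg = 15, seed = 9,
                 minimize = TRUE)
  expect_equal(rm$best_fitness, sum(rm$best_position^2))
})

test_that("strategy II usage decays from ~0.7 of moves toward 0", {
  space <- search_space(3, -0.5, 0.5)
  res <- afoa_run(function(x) -sum(x^2), space, n = 8, maxg = 40, seed = 2)
  use2 <- vapply(res$history, function(h) h$strategy_counts$II, numeric(1))
  early <- mean(use2[1:10]) / 8
  late <- mean(use2[31:40]) / 8
  expect_gt(early, 0.4)
  expect_lt(late, 0.1)
})

test_that("the metaheuristic beats seed-matched random search on the sphere", {
  df <- benchmark_optimizer("sphere", dim = 5, n = 8, maxg = 20, seeds = 1:3)
  expect_true(all(df$afoa_best >= df$random_best))
})
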