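# Multi-objective fitness over validation mIoU, parameter count and FLOPs,
# and the channel-search harness that trains decoded candidate networks
# briefly and searches the 43-dimensional box with the metaheuristic.

#' Fitness weights
#'
#' Weighted importance of accuracy (mIoU), parameter count and
#' computational load in the scalar fitness; the published weighting is
#' 0.6 / 0.1 / 0.3.
#'
#' @param w_miou,w_params,w_flops Nonnegative weights summing to 1.
#' @return List of the three weights.
#' @export
fitness_weights <- function(w_miou = 0.6, w_params = 0.1, w_flops = 0.3) {
  if (abs(w_miou + w_params + w_flops - 1) > 1e-9)
    stop("fitness weights must sum to 1")
  list(w_miou = w_miou, w_params = w_params, w_flops = w_flops)
}

#' Population-relative complexity components
#'
#' For a comparison pool of records, `P_i = 1 - pr_i / sum(pr)` and
#' `f_i = 1 - fl_i / sum(fl)`: candidates that are light relative to the
#' pool score close to 1. The normalization makes fitness values
#' pool-relative, so comparisons must always be made under one pool.
#'
#' @param records List of objective records (each with `params`, `flops`).
#' @return Data frame with columns `P` and `f`, one row per record.
#' @export
fitness_components <- function(records) {
  if (length(records) < 2)
    stop("complexity normalization needs a pool of at least 2 records")
  pr <- vapply(records, `[[`, numeric(1), "params")
  fl <- vapply(records, `[[`, numeric(1), "flops")
  if (any(pr <= 0) || any(fl <= 0)) stop("params and flops must be positive")
  data.frame(P = 1 - pr / sum(pr), f = 1 - fl / sum(fl))
}

#' Scalar multi-objective fitness
#'
#' `fit = w_miou * mIoU + w_params * P + w_flops * f`; higher is better.
#'
#' @param miou Validation mean IoU in `[0, 1]`.
#' @param P,f Pool-relative complexity components.
#' @param weights A [fitness_weights()].
#' @return Scalar fitness.
#' @export
fitness <- function(miou, P, f, weights = fitness_weights()) {
  weights$w_miou * miou + weights$w_params * P + weights$w_flops * f
}

pool_fitness <- function(records, weights = fitness_weights()) {
  comp <- fitness_components(records)
  vapply(seq_along(records), function(i)
    fitness(records[[i]]$miou, comp$P[i], comp$f[i], weights),
    numeric(1))
}

#' Train and score one candidate channel plan
#'
#' Decodes the decision vector, builds and trains the network for a short
#' budget with the combined focal + dice loss under AdamW (learning rate
#' 0.0015, weight decay 5e-5), and measures validation mIoU plus the
#' plan's deterministic parameter and FLOP counts. Training divergence
#' (non-finite loss) yields `miou = 0` with a warning rather than
#' aborting a search.
#'
#' @param x Decision vector in `[-0.5, 0.5]^43`.
#' @param base_plan Base [channel_plan()].
#' @param train,val Scene lists (see [generate_scenes()]).
#' @param epochs Training epochs per candidate (desk-scale default 3).
#' @param seed Training seed (weights and shuffling).
#' @param lr,weight_decay Optimizer hyperparameters.
#' @param flops_hw Resolution at which FLOPs are counted; defaults to the
#'   scene resolution.
#' @return Object of class `"objective_record"`: list with `miou`,
#'   `params`, `flops`, `plan`, `net`, `loss_history`.
#' @export
evaluate_candidate <- function(x, base_plan = base_channel_plan(),
                               train, val, epochs = 3, seed = 1L,
                               lr = 0.0015, weight_decay = 5e-5,
                               flops_hw = NULL) {
  stopifnot(length(train) >= 1, length(val) >= 1)
  plan <- decode_channels(x, base_plan)
  hw <- dim(train[[1]]$image)[1:2]
  if (is.null(flops_hw)) flops_hw <- hw
  spec <- reference_spec(plan, input_size = hw)
  net <- build_network(spec, seed = seed)
  rec_params <- count_parameters(spec)
  rec_flops <- count_flops(spec, flops_hw)
  tr <- tryCatch(
    train_network(net, train, epochs = epochs, lr = lr,
                  weight_decay = weight_decay, seed = seed),
    error = function(e) e)
  if (inherits(tr, "error")) {
    warning("candidate training diverged; scoring miou = 0 (",
            conditionMessage(tr), ")")
    return(structure(list(miou = 0, params = rec_params,
                          flops = rec_flops, plan = plan, net = NULL,
                          loss_history = numeric(0)),
                     class = "objective_record"))
  }
  rep <- evaluate_network(tr$net, val)
  structure(list(miou = rep$miou, params = rec_params, flops = rec_flops,
                 plan = plan, net = tr$net,
                 loss_history = tr$loss_history),
            class = "objective_record")
}

candidate_seed <- function(run_seed, individual, iteration) {
  (run_seed * 1009L + individual * 101L + iteration * 7L) %% 2147483647L
}

#' Search channel plans with the adaptive metaheuristic
#'
#' Runs the population search over `[-0.5, 0.5]^43`. Each candidate is
#' trained briefly ([evaluate_candidate()]) and described by its raw
#' record (mIoU, params, FLOPs); scalar fitness is recomputed whenever
#' needed by normalizing the complexity components over the cumulative
#' pool of every record evaluated so far, which gives one consistent
#' ordering for memory updates, the elitist archive, and the reported
#' history (whose best-so-far fitness, under the final pool, is monotone
#' by construction).
#'
#' @param base_plan Base [channel_plan()].
#' @param train,val Scene lists.
#' @param n Population size (published search used 8).
#' @param iters Iterations (published search used 10).
#' @param epochs Training epochs per candidate.
#' @param seed Run seed; per-candidate training seeds are derived from
#'   `(seed, individual, iteration)`.
#' @param weights A [fitness_weights()].
#' @param verbose Print per-iteration progress.
#' @return List with `best` (objective record of the elitist best),
#'   `best_x`, `report` ([summarize_plan()] of the best plan), `history`
#'   (per-iteration best fitness under the final pool and strategy
#'   counts), `records` (all evaluations), `initial_best_fitness` and
#'   `final_best_fitness` (both under the final pool).
#' @export
channel_search <- function(base_plan = base_channel_plan(), train, val,
                           n = 8, iters = 10, epochs = 3, seed = 1L,
                           weights = fitness_weights(), verbose = FALSE) {
  m <- nrow(base_plan)
  space <- search_space(m, -0.5, 0.5)
  params <- strategy_params(max(iters, 1L), seed = seed)

  records <- list()         # cumulative pool
  eval_gen <- integer(0)    # generation each record was evaluated in
  add_record <- function(x, indiv, iter) {
    rec <- evaluate_candidate(x, base_plan, train, val, epochs = epochs,
                              seed = candidate_seed(seed, indiv, iter))
    rec$net <- NULL  # keep the pool light
    rec$x <- x
    records[[length(records) + 1L]] <<- rec
    eval_gen[length(records)] <<- iter
    length(records)
  }

  set.seed(seed)
  pop <- vector("list", n)
  for (i in seq_len(n)) {
    x <- space$lower + stats::runif(m) * (space$upper - space$lower)
    rid <- add_record(x, i, 0L)
    pop[[i]] <- list(position = x, velocity = numeric(m),
                     memory_rid = rid, rid = rid)
  }
  refit <- function() pool_fitness(records, weights)
  fits <- refit()
  best_rid <- which.max(fits)

  state_stub <- function() {
    # minimal optimizer state view for the shared movement primitives
    list(population = lapply(pop, function(ind) list(
           position = ind$position, velocity = ind$velocity,
           memory_position = records[[ind$memory_rid]]$x)),
         global_best = list(position = records[[best_rid]]$x,
                            fitness = fits[best_rid]),
         space = space, params = params)
  }

  history <- vector("list", iters)
  if (iters > 0) for (t in seq_len(iters)) {
    counts <- c(I = 0L, II = 0L, III = 0L, MUTATE = 0L)
    for (i in seq_len(n)) {
      s <- select_strategy(t, params)
      counts[s] <- counts[s] + 1L
      st <- state_stub()
      if (s == "I") {
        pert <- compute_perturbation(t, space, params)
        xb <- st$global_best$position
        xp <- clip_box(xb + pert$v + pert$beta, space)
        xm <- clip_box(xb - pert$v - pert$beta, space)
        rp <- add_record(xp, i, t)
        rm <- add_record(xm, i, t)
        fits <- refit()
        new_rid <- if (fits[rp] >= fits[rm]) rp else rm
        pop[[i]]$position <- records[[new_rid]]$x
      } else {
        x <- if (s == "II") strategy_two(st)
        else if (s == "III") {
          mv <- strategy_three(i, st)
          pop[[i]]$velocity <- mv$velocity
          mv$position
        } else mutate_position(pop[[i]]$position, space, params)
        new_rid <- add_record(x, i, t)
        fits <- refit()
        pop[[i]]$position <- x
      }
      pop[[i]]$rid <- new_rid
      if (fits[new_rid] > fits[pop[[i]]$memory_rid])
        pop[[i]]$memory_rid <- new_rid
      best_rid <- which.max(fits)
    }
    history[[t]] <- list(iteration = t,
                         strategy_counts = as.list(counts),
                         n_evaluated = length(records))
    if (verbose)
      message(sprintf("iter %d: %d records, best fitness %.4f (miou %.3f)",
                      t, length(records), fits[best_rid],
                      records[[best_rid]]$miou))
  }

  fits <- refit()
  best_rid <- which.max(fits)
  # best-so-far fitness under the final pool, per generation
  for (t in seq_len(iters)) {
    upto <- which(eval_gen <= t)
    history[[t]]$best_fitness <- max(fits[upto])
  }
  init_best <- max(fits[eval_gen == 0L])
  best <- records[[best_rid]]
  list(best = best, best_x = best$x, report = summarize_plan(best$plan),
       history = history, records = records,
       initial_best_fitness = init_best,
       final_best_fitness = max(fits))
}
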