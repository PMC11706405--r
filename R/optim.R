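#' Bounded-box parameter space
#'
#' @param names Character vector of parameter names.
#' @param lower,upper Numeric bound vectors, `lower < upper` elementwise.
#' @return An object of class `parameter_space`.
#' @export
parameter_space <- function(names, lower, upper) {
  stopifnot(length(names) >= 1L, length(lower) == length(names),
            length(upper) == length(names))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!all(lower < upper))
    stop("lower bounds must be strictly below upper bounds", call. = FALSE)
  structure(list(names = as.character(names), lower = lower, upper = upper,
                 dimension = length(names)),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("<parameter_space> %d parameters\n", x$dimension))
  print(data.frame(name = x$names, lower = x$lower, upper = x$upper))
  invisible(x)
}

# physical <-> normalized [0,1] coordinates
denormalize <- function(U, space) {
  U <- rbind(U) # ensure matrix
  sweep(sweep(U, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
}
normalize_params <- function(X, space) {
  X <- rbind(X)
  sweep(sweep(X, 2, space$lower, "-"), 2, space$upper - space$lower, "/")
}

#' Define an optimization problem
#'
#' The objective follows a batch-evaluation contract: it receives a matrix of
#' candidate parameter vectors (one row per candidate, physical units) and
#' must return their objective values ordered as submitted — a numeric vector
#' for single-objective problems, or an `n x n_objectives` matrix. Candidate
#' evaluations must not share mutable state, so an implementation is free to
#' evaluate a batch in parallel.
#'
#' @param space A [parameter_space()].
#' @param objective Batch objective function (see Details).
#' @param n_objectives Number of objectives (1 for single-objective).
#' @param weights Objective weights used to collapse multi-objective values
#'   to the scalar total (normalized to sum 1); default uniform.
#' @return An object of class `opt_problem`.
#' @export
make_problem <- function(space, objective, n_objectives = 1L,
                         weights = NULL) {
  stopifnot(inherits(space, "parameter_space"), is.function(objective),
            n_objectives >= 1L)
  if (is.null(weights)) weights <- rep(1, n_objectives)
  stopifnot(length(weights) == n_objectives, all(weights >= 0),
            sum(weights) > 0)
  structure(list(space = space, objective = objective,
                 n_objectives = as.integer(n_objectives),
                 weights = weights / sum(weights)),
            class = "opt_problem")
}

#' Optimizer run configuration
#'
#' @param algorithm One of `"random_search"`, `"nelder_mead"`, `"ceo"`,
#'   `"cmaes"`, `"pso"`, `"de"`, `"nsga2"`.
#' @param pop_size Candidates evaluated per generation (batch size).
#' @param n_generations Number of generations; the evaluation budget is
#'   `pop_size * n_generations`.
#' @param seed Integer seed; all randomness of a run derives from it.
#' @param target_error Optional early-stopping level: the run ends after the
#'   first completed generation whose cumulative-minimum total error is at or
#'   below this value. `NULL` (default) always spends the full budget.
#' @param hyperparams Named list of algorithm hyperparameters overriding the
#'   defaults (see each algorithm's documentation).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm, pop_size = 100L, n_generations = 100L,
                             seed = 1L, target_error = NULL,
                             hyperparams = list()) {
  algorithm <- match.arg(algorithm, names(optimizer_registry()))
  stopifnot(pop_size >= 1L, n_generations >= 1L)
  structure(list(algorithm = algorithm, pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed), target_error = target_error,
                 hyperparams = hyperparams),
            class = "optimizer_config")
}

optimizer_registry <- function() {
  list(random_search = opt_random_search,
       nelder_mead = opt_nelder_mead,
       ceo = opt_ceo,
       cmaes = opt_cmaes,
       pso = opt_pso,
       de = opt_de,
       nsga2 = opt_nsga2)
}

# ---- evaluation recorder -------------------------------------------------
# Append-only log of (params, objectives); enforces the bound invariant and
# the evaluation budget, and computes scalar totals from objective weights.
new_recorder <- function(problem, budget) {
  rec <- new.env(parent = emptyenv())
  rec$problem <- problem
  rec$budget <- budget
  rec$X <- matrix(NA_real_, budget, problem$space$dimension,
                  dimnames = list(NULL, problem$space$names))
  rec$F <- matrix(NA_real_, budget, problem$n_objectives)
  rec$total <- rep(NA_real_, budget)
  rec$gen <- rep(NA_integer_, budget)
  rec$n <- 0L
  rec
}

record_eval <- function(rec, X, gen) {
  X <- rbind(X)
  p <- rec$problem
  m <- nrow(X)
  if (rec$n + m > rec$budget)
    stop("evaluation budget exceeded", call. = FALSE)
  tol <- 1e-9 * (p$space$upper - p$space$lower)
  ok <- sweep(X, 2, p$space$lower - tol, ">=") &
        sweep(X, 2, p$space$upper + tol, "<=")
  if (!all(ok))
    stop("candidate outside parameter bounds submitted for evaluation",
         call. = FALSE)
  # snap round-off overshoot back onto the box
  X <- pmin(pmax(X, matrix(p$space$lower, m, ncol(X), byrow = TRUE)),
            matrix(p$space$upper, m, ncol(X), byrow = TRUE))
  FF <- p$objective(X)
  FF <- if (is.matrix(FF)) FF else matrix(FF, ncol = 1L)
  if (nrow(FF) != m || ncol(FF) != p$n_objectives)
    stop("objective returned results of the wrong shape", call. = FALSE)
  if (any(!is.finite(FF)) || any(FF < 0))
    stop("objective values must be finite and non-negative", call. = FALSE)
  idx <- rec$n + seq_len(m)
  rec$X[idx, ] <- X
  rec$F[idx, ] <- FF
  rec$total[idx] <- as.vector(FF %*% p$weights)
  rec$gen[idx] <- gen
  rec$n <- rec$n + m
  list(F = FF, total = rec$total[idx])
}

best_so_far <- function(rec) if (rec$n == 0L) Inf else
  min(rec$total[seq_len(rec$n)])

# finalize a recorder into a run_result
finish_run <- function(rec, config, algorithm, started,
                       benchmark_id = NA_character_,
                       final_population = NULL) {
  n <- rec$n
  idx <- seq_len(n)
  total <- rec$total[idx]
  gen <- rec$gen[idx]
  gens <- sort(unique(gen))
  gen_best <- vapply(gens, function(g) min(total[gen == g]), 0)
  gen_median <- vapply(gens, function(g) stats::median(total[gen == g]), 0)
  gen_cummin <- cummin(gen_best)
  best_index <- which.min(total)
  structure(list(
    benchmark_id = benchmark_id,
    algorithm = algorithm,
    seed = config$seed,
    config = config,
    space = rec$problem$space,
    weights = rec$problem$weights,
    n_objectives = rec$problem$n_objectives,
    params = rec$X[idx, , drop = FALSE],
    objectives = rec$F[idx, , drop = FALSE],
    totals = total,
    generation = gen,
    gen_stats = data.frame(generation = gens, best = gen_best,
                           median = gen_median, cummin = gen_cummin),
    best = list(index = best_index,
                params = rec$X[best_index, ],
                objectives = rec$F[best_index, ],
                total = total[best_index]),
    final_population = final_population,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s on %s (seed %d): %d evaluations in %d generations\n",
              x$algorithm, x$benchmark_id, x$seed, length(x$totals),
              nrow(x$gen_stats)))
  cat(sprintf("  best total error %.6g at evaluation %d\n",
              x$best$total, x$best$index))
  invisible(x)
}

#' Run an optimization algorithm on a problem
#'
#' Dispatches to the algorithm named in `config`. Every algorithm operates
#' internally in normalized `[0, 1]^d` coordinates with an affine map to the
#' physical bounds, draws all randomness from a generator seeded by
#' `config$seed`, evaluates whole generations as batches, and (unless
#' `target_error` stops it early) spends exactly
#' `pop_size * n_generations` evaluations.
#'
#' @param problem An [make_problem()] object.
#' @param config An [optimizer_config()].
#' @param benchmark_id Optional label recorded in the result.
#' @return A `run_result` (see [final_score()], [cumulative_min_curve()]).
#' @export
run_optimizer <- function(problem, config, benchmark_id = NA_character_) {
  stopifnot(inherits(problem, "opt_problem"),
            inherits(config, "optimizer_config"))
  fn <- optimizer_registry()[[config$algorithm]]
  if (config$algorithm == "nsga2" && problem$n_objectives < 2L)
    stop("nsga2 requires a multi-objective problem", call. = FALSE)
  if (config$algorithm != "nsga2" && problem$n_objectives > 1L &&
      config$algorithm %in% c("nelder_mead", "cmaes", "pso", "de", "ceo")) {
    # single-objective methods minimize the weighted total; allowed
  }
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  set.seed(config$seed)
  fn(problem, config, started, benchmark_id)
}

stop_early <- function(rec, config) {
  !is.null(config$target_error) && best_so_far(rec) <= config$target_error
}

default_hp <- function(config, defaults) {
  hp <- utils::modifyList(defaults, config$hyperparams)
  config$hyperparams <- hp
  hp
}

clip01 <- function(U) pmin(pmax(U, 0), 1)

# ---- random search -------------------------------------------------------

#' @rdname run_optimizer
#' @section Algorithms:
#' `random_search` draws i.i.d. uniform samples over the box; the history is
#' partitioned into generations of `pop_size` for reporting.
opt_random_search <- function(problem, config, started, benchmark_id) {
  d <- problem$space$dimension
  rec <- new_recorder(problem, config$pop_size * config$n_generations)
  for (g in seq_len(config$n_generations)) {
    U <- matrix(stats::runif(config$pop_size * d), config$pop_size, d)
    record_eval(rec, denormalize(U, problem$space), g)
    if (stop_early(rec, config)) break
  }
  finish_run(rec, config, "random_search", started, benchmark_id)
}

# ---- Nelder-Mead with restarts -------------------------------------------

# standard reflection/expansion/contraction/shrink simplex (1, 2, 0.5, 0.5)
# in normalized coordinates; proposals clipped to the box; restarts from a
# fresh uniform point when the simplex collapses, until the budget is spent
opt_nelder_mead <- function(problem, config, started, benchmark_id) {
  d <- problem$space$dimension
  budget <- config$pop_size * config$n_generations
  rec <- new_recorder(problem, budget)
  hp <- default_hp(config, list(alpha = 1, gamma = 2, rho = 0.5, sigma = 0.5,
                                init_step = 0.1, tol_x = 1e-10,
                                tol_f = 1e-12))
  gen_of <- function() min((rec$n %/% config$pop_size) + 1L,
                           config$n_generations)
  evl <- function(U) {
    record_eval(rec, denormalize(clip01(U), problem$space), gen_of())$total
  }
  left <- function() budget - rec$n
  while (left() > 0L && !stop_early(rec, config)) {
    # fresh simplex around a uniform random start
    x0 <- stats::runif(d)
    S <- matrix(rep(x0, d + 1L), d + 1L, d, byrow = TRUE)
    for (j in seq_len(d)) {
      step <- if (x0[j] + hp$init_step <= 1) hp$init_step else -hp$init_step
      S[j + 1L, j] <- x0[j] + step
    }
    S <- clip01(S)
    fS <- numeric(d + 1L)
    for (i in seq_len(d + 1L)) {
      if (left() == 0L) return(finish_run(rec, config, "nelder_mead",
                                          started, benchmark_id))
      fS[i] <- evl(S[i, , drop = FALSE])
    }
    repeat {
      if (left() == 0L || stop_early(rec, config)) break
      ord <- order(fS)
      S <- S[ord, , drop = FALSE]; fS <- fS[ord]
      # collapse test
      if (max(apply(S, 2, function(c) diff(range(c)))) < hp$tol_x ||
          (fS[d + 1L] - fS[1L]) < hp$tol_f) break
      centroid <- colMeans(S[seq_len(d), , drop = FALSE])
      xr <- clip01(centroid + hp$alpha * (centroid - S[d + 1L, ]))
      fr <- evl(rbind(xr))
      if (fr < fS[1L]) {
        if (left() == 0L) { S[d + 1L, ] <- xr; fS[d + 1L] <- fr; break }
        xe <- clip01(centroid + hp$gamma * (xr - centroid))
        fe <- evl(rbind(xe))
        if (fe < fr) { S[d + 1L, ] <- xe; fS[d + 1L] <- fe }
        else { S[d + 1L, ] <- xr; fS[d + 1L] <- fr }
      } else if (fr < fS[d]) {
        S[d + 1L, ] <- xr; fS[d + 1L] <- fr
      } else {
        xc <- clip01(centroid + hp$rho * (S[d + 1L, ] - centroid))
        if (left() == 0L) break
        fc <- evl(rbind(xc))
        if (fc < fS[d + 1L]) { S[d + 1L, ] <- xc; fS[d + 1L] <- fc }
        else {
          # shrink toward the best vertex
          for (i in 2:(d + 1L)) {
            S[i, ] <- clip01(S[1L, ] + hp$sigma * (S[i, ] - S[1L, ]))
            if (left() == 0L) break
            fS[i] <- evl(S[i, , drop = FALSE])
          }
          if (left() == 0L) break
        }
      }
    }
  }
  finish_run(rec, config, "nelder_mead", started, benchmark_id)
}

# ---- elitist evolutionary algorithm (CEO) --------------------------------

# generational EA: binary-tournament parent selection, blend crossover
# (alpha on normalized coordinates), per-gene Gaussian mutation, elitism
# preserving the best half of the population
opt_ceo <- function(problem, config, started, benchmark_id) {
  d <- problem$space$dimension
  lambda <- config$pop_size
  rec <- new_recorder(problem, lambda * config$n_generations)
  hp <- default_hp(config, list(
    n_elites = lambda %/% 2L, mutation_rate = 0.25, mutation_sigma = 0.5,
    blend_alpha = 0.1, crossover_rate = 1.0, tournament_size = 2L))
  U <- matrix(stats::runif(lambda * d), lambda, d)
  f <- record_eval(rec, denormalize(U, problem$space), 1L)$total
  for (g in seq_len(config$n_generations - 1L) + 1L) {
    if (stop_early(rec, config)) break
    pick <- function() { # binary tournament
      c2 <- sample.int(lambda, hp$tournament_size)
      c2[which.min(f[c2])]
    }
    Off <- matrix(NA_real_, lambda, d)
    for (i in seq(1L, lambda, by = 2L)) {
      p1 <- U[pick(), ]; p2 <- U[pick(), ]
      if (stats::runif(1) < hp$crossover_rate) {
        lo <- pmin(p1, p2); hi <- pmax(p1, p2); span <- hi - lo
        c1 <- stats::runif(d, lo - hp$blend_alpha * span,
                           hi + hp$blend_alpha * span)
        c2 <- stats::runif(d, lo - hp$blend_alpha * span,
                           hi + hp$blend_alpha * span)
      } else { c1 <- p1; c2 <- p2 }
      Off[i, ] <- c1
      if (i + 1L <= lambda) Off[i + 1L, ] <- c2
    }
    mut <- matrix(stats::runif(lambda * d) < hp$mutation_rate, lambda, d)
    Off[mut] <- Off[mut] + stats::rnorm(sum(mut), 0, hp$mutation_sigma)
    Off <- clip01(Off)
    f_off <- record_eval(rec, denormalize(Off, problem$space), g)$total
    # elitism: best n_elites of the current population survive, the rest of
    # the next population is filled with the best offspring
    el <- order(f)[seq_len(hp$n_elites)]
    fill <- order(f_off)[seq_len(lambda - hp$n_elites)]
    U <- rbind(U[el, , drop = FALSE], Off[fill, , drop = FALSE])
    f <- c(f[el], f_off[fill])
  }
  finish_run(rec, config, "ceo", started, benchmark_id)
}

# ---- CMA-ES --------------------------------------------------------------

# standard CMA-ES (weighted recombination of the best mu = pop/2, rank-1 +
# rank-mu covariance update, cumulative step-size adaptation), sampling in
# normalized [0,1]^d coordinates; initial mean at the box center, initial
# sigma 0.3; out-of-bounds samples are resampled up to a retry cap, then
# clipped; a covariance that loses positive-definiteness triggers a restart
# with inflated sigma (the evaluation budget is preserved)
opt_cmaes <- function(problem, config, started, benchmark_id) {
  d <- problem$space$dimension
  lambda <- config$pop_size
  rec <- new_recorder(problem, lambda * config$n_generations)
  hp <- default_hp(config, list(sigma0 = 0.3, mu = lambda %/% 2L,
                                resample_cap = 100L))
  mu <- hp$mu
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  c_sigma <- (mu_eff + 2) / (d + mu_eff + 5)
  d_sigma <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (d + 1)) - 1) + c_sigma
  c_c <- (4 + mu_eff / d) / (d + 4 + 2 * mu_eff / d)
  c_1 <- 2 / ((d + 1.3)^2 + mu_eff)
  c_mu <- min(1 - c_1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((d + 2)^2 + mu_eff))
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))
  restart <- function() {
    list(m = rep(0.5, d), sigma = hp$sigma0, C = diag(d),
         p_sigma = rep(0, d), p_c = rep(0, d), g0 = 0L)
  }
  st <- restart()
  for (g in seq_len(config$n_generations)) {
    if (stop_early(rec, config)) break
    eig <- eigen(st$C, symmetric = TRUE)
    if (any(!is.finite(eig$values)) || min(eig$values) <= 0) {
      st <- restart(); st$sigma <- hp$sigma0 * 2; st$g0 <- g - 1L
      eig <- eigen(st$C, symmetric = TRUE)
    }
    B <- eig$vectors
    Dd <- sqrt(pmax(eig$values, 0))
    BD <- B %*% diag(Dd, d)
    invsqrtC <- B %*% diag(1 / Dd, d) %*% t(B)
    # sample lambda candidates; resample rows leaving the box, then clip
    Z <- matrix(stats::rnorm(lambda * d), lambda, d)
    X <- matrix(rep(st$m, each = lambda), lambda, d) +
      st$sigma * Z %*% t(BD)
    for (r in seq_len(hp$resample_cap)) {
      bad <- which(apply(X < 0 | X > 1, 1, any))
      if (!length(bad)) break
      Zb <- matrix(stats::rnorm(length(bad) * d), length(bad), d)
      X[bad, ] <- matrix(rep(st$m, each = length(bad)), length(bad), d) +
        st$sigma * Zb %*% t(BD)
    }
    X <- clip01(X)
    f <- record_eval(rec, denormalize(X, problem$space), g)$total
    ord <- order(f)[seq_len(mu)]
    Y <- (X - matrix(rep(st$m, each = lambda), lambda, d)) / st$sigma
    y_w <- as.vector(w %*% Y[ord, , drop = FALSE])
    st$m <- st$m + st$sigma * y_w
    st$p_sigma <- (1 - c_sigma) * st$p_sigma +
      sqrt(c_sigma * (2 - c_sigma) * mu_eff) * as.vector(invsqrtC %*% y_w)
    gi <- g - st$g0
    h_sig <- sqrt(sum(st$p_sigma^2)) /
      sqrt(1 - (1 - c_sigma)^(2 * gi)) / chiN < 1.4 + 2 / (d + 1)
    st$p_c <- (1 - c_c) * st$p_c +
      (if (h_sig) sqrt(c_c * (2 - c_c) * mu_eff) else 0) * y_w
    Ymu <- Y[ord, , drop = FALSE]
    rank_mu <- t(Ymu) %*% (w * Ymu)
    st$C <- (1 - c_1 - c_mu) * st$C +
      c_1 * (tcrossprod(st$p_c) +
             (if (h_sig) 0 else c_c * (2 - c_c)) * st$C) +
      c_mu * rank_mu
    st$C <- (st$C + t(st$C)) / 2
    st$sigma <- st$sigma *
      exp((c_sigma / d_sigma) * (sqrt(sum(st$p_sigma^2)) / chiN - 1))
    if (!is.finite(st$sigma) || st$sigma > 1e4) {
      st <- restart(); st$sigma <- hp$sigma0 * 2; st$g0 <- g
    }
  }
  finish_run(rec, config, "cmaes", started, benchmark_id)
}

# ---- particle swarm (generational) ---------------------------------------

# v <- omega v + c1 r1 (pbest - x) + c2 r2 (gbest - x); x <- x + v, with the
# constriction defaults omega = 0.7298, c1 = c2 = 1.49618; velocities
# clamped to half the (normalized) box width, positions clipped; all
# particles are updated from the same gbest snapshot in each generation
opt_pso <- function(problem, config, started, benchmark_id) {
  d <- problem$space$dimension
  lambda <- config$pop_size
  rec <- new_recorder(problem, lambda * config$n_generations)
  hp <- default_hp(config, list(omega = 0.7298, c1 = 1.49618, c2 = 1.49618,
                                v_max = 0.5, init = NULL))
  U <- if (!is.null(hp$init)) rbind(hp$init)
       else matrix(stats::runif(lambda * d), lambda, d)
  V <- matrix(0, lambda, d)
  f <- record_eval(rec, denormalize(U, problem$space), 1L)$total
  P <- U; fp <- f
  gi <- which.min(fp)
  gbest <- P[gi, ]; fg <- fp[gi]
  for (g in seq_len(config$n_generations - 1L) + 1L) {
    if (stop_early(rec, config)) break
    R1 <- matrix(stats::runif(lambda * d), lambda, d)
    R2 <- matrix(stats::runif(lambda * d), lambda, d)
    G <- matrix(rep(gbest, each = lambda), lambda, d)
    V <- hp$omega * V + hp$c1 * R1 * (P - U) + hp$c2 * R2 * (G - U)
    V <- pmin(pmax(V, -hp$v_max), hp$v_max)
    U <- clip01(U + V)
    f <- record_eval(rec, denormalize(U, problem$space), g)$total
    better <- f < fp
    P[better, ] <- U[better, , drop = FALSE]
    fp[better] <- f[better]
    gi <- which.min(fp)
    if (fp[gi] < fg) { gbest <- P[gi, ]; fg <- fp[gi] }
  }
  finish_run(rec, config, "pso", started, benchmark_id)
}

# ---- differential evolution ----------------------------------------------

# DE/rand/1/bin with F = 0.8, CR = 0.9, greedy one-to-one replacement,
# trial vectors clipped to the box
opt_de <- function(problem, config, started, benchmark_id) {
  d <- problem$space$dimension
  lambda <- config$pop_size
  if (lambda < 4L) stop("differential evolution needs pop_size >= 4",
                        call. = FALSE)
  rec <- new_recorder(problem, lambda * config$n_generations)
  hp <- default_hp(config, list(F = 0.8, CR = 0.9))
  U <- matrix(stats::runif(lambda * d), lambda, d)
  f <- record_eval(rec, denormalize(U, problem$space), 1L)$total
  for (g in seq_len(config$n_generations - 1L) + 1L) {
    if (stop_early(rec, config)) break
    Trial <- matrix(NA_real_, lambda, d)
    for (i in seq_len(lambda)) {
      r <- sample(setdiff(seq_len(lambda), i), 3L)
      mutant <- U[r[1], ] + hp$F * (U[r[2], ] - U[r[3], ])
      jrand <- sample.int(d, 1L)
      cross <- stats::runif(d) < hp$CR
      cross[jrand] <- TRUE
      trial <- U[i, ]
      trial[cross] <- mutant[cross]
      Trial[i, ] <- trial
    }
    Trial <- clip01(Trial)
    f_tr <- record_eval(rec, denormalize(Trial, problem$space), g)$total
    better <- f_tr < f
    U[better, ] <- Trial[better, , drop = FALSE]
    f[better] <- f_tr[better]
  }
  finish_run(rec, config, "de", started, benchmark_id)
}

#' Select the single preferred solution from a set of candidates
#'
#' Picks the candidate minimizing the normalized-weighted sum of its
#' objectives. Ties are broken by the earliest evaluation (row) index. This
#' is how a single winner is chosen from the set returned by a
#' multi-objective algorithm.
#'
#' @param objectives Numeric matrix of objective values, one candidate per
#'   row (a single-objective vector is accepted).
#' @param weights Non-negative objective weights; normalized to sum 1.
#'   Default uniform.
#' @param params Optional matrix of the candidates' parameter vectors.
#' @return A list with `index`, `total`, `objectives` and (if supplied)
#'   `params` of the winner.
#' @export
select_winner <- function(objectives, weights = NULL, params = NULL) {
  FF <- if (is.matrix(objectives)) objectives else matrix(objectives, ncol = 1)
  if (nrow(FF) == 0L) stop("empty candidate set", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, ncol(FF))
  stopifnot(length(weights) == ncol(FF), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  tot <- as.vector(FF %*% weights)
  i <- which.min(tot) # which.min returns the earliest index on ties
  out <- list(index = i, total = tot[i], objectives = FF[i, ])
  if (!is.null(params)) out$params <- rbind(params)[i, ]
  out
}
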