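ALGOS <- c("random_search", "nelder_mead", "ceo", "cmaes", "pso", "de")

test_that("every algorithm spends exactly its budget, in bounds,
           deterministically under a fixed seed", {
  prob <- sphere_problem(d = 2)
  for (alg in ALGOS) {
    cfg <- optimizer_config(alg, pop_size = 10, n_generations = 6, seed = 3)
    r1 <- run_optimizer(prob, cfg)
    r2 <- run_optimizer(prob, cfg)
    expect_equal(length(r1$totals), 60, info = alg)
    expect_true(all(r1$params >= -5 & r1$params <= 5), info = alg)
    expect_identical(r1$params, r2$params, info = alg)
    expect_identical(r1$totals, r2$totals, info = alg)
    r3 <- run_optimizer(prob, optimizer_config(alg, 10, 6, seed = 4))
    expect_false(identical(r1$params, r3$params), info = alg)
    expect_true(all(diff(r1$gen_stats$cummin) <= 0), info = alg)
    expect_equal(r1$best$total, min(r1$totals), info = alg)
  }
  # multi-objective budget and determinism
  mo <- make_problem(parameter_space(c("x", "y"), c(-1, -1), c(2, 2)),
                     function(X) cbind(rowSums(X^2),
                                       rowSums((X - 1)^2)),
                     n_objectives = 2)
  n1 <- run_optimizer(mo, optimizer_config("nsga2", 10, 6, seed = 3))
  n2 <- run_optimizer(mo, optimizer_config("nsga2", 10, 6, seed = 3))
  expect_equal(length(n1$totals), 60)
  expect_identical(n1$params, n2$params)
})

test_that("random search matches the uniform order-statistic expectation", {
  # f(x) = x on [0, 1]: the best of n uniform draws has mean 1/(n+1)
  prob <- make_problem(parameter_space("x", 0, 1), function(X) X[, 1])
  n <- 100
  best <- vapply(1:200, function(s)
    final_score(run_optimizer(prob, optimizer_config(
      "random_search", pop_size = n, n_generations = 1, seed = s))), 0)
  se <- stats::sd(best) / sqrt(length(best))
  expect_lt(abs(mean(best) - 1 / (n + 1)), 3 * se)
  # budget 1: exactly one evaluation logged
  r1 <- run_optimizer(prob, optimizer_config("random_search", 1, 1, seed = 1))
  expect_equal(length(r1$totals), 1)
})

test_that("Nelder-Mead converges on a smooth convex function and respects
           bounds", {
  prob <- sphere_problem(d = 2)
  r <- run_optimizer(prob, optimizer_config("nelder_mead", pop_size = 100,
                                            n_generations = 5, seed = 1))
  expect_lt(min(cummin(r$totals)[500]), 1e-8)
  # constant objective: spends the budget, best equals the constant
  cst <- make_problem(parameter_space("x", 0, 1), function(X)
    rep(3.5, nrow(X)))
  rc <- run_optimizer(cst, optimizer_config("nelder_mead", 10, 5, seed = 1))
  expect_equal(length(rc$totals), 50)
  expect_equal(final_score(rc), 3.5)
  # optimum outside the box: the best stays on the boundary
  lin <- make_problem(parameter_space("x", 2, 4), function(X) X[, 1])
  rl <- run_optimizer(lin, optimizer_config("nelder_mead", 20, 5, seed = 2))
  expect_equal(final_score(rl), 2, tolerance = 1e-6)
})

test_that("the elitist EA keeps its best and degenerates without variation", {
  prob <- sphere_problem(d = 3)
  r <- run_optimizer(prob, optimizer_config("ceo", 20, 20, seed = 1))
  gb <- vapply(split(r$totals, r$generation), min, 0)
  expect_true(all(diff(cummin(gb)) <= 0))
  # elitism: the running best never worsens generation to generation
  expect_true(all(diff(r$gen_stats$cummin) <= 0))
  # no mutation, no crossover: offspring are copies of selected parents
  r0 <- run_optimizer(prob, optimizer_config(
    "ceo", 12, 6, seed = 5,
    hyperparams = list(mutation_rate = 0, crossover_rate = 0)))
  first <- r0$params[r0$generation == 1, , drop = FALSE]
  last <- r0$params[r0$generation == 6, , drop = FALSE]
  in_first <- apply(last, 1, function(row)
    any(apply(first, 1, function(p) all(p == row))))
  expect_true(all(in_first))
})

test_that("CEO reliably minimizes a small sphere at the study budget", {
  best <- vapply(1:10, function(s)
    final_score(run_optimizer(sphere_problem(d = 3),
                              optimizer_config("ceo", 100, 100, seed = s))),
    0)
  # < 1e-3 in normalized coordinates = < 1e-3 * 10^2 in physical units
  expect_gte(sum(best < 1e-3 * 100), 9)
})

test_that("native CMA-ES matches the reference implementation on the
           sphere and Rosenbrock at equal budget", {
  sp <- sphere_problem(d = 10, lim = 5)
  nat <- final_score(run_optimizer(sp, optimizer_config("cmaes", 100, 100,
                                                        seed = 1)))
  ref <- reference_cmaes(sp$objective, rep(-5, 10), rep(5, 10),
                         lambda = 100, gens = 100, seed = 1)
  # both routes reach the convergence floor; compare magnitudes floored
  # there (below the floor the values are numerical noise)
  expect_lt(nat, 1e-10)
  expect_lt(ref, 1e-10)
  expect_lte(max(nat, 1e-10), 10 * max(ref, 1e-10))
  ros <- rosenbrock_problem(d = 5)
  ok <- 0
  for (s in 1:5) {
    nat_r <- final_score(run_optimizer(ros, optimizer_config(
      "cmaes", 100, 100, seed = s)))
    if (nat_r < 1e-6) ok <- ok + 1
  }
  expect_gte(ok, 4)
  ref_r <- reference_cmaes(ros$objective, rep(-2, 5), rep(2, 5),
                           lambda = 100, gens = 100, seed = 1)
  expect_lt(ref_r, 1e-6) # both routes solve it
})

test_that("PSO holds its fixed point and improves monotonically in gbest", {
  prob <- sphere_problem(d = 2)
  # a single particle starting at the optimum with zero velocity stays
  r <- run_optimizer(prob, optimizer_config(
    "pso", pop_size = 1, n_generations = 10, seed = 1,
    hyperparams = list(init = matrix(0.5, 1, 2))))
  expect_true(all(r$totals == 0))
  expect_true(all(r$params == 0))
  r2 <- run_optimizer(prob, optimizer_config("pso", 30, 30, seed = 2))
  expect_true(all(diff(r2$gen_stats$cummin) <= 0))
})

test_that("PSO reliably minimizes a small sphere at the study budget", {
  best <- vapply(1:10, function(s)
    final_score(run_optimizer(sphere_problem(d = 3),
                              optimizer_config("pso", 100, 100, seed = s))),
    0)
  expect_gte(sum(best < 1e-6), 9)
})

test_that("differential evolution improves greedily and its operators are
           correct in the degenerate limit", {
  best <- vapply(1:10, function(s)
    final_score(run_optimizer(sphere_problem(d = 3),
                              optimizer_config("de", 100, 100, seed = s))),
    0)
  expect_gte(sum(best < 1e-6), 9)
  r <- run_optimizer(sphere_problem(d = 3),
                     optimizer_config("de", 20, 20, seed = 1))
  pb <- vapply(split(r$totals, r$generation), min, 0)
  expect_true(all(diff(cummin(pb)) <= 0))
  # CR = 0, F = 0: each trial equals its target except one coordinate,
  # which is copied from some member of the previous population
  r0 <- run_optimizer(sphere_problem(d = 4), optimizer_config(
    "de", 4, 2, seed = 7, hyperparams = list(F = 0, CR = 0)))
  pop <- r0$params[r0$generation == 1, , drop = FALSE]
  tri <- r0$params[r0$generation == 2, , drop = FALSE]
  for (i in 1:4) {
    changed <- which(tri[i, ] != pop[i, ])
    expect_lte(length(changed), 1)
    if (length(changed) == 1)
      expect_true(tri[i, changed] %in% pop[, changed])
  }
})

test_that("winner selection minimizes the weighted sum with early tie-break", {
  expect_equal(select_winner(matrix(c(3, 1), 1, 2))$index, 1)
  FF <- rbind(c(1, 0), c(0, 1))
  expect_equal(select_winner(FF, c(1, 1))$index, 1) # tie -> earliest
  FF3 <- rbind(c(0.5, 9), c(0.4, 10), c(0.6, 0))
  expect_equal(select_winner(FF3, c(1, 0))$index, 2)
  w <- select_winner(FF3, c(1, 1), params = diag(3))
  expect_equal(w$index, 3)
  expect_equal(w$params, c(0, 0, 1))
  expect_error(select_winner(matrix(numeric(0), 0, 2)), "empty")
})

test_that("fast non-dominated sort agrees with the brute-force oracle", {
  # hand-built six-point set: front {(1,1),(0.5,3),(3,0.5)}, then (1,2)
  # alone (it dominates (2,2)), then (2,2), then (2.5,2.5)
  FF <- rbind(c(1, 1), c(2, 2), c(1, 2), c(0.5, 3), c(3, 0.5), c(2.5, 2.5))
  expect_equal(fast_nondominated_sort(FF), c(1L, 3L, 2L, 1L, 1L, 4L))
  expect_equal(brute_force_ranks(FF), c(1L, 3L, 2L, 1L, 1L, 4L))
  set.seed(11)
  for (m in 2:3) {
    FF <- matrix(runif(50 * m), 50, m)
    expect_equal(fast_nondominated_sort(FF), brute_force_ranks(FF))
  }
})

test_that("crowding distance rewards boundary and isolated points", {
  FF <- rbind(c(0, 1), c(0.5, 0.5), c(1, 0))
  cd <- crowding_distance(FF)
  expect_true(all(is.infinite(cd[c(1, 3)])))
  expect_equal(cd[2], 2) # normalized gaps sum to 1 + 1
})

test_that("NSGA-II approximates the Schaffer Pareto set and returns a
           mutually non-dominated front", {
  sch <- make_problem(parameter_space("x", -1, 2),
                      function(X) cbind(X[, 1]^2, (X[, 1] - 1)^2),
                      n_objectives = 2)
  r <- run_optimizer(sch, optimizer_config("nsga2", 40, 25, seed = 1))
  fp <- r$final_population
  front <- fp$params[fp$rank == 1, 1]
  expect_true(all(front >= -0.05 & front <= 1.05))
  expect_gt(length(front), 10)
  FF <- fp$objectives[fp$rank == 1, , drop = FALSE]
  expect_true(all(fast_nondominated_sort(FF) == 1L))
  expect_error(run_optimizer(sphere_problem(2),
                             optimizer_config("nsga2", 10, 5, seed = 1)),
               "multi-objective")
})

test_that("early stopping ends a run at the first generation reaching the
           target error", {
  prob <- sphere_problem(d = 2)
  r <- run_optimizer(prob, optimizer_config("cmaes", 50, 100, seed = 1,
                                            target_error = 1e-6))
  expect_lt(length(r$totals), 50 * 100)
  expect_lte(final_score(r), 1e-6)
  expect_equal(length(r$totals) %% 50, 0) # whole generations only
})
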