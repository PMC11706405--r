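#' Fast non-dominated sorting
#'
#' Assigns each candidate its Pareto rank: rank 1 is the non-dominated set,
#' rank 2 the non-dominated set after removing rank 1, and so on. Candidate
#' `i` dominates `j` when it is no worse on every objective and strictly
#' better on at least one (all objectives minimized).
#'
#' @param FF Numeric matrix of objective values, one candidate per row.
#' @return Integer vector of ranks.
#' @export
fast_nondominated_sort <- function(FF) {
  FF <- rbind(FF)
  n <- nrow(FF)
  dominates <- function(i, j) {
    all(FF[i, ] <= FF[j, ]) && any(FF[i, ] < FF[j, ])
  }
  S <- vector("list", n)     # who i dominates
  cnt <- integer(n)          # how many dominate i
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) S[[i]] <- c(S[[i]], j)
      else if (dominates(j, i)) cnt[i] <- cnt[i] + 1L
    }
  }
  rank <- integer(n)
  front <- which(cnt == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in S[[i]]) {
        cnt[j] <- cnt[j] - 1L
        if (cnt[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    r <- r + 1L
  }
  rank
}

#' Crowding distance within a front
#'
#' Sum over objectives of the normalized gap between a candidate's
#' neighbours when the front is sorted by that objective; boundary
#' candidates get `Inf`.
#'
#' @param FF Numeric matrix of objective values (all rows one front).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(FF) {
  FF <- rbind(FF)
  n <- nrow(FF)
  if (n <= 2L) return(rep(Inf, n))
  dist <- numeric(n)
  for (m in seq_len(ncol(FF))) {
    ord <- order(FF[, m])
    rng <- FF[ord[n], m] - FF[ord[1], m]
    dist[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      mid <- ord[2:(n - 1L)]
      dist[mid] <- dist[mid] +
        (FF[ord[3:n], m] - FF[ord[1:(n - 2L)], m]) / rng
    }
  }
  dist
}

# simulated binary crossover (SBX), eta_c distribution index; operates on a
# pair of normalized parents; per-gene crossover with probability 0.5
sbx_pair <- function(p1, p2, eta) {
  d <- length(p1)
  c1 <- p1; c2 <- p2
  do <- stats::runif(d) < 0.5
  u <- stats::runif(d)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1[do] <- 0.5 * ((1 + beta[do]) * p1[do] + (1 - beta[do]) * p2[do])
  c2[do] <- 0.5 * ((1 - beta[do]) * p1[do] + (1 + beta[do]) * p2[do])
  list(clip01(c1), clip01(c2))
}

# polynomial mutation, eta_m distribution index, per-gene rate
poly_mutate <- function(x, eta, rate) {
  d <- length(x)
  do <- stats::runif(d) < rate
  if (!any(do)) return(x)
  u <- stats::runif(sum(do))
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[do] <- x[do] + delta
  clip01(x)
}

# NSGA-II: fast non-dominated sorting, crowding-distance truncation of the
# merged parent+child population, binary tournament on (rank, crowding),
# SBX crossover (eta 15) and polynomial mutation (eta 20, rate 1/d)
opt_nsga2 <- function(problem, config, started, benchmark_id) {
  d <- problem$space$dimension
  lambda <- config$pop_size
  rec <- new_recorder(problem, lambda * config$n_generations)
  hp <- default_hp(config, list(eta_c = 15, eta_m = 20,
                                mutation_rate = 1 / d, crossover_rate = 0.9))
  U <- matrix(stats::runif(lambda * d), lambda, d)
  FF <- record_eval(rec, denormalize(U, problem$space), 1L)$F
  rank <- fast_nondominated_sort(FF)
  crowd <- crowd_by_front(FF, rank)
  for (g in seq_len(config$n_generations - 1L) + 1L) {
    if (stop_early(rec, config)) break
    pick <- function() { # binary tournament on (rank, crowding)
      ij <- sample.int(lambda, 2L)
      i <- ij[1]; j <- ij[2]
      if (rank[i] < rank[j]) i
      else if (rank[j] < rank[i]) j
      else if (crowd[i] >= crowd[j]) i else j
    }
    Off <- matrix(NA_real_, lambda, d)
    for (i in seq(1L, lambda, by = 2L)) {
      p1 <- U[pick(), ]; p2 <- U[pick(), ]
      if (stats::runif(1) < hp$crossover_rate) {
        ch <- sbx_pair(p1, p2, hp$eta_c)
      } else ch <- list(p1, p2)
      Off[i, ] <- poly_mutate(ch[[1]], hp$eta_m, hp$mutation_rate)
      if (i + 1L <= lambda)
        Off[i + 1L, ] <- poly_mutate(ch[[2]], hp$eta_m, hp$mutation_rate)
    }
    FF_off <- record_eval(rec, denormalize(Off, problem$space), g)$F
    # environmental selection on the merged population
    MU <- rbind(U, Off)
    MF <- rbind(FF, FF_off)
    mrank <- fast_nondominated_sort(MF)
    mcrowd <- crowd_by_front(MF, mrank)
    ord <- order(mrank, -mcrowd)
    keep <- ord[seq_len(lambda)]
    U <- MU[keep, , drop = FALSE]
    FF <- MF[keep, , drop = FALSE]
    rank <- mrank[keep]
    crowd <- mcrowd[keep]
  }
  final_pop <- list(params = denormalize(U, problem$space),
                    objectives = FF,
                    rank = fast_nondominated_sort(FF))
  finish_run(rec, config, "nsga2", started, benchmark_id,
             final_population = final_pop)
}

crowd_by_front <- function(FF, rank) {
  crowd <- numeric(nrow(FF))
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowding_distance(FF[idx, , drop = FALSE])
  }
  crowd
}
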