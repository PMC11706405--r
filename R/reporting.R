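#' Cumulative-minimum convergence curve of a run
#'
#' Element `g` is the minimum total error over all evaluations in
#' generations `1..g`; non-increasing by construction.
#'
#' @param run A `run_result`.
#' @return Numeric vector, one element per generation.
#' @export
cumulative_min_curve <- function(run) {
  stopifnot(inherits(run, "run_result"))
  run$gen_stats$cummin
}

#' Final score: the lowest total error achieved during a run
#'
#' Equals the last element of [cumulative_min_curve()].
#'
#' @param run A `run_result`.
#' @return Unitless scalar.
#' @export
final_score <- function(run) {
  stopifnot(inherits(run, "run_result"))
  curve <- run$gen_stats$cummin
  curve[length(curve)]
}

#' Convergence score: area under the logarithmic convergence curve
#'
#' The sum over generations of `log10` of the cumulative-minimum error,
#' floored at `floor` to guard exact-zero surrogate fits. Lower is faster
#' convergence. The cumulative minimum (rather than the per-generation best)
#' is used; the two differ only for non-elitist algorithms.
#'
#' @param run A `run_result`.
#' @param floor Positive floor applied inside the logarithm.
#' @return Unitless scalar (may be negative).
#' @export
convergence_score <- function(run, floor = 1e-12) {
  stopifnot(inherits(run, "run_result"), floor > 0)
  sum(log10(pmax(run$gen_stats$cummin, floor)))
}

#' Score table over a set of runs
#'
#' @param runs A list of `run_result` objects (possibly spanning several
#'   benchmarks and algorithms).
#' @return A data frame with one row per run: `benchmark`, `algorithm`,
#'   `seed`, `final_score`, `convergence_score`.
#' @export
score_table <- function(runs) {
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, TRUE, "run_result")))
  do.call(rbind, lapply(runs, function(r) data.frame(
    benchmark = r$benchmark_id, algorithm = r$algorithm, seed = r$seed,
    final_score = final_score(r), convergence_score = convergence_score(r),
    stringsAsFactors = FALSE)))
}

#' Rank algorithms on one benchmark by the median of a score
#'
#' Algorithms are ordered ascending by the median of `metric` over their
#' seeded runs; tied medians share the mean of the tied ranks.
#'
#' @param scores A [score_table()] data frame.
#' @param benchmark Benchmark id to rank on.
#' @param metric `"final_score"` or `"convergence_score"`.
#' @return A data frame with `algorithm`, `median`, `rank`, ordered by rank.
#' @export
rank_algorithms <- function(scores, benchmark,
                            metric = c("final_score", "convergence_score")) {
  metric <- match.arg(metric)
  sub <- scores[scores$benchmark == benchmark, , drop = FALSE]
  if (length(unique(sub$algorithm)) < 2L)
    stop("ranking needs at least 2 algorithms with runs on the benchmark",
         call. = FALSE)
  med <- tapply(sub[[metric]], sub$algorithm, stats::median)
  out <- data.frame(algorithm = names(med), median = as.vector(med),
                    rank = rank(as.vector(med), ties.method = "average"),
                    stringsAsFactors = FALSE)
  out[order(out$rank), , drop = FALSE]
}

#' Rank statistics of each algorithm across benchmarks
#'
#' Ranks every algorithm on every benchmark via [rank_algorithms()], then
#' summarizes each algorithm's ranks by their median, minimum and maximum.
#'
#' @param scores A [score_table()] data frame.
#' @param benchmarks Character vector of benchmark ids; every algorithm must
#'   have runs on each of them.
#' @param metric `"final_score"` or `"convergence_score"`.
#' @return A data frame with `algorithm`, `median_rank`, `min_rank`,
#'   `max_rank`, ordered by median rank.
#' @export
overall_rank_stats <- function(scores, benchmarks,
                               metric = c("final_score",
                                          "convergence_score")) {
  metric <- match.arg(metric)
  algos <- unique(scores$algorithm)
  for (b in benchmarks) {
    have <- unique(scores$algorithm[scores$benchmark == b])
    missing <- setdiff(algos, have)
    if (length(missing))
      stop(sprintf("missing runs: %s on benchmark '%s'",
                   paste(missing, collapse = ", "), b), call. = FALSE)
  }
  rk <- sapply(benchmarks, function(b) {
    r <- rank_algorithms(scores, b, metric)
    r$rank[match(algos, r$algorithm)]
  })
  rk <- rbind(rk) # algorithms x benchmarks
  out <- data.frame(algorithm = algos,
                    median_rank = apply(rk, 1, stats::median),
                    min_rank = apply(rk, 1, min),
                    max_rank = apply(rk, 1, max),
                    stringsAsFactors = FALSE)
  out[order(out$median_rank), , drop = FALSE]
}

METADATA_SCHEMA_VERSION <- "1.0"

#' Write the machine-readable JSON record of a run
#'
#' A single JSON object holding the run and benchmark names; the parameter
#' names, bounds and best values; the error components of the best candidate
#' (name, raw value, weight, weighted value); the algorithm with its full
#' effective hyperparameters and seed; the per-generation statistics (best,
#' median, cumulative minimum); timestamps; and schema/package versions.
#'
#' @param run A `run_result`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(run, path) {
  stopifnot(inherits(run, "run_result"))
  comp_names <- if (!is.null(run$best$error_vector))
    run$best$error_vector$components$name
  else if (!is.null(names(run$best$objectives)))
    names(run$best$objectives)
  else paste0("objective_", seq_len(run$n_objectives))
  raw <- as.numeric(run$best$objectives)
  doc <- list(
    schema_version = METADATA_SCHEMA_VERSION,
    artifact = list(name = "neurofitr",
                    version = as.character(utils::packageVersion("neurofitr"))),
    run_name = sprintf("%s_%s_seed%d", run$benchmark_id, run$algorithm,
                       run$seed),
    benchmark = run$benchmark_id,
    algorithm = list(name = run$algorithm, seed = run$seed,
                     pop_size = run$config$pop_size,
                     n_generations = run$config$n_generations,
                     hyperparams = run$config$hyperparams),
    parameters = list(names = run$space$names, lower = run$space$lower,
                      upper = run$space$upper,
                      best = as.numeric(run$best$params)),
    error_components = data.frame(name = comp_names, raw_value = raw,
                                  weight = run$weights,
                                  weighted_value = raw * run$weights),
    final_score = final_score(run),
    convergence_score = convergence_score(run),
    generation_stats = run$gen_stats,
    started = run$started, finished = run$finished)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read back a JSON run record
#'
#' @param path A file written by [write_metadata()].
#' @return The parsed record (a list).
#' @export
read_metadata <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# reconstruct a lightweight run_result (generation stats, best candidate,
# config echo) from a JSON record; used to resume interrupted studies
read_metadata_run <- function(path) {
  doc <- tryCatch(read_metadata(path), error = function(e) NULL)
  if (is.null(doc) || is.null(doc$generation_stats)) return(NULL)
  space <- parameter_space(doc$parameters$names, doc$parameters$lower,
                           doc$parameters$upper)
  w <- doc$error_components$weight
  cfg <- optimizer_config(doc$algorithm$name,
                          pop_size = doc$algorithm$pop_size,
                          n_generations = doc$algorithm$n_generations,
                          seed = doc$algorithm$seed,
                          hyperparams = as.list(doc$algorithm$hyperparams))
  best_p <- stats::setNames(doc$parameters$best, doc$parameters$names)
  structure(list(
    benchmark_id = doc$benchmark, algorithm = doc$algorithm$name,
    seed = doc$algorithm$seed, config = cfg, space = space,
    weights = w, n_objectives = length(w),
    params = NULL, objectives = NULL, totals = NULL, generation = NULL,
    gen_stats = as.data.frame(doc$generation_stats),
    best = list(index = NA_integer_, params = best_p,
                objectives = doc$error_components$raw_value,
                total = doc$final_score),
    final_population = NULL,
    started = doc$started, finished = doc$finished
  ), class = "run_result")
}

#' Plot the benchmark report figures
#'
#' Writes three figures: median convergence curves per algorithm (log scale),
#' and box plots of the final and convergence scores over seeds, sorted
#' ascending by median (Tukey boxes: median, interquartile box, whiskers to
#' the most extreme points within 1.5 IQR, outliers as circles).
#'
#' @param scores A [score_table()] data frame for one benchmark.
#' @param runs The corresponding list of `run_result` objects.
#' @param dir Output directory for PNG files.
#' @param prefix File-name prefix (defaults to the benchmark id).
#' @return Invisibly, the paths of the written files.
#' @export
plot_report <- function(scores, runs, dir = ".", prefix = NULL) {
  stopifnot(nrow(scores) >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- scores$benchmark[1]
  paths <- character(0)

  # median convergence curve per algorithm
  p1 <- file.path(dir, paste0(prefix, "_convergence.png"))
  grDevices::png(p1, width = 900, height = 600)
  algos <- unique(vapply(runs, function(r) r$algorithm, ""))
  curves <- lapply(algos, function(a) {
    cs <- lapply(Filter(function(r) r$algorithm == a, runs),
                 cumulative_min_curve)
    len <- max(lengths(cs))
    cs <- lapply(cs, function(x) c(x, rep(x[length(x)], len - length(x))))
    apply(do.call(cbind, cs), 1, stats::median)
  })
  ymin <- max(min(unlist(curves)), 1e-12)
  ymax <- max(unlist(curves))
  graphics::plot(NULL, xlim = c(1, max(lengths(curves))),
                 ylim = c(ymin, ymax), log = "y",
                 xlab = "generation", ylab = "cumulative minimum error",
                 main = paste0(prefix, ": median convergence over seeds"))
  for (i in seq_along(algos))
    graphics::lines(seq_along(curves[[i]]), pmax(curves[[i]], ymin),
                    col = i, lwd = 2)
  graphics::legend("topright", legend = algos, col = seq_along(algos),
                   lwd = 2, bty = "n")
  grDevices::dev.off()
  paths <- c(paths, p1)

  # score box plots sorted ascending by median
  for (metric in c("final_score", "convergence_score")) {
    p <- file.path(dir, paste0(prefix, "_", metric, ".png"))
    grDevices::png(p, width = 900, height = 600)
    med <- tapply(scores[[metric]], scores$algorithm, stats::median)
    ord <- names(sort(med))
    graphics::boxplot(stats::reformulate("algorithm", metric),
                      data = transform(scores,
                                       algorithm = factor(algorithm, ord)),
                      range = 1.5, ylab = metric,
                      main = paste0(prefix, ": ", metric, " over seeds"))
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' First generation whose cumulative minimum reaches a floor
#'
#' @param run A `run_result`.
#' @param floor Error level to reach.
#' @return The 1-based generation index, or `NA` if never reached.
#' @export
generations_to_floor <- function(run, floor) {
  hit <- which(cumulative_min_curve(run) <= floor)
  if (length(hit)) hit[1] else NA_integer_
}

#' First evaluation whose running minimum reaches a floor
#'
#' @param run A `run_result` (must carry its full evaluation log).
#' @param floor Error level to reach.
#' @return The 1-based evaluation index, or `NA` if never reached.
#' @export
evaluations_to_floor <- function(run, floor) {
  if (is.null(run$totals))
    stop("run does not carry its evaluation log", call. = FALSE)
  hit <- which(cummin(run$totals) <= floor)
  if (length(hit)) hit[1] else NA_integer_
}
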