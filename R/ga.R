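# Genetic-algorithm descriptor selection scored by MLR cross-validation.
#
# Each individual is a fixed-size subset of the descriptor pool. Parents
# are drawn by rank-proportional roulette, recombined by single-point
# crossover on the sorted gene lists (repaired to keep genes distinct),
# and mutated per gene by swapping a member for a random non-member. The
# single best individual is carried over unchanged (elitism), which makes
# the best-so-far fitness non-decreasing by construction.

#' GA configuration
#'
#' Defaults mirror the production search settings (population 500,
#' 3000 generations, mutation rate 0.35, 3-descriptor models); tests and
#' examples use reduced settings.
#'
#' @param population_size number of individuals per generation (>= 2)
#' @param generations number of evolution cycles
#' @param mutation_rate per-gene replacement probability in `[0, 1]`
#' @param model_size number of descriptors per model
#' @param fitness `"q2_loo"` (default) or `"r2"`
#' @param seed integer seed; the whole run is deterministic given it
#' @return list of class `ga_config`
#' @export
ga_config <- function(population_size = 500, generations = 3000,
                      mutation_rate = 0.35, model_size = 3,
                      fitness = c("q2_loo", "r2"), seed = 1L) {
  fitness <- match.arg(fitness)
  stopifnot(population_size >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1, model_size >= 1)
  structure(list(population_size = population_size,
                 generations = generations,
                 mutation_rate = mutation_rate,
                 model_size = model_size,
                 fitness = fitness,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Fitness of a descriptor subset
#'
#' Fits an OLS model on the subset and returns the configured validation
#' statistic (leave-one-out Q2 by default, training R2 otherwise).
#' Rank-deficient subsets score `-Inf` during a GA run so they are selected
#' away rather than aborting the search.
#'
#' @param X descriptor matrix (or `descriptor_matrix`)
#' @param y response vector
#' @param subset descriptor names (or column indices)
#' @param kind `"q2_loo"` or `"r2"`
#' @return numeric fitness
#' @export
ga_fitness <- function(X, y, subset, kind = c("q2_loo", "r2")) {
  kind <- match.arg(kind)
  if (inherits(X, "descriptor_matrix")) X <- X$values
  Xs <- as.matrix(X)[, subset, drop = FALSE]
  if (kind == "q2_loo") {
    q2_loo(Xs, y)$q2
  } else {
    m <- fit_mlr(Xs, y)
    r_squared(as.numeric(y), m$fitted)
  }
}

.safe_fitness <- function(X, y, subset, kind, cache) {
  key <- paste(sort(subset), collapse = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- tryCatch(ga_fitness(X, y, subset, kind), error = function(e) -Inf)
  cache[[key]] <- val
  val
}

#' Run the genetic algorithm
#'
#' @param X descriptor matrix (columns = descriptor pool)
#' @param y response vector
#' @param config a [ga_config()]
#' @return object of class `ga_result`: `best_subset`, `best_fitness`,
#'   `trace` (per-generation best fitness, non-decreasing), `population`
#'   (final generation, list of subsets), `config`
#' @export
run_ga <- function(X, y, config = ga_config()) {
  if (inherits(X, "descriptor_matrix")) X <- X$values
  X <- as.matrix(X)
  pool <- colnames(X)
  if (is.null(pool)) pool <- as.character(seq_len(ncol(X)))
  colnames(X) <- pool
  p <- length(pool); m <- config$model_size
  if (p < m) stop("descriptor pool (", p, ") smaller than model size ", m)
  if (length(y) <= m + 2) stop("too few observations for model size ", m)
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("degenerate pool: constant descriptor column(s) present")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  cache <- new.env(parent = emptyenv())
  npop <- config$population_size
  pop <- replicate(npop, sort(sample(pool, m)), simplify = FALSE)
  fit <- vapply(pop, function(s) .safe_fitness(X, y, s, config$fitness, cache),
                numeric(1))
  best_i <- which.max(fit)
  best_subset <- pop[[best_i]]; best_fitness <- fit[best_i]
  trace <- numeric(config$generations)

  for (gen in seq_len(config$generations)) {
    # rank-proportional roulette selection
    rk <- rank(fit, ties.method = "first")
    prob <- rk / sum(rk)
    new_pop <- vector("list", npop)
    new_pop[[1]] <- best_subset        # elitist carry-over
    for (i in seq(2, npop)) {
      parents <- sample.int(npop, 2, prob = prob, replace = TRUE)
      a <- pop[[parents[1]]]; b <- pop[[parents[2]]]
      # single-point crossover on the sorted gene lists, repaired to keep
      # the child's genes distinct
      cut <- sample.int(m, 1)
      child <- unique(c(a[seq_len(cut)], b))[seq_len(m)]
      child <- child[!is.na(child)]
      while (length(child) < m) {
        child <- unique(c(child, sample(pool, m - length(child))))
      }
      # per-gene mutation: swap a member for a random non-member
      mut <- stats::runif(m) < config$mutation_rate
      if (any(mut)) {
        outside <- setdiff(pool, child)
        for (gidx in which(mut)) {
          if (!length(outside)) break
          pick <- sample(outside, 1)
          outside <- c(setdiff(outside, pick), child[gidx])
          child[gidx] <- pick
        }
      }
      new_pop[[i]] <- sort(child)
    }
    pop <- new_pop
    fit <- vapply(pop, function(s) .safe_fitness(X, y, s, config$fitness, cache),
                  numeric(1))
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fitness) {
      best_fitness <- fit[gen_best]
      best_subset <- pop[[gen_best]]
    }
    trace[gen] <- best_fitness
  }

  structure(list(best_subset = best_subset,
                 best_fitness = best_fitness,
                 trace = trace,
                 population = pop,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result: best {%s}, fitness %.4f (%s), %d generations>\n",
              paste(x$best_subset, collapse = ", "), x$best_fitness,
              x$config$fitness, x$config$generations))
  invisible(x)
}

#' Write a per-generation GA log
#'
#' @param result a `ga_result`
#' @param path output CSV path
#' @export
write_ga_log <- function(result, path) {
  utils::write.csv(
    data.frame(generation = seq_along(result$trace),
               best_fitness = result$trace),
    path, row.names = FALSE)
  invisible(path)
}
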