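#' Genetic-algorithm parameters
#'
#' Defaults: a population of 50 replicas (use 100 for the `min_edges`
#' fitness variant, which converges more slowly) and a halt after more than
#' 10 iterations without improvement of the best fitness.  The operators are
#' standard: single elite, tournament selection (size 2), uniform crossover
#' (rate 0.9) and independent per-bit mutation at rate 1/M for a PKN with M
#' edges.
#'
#' @param populationSize number of replicas (>= 2).
#' @param stagnationLimit halt after more than this many iterations without
#'   strict improvement of the best-ever fitness (>= 1).
#' @param mutationRate per-bit flip probability; `NULL` means 1/M.
#' @param crossoverRate probability that a child is produced by uniform
#'   crossover rather than cloning.
#' @param tournamentSize parents are the best of this many uniformly drawn
#'   replicas.
#' @param maxIterations safety bound on the number of iterations.
#' @param seed optional integer seed making the run reproducible.
#' @return a list of class `GAParams`.
#' @export
gaParams <- function(populationSize = 50L, stagnationLimit = 10L,
                     mutationRate = NULL, crossoverRate = 0.9,
                     tournamentSize = 2L, maxIterations = 1000L,
                     seed = NULL) {
  stopifnot(populationSize >= 2L, stagnationLimit >= 1L,
            tournamentSize >= 1L, crossoverRate >= 0, crossoverRate <= 1)
  structure(list(populationSize = as.integer(populationSize),
                 stagnationLimit = as.integer(stagnationLimit),
                 mutationRate = mutationRate,
                 crossoverRate = crossoverRate,
                 tournamentSize = as.integer(tournamentSize),
                 maxIterations = as.integer(maxIterations),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "GAParams")
}

#' @rdname GARun-class
setMethod("bestFitness", "GARun", function(x) x@bestFitness)

#' @rdname GARun-class
setMethod("bestNetwork", "GARun", function(x) x@bestNetwork)

#' @rdname GARun-class
setMethod("gaTrace", "GARun", function(x) x@trace)

setMethod("show", "GARun", function(object) {
  cat(sprintf("GARun: %d iteration(s), %d evaluation(s)\n",
              object@iterations, object@evaluations))
  show(object@bestFitness)
  invisible(NULL)
})

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  expr
}

.traceRow <- function(iteration, evaluations, f, medianFT) {
  data.frame(iteration = iteration, evaluations = evaluations, fT = f@fT,
             nEss = f@nEss, nNodes = f@nNodes, nEdges = f@nEdges,
             medianFT = medianFT)
}

#' Optimize a model network by genetic algorithm
#'
#' Searches the 2^M edge subsets of the PKN for the sub-network minimizing
#' the lexicographic fitness.  All replicas are initialized to the empty
#' network; each iteration keeps the best replica unchanged (elitism) and
#' fills the population with children obtained by tournament selection,
#' uniform crossover and per-bit mutation.  The run halts once the best-ever
#' fitness has not improved for more than `stagnationLimit` iterations.  The
#' same seed always yields an identical run.
#'
#' @inheritParams evaluateFitness
#' @param gparams a [gaParams()] list.
#' @return a [GARun-class]; the trace's best-fitness sequence is
#'   non-increasing by elitism.
#' @export
runGA <- function(pkn, ts, essentialNodes, gparams = gaParams(),
                  variant = "max_edges",
                  engine = c("exact", "stochastic"),
                  params = stochasticParams(),
                  maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  stopifnot(is(pkn, "BooleanNetwork"))
  M <- nEdges(pkn)
  if (!M) stop("the PKN has no edges; nothing to optimize")
  stopifnot(length(ts@ids) >= 1L)
  mu <- if (is.null(gparams$mutationRate)) 1 / M else gparams$mutationRate
  pop <- gparams$populationSize
  cache <- new.env(parent = emptyenv())
  evalG <- function(g) evaluateFitness(pkn, g, ts, essentialNodes, variant,
                                       engine, params, maxFreeNodes, cache)
  .withSeed(gparams$seed, {
    genomes <- lapply(seq_len(pop), function(i) rep(FALSE, M))
    fits <- lapply(genomes, evalG)
    keys <- vapply(fits, fitnessKey, numeric(length(fitnessKey(fits[[1]]))))
    bestIdxOf <- function(keys) {
      b <- 1L
      for (j in seq_len(ncol(keys))[-1])
        if (.compareKeys(keys[, j], keys[, b]) < 0L) b <- j
      b
    }
    evals <- pop
    b <- bestIdxOf(keys)
    bestGenome <- genomes[[b]]; bestFit <- fits[[b]]
    trace <- .traceRow(0L, evals, bestFit,
                       stats::median(vapply(fits, function(f) f@fT, numeric(1))))
    stagnation <- 0L
    iter <- 0L
    tournament <- function() {
      idx <- sample.int(pop, gparams$tournamentSize, replace = TRUE)
      idx[bestIdxOf(keys[, idx, drop = FALSE])]
    }
    while (stagnation <= gparams$stagnationLimit &&
           iter < gparams$maxIterations) {
      iter <- iter + 1L
      children <- vector("list", pop)
      children[[1L]] <- bestGenome        # elite
      for (j in 2:pop) {
        g1 <- genomes[[tournament()]]
        if (stats::runif(1) < gparams$crossoverRate) {
          g2 <- genomes[[tournament()]]
          mask <- stats::runif(M) < 0.5
          child <- ifelse(mask, g1, g2)
        } else child <- g1
        flip <- stats::runif(M) < mu
        child[flip] <- !child[flip]
        children[[j]] <- child
      }
      genomes <- children
      fits <- lapply(genomes, evalG)
      keys <- vapply(fits, fitnessKey, numeric(length(fitnessKey(fits[[1]]))))
      evals <- evals + (pop - 1L)
      b <- bestIdxOf(keys)
      if (.compareKeys(keys[, b], fitnessKey(bestFit)) < 0L) {
        bestGenome <- genomes[[b]]; bestFit <- fits[[b]]
        stagnation <- 0L
      } else stagnation <- stagnation + 1L
      trace <- rbind(trace, .traceRow(
        iter, evals, bestFit,
        stats::median(vapply(fits, function(f) f@fT, numeric(1)))))
    }
    new("GARun", bestGenome = bestGenome, bestFitness = bestFit,
        bestNetwork = subnetwork(pkn, bestGenome), trace = trace,
        iterations = iter, evaluations = as.integer(evals),
        seed = if (is.null(gparams$seed)) NA_integer_ else gparams$seed)
  })
}

#' Multiple independent optimization runs
#'
#' Performs `nRuns` independent seeded runs (seeds derived deterministically
#' from `masterSeed`) and returns the `keepBest` results sorted from best to
#' worst fitness.
#'
#' @inheritParams runGA
#' @param nRuns number of independent runs.
#' @param keepBest how many of the best runs to return (`<= nRuns`).
#' @param masterSeed integer seed from which per-run seeds are derived.
#' @return list of [GARun-class], best first.
#' @export
runMany <- function(pkn, ts, essentialNodes, gparams = gaParams(),
                    nRuns = 500L, keepBest = 50L, masterSeed = 1L,
                    variant = "max_edges",
                    engine = c("exact", "stochastic"),
                    params = stochasticParams(),
                    maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  stopifnot(keepBest <= nRuns, keepBest >= 1L)
  seeds <- .withSeed(as.integer(masterSeed),
                     sample.int(.Machine$integer.max - 1L, nRuns))
  runs <- lapply(seeds, function(s) {
    gp <- gparams; gp$seed <- s
    runGA(pkn, ts, essentialNodes, gp, variant, engine, params, maxFreeNodes)
  })
  keys <- vapply(runs, function(r) fitnessKey(r@bestFitness),
                 numeric(length(fitnessKey(runs[[1]]@bestFitness))))
  ord <- do.call(order, lapply(seq_len(nrow(keys)), function(i) keys[i, ]))
  runs[ord][seq_len(keepBest)]
}

#' Random-search baseline with a matched evaluation budget
#'
#' Evaluates `nEvaluations` independent random sub-networks of the PKN (each
#' edge kept with probability 0.5) and tracks the best fitness seen so far,
#' producing a trace comparable to a GA run with the same number of network
#' evaluations.
#'
#' @inheritParams runGA
#' @param nEvaluations number of random networks to draw (>= 1).
#' @param seed integer seed.
#' @param keepProb per-edge keep probability (0.5, matching the
#'   random-sub-network baseline of the benchmarking workflow).
#' @return a [GARun-class] whose trace has one row per evaluation.
#' @export
randomSearchBaseline <- function(pkn, ts, essentialNodes, nEvaluations,
                                 seed = NULL, keepProb = 0.5,
                                 variant = "max_edges",
                                 engine = c("exact", "stochastic"),
                                 params = stochasticParams(),
                                 maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  stopifnot(nEvaluations >= 1L)
  M <- nEdges(pkn)
  if (!M) stop("the PKN has no edges")
  cache <- new.env(parent = emptyenv())
  .withSeed(seed, {
    bestGenome <- NULL; bestFit <- NULL
    trace <- NULL
    for (e in seq_len(nEvaluations)) {
      g <- stats::runif(M) < keepProb
      f <- evaluateFitness(pkn, g, ts, essentialNodes, variant, engine,
                           params, maxFreeNodes, cache)
      if (is.null(bestFit) ||
          .compareKeys(fitnessKey(f), fitnessKey(bestFit)) < 0L) {
        bestFit <- f; bestGenome <- g
      }
      trace <- rbind(trace, .traceRow(e, e, bestFit, bestFit@fT))
    }
    new("GARun", bestGenome = bestGenome, bestFitness = bestFit,
        bestNetwork = subnetwork(pkn, bestGenome), trace = trace,
        iterations = as.integer(nEvaluations),
        evaluations = as.integer(nEvaluations),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}
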