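#' Construct a fitness value
#'
#' @param fT training distance in \[0,1\].
#' @param nEss,nNodes,nEdges network counts.
#' @param variant `"max_edges"` (default) or `"min_edges"`.
#' @return a [Fitness-class].
#' @export
fitness <- function(fT, nEss, nNodes, nEdges, variant = "max_edges") {
  new("Fitness", fT = as.numeric(fT), nEss = as.integer(nEss),
      nNodes = as.integer(nNodes), nEdges = as.integer(nEdges),
      variant = variant)
}

#' @rdname Fitness-class
#' @details `fitnessKey` returns the numeric comparison key:
#'   `(fT, -nEss, nNodes, -nEdges)` for the `max_edges` variant and
#'   `(fT, -nEss, nEdges)` for `min_edges`; smaller keys (lexicographically)
#'   are better.
setMethod("fitnessKey", "Fitness", function(x) {
  if (x@variant == "max_edges") c(x@fT, -x@nEss, x@nNodes, -x@nEdges)
  else c(x@fT, -x@nEss, x@nEdges)
})

setMethod("show", "Fitness", function(object) {
  cat(sprintf("Fitness [%s]: fT = %.6g, nEss = %d, nNodes = %d, nEdges = %d\n",
              object@variant, object@fT, object@nEss, object@nNodes,
              object@nEdges))
  invisible(NULL)
})

## lexicographic comparison of numeric keys: -1 if a better (smaller), 0, +1
.compareKeys <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  if (!length(nz)) 0L else if (d[nz[1]] < 0) -1L else 1L
}

#' Compare two fitness values
#'
#' Strict lexicographic comparison of the variant's key; fitness values form
#' a total order.  `fT` dominates, then essential-node count (more is
#' better), then node count (fewer is better), then edge count (more is
#' better under `max_edges`, fewer under `min_edges`, where node count is not
#' constrained).
#'
#' @param a,b [Fitness-class] objects with the same variant.
#' @return `"better"` if `a` is better than `b`, `"equal"`, or `"worse"`.
#' @export
compareFitness <- function(a, b) {
  stopifnot(is(a, "Fitness"), is(b, "Fitness"))
  if (a@variant != b@variant)
    stop("cannot compare fitness values of different variants: ",
         a@variant, " vs ", b@variant)
  switch(as.character(.compareKeys(fitnessKey(a), fitnessKey(b))),
         "-1" = "better", "0" = "equal", "1" = "worse")
}

## cache key for a genome (logical edge-subset vector)
.genomeKey <- function(genome) rawToChar(as.raw(48L + as.integer(genome)))

#' Fitness of a PKN edge subset
#'
#' Decodes the genome into a sub-network of the PKN (isolated nodes
#' dropped), computes `f_T` against the training set, and counts essential
#' nodes present, nodes and edges.  With a `cache` environment, identical
#' genomes are never re-simulated.
#'
#' @inheritParams computeFT
#' @param pkn the prior knowledge network ([BooleanNetwork-class]).
#' @param genome logical vector over `edges(pkn)` rows (TRUE = edge kept).
#' @param essentialNodes character vector of essential node names.
#' @param variant `"max_edges"` or `"min_edges"`.
#' @param cache optional environment used as fitness cache.
#' @return a [Fitness-class].
#' @export
evaluateFitness <- function(pkn, genome, ts, essentialNodes,
                            variant = "max_edges",
                            engine = c("exact", "stochastic"),
                            params = stochasticParams(),
                            maxFreeNodes = .MAX_FREE_NODES,
                            cache = NULL) {
  engine <- match.arg(engine)
  key <- .genomeKey(genome)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  net <- subnetwork(pkn, genome)
  fT <- computeFT(net, ts, engine = engine, params = params,
                  maxFreeNodes = maxFreeNodes)$fT
  f <- fitness(fT, sum(essentialNodes %in% net@nodes), nNodes(net),
               nEdges(net), variant)
  if (!is.null(cache)) cache[[key]] <- f
  f
}
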