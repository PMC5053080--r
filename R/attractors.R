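#' Parameters of the stochastic attractor search
#'
#' The stochastic engine explores the asynchronous state transition graph by
#' repeated random walks: each restart walks up to `walkLength` uniformly
#' chosen asynchronous updates, then computes the bounded forward closure of
#' the final state; if the closure completes within `closureCap` states, its
#' terminal strongly connected components are certified attractors of the
#' full transition graph.  Restart start states are drawn from the not yet
#' visited part of the state space (or from a supplied start set), so no
#' false positive is ever returned and every attractor is found with
#' probability approaching 1 as `restarts` grows.
#'
#' @param restarts number of restarts per search (default 50).
#' @param walkLength maximum number of walk steps per restart (default 1000).
#' @param closureCap maximum number of states explored when verifying a
#'   candidate (default 5000); a candidate whose closure exceeds the cap is
#'   discarded with a warning.
#' @param seed optional integer seed; `NULL` uses (and advances) the caller's
#'   RNG state.
#' @return a list of class `StochasticParams`.
#' @export
stochasticParams <- function(restarts = 50L, walkLength = 1000L,
                             closureCap = 5000L, seed = NULL) {
  stopifnot(restarts >= 1L, walkLength >= 0L, closureCap >= 1L)
  structure(list(restarts = as.integer(restarts),
                 walkLength = as.integer(walkLength),
                 closureCap = as.integer(closureCap),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "StochasticParams")
}

.MAX_FREE_NODES <- 25L  # default cap on non-clamped nodes for the exact engine

.avgFromCodes <- function(n, codes) {
  if (!n) return(numeric(0))
  vapply(seq_len(n), function(i)
    mean(bitwAnd(bitwShiftR(codes, i - 1L), 1L)), numeric(1))
}

.newAttractor <- function(network, codes, p) {
  ss <- .stateString(network, codes)
  o <- order(ss)
  codes <- as.integer(codes[o]); ss <- ss[o]
  avg <- stats::setNames(.avgFromCodes(length(network@nodes), codes),
                         network@nodes)
  new("Attractor", nodes = network@nodes, states = codes, avgState = avg,
      perturbation = p, key = paste(ss, collapse = "|"))
}

#' @rdname Attractor-class
setMethod("states", "Attractor", function(x) x@states)

#' @rdname Attractor-class
setMethod("stateStrings", "Attractor", function(x)
  vapply(x@states, function(s)
    paste(bitwAnd(bitwShiftR(s, seq_along(x@nodes) - 1L), 1L), collapse = ""),
    character(1)))

#' @rdname Attractor-class
setMethod("avgState", "Attractor", function(x) x@avgState)

#' @rdname Attractor-class
setMethod("attractorKey", "Attractor", function(x) x@key)

#' @rdname Attractor-class
#' @param a an [Attractor-class].
#' @return `attractorPerturbation`: the perturbation the attractor was
#'   computed under.
#' @export
attractorPerturbation <- function(a) a@perturbation

#' @rdname Attractor-class
setMethod("nodes", "Attractor", function(x) x@nodes)

setMethod("show", "Attractor", function(object) {
  kind <- if (length(object@states) == 1L) "steady state" else
    sprintf("cyclic attractor (%d states)", length(object@states))
  cat(sprintf("Attractor [%s], perturbation '%s'\n", kind,
              perturbationKey(object@perturbation)))
  up <- names(object@avgState)[object@avgState > 0]
  cat("  active: ", if (length(up)) paste(sprintf("%s=%.3g", up,
      object@avgState[up]), collapse = " ") else "(none)", "\n", sep = "")
  invisible(NULL)
})

## shared argument preparation for the engines
.prepEngine <- function(network, p, checkNodes = TRUE) {
  stopifnot(is(network, "BooleanNetwork"))
  if (checkNodes) .checkPerturbationNodes(network, p)
  .compileDynamics(network, p)
}

#' Find the attractors of a perturbed asynchronous Boolean network
#'
#' Attractors are the terminal strongly connected components of the
#' asynchronous state transition graph under the perturbation; a single-state
#' attractor is a steady state.  The exact engine enumerates the full state
#' space (2^f states for f non-clamped nodes) and is guaranteed complete; the
#' stochastic engine (see [stochasticParams()]) scales to larger networks,
#' never returns a false positive, but may miss attractors.
#'
#' @param network a [BooleanNetwork-class].
#' @param p a [perturbation()] (default: unperturbed).
#' @param engine `"exact"` or `"stochastic"`.
#' @param params a [stochasticParams()] list (stochastic engine only).
#' @param initialStates optional set of start states for the stochastic
#'   engine: an [Attractor-class], a list of named 0/1 vectors, or a vector
#'   of integer state codes.
#' @param maxFreeNodes refusal cap on the number of non-clamped nodes for the
#'   exact engine (default 25).
#' @return list of [Attractor-class] objects in deterministic canonical order
#'   (sorted by smallest member state).
#' @examples
#' osc <- booleanNetwork(data.frame(from = "A", to = "A", sign = -1L))
#' findAttractors(osc)  # one cyclic attractor {0, 1}, average state 0.5
#' @export
findAttractors <- function(network, p = perturbation(),
                           engine = c("exact", "stochastic"),
                           params = stochasticParams(),
                           initialStates = NULL,
                           maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  dyn <- .prepEngine(network, p)
  if (engine == "exact") {
    if (length(dyn$freeIdx0) > maxFreeNodes)
      stop(sprintf(paste0("state-space cap exceeded: %d non-clamped nodes, ",
                          "exact engine cap is %d (see 'maxFreeNodes')"),
                   length(dyn$freeIdx0), maxFreeNodes))
    sets <- .cpp_exact_attractors(dyn$n, dyn$act, dyn$inh, dyn$regType,
                                  dyn$freeIdx0, dyn$forcedState)
    lapply(sets, .newAttractor, network = network, p = dyn$perturbation)
  } else {
    .stochasticSearch(network, dyn, params, initialStates)
  }
}

.resolveStartCodes <- function(network, dyn, initialStates) {
  if (is.null(initialStates)) return(NULL)
  codes <- if (is(initialStates, "Attractor")) initialStates@states
  else if (is.list(initialStates))
    vapply(initialStates, .encodeState, integer(1), network = network)
  else as.integer(initialStates)
  if (!length(codes)) stop("empty set of start states")
  ## overwrite clamped bits
  freeMask <- sum(2^dyn$freeIdx0)
  as.integer(bitwAnd(codes, as.integer(freeMask)) + dyn$forcedState)
}

## Stochastic search: random restarts (walk + bounded closure verification).
## A visited-state bitmap steers restarts towards unexplored regions when the
## free state space is small enough to track (<= 2^22 states).
.stochasticSearch <- function(network, dyn, params, initialStates = NULL) {
  if (!is.null(params$seed)) {
    old <- globalenv()$.Random.seed
    set.seed(params$seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  f <- length(dyn$freeIdx0)
  starts <- .resolveStartCodes(network, dyn, initialStates)
  track <- is.null(starts) && f <= 22L
  visited <- if (track) logical(2^f) else NULL
  freeFromFull <- function(code) {
    bits <- bitwAnd(bitwShiftR(code, dyn$freeIdx0), 1L)
    as.integer(sum(bits * 2^(seq_len(f) - 1L)))
  }
  fullFromFree <- function(j) {
    bits <- bitwAnd(bitwShiftR(j, seq_len(f) - 1L), 1L)
    as.integer(sum(bits * 2^dyn$freeIdx0) + dyn$forcedState)
  }
  found <- list()
  for (r in seq_len(params$restarts)) {
    if (!is.null(starts)) {
      ## cycle through the supplied start set first, then resample from it
      s0 <- if (r <= length(starts)) starts[r]
      else starts[sample.int(length(starts), 1L)]
    } else if (track) {
      unvis <- which(!visited)
      if (!length(unvis)) break
      s0 <- fullFromFree(unvis[sample.int(length(unvis), 1L)] - 1L)
    } else {
      s0 <- fullFromFree(as.integer(floor(stats::runif(1) * 2^f)))
    }
    ## bounded closure from the start state certifies every attractor in its
    ## forward cone; if the cone overflows the cap, walk towards an attractor
    ## first so the closure to verify is small
    path <- integer(0)
    res <- .cpp_closure_attractors(dyn$n, dyn$act, dyn$inh, dyn$regType,
                                   dyn$freeIdx0, dyn$forcedState, s0,
                                   params$closureCap)
    if (!res$complete) {
      path <- .cpp_walk(dyn$n, dyn$act, dyn$inh, dyn$regType, dyn$freeIdx0,
                        dyn$forcedState, s0, params$walkLength)
      res <- .cpp_closure_attractors(dyn$n, dyn$act, dyn$inh, dyn$regType,
                                     dyn$freeIdx0, dyn$forcedState,
                                     path[length(path)], params$closureCap)
    }
    if (track) {
      seen <- vapply(c(path, res$visited), freeFromFull, integer(1))
      visited[seen + 1L] <- TRUE
    }
    if (!res$complete) {
      warning("closure cap exceeded during attractor verification; ",
              "candidate discarded (restart ", r, ")")
      next
    }
    for (codes in res$attractors) {
      a <- .newAttractor(network, codes, dyn$perturbation)
      if (is.null(found[[a@key]])) found[[a@key]] <- a
    }
  }
  ## canonical order: by smallest member state string
  found <- found[order(vapply(found, function(a) a@key, character(1)))]
  unname(found)
}

#' Attractors reachable from a set of states
#'
#' Applies the target perturbation to the given start states (overwriting the
#' clamped nodes), explores the asynchronous state transition graph under
#' that perturbation, and returns the attractors whose states intersect the
#' forward-reachable set.  Every start state reaches at least one returned
#' attractor.
#'
#' @inheritParams findAttractors
#' @param fromStates an [Attractor-class], a list of named 0/1 state vectors,
#'   or a vector of integer state codes.
#' @return list of [Attractor-class] objects (canonical order).
#' @export
reachableAttractors <- function(network, fromStates, p = perturbation(),
                                engine = c("exact", "stochastic"),
                                params = stochasticParams(),
                                maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  dyn <- .prepEngine(network, p)
  starts <- .resolveStartCodes(network, dyn, fromStates)
  if (is.null(starts)) stop("empty set of start states")
  if (engine == "exact") {
    if (length(dyn$freeIdx0) > maxFreeNodes)
      stop(sprintf("state-space cap exceeded: %d non-clamped nodes (cap %d)",
                   length(dyn$freeIdx0), maxFreeNodes))
    reach <- .cpp_reachable_states(dyn$n, dyn$act, dyn$inh, dyn$regType,
                                   dyn$freeIdx0, dyn$forcedState, starts)
    atts <- findAttractors(network, p, engine = "exact",
                           maxFreeNodes = maxFreeNodes)
    atts[vapply(atts, function(a) any(a@states %in% reach), logical(1))]
  } else {
    .stochasticSearch(network, dyn, params, initialStates = starts)
  }
}

#' Build an attractor reachability graph
#'
#' Computes attractors once per distinct perturbation appearing in the
#' requested transitions, then adds an edge from each attractor A1 under P1
#' to every attractor of P2 reachable from A1's states (clamped values of P2
#' overwritten) for each transition P1 -> P2.
#'
#' @inheritParams findAttractors
#' @param transitions list of length-2 lists/vectors of perturbations
#'   `(P1, P2)`; `P1` may equal `P2`.
#' @return a [ReachabilityGraph-class].
#' @export
buildReachabilityGraph <- function(network, transitions,
                                   engine = c("exact", "stochastic"),
                                   params = stochasticParams(),
                                   maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  perts <- list()
  for (tr in transitions) {
    stopifnot(length(tr) == 2L)
    for (p in tr) perts[[perturbationKey(p)]] <- p
  }
  sets <- lapply(perts, function(p)
    findAttractors(network, p, engine = engine, params = params,
                   maxFreeNodes = maxFreeNodes))
  edges <- data.frame(fromPert = character(), fromKey = character(),
                      toPert = character(), toKey = character(),
                      stringsAsFactors = FALSE)
  done <- character()
  for (tr in transitions) {
    k1 <- perturbationKey(tr[[1]]); k2 <- perturbationKey(tr[[2]])
    id <- paste(k1, k2, sep = " => ")
    if (id %in% done) next
    done <- c(done, id)
    for (a1 in sets[[k1]]) {
      reached <- reachableAttractors(network, a1, perts[[k2]],
                                     engine = engine, params = params,
                                     maxFreeNodes = maxFreeNodes)
      for (a2 in reached)
        edges[nrow(edges) + 1L, ] <- c(k1, a1@key, k2, a2@key)
    }
  }
  new("ReachabilityGraph", attractorSets = sets, perturbations = perts,
      edges = edges)
}

#' @rdname ReachabilityGraph-class
#' @param x an object.
setMethod("edges", "ReachabilityGraph", function(x) x@edges)

setMethod("show", "ReachabilityGraph", function(object) {
  cat(sprintf("ReachabilityGraph: %d perturbation(s), %d attractor(s), %d edge(s)\n",
              length(object@attractorSets),
              sum(lengths(object@attractorSets)), nrow(object@edges)))
  invisible(NULL)
})

#' Attractor report and DOT export
#'
#' `attractorReport` summarizes an attractor search as a plain list (ready
#' for JSON serialization): the perturbation, the engine used and, per
#' attractor, its size, member states as bit-strings in node order, and the
#' per-node average state.  `writeAttractorReport` writes it as JSON;
#' `reachabilityGraphDOT` renders a [ReachabilityGraph-class] in DOT format.
#'
#' @inheritParams findAttractors
#' @return `attractorReport`: a list; `reachabilityGraphDOT`: a character
#'   vector of DOT lines.
#' @export
attractorReport <- function(network, p = perturbation(),
                            engine = c("exact", "stochastic"),
                            params = stochasticParams(),
                            maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  atts <- findAttractors(network, p, engine = engine, params = params,
                         maxFreeNodes = maxFreeNodes)
  list(nodes = as.list(network@nodes),
       perturbation = as.list(p),
       engine = engine,
       attractors = lapply(atts, function(a)
         list(size = length(a@states),
              states = as.list(stateStrings(a)),
              avgState = as.list(a@avgState))))
}

#' @rdname attractorReport
#' @param report a list from `attractorReport`.
#' @param path output file path.
#' @export
writeAttractorReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname attractorReport
#' @param rg a [ReachabilityGraph-class].
#' @export
reachabilityGraphDOT <- function(rg) {
  stopifnot(is(rg, "ReachabilityGraph"))
  nodeId <- function(pert, key) sprintf("\"%s | %s\"", pert, key)
  lines <- c("digraph reachability {")
  for (k in names(rg@attractorSets))
    for (a in rg@attractorSets[[k]])
      lines <- c(lines, sprintf("  %s;", nodeId(k, a@key)))
  e <- rg@edges
  for (i in seq_len(nrow(e)))
    lines <- c(lines, sprintf("  %s -> %s [label=\"%s => %s\"];",
                              nodeId(e$fromPert[i], e$fromKey[i]),
                              nodeId(e$toPert[i], e$toKey[i]),
                              e$fromPert[i], e$toPert[i]))
  c(lines, "}")
}
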