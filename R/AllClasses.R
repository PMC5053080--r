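#' @import methods
NULL

.NODE_NAME_RE <- "^[A-Za-z0-9_]+$"

#' Signed Boolean regulatory network
#'
#' A signed directed graph with asynchronous Boolean update semantics.
#' Nodes are genes/proteins whose state is a Boolean variable; edges are
#' activating (`sign = +1`) or inhibiting (`sign = -1`) regulations.  Node
#' order is lexicographic so that state vectors and their serializations are
#' reproducible across sessions.
#'
#' @slot nodes character vector of node names, sorted lexicographically.
#' @slot edges data.frame with columns `from`, `to` (node names) and `sign`
#'   (+1 activating, -1 inhibiting); (from, to, sign) triples are unique.
#'   Both signs may coexist between the same ordered pair, and self-edges are
#'   allowed.
#' @exportClass BooleanNetwork
setClass("BooleanNetwork",
  representation(nodes = "character", edges = "data.frame"))

setValidity("BooleanNetwork", function(object) {
  msg <- character()
  nd <- object@nodes
  if (anyDuplicated(nd)) msg <- c(msg, "duplicated node names")
  if (length(nd) && !all(grepl(.NODE_NAME_RE, nd)))
    msg <- c(msg, "node names must match [A-Za-z0-9_]+")
  if (is.unsorted(nd)) msg <- c(msg, "nodes must be sorted lexicographically")
  e <- object@edges
  if (!identical(names(e), c("from", "to", "sign")))
    msg <- c(msg, "edges must have columns from, to, sign")
  else {
    if (!all(e$from %in% nd) || !all(e$to %in% nd))
      msg <- c(msg, "edge endpoints must be network nodes")
    if (!all(e$sign %in% c(1L, -1L)))
      msg <- c(msg, "edge sign must be +1 or -1")
    if (anyDuplicated(paste(e$from, e$to, e$sign)))
      msg <- c(msg, "duplicated (from, to, sign) triples")
  }
  if (length(msg)) msg else TRUE
})

#' Attractor of a perturbed asynchronous Boolean network
#'
#' A terminal strongly connected component of the asynchronous state
#' transition graph under a perturbation: a steady state (one state) or a
#' cyclic attractor.  `avgState` holds, per node, the mean of its Boolean
#' value over the attractor's states; for a steady state it is 0/1-valued.
#'
#' @slot nodes node names of the network the attractor belongs to.
#' @slot states integer codes of the member states (bit i-1 of a code is the
#'   value of node i), sorted canonically.
#' @slot avgState named numeric in \[0,1\], one entry per node.
#' @slot perturbation named integer vector of clamped nodes (1 =
#'   over-expression, 0 = knock-out); empty when unperturbed.
#' @slot key canonical identifier: the sorted member-state bit-strings joined
#'   by "|"; stable across runs and engines.
#' @exportClass Attractor
setClass("Attractor",
  representation(nodes = "character", states = "integer",
                 avgState = "numeric", perturbation = "integer",
                 key = "character"))

setValidity("Attractor", function(object) {
  msg <- character()
  if (length(object@states) < 1L) msg <- c(msg, "attractor must contain >= 1 state")
  if (!identical(names(object@avgState), object@nodes))
    msg <- c(msg, "avgState must be named by the network nodes")
  if (length(object@avgState) &&
      (any(object@avgState < 0) || any(object@avgState > 1)))
    msg <- c(msg, "avgState components must lie in [0,1]")
  p <- object@perturbation
  if (length(p) && (is.null(names(p)) || anyDuplicated(names(p)) ||
                    !all(p %in% c(0L, 1L))))
    msg <- c(msg, "perturbation must map distinct node names to 0/1")
  if (length(msg)) msg else TRUE
})

#' Attractor reachability graph
#'
#' Nodes are attractors computed under the distinct perturbations involved in
#' a set of requested transitions; a directed edge links an attractor A1
#' (under P1) to an attractor A2 (under P2) when, for a requested transition
#' P1 -> P2, some state of A1 (with P2's clamped values overwritten) reaches
#' some state of A2 in the asynchronous state transition graph under P2.
#'
#' @slot attractorSets named list (by perturbation key) of lists of
#'   [Attractor] objects.
#' @slot perturbations named list (by perturbation key) of perturbation
#'   vectors.
#' @slot edges data.frame: `fromPert`, `fromKey`, `toPert`, `toKey`.
#' @exportClass ReachabilityGraph
setClass("ReachabilityGraph",
  representation(attractorSets = "list", perturbations = "list",
                 edges = "data.frame"))

#' Training set graph
#'
#' Experimental constraints as a graph: each node is a (perturbation,
#' observation) pair -- a stable phenotype observed at equilibrium under the
#' perturbation -- and an edge from node 1 to node 2 means the first
#' phenotype evolves into the second upon applying the second node's
#' perturbation.  P1 = P2 and O1 = O2 are allowed, as are self-edges.
#'
#' @slot ids character vector of unique node identifiers.
#' @slot perturbations list of named integer vectors (parallel to `ids`).
#' @slot observations list of non-empty named integer vectors with values in
#'   \{0, 1\} (parallel to `ids`).
#' @slot edges data.frame with character columns `from`, `to` (node ids).
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(ids = "character", perturbations = "list",
                 observations = "list", edges = "data.frame"))

setValidity("TrainingSet", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicated training node ids")
  if (length(object@perturbations) != n || length(object@observations) != n)
    msg <- c(msg, "perturbations/observations must parallel ids")
  for (i in seq_len(n)) {
    o <- object@observations[[i]]
    if (!length(o) || is.null(names(o)) || !all(o %in% c(0L, 1L))) {
      msg <- c(msg, sprintf(
        "observation of node '%s' must be a non-empty map to {0,1}",
        object@ids[i]))
      break
    }
    p <- object@perturbations[[i]]
    if (length(p) && (is.null(names(p)) || anyDuplicated(names(p)) ||
                      !all(p %in% c(0L, 1L)))) {
      msg <- c(msg, sprintf("invalid perturbation for node '%s'", object@ids[i]))
      break
    }
  }
  e <- object@edges
  if (!identical(names(e), c("from", "to")))
    msg <- c(msg, "edges must have columns from, to")
  else if (nrow(e) && !all(c(e$from, e$to) %in% object@ids))
    msg <- c(msg, "training edge endpoints must be training node ids")
  if (length(msg)) msg else TRUE
})

#' Lexicographic multi-objective fitness
#'
#' The fitness of a candidate model network is the tuple
#' `(f_T, -N_ess, N_nodes, -N_edges)` (variant `"max_edges"`, the default:
#' reproduce the training set, then include essential nodes, then minimize
#' nodes, then maximize edges) or `(f_T, -N_ess, N_edges)` (variant
#' `"min_edges"`).  Tuples are compared lexicographically; a smaller key is a
#' better fitness.
#'
#' @slot fT training distance in \[0,1\] (0 = training set perfectly
#'   reproduced).
#' @slot nEss number of essential nodes present in the network.
#' @slot nNodes,nEdges network size counts.
#' @slot variant `"max_edges"` or `"min_edges"`.
#' @exportClass Fitness
setClass("Fitness",
  representation(fT = "numeric", nEss = "integer", nNodes = "integer",
                 nEdges = "integer", variant = "character"))

setValidity("Fitness", function(object) {
  msg <- character()
  if (length(object@fT) != 1L || is.na(object@fT) ||
      object@fT < 0 || object@fT > 1)
    msg <- c(msg, "fT must be a single value in [0,1]")
  if (object@nEss < 0L || object@nNodes < 0L || object@nEdges < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (!object@variant %in% c("max_edges", "min_edges"))
    msg <- c(msg, "variant must be 'max_edges' or 'min_edges'")
  if (length(msg)) msg else TRUE
})

#' Result of one genetic-algorithm optimization run
#'
#' @slot bestGenome logical vector over the PKN's edges (TRUE = edge kept)
#'   encoding the best network found during the run.
#' @slot bestFitness the corresponding [Fitness].
#' @slot bestNetwork the decoded [BooleanNetwork].
#' @slot trace per-iteration data.frame: `iteration`, cumulative
#'   `evaluations`, best-ever fitness components and population median `fT`.
#' @slot iterations,evaluations totals for the run.
#' @slot seed RNG seed used (NA if the caller's RNG state was used).
#' @exportClass GARun
setClass("GARun",
  representation(bestGenome = "logical", bestFitness = "Fitness",
                 bestNetwork = "BooleanNetwork", trace = "data.frame",
                 iterations = "integer", evaluations = "integer",
                 seed = "integer"))
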