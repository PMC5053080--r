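## Asynchronous Boolean update semantics.
##
## The per-node update rule is sign-based: a node with at least one activating
## in-edge takes value 1 iff some activator is active and no inhibitor is
## active; a node with only inhibiting in-edges takes value 1 iff no inhibitor
## is active; a node without regulators holds its current value (so
## unstimulated input nodes are stable).  Clamped (perturbed) nodes never
## change.  One transition updates exactly one node.

.MAX_NODES <- 30L  # integer state codes: bit i-1 of a code = value of node i

## Compile a network + perturbation into the mask representation used by the
## C++ engine: per-node activator/inhibitor bit masks, regulator type, free
## (non-clamped) node indices and the clamped base state.
.compileDynamics <- function(network, p = perturbation()) {
  nd <- network@nodes
  n <- length(nd)
  if (n > .MAX_NODES)
    stop(sprintf("network has %d nodes; the explicit-state engine supports at most %d",
                 n, .MAX_NODES))
  act <- inh <- integer(n)
  e <- network@edges
  if (nrow(e)) {
    fromBit <- bitwShiftL(1L, match(e$from, nd) - 1L)
    toIdx <- match(e$to, nd)
    for (k in seq_len(nrow(e))) {
      if (e$sign[k] == 1L) act[toIdx[k]] <- bitwOr(act[toIdx[k]], fromBit[k])
      else inh[toIdx[k]] <- bitwOr(inh[toIdx[k]], fromBit[k])
    }
  }
  regType <- ifelse(act != 0L, 1L, ifelse(inh != 0L, 2L, 0L))
  p <- p[names(p) %in% nd]
  forcedIdx <- match(names(p), nd)
  freeIdx <- setdiff(seq_len(n), forcedIdx)
  forcedState <- 0L
  if (length(p))
    forcedState <- as.integer(sum(2^(forcedIdx - 1L) * as.numeric(p)))
  list(n = n, nodes = nd, act = act, inh = inh, regType = as.integer(regType),
       freeIdx0 = as.integer(freeIdx - 1L), forcedState = forcedState,
       perturbation = p)
}

## ---- state coding ----------------------------------------------------------

.encodeState <- function(network, state) {
  nd <- network@nodes
  if (is.null(names(state)) || !all(nd %in% names(state)))
    stop("state must be a named 0/1 vector covering all network nodes")
  v <- as.integer(state[nd])
  if (!all(v %in% c(0L, 1L))) stop("state values must be 0 or 1")
  as.integer(sum(2^(seq_along(nd) - 1L) * v))
}

.decodeState <- function(network, code) {
  nd <- network@nodes
  stats::setNames(as.integer(bitwAnd(bitwShiftR(as.integer(code),
                                                seq_along(nd) - 1L), 1L)), nd)
}

.stateString <- function(network, code) {
  vapply(code, function(s)
    paste(bitwAnd(bitwShiftR(as.integer(s), seq_along(network@nodes) - 1L), 1L),
          collapse = ""), character(1))
}

## ---- elementary update operations ------------------------------------------

#' Asynchronous update target of one node
#'
#' The value node `node` would take if updated in `state` under
#' `perturbation`: its forced value if clamped; otherwise 1 iff some active
#' activator and no active inhibitor (when it has activating in-edges), 1 iff
#' no active inhibitor (when it has only inhibiting in-edges), or its current
#' value (no regulators).
#'
#' @param network a [BooleanNetwork-class].
#' @param state named 0/1 vector over all network nodes.
#' @param node a node name.
#' @param p a [perturbation()].
#' @return 0 or 1.
#' @export
targetValue <- function(network, state, node, p = perturbation()) {
  stopifnot(is(network, "BooleanNetwork"))
  if (!node %in% network@nodes) stop("unknown node: ", node)
  .checkPerturbationNodes(network, p)
  if (node %in% names(p)) return(as.integer(p[[node]]))
  e <- network@edges[network@edges$to == node, , drop = FALSE]
  if (!nrow(e)) return(as.integer(state[[node]]))
  active <- vapply(e$from, function(s) as.integer(state[[s]]) == 1L, logical(1))
  anyAct <- any(e$sign == 1L & active)
  anyInh <- any(e$sign == -1L & active)
  if (any(e$sign == 1L)) as.integer(anyAct && !anyInh)
  else as.integer(!anyInh)
}

#' Asynchronous successor states
#'
#' One successor per non-clamped node whose update target differs from its
#' current value; each successor equals `state` with exactly that node
#' flipped.  An empty result means `state` is a steady state under the
#' perturbation.
#'
#' @inheritParams targetValue
#' @return list of named 0/1 state vectors.
#' @export
asyncSuccessors <- function(network, state, p = perturbation()) {
  stopifnot(is(network, "BooleanNetwork"))
  .checkPerturbationNodes(network, p)
  forced <- names(p)
  bad <- forced[as.integer(state[forced]) != as.integer(p)]
  if (length(bad))
    stop("state inconsistent with perturbation at node(s): ",
         paste(bad, collapse = ", "))
  out <- list()
  for (node in setdiff(network@nodes, forced)) {
    t <- targetValue(network, state, node, p)
    if (t != as.integer(state[[node]])) {
      s2 <- state
      s2[[node]] <- t
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}
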