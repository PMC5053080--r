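## In-silico benchmark generation: everything needed to evaluate the
## optimization method against a known gold-standard network -- transition
## tables from single-node perturbation experiments, the PKN derived from
## them, noisy PKNs, training sets (with optional corruption), random
## sub-networks and synthetic gold standards.

#' Single-node perturbation transition table of a gold standard
#'
#' Performs every possible single-node perturbation experiment on the gold
#' standard: for every node, both forcing it to 1 (direction +1,
#' over-expression) and to 0 (direction -1, knock-out), starting from each
#' attractor of the unperturbed network.  Each row is one edge of the
#' attractor reachability graph: the source attractor's average state
#' (`before`) and one reached attractor's average state (`after`); a cyclic
#' attractor is replaced by the average of its states.
#'
#' @inheritParams findAttractors
#' @param gold the gold-standard [BooleanNetwork-class] (within the exact
#'   engine's cap).
#' @return data.frame with columns `perturbedNode`, `direction` and matrix
#'   columns `before`, `after` indexed by the gold standard's nodes.
#' @export
buildTransitionTable <- function(gold, maxFreeNodes = .MAX_FREE_NODES) {
  stopifnot(is(gold, "BooleanNetwork"))
  unpert <- findAttractors(gold, maxFreeNodes = maxFreeNodes)
  nd <- gold@nodes
  rows <- list()
  for (node in nd) {
    for (d in c(1L, -1L)) {
      p <- perturbation(stats::setNames(if (d == 1L) 1L else 0L, node))
      for (a in unpert) {
        reached <- reachableAttractors(gold, a, p, maxFreeNodes = maxFreeNodes)
        for (r in reached)
          rows[[length(rows) + 1L]] <-
            list(node = node, d = d, before = a@avgState, after = r@avgState)
      }
    }
  }
  out <- data.frame(
    perturbedNode = vapply(rows, `[[`, character(1), "node"),
    direction = vapply(rows, `[[`, integer(1), "d"),
    stringsAsFactors = FALSE)
  out$before <- matrix(unlist(lapply(rows, `[[`, "before")),
                       ncol = length(nd), byrow = TRUE)
  out$after <- matrix(unlist(lapply(rows, `[[`, "after")),
                      ncol = length(nd), byrow = TRUE)
  colnames(out$before) <- colnames(out$after) <- nd
  out
}

#' Derive an in-silico PKN from a transition table
#'
#' Each transition row contributes one edge from the perturbed node to every
#' observed node whose average state changes by more than 0.5 in absolute
#' value; the edge is activating when the perturbation direction and the
#' observed change have the same sign, inhibiting otherwise.  The perturbed
#' node itself is not an observed target (its change is forced, not
#' regulatory).  All edges of the gold standard are then added, and
#' duplicates collapsed.
#'
#' @param table a transition table from [buildTransitionTable()].
#' @param gold the gold-standard network.
#' @return a [BooleanNetwork-class] over the gold standard's nodes.
#' @export
buildPKN <- function(table, gold) {
  stopifnot(is(gold, "BooleanNetwork"))
  nd <- colnames(table$before)
  from <- to <- character(); sign <- integer()
  for (i in seq_len(nrow(table))) {
    delta <- table$after[i, ] - table$before[i, ]
    ## the perturbed node's own (forced) change is not an observation
    sel <- which(abs(delta) > 0.5 & nd != table$perturbedNode[i])
    if (!length(sel)) next
    from <- c(from, rep(table$perturbedNode[i], length(sel)))
    to <- c(to, nd[sel])
    sign <- c(sign, as.integer(table$direction[i] * base::sign(delta[sel])))
  }
  e <- rbind(data.frame(from = from, to = to, sign = sign,
                        stringsAsFactors = FALSE),
             gold@edges)
  booleanNetwork(e, nodes = gold@nodes)
}

#' Inject noise into a PKN
#'
#' Randomly replaces a fraction `q` of the PKN's edges: `round(q * M)` edges
#' are removed uniformly and the same number are added, sampled without
#' replacement from the complement set of candidate signed edges
#' (`n1 -> n2` and `n1 -| n2` over the ideal PKN's nodes, self-edges
#' included) that are not in the ideal PKN.  The edge count is preserved
#' exactly and the result is deterministic under `seed`.
#'
#' @param pkn the PKN to perturb.
#' @param q fraction of edges to replace, in \[0,1\].
#' @param seed integer seed.
#' @param ideal the ideal PKN defining the complement (defaults to `pkn`).
#' @return a [BooleanNetwork-class] over the same node set.
#' @export
addPKNNoise <- function(pkn, q, seed = NULL, ideal = pkn) {
  stopifnot(is(pkn, "BooleanNetwork"), q >= 0, q <= 1)
  M <- nEdges(pkn)
  nRepl <- round(q * M)
  if (!nRepl) return(pkn)
  .withSeed(seed, {
    keepIdx <- sample.int(M, M - nRepl)
    kept <- pkn@edges[sort(keepIdx), , drop = FALSE]
    nd <- pkn@nodes
    all <- expand.grid(from = nd, to = nd, sign = c(1L, -1L),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    idealKey <- paste(ideal@edges$from, ideal@edges$to, ideal@edges$sign)
    comp <- all[!(paste(all$from, all$to, all$sign) %in% idealKey), ,
                drop = FALSE]
    if (nrow(comp) < nRepl)
      stop(sprintf("complement has only %d candidate edges, %d needed",
                   nrow(comp), nRepl))
    added <- comp[sample.int(nrow(comp), nRepl), , drop = FALSE]
    booleanNetwork(rbind(kept, added), nodes = nd)
  })
}

#' Generate a training set from a gold-standard network
#'
#' Emulates a panel of perturbation experiments on the gold standard: for
#' each background (mutant) perturbation, the system is placed in
#' `initialState`, allowed to settle into its attractor under the background
#' alone (the initial phenotype), and then each stimulus is applied on top
#' of the background.  Every attractor reached contributes one training node
#' (perturbation = background + stimulus, observation = states of the
#' essential nodes in the attractor) and one training edge from the
#' background's initial node; all stimuli of one background share that
#' initial node.  Only essential nodes with a constant Boolean value across
#' the attractor's states are observed, so the gold standard itself always
#' scores `f_T = 0` on the generated training set.
#'
#' @inheritParams buildTransitionTable
#' @param backgrounds list of background perturbations (include
#'   `perturbation()` for wild type).
#' @param stimuli list of stimulus perturbations applied on top of each
#'   background; must not clash with the background on a shared node.
#' @param initialState named 0/1 vector over the gold standard's nodes.
#' @param essentialNodes nodes whose states are observed.
#' @return a [TrainingSet-class].
#' @export
generateTrainingSet <- function(gold, backgrounds, stimuli, initialState,
                                essentialNodes,
                                maxFreeNodes = .MAX_FREE_NODES) {
  stopifnot(is(gold, "BooleanNetwork"), length(backgrounds) >= 1L)
  essentialNodes <- intersect(essentialNodes, gold@nodes)
  stopifnot(length(essentialNodes) >= 1L)
  obsOf <- function(a) {
    v <- a@avgState[essentialNodes]
    v <- v[v %in% c(0, 1)]          # only stably Boolean essential nodes
    stats::setNames(as.integer(v), names(v))
  }
  nodes <- list(); edges <- NULL
  for (b in backgrounds) {
    bLabel <- perturbationKey(b)
    ## initial phenotype: the attractor the initial state settles into under
    ## the background alone
    dyn <- .compileDynamics(gold, b)
    start <- .resolveStartCodes(gold, dyn, list(initialState))
    atts <- findAttractors(gold, b, maxFreeNodes = maxFreeNodes)
    inAtt <- vapply(atts, function(a) start %in% a@states, logical(1))
    init <- if (any(inAtt)) atts[[which(inAtt)[1]]]
    else {
      reached <- reachableAttractors(gold, start, b,
                                     maxFreeNodes = maxFreeNodes)
      if (length(reached) != 1L)
        stop(sprintf(paste0("ambiguous initial attractor for background '%s':",
                            " %d candidates (%s)"), bLabel, length(reached),
                     paste(vapply(reached, attractorKey, character(1)),
                           collapse = "; ")))
      reached[[1]]
    }
    initObs <- obsOf(init)
    if (!length(initObs)) next      # no stably observed essential node
    initId <- paste0(bLabel, ":initial")
    nodes[[length(nodes) + 1L]] <-
      list(id = initId, perturbation = b, observation = initObs)
    for (s in stimuli) {
      clash <- intersect(names(b), names(s))
      if (any(b[clash] != s[clash]))
        stop("stimulus contradicts background on node(s): ",
             paste(clash[b[clash] != s[clash]], collapse = ", "))
      combined <- perturbation(c(b[setdiff(names(b), names(s))], s))
      reached <- reachableAttractors(gold, init, combined,
                                     maxFreeNodes = maxFreeNodes)
      for (j in seq_along(reached)) {
        o <- obsOf(reached[[j]])
        if (!length(o)) next
        id <- sprintf("%s+%s:%d", bLabel, perturbationKey(s), j)
        nodes[[length(nodes) + 1L]] <-
          list(id = id, perturbation = combined, observation = o)
        edges <- rbind(edges, data.frame(from = initId, to = id,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  if (!length(nodes)) stop("no training node could be generated")
  trainingSet(nodes, edges)
}

#' Corrupt a training set
#'
#' Flips `round(q * S)` of the `S` observed node states, chosen uniformly
#' without replacement; the graph structure is unchanged.  Deterministic
#' under `seed`.
#'
#' @param ts a [TrainingSet-class].
#' @param q fraction of observed states to reverse, in \[0,1\].
#' @param seed integer seed.
#' @return a [TrainingSet-class].
#' @export
corruptTrainingSet <- function(ts, q, seed = NULL) {
  stopifnot(is(ts, "TrainingSet"), q >= 0, q <= 1)
  sizes <- lengths(ts@observations)
  S <- sum(sizes)
  nFlip <- round(q * S)
  if (!nFlip) return(ts)
  .withSeed(seed, {
    flat <- sample.int(S, nFlip)
    offsets <- cumsum(c(0L, sizes))
    obs <- ts@observations
    for (f in flat) {
      i <- findInterval(f, offsets + 1L)   # training node index
      j <- f - offsets[i]                  # entry within observation
      obs[[i]][j] <- 1L - obs[[i]][j]
    }
    initialize(ts, observations = obs)
  })
}

#' Random sub-network of a PKN
#'
#' Keeps each PKN edge independently with probability `p` (0.5 for the
#' standard random-network baseline); isolated nodes are dropped.
#'
#' @param pkn a [BooleanNetwork-class].
#' @param p keep probability in \[0,1\].
#' @param seed integer seed.
#' @return a [BooleanNetwork-class].
#' @export
randomSubnetwork <- function(pkn, p = 0.5, seed = NULL) {
  stopifnot(is(pkn, "BooleanNetwork"), p >= 0, p <= 1)
  .withSeed(seed, subnetwork(pkn, stats::runif(nEdges(pkn)) < p))
}

#' Synthetic gold-standard network
#'
#' A random signed directed graph used as a self-contained benchmark gold
#' standard: `nEdges` distinct ordered node pairs (self-edges allowed) are
#' drawn uniformly and `round(fracInhibiting * nEdges)` of them are made
#' inhibiting.  Every finite asynchronous state transition graph has at
#' least one terminal SCC, so the result always has at least one attractor.
#' Deterministic under `seed`.
#'
#' @param nNodes number of nodes.
#' @param nEdges number of edges (`<= nNodes^2`).
#' @param fracInhibiting fraction of inhibiting edges.
#' @param seed integer seed.
#' @return a [BooleanNetwork-class].
#' @export
randomGoldStandard <- function(nNodes, nEdges, fracInhibiting = 0.3,
                               seed = NULL) {
  stopifnot(nNodes >= 1L, nEdges <= nNodes^2, nEdges >= 0L,
            fracInhibiting >= 0, fracInhibiting <= 1)
  nd <- sprintf("G%02d", seq_len(nNodes))
  .withSeed(seed, {
    pairIdx <- sample.int(nNodes^2, nEdges)
    from <- nd[(pairIdx - 1L) %% nNodes + 1L]
    to <- nd[(pairIdx - 1L) %/% nNodes + 1L]
    sign <- rep(1L, nEdges)
    nInh <- round(fracInhibiting * nEdges)
    if (nInh) sign[seq_len(nInh)] <- -1L   # pairIdx is already in random order
    booleanNetwork(data.frame(from = from, to = to, sign = sign,
                              stringsAsFactors = FALSE), nodes = nd)
  })
}
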