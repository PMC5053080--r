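#' Construct a training set graph
#'
#' @param nodes a list; each element is a list with fields `id` (unique
#'   name), `perturbation` (named 0/1 vector, possibly empty) and
#'   `observation` (non-empty named 0/1 vector of node states measured at
#'   equilibrium).
#' @param edges a data.frame (or 2-column matrix) of `from`/`to` node ids;
#'   an edge means the first phenotype evolves into the second upon the
#'   second perturbation.
#' @return a [TrainingSet-class].
#' @export
trainingSet <- function(nodes, edges = NULL) {
  ids <- vapply(nodes, function(x) as.character(x$id), character(1))
  perts <- lapply(nodes, function(x) perturbation(x$perturbation))
  obs <- lapply(nodes, function(x) {
    o <- x$observation
    v <- stats::setNames(as.integer(unlist(o)), names(o))
    v
  })
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges) <- c("from", "to")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  rownames(edges) <- NULL
  new("TrainingSet", ids = ids, perturbations = perts, observations = obs,
      edges = edges)
}

#' @rdname TrainingSet-class
setMethod("trainingIds", "TrainingSet", function(x) x@ids)

#' @rdname TrainingSet-class
setMethod("observations", "TrainingSet", function(x)
  stats::setNames(x@observations, x@ids))

#' @rdname TrainingSet-class
setMethod("perturbations", "TrainingSet", function(x)
  stats::setNames(x@perturbations, x@ids))

#' @rdname TrainingSet-class
setMethod("edges", "TrainingSet", function(x) x@edges)

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: %d node(s), %d transition edge(s), %d observed states\n",
              length(object@ids), nrow(object@edges),
              sum(lengths(object@observations))))
  invisible(NULL)
})

#' Read and write training sets as JSON
#'
#' Format: `{"nodes": [{"id": ..., "perturbation": {node: 0|1, ...},
#' "observation": {node: 0|1, ...}}, ...], "edges": [["id1","id2"], ...]}`.
#' The reader validates that observations are non-empty and Boolean and that
#' edge endpoints exist.
#'
#' @param path file path.
#' @return `readTrainingSet`: a [TrainingSet-class].
#' @export
readTrainingSet <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$nodes)) stop("training set JSON lacks a 'nodes' field")
  nodes <- lapply(x$nodes, function(nd) {
    if (is.null(nd$id)) stop("training node without 'id'")
    obs <- unlist(nd$observation)
    if (length(obs) && !all(obs %in% c(0, 1)))
      stop(sprintf("non-Boolean observation for training node '%s'", nd$id))
    list(id = nd$id,
         perturbation = unlist(nd$perturbation),
         observation = obs)
  })
  edges <- NULL
  if (length(x$edges))
    edges <- do.call(rbind, lapply(x$edges, function(e) {
      if (length(e) != 2L) stop("training edge must have two endpoints")
      data.frame(from = e[[1]], to = e[[2]], stringsAsFactors = FALSE)
    }))
  trainingSet(nodes, edges)
}

#' @rdname readTrainingSet
#' @param ts a [TrainingSet-class].
#' @export
writeTrainingSet <- function(ts, path) {
  stopifnot(is(ts, "TrainingSet"))
  nodes <- lapply(seq_along(ts@ids), function(i)
    list(id = ts@ids[i],
         perturbation = as.list(ts@perturbations[[i]]),
         observation = as.list(ts@observations[[i]])))
  edges <- lapply(seq_len(nrow(ts@edges)),
                  function(i) list(ts@edges$from[i], ts@edges$to[i]))
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Distance between an observation and an attractor
#'
#' Mean over the observed nodes of the absolute difference between the
#' observed Boolean value and the attractor's average state for that node.
#' An observed node absent from the model network is treated as constantly
#' inactive (average state 0).
#'
#' @param attractor an [Attractor-class].
#' @param observation non-empty named 0/1 vector.
#' @param modelNodes node names of the model network (defaults to the
#'   attractor's nodes).
#' @return a value in \[0, 1\]; 0 means a perfect match.
#' @export
observationDistance <- function(attractor, observation,
                                modelNodes = nodes(attractor)) {
  stopifnot(length(observation) >= 1L, !is.null(names(observation)))
  a <- vapply(names(observation), function(n)
    if (n %in% modelNodes) attractor@avgState[[n]] else 0, numeric(1))
  mean(abs(as.numeric(observation) - a))
}

## ---- f_T: constrained optimal matching ------------------------------------

## Branch-and-bound over one connected component of the training graph.
## cand[[i]]: candidate attractor count; dist[[i]]: distances; edges:
## matrix of (fromPos, toPos) within the component; reach[[e]]: logical
## matrix over (cand[from], cand[to]); samePert: perturbation key per pos.
## Returns list(cost, assign) with assign = NA_integer_ on infeasibility.
.matchComponent <- function(nCand, dist, edgesWithin, reach, pertKeys) {
  k <- length(nCand)
  best <- Inf
  bestAssign <- NULL
  assign <- rep(NA_integer_, k)
  ## order candidates by distance so good assignments are found early
  candOrder <- lapply(seq_len(k), function(i) order(dist[[i]]))
  ## index incident edges per position for incremental checking
  incident <- lapply(seq_len(k), function(i) {
    if (!nrow(edgesWithin)) integer(0)
    else which(edgesWithin[, 1L] == i | edgesWithin[, 2L] == i)
  })
  recurse <- function(pos, cost) {
    if (cost >= best) return(invisible(NULL))
    if (pos > k) {
      best <<- cost
      bestAssign <<- assign
      return(invisible(NULL))
    }
    for (a in candOrder[[pos]]) {
      ok <- TRUE
      ## constraint (2): distinct observations under one perturbation must
      ## map to distinct attractors
      for (j in seq_len(pos - 1L))
        if (pertKeys[j] == pertKeys[pos] && assign[j] == a) { ok <- FALSE; break }
      if (!ok) next
      ## constraint (1): training edges between assigned nodes must be
      ## realized as reachability edges
      for (e in incident[[pos]]) {
        i1 <- edgesWithin[e, 1L]; i2 <- edgesWithin[e, 2L]
        a1 <- if (i1 == pos) a else assign[i1]
        a2 <- if (i2 == pos) a else assign[i2]
        if (!is.na(a1) && !is.na(a2) && !reach[[e]][a1, a2]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[pos] <<- a
      recurse(pos + 1L, cost + dist[[pos]][a])
      assign[pos] <<- NA_integer_
    }
    invisible(NULL)
  }
  recurse(1L, 0)
  if (is.infinite(best)) list(cost = k, assign = rep(NA_integer_, k))
  else list(cost = best, assign = bestAssign)
}

#' Training distance f_T of a network
#'
#' `f_T` is the minimum, over feasible assignments of one attractor to each
#' training node, of the mean observation--attractor distance.  A feasible
#' assignment must (1) realize every training edge as an edge of the
#' attractor reachability graph and (2) be injective among training nodes
#' sharing a perturbation.  The minimization decomposes over connected
#' components of the training graph (components sharing a perturbation are
#' merged, since uniqueness couples them) and is solved exactly by
#' branch-and-bound; a component with no feasible assignment contributes
#' distance 1 per training node, so `f_T` is, approximately, the fraction of
#' observations not reproduced by the network.
#'
#' @inheritParams findAttractors
#' @param ts a [TrainingSet-class].
#' @return list with `fT` (in \[0,1\]) and `assignment` (named list mapping
#'   training node id to the matched [Attractor-class], or `NULL` for nodes
#'   of infeasible components).
#' @export
computeFT <- function(network, ts, engine = c("exact", "stochastic"),
                      params = stochasticParams(),
                      maxFreeNodes = .MAX_FREE_NODES) {
  stopifnot(is(network, "BooleanNetwork"), is(ts, "TrainingSet"))
  engine <- match.arg(engine)
  nT <- length(ts@ids)
  if (!nT) stop("empty training set")

  pertKeys <- vapply(ts@perturbations, perturbationKey, character(1))
  uperts <- ts@perturbations[!duplicated(pertKeys)]
  names(uperts) <- pertKeys[!duplicated(pertKeys)]

  n <- length(network@nodes)
  if (engine == "exact") {
    ## raw representation (integer state codes, no S4 in the hot path):
    ## attractor sets, average-state vectors and reachability computed
    ## straight on the compiled dynamics
    dyns <- lapply(uperts, function(p)
      .compileDynamics(network, .restrictPerturbation(network, p)))
    for (d in dyns)
      if (length(d$freeIdx0) > maxFreeNodes)
        stop(sprintf("state-space cap exceeded: %d non-clamped nodes (cap %d)",
                     length(d$freeIdx0), maxFreeNodes))
    raw <- lapply(dyns, function(d)
      .cpp_attractors_avg(d$n, d$act, d$inh, d$regType, d$freeIdx0,
                          d$forcedState))
    sets <- lapply(raw, `[[`, "sets")
    avgs <- lapply(raw, `[[`, "avg")   # nodes x attractors matrices
    nCandOf <- lengths(sets)
    distOf <- function(i) {
      obs <- ts@observations[[i]]
      rowIdx <- match(names(obs), network@nodes)   # NA for absent nodes
      present <- !is.na(rowIdx)
      avg <- avgs[[pertKeys[i]]]
      v <- numeric(ncol(avg))
      o <- as.numeric(obs)
      for (j in seq_len(ncol(avg))) {
        a <- numeric(length(o))
        a[present] <- avg[rowIdx[present], j]
        v[j] <- mean(abs(o - a))
      }
      v
    }
    attractorAt <- function(k, j)
      .newAttractor(network, sets[[k]][[j]],
                    .restrictPerturbation(network, uperts[[k]]))
    rawReachMatrix <- function(kFrom, kTo) {
      d <- dyns[[kTo]]
      .cpp_reach_matrix(d$n, d$act, d$inh, d$regType, d$freeIdx0,
                        d$forcedState, sets[[kFrom]], sets[[kTo]])
    }
  } else {
    atts <- lapply(uperts, function(p)
      findAttractors(network, .restrictPerturbation(network, p),
                     engine = engine, params = params,
                     maxFreeNodes = maxFreeNodes))
    nCandOf <- lengths(atts)
    distOf <- function(i)
      vapply(atts[[pertKeys[i]]], observationDistance, numeric(1),
             observation = ts@observations[[i]], modelNodes = network@nodes)
    attractorAt <- function(k, j) atts[[k]][[j]]
    rawReachMatrix <- function(kFrom, kTo) {
      keys2 <- vapply(atts[[kTo]], function(a) a@key, character(1))
      m <- matrix(FALSE, length(atts[[kFrom]]), length(keys2))
      for (i in seq_len(nrow(m))) {
        reached <- reachableAttractors(network, atts[[kFrom]][[i]],
                                       .restrictPerturbation(network, uperts[[kTo]]),
                                       engine = engine, params = params,
                                       maxFreeNodes = maxFreeNodes)
        m[i, ] <- keys2 %in% vapply(reached, function(a) a@key, character(1))
      }
      m
    }
  }
  dist <- lapply(seq_len(nT), distOf)

  ## reachability matrices, one per distinct ordered perturbation-key pair
  ## appearing on a training edge
  em <- ts@edges
  reachCache <- new.env(parent = emptyenv())
  reachMatrix <- function(kFrom, kTo) {
    id <- paste(kFrom, kTo, sep = " => ")
    if (is.null(reachCache[[id]]))
      reachCache[[id]] <- rawReachMatrix(kFrom, kTo)
    reachCache[[id]]
  }

  ## independent sub-problems: connected components of the training graph,
  ## merged when they share a perturbation (the uniqueness constraint couples
  ## same-perturbation nodes even without a connecting edge)
  comp <- seq_len(nT)
  links <- rbind(
    if (nrow(em)) cbind(match(em$from, ts@ids), match(em$to, ts@ids)),
    do.call(rbind, lapply(unique(pertKeys), function(k) {
      idx <- which(pertKeys == k)
      if (length(idx) > 1L) cbind(idx[-length(idx)], idx[-1]) else NULL
    })))
  if (!is.null(links) && nrow(links)) {
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(links))) {
        u <- links[i, 1L]; v <- links[i, 2L]
        if (comp[u] != comp[v]) {
          comp[comp == comp[v]] <- comp[u]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  total <- 0
  assignment <- stats::setNames(vector("list", nT), ts@ids)
  for (c0 in unique(comp)) {
    posIdx <- which(comp == c0)
    within <- if (nrow(em)) {
      sel <- match(em$from, ts@ids) %in% posIdx
      cbind(match(match(em$from[sel], ts@ids), posIdx),
            match(match(em$to[sel], ts@ids), posIdx))
    } else matrix(integer(0), 0, 2)
    reach <- if (nrow(within)) {
      emSel <- em[match(em$from, ts@ids) %in% posIdx, , drop = FALSE]
      lapply(seq_len(nrow(emSel)), function(e)
        reachMatrix(pertKeys[match(emSel$from[e], ts@ids)],
                    pertKeys[match(emSel$to[e], ts@ids)]))
    } else list()
    res <- .matchComponent(
      nCand = as.integer(nCandOf[pertKeys[posIdx]]),
      dist = dist[posIdx],
      edgesWithin = within,
      reach = reach,
      pertKeys = pertKeys[posIdx])
    total <- total + res$cost
    for (j in seq_along(posIdx))
      if (!is.na(res$assign[j]))
        assignment[[posIdx[j]]] <-
          attractorAt(pertKeys[posIdx[j]], res$assign[j])
  }
  list(fT = total / nT, assignment = assignment)
}
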