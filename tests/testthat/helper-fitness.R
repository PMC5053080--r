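# Exhaustive-enumeration oracle for f_T: tries every joint assignment of
# attractors to training nodes within each connected component of the
# training graph, checking the reachability constraint by explicit path
# search on the oracle STG and the uniqueness constraint directly.

oracleFT <- function(net, ts) {
  ids <- trainingIds(ts)
  perts <- BoolContext::perturbations(ts)
  obs <- observations(ts)
  pk <- vapply(perts, perturbationKey, character(1))
  uk <- unique(pk)
  atts <- lapply(uk, function(k) {
    p <- perts[[match(k, pk)]]
    findAttractors(net, p[names(p) %in% nodes(net)])
  })
  names(atts) <- uk

  reachCache <- new.env(parent = emptyenv())
  reachKeys <- function(a, kTo) {
    id <- paste(attractorKey(a), kTo, sep = "=>")
    if (is.null(reachCache[[id]])) {
      pTo <- perts[[match(kTo, pk)]]
      reachCache[[id]] <- oracleReachableKeys(net, attractorStateVectors(a),
                                              pTo[names(pTo) %in% nodes(net)])
    }
    reachCache[[id]]
  }

  em <- edges(ts)
  ## clusters: training edges plus links between same-perturbation nodes
  ## (the uniqueness constraint couples those even without an edge)
  extra <- do.call(rbind, lapply(unique(pk), function(k) {
    idx <- ids[pk == k]
    if (length(idx) > 1L)
      data.frame(from = idx[-length(idx)], to = idx[-1]) else NULL
  }))
  g <- igraph::graph_from_data_frame(
    rbind(em, extra), directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]

  total <- 0
  for (c0 in unique(comp)) {
    members <- ids[comp == c0]
    emc <- em[em$from %in% members, , drop = FALSE]
    counts <- vapply(members, function(id) length(atts[[pk[[id]]]]), integer(1))
    grid <- expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE)
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      asg <- as.integer(grid[r, ])
      ## uniqueness among nodes sharing a perturbation
      dup <- FALSE
      for (i in seq_along(members))
        for (j in seq_len(i - 1L))
          if (pk[[members[i]]] == pk[[members[j]]] && asg[i] == asg[j])
            dup <- TRUE
      if (dup) next
      ok <- TRUE
      for (e in seq_len(nrow(emc))) {
        iu <- match(emc$from[e], members); iv <- match(emc$to[e], members)
        a1 <- atts[[pk[[members[iu]]]]][[asg[iu]]]
        a2key <- attractorKey(atts[[pk[[members[iv]]]]][[asg[iv]]])
        if (!(a2key %in% reachKeys(a1, pk[[members[iv]]]))) { ok <- FALSE; break }
      }
      if (!ok) next
      cost <- sum(vapply(seq_along(members), function(i)
        observationDistance(atts[[pk[[members[i]]]]][[asg[i]]],
                            obs[[members[i]]], nodes(net)), numeric(1)))
      if (cost < best) best <- cost
    }
    total <- total + if (is.infinite(best)) length(members) else best
  }
  total / length(ids)
}

randomTrainingInstance <- function(seed, nNet = 5L, nEdgesNet = 10L) {
  set.seed(seed)
  gold <- randomGoldStandard(nNet, nEdgesNet, 0.3, seed = seed)
  nd <- nodes(gold)
  pertPool <- list(perturbation(),
                   perturbation(stats::setNames(1L, nd[1])),
                   perturbation(stats::setNames(0L, nd[2])))
  nTS <- sample(2:4, 1)
  tsNodes <- lapply(seq_len(nTS), function(i) {
    m <- sample(2:4, 1)
    list(id = paste0("t", i),
         perturbation = pertPool[[sample.int(3, 1)]],
         observation = stats::setNames(sample(0:1, m, replace = TRUE),
                                       sample(nd, m)))
  })
  edges <- NULL
  for (i in seq_len(nTS - 1L))
    if (stats::runif(1) < 0.6)
      edges <- rbind(edges, data.frame(from = paste0("t", i),
                                       to = paste0("t", i + 1L)))
  list(gold = gold, ts = trainingSet(tsNodes, edges))
}
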