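# Independent reference implementation used as oracle: enumerates the full
# asynchronous state transition graph through asyncSuccessors() (pure R) and
# finds terminal SCCs / reachability with igraph.  Shares no code path with
# the package's C++ engine beyond the single-state update rule.

.oracleStates <- function(net, p = perturbation()) {
  nd <- nodes(net)
  free <- setdiff(nd, names(p))
  if (length(free)) {
    grid <- expand.grid(rep(list(0:1), length(free)), KEEP.OUT.ATTRS = FALSE)
    states <- lapply(seq_len(nrow(grid)), function(i) {
      s <- stats::setNames(integer(length(nd)), nd)
      s[free] <- as.integer(unlist(grid[i, ]))
      s[names(p)] <- p
      s
    })
  } else {
    s <- stats::setNames(integer(length(nd)), nd)
    s[names(p)] <- p
    states <- list(s)
  }
  states
}

.stateKeyOf <- function(s, nd) paste(s[nd], collapse = "")

# full STG: vertices = state keys, edge list from asyncSuccessors
oracleSTG <- function(net, p = perturbation()) {
  nd <- nodes(net)
  states <- .oracleStates(net, p)
  keys <- vapply(states, .stateKeyOf, character(1), nd = nd)
  idx <- stats::setNames(seq_along(states), keys)
  from <- to <- integer(0)
  for (i in seq_along(states)) {
    for (s2 in asyncSuccessors(net, states[[i]], p)) {
      from <- c(from, i)
      to <- c(to, idx[[.stateKeyOf(s2, nd)]])
    }
  }
  g <- igraph::make_empty_graph(n = length(states), directed = TRUE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  list(graph = g, keys = keys)
}

# attractors as a sorted character vector of canonical keys
# ("bits|bits|..."), directly comparable to attractorKey()
oracleAttractorKeys <- function(net, p = perturbation()) {
  stg <- oracleSTG(net, p)
  comp <- igraph::components(stg$graph, mode = "strong")
  el <- igraph::as_edgelist(stg$graph, names = FALSE)
  terminal <- rep(TRUE, comp$no)
  if (nrow(el))
    for (r in seq_len(nrow(el)))
      if (comp$membership[el[r, 1]] != comp$membership[el[r, 2]])
        terminal[comp$membership[el[r, 1]]] <- FALSE
  keys <- character(0)
  for (c0 in which(terminal)) {
    members <- sort(stg$keys[comp$membership == c0])
    keys <- c(keys, paste(members, collapse = "|"))
  }
  sort(keys)
}

# keys of attractors (under p) reachable from given full states, by explicit
# path search on the oracle STG
oracleReachableKeys <- function(net, fromStates, p = perturbation()) {
  nd <- nodes(net)
  stg <- oracleSTG(net, p)
  starts <- vapply(fromStates, function(s) {
    s[names(p)] <- p                       # clamp overwrites
    .stateKeyOf(s, nd)
  }, character(1))
  reach <- unique(unlist(lapply(match(starts, stg$keys), function(v)
    stg$keys[igraph::subcomponent(stg$graph, v, mode = "out")])))
  keys <- character(0)
  for (ak in oracleAttractorKeys(net, p)) {
    members <- strsplit(ak, "|", fixed = TRUE)[[1]]
    if (any(members %in% reach)) keys <- c(keys, ak)
  }
  sort(keys)
}

engineAttractorKeys <- function(atts) sort(vapply(atts, attractorKey, character(1)))

# decode an attractor's member states into named vectors (for oracle calls)
attractorStateVectors <- function(a) {
  nd <- nodes(a)
  lapply(stateStrings(a), function(ss)
    stats::setNames(as.integer(strsplit(ss, "")[[1]]), nd))
}

toggle2 <- function() booleanNetwork(
  data.frame(from = c("A", "B"), to = c("B", "A"), sign = 1L))
negLoop <- function() booleanNetwork(
  data.frame(from = "A", to = "A", sign = -1L))
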