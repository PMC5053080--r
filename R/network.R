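#' Construct a signed Boolean network
#'
#' @param edges a data.frame with columns `from`, `to`, `sign` (+1/-1), or
#'   `NULL` for an edgeless network.  Duplicated (from, to, sign) triples are
#'   collapsed.
#' @param nodes optional extra node names (isolated nodes); the node set is
#'   the union of `nodes` and all edge endpoints, sorted lexicographically.
#' @return a [BooleanNetwork-class] object.
#' @examples
#' net <- booleanNetwork(data.frame(from = "A", to = "B", sign = 1L))
#' nodes(net)
#' @export
booleanNetwork <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        sign = as.integer(edges$sign),
                        stringsAsFactors = FALSE)
    edges <- unique(edges)
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  edges <- edges[order(edges$from, edges$to, -edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  new("BooleanNetwork", nodes = nodes, edges = edges)
}

#' @rdname BooleanNetwork-class
#' @aliases nodes,BooleanNetwork-method
setMethod("nodes", "BooleanNetwork", function(x) x@nodes)

#' @rdname BooleanNetwork-class
setMethod("edges", "BooleanNetwork", function(x) x@edges)

#' @rdname BooleanNetwork-class
setMethod("nNodes", "BooleanNetwork", function(x) length(x@nodes))

#' @rdname BooleanNetwork-class
setMethod("nEdges", "BooleanNetwork", function(x) nrow(x@edges))

setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork: %d nodes, %d edges (%d activating, %d inhibiting)\n",
              nNodes(object), nEdges(object),
              sum(object@edges$sign == 1L), sum(object@edges$sign == -1L)))
  if (nNodes(object)) {
    shown <- utils::head(object@nodes, 8L)
    cat("  nodes: ", paste(shown, collapse = ", "),
        if (nNodes(object) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(NULL)
})

#' Edge subset of a prior knowledge network
#'
#' Returns the sub-network induced by a subset of the PKN's edges.  Nodes are
#' the endpoints of the kept edges: isolated nodes are dropped, so the node
#' and edge counts are the ones entering the fitness.
#'
#' @param pkn a [BooleanNetwork-class].
#' @param keep either a logical vector over `edges(pkn)` rows, or a
#'   data.frame of edges that must all belong to the PKN.
#' @return a [BooleanNetwork-class] with `edges = keep`.
#' @export
subnetwork <- function(pkn, keep) {
  stopifnot(is(pkn, "BooleanNetwork"))
  pe <- pkn@edges
  if (is.logical(keep)) {
    if (length(keep) != nrow(pe))
      stop("logical 'keep' must have one entry per PKN edge")
    sub <- pe[keep, , drop = FALSE]
  } else {
    sub <- data.frame(from = as.character(keep$from),
                      to = as.character(keep$to),
                      sign = as.integer(keep$sign), stringsAsFactors = FALSE)
    missing <- !(paste(sub$from, sub$to, sub$sign) %in%
                   paste(pe$from, pe$to, pe$sign))
    if (any(missing))
      stop("edges not present in the PKN: ",
           paste(sprintf("%s %s %s", sub$from[missing],
                         ifelse(sub$sign[missing] == 1L, "->", "-|"),
                         sub$to[missing]), collapse = ", "))
  }
  booleanNetwork(sub)
}

## ---- perturbations ---------------------------------------------------------

#' Node perturbations
#'
#' A perturbation clamps a set of nodes to fixed Boolean values for the
#' duration of a simulation: over-expression forces a node to 1, knock-out
#' forces it to 0.  It is represented as a named integer vector; the empty
#' vector is the unperturbed condition.
#'
#' @param ... clamped values, e.g. `perturbation(TNF = 1, CASP8 = 0)`, or a
#'   single named vector/list.
#' @return a named integer vector with values in \{0, 1\}.
#' @export
perturbation <- function(...) {
  args <- list(...)
  if (length(args) == 1L && (is.list(args[[1]]) ||
      (length(args[[1]]) != 1L || !is.null(names(args[[1]])))) &&
      is.null(names(args)))
    args <- as.list(args[[1]])
  v <- vapply(args, function(x) as.integer(x), integer(1))
  if (length(v)) {
    if (is.null(names(v)) || any(names(v) == ""))
      stop("perturbation values must be named by node")
    if (anyDuplicated(names(v))) stop("duplicated node in perturbation")
    if (!all(v %in% c(0L, 1L))) stop("perturbation values must be 0 or 1")
  }
  v
}

#' @rdname perturbation
#' @param p a perturbation.
#' @return `perturbationKey`: a canonical string id, `"unperturbed"` for the
#'   empty perturbation.
#' @export
perturbationKey <- function(p) {
  if (!length(p)) return("unperturbed")
  o <- order(names(p))
  paste(sprintf("%s=%d", names(p)[o], p[o]), collapse = ",")
}

.checkPerturbationNodes <- function(network, p) {
  unknown <- setdiff(names(p), network@nodes)
  if (length(unknown))
    stop("unknown node(s) in perturbation: ", paste(unknown, collapse = ", "))
  invisible(p)
}

## restrict a perturbation to the nodes of a (sub)network
.restrictPerturbation <- function(network, p) {
  p[names(p) %in% network@nodes]
}

## ---- edge-list text format -------------------------------------------------

#' Read and write networks in the signed edge-list text format
#'
#' One edge per line, `SOURCE -> TARGET` for activation and `SOURCE -| TARGET`
#' for inhibition; `#` starts a comment; node names match `[A-Za-z0-9_]+`.
#' Isolated nodes are carried by `# node: NAME` directive lines so that
#' writing and re-reading a network is lossless.  The writer emits sorted
#' lines for diff-stability.
#'
#' @param path file path.
#' @return `readBooleanNetwork`: a [BooleanNetwork-class].
#' @export
readBooleanNetwork <- function(path) {
  lines <- readLines(path, warn = FALSE)
  extra <- character()
  from <- to <- character(); sign <- integer()
  for (i in seq_along(lines)) {
    line <- lines[i]
    m <- regmatches(line, regexec("^#\\s*node:\\s*([A-Za-z0-9_]+)\\s*$", line))[[1]]
    if (length(m) == 2L) { extra <- c(extra, m[2]); next }
    line <- sub("#.*$", "", line)
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec(
      "^\\s*([A-Za-z0-9_]+)\\s*(->|-\\|)\\s*([A-Za-z0-9_]+)\\s*$", line))[[1]]
    if (length(m) != 4L)
      stop(sprintf("%s:%d: cannot parse edge line: '%s'", path, i, lines[i]))
    from <- c(from, m[2]); to <- c(to, m[4])
    sign <- c(sign, if (m[3] == "->") 1L else -1L)
  }
  booleanNetwork(data.frame(from = from, to = to, sign = sign,
                            stringsAsFactors = FALSE), nodes = extra)
}

#' @rdname readBooleanNetwork
#' @param network a [BooleanNetwork-class].
#' @export
writeBooleanNetwork <- function(network, path) {
  stopifnot(is(network, "BooleanNetwork"))
  e <- network@edges
  lines <- sprintf("%s %s %s", e$from, ifelse(e$sign == 1L, "->", "-|"), e$to)
  isolated <- setdiff(network@nodes, c(e$from, e$to))
  lines <- c(sort(lines), sprintf("# node: %s", sort(isolated)))
  writeLines(lines, path)
  invisible(path)
}
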