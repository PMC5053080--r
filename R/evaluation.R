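## Gold-standard comparison: the s_all predictive-power score, and combined
## (ensemble) predictions with their error-versus-variance analysis.

#' All single-node perturbations of the essential nodes
#'
#' The unperturbed condition plus, for each essential node, forcing it to 1
#' and forcing it to 0: `2k + 1` perturbations for `k` essential nodes (29
#' for the canonical 14-node readout set).
#'
#' @param essentialNodes non-empty character vector.
#' @return list of [perturbation()] vectors, the unperturbed one first.
#' @export
singleNodePerturbations <- function(essentialNodes) {
  if (!length(essentialNodes)) stop("essentialNodes must be non-empty")
  c(list(perturbation()),
    lapply(essentialNodes, function(n) perturbation(stats::setNames(1L, n))),
    lapply(essentialNodes, function(n) perturbation(stats::setNames(0L, n))))
}

## Project full states of one network onto another: named values carried
## over, nodes absent from the source set to 0.
.projectStates <- function(codes, fromNodes, toNetwork) {
  toNd <- toNetwork@nodes
  common <- intersect(toNd, fromNodes)
  fromIdx <- match(common, fromNodes) - 1L
  toBit <- 2^(match(common, toNd) - 1L)
  vapply(codes, function(s)
    as.integer(sum(bitwAnd(bitwShiftR(s, fromIdx), 1L) * toBit)), integer(1))
}

#' Average state reached after a perturbation
#'
#' Applies the perturbation to the initial states, finds all attractors
#' reachable in the asynchronous state transition graph, and returns the
#' vector over essential nodes of the mean (over reached attractors, equally
#' weighted) of the attractor average states.  Essential nodes absent from
#' the network contribute 0.
#'
#' @inheritParams findAttractors
#' @param initialStates an [Attractor-class], a list of named 0/1 state
#'   vectors over the *network's* nodes, or integer state codes.
#' @param essentialNodes the readout node set.
#' @return named numeric vector over `essentialNodes` with entries in
#'   \[0,1\].
#' @export
averageReachedState <- function(network, initialStates, p = perturbation(),
                                essentialNodes,
                                engine = c("exact", "stochastic"),
                                params = stochasticParams(),
                                maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  reached <- reachableAttractors(network, initialStates,
                                 .restrictPerturbation(network, p),
                                 engine = engine, params = params,
                                 maxFreeNodes = maxFreeNodes)
  if (!length(reached)) stop("no attractor reached")
  per <- vapply(reached, function(a)
    vapply(essentialNodes, function(n)
      if (n %in% a@nodes) a@avgState[[n]] else 0, numeric(1)),
    numeric(length(essentialNodes)))
  stats::setNames(rowMeans(matrix(per, nrow = length(essentialNodes))),
                  essentialNodes)
}

#' Predictive-power score s_all of a model network
#'
#' For every single-node perturbation of the essential nodes and every
#' attractor of the unperturbed gold standard as initial condition, the
#' average reached states of model and gold standard are compared by
#' Manhattan distance (model initial states are the gold attractor's states
#' projected onto the model's nodes, absent nodes set to 0).  With Delta the
#' mean distance over all (perturbation, initial state) pairs and k the
#' number of essential nodes, `s_all = 1 - Delta / k`: 1 when the average
#' predictions always agree, 0 when they are consistently opposite.
#' Experiments underlying `s_all` are not part of the training set, so the
#' score measures predictive power, not goodness of fit.
#'
#' @inheritParams averageReachedState
#' @param model the model [BooleanNetwork-class].
#' @param gold the gold-standard [BooleanNetwork-class] (within the exact
#'   engine's cap; the gold side always uses the exact engine).
#' @return a value in \[0, 1\].
#' @export
sAll <- function(model, gold, essentialNodes,
                 engine = c("exact", "stochastic"),
                 params = stochasticParams(),
                 maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  stopifnot(length(essentialNodes) >= 1L)
  k <- length(essentialNodes)
  goldAtts <- findAttractors(gold, maxFreeNodes = maxFreeNodes)
  perts <- singleNodePerturbations(essentialNodes)
  dists <- numeric(0)
  for (a in goldAtts) {
    modelStarts <- .projectStates(a@states, gold@nodes, model)
    for (p in perts) {
      gv <- averageReachedState(gold, a, p, essentialNodes,
                                maxFreeNodes = maxFreeNodes)
      mv <- averageReachedState(model, modelStarts, p, essentialNodes,
                                engine = engine, params = params,
                                maxFreeNodes = maxFreeNodes)
      dists <- c(dists, sum(abs(gv - mv)))
    }
  }
  1 - mean(dists) / k
}

#' Combined predictions of a model-network ensemble
#'
#' For each single-node perturbation of the essential nodes, each attractor
#' of the unperturbed gold standard (initial condition) and each essential
#' node, records the mean and population variance, across the ensemble of
#' model networks, of the per-network average reached state, together with
#' the prediction error: the absolute difference between the ensemble mean
#' and the gold standard's average reached state.  The record count is
#' `k * (2k + 1) * a` for `k` essential nodes and `a` unperturbed gold
#' attractors.
#'
#' @inheritParams sAll
#' @param models list of at least two model [BooleanNetwork-class] objects.
#' @param datasetId label stored in the `dataset` column.
#' @return data.frame with columns `dataset`, `perturbation`,
#'   `initialAttractor`, `node`, `mean`, `variance`, `error`, `gold`.
#' @export
combinedPredictions <- function(models, gold, essentialNodes,
                                datasetId = "dataset1",
                                engine = c("exact", "stochastic"),
                                params = stochasticParams(),
                                maxFreeNodes = .MAX_FREE_NODES) {
  engine <- match.arg(engine)
  stopifnot(length(models) >= 2L, length(essentialNodes) >= 1L)
  k <- length(essentialNodes)
  goldAtts <- findAttractors(gold, maxFreeNodes = maxFreeNodes)
  perts <- singleNodePerturbations(essentialNodes)
  out <- list()
  for (ai in seq_along(goldAtts)) {
    a <- goldAtts[[ai]]
    starts <- lapply(models, function(m) .projectStates(a@states, gold@nodes, m))
    for (p in perts) {
      gv <- averageReachedState(gold, a, p, essentialNodes,
                                maxFreeNodes = maxFreeNodes)
      preds <- vapply(seq_along(models), function(mi)
        averageReachedState(models[[mi]], starts[[mi]], p, essentialNodes,
                            engine = engine, params = params,
                            maxFreeNodes = maxFreeNodes),
        numeric(k))
      preds <- matrix(preds, nrow = k)
      mu <- rowMeans(preds)
      v <- rowMeans(preds^2) - mu^2        # population variance
      out[[length(out) + 1L]] <- data.frame(
        dataset = datasetId, perturbation = perturbationKey(p),
        initialAttractor = sprintf("A%d", ai), node = essentialNodes,
        mean = mu, variance = pmax(v, 0), error = abs(mu - gv), gold = gv,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman correlation between prediction error and ensemble variance
#'
#' Rank correlation (average ranks for ties) between the `error` and
#' `variance` columns of combined-prediction records.  A strong positive
#' correlation means the ensemble variance, which is observable without
#' knowing the truth, approximates the prediction error, which is not.
#'
#' @param records data.frame from [combinedPredictions()] (>= 3 rows).
#' @return the Spearman rho, or `NA` (with a warning) when either variable
#'   is constant so the coefficient is undefined.
#' @export
errorVarianceCorrelation <- function(records) {
  stopifnot(all(c("error", "variance") %in% names(records)),
            nrow(records) >= 3L)
  if (stats::sd(records$error) == 0 || stats::sd(records$variance) == 0) {
    warning("error/variance ranks are constant; Spearman rho is undefined")
    return(NA_real_)
  }
  stats::cor(records$error, records$variance, method = "spearman")
}
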