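test_that("transition tables enumerate single-node perturbations from each attractor", {
  ## single isolated node: 2 unperturbed steady states, forcing each
  ## direction from each -> 4 rows, all deterministic
  one <- booleanNetwork(nodes = "A")
  tab <- buildTransitionTable(one)
  expect_identical(nrow(tab), 4L)
  r <- tab[tab$direction == 1L & tab$before[, "A"] == 0, ]
  expect_identical(nrow(r), 1L)
  expect_equal(r$after[1, "A"], c(A = 1))

  ## deterministic 2-node chain: 2 nodes x 2 directions x k attractors rows
  net <- toggle2()
  k <- length(findAttractors(net))
  tab2 <- buildTransitionTable(net)
  expect_identical(nrow(tab2), 2L * 2L * k)       # every reach is unique here
  expect_true(all(tab2$before >= 0 & tab2$before <= 1))
})

test_that("the PKN rule thresholds shifts at 0.5 and signs by direction x change", {
  gold <- booleanNetwork(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    sign = c(1L, -1L)))
  tab <- data.frame(perturbedNode = c("A", "A", "B"),
                    direction = c(1L, -1L, -1L), stringsAsFactors = FALSE)
  tab$before <- rbind(c(A = 0, B = 0, C = 1), c(A = 1, B = 1, C = 0),
                      c(A = 0, B = 1, C = 0))
  tab$after <- rbind(c(A = 1, B = 1, C = 0), c(A = 0, B = 0.6, C = 0.4),
                     c(A = 0, B = 0, C = 1))
  pkn <- buildPKN(tab, gold)
  e <- edges(pkn)
  key <- paste(e$from, e$to, e$sign)
  ## row 1 (over-expression): B rises by 1 -> positive; C falls by 1 -> negative
  expect_true("A B 1" %in% key)
  expect_true("A C -1" %in% key)
  ## row 2: |delta| = 0.4 for both observables -> no edge from the threshold
  ## row 3 (knock-out): C rises -> sign product (-1)(+1) -> negative
  expect_true("B C -1" %in% key)
  expect_false("A B -1" %in% key)
  ## gold edges are always unioned in
  expect_true(all(paste(gold@edges$from, gold@edges$to, gold@edges$sign)
                  %in% key))
  ## the perturbed node's own forced change never creates a self-edge
  expect_false("A A 1" %in% key)
})

test_that("the derived PKN contains the gold standard", {
  for (seed in 1:5) {
    gold <- randomGoldStandard(5, 9, 0.3, seed = 400 + seed)
    pkn <- buildPKN(buildTransitionTable(gold), gold)
    expect_identical(nodes(pkn), nodes(gold))
    expect_true(all(paste(gold@edges$from, gold@edges$to, gold@edges$sign) %in%
                      paste(pkn@edges$from, pkn@edges$to, pkn@edges$sign)))
  }
})

test_that("PKN noise injection preserves edge counts and hits the exact fraction", {
  pkn <- randomGoldStandard(6, 10, 0.3, seed = 1)
  expect_identical(addPKNNoise(pkn, 0, seed = 1), pkn)

  key <- function(net) paste(net@edges$from, net@edges$to, net@edges$sign)
  half <- addPKNNoise(pkn, 0.5, seed = 2)
  expect_identical(nEdges(half), 10L)
  expect_identical(sum(key(half) %in% key(pkn)), 5L)
  expect_identical(nodes(half), nodes(pkn))

  full <- addPKNNoise(pkn, 1, seed = 3)
  expect_identical(nEdges(full), 10L)
  expect_identical(sum(key(full) %in% key(pkn)), 0L)

  expect_identical(key(addPKNNoise(pkn, 0.3, seed = 9)),
                   key(addPKNNoise(pkn, 0.3, seed = 9)))
})

test_that("generated training sets are self-consistent: the gold scores f_T = 0", {
  for (seed in 1:6) {
    gold <- randomGoldStandard(6, 12, 0.3, seed = 500 + seed)
    nd <- nodes(gold)
    ts <- generateTrainingSet(
      gold,
      backgrounds = list(perturbation(), perturbation(stats::setNames(0L, nd[4]))),
      stimuli = list(perturbation(stats::setNames(1L, nd[1])),
                     perturbation(stats::setNames(1L, nd[2]))),
      initialState = stats::setNames(rep(0L, 6), nd),
      essentialNodes = nd)
    expect_equal(computeFT(gold, ts)$fT, 0, info = sprintf("seed %d", seed))
    ## all stimulus nodes of one background attach to its initial node
    e <- edges(ts)
    expect_true(all(grepl(":initial$", e$from)))
  }
})

test_that("a background knock-out forces its observation to 0", {
  gold <- randomGoldStandard(5, 10, 0.3, seed = 77)
  nd <- nodes(gold)
  ts <- generateTrainingSet(
    gold, backgrounds = list(perturbation(stats::setNames(0L, nd[1]))),
    stimuli = list(perturbation(stats::setNames(1L, nd[2]))),
    initialState = stats::setNames(rep(0L, 5), nd),
    essentialNodes = nd)
  for (o in observations(ts))
    if (nd[1] %in% names(o)) expect_identical(o[[nd[1]]], 0L)
})

test_that("training-set corruption flips exactly the requested fraction", {
  gold <- randomGoldStandard(6, 12, 0.3, seed = 501)
  nd <- nodes(gold)
  ts <- generateTrainingSet(
    gold, backgrounds = list(perturbation()),
    stimuli = list(perturbation(stats::setNames(1L, nd[1]))),
    initialState = stats::setNames(rep(0L, 6), nd), essentialNodes = nd)
  S <- sum(lengths(observations(ts)))

  expect_identical(corruptTrainingSet(ts, 0), ts)
  allFlip <- corruptTrainingSet(ts, 1, seed = 1)
  expect_identical(unlist(observations(allFlip)),
                   1L - unlist(observations(ts)))
  q <- 0.25
  some <- corruptTrainingSet(ts, q, seed = 2)
  expect_identical(sum(unlist(observations(some)) !=
                         unlist(observations(ts))), as.integer(round(q * S)))
  ## structure untouched
  expect_identical(edges(some), edges(ts))
  expect_identical(BoolContext::perturbations(some), BoolContext::perturbations(ts))
})

test_that("random sub-networks keep each edge independently", {
  pkn <- randomGoldStandard(8, 30, 0.3, seed = 3)
  expect_identical(randomSubnetwork(pkn, 1, seed = 1), subnetwork(pkn, rep(TRUE, 30)))
  expect_identical(nEdges(randomSubnetwork(pkn, 0, seed = 1)), 0L)
  ## kept-edge counts across seeds stay inside the binomial 99.9% band
  counts <- vapply(1:60, function(s) nEdges(randomSubnetwork(pkn, 0.5, seed = s)),
                   integer(1))
  band <- stats::qbinom(c(5e-4, 1 - 5e-4), 30, 0.5)
  expect_true(all(counts >= band[1] & counts <= band[2]))
  expect_gt(stats::sd(counts), 0)
})

test_that("synthetic gold standards are reproducible with the requested size and sign mix", {
  g1 <- randomGoldStandard(6, 10, 0.3, seed = 5)
  expect_identical(g1, randomGoldStandard(6, 10, 0.3, seed = 5))
  expect_identical(nEdges(g1), 10L)
  expect_identical(sum(edges(g1)$sign == -1L), 3L)
  expect_gte(length(findAttractors(g1)), 1L)
  one <- randomGoldStandard(1, 0, seed = 1)
  expect_length(findAttractors(one), 2L)          # isolated node holds 0 or 1
  expect_error(randomGoldStandard(3, 10, seed = 1))
})
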