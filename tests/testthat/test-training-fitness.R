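test_that("observation distance averages per-node deviations, absent nodes count as 0", {
  net <- toggle2()
  a <- findAttractors(net)[[2]]                      # steady state (1,1)
  expect_equal(observationDistance(a, c(A = 1L, B = 1L)), 0)
  expect_equal(observationDistance(a, c(A = 1L, B = 0L)), 0.5)
  ## observed node absent from the model: treated as constantly inactive
  expect_equal(observationDistance(a, c(X = 1L), modelNodes = nodes(net)), 1.0)
  expect_equal(observationDistance(a, c(X = 0L, A = 1L),
                                   modelNodes = nodes(net)), 0)
  ## cyclic attractor contributes its average state
  osc <- findAttractors(negLoop())[[1]]
  expect_equal(observationDistance(osc, c(A = 1L)), 0.5)
})

test_that("f_T picks the best attractor for a single observation", {
  ## A oscillates (avg 0.5), B is an input: attractors differ only in B
  net <- booleanNetwork(data.frame(from = "A", to = "A", sign = -1L),
                        nodes = "B")
  ts <- trainingSet(list(list(id = "t1", perturbation = NULL,
                              observation = c(A = 1L, B = 1L))))
  res <- computeFT(net, ts)
  expect_equal(res$fT, 0.25)                         # (0.5 + 0) / 2, best of {0.25, 0.75}
  expect_equal(avgState(res$assignment$t1)[["B"]], 1)
})

test_that("training-set JSON round-trips and the validator rejects bad input", {
  ts <- trainingSet(
    list(list(id = "wt", perturbation = NULL, observation = c(G01 = 1L)),
         list(id = "ko", perturbation = c(G02 = 0L),
              observation = c(G01 = 0L, G03 = 1L))),
    data.frame(from = "wt", to = "ko"))
  path <- withr::local_tempfile(fileext = ".json")
  writeTrainingSet(ts, path)
  back <- readTrainingSet(path)
  expect_identical(trainingIds(back), trainingIds(ts))
  expect_identical(observations(back), observations(ts))
  expect_identical(edges(back), edges(ts))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": [{"id": "x", "observation": {"A": 0.5}}]}', bad)
  expect_error(readTrainingSet(bad), "non-Boolean")
  ## dangling edge
  expect_error(trainingSet(list(list(id = "a", perturbation = NULL,
                                     observation = c(X = 1L))),
                           data.frame(from = "a", to = "ghost")),
               "endpoints")
  ## empty observation
  expect_error(trainingSet(list(list(id = "a", perturbation = NULL,
                                     observation = NULL))))
})

test_that("branch-and-bound f_T equals exhaustive assignment enumeration", {
  for (seed in 1:12) {
    inst <- randomTrainingInstance(seed)
    expect_equal(computeFT(inst$gold, inst$ts)$fT,
                 oracleFT(inst$gold, inst$ts),
                 info = sprintf("seed %d", seed))
  }
})

test_that("adding a training edge never decreases the optimal f_T", {
  for (seed in 13:20) {
    inst <- randomTrainingInstance(seed)
    ts <- inst$ts
    ids <- trainingIds(ts)
    withEdge <- trainingSet(
      lapply(seq_along(ids), function(i)
        list(id = ids[i], perturbation = BoolContext::perturbations(ts)[[i]],
             observation = observations(ts)[[i]])),
      rbind(edges(ts), data.frame(from = ids[1], to = ids[length(ids)])))
    expect_gte(computeFT(inst$gold, withEdge)$fT,
               computeFT(inst$gold, ts)$fT)
  }
})

test_that("uniqueness constraint forces distinct attractors per perturbation", {
  ## two training nodes, same (unperturbed) condition, same observation; the
  ## toggle net has two steady states at distance 0 and 1 from (1,1):
  ## injectivity forces the second node onto the worse attractor
  net <- toggle2()
  mk <- function(n) lapply(seq_len(n), function(i)
    list(id = paste0("t", i), perturbation = NULL,
         observation = c(A = 1L, B = 1L)))
  expect_equal(computeFT(net, trainingSet(mk(1)))$fT, 0)
  expect_equal(computeFT(net, trainingSet(mk(2)))$fT, 0.5)
  ## a third node cannot be assigned at all: infeasible component penalty
  ts3 <- trainingSet(mk(3), data.frame(from = c("t1", "t1"), to = c("t2", "t3")))
  expect_equal(computeFT(net, ts3)$fT, 1)
})

test_that("fitness comparison is lexicographic with f_T dominant", {
  f <- function(...) fitness(...)
  expect_identical(compareFitness(f(0, 14, 15, 58), f(0, 14, 16, 99)), "better")
  expect_identical(compareFitness(f(0.01, 14, 14, 80), f(0, 10, 5, 3)), "worse")
  expect_identical(compareFitness(f(0, 14, 15, 58), f(0, 14, 15, 58)), "equal")
  ## same nodes: more edges wins under max_edges
  expect_identical(compareFitness(f(0, 14, 15, 58), f(0, 14, 15, 50)), "better")
  ## min_edges variant: fewer edges wins, node count not compared
  expect_identical(compareFitness(f(0, 14, 15, 50, "min_edges"),
                                  f(0, 14, 15, 58, "min_edges")), "better")
  expect_error(compareFitness(f(0, 1, 1, 1), f(0, 1, 1, 1, "min_edges")),
               "variant")
})

test_that("fitness comparison is a total order", {
  set.seed(99)
  pool <- lapply(1:12, function(i)
    fitness(sample(c(0, 0.25, 0.5), 1), sample(0:3, 1), sample(0:5, 1),
            sample(0:8, 1)))
  for (i in seq_along(pool)) for (j in seq_along(pool)) {
    ab <- compareFitness(pool[[i]], pool[[j]])
    ba <- compareFitness(pool[[j]], pool[[i]])
    expect_identical(ab, switch(ba, better = "worse", worse = "better",
                                equal = "equal"))
    for (k in seq_along(pool))
      if (ab == "better" && compareFitness(pool[[j]], pool[[k]]) == "better")
        expect_identical(compareFitness(pool[[i]], pool[[k]]), "better")
  }
})

test_that("evaluateFitness counts essential nodes and caches by genome", {
  inst <- randomTrainingInstance(3)
  pkn <- inst$gold
  ess <- nodes(pkn)[1:3]
  empty <- evaluateFitness(pkn, rep(FALSE, nEdges(pkn)), inst$ts, ess)
  expect_identical(empty@nNodes, 0L)
  expect_identical(empty@nEdges, 0L)
  expect_identical(empty@nEss, 0L)
  full <- evaluateFitness(pkn, rep(TRUE, nEdges(pkn)), inst$ts, ess)
  expect_identical(full@nEdges, nEdges(pkn))
  cache <- new.env()
  f1 <- evaluateFitness(pkn, rep(TRUE, nEdges(pkn)), inst$ts, ess,
                        cache = cache)
  expect_length(ls(cache), 1L)
  f2 <- evaluateFitness(pkn, rep(TRUE, nEdges(pkn)), inst$ts, ess,
                        cache = cache)
  expect_identical(f1, f2)
})
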