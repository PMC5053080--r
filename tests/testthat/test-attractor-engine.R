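test_that("exact engine solves hand-enumerable state transition graphs", {
  ## negative self-loop: one cyclic attractor {0, 1}, average 0.5
  atts <- findAttractors(negLoop())
  expect_length(atts, 1L)
  expect_identical(stateStrings(atts[[1]]), c("0", "1"))
  expect_equal(avgState(atts[[1]]), c(A = 0.5))

  ## mutual activation: two steady states (0,0) and (1,1)
  atts <- findAttractors(toggle2())
  expect_length(atts, 2L)
  expect_identical(engineAttractorKeys(atts), c("00", "11"))
  for (a in atts) expect_true(all(avgState(a) %in% c(0, 1)))

  ## clamping removes one steady state
  atts <- findAttractors(toggle2(), perturbation(A = 1))
  expect_length(atts, 1L)
  expect_identical(attractorKey(atts[[1]]), "11")
})

test_that("exact engine equals the igraph terminal-SCC oracle on random networks", {
  for (seed in 1:30) {
    n <- 4L + seed %% 5L
    net <- randomGoldStandard(n, 2L * n, 0.3, seed = seed)
    p <- if (seed %% 3L == 0L)
      perturbation(stats::setNames(seed %% 2L, nodes(net)[1])) else perturbation()
    expect_identical(engineAttractorKeys(findAttractors(net, p)),
                     oracleAttractorKeys(net, p),
                     info = sprintf("seed %d", seed))
  }
})

test_that("every state reaches at least one attractor", {
  for (seed in 1:8) {
    net <- randomGoldStandard(5, 10, 0.3, seed = 100 + seed)
    atts <- findAttractors(net)
    attStates <- unlist(lapply(atts, states))
    for (s in .oracleStates(net)) {
      reached <- reachableAttractors(net, list(s))
      expect_gte(length(reached), 1L)
      expect_true(all(unlist(lapply(reached, states)) %in% attStates))
    }
  }
})

test_that("the state-space cap triggers an explicit refusal", {
  net <- randomGoldStandard(12, 24, 0.3, seed = 1)
  expect_error(findAttractors(net, maxFreeNodes = 10), "cap")
  expect_silent(findAttractors(net, maxFreeNodes = 12))
})

test_that("stochastic search is seed-reproducible and free of false positives", {
  for (seed in 1:10) {
    net <- randomGoldStandard(6, 12, 0.3, seed = 200 + seed)
    exact <- engineAttractorKeys(findAttractors(net))
    st1 <- findAttractors(net, engine = "stochastic",
                          params = stochasticParams(seed = seed))
    st2 <- findAttractors(net, engine = "stochastic",
                          params = stochasticParams(seed = seed))
    expect_identical(engineAttractorKeys(st1), engineAttractorKeys(st2))
    ## never a state set the exact engine rejects
    expect_true(all(engineAttractorKeys(st1) %in% exact))
  }
})

test_that("a closed attractor state set maps to itself under reachability", {
  net <- randomGoldStandard(6, 12, 0.3, seed = 42)
  for (a in findAttractors(net)) {
    reached <- reachableAttractors(net, a)
    expect_length(reached, 1L)
    expect_identical(attractorKey(reached[[1]]), attractorKey(a))
  }
})

test_that("reachable attractors match explicit STG path search", {
  net <- toggle2()
  reached <- reachableAttractors(net, list(c(A = 1L, B = 0L)))
  expect_identical(engineAttractorKeys(reached), c("00", "11"))
  for (seed in 1:10) {
    net <- randomGoldStandard(5, 10, 0.3, seed = 300 + seed)
    p <- perturbation(stats::setNames(1L, nodes(net)[2]))
    start <- .oracleStates(net)[[seed]]
    expect_identical(
      engineAttractorKeys(reachableAttractors(net, list(start), p)),
      oracleReachableKeys(net, list(start), p))
  }
})

test_that("reachability graphs are reflexive on same-perturbation transitions", {
  net <- randomGoldStandard(5, 10, 0.3, seed = 7)
  p <- perturbation()
  rg <- buildReachabilityGraph(net, list(list(p, p)))
  atts <- rg@attractorSets[["unperturbed"]]
  e <- edges(rg)
  for (a in atts)
    expect_true(any(e$fromKey == attractorKey(a) & e$toKey == attractorKey(a)))
})

test_that("a clamp funnels both toy steady states into one attractor", {
  net <- toggle2()
  rg <- buildReachabilityGraph(net, list(list(perturbation(),
                                              perturbation(A = 1))))
  expect_length(rg@attractorSets[["unperturbed"]], 2L)
  expect_length(rg@attractorSets[["A=1"]], 1L)
  e <- edges(rg)
  expect_identical(sort(e$fromKey), c("00", "11"))
  expect_identical(unique(e$toKey), "11")
})

test_that("attractor reports serialize states in node order", {
  rep <- attractorReport(negLoop())
  expect_identical(rep$attractors[[1]]$size, 2L)
  expect_identical(unlist(rep$attractors[[1]]$states), c("0", "1"))
  path <- withr::local_tempfile(fileext = ".json")
  writeAttractorReport(rep, path)
  back <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(back$attractors[[1]]$avgState$A, 0.5)
})
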