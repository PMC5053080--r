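test_that("update rule: activators OR'd, inhibition dominant, inputs hold", {
  net <- booleanNetwork(data.frame(from = c("A", "C"), to = c("B", "B"),
                                   sign = c(1L, -1L)))
  s <- c(A = 1L, B = 0L, C = 0L)
  expect_identical(targetValue(net, s, "B"), 1L)          # active activator
  s2 <- c(A = 1L, B = 1L, C = 1L)
  expect_identical(targetValue(net, s2, "B"), 0L)         # inhibitor dominates
  expect_identical(targetValue(net, s2, "A"), 1L)         # input holds
  expect_identical(targetValue(net, c(A = 0L, B = 0L, C = 0L), "A"), 0L)

  osc <- negLoop()
  expect_identical(targetValue(osc, c(A = 1L), "A"), 0L)
  expect_identical(targetValue(osc, c(A = 0L), "A"), 1L)

  ## only-inhibitor node is active iff no inhibitor is active
  inhOnly <- booleanNetwork(data.frame(from = "A", to = "B", sign = -1L))
  expect_identical(targetValue(inhOnly, c(A = 0L, B = 0L), "B"), 1L)
  expect_identical(targetValue(inhOnly, c(A = 1L, B = 1L), "B"), 0L)

  expect_error(targetValue(net, s, "Z"), "unknown node")
})

test_that("clamped nodes take their forced value", {
  net <- toggle2()
  p <- perturbation(A = 0)
  expect_identical(targetValue(net, c(A = 0L, B = 1L), "A", p), 0L)
  ## dual-sign pair between one ordered pair: inhibition dominant
  dual <- booleanNetwork(data.frame(from = c("A", "A"), to = c("B", "B"),
                                    sign = c(1L, -1L)))
  expect_identical(targetValue(dual, c(A = 1L, B = 0L), "B"), 0L)
  expect_identical(targetValue(dual, c(A = 0L, B = 1L), "B"), 0L)
})

test_that("asynchronous successors flip exactly one non-clamped node", {
  net <- toggle2()
  succ <- asyncSuccessors(net, c(A = 1L, B = 0L))
  keys <- sort(vapply(succ, function(s) paste(s[c("A", "B")], collapse = ""),
                      character(1)))
  expect_identical(keys, c("00", "11"))
  expect_length(asyncSuccessors(net, c(A = 1L, B = 1L)), 0L)  # fixed point
  succOsc <- asyncSuccessors(negLoop(), c(A = 0L))
  expect_identical(succOsc[[1]][["A"]], 1L)
  expect_error(asyncSuccessors(net, c(A = 1L, B = 0L), perturbation(A = 0)),
               "inconsistent")
})

test_that("successor states are at Hamming distance 1 and respect clamps", {
  for (seed in 1:5) {
    net <- randomGoldStandard(6, 12, 0.3, seed = seed)
    p <- perturbation(stats::setNames(seed %% 2L, nodes(net)[1]))
    allStates <- .oracleStates(net, p)
    for (s in allStates[seq(1, length(allStates), by = 5)]) {
      for (s2 in asyncSuccessors(net, s, p)) {
        expect_identical(sum(s != s2), 1L)
        expect_identical(s2[names(p)], stats::setNames(p, names(p)))
      }
    }
  }
})

test_that("subnetwork keeps exactly the requested PKN edges", {
  pkn <- booleanNetwork(data.frame(from = c("A", "B", "C"),
                                   to = c("B", "C", "A"),
                                   sign = c(1L, 1L, -1L)))
  expect_identical(subnetwork(pkn, rep(TRUE, 3)), pkn)
  empty <- subnetwork(pkn, rep(FALSE, 3))
  expect_identical(nNodes(empty), 0L)
  expect_identical(nEdges(empty), 0L)
  one <- subnetwork(pkn, c(TRUE, FALSE, FALSE))
  expect_identical(nodes(one), c("A", "B"))
  expect_identical(nEdges(one), 1L)
  expect_error(subnetwork(pkn, data.frame(from = "A", to = "C", sign = 1L)),
               "not present in the PKN")
})

test_that("edge-list text format round-trips, including isolated nodes", {
  net <- booleanNetwork(data.frame(from = c("A", "B"), to = c("B", "A"),
                                   sign = c(1L, -1L)), nodes = "LONER_1")
  path <- withr::local_tempfile(fileext = ".net")
  writeBooleanNetwork(net, path)
  expect_identical(readBooleanNetwork(path), net)
  ## deterministic sorted edge lines
  edgeLines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  expect_identical(edgeLines, sort(edgeLines))

  bad <- withr::local_tempfile(fileext = ".net")
  writeLines(c("A -> B", "A -*> C"), bad)
  expect_error(readBooleanNetwork(bad), ":2:")
})

test_that("network validity rejects malformed objects", {
  expect_error(booleanNetwork(data.frame(from = "a b", to = "C", sign = 1L)),
               "A-Za-z0-9_")
  expect_error(booleanNetwork(data.frame(from = "A", to = "B", sign = 2L)))
  ## duplicates are collapsed, not duplicated
  net <- booleanNetwork(data.frame(from = c("A", "A"), to = c("B", "B"),
                                   sign = c(1L, 1L)))
  expect_identical(nEdges(net), 1L)
})
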