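# Shared desk-scale benchmark fixtures.
#
# The optimization benchmark follows the standard in-silico evaluation
# design at desk scale: a random gold standard, its ideal PKN derived from the
# single-node-perturbation transition table, and a training set measuring
# several knock-out backgrounds (mutants) under over-expression stimuli,
# starting from the all-inactive state, with every node essential.

benchmarkTrainingSet <- function(gold, rich = TRUE) {
  nd <- nodes(gold)
  backgrounds <- if (rich)
    list(perturbation(),
         perturbation(stats::setNames(0L, nd[4])),
         perturbation(stats::setNames(0L, nd[5])),
         perturbation(stats::setNames(0L, nd[6])),
         perturbation(stats::setNames(c(0L, 0L), nd[c(4, 6)])))
  else
    list(perturbation(), perturbation(stats::setNames(0L, nd[4])))
  generateTrainingSet(
    gold, backgrounds,
    stimuli = list(perturbation(stats::setNames(1L, nd[1])),
                   perturbation(stats::setNames(1L, nd[2])),
                   perturbation(stats::setNames(c(1L, 1L), nd[c(1, 2)]))),
    initialState = stats::setNames(rep(0L, length(nd)), nd),
    essentialNodes = nd)
}

# 10-node gold standard whose ideal PKN has 66 edges: large enough that
# random 0.5-subnetworks essentially never reproduce the training set, small
# enough for the exact engine throughout
optimizationBenchmark <- function() {
  gold <- randomGoldStandard(10, 25, 0.3, seed = 7)
  pkn <- buildPKN(buildTransitionTable(gold), gold)
  list(gold = gold, pkn = pkn, ts = benchmarkTrainingSet(gold),
       ess = nodes(gold))
}
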