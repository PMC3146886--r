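# Summaries, consensus, ROC/AUC and convergence diagnostics.

collectionFixture <- function() {
  nodes <- c("A", "B", "C")
  base <- netFromEdges(nodes, list(c("A", "B", 1), c("B", "C", -1)))
  other <- netFromEdges(nodes, list(c("A", "B", 1)))
  third <- netFromEdges(nodes, list(c("A", "B", -1), c("B", "C", -1)))
  list(nodes = nodes, nets = list(base, other, third))
}

test_that("edge frequencies sum to one and recount the collection", {
  fx <- collectionFixture()
  ft <- edgeFrequencyTable(fx$nets)
  expect_equal(ft$activation + ft$inhibition + ft$none,
               matrix(1, 3, 3, dimnames = list(fx$nodes, fx$nodes)),
               tolerance = 1e-12)
  expect_equal(ft$activation["A", "B"], 2 / 3)
  expect_equal(ft$inhibition["A", "B"], 1 / 3)
  expect_equal(ft$inhibition["B", "C"], 2 / 3)
  expect_equal(ft$none["C", "A"], 1)
})

test_that("threshold summarisation follows the inclusion rule", {
  fx <- collectionFixture()
  # all networks identical, th = 1 -> that network
  same <- replicate(4, fx$nets[[1]], simplify = FALSE)
  expect_identical(adjacency(summariseNetworks(same, 1)),
                   adjacency(fx$nets[[1]]))
  # activation 2/3: included at th = 0.5, excluded at th = 0.7
  expect_identical(adjacency(summariseNetworks(fx$nets, 0.5))["A", "B"], 1L)
  expect_identical(adjacency(summariseNetworks(fx$nets, 0.7))["A", "B"], 0L)
  # th = 0: every pair takes its modal nonzero type if any network has it
  s0 <- adjacency(summariseNetworks(fx$nets, 0))
  expect_identical(s0["A", "B"], 1L)
  expect_identical(s0["B", "C"], -1L)
  expect_identical(s0["C", "A"], 0L)
  # monotone in th, per edge type
  set.seed(14)
  mats <- replicate(9, randomAdjacency(4, 0.4), simplify = FALSE)
  ths <- seq(0, 1, by = 0.1)
  prev <- NULL
  for (th in rev(ths)) {
    cur <- adjacency(summariseNetworks(mats, th))
    if (!is.null(prev)) {
      # edges present at the higher threshold survive at the lower one
      expect_true(all(cur[prev != 0L] == prev[prev != 0L]))
    }
    prev <- cur
  }
})

test_that("ROC against the truth behaves at its extremes", {
  truth <- netFromEdges(c("A", "B", "C"),
                        list(c("A", "B", 1), c("C", "B", -1)))
  # collection = {truth} gives AUC 1
  roc <- rocAuc(replicate(5, truth, simplify = FALSE), truth)
  expect_equal(roc$auc, 1)
  expect_true(all(roc$points$TPR >= 0 & roc$points$TPR <= 1))
  # truth without edges is undefined
  expect_error(rocAuc(list(truth), netFromEdges(c("A", "B", "C"))),
               "no edges")
  # label-randomised collections give AUC near 1/2 on average
  set.seed(25)
  aucs <- vapply(1:200, function(k) {
    truth <- SignedNetwork(randomAdjacency(5, 0.3))
    mats <- replicate(12, randomAdjacency(5, 0.3), simplify = FALSE)
    rocAuc(mats, truth)$auc
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  expect_true(all(aucs >= 0 & aucs <= 1))
})

test_that("trapezoid AUC agrees with a fine rectangle refinement", {
  set.seed(26)
  mats <- replicate(15, randomAdjacency(4, 0.4), simplify = FALSE)
  truth <- SignedNetwork(randomAdjacency(4, 0.4))
  while (sum(adjacency(truth) != 0) == 0)
    truth <- SignedNetwork(randomAdjacency(4, 0.4))
  roc <- rocAuc(mats, truth)
  xy <- unique(rbind(c(0, 0), cbind(roc$points$FPR, roc$points$TPR), c(1, 1)))
  xy <- xy[order(xy[, 1], xy[, 2]), , drop = FALSE]
  # midpoint-rectangle refinement of every linear segment of the curve
  rectangle <- 0
  for (s in seq_len(nrow(xy) - 1)) {
    x0 <- xy[s, 1]; x1 <- xy[s + 1, 1]
    if (x1 == x0) next
    mids <- seq(x0, x1, length.out = 1001)
    mids <- (head(mids, -1) + tail(mids, -1)) / 2
    yMid <- xy[s, 2] + (mids - x0) / (x1 - x0) * (xy[s + 1, 2] - xy[s, 2])
    rectangle <- rectangle + sum(yMid) * (x1 - x0) / 1000
  }
  expect_equal(roc$auc, rectangle, tolerance = 1e-9)
})

test_that("consensus follows majority rule with posterior tie-breaking", {
  nodes <- c("A", "B")
  act <- netFromEdges(nodes, list(c("A", "B", 1)))
  inh <- netFromEdges(nodes, list(c("A", "B", -1)))
  non <- netFromEdges(nodes)
  # 6 activation, 3 none, 1 inhibition -> activation
  cons <- consensusNetwork(c(replicate(6, act, simplify = FALSE),
                             replicate(3, non, simplify = FALSE),
                             list(inh)))
  expect_identical(adjacency(cons)["A", "B"], 1L)
  # single summary -> itself
  expect_identical(adjacency(consensusNetwork(list(inh))), adjacency(inh))
  # 5 vs 5 tie resolved by the larger posterior-frequency average
  ftOf <- function(fAct, fInh) {
    structure(list(
      activation = matrix(c(0, 0, fAct, 0), 2, 2,
                          dimnames = list(nodes, nodes)),
      inhibition = matrix(c(0, 0, fInh, 0), 2, 2,
                          dimnames = list(nodes, nodes)),
      none = matrix(c(1, 1, 1 - fAct - fInh, 1), 2, 2,
                    dimnames = list(nodes, nodes)),
      n = 10, nodes = nodes), class = "edgeFrequencyTable")
  }
  summaries <- c(replicate(5, act, simplify = FALSE),
                 replicate(5, inh, simplify = FALSE))
  freqs <- c(replicate(5, ftOf(0.9, 0.1), simplify = FALSE),
             replicate(5, ftOf(0.2, 0.6), simplify = FALSE))
  cons <- consensusNetwork(summaries, freqs)
  expect_identical(adjacency(cons)["A", "B"], 1L)   # 0.9 beats 0.6
  freqs <- c(replicate(5, ftOf(0.5, 0.1), simplify = FALSE),
             replicate(5, ftOf(0.2, 0.8), simplify = FALSE))
  cons <- consensusNetwork(summaries, freqs)
  expect_identical(adjacency(cons)["A", "B"], -1L)  # 0.8 beats 0.5
  # a tie without posterior information is an error naming the pair
  expect_error(consensusNetwork(summaries), "A -> B")
  # consensus of identical summaries is that summary, for any count
  for (k in c(1, 2, 7))
    expect_identical(
      adjacency(consensusNetwork(replicate(k, act, simplify = FALSE))),
      adjacency(act))
})

test_that("cross-chain diagnostics flag disagreeing edges", {
  fx <- simFixture(N = 4, seed = 33)
  tr1 <- runMCMC(fx$data, NULL, nIter = 100, burnin = 20, thin = 5, seed = 1)
  rep1 <- mcmcDiagnostics(list(tr1, tr1))
  expect_identical(nrow(rep1$flagged), 0L)
  expect_true(all(rep1$variance$activation == 0))
  expect_identical(ncol(rep1$posterior), 2L)
  # frequencies recomputed by the oracle recount
  ft <- edgeFrequencyTable(tr1@networks)
  expect_equal(rep1$edgeFrequencies[[1]]$activation, ft$activation)

  # chains stuck on opposite networks disagree maximally
  mk <- function(a) new("McmcTrace",
    steps = data.frame(iteration = 1:4, logLik = 0, logPrior = 0,
                       posterior = 0, move = "delete", accepted = FALSE),
    networks = replicate(4, a, simplify = FALSE), params = list())
  nodes <- c("A", "B")
  aAct <- matrix(c(0L, 0L, 1L, 0L), 2, 2, dimnames = list(nodes, nodes))
  aInh <- matrix(c(0L, 0L, -1L, 0L), 2, 2, dimnames = list(nodes, nodes))
  rep2 <- mcmcDiagnostics(list(mk(aAct), mk(aInh)))
  expect_identical(nrow(rep2$flagged), 1L)
  expect_identical(rep2$flagged$source, "A")
  expect_identical(rep2$flagged$target, "B")
  expect_equal(rep2$flagged$maxVariance, 0.5)
  # per-chain signed edge counts
  expect_equal(rep2$edgeCounts$nActivation[rep2$edgeCounts$chain == 1],
               rep(1L, 4))
  expect_equal(rep2$edgeCounts$nInhibition[rep2$edgeCounts$chain == 2],
               rep(1L, 4))
})

test_that("likelihood/prior ratio diagnostics support lambda tuning", {
  mkTrace <- function(logLik, logPrior) new("McmcTrace",
    steps = data.frame(iteration = seq_along(logLik), logLik = logLik,
                       logPrior = logPrior,
                       posterior = logLik + logPrior,
                       move = "delete", accepted = TRUE),
    networks = list(), params = list())
  # constant chain: both difference series are identically zero
  flat <- ratioDiagnostics(mkTrace(rep(-10, 6), rep(-3, 6)))
  expect_identical(length(flat$likelihoodDiff), 5L)
  expect_true(all(flat$likelihoodDiff == 0) && all(flat$priorDiff == 0))
  expect_false(flat$rescaleFlag)

  # lambda = 1e-3 with unit mismatches: prior swings of ~1e3 dwarf
  # likelihood swings of ~10 and trip the rescale heuristic
  set.seed(41)
  ll <- cumsum(rnorm(200, sd = 10))
  lp <- cumsum(sample(c(-1e3, 1e3), 200, replace = TRUE))
  diag <- ratioDiagnostics(mkTrace(ll, lp))
  expect_identical(length(diag$priorDiff), 199L)
  expect_gt(diag$priorScale / diag$likelihoodScale, 10)
  expect_true(diag$rescaleFlag)
  expect_gt(diag$suggestedLambdaFactor, 10)
})
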