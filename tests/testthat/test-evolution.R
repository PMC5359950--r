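# GTR model construction, transition probabilities, column simulation.

test_that("base frequencies come from anchor composition, N excluded", {
  expect_equal(unname(baseFrequencies(genomeFromString("AACG"))),
               c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(baseFrequencies(genomeFromString("ACGTN"))),
               rep(0.25, 4))
  # a genome built at the Listeria-composition fractions reproduces them
  counts <- LISTERIA_FREQS * 1e6
  expect_true(all(counts == round(counts)))  # fractions are exact at 1e6
  s <- paste0(strrep("A", counts[1]), strrep("C", counts[2]),
              strrep("G", counts[3]), strrep("T", counts[4]))
  expect_equal(unname(baseFrequencies(genomeFromString(s))), LISTERIA_FREQS)
})

test_that("GTR construction: JC limit, detailed balance, rate ratios", {
  jc <- buildGTR(rep(1, 6), rep(0.25, 4))
  off <- jc@Q[row(jc@Q) != col(jc@Q)]
  expect_equal(off, rep(1 / 3, 12))

  m <- buildGTR(LISTERIA_RATES, LISTERIA_FREQS)
  # detailed balance pi_i Q_ij = pi_j Q_ji for all pairs
  pi <- m@freqs
  for (i in 1:4) for (j in 1:4)
    expect_equal(unname(pi[i] * m@Q[i, j]), unname(pi[j] * m@Q[j, i]),
                 tolerance = 1e-12)
  # scaling: one expected substitution per site per unit branch length
  expect_equal(-sum(pi * diag(m@Q)), 1, tolerance = 1e-12)

  u <- buildGTR(LISTERIA_RATES, rep(0.25, 4))
  expect_equal(u@Q["A", "G"] / u@Q["G", "T"], 5.9306, tolerance = 1e-10)

  expect_error(buildGTR(c(0, 1, 1, 1, 1, 1), rep(0.25, 4)))
  expect_silent(buildGTR(rep(1, 6), c(0.5, 0.5, 0, 0)))  # zero freq allowed
})

test_that("transition probabilities: identity, JC closed form, stationarity", {
  m <- buildGTR(LISTERIA_RATES, LISTERIA_FREQS)
  expect_equal(unname(transitionProbs(m, 0)), diag(4))

  jc <- buildGTR(rep(1, 6), rep(0.25, 4))
  P <- transitionProbs(jc, 0.75)
  expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-1), 4),
               tolerance = 1e-8)

  Pinf <- transitionProbs(m, 100)
  for (i in 1:4)
    expect_lt(max(abs(Pinf[i, ] - m@freqs)), 1e-6)
  expect_error(transitionProbs(m, -1))
})

test_that("column simulation matches closed forms on degenerate trees", {
  jc <- buildGTR(rep(1, 6), rep(0.25, 4))
  flat <- treeFromNewick("((A:0,B:0):0,C:0);", "A")
  cols <- simulateColumns(jc, flat, 500)
  expect_false(any(cols$variable))
  expect_true(all(cols$tips[, "A"] == cols$tips[, "C"]))

  two <- treeFromNewick("(A:0.1,B:0.1);", "A")
  set.seed(11)
  cols <- simulateColumns(jc, two, 100000)
  pDiff <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  expect_lt(abs(mean(cols$variable) - pDiff), 0.005)
})

test_that("tip-pattern distribution is invariant to the anchor choice", {
  m <- buildGTR(LISTERIA_RATES, LISTERIA_FREQS)
  nwk <- "((A:0.12,B:0.3):0.05,C:0.2);"
  pA <- enumPatternProbs(m, treeFromNewick(nwk, "A"))
  pB <- enumPatternProbs(m, treeFromNewick(nwk, "B"))
  pC <- enumPatternProbs(m, treeFromNewick(nwk, "C"))
  expect_lt(max(abs(pA - pB)), 1e-10)
  expect_lt(max(abs(pA - pC)), 1e-10)

  # and simulation agrees with the enumeration on the 3-tip tree
  set.seed(21)
  cols <- simulateColumns(m, treeFromNewick(nwk, "B"), 50000)
  counts <- tabulate(patternIndex(cols$tips), nbins = 64)
  expect_gt(chisqPatterns(counts, pA), 0.001)
})

test_that("variable-column probability increases with path length", {
  m <- buildGTR(LISTERIA_RATES, LISTERIA_FREQS)
  pVar <- vapply(c(0.02, 0.05, 0.1, 0.3, 0.8, 2), function(t) {
    P <- transitionProbs(m, t)
    1 - sum(m@freqs * diag(P))
  }, numeric(1))
  expect_true(all(diff(pVar) > 0))
})
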