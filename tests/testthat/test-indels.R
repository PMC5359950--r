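# Lavalette sampler and branch indel events.

test_that("Lavalette pmf matches brute-force normalisation", {
  expect_equal(lavalettePmf(1.7, 1), 1)
  expect_true(all(sampleLavalette(100, 1.7, 1) == 1L))

  # two-point case by hand: w_L = (L*M/(M-L+1))^(-a)
  w <- c((1 * 2 / 2)^(-1.7), (2 * 2 / 1)^(-1.7))
  expect_equal(lavalettePmf(1.7, 2), w / sum(w), tolerance = 1e-12)
  expect_equal(lavalettePmf(1.7, 2)[1], 1 / (1 + 4^(-1.7)),
               tolerance = 1e-12)

  set.seed(2)
  draws <- sampleLavalette(100000, 1.7, 2)
  expect_lt(abs(mean(draws == 1L) - w[1] / sum(w)), 0.005)

  # samples respect the maximum and cover the support
  set.seed(7)
  big <- sampleLavalette(100000, 1.7, 541)
  expect_lte(max(big), 541L)
  expect_gte(min(big), 1L)
  counts <- tabulate(big, nbins = 541)
  expect_gt(chisqPatterns(counts, lavalettePmf(1.7, 541)), 0.001)
})

test_that("indel event counts scale with the SNP count", {
  fx <- generateFixture(10, 100000, seed = 4)
  m <- buildGTR(rep(1, 6), baseFrequencies(fx$genome))
  set.seed(1)
  plan <- placeUniform(fx$genome, 500)

  set.seed(99)
  expect_equal(nrow(simulateIndelEvents(fx$tree, 500, 0, 0, 1.7, 100,
                                        fx$genome, plan, m)), 0L)

  totals <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    ev <- simulateIndelEvents(fx$tree, 500, 0.1, 0.1, 1.7, 100,
                              fx$genome, plan, m)
    nrow(ev)
  }, numeric(1))
  se <- sqrt(100 / 50)   # Poisson(100) mean over 50 runs
  expect_lt(abs(mean(totals) - 100), 3 * se)
})

test_that("events never touch the anchor, SNP sites or contig boundaries", {
  fa <- tempfile(fileext = ".fasta")
  set.seed(3)
  writeLines(c(">c1", paste(sample(c("A", "C", "G", "T"), 4000, TRUE),
                            collapse = ""),
               ">c2", paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                            collapse = "")), fa)
  g <- loadGenome(fa)
  fx <- generateFixture(8, 100, seed = 6)   # tree only
  m <- buildGTR(rep(1, 6), rep(0.25, 4))
  set.seed(10)
  plan <- placeUniform(g, 200)
  ev <- simulateIndelEvents(fx$tree, 200, 0.3, 0.3, 1.7, 60, g, plan, m)
  expect_gt(nrow(ev), 0)

  anchor <- anchorTip(fx$tree)
  carriers <- strsplit(ev$tips, ",", fixed = TRUE)
  expect_false(any(vapply(carriers, function(x) anchor %in% x, logical(1))))

  w <- Biostrings::width(contigs(g))
  dels <- ev[ev$kind == "deletion", ]
  expect_true(all(dels$pos0 >= 0 & dels$pos0 + dels$length <= w[dels$contig]))
  snpKey <- paste(sitePositions(plan)$contig, sitePositions(plan)$pos0)
  for (i in seq_len(nrow(dels)))
    expect_false(any(paste(dels$contig[i],
                           dels$pos0[i]:(dels$pos0[i] + dels$length[i] - 1))
                     %in% snpKey))
  ins <- ev[ev$kind == "insertion", ]
  expect_true(all(!is.na(ins$seq) & nchar(ins$seq) == ins$length))
  expect_true(all(strsplit(paste(ins$seq, collapse = ""), NULL)[[1]]
                  %in% c("A", "C", "G", "T")))
  expect_false(any(paste(ins$contig, ins$pos0) %in% snpKey |
                   paste(ins$contig, ins$pos0 + 1) %in% snpKey))
  # anchor spans disjoint so the truth alignment is exactly invertible
  spans <- rbind(
    if (nrow(dels)) cbind(dels$contig, dels$pos0,
                          dels$pos0 + dels$length - 1),
    if (nrow(ins)) cbind(ins$contig, ins$pos0, ins$pos0 + 1))
  spans <- spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
  same <- spans[-1, 1] == spans[-nrow(spans), 1]
  expect_true(all(spans[-1, 2][same] > spans[-nrow(spans), 3][same]))
})

test_that("insertion inheritance follows the branch's subtree", {
  g <- genomeFromString(strrep("ACGT", 10))
  tr <- treeFromNewick("((A:0.1,(B:0.1,C:0.1):0.1):0.1,D:0.1);", "A")
  # hand-built event on the branch subtending {B, C}
  ev <- data.frame(kind = "insertion", node = 0L, contig = 1L, pos0 = 9L,
                   length = 3L, seq = "TTT", tips = "B,C")
  sites <- new("MutationSites",
               sites = data.frame(contig = integer(0), pos0 = integer(0),
                                  anchorBase = character(0),
                                  clustered = logical(0)),
               tipBases = matrix(character(0), 0, 4,
                                 dimnames = list(NULL, tipLabels(tr))),
               anchor = "A")
  lens <- vapply(tipLabels(tr), function(tip)
    sum(Biostrings::width(buildTipGenome(g, tip, sites, ev)@contigs)),
    numeric(1))
  expect_equal(unname(lens[c("B", "C")]), c(43, 43))
  expect_equal(unname(lens[c("A", "D")]), c(40, 40))
  b <- buildTipGenome(g, "B", sites, ev)
  expect_equal(substr(as.character(b@contigs[[1]]), 10, 14), "CTTTG")
})
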