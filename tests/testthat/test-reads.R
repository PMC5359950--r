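# Paired-end read simulation and FASTQ output.

test_that("pair counts follow the coverage arithmetic", {
  p <- readProfile(readLength = 250, coverage = 20)
  expect_equal(nPairsForCoverage(100000, p), 4000L)
  p40 <- readProfile(readLength = 250, coverage = 40)
  expect_equal(nPairsForCoverage(100000, p40), 8000L)
  tiny <- readProfile(readLength = 250, coverage = 0.001)
  expect_warning(n0 <- nPairsForCoverage(100000, tiny), "zero read pairs")
  expect_equal(n0, 0L)
})

test_that("error-free reads are exact substrings of the source genome", {
  fx <- generateFixture(2, 20000, seed = 40)
  g <- new("TipGenome", tipName = "t", contigs = contigs(fx$genome),
           provenance = list())
  prof <- readProfile(readLength = 100, coverage = 2, fragmentMean = 300,
                      fragmentSd = 20, errorModel = "flat:0")
  set.seed(41)
  pairs <- simulateReadPairs(g, prof)
  expect_equal(length(pairs$seq1), nPairsForCoverage(20000, prof))
  expect_true(all(nchar(pairs$seq1) == 100))
  expect_true(all(nchar(pairs$qual1) == 100))
  genomeStr <- as.character(contigs(fx$genome)[[1]])
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(s)))
  hit1 <- vapply(pairs$seq1, function(s) grepl(s, genomeStr, fixed = TRUE),
                 logical(1)) |
    vapply(rc(pairs$seq1), function(s) grepl(s, genomeStr, fixed = TRUE),
           logical(1))
  expect_true(all(hit1))
  hit2 <- vapply(pairs$seq2, function(s) grepl(s, genomeStr, fixed = TRUE),
                 logical(1)) |
    vapply(rc(pairs$seq2), function(s) grepl(s, genomeStr, fixed = TRUE),
           logical(1))
  expect_true(all(hit2))
})

test_that("flat error model reproduces the configured mismatch rate", {
  fx <- generateFixture(2, 50000, seed = 42)
  g <- new("TipGenome", tipName = "t", contigs = contigs(fx$genome),
           provenance = list())
  prof <- readProfile(readLength = 100, coverage = 20, fragmentMean = 300,
                      fragmentSd = 0, errorModel = "flat:0.01")
  set.seed(43)
  pairs <- simulateReadPairs(g, prof)
  # read names encode contig:start:end:strand; rebuild the true reads
  genomeSeq <- contigs(fx$genome)[[1]]
  meta <- do.call(rbind, strsplit(pairs$names, ":"))
  start <- as.integer(meta[, 3]); end <- as.integer(meta[, 4])
  frag <- Biostrings::extractAt(genomeSeq,
                                IRanges::IRanges(start, end))
  minus <- meta[, 5] == "R"
  frag[minus] <- Biostrings::reverseComplement(frag[minus])
  expect_true(all(end - start + 1L == 300L))  # sd 0: exact fragment length
  true1 <- as.character(Biostrings::subseq(frag, 1, 100))
  mism <- sum(mapply(function(a, b)
    sum(charToRaw(a) != charToRaw(b)), pairs$seq1, true1))
  nCycles <- length(true1) * 100
  se <- sqrt(0.01 * 0.99 / nCycles)
  expect_lt(abs(mism / nCycles - 0.01), 3 * se)
})

test_that("realized depth matches the configured coverage", {
  fx <- generateFixture(2, 100000, seed = 44)
  g <- new("TipGenome", tipName = "t", contigs = contigs(fx$genome),
           provenance = list())
  for (cov in c(20, 40)) {
    prof <- readProfile(readLength = 250, coverage = cov)
    n <- nPairsForCoverage(100000, prof)
    set.seed(11)
    pairs <- simulateReadPairs(g, prof)
    realized <- sum(nchar(pairs$seq1)) + sum(nchar(pairs$seq2))
    realized <- realized / 100000
    expect_lt(abs(realized - cov), 0.05)
  }
})

test_that("FASTQ output is well-formed, matched and deterministic", {
  fx <- generateFixture(2, 10000, seed = 45)
  g <- new("TipGenome", tipName = "tipA", contigs = contigs(fx$genome),
           provenance = list())
  prof <- readProfile(readLength = 80, coverage = 1.6, fragmentMean = 200,
                      fragmentSd = 10)
  set.seed(46)
  pairs <- simulateReadPairs(g, prof, nPairs = 100)
  out <- tempfile("fq")
  paths <- writeFastqPairs(pairs, out, "tipA")
  l1 <- readLines(gzfile(paths[1])); l2 <- readLines(gzfile(paths[2]))
  expect_length(l1, 400)
  expect_length(l2, 400)
  ids1 <- sub("/1$", "", l1[seq(1, 400, 4)])
  ids2 <- sub("/2$", "", l2[seq(1, 400, 4)])
  expect_identical(ids1, ids2)          # mates in matched order
  expect_false(anyDuplicated(ids1) > 0)
  expect_true(all(l1[seq(3, 400, 4)] == "+"))

  # zero pairs produce two valid empty gzip files
  none <- simulateReadPairs(g, prof, nPairs = 0)
  p0 <- writeFastqPairs(none, tempfile("fq0"), "tipA")
  expect_length(readLines(gzfile(p0[1])), 0)

  # seeded determinism: identical bytes across repeated simulation
  o1 <- tempfile("d1"); o2 <- tempfile("d2")
  set.seed(47); writeFastqPairs(simulateReadPairs(g, prof, 50), o1, "tipA")
  set.seed(47); writeFastqPairs(simulateReadPairs(g, prof, 50), o2, "tipA")
  expect_identical(
    unname(tools::md5sum(file.path(o1, "fastq", "tipA", "tipA_R1.fastq.gz"))),
    unname(tools::md5sum(file.path(o2, "fastq", "tipA", "tipA_R1.fastq.gz"))))
})
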