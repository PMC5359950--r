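# Tip genome materialisation, truth VCF, alignment reconstruction.

emptyEvents <- function() {
  data.frame(kind = character(0), node = integer(0), contig = integer(0),
             pos0 = integer(0), length = integer(0), seq = character(0),
             tips = character(0))
}

siteFixture <- function() {
  g <- genomeFromString("AAAA")
  tr <- treeFromNewick("(X:0.1,Y:0.1);", "Y")
  sites <- new("MutationSites",
               sites = data.frame(contig = 1L, pos0 = 1L, anchorBase = "A",
                                  clustered = FALSE),
               tipBases = matrix(c("G", "A"), 1, 2,
                                 dimnames = list(NULL, c("X", "Y"))),
               anchor = "Y")
  list(g = g, tr = tr, sites = sites)
}

test_that("substitutions and deletions edit the right coordinates", {
  f <- siteFixture()
  x <- buildTipGenome(f$g, "X", f$sites, emptyEvents())
  expect_equal(as.character(x@contigs[[1]]), "AGAA")
  y <- buildTipGenome(f$g, "Y", f$sites, emptyEvents())
  expect_equal(as.character(y@contigs[[1]]), "AAAA")

  del <- data.frame(kind = "deletion", node = 0L, contig = 1L, pos0 = 1L,
                    length = 2L, seq = NA_character_, tips = "X")
  noSites <- new("MutationSites",
                 sites = f$sites@sites[0, ],
                 tipBases = matrix(character(0), 0, 2,
                                   dimnames = list(NULL, c("X", "Y"))),
                 anchor = "Y")
  xd <- buildTipGenome(f$g, "X", noSites, del)
  expect_equal(as.character(xd@contigs[[1]]), "AA")
})

test_that("per-tip genome lengths obey signed event conservation", {
  fx <- generateFixture(8, 30000, seed = 20)
  m <- buildGTR(rep(1, 6), baseFrequencies(fx$genome))
  set.seed(30)
  plan <- placeUniform(fx$genome, 60)
  demand <- table(anchorsim:::planAnchorBases(plan, fx$genome))
  pool <- buildColumnPool(m, fx$tree,
                          setNames(as.integer(demand), names(demand)))
  sites <- assignSites(plan, fx$genome, pool, fx$tree)
  ev <- simulateIndelEvents(fx$tree, 60, 0.3, 0.3, 1.7, 80, fx$genome,
                            plan, m)
  carriers <- strsplit(ev$tips, ",", fixed = TRUE)
  for (tip in tipLabels(fx$tree)) {
    tg <- buildTipGenome(fx$genome, tip, sites, ev)
    mine <- vapply(carriers, function(x) tip %in% x, logical(1))
    signed <- sum(ifelse(ev$kind[mine] == "insertion", 1L, -1L) *
                    ev$length[mine])
    expect_equal(sum(Biostrings::width(tg@contigs)),
                 totalLength(fx$genome) + signed, info = tip)
  }
})

test_that("truth VCF uses 1-based coordinates and haploid genotypes", {
  g <- generateFixture(2, 200, seed = 2)$genome
  tr <- treeFromNewick("(X:0.2,Y:0.2);", "Y")
  ref99 <- as.character(Biostrings::extractAt(
    contigs(g)[[1]], IRanges::IRanges(100, 100)))
  alt <- setdiff(c("A", "C", "G", "T"), ref99)[1]
  sites <- new("MutationSites",
               sites = data.frame(contig = 1L, pos0 = 99L,
                                  anchorBase = ref99, clustered = FALSE),
               tipBases = matrix(c(alt, ref99), 1, 2,
                                 dimnames = list(NULL, c("X", "Y"))),
               anchor = "Y")
  vcf <- tempfile(fileext = ".vcf")
  writeTruthVcf(sites, g, vcf)
  lines <- readLines(vcf)
  rec <- strsplit(lines[!grepl("^#", lines)], "\t")[[1]]
  expect_equal(rec[2], "100")
  expect_equal(rec[4], ref99)
  expect_equal(rec[5], alt)
  expect_equal(rec[10:11], c("1", "0"))  # X carries the alt, anchor Y is 0

  # header-only VCF is accepted by an independent reader
  empty <- new("MutationSites", sites = sites@sites[0, ],
               tipBases = matrix(character(0), 0, 2,
                                 dimnames = list(NULL, c("X", "Y"))),
               anchor = "Y")
  vcf0 <- tempfile(fileext = ".vcf")
  writeTruthVcf(empty, g, vcf0)
  v <- vcfR::read.vcfR(vcf0, verbose = FALSE)
  expect_equal(nrow(v@fix), 0L)
})

test_that("tip FASTA output round-trips and the anchor equals the input", {
  fx <- generateFixture(10, 5000, seed = 14)
  m <- buildGTR(rep(1, 6), baseFrequencies(fx$genome))
  set.seed(15)
  plan <- placeUniform(fx$genome, 40)
  demand <- table(anchorsim:::planAnchorBases(plan, fx$genome))
  pool <- buildColumnPool(m, fx$tree,
                          setNames(as.integer(demand), names(demand)))
  sites <- assignSites(plan, fx$genome, pool, fx$tree)
  genomes <- lapply(tipLabels(fx$tree), function(tip)
    buildTipGenome(fx$genome, tip, sites, emptyEvents()))
  out <- tempfile("fasta")
  paths <- writeTipFastas(genomes, out, "sim")
  expect_length(paths, 10)
  expect_length(list.dirs(file.path(out, "fasta"), recursive = FALSE), 10)
  for (i in seq_along(genomes)) {
    back <- Biostrings::readDNAStringSet(paths[i])
    expect_identical(as.character(back[[1]]),
                     as.character(genomes[[i]]@contigs[[1]]))
  }
  anchorBack <- Biostrings::readDNAStringSet(paths[anchorTip(fx$tree)])
  expect_identical(as.character(anchorBack[[1]]),
                   as.character(contigs(fx$genome)[[1]]))
})

test_that("alignment agrees with the VCF genotypes and the event log", {
  fx <- generateFixture(6, 20000, seed = 31)
  m <- buildGTR(LISTERIA_RATES, baseFrequencies(fx$genome))
  set.seed(32)
  plan <- placeUniform(fx$genome, 80)
  demand <- table(anchorsim:::planAnchorBases(plan, fx$genome))
  pool <- buildColumnPool(m, fx$tree,
                          setNames(as.integer(demand), names(demand)))
  sites <- assignSites(plan, fx$genome, pool, fx$tree)
  ev <- simulateIndelEvents(fx$tree, 80, 0.2, 0.2, 1.7, 50, fx$genome,
                            plan, m)
  aln <- buildAlignment(fx$genome, fx$tree, sites, ev)

  expect_equal(countVariableColumns(aln), 80)

  # genotype consistency: the alignment base at each site's anchor-indexed
  # column equals the recorded tip base (no deletion can cover a site)
  a <- aln[[1]]
  anchorRow <- charToRaw(as.character(a[[anchorTip(fx$tree)]]))
  colOfAnchorPos <- which(anchorRow != charToRaw("-"))
  st <- siteTable(sites)
  for (tip in tipLabels(fx$tree)) {
    row <- as.character(a[[tip]])
    got <- substring(row, colOfAnchorPos[st$pos0 + 1],
                     colOfAnchorPos[st$pos0 + 1])
    expect_identical(got, unname(tipBases(sites)[, tip]), info = tip)
  }

  # gap structure inverts exactly to the simulated events
  der <- deriveEventsFromAlignment(aln, anchorTip(fx$tree))
  expect_equal(eventLogDiscrepancies(ev, der), 0)
  expect_equal(sum(der$kind == "insertion"), sum(ev$kind == "insertion"))
})
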