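# Synthetic test inputs: random trees and genomes.

#' Generate a synthetic tree and anchor genome
#'
#' Produces a random bifurcating tree with exponential branch lengths and a
#' random i.i.d. A/C/G/T genome at the requested composition. Deterministic
#' given the seed. The first tip ("t1") is the anchor unless overridden.
#' Defaults emulate a small bacterial outbreak panel: 10 tips and
#' exponential branch lengths with mean 0.1 substitutions/site.
#'
#' @param nTips Number of tips (>= 2).
#' @param genomeLength Genome length in bp (>= 1).
#' @param seed Integer seed.
#' @param composition Base frequencies (A, C, G, T) of the genome.
#' @param branchMean Mean branch length, substitutions per site.
#' @param anchor Anchor tip label (default first tip).
#' @param nContigs Split the genome into this many contigs.
#' @return List with \code{tree} (\linkS4class{SimTree}), \code{genome}
#'   (\linkS4class{AnchorGenome}) and \code{newick} (the tree string).
#' @examples
#' fx <- generateFixture(4, 1000, seed = 1)
#' fx$tree
#' @export
generateFixture <- function(nTips, genomeLength, seed,
                            composition = c(0.25, 0.25, 0.25, 0.25),
                            branchMean = 0.1, anchor = NULL,
                            nContigs = 1L) {
  stopifnot(nTips >= 2L, genomeLength >= 1L, nContigs >= 1L,
            genomeLength >= nContigs)
  stopifnot(length(composition) == 4L, all(composition >= 0),
            abs(sum(composition) - 1) < 1e-8)
  set.seed(as.integer(seed))
  phy <- ape::rtree(nTips, br = function(n) rexp(n, rate = 1 / branchMean))
  if (is.null(anchor)) anchor <- phy$tip.label[1L]
  tree <- newSimTree(phy, anchor)

  bounds <- unique(round(seq(0, genomeLength, length.out = nContigs + 1L)))
  widths <- diff(bounds)
  letters <- sample(BASES, genomeLength, replace = TRUE, prob = composition)
  starts <- c(0L, cumsum(widths))[seq_along(widths)]
  contigSeqs <- vapply(seq_along(widths), function(i)
    paste(letters[(starts[i] + 1L):(starts[i] + widths[i])], collapse = ""),
    character(1))
  contigs <- Biostrings::DNAStringSet(contigSeqs)
  names(contigs) <- sprintf("contig%02d", seq_along(contigs))
  list(tree = tree, genome = newAnchorGenome(contigs),
       newick = ape::write.tree(phy))
}

#' Write fixture inputs (tree, genome, config) to a directory
#'
#' Convenience wrapper around \code{\link{generateFixture}} that writes a
#' Newick file, a FASTA genome and a configuration file ready for
#' \code{\link{runSimulation}}.
#'
#' @inheritParams generateFixture
#' @param dir Output directory (created if needed).
#' @param ... Named configuration overrides: any of nSites, coverage,
#'   indelRate, clustering, clusteredFraction, exponentialMean, lavaletteA,
#'   lavaletteMax, readLength, fragmentMean, fragmentSd, errorModel,
#'   gtrRates, prefix.
#' @return Path of the written config file; the fixture objects as
#'   attributes.
#' @export
writeFixture <- function(dir, nTips = 10L, genomeLength = 100000L, seed = 1L,
                         composition = c(0.25, 0.25, 0.25, 0.25),
                         branchMean = 0.1, anchor = NULL, nContigs = 1L,
                         ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- generateFixture(nTips, genomeLength, seed, composition, branchMean,
                        anchor, nContigs)
  treePath <- file.path(dir, "fixture.nwk")
  writeLines(fx$newick, treePath)
  genomePath <- file.path(dir, "fixture.fasta")
  Biostrings::writeXStringSet(fx$genome@contigs, genomePath, width = 70L)

  opts <- list(...)
  slotFor <- c(nSites = "number_of_variable_sites", coverage = "coverage",
               indelRate = "indel_rate", clustering = "mutation_clustering",
               clusteredFraction = "percent_clustered",
               exponentialMean = "exponential_mean",
               lavaletteA = "lavalette_a", lavaletteMax = "lavalette_max",
               readLength = "read_length", fragmentMean = "fragment_size",
               fragmentSd = "stdev_frag_size", errorModel = "error_model",
               prefix = "prefix")
  # write absolute paths so the config works from any working directory
  absDir <- normalizePath(dir)
  lines <- c(paste0("treefile_path=", file.path(absDir, "fixture.nwk")),
             paste0("base_genome_path=", file.path(absDir, "fixture.fasta")),
             paste0("base_genome_name=", anchorTip(fx$tree)),
             paste0("number_of_variable_sites=",
                    opts$nSites %||% 100L),
             paste0("seed=", seed),
             paste0("output_dir=", file.path(absDir, "output")))
  if (!is.null(opts$gtrRates))
    lines <- c(lines, paste0("rate_matrix=",
                             paste(opts$gtrRates, collapse = ",")))
  for (nm in names(opts)) {
    if (nm %in% c("nSites", "gtrRates")) next
    key <- slotFor[[nm]]
    if (is.null(key)) fatal("unknown fixture option: ", nm)
    val <- opts[[nm]]
    if (is.logical(val)) val <- as.integer(val)
    lines <- c(lines, paste0(key, "=", val))
  }
  cfgPath <- file.path(dir, "fixture.config")
  writeLines(lines, cfgPath)
  attr(cfgPath, "fixture") <- fx
  cfgPath
}
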