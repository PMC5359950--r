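#' @import methods
#' @importFrom stats rexp rnorm rpois runif rbinom setNames
#' @importFrom utils head tail
#' @importClassesFrom Biostrings DNAStringSet
NULL

setOldClass("phylo")

#' Anchor genome: observed contigs plus base composition
#'
#' Holds the observed genome assigned to one tip of the simulation tree.
#' The anchor is reproduced unchanged in the output, so simulated reads can
#' be mapped against the same reference as empirical reads.
#'
#' @slot contigs A \link[Biostrings]{DNAStringSet} of uppercase contigs.
#' @slot composition Named counts of A, C, G, T and \code{other}
#'   (ambiguity codes); sums to the total genome length.
#'
#' @aliases AnchorGenome-class
#' @exportClass AnchorGenome
setClass("AnchorGenome",
  representation(contigs = "DNAStringSet", composition = "numeric"))

setValidity("AnchorGenome", function(object) {
  if (length(object@contigs) < 1L)
    return("anchor genome must contain at least one contig")
  if (any(Biostrings::width(object@contigs) < 1L))
    return("zero-length contig in anchor genome")
  want <- c("A", "C", "G", "T", "other")
  if (!identical(names(object@composition), want))
    return("composition must be named counts of A, C, G, T, other")
  if (sum(object@composition) != sum(Biostrings::width(object@contigs)))
    return("composition counts must sum to the total genome length")
  TRUE
})

#' Simulation tree: phylogeny with branch lengths, oriented at the anchor tip
#'
#' The input phylogeny with edges re-oriented away from the anchor tip.
#' Under a time-reversible, stationary substitution process the tip-pattern
#' distribution is invariant to root placement, and rooting at the anchor
#' makes "the anchor is never mutated" structurally guaranteed: every edge
#' subtends only non-anchor tips.
#'
#' @slot phy The original \code{phylo} object as read from Newick.
#' @slot anchor Label of the anchor tip.
#' @slot edges Two-column integer matrix (parent node, child node) in
#'   parent-before-child order, oriented away from the anchor tip.
#' @slot lengths Branch length (expected substitutions per site) per edge.
#' @slot tipLabels Tip labels in \code{phy} order (tips are nodes
#'   \code{1..nTips}).
#' @slot tipSets Integer vector of tip indices subtended by each edge's
#'   child, as a list parallel to \code{edges}.
#'
#' @aliases SimTree-class
#' @exportClass SimTree
setClass("SimTree",
  representation(phy = "phylo", anchor = "character", edges = "matrix",
                 lengths = "numeric", tipLabels = "character",
                 tipSets = "list"))

setValidity("SimTree", function(object) {
  if (length(object@tipLabels) < 2L) return("tree must have at least 2 tips")
  if (anyDuplicated(object@tipLabels)) return("tip labels must be unique")
  if (!(object@anchor %in% object@tipLabels))
    return("anchor tip not among tip labels")
  if (any(object@lengths < 0)) return("negative branch length")
  if (nrow(object@edges) != length(object@lengths))
    return("edges and lengths disagree")
  TRUE
})

#' General time-reversible substitution model
#'
#' Six exchangeabilities (ac, ag, at, cg, ct, gt; gt normalised to 1) and
#' four stationary base frequencies. The rate matrix Q is scaled so that the
#' expected substitution rate at stationarity is 1 per unit branch length,
#' i.e. branch lengths are in expected substitutions per site.
#'
#' @slot rates Named numeric(6): ac, ag, at, cg, ct, gt with gt = 1.
#' @slot freqs Named numeric(4): stationary frequencies of A, C, G, T.
#' @slot Q Scaled 4x4 rate matrix; rows sum to 0, detailed balance holds.
#'
#' @aliases GTRModel-class
#' @exportClass GTRModel
setClass("GTRModel",
  representation(rates = "numeric", freqs = "numeric", Q = "matrix"))

setValidity("GTRModel", function(object) {
  if (!identical(names(object@rates), c("ac", "ag", "at", "cg", "ct", "gt")))
    return("rates must be named ac, ag, at, cg, ct, gt")
  if (any(object@rates <= 0)) return("all exchangeabilities must be > 0")
  if (abs(object@rates[["gt"]] - 1) > 1e-12)
    return("gt exchangeability must be normalised to 1")
  if (!identical(names(object@freqs), c("A", "C", "G", "T")))
    return("freqs must be named A, C, G, T")
  if (any(object@freqs < 0) || abs(sum(object@freqs) - 1) > 1e-8)
    return("freqs must be non-negative and sum to 1")
  if (max(abs(rowSums(object@Q))) > 1e-8) return("rows of Q must sum to 0")
  TRUE
})

#' Plan of variable-site genomic coordinates
#'
#' Where the N variable sites fall on the anchor genome, before bases are
#' assigned. Positions are unique and always address an unambiguous A/C/G/T
#' base. Clustered sites record the signed offset from their seed site.
#'
#' @slot positions \code{data.frame} with columns \code{contig} (integer
#'   contig index), \code{pos0} (0-based offset), \code{clustered}
#'   (logical), \code{offset} (signed bp offset for clustered sites, NA
#'   otherwise), sorted by (contig, pos0).
#' @slot contigNames Contig names of the genome the plan addresses.
#'
#' @aliases SitePlan-class
#' @exportClass SitePlan
setClass("SitePlan",
  representation(positions = "data.frame", contigNames = "character"))

setValidity("SitePlan", function(object) {
  p <- object@positions
  need <- c("contig", "pos0", "clustered", "offset")
  if (!all(need %in% names(p))) return("missing SitePlan columns")
  if (anyDuplicated(p[c("contig", "pos0")])) return("duplicate site positions")
  if (nrow(p) && any(p$pos0 < 0)) return("negative position")
  TRUE
})

#' Variable sites with per-tip base assignments
#'
#' One row per simulated variable site: the anchor coordinate, the anchor
#' base, and the base carried by every tip. The anchor tip's base always
#' equals the anchor genome's base, and every column is variable (at least
#' two distinct bases among tips).
#'
#' @slot sites \code{data.frame} with columns \code{contig}, \code{pos0},
#'   \code{anchorBase}, \code{clustered}.
#' @slot tipBases Character matrix (sites x tips) of bases in {A,C,G,T};
#'   column names are tip labels.
#' @slot anchor Anchor tip label.
#'
#' @aliases MutationSites-class
#' @exportClass MutationSites
setClass("MutationSites",
  representation(sites = "data.frame", tipBases = "matrix",
                 anchor = "character"))

setValidity("MutationSites", function(object) {
  if (nrow(object@sites) != nrow(object@tipBases))
    return("sites and tipBases disagree in length")
  if (nrow(object@tipBases)) {
    if (!(object@anchor %in% colnames(object@tipBases)))
      return("anchor tip missing from tipBases")
    if (!all(object@tipBases %in% c("A", "C", "G", "T")))
      return("tip bases must be in {A,C,G,T}")
    if (!identical(unname(object@tipBases[, object@anchor]),
                   unname(object@sites$anchorBase)))
      return("anchor tip bases must equal the anchor genome bases")
    nv <- apply(object@tipBases, 1L, function(r) length(unique(r)) < 2L)
    if (any(nv)) return("non-variable column among mutation sites")
  }
  TRUE
})

#' One tip's simulated genome
#'
#' @slot tipName Tip label.
#' @slot contigs \link[Biostrings]{DNAStringSet} of the tip's contigs
#'   (anchor contig names preserved).
#' @slot provenance List recording the number of substitutions applied and
#'   the inherited indel event indices.
#'
#' @aliases TipGenome-class
#' @exportClass TipGenome
setClass("TipGenome",
  representation(tipName = "character", contigs = "DNAStringSet",
                 provenance = "list"))

#' Paired-end read simulation profile
#'
#' @slot readLength Read length, bp.
#' @slot coverage Target mean fold coverage (reads per site).
#' @slot fragmentMean,fragmentSd Fragment length distribution, bp.
#' @slot errorRates Per-cycle substitution-error probability, length
#'   \code{readLength}, each in [0, 0.75].
#' @slot quals Per-cycle Phred quality emitted for every base.
#'
#' @aliases ReadProfile-class
#' @exportClass ReadProfile
setClass("ReadProfile",
  representation(readLength = "integer", coverage = "numeric",
                 fragmentMean = "numeric", fragmentSd = "numeric",
                 errorRates = "numeric", quals = "integer"))

setValidity("ReadProfile", function(object) {
  if (object@readLength < 1L) return("readLength must be >= 1")
  if (object@coverage <= 0) return("coverage must be > 0")
  if (object@fragmentMean < object@readLength)
    return("fragment mean must be >= read length")
  if (object@fragmentSd < 0) return("fragment sd must be >= 0")
  if (length(object@errorRates) != object@readLength ||
      any(object@errorRates < 0) || any(object@errorRates > 0.75))
    return("errorRates must have one entry per cycle, each in [0, 0.75]")
  if (length(object@quals) != object@readLength)
    return("quals must have one entry per cycle")
  TRUE
})

#' Full simulation configuration
#'
#' Parsed, validated contents of a key=value configuration file; see
#' \code{\link{parseConfig}} for the key vocabulary and defaults.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    treePath = "character", genomePath = "character", anchorName = "character",
    nSites = "integer", gtrRates = "numeric", baseFreqs = "numeric",
    clustering = "logical", clusteredFraction = "numeric",
    exponentialMean = "numeric", indelRate = "numeric",
    lavaletteA = "numeric", lavaletteMax = "integer",
    coverage = "numeric", readLength = "integer", fragmentMean = "numeric",
    fragmentSd = "numeric", errorModel = "character", seed = "integer",
    outputDir = "character", prefix = "character"))

setValidity("SimulationConfig", function(object) {
  if (object@nSites < 1L) return("number_of_variable_sites must be >= 1")
  if (length(object@gtrRates) != 6L || any(object@gtrRates <= 0))
    return("rate_matrix must be six positive rates")
  if (length(object@baseFreqs) &&
      (length(object@baseFreqs) != 4L || any(object@baseFreqs < 0) ||
       abs(sum(object@baseFreqs) - 1) > 1e-6))
    return("base_frequencies must be four non-negative values summing to 1")
  if (object@clusteredFraction < 0 || object@clusteredFraction > 1)
    return("percent_clustered must be in [0, 1]")
  if (object@exponentialMean <= 0) return("exponential_mean must be > 0")
  if (object@indelRate < 0) return("indel_rate must be >= 0")
  if (object@lavaletteA <= 0) return("lavalette_a must be > 0")
  if (object@lavaletteMax < 1L) return("lavalette_max must be >= 1")
  if (object@coverage <= 0) return("coverage must be > 0")
  if (object@readLength < 1L) return("read_length must be >= 1")
  if (object@fragmentMean < object@readLength)
    return("fragment_size must be >= read_length")
  if (object@fragmentSd < 0) return("stdev_frag_size must be >= 0")
  TRUE
})
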