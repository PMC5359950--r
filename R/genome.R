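# Anchor genome IO and composition.

#' Load an anchor genome from FASTA
#'
#' Reads one or more contigs, uppercases them, and tallies the base
#' composition. Ambiguity codes are retained in the sequence (they are
#' ineligible as variable-site positions) but tallied separately.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return An \linkS4class{AnchorGenome}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "ACGTN"), fa)
#' g <- loadGenome(fa)
#' composition(g)
#' @export
loadGenome <- function(path) {
  if (!file.exists(path)) fatal("genome FASTA not found: ", path)
  contigs <- Biostrings::readDNAStringSet(path)
  if (length(contigs) == 0L) fatal("genome FASTA is empty: ", path)
  if (any(Biostrings::width(contigs) == 0L))
    fatal("zero-length contig in ", path)
  contigs <- Biostrings::DNAStringSet(toupper(contigs))
  # keep only the first whitespace-delimited token of each header
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  newAnchorGenome(contigs)
}

newAnchorGenome <- function(contigs) {
  af <- Biostrings::alphabetFrequency(contigs, baseOnly = TRUE)
  comp <- colSums(af)
  comp <- c(comp[c("A", "C", "G", "T")], other = unname(comp[["other"]]))
  new("AnchorGenome", contigs = contigs, composition = comp)
}

#' @describeIn loadGenome Total genome length in bp.
#' @param genome An \linkS4class{AnchorGenome}.
#' @export
totalLength <- function(genome) sum(Biostrings::width(genome@contigs))

#' @describeIn loadGenome The contigs as a DNAStringSet.
#' @export
contigs <- function(genome) genome@contigs

#' @describeIn loadGenome Named counts of A, C, G, T and ambiguous bases.
#' @export
composition <- function(genome) genome@composition

setMethod("show", "AnchorGenome", function(object) {
  cat("AnchorGenome:", length(object@contigs), "contig(s),",
      totalLength(object), "bp\n")
  fr <- baseFrequencies(object)
  cat("  base frequencies:",
      paste(sprintf("%s=%.4f", names(fr), fr), collapse = " "), "\n")
  if (object@composition[["other"]] > 0)
    cat("  ambiguous bases:", object@composition[["other"]], "\n")
})

#' Stationary base frequencies from anchor composition
#'
#' Frequencies are the counts of A/C/G/T divided by their sum; ambiguous
#' characters are excluded. These serve as the stationary frequencies of the
#' substitution model unless overridden in the configuration.
#'
#' @param genome An \linkS4class{AnchorGenome}.
#' @return Named numeric(4) summing to 1.
#' @export
baseFrequencies <- function(genome) {
  counts <- genome@composition[c("A", "C", "G", "T")]
  if (sum(counts) == 0) fatal("anchor genome has no unambiguous A/C/G/T base")
  counts / sum(counts)
}

# logical eligibility (unambiguous A/C/G/T) per contig
eligibleByContig <- function(genome) {
  lapply(seq_along(genome@contigs), function(i) {
    r <- charToRaw(as.character(genome@contigs[[i]]))
    r == BASE_RAW[1] | r == BASE_RAW[2] | r == BASE_RAW[3] | r == BASE_RAW[4]
  })
}
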