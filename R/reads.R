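# Illumina-like paired-end read simulation.

#' Construct a read-simulation profile
#'
#' The default error model is a per-cycle substitution-error probability
#' rising linearly from 0.001 at cycle 1 to 0.01 at the last cycle, a
#' caricature of MiSeq behaviour; qualities are -10*log10(rate), rounded
#' and capped to [2, 40]. \code{errorModel} may also be
#' \code{"flat:<rate>"} (constant per-cycle rate) or
#' \code{"profile:<path>"}, a tab-delimited file with header columns
#' cycle, error_rate, mean_quality covering every cycle.
#'
#' @param readLength Read length, bp.
#' @param coverage Target mean fold coverage.
#' @param fragmentMean,fragmentSd Fragment length Normal parameters, bp.
#' @param errorModel "default", "flat:<rate>" or "profile:<path>".
#' @return A \linkS4class{ReadProfile}.
#' @export
readProfile <- function(readLength = 250L, coverage = 20,
                        fragmentMean = 500, fragmentSd = 50,
                        errorModel = "default") {
  readLength <- as.integer(readLength)
  if (identical(errorModel, "default")) {
    rates <- if (readLength == 1L) 0.001 else
      seq(0.001, 0.01, length.out = readLength)
    quals <- pmin(40L, pmax(2L, as.integer(round(-10 * log10(rates)))))
  } else if (grepl("^flat:", errorModel)) {
    rate <- as.numeric(sub("^flat:", "", errorModel))
    if (is.na(rate) || rate < 0 || rate > 0.75)
      fatal("flat error rate must be in [0, 0.75]")
    rates <- rep(rate, readLength)
    quals <- rep(if (rate > 0)
      pmin(40L, pmax(2L, as.integer(round(-10 * log10(rate))))) else 40L,
      readLength)
  } else if (grepl("^profile:", errorModel)) {
    path <- sub("^profile:", "", errorModel)
    if (!file.exists(path)) fatal("error-model profile not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    need <- c("cycle", "error_rate", "mean_quality")
    if (!all(need %in% names(tab)))
      fatal("error-model profile needs columns: ",
            paste(need, collapse = ", "))
    m <- match(seq_len(readLength), tab$cycle)
    if (anyNA(m)) fatal("error-model profile does not cover every cycle ",
                        "1..", readLength)
    rates <- tab$error_rate[m]
    quals <- as.integer(round(tab$mean_quality[m]))
  } else {
    fatal("unknown error model '", errorModel,
          "'; use default, flat:<rate> or profile:<path>")
  }
  new("ReadProfile", readLength = readLength, coverage = as.numeric(coverage),
      fragmentMean = as.numeric(fragmentMean),
      fragmentSd = as.numeric(fragmentSd),
      errorRates = as.numeric(rates), quals = quals)
}

setMethod("show", "ReadProfile", function(object) {
  cat("ReadProfile: ", object@readLength, " bp reads, ", object@coverage,
      "x coverage, fragments ", object@fragmentMean, " +/- ",
      object@fragmentSd, " bp, mean error rate ",
      signif(mean(object@errorRates), 3), "\n", sep = "")
})

#' Read pairs needed for a target fold coverage
#'
#' round(coverage * genomeLength / (2 * readLength)); each pair contributes
#' two full-length reads.
#'
#' @param genomeLength Genome length in bp.
#' @param profile A \linkS4class{ReadProfile}.
#' @return Integer pair count (0 with a warning if coverage is too low for
#'   a single pair).
#' @export
nPairsForCoverage <- function(genomeLength, profile) {
  if (genomeLength < profile@readLength)
    fatal("genome shorter than the read length")
  n <- round(profile@coverage * genomeLength / (2 * profile@readLength))
  if (n < 1) {
    warning("requested coverage yields zero read pairs")
    return(0L)
  }
  as.integer(n)
}

#' Simulate paired-end read pairs from a genome
#'
#' Fragments are drawn per pair: a contig with probability proportional to
#' length, a fragment length Normal(fragmentMean, fragmentSd) rounded and
#' truncated to [readLength, contig length], a uniform start, and a
#' fair-coin strand. Read 1 is the 5' end of the fragment, read 2 the
#' reverse complement of its 3' end. Each cycle substitutes a base
#' (uniformly among the other three) with that cycle's error probability.
#'
#' @param tipGenome A \linkS4class{TipGenome} (or
#'   \link[Biostrings]{DNAStringSet}).
#' @param profile A \linkS4class{ReadProfile}.
#' @param nPairs Number of pairs (default: from
#'   \code{\link{nPairsForCoverage}}).
#' @param tipName Name used in read identifiers.
#' @param idOffset Offset for the pair serial number in read names (used by
#'   chunked generation to keep identifiers unique).
#' @return List with character vectors \code{names}, \code{seq1},
#'   \code{seq2} and quality strings \code{qual1}, \code{qual2}.
#' @export
simulateReadPairs <- function(tipGenome, profile, nPairs = NULL,
                              tipName = NULL, idOffset = 0L) {
  seqs <- if (is(tipGenome, "TipGenome")) tipGenome@contigs else tipGenome
  if (is.null(tipName))
    tipName <- if (is(tipGenome, "TipGenome")) tipGenome@tipName else "sample"
  widths <- Biostrings::width(seqs)
  rl <- profile@readLength
  if (all(widths < rl)) fatal("all contigs are shorter than the read length")
  usable <- which(widths >= rl)
  if (is.null(nPairs)) nPairs <- nPairsForCoverage(sum(widths), profile)
  qualStr <- intToUtf8(profile@quals + 33L)
  if (nPairs == 0L)
    return(list(names = character(0), seq1 = character(0),
                seq2 = character(0), qual1 = character(0),
                qual2 = character(0)))

  ci <- usable[sample.int(length(usable), nPairs, replace = TRUE,
                          prob = widths[usable])]
  flen <- as.integer(round(rnorm(nPairs, profile@fragmentMean,
                                 profile@fragmentSd)))
  flen <- pmax(rl, pmin(flen, widths[ci]))
  start <- 1L + as.integer(floor(runif(nPairs) * (widths[ci] - flen + 1L)))
  minus <- runif(nPairs) < 0.5

  seq1 <- character(nPairs); seq2 <- character(nPairs)
  for (c1 in unique(ci)) {
    sel <- which(ci == c1)
    frags <- Biostrings::extractAt(
      seqs[[c1]], IRanges::IRanges(start[sel], width = flen[sel]))
    frags[minus[sel]] <- Biostrings::reverseComplement(frags[minus[sel]])
    seq1[sel] <- as.character(Biostrings::subseq(frags, 1L, rl))
    seq2[sel] <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(frags, Biostrings::width(frags) - rl + 1L)))
  }
  seq1 <- applyCycleErrors(seq1, profile@errorRates)
  seq2 <- applyCycleErrors(seq2, profile@errorRates)
  names <- sprintf("%s:%s:%d:%d:%s", tipName, names(seqs)[ci], start,
                   start + flen - 1L, ifelse(minus, "R", "F"))
  names <- paste0(names, ":", idOffset + seq_len(nPairs))
  list(names = names, seq1 = seq1, seq2 = seq2,
       qual1 = rep(qualStr, nPairs), qual2 = rep(qualStr, nPairs))
}

# substitute bases per cycle with the given error probabilities; errors go
# uniformly to one of the other three bases
applyCycleErrors <- function(reads, rates) {
  if (!length(reads) || all(rates == 0)) return(reads)
  n <- length(reads); rl <- nchar(reads[1])
  hit <- matrix(runif(n * rl), n, rl) < rep(rates, each = n)
  nHits <- sum(hit)
  if (nHits == 0L) return(reads)
  cm <- matrix(unlist(strsplit(reads, NULL), use.names = FALSE),
               nrow = n, byrow = TRUE)
  cur <- match(cm[hit], BASES)
  shift <- sample.int(3L, nHits, replace = TRUE)
  repl <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  repl[is.na(cur)] <- cm[hit][is.na(cur)]   # leave ambiguity codes alone
  cm[hit] <- repl
  do.call(paste0, lapply(seq_len(rl), function(j) cm[, j]))
}

#' Write paired FASTQ files for one tip
#'
#' \code{<outputDir>/fastq/<tip>/<tip>_R1.fastq.gz} and \code{_R2}, 4-line
#' records, Phred+33, mates in matched order. Zero pairs produce two valid
#' empty gzip files.
#'
#' @param pairs List from \code{\link{simulateReadPairs}}.
#' @param outputDir Output directory root.
#' @param tip Tip label.
#' @param append Append to existing files (for chunked generation).
#' @return Character vector of the two paths.
#' @export
writeFastqPairs <- function(pairs, outputDir, tip, append = FALSE) {
  safe <- sanitizeLabel(tip)
  dir <- file.path(outputDir, "fastq", safe)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(safe, "_R1.fastq.gz"))
  p2 <- file.path(dir, paste0(safe, "_R2.fastq.gz"))
  mode <- if (append) "ab" else "wb"
  writeOne <- function(path, seqs, quals, mate) {
    con <- gzfile(path, mode)
    on.exit(close(con))
    if (length(seqs)) {
      rec <- rbind(paste0("@", pairs$names, "/", mate), seqs, "+", quals)
      writeLines(as.vector(rec), con)
    } else {
      writeLines(character(0), con)
    }
  }
  writeOne(p1, pairs$seq1, pairs$qual1, 1L)
  writeOne(p2, pairs$seq2, pairs$qual2, 2L)
  c(p1, p2)
}

# chunked simulate + write for one tip; returns realized depth bookkeeping
writeReadsForTip <- function(tipGenome, profile, outputDir,
                             chunk = 20000L) {
  glen <- sum(Biostrings::width(tipGenome@contigs))
  total <- nPairsForCoverage(glen, profile)
  done <- 0L
  paths <- writeFastqPairs(list(names = character(0), seq1 = character(0),
                                seq2 = character(0), qual1 = character(0),
                                qual2 = character(0)),
                           outputDir, tipGenome@tipName, append = FALSE)
  while (done < total) {
    k <- min(chunk, total - done)
    pairs <- simulateReadPairs(tipGenome, profile, nPairs = k,
                               idOffset = done)
    writeFastqPairs(pairs, outputDir, tipGenome@tipName, append = TRUE)
    done <- done + k
  }
  list(nPairs = total, bases = 2 * total * profile@readLength,
       realizedCoverage = 2 * total * profile@readLength / glen,
       paths = paths)
}
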