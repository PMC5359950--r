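# Branch indel events with Lavalette-distributed lengths.

#' Lavalette length distribution
#'
#' Bounded heavy-tailed discrete distribution over indel lengths:
#' P(L) proportional to (L*M/(M-L+1))^(-a) for L in 1..M. Sampling is by
#' inverse CDF over the normalised table.
#'
#' @param n Number of draws.
#' @param a Shape parameter (> 0); larger a gives shorter indels.
#' @param M Maximum length in bp (>= 1).
#' @return Integer vector of lengths in 1..M.
#' @examples
#' table(sampleLavalette(1000, a = 1.7, M = 5))
#' @export
sampleLavalette <- function(n, a, M) {
  stopifnot(n >= 0)
  p <- lavalettePmf(a, M)
  sample.int(M, n, replace = TRUE, prob = p)
}

#' @describeIn sampleLavalette The normalised probability mass function
#'   over 1..M.
#' @export
lavalettePmf <- function(a, M) {
  if (!is.finite(a) || a <= 0) fatal("lavalette a must be > 0")
  M <- as.integer(M)
  if (is.na(M) || M < 1L) fatal("lavalette max must be >= 1")
  L <- seq_len(M)
  w <- (L * M / (M - L + 1))^(-a)
  w / sum(w)
}

#' Simulate insertion and deletion events on tree branches
#'
#' Event counts are Poisson with mean rate * nSnps for each kind, so the
#' expected number of indels scales with the simulated number of
#' substitutions. Each event falls on a branch with probability
#' proportional to branch length (the tree is anchor-oriented, so the
#' anchor tip is never affected), at a uniform anchor coordinate. All
#' insertions and deletions are expressed relative to the anchor: carriers
#' are the tips subtended by the event's branch. Deletion spans may not
#' cover a planned variable site, insertion points may not separate a
#' variable site from its neighbour, events may not cross contig
#' boundaries, and anchor spans of distinct events are kept disjoint;
#' colliding draws are rejected and redrawn. Inserted sequences are drawn
#' i.i.d. from the model's stationary frequencies.
#'
#' @param tree A \linkS4class{SimTree}.
#' @param nSnps The configured number of variable sites (the scaling unit).
#' @param insertionRate,deletionRate Expected events per substitution.
#' @param a,M Lavalette shape and maximum length.
#' @param genome The \linkS4class{AnchorGenome}.
#' @param plan \linkS4class{SitePlan} of variable sites to avoid (or NULL).
#' @param model \linkS4class{GTRModel} supplying insertion-base
#'   frequencies.
#' @param maxRetries Rejection budget per event.
#' @return \code{data.frame} with one row per event: \code{kind}
#'   ("insertion"/"deletion"), \code{node} (child node of the branch),
#'   \code{contig}, \code{pos0} (0-based left attachment; for deletions the
#'   first deleted base, for insertions the base the insert follows),
#'   \code{length}, \code{seq} (inserted sequence or NA), \code{tips}
#'   (comma-joined carrier tip labels).
#' @export
simulateIndelEvents <- function(tree, nSnps, insertionRate, deletionRate,
                                a, M, genome, plan = NULL, model,
                                maxRetries = 10000L) {
  stopifnot(insertionRate >= 0, deletionRate >= 0, nSnps >= 0)
  nIns <- rpois(1L, insertionRate * nSnps)
  nDel <- rpois(1L, deletionRate * nSnps)
  nEv <- nIns + nDel
  empty <- data.frame(kind = character(0), node = integer(0),
                      contig = integer(0), pos0 = integer(0),
                      length = integer(0), seq = character(0),
                      tips = character(0))
  if (nEv == 0L) return(empty)
  if (sum(tree@lengths) <= 0)
    fatal("cannot place indel events: all branch lengths are zero")

  widths <- Biostrings::width(genome@contigs)
  snpKey <- character(0)
  if (!is.null(plan) && nrow(plan@positions))
    snpKey <- paste(plan@positions$contig, plan@positions$pos0)
  # occupied anchor intervals per contig, kept globally disjoint
  occ <- lapply(seq_along(widths), function(i) cbind(start = integer(0),
                                                     end = integer(0)))
  kinds <- sample(c(rep("insertion", nIns), rep("deletion", nDel)))
  lens <- sampleLavalette(nEv, a, M)
  nodes <- tree@edges[sample.int(length(tree@lengths), nEv, replace = TRUE,
                                 prob = tree@lengths), "child"]
  pos0 <- integer(nEv); ctg <- integer(nEv)
  seqs <- rep(NA_character_, nEv)

  for (i in seq_len(nEv)) {
    L <- lens[i]; kind <- kinds[i]
    placed <- FALSE
    for (try in seq_len(maxRetries)) {
      ci <- sample.int(length(widths), 1L, prob = widths)
      w <- widths[ci]
      if (kind == "deletion") {
        if (w < L) next
        s <- sample.int(w - L + 1L, 1L) - 1L        # 0-based first deleted
        span <- c(s, s + L - 1L)
        if (any(paste(ci, span[1]:span[2]) %in% snpKey)) next
      } else {
        if (w < 2L) next
        s <- sample.int(w - 1L, 1L) - 1L            # insert after pos0
        if (any(paste(ci, c(s, s + 1L)) %in% snpKey)) next
        span <- c(s, s + 1L)   # reserve the flanking pair
      }
      o <- occ[[ci]]
      # disjoint with a 1 bp buffer, so gap runs of adjacent events never
      # merge in the reconstructed alignment
      if (nrow(o) && any(span[1] <= o[, "end"] + 1L &
                         span[2] >= o[, "start"] - 1L))
        next
      occ[[ci]] <- rbind(o, span)
      colnames(occ[[ci]]) <- c("start", "end")
      pos0[i] <- s; ctg[i] <- ci
      if (kind == "insertion")
        seqs[i] <- paste(sample(BASES, L, replace = TRUE, prob = model@freqs),
                         collapse = "")
      placed <- TRUE
      break
    }
    if (!placed)
      fatal("could not place ", kind, " of length ", L, " after ",
            maxRetries, " retries; reduce the indel rate or n, or use a ",
            "larger genome")
  }
  nodeIdx <- match(nodes, tree@edges[, "child"])
  tips <- vapply(nodeIdx, function(j)
    paste(tree@tipLabels[tree@tipSets[[j]]], collapse = ","), character(1))
  data.frame(kind = kinds, node = as.integer(nodes), contig = ctg,
             pos0 = pos0, length = as.integer(lens), seq = seqs, tips = tips)
}

# carrier tip labels of an event row, as a character vector
eventCarriers <- function(events) strsplit(events$tips, ",", fixed = TRUE)

#' Write the indel event log
#'
#' Tab-delimited: kind, branch (child-node id), contig, 1-based anchor
#' position of the left attachment, length, inserted sequence (dot for
#' deletions), carrier tips.
#'
#' @param events Event table from \code{\link{simulateIndelEvents}}.
#' @param genome The \linkS4class{AnchorGenome} (for contig names).
#' @param path Output file path.
#' @export
writeEventLog <- function(events, genome, path) {
  df <- data.frame(kind = events$kind, branch = events$node,
                   contig = names(genome@contigs)[events$contig],
                   pos1 = events$pos0 + 1L, length = events$length,
                   seq = ifelse(is.na(events$seq), ".", events$seq),
                   tips = events$tips)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
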