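# Genomic placement of variable sites: uniform or exponentially clustered.

newSitePlan <- function(df, genome) {
  ord <- order(df$contig, df$pos0)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  new("SitePlan", positions = df, contigNames = names(genome@contigs))
}

#' @describeIn placeUniform Number of planned sites.
#' @param plan A \linkS4class{SitePlan}.
#' @export
nSites <- function(plan) nrow(plan@positions)

#' @describeIn placeUniform The positions table (contig index, 0-based
#'   offset, clustered flag, signed clustered offset).
#' @export
sitePositions <- function(plan) plan@positions

setMethod("show", "SitePlan", function(object) {
  cat("SitePlan:", nrow(object@positions), "sites (",
      sum(object@positions$clustered), "clustered ) on",
      length(object@contigNames), "contig(s)\n")
})

# concatenated-coordinate frame: sample over all contigs at once, then map
# back to (contig, offset)
globalFrame <- function(genome) {
  w <- Biostrings::width(genome@contigs)
  list(widths = w, starts = c(0L, cumsum(w))[seq_along(w)], total = sum(w))
}

#' Place variable sites uniformly across the genome
#'
#' Samples n distinct positions without replacement, uniformly over all
#' eligible (unambiguous A/C/G/T) positions across all contigs in a single
#' concatenated coordinate system.
#'
#' @param genome An \linkS4class{AnchorGenome}.
#' @param n Number of sites; must not exceed the eligible position count.
#' @return A \linkS4class{SitePlan} sorted by (contig, position).
#' @export
placeUniform <- function(genome, n) {
  stopifnot(n >= 0)
  elig <- eligibleByContig(genome)
  fr <- globalFrame(genome)
  eligGlobal <- which(unlist(elig, use.names = FALSE))
  if (n > length(eligGlobal))
    fatal("requested ", n, " sites but only ", length(eligGlobal),
          " eligible positions exist")
  pick <- if (n == 0L) integer(0) else sort(sample(eligGlobal, n))
  ci <- findInterval(pick - 1L, fr$starts)
  newSitePlan(data.frame(contig = ci, pos0 = pick - 1L - fr$starts[ci],
                         clustered = logical(length(pick)),
                         offset = rep(NA_integer_, length(pick))),
              genome)
}

#' Place variable sites with an exponentially clustered fraction
#'
#' A fraction of the n sites is clustered: each clustered site sits at a
#' signed offset d from a uniformly chosen already-placed site, where
#' |d| = 1 + floor(Exponential(mean)) and the sign is a fair coin. The
#' remaining sites are uniform seeds. Draws that fall off the contig, on an
#' ambiguous base, or on an occupied position are rejected and redrawn
#' (up to \code{maxRetries} per site). The clustered count is
#' round(fraction * n) with R's round-half-to-even, so n partitions
#' deterministically.
#'
#' @param genome An \linkS4class{AnchorGenome}.
#' @param n Total number of sites.
#' @param fraction Fraction of sites to cluster, in [0, 1].
#' @param mean Mean of the exponential inter-site distance, bp.
#' @param maxRetries Rejection budget per clustered site.
#' @return A \linkS4class{SitePlan}; clustered rows carry their signed
#'   offset in the \code{offset} column.
#' @export
placeClustered <- function(genome, n, fraction, mean, maxRetries = 10000L) {
  stopifnot(n >= 0, fraction >= 0, fraction <= 1, mean > 0)
  nClustered <- round(fraction * n)
  nUniform <- n - nClustered
  if (nUniform == 0L && nClustered > 0L)
    nUniform <- 1L  # clustered sites need at least one seed
  elig <- eligibleByContig(genome)
  fr <- globalFrame(genome)
  eligGlobal <- which(unlist(elig, use.names = FALSE))
  if (n > length(eligGlobal))
    fatal("requested ", n, " sites but only ", length(eligGlobal),
          " eligible positions exist")
  seeds <- sort(sample(eligGlobal, nUniform))
  occupied <- logical(fr$total)
  occupied[seeds] <- TRUE
  eligMask <- logical(fr$total)
  eligMask[eligGlobal] <- TRUE
  ci <- findInterval(seeds - 1L, fr$starts)
  contigOf <- rep.int(seq_along(fr$widths), fr$widths)

  placed <- seeds                       # global 1-based coordinates
  cOffsets <- integer(nClustered)
  nClustered <- min(nClustered, n)      # guard the nUniform bump above
  k <- 0L
  while (k < nClustered) {
    ok <- FALSE
    for (try in seq_len(maxRetries)) {
      src <- placed[sample.int(length(placed), 1L)]
      d <- (1L + as.integer(floor(rexp(1L, rate = 1 / mean)))) *
        (if (runif(1L) < 0.5) 1L else -1L)
      cand <- src + d
      if (cand < 1L || cand > fr$total) next
      if (contigOf[cand] != contigOf[src]) next   # no crossing contigs
      if (!eligMask[cand] || occupied[cand]) next
      occupied[cand] <- TRUE
      placed <- c(placed, cand)
      k <- k + 1L
      cOffsets[k] <- d
      ok <- TRUE
      break
    }
    if (!ok)
      fatal("could not place clustered site after ", maxRetries,
            " retries; use a smaller n or a larger genome")
  }
  allPos <- c(seeds, placed[seq_len(k) + length(seeds)])
  clustered <- c(rep(FALSE, length(seeds)), rep(TRUE, k))
  offset <- c(rep(NA_integer_, length(seeds)), cOffsets[seq_len(k)])
  # trim the extra seed if we bumped nUniform for an all-clustered request
  if (length(allPos) > n) {
    drop <- 1L
    allPos <- allPos[-drop]; clustered <- clustered[-drop]
    offset <- offset[-drop]
  }
  ci <- findInterval(allPos - 1L, fr$starts)
  newSitePlan(data.frame(contig = ci, pos0 = allPos - 1L - fr$starts[ci],
                         clustered = clustered, offset = offset),
              genome)
}

# anchor base (character) at each planned position
planAnchorBases <- function(plan, genome) {
  p <- plan@positions
  if (!nrow(p)) return(character(0))
  out <- character(nrow(p))
  for (ci in unique(p$contig)) {
    sel <- p$contig == ci
    s <- genome@contigs[[ci]]
    out[sel] <- as.character(
      Biostrings::extractAt(s, IRanges::IRanges(p$pos0[sel] + 1L, width = 1L)))
  }
  out
}
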