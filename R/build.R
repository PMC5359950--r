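# Materialise tip genomes, gapped alignment, truth VCF.

# events inherited by one tip: every event whose branch subtends that tip
eventsForTip <- function(events, tip) {
  if (!nrow(events)) return(events)
  carriers <- eventCarriers(events)
  events[vapply(carriers, function(x) tip %in% x, logical(1)), ,
         drop = FALSE]
}

#' Build one tip's genome
#'
#' Applies the tip's substitutions at anchor coordinates, then the indel
#' events inherited along the anchor-to-tip path, applied in decreasing
#' coordinate order so earlier coordinates stay valid. The anchor tip's
#' genome is byte-identical to the input regardless of settings.
#'
#' @param genome The \linkS4class{AnchorGenome}.
#' @param tip Tip label.
#' @param sites A \linkS4class{MutationSites}.
#' @param events Event table from \code{\link{simulateIndelEvents}} (may
#'   have zero rows).
#' @return A \linkS4class{TipGenome}.
#' @export
buildTipGenome <- function(genome, tip, sites, events) {
  seqs <- genome@contigs
  st <- sites@sites
  nSub <- 0L
  if (nrow(st)) {
    bases <- sites@tipBases[, tip]
    for (ci in unique(st$contig)) {
      sel <- st$contig == ci
      s <- seqs[[ci]]
      seqs[[ci]] <- Biostrings::replaceLetterAt(s, st$pos0[sel] + 1L,
                                                bases[sel])
    }
    nSub <- sum(bases != st$anchorBase)
  }
  ev <- eventsForTip(events, tip)
  if (nrow(ev)) {
    for (ci in unique(ev$contig)) {
      sel <- which(ev$contig == ci)
      sel <- sel[order(ev$pos0[sel], decreasing = TRUE)]
      s <- seqs[[ci]]
      for (j in sel) {
        if (ev$kind[j] == "deletion") {
          s <- Biostrings::replaceAt(
            s, IRanges::IRanges(ev$pos0[j] + 1L, width = ev$length[j]), "")
        } else {
          s <- Biostrings::replaceAt(
            s, IRanges::IRanges(start = ev$pos0[j] + 2L, width = 0L),
            ev$seq[j])
        }
      }
      seqs[[ci]] <- s
    }
  }
  new("TipGenome", tipName = tip, contigs = seqs,
      provenance = list(nSubstitutions = nSub, nEvents = nrow(ev)))
}

setMethod("show", "TipGenome", function(object) {
  cat("TipGenome '", object@tipName, "': ", length(object@contigs),
      " contig(s), ", sum(Biostrings::width(object@contigs)), " bp (",
      object@provenance$nSubstitutions, " substitutions, ",
      object@provenance$nEvents, " indel events)\n", sep = "")
})

#' Reconstruct the true gapped multiple alignment
#'
#' Builds, per contig, the alignment of all tips in anchor coordinates plus
#' one column block per insertion: deletions appear as gap runs in carrier
#' rows, insertions as blocks that are gaps in all non-carrier rows
#' (including the anchor - the "apparent deletions" caused by insertions in
#' other lineages).
#'
#' @param genome The \linkS4class{AnchorGenome}.
#' @param tree A \linkS4class{SimTree}.
#' @param sites A \linkS4class{MutationSites}.
#' @param events Event table (may have zero rows).
#' @return A list, one \link[Biostrings]{DNAStringSet} per contig (rows =
#'   tips), named by contig.
#' @export
buildAlignment <- function(genome, tree, sites, events) {
  tipsV <- tipLabels(tree)
  st <- sites@sites
  out <- vector("list", length(genome@contigs))
  names(out) <- names(genome@contigs)
  carriers <- eventCarriers(events)
  for (ci in seq_along(genome@contigs)) {
    anchorSeq <- genome@contigs[[ci]]
    evc <- which(events$contig == ci)
    ins <- evc[events$kind[evc] == "insertion"]
    ins <- ins[order(events$pos0[ins])]
    insAt <- IRanges::IRanges(start = events$pos0[ins] + 2L, width = 0L)
    del <- evc[events$kind[evc] == "deletion"]
    siteSel <- which(st$contig == ci)
    rows <- vector("list", length(tipsV))
    for (k in seq_along(tipsV)) {
      tip <- tipsV[k]
      s <- anchorSeq
      if (length(siteSel))
        s <- Biostrings::replaceLetterAt(s, st$pos0[siteSel] + 1L,
                                         sites@tipBases[siteSel, tip])
      if (length(del)) {
        mine <- del[vapply(carriers[del], function(x) tip %in% x,
                           logical(1))]
        if (length(mine))
          s <- Biostrings::replaceAt(
            s, IRanges::IRanges(events$pos0[mine] + 1L,
                                width = events$length[mine]),
            strrep("-", events$length[mine]))
      }
      if (length(ins)) {
        fill <- ifelse(vapply(carriers[ins], function(x) tip %in% x,
                              logical(1)),
                       events$seq[ins], strrep("-", events$length[ins]))
        s <- Biostrings::replaceAt(s, insAt, fill)
      }
      rows[[k]] <- s
    }
    aln <- Biostrings::DNAStringSet(rows)
    names(aln) <- tipsV
    out[[ci]] <- aln
  }
  out
}

#' Count variable columns of a gapped alignment
#'
#' Columns where at least two tips carry distinct unambiguous bases
#' (gap-only differences do not count).
#'
#' @param aln One contig's gapped \link[Biostrings]{DNAStringSet} or the
#'   list returned by \code{\link{buildAlignment}}.
#' @return Integer count summed over contigs.
#' @export
countVariableColumns <- function(aln) {
  if (is.list(aln)) return(sum(vapply(aln, countVariableColumns, numeric(1))))
  raws <- lapply(seq_along(aln), function(i) charToRaw(as.character(aln[[i]])))
  n <- length(raws[[1]])
  isBase <- function(r) r == BASE_RAW[1] | r == BASE_RAW[2] |
    r == BASE_RAW[3] | r == BASE_RAW[4]
  first <- rep(as.raw(0), n)
  varies <- logical(n)
  for (r in raws) {
    b <- isBase(r)
    newFirst <- b & first == as.raw(0)
    first[newFirst] <- r[newFirst]
    varies <- varies | (b & first != r)
  }
  sum(varies)
}

#' Derive indel events back from a gapped alignment
#'
#' Independent inversion of the alignment's gap structure: runs of gaps in
#' the anchor row are insertions (carriers are rows with bases there); runs
#' of gaps in a tip row restricted to anchor-base columns are deletions, in
#' anchor coordinates. Used to verify the event log.
#'
#' @param aln List of per-contig gapped alignments from
#'   \code{\link{buildAlignment}} (or read back from disk).
#' @param anchor Anchor tip label.
#' @return \code{data.frame} with kind, contig (index), pos0, length, tips
#'   (comma-joined carriers, sorted).
#' @export
deriveEventsFromAlignment <- function(aln, anchor) {
  res <- list()
  for (ci in seq_along(aln)) {
    a <- aln[[ci]]
    tipsV <- names(a)
    raws <- lapply(seq_along(a), function(i) charToRaw(as.character(a[[i]])))
    names(raws) <- tipsV
    gapRaw <- charToRaw("-")
    anchorGap <- raws[[anchor]] == gapRaw
    anchorCoord <- cumsum(!anchorGap)           # 1-based anchor position
    # insertions: gap runs in the anchor row
    r <- rle(anchorGap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      st <- starts[j]; en <- ends[j]
      carr <- tipsV[vapply(raws, function(x) any(x[st:en] != gapRaw),
                           logical(1))]
      res[[length(res) + 1L]] <- data.frame(
        kind = "insertion", contig = ci,
        pos0 = anchorCoord[st] - 1L,            # left attachment, 0-based
        length = en - st + 1L,
        tips = paste(sort(carr), collapse = ","))
    }
    # deletions: per-tip gap runs over anchor-base columns
    keep <- !anchorGap
    dels <- list()
    for (tip in setdiff(tipsV, anchor)) {
      g <- (raws[[tip]] == gapRaw)[keep]
      r2 <- rle(g)
      e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1L
      for (j in which(r2$values)) {
        key <- paste(s2[j], e2[j])
        dels[[key]] <- c(dels[[key]], tip)
      }
    }
    for (key in names(dels)) {
      se <- as.integer(strsplit(key, " ")[[1]])
      res[[length(res) + 1L]] <- data.frame(
        kind = "deletion", contig = ci, pos0 = se[1] - 1L,
        length = se[2] - se[1] + 1L,
        tips = paste(sort(dels[[key]]), collapse = ","))
    }
  }
  if (!length(res))
    return(data.frame(kind = character(0), contig = integer(0),
                      pos0 = integer(0), length = integer(0),
                      tips = character(0)))
  do.call(rbind, res)
}

#' Count discrepancies between an event log and alignment-derived events
#'
#' Events are matched on (kind, contig, position, length, carrier set);
#' the count is the size of the symmetric difference. Zero means the
#' alignment's gap structure exactly reproduces the simulated events.
#'
#' @param events Simulated event table.
#' @param derived Output of \code{\link{deriveEventsFromAlignment}}.
#' @return Non-negative integer.
#' @export
eventLogDiscrepancies <- function(events, derived) {
  keyOf <- function(df) {
    if (!nrow(df)) return(character(0))
    tipsSorted <- vapply(strsplit(df$tips, ",", fixed = TRUE),
                         function(x) paste(sort(x), collapse = ","),
                         character(1))
    paste(df$kind, df$contig, df$pos0, df$length, tipsSorted)
  }
  k1 <- keyOf(events); k2 <- keyOf(derived)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Write the truth VCF
#'
#' VCF 4.2 with one record per variable site: CHROM is the contig name,
#' POS the 1-based anchor coordinate, REF the anchor base, ALT the distinct
#' non-anchor bases in first-seen tip order, and one haploid GT sample
#' column per tip (the anchor tip is 0 everywhere).
#'
#' @param sites A \linkS4class{MutationSites}.
#' @param genome The \linkS4class{AnchorGenome}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTruthVcf <- function(sites, genome, path) {
  tipsV <- colnames(sites@tipBases)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=anchorsim ",
           as.character(utils::packageVersion("anchorsim"))),
    sprintf("##contig=<ID=%s,length=%d>", names(genome@contigs),
            Biostrings::width(genome@contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", tipsV), collapse = "\t"))
  st <- sites@sites
  lines <- character(0)
  if (nrow(st)) {
    ord <- order(st$contig, st$pos0)
    lines <- vapply(ord, function(i) {
      ref <- st$anchorBase[i]
      bases <- sites@tipBases[i, ]
      alts <- unique(bases[bases != ref])
      gt <- match(bases, c(ref, alts)) - 1L
      paste(c(names(genome@contigs)[st$contig[i]], st$pos0[i] + 1L, ".",
              ref, paste(alts, collapse = ","), ".", ".", ".", "GT", gt),
            collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write per-tip FASTA genomes
#'
#' One directory per tip under \code{outputDir/fasta}, each holding
#' \code{<prefix>_<tip>.fasta} (70-column wrap). Contig names gain a
#' tip-identifying suffix. Tip labels unusable as file names are sanitised
#' with a message.
#'
#' @param genomes List of \linkS4class{TipGenome}.
#' @param outputDir Output directory root.
#' @param prefix File-name prefix.
#' @return Named character vector of FASTA paths.
#' @export
writeTipFastas <- function(genomes, outputDir, prefix) {
  paths <- character(length(genomes))
  names(paths) <- vapply(genomes, function(g) g@tipName, character(1))
  for (g in genomes) {
    safe <- sanitizeLabel(g@tipName)
    dir <- file.path(outputDir, "fasta", safe)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out <- g@contigs
    names(out) <- paste0(names(out), "_", safe)
    fp <- file.path(dir, paste0(prefix, "_", safe, ".fasta"))
    Biostrings::writeXStringSet(out, fp, width = 70L)
    paths[g@tipName] <- fp
  }
  paths
}

sanitizeLabel <- function(x) {
  safe <- gsub("[^A-Za-z0-9._-]", "_", x)
  if (safe != x)
    message("tip label '", x, "' sanitised to '", safe, "' for file naming")
  safe
}

#' Write the gapped truth alignment
#'
#' One gapped FASTA per contig: \code{<prefix>_alignment_<contig>.fasta}.
#'
#' @param aln Output of \code{\link{buildAlignment}}.
#' @param outputDir Output directory root.
#' @param prefix File-name prefix.
#' @return Character vector of paths.
#' @export
writeAlignment <- function(aln, outputDir, prefix) {
  vapply(seq_along(aln), function(ci) {
    fp <- file.path(outputDir, paste0(prefix, "_alignment_",
                                      sanitizeLabel(names(aln)[ci]),
                                      ".fasta"))
    Biostrings::writeXStringSet(aln[[ci]], fp, width = 70L)
    fp
  }, character(1))
}
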