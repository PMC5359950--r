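# Anchor-conditioned column pools and per-site base assignment.

#' Simulate a pool of variable columns conditioned on the anchor base
#'
#' For each anchor base in demand, columns are simulated with the anchor
#' state fixed to that base (the tree is anchor-oriented, so fixing the
#' origin state conditions exactly on the anchor tip; by reversibility this
#' equals rejection sampling on unconditioned columns) and non-variable
#' columns are discarded. Batches continue until each base class holds at
#' least its demanded count or the total simulated column budget is
#' exhausted, which signals near-zero branch lengths or extreme
#' frequencies.
#'
#' @param model A \linkS4class{GTRModel}.
#' @param tree A \linkS4class{SimTree}.
#' @param demand Named integer vector: required number of variable columns
#'   per anchor base (names among A, C, G, T).
#' @param batchSize Columns simulated per round.
#' @param maxColumns Total column budget before aborting.
#' @return List with \code{pools} (per-base character matrices, rows =
#'   retained variable columns, columns = tips), \code{simulated} and
#'   \code{kept} counts.
#' @export
buildColumnPool <- function(model, tree, demand,
                            batchSize = 10000L, maxColumns = 1e6) {
  demand <- demand[demand > 0]
  if (!all(names(demand) %in% BASES))
    fatal("demand must be named by anchor bases A, C, G, T")
  pools <- setNames(vector("list", length(demand)), names(demand))
  simulated <- 0L; kept <- 0L
  for (b in names(demand)) {
    got <- 0L
    rows <- list()
    while (got < demand[[b]]) {
      if (simulated >= maxColumns) {
        counts <- vapply(pools, function(m) if (is.null(m)) 0L else nrow(m),
                         integer(1))
        fatal("column budget (", maxColumns, ") exhausted before filling ",
              "the pool; variable columns kept per base so far: ",
              paste(sprintf("%s=%d", names(demand),
                            vapply(names(demand), function(x)
                              if (x == b) got else counts[[x]] %||% 0L,
                              integer(1))), collapse = ", "),
              ". Near-zero branch lengths or extreme base frequencies ",
              "make variable columns too rare.")
      }
      nb <- as.integer(min(batchSize, maxColumns - simulated))
      sim <- simulateColumns(model, tree, nb, rootState = b)
      simulated <- simulated + nb
      keepRows <- sim$tips[sim$variable, , drop = FALSE]
      if (nrow(keepRows)) {
        rows[[length(rows) + 1L]] <- keepRows
        got <- got + nrow(keepRows)
      }
    }
    pools[[b]] <- do.call(rbind, rows)
    kept <- kept + nrow(pools[[b]])
  }
  list(pools = pools, simulated = simulated, kept = kept)
}

#' Assign simulated columns to planned genomic sites
#'
#' For each planned position with anchor base b, one unused column whose
#' anchor state equals b is drawn uniformly without replacement from the
#' pool. The result has exactly one \linkS4class{MutationSites} row per
#' planned site; the anchor tip's base equals the genome base everywhere,
#' so the anchor genome remains unchanged by construction.
#'
#' @param plan A \linkS4class{SitePlan}.
#' @param genome The \linkS4class{AnchorGenome} the plan addresses.
#' @param pool Result of \code{\link{buildColumnPool}}.
#' @param tree The \linkS4class{SimTree} (for the anchor label).
#' @return A \linkS4class{MutationSites}.
#' @export
assignSites <- function(plan, genome, pool, tree) {
  p <- plan@positions
  bases <- planAnchorBases(plan, genome)
  tipNames <- tipLabels(tree)
  tb <- matrix(character(0), nrow = 0, ncol = length(tipNames),
               dimnames = list(NULL, tipNames))
  if (nrow(p)) {
    tb <- matrix(NA_character_, nrow = nrow(p), ncol = length(tipNames),
                 dimnames = list(NULL, tipNames))
    for (b in unique(bases)) {
      idx <- which(bases == b)
      m <- pool$pools[[b]]
      if (is.null(m) || nrow(m) < length(idx))
        fatal("column pool underflow for anchor base ", b)
      take <- sample.int(nrow(m), length(idx))
      tb[idx, ] <- m[take, tipNames, drop = FALSE]
    }
  }
  new("MutationSites",
      sites = data.frame(contig = p$contig, pos0 = p$pos0,
                         anchorBase = bases, clustered = p$clustered),
      tipBases = tb, anchor = anchorTip(tree))
}

#' @describeIn assignSites Number of variable sites.
#' @param sites A \linkS4class{MutationSites}.
#' @export
nMutationSites <- function(sites) nrow(sites@sites)

#' @describeIn assignSites The site table (contig, pos0, anchorBase,
#'   clustered).
#' @export
siteTable <- function(sites) sites@sites

#' @describeIn assignSites The per-tip base matrix.
#' @export
tipBases <- function(sites) sites@tipBases

setMethod("show", "MutationSites", function(object) {
  cat("MutationSites:", nrow(object@sites), "variable sites,",
      ncol(object@tipBases), "tips, anchor '", object@anchor, "'\n")
})
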