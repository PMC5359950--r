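# Independent oracles: exhaustive site-pattern enumeration (brute force over
# all node-state assignments, transition matrices via ape::matexpo rather
# than the package's own path) and small utilities shared by tests.

# exact probability of every tip pattern (4^ntip vector, base-4 index with
# tip 1 least significant); optionally conditioned on the anchor state
enumPatternProbs <- function(model, tree, rootState = NULL) {
  edges <- tree@edges
  lens <- tree@lengths
  ntip <- length(tree@tipLabels)
  nNodes <- max(edges)
  root <- match(tree@anchor, tree@tipLabels)
  Ps <- lapply(lens, function(t)
    if (t == 0) diag(4) else ape::matexpo(model@Q * t))
  grid <- as.matrix(expand.grid(rep(list(1:4), nNodes)))
  pr <- if (is.null(rootState)) {
    as.numeric(model@freqs[grid[, root]])
  } else {
    as.numeric(grid[, root] == match(rootState, c("A", "C", "G", "T")))
  }
  for (i in seq_along(lens))
    pr <- pr * Ps[[i]][cbind(grid[, edges[i, 1]], grid[, edges[i, 2]])]
  idx <- as.vector((grid[, seq_len(ntip), drop = FALSE] - 1) %*%
                     4^(seq_len(ntip) - 1)) + 1L
  out <- numeric(4^ntip)
  agg <- tapply(pr, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

# base-4 pattern index of simulated columns (tips matrix from
# simulateColumns, columns already in node order)
patternIndex <- function(tips) {
  m <- matrix(match(tips, c("A", "C", "G", "T")) - 1L, nrow = nrow(tips))
  as.vector(m %*% 4^(seq_len(ncol(tips)) - 1)) + 1L
}

# whether each pattern index (1..4^ntip) is a variable column
patternIsVariable <- function(ntip) {
  idx <- 0:(4^ntip - 1)
  states <- sapply(seq_len(ntip), function(k) (idx %/% 4^(k - 1)) %% 4)
  apply(states, 1, function(r) length(unique(r)) > 1)
}

# chi-square goodness of fit with small-expectation cells pooled
chisqPatterns <- function(counts, probs, minExpected = 5) {
  n <- sum(counts)
  exp <- probs * n
  keep <- exp >= minExpected
  obs <- c(counts[keep], sum(counts[!keep]))
  ex <- c(exp[keep], sum(exp[!keep]))
  use <- ex > 0
  stat <- sum((obs[use] - ex[use])^2 / ex[use])
  df <- sum(use) - 1
  stats::pchisq(stat, df, lower.tail = FALSE)
}

# small deterministic trees for tests
treeFromNewick <- function(text, anchor) {
  newSimTree(ape::read.tree(text = text), anchor)
}

# genome built from an explicit sequence string
genomeFromString <- function(s, name = "chr") {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", name), s), fa)
  loadGenome(fa)
}

LISTERIA_RATES <- c(1.2070, 5.9306, 1.7425, 0.4610, 5.1238, 1)
LISTERIA_FREQS <- c(0.311521, 0.190709, 0.189125, 0.308645)
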