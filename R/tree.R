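# Tree IO and anchor-oriented edge traversal.

#' Load a phylogeny and orient it at the anchor tip
#'
#' Reads a Newick tree with branch lengths (expected substitutions per
#' site) and re-orients all edges away from the named anchor tip. For a
#' time-reversible stationary model the tip-pattern distribution is
#' invariant to root placement, so this is a representational choice that
#' makes the anchor structurally immutable: no edge subtends the anchor.
#' Zero-length edges are allowed (clonal replicates) and receive no
#' mutations or indel events.
#'
#' @param path Path to a Newick file.
#' @param anchor Label of the tip carrying the anchor genome.
#' @return A \linkS4class{SimTree}.
#' @examples
#' nwk <- tempfile(fileext = ".nwk")
#' writeLines("((A:0.1,B:0.1):0.05,C:0.2);", nwk)
#' tr <- loadTree(nwk, "A")
#' tipLabels(tr)
#' @export
loadTree <- function(path, anchor) {
  if (!file.exists(path)) fatal("tree file not found: ", path)
  phy <- ape::read.tree(path)
  if (is.null(phy)) fatal("could not parse Newick tree in ", path)
  newSimTree(phy, anchor)
}

#' Build a SimTree from a phylo object
#'
#' @param phy An \code{ape} \code{phylo} object with edge lengths.
#' @param anchor Anchor tip label.
#' @return A \linkS4class{SimTree}.
#' @export
newSimTree <- function(phy, anchor) {
  if (is.null(phy$tip.label) || any(is.na(phy$tip.label)) ||
      any(phy$tip.label == ""))
    fatal("tree has unlabeled tips")
  if (anyDuplicated(phy$tip.label))
    fatal("tree has duplicate tip labels")
  if (is.null(phy$edge.length))
    fatal("tree has no branch lengths; lengths in substitutions/site required")
  if (any(is.na(phy$edge.length)) || any(phy$edge.length < 0))
    fatal("tree has missing or negative branch lengths")
  if (!(anchor %in% phy$tip.label))
    fatal("anchor tip '", anchor, "' not in tree; available tips: ",
          paste(phy$tip.label, collapse = ", "))
  nTips <- length(phy$tip.label)
  if (nTips < 2L) fatal("tree must have at least 2 tips")
  nNodes <- nTips + phy$Nnode

  # orient every edge away from the anchor tip by BFS on the undirected graph
  adj <- vector("list", nNodes)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], i)
    adj[[b]] <- c(adj[[b]], i)
  }
  rootNode <- match(anchor, phy$tip.label)
  seen <- logical(nNodes); seen[rootNode] <- TRUE
  queue <- rootNode
  parent <- integer(0); child <- integer(0); len <- numeric(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ei in adj[[v]]) {
      w <- setdiff(phy$edge[ei, ], v)
      if (length(w) != 1L || seen[w]) next
      seen[w] <- TRUE
      parent <- c(parent, v); child <- c(child, w)
      len <- c(len, phy$edge.length[ei])
      queue <- c(queue, w)
    }
  }
  if (!all(seen[seq_len(nTips)])) fatal("tree is not connected")

  # tips subtended by each edge's child (walk edges in reverse BFS order)
  below <- vector("list", nNodes)
  for (t in seq_len(nTips)) below[[t]] <- t
  tipSets <- vector("list", length(child))
  for (i in rev(seq_along(child))) {
    tipSets[[i]] <- below[[child[i]]]
    below[[parent[i]]] <- c(below[[parent[i]]], below[[child[i]]])
  }

  new("SimTree", phy = phy, anchor = anchor,
      edges = cbind(parent = parent, child = child),
      lengths = len, tipLabels = phy$tip.label, tipSets = tipSets)
}

#' @describeIn loadTree Tip labels in node-index order.
#' @param tree A \linkS4class{SimTree}.
#' @export
tipLabels <- function(tree) tree@tipLabels

#' @describeIn loadTree The anchor tip label.
#' @export
anchorTip <- function(tree) tree@anchor

#' @describeIn loadTree Number of tips.
#' @export
nTips <- function(tree) length(tree@tipLabels)

setMethod("show", "SimTree", function(object) {
  cat("SimTree:", nTips(object), "tips, anchored at '", object@anchor,
      "'\n  total tree length: ", sum(object@lengths), "\n", sep = "")
})

# sum of branch lengths on the anchor-to-tip path, for tests and reporting
pathLengthFromAnchor <- function(tree, tip) {
  target <- match(tip, tree@tipLabels)
  if (is.na(target)) fatal("unknown tip: ", tip)
  par <- integer(max(tree@edges)); lens <- numeric(max(tree@edges))
  par[tree@edges[, "child"]] <- tree@edges[, "parent"]
  lens[tree@edges[, "child"]] <- tree@lengths
  root <- match(tree@anchor, tree@tipLabels)
  total <- 0; v <- target
  while (v != root) { total <- total + lens[v]; v <- par[v] }
  total
}
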