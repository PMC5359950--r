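# GTR model construction, transition probabilities, column simulation.

#' Build a GTR substitution model
#'
#' Constructs the rate matrix Q with Q_ij = s_ij * pi_j (i != j), where the
#' six symmetric exchangeabilities s are given in the order ac, ag, at, cg,
#' ct, gt and are normalised so gt = 1 (relative rates are scale-invariant).
#' The diagonal makes rows sum to zero and Q is rescaled so the expected
#' substitution rate at stationarity, -sum_i pi_i Q_ii, equals 1: branch
#' lengths are then in the conventional expected-substitutions-per-site
#' units.
#'
#' @param rates Six positive exchangeabilities (ac, ag, at, cg, ct, gt).
#' @param freqs Four stationary frequencies (A, C, G, T) summing to 1; a
#'   zero frequency is permitted (the state is unreachable).
#' @return A \linkS4class{GTRModel}.
#' @examples
#' jc <- buildGTR(rep(1, 6), rep(0.25, 4))
#' transitionProbs(jc, 0.1)
#' @export
buildGTR <- function(rates, freqs) {
  if (length(rates) != 6L || any(!is.finite(rates)) || any(rates <= 0))
    fatal("rates must be six positive reals (ac, ag, at, cg, ct, gt)")
  if (length(freqs) != 4L || any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
    fatal("freqs must be four non-negative reals summing to 1")
  rates <- rates / rates[6L]
  names(rates) <- c("ac", "ag", "at", "cg", "ct", "gt")
  freqs <- setNames(as.numeric(freqs), BASES)

  S <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  S["A", "C"] <- S["C", "A"] <- rates[["ac"]]
  S["A", "G"] <- S["G", "A"] <- rates[["ag"]]
  S["A", "T"] <- S["T", "A"] <- rates[["at"]]
  S["C", "G"] <- S["G", "C"] <- rates[["cg"]]
  S["C", "T"] <- S["T", "C"] <- rates[["ct"]]
  S["G", "T"] <- S["T", "G"] <- rates[["gt"]]
  Q <- S * rep(freqs, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  if (mu <= 0) fatal("degenerate model: zero total substitution rate")
  Q <- Q / mu
  new("GTRModel", rates = rates, freqs = freqs, Q = Q)
}

setMethod("show", "GTRModel", function(object) {
  cat("GTRModel\n  exchangeabilities:",
      paste(sprintf("%s=%.4g", names(object@rates), object@rates),
            collapse = " "),
      "\n  stationary freqs: ",
      paste(sprintf("%s=%.4f", names(object@freqs), object@freqs),
            collapse = " "), "\n")
})

#' Branch transition probabilities
#'
#' P(t) = expm(Q t) for a branch of length t expected substitutions per
#' site. Rows sum to 1; t = 0 gives the identity.
#'
#' @param model A \linkS4class{GTRModel}.
#' @param t Non-negative branch length.
#' @return 4x4 row-stochastic matrix over A, C, G, T.
#' @export
transitionProbs <- function(model, t) {
  if (!is.finite(t) || t < 0) fatal("branch length must be >= 0")
  if (t == 0) {
    P <- diag(4)
    dimnames(P) <- list(BASES, BASES)
    return(P)
  }
  P <- as.matrix(Matrix::expm(model@Q * t))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}

# cache of cumulative-probability matrices keyed by exact branch length
cumProbCache <- function(model) {
  env <- new.env(parent = emptyenv())
  function(t) {
    key <- sprintf("%.17g", t)
    cp <- env[[key]]
    if (is.null(cp)) {
      P <- transitionProbs(model, t)
      cp <- t(apply(P, 1L, cumsum))
      env[[key]] <- cp
    }
    cp
  }
}

#' Simulate alignment columns down the tree
#'
#' Draws the state at the tree's origin (the anchor tip, since the tree is
#' anchor-oriented) and propagates it along every edge: each child state is
#' drawn from the row of P(branch length) indexed by its parent state.
#' Under reversibility and stationarity this yields the same tip-pattern
#' distribution as rooting anywhere else. The origin state is drawn from
#' the stationary distribution unless \code{rootState} fixes it, which is
#' how columns are conditioned on the anchor base.
#'
#' @param model A \linkS4class{GTRModel}.
#' @param tree A \linkS4class{SimTree}.
#' @param n Number of independent columns.
#' @param rootState Optional base in {A,C,G,T} fixing the anchor state.
#' @return List with \code{tips}, an n x nTips character matrix of bases
#'   (column names are tip labels), and \code{variable}, logical(n) marking
#'   columns with at least two distinct tip bases.
#' @export
simulateColumns <- function(model, tree, n, rootState = NULL) {
  stopifnot(n >= 0)
  ntip <- nTips(tree)
  nNodes <- max(tree@edges)
  states <- matrix(0L, nrow = n, ncol = nNodes)
  root <- match(tree@anchor, tree@tipLabels)
  states[, root] <- if (is.null(rootState)) {
    sample.int(4L, n, replace = TRUE, prob = model@freqs)
  } else {
    rep.int(match(rootState, BASES), n)
  }
  getCum <- cumProbCache(model)
  for (i in seq_along(tree@lengths)) {
    p <- tree@edges[i, 1L]; ch <- tree@edges[i, 2L]; t <- tree@lengths[i]
    if (t == 0 || n == 0L) {
      states[, ch] <- states[, p]
    } else {
      cp <- getCum(t)
      u <- runif(n)
      states[, ch] <- 1L + as.integer(
        rowSums(cp[states[, p], , drop = FALSE] < u))
    }
  }
  tipInt <- states[, seq_len(ntip), drop = FALSE]
  cols <- asplit(tipInt, 2L)
  variable <- do.call(pmax, cols) != do.call(pmin, cols)
  tips <- matrix(BASES[tipInt], nrow = n, ncol = ntip,
                 dimnames = list(NULL, tree@tipLabels))
  list(tips = tips, variable = variable)
}
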