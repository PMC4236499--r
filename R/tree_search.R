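## Maximum-likelihood tree search on the binary encoding.
##
## Pipeline: pairwise ML distances -> neighbor joining start tree -> NNI hill
## climbing with branch re-optimization, accepting only strict improvements.
## Bootstrap supports come from column resampling of the encoding (adjacency,
## telomere and gene-family characters resampled jointly, as one alignment).

#' Search configuration
#'
#' @param max_rounds Maximum NNI acceptance rounds.
#' @param eps Minimum log-likelihood gain to accept a move / continue sweeps.
#' @param tol Brent tolerance for branch-length optimization.
#' @param max_len Upper bound on a branch length.
#' @param cap Distance cap for the NJ start (saturated pairs).
#' @param seed Optional RNG seed recorded in run metadata (the search itself
#'   is deterministic; the seed drives bootstrap and simulation).
#' @return A list of class \code{go_search_config}.
#' @export
search_config <- function(max_rounds = 50L, eps = 1e-4, tol = 1e-6,
                          max_len = 10, cap = 5, seed = NULL) {
  stopifnot(max_rounds >= 1L, eps > 0, tol > 0, max_len > 0, cap > 0)
  structure(list(max_rounds = as.integer(max_rounds), eps = eps, tol = tol,
                 max_len = max_len, cap = cap, seed = seed),
            class = "go_search_config")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (via \pkg{ape}); negative inferred branch lengths are clamped
#' to zero.
#'
#' @param d Symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return An unrooted \code{phylo} tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (anyNA(d) || any(!is.finite(d))) stop("distance matrix contains NA/Inf")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## All NNI rearrangements of a binary (possibly basal-trifurcation) tree.
## For internal edge u-v, exchanging one child subtree of v with a sibling
## subtree x of u yields the two alternative resolutions. Returns a list of
## candidates: tree plus the edge indices whose lengths a local
## re-optimization should revisit.
.nni_neighbors <- function(tree) {
  nt <- length(tree$tip.label)
  ce <- .children_edges(tree)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 2L]
    if (v <= nt) next                       # need an internal child
    u <- tree$edge[e, 1L]
    sib <- ce[[u]][ce[[u]] != e]
    if (!length(sib)) next                  # u is a root of degree 1 (cannot happen)
    x <- sib[1L]
    for (ci in ce[[v]]) {
      tr2 <- tree
      tr2$edge[x, 2L] <- tree$edge[ci, 2L]
      tr2$edge[ci, 2L] <- tree$edge[x, 2L]
      out[[length(out) + 1L]] <- list(tree = tr2,
                                      local = unique(c(e, x, ce[[v]], ce[[u]])))
    }
  }
  out
}

#' Maximum-likelihood tree search
#'
#' Starts from a neighbor-joining tree on pairwise ML distances, then hill
#' climbs over nearest-neighbor interchanges: every candidate is scored after
#' re-optimizing the branch lengths around the rearranged edge, the best
#' strictly-improving candidate is accepted and fully re-optimized, and the
#' search stops when no candidate improves the log-likelihood (or
#' \code{max_rounds} is hit). Deterministic given the input order.
#'
#' @param enc A \code{go_encoding} (>= 3 taxa; >= 4 for an actual search).
#' @param model A \code{go_model}.
#' @param config A \code{\link{search_config}}.
#' @return A list of class \code{go_ml_fit}: \code{tree} (unrooted
#'   \code{phylo} with optimized lengths), \code{loglik}, \code{trace}
#'   (log-likelihood after each accepted move), and \code{config}.
#' @export
ml_tree <- function(enc, model, config = search_config()) {
  stopifnot(inherits(enc, "go_encoding"), inherits(model, "go_model"))
  dm <- ml_distance_matrix(enc, model, cap = config$cap)
  tr <- nj_tree(dm)
  tr <- optimize_branch_lengths(tr, enc, model, eps = config$eps,
                                tol = config$tol, max_len = config$max_len)
  ll <- attr(tr, "loglik")
  trace <- ll
  if (length(enc$taxa) >= 4L) {
    for (round in seq_len(config$max_rounds)) {
      cands <- .nni_neighbors(tr)
      scores <- vapply(cands, function(cd) {
        ct <- optimize_branch_lengths(cd$tree, enc, model, edges = cd$local,
                                      max_sweeps = 1L, eps = config$eps,
                                      tol = config$tol, max_len = config$max_len)
        attr(ct, "loglik")
      }, 0)
      best <- which.max(scores)
      if (scores[best] <= ll + config$eps) break
      tr <- optimize_branch_lengths(cands[[best]]$tree, enc, model,
                                    max_sweeps = 5L, eps = config$eps,
                                    tol = config$tol, max_len = config$max_len)
      ll <- attr(tr, "loglik")
      trace <- c(trace, ll)
    }
  }
  attr(tr, "loglik") <- NULL
  structure(list(tree = tr, loglik = ll, trace = trace, config = config),
            class = "go_ml_fit")
}

#' @export
print.go_ml_fit <- function(x, ...) {
  cat("ML gene-order tree:", length(x$tree$tip.label), "taxa, log-likelihood",
      sprintf("%.4f", x$loglik), "after", length(x$trace) - 1L, "NNI move(s)\n")
  invisible(x)
}

## Non-trivial bipartitions of a tree as canonical keys (side not containing
## the alphabetically first taxon, sorted, pipe-joined).
.bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  all_t <- sort(tree$tip.label)
  ref <- all_t[1L]
  ce <- .children_edges(tree)
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  for (e in .postorder_edges(tree, ce)) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    below[[u]] <- c(below[[u]], below[[v]])
  }
  keys <- character(); edges <- integer(); nodes <- integer()
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 2L]
    if (v <= nt) next
    side <- below[[v]]
    if (length(side) < 2L || length(side) > nt - 2L) next
    if (ref %in% side) side <- setdiff(all_t, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    edges <- c(edges, e); nodes <- c(nodes, v)
  }
  list(keys = keys, edges = edges, nodes = nodes)
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two trees
#' (0 for identical unrooted topologies).
#'
#' @param t1,t2 \code{phylo} trees over the same leaf set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  k1 <- unique(.bipartitions(t1)$keys)
  k2 <- unique(.bipartitions(t2)$keys)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Bootstrap support for an ML gene-order tree
#'
#' Resamples encoding columns with replacement (all character classes jointly,
#' as one alignment), re-runs the ML search per replicate and annotates each
#' internal edge of the point-estimate tree with the percentage of replicates
#' whose tree contains the same bipartition. Supports are placed as integer
#' internal-node labels.
#'
#' @param enc,model,config As in \code{\link{ml_tree}}.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed (required: resampling must be reproducible).
#' @param fit Optional precomputed point estimate from \code{\link{ml_tree}}.
#' @param consensus If \code{TRUE}, also return the majority-rule consensus of
#'   the replicate trees.
#' @return The point-estimate \code{go_ml_fit} with \code{tree$node.label}
#'   carrying supports, plus elements \code{supports} (per internal edge) and
#'   optionally \code{consensus}.
#' @export
bootstrap_supports <- function(enc, model, replicates = 100L, seed,
                               config = search_config(), fit = NULL,
                               consensus = FALSE) {
  stopifnot(replicates >= 1L)
  if (missing(seed) || is.null(seed)) stop("bootstrap requires a seed")
  if (is.null(fit)) fit <- ml_tree(enc, model, config)
  set.seed(seed)
  C <- ncol(enc$mat)
  rep_trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    idx <- sample.int(C, C, replace = TRUE)
    rep_trees[[r]] <- ml_tree(.encoding_subset(enc, idx), model, config)$tree
  }
  bp <- .bipartitions(fit$tree)
  counts <- integer(length(bp$keys))
  for (tr in rep_trees) {
    rk <- unique(.bipartitions(tr)$keys)
    counts <- counts + (bp$keys %in% rk)
  }
  pct <- as.integer(round(100 * counts / replicates))
  nt <- length(fit$tree$tip.label)
  lab <- rep("", fit$tree$Nnode)
  lab[bp$nodes - nt] <- as.character(pct)
  fit$tree$node.label <- lab
  fit$supports <- setNames(pct, bp$keys)
  if (consensus)
    fit$consensus <- ape::consensus(rep_trees, p = 0.5)
  fit
}
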