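## Likelihood machinery: Felsenstein pruning over the binary encoding.
##
## Characters (encoding columns) are treated as independent two-state sites.
## Conditional likelihoods are scaled per node and per character to avoid
## underflow; the root prior is the stationary distribution, which together
## with detailed balance of the two-state chain makes the likelihood
## invariant to root placement.

## Robust 1-D maximization on [0, upper]: the likelihood in t is sharply
## peaked near 0 (rates scale with n) and flat near the stationary plateau,
## where plain Brent can stall. Bracket the maximum on a geometric grid
## first, then refine with Brent between the flanking grid points.
.max_1d <- function(f, upper, tol = 1e-8, n_grid = 24L) {
  ts <- c(0, exp(seq(log(1e-8), log(upper), length.out = n_grid)))
  vals <- vapply(ts, f, 0)
  i <- which.max(vals)
  lo <- ts[max(1L, i - 1L)]
  hi <- ts[min(length(ts), i + 1L)]
  if (lo >= hi) return(list(maximum = ts[i], objective = vals[i]))
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  if (vals[i] > opt$objective) list(maximum = ts[i], objective = vals[i])
  else opt
}

## transition matrix without argument checking (hot path)
.pmat <- function(model, t) {
  e <- exp(-(model$q01 + model$q10) * t)
  p0 <- model$pi[1L]; p1 <- model$pi[2L]
  matrix(c(p0 + p1 * e, p0 * (1 - e), p1 * (1 - e), p1 + p0 * e), 2L, 2L)
}

.children_edges <- function(tree) {
  ce <- vector("list", length(tree$tip.label) + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1L]
    ce[[u]] <- c(ce[[u]], e)
  }
  ce
}

## edge indices in postorder (children before parents)
.postorder_edges <- function(tree, ce = .children_edges(tree)) {
  res <- integer(nrow(tree$edge)); k <- 0L
  rec <- function(node) {
    for (e in ce[[node]]) {
      rec(tree$edge[e, 2L])
      k <<- k + 1L
      res[k] <<- e
    }
  }
  rec(length(tree$tip.label) + 1L)
  res
}

.check_tree_enc <- function(tree, enc) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  bad <- c(setdiff(tree$tip.label, enc$taxa), setdiff(enc$taxa, tree$tip.label))
  if (length(bad))
    stop("tree/encoding taxon mismatch: ", paste(unique(bad), collapse = ", "))
}

## Down (postorder) pass; optionally the up (preorder) pass too.
## Returns conditional likelihood tables D, outside-subtree tables U, their
## per-character log scale factors, per-edge child contributions cv, and the
## total log-likelihood.
.lik_workspace <- function(tree, enc, model, up = FALSE) {
  nt <- length(tree$tip.label); nn <- tree$Nnode; root <- nt + 1L
  X <- enc$mat[match(tree$tip.label, enc$taxa), , drop = FALSE]
  C <- ncol(X)
  ce <- .children_edges(tree)
  po <- .postorder_edges(tree, ce)
  E <- tree$edge; elen <- tree$edge.length

  D <- vector("list", nt + nn)
  logsc <- matrix(0, nt + nn, C)
  cv <- vector("list", nrow(E))
  for (i in seq_len(nt)) D[[i]] <- rbind(1 - X[i, ], X[i, ])

  for (e in po) {
    u <- E[e, 1L]; v <- E[e, 2L]
    if (v > nt) {                       # internal child now complete: rescale
      m <- pmax(D[[v]][1L, ], D[[v]][2L, ])
      m[m <= 0] <- 1
      D[[v]] <- D[[v]] / rep(m, each = 2L)
      logsc[v, ] <- logsc[v, ] + log(m)
    }
    P <- .pmat(model, elen[e])
    cv[[e]] <- P %*% D[[v]]
    if (is.null(D[[u]])) D[[u]] <- cv[[e]] else D[[u]] <- D[[u]] * cv[[e]]
    logsc[u, ] <- logsc[u, ] + logsc[v, ]
  }
  lr <- model$pi[1L] * D[[root]][1L, ] + model$pi[2L] * D[[root]][2L, ]
  ## a zero-length branch can make conflicting leaf states impossible;
  ## floor the per-character likelihood so the optimizer sees a finite value
  ll <- sum(log(pmax(lr, 1e-300)) + logsc[root, ])

  ws <- list(tree = tree, enc = enc, model = model, nt = nt, root = root,
             C = C, ce = ce, po = po, D = D, logsc = logsc, cv = cv, ll = ll)
  if (!up) return(ws)

  U <- vector("list", nt + nn)
  logscU <- matrix(0, nt + nn, C)
  U[[root]] <- rbind(rep(model$pi[1L], C), rep(model$pi[2L], C))
  for (e in rev(po)) {                   # preorder
    u <- E[e, 1L]; v <- E[e, 2L]
    G <- U[[u]]; sc <- logscU[u, ]
    for (e2 in ce[[u]]) if (e2 != e) {
      G <- G * cv[[e2]]
      sc <- sc + logsc[E[e2, 2L], ]
    }
    P <- .pmat(model, elen[e])
    Uv <- crossprod(P, G)
    m <- pmax(Uv[1L, ], Uv[2L, ])
    m[m <= 0] <- 1
    U[[v]] <- Uv / rep(m, each = 2L)
    logscU[v, ] <- sc + log(m)
  }
  ws$U <- U; ws$logscU <- logscU
  ws
}

#' Log-likelihood of an encoding on a tree
#'
#' Felsenstein pruning over independent binary characters, stationary root
#' prior. Valid for rooted and unrooted (\pkg{ape}-style basal multifurcation)
#' trees; by reversibility the value does not depend on root placement.
#'
#' @param tree A \code{phylo} tree with branch lengths; tip labels must match
#'   the encoding's taxa.
#' @param enc A \code{go_encoding}.
#' @param model A \code{go_model}.
#' @return The log-likelihood (a scalar).
#' @export
tree_log_likelihood <- function(tree, enc, model) {
  .check_tree_enc(tree, enc)
  stopifnot(inherits(enc, "go_encoding"), inherits(model, "go_model"))
  .lik_workspace(tree, enc, model)$ll
}

## Log-likelihood of one edge as a function of its length, all else fixed:
## ll(t) = sum_c log( sum_ab G[a,c] P_ab(t) D_v[b,c] ) + scale terms.
## G = outside-edge partial at the parent (prior included).
.edge_loglik_closure <- function(ws, e) {
  E <- ws$tree$edge
  u <- E[e, 1L]; v <- E[e, 2L]
  G <- ws$U[[u]]; sc <- ws$logscU[u, ]
  for (e2 in ws$ce[[u]]) if (e2 != e) {
    G <- G * ws$cv[[e2]]
    sc <- sc + ws$logsc[E[e2, 2L], ]
  }
  Dv <- ws$D[[v]]
  const <- sum(sc + ws$logsc[v, ])
  model <- ws$model
  function(t) {
    P <- .pmat(model, t)
    lr <- (G[1L, ] * P[1L, 1L] + G[2L, ] * P[2L, 1L]) * Dv[1L, ] +
          (G[1L, ] * P[1L, 2L] + G[2L, ] * P[2L, 2L]) * Dv[2L, ]
    sum(log(pmax(lr, 1e-300))) + const
  }
}

#' Optimize branch lengths by coordinate ascent
#'
#' One-dimensional (Brent) optimization of each branch in turn, sweeping until
#' the total log-likelihood gain falls below \code{eps}. The log-likelihood
#' never decreases across sweeps.
#'
#' @param tree,enc,model As in \code{\link{tree_log_likelihood}}.
#' @param edges Optional integer vector of edge indices (rows of
#'   \code{tree$edge}) to optimize; default all.
#' @param max_sweeps Maximum number of sweeps over the edges.
#' @param eps Stop when a full sweep improves the log-likelihood by less.
#' @param tol Brent tolerance for each branch.
#' @param max_len Upper bound on a branch length (expected changes per
#'   character).
#' @return The tree with optimized \code{edge.length}; the final
#'   log-likelihood is attached as attribute \code{"loglik"}.
#' @export
optimize_branch_lengths <- function(tree, enc, model, edges = NULL,
                                    max_sweeps = 10L, eps = 1e-4,
                                    tol = 1e-6, max_len = 10) {
  .check_tree_enc(tree, enc)
  if (is.null(edges)) edges <- seq_len(nrow(tree$edge))
  ll_prev <- -Inf
  for (sweep in seq_len(max_sweeps)) {
    for (e in edges) {
      ws <- .lik_workspace(tree, enc, model, up = TRUE)
      f <- .edge_loglik_closure(ws, e)
      opt <- .max_1d(f, max_len, tol = tol)
      tree$edge.length[e] <- opt$maximum
    }
    ll <- tree_log_likelihood(tree, enc, model)
    if (ll - ll_prev < eps) { ll_prev <- max(ll, ll_prev); break }
    ll_prev <- ll
  }
  attr(tree, "loglik") <- ll_prev
  tree
}

#' Maximum-likelihood distance between two encoded genomes
#'
#' The branch length t >= 0 maximizing the two-sequence likelihood
#' \code{prod_c pi[x_c] P_{x_c, y_c}(t)} under the reversible two-state
#' model. Saturated pairs return the cap.
#'
#' @param xi,yi Equal-length 0/1 vectors (encoding rows).
#' @param model A \code{go_model}.
#' @param cap Maximum reportable distance (default 5 expected changes).
#' @param tol Optimization tolerance.
#' @return The ML distance (scalar).
#' @export
pairwise_ml_distance <- function(xi, yi, model, cap = 5, tol = 1e-8) {
  if (length(xi) == 0L || length(xi) != length(yi)) stop("rows must be non-empty and equal length")
  n00 <- sum(xi == 0 & yi == 0); n01 <- sum(xi == 0 & yi == 1)
  n10 <- sum(xi == 1 & yi == 0); n11 <- sum(xi == 1 & yi == 1)
  if (n01 + n10 == 0L) return(0)
  p0 <- model$pi[1L]; p1 <- model$pi[2L]
  f <- function(t) {
    P <- .pmat(model, t)
    n00 * log(p0 * P[1L, 1L]) + n01 * log(p0 * P[1L, 2L]) +
      n10 * log(p1 * P[2L, 1L]) + n11 * log(p1 * P[2L, 2L])
  }
  opt <- .max_1d(f, cap, tol = tol)
  if (f(cap) >= opt$objective) return(cap)
  opt$maximum
}

#' Pairwise ML distance matrix of an encoding
#'
#' @param enc A \code{go_encoding}.
#' @inheritParams pairwise_ml_distance
#' @return A symmetric matrix of ML distances with zero diagonal.
#' @export
ml_distance_matrix <- function(enc, model, cap = 5, tol = 1e-8) {
  stopifnot(inherits(enc, "go_encoding"))
  X <- enc$mat
  k <- nrow(X)
  Dm <- matrix(0, k, k, dimnames = list(enc$taxa, enc$taxa))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    Dm[i, j] <- Dm[j, i] <- pairwise_ml_distance(X[i, ], X[j, ], model,
                                                 cap = cap, tol = tol)
  Dm
}
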