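# Independent oracles used across the suite. These deliberately avoid the
# package's pruning / DP code paths: likelihoods by exhaustive enumeration of
# internal states, posteriors by Bayes over full-tree likelihoods, TSP by
# brute-force tour enumeration, transition matrices by truncated series.

# wrap a plain 0/1 matrix as an encoding (adjacency-kind columns)
enc_from_matrix <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("c", seq_len(ncol(X)))
  meta <- data.frame(kind = rep("adjacency", ncol(X)),
                     left = NA_integer_, right = NA_integer_,
                     family = NA_integer_)
  rownames(meta) <- colnames(X)
  structure(list(taxa = rownames(X), mat = X, meta = meta),
            class = "go_encoding")
}

# exponential series for the 2-state generator, with scaling-and-squaring so
# large rate*t products do not lose precision to cancellation
series_pmat <- function(model, t, terms = 40L) {
  Q <- matrix(c(-model$q01, model$q10, model$q01, -model$q10), 2L, 2L)
  s <- max(0L, ceiling(log2(max(1, (model$q01 + model$q10) * t))))
  ts <- t / 2^s
  S <- diag(2); term <- diag(2)
  for (k in seq_len(terms)) {
    term <- term %*% (Q * ts) / k
    S <- S + term
  }
  for (i in seq_len(s)) S <- S %*% S
  S
}

# log-likelihood by summing over all internal-state assignments
brute_loglik <- function(tree, X, model) {
  nt <- length(tree$tip.label); nn <- tree$Nnode
  E <- tree$edge
  P <- lapply(tree$edge.length, function(t) transition_matrix(model, t))
  total <- 0
  for (cc in seq_len(ncol(X))) {
    xc <- X[match(tree$tip.label, rownames(X)), cc]
    lik <- 0
    for (a in 0:(2^nn - 1)) {
      st <- c(xc, as.integer(intToBits(a))[seq_len(nn)])
      pr <- model$pi[st[nt + 1] + 1]
      for (e in seq_len(nrow(E)))
        pr <- pr * P[[e]][st[E[e, 1]] + 1, st[E[e, 2]] + 1]
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

# posterior of state 1 at one internal node / character, by brute-force Bayes
brute_posterior <- function(tree, X, model, node, cc) {
  nt <- length(tree$tip.label); nn <- tree$Nnode
  E <- tree$edge
  P <- lapply(tree$edge.length, function(t) transition_matrix(model, t))
  xc <- X[match(tree$tip.label, rownames(X)), cc]
  liks <- c(0, 0)
  for (a in 0:(2^nn - 1)) {
    st <- c(xc, as.integer(intToBits(a))[seq_len(nn)])
    pr <- model$pi[st[nt + 1] + 1]
    for (e in seq_len(nrow(E)))
      pr <- pr * P[[e]][st[E[e, 1]] + 1, st[E[e, 2]] + 1]
    liks[st[node] + 1] <- liks[st[node] + 1] + pr
  }
  liks[2] / sum(liks)
}

# all permutations of 1..n (small n)
all_perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    rec <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      out
    }
    res <- rec(seq_len(n))
    cache[[key]] <<- res
    res
  }
})

# minimum Hamiltonian cycle weight by enumerating all tours (vertex 1 fixed)
brute_tsp_weight <- function(W) {
  n <- nrow(W)
  best <- Inf
  for (p in all_perms(n - 1L)) {
    tour <- c(1L, p + 1L)
    w <- sum(W[cbind(tour, c(tour[-1L], tour[1L]))])
    if (w < best) best <- w
  }
  best
}

# independent gene-order decoder: rebuild a duplication-free genome from its
# canonical adjacency/telomere set by walking extremity links
walk_rebuild <- function(adj) {
  fams <- sort(unique(abs(c(adj[, 1], adj[, 2]))))
  fams <- fams[fams != 0]
  ext <- function(f, end) paste0(f, end)         # "5h" / "5t"
  trail_of <- function(x) if (x > 0) ext(x, "h") else ext(-x, "t")
  lead_of <- function(x) if (x > 0) ext(x, "t") else ext(-x, "h")
  nbr <- character(); telo <- character()
  for (r in seq_len(nrow(adj))) {
    l <- adj[r, 1]; rr <- adj[r, 2]
    if (l == 0) telo <- c(telo, lead_of(rr))
    else if (rr == 0) telo <- c(telo, trail_of(l))
    else { a <- trail_of(l); b <- lead_of(rr); nbr[a] <- b; nbr[b] <- a }
  }
  other <- function(e) {
    f <- as.integer(sub("[th]$", "", e))
    if (grepl("t$", e)) ext(f, "h") else ext(f, "t")
  }
  visited <- setNames(rep(FALSE, length(fams)), fams)
  chroms <- list(); circ <- logical()
  for (e0 in sort(telo)) {
    f0 <- sub("[th]$", "", e0)
    if (visited[f0]) next
    genes <- integer(); e <- e0
    repeat {
      f <- as.integer(sub("[th]$", "", e))
      visited[as.character(f)] <- TRUE
      genes <- c(genes, if (grepl("t$", e)) f else -f)
      oe <- other(e)
      if (oe %in% telo && is.na(nbr[oe])) break
      if (is.na(nbr[oe])) break
      e <- unname(nbr[oe])
    }
    chroms[[length(chroms) + 1L]] <- genes; circ <- c(circ, FALSE)
  }
  for (f0 in fams[!visited[as.character(fams)]]) {
    if (visited[as.character(f0)]) next
    genes <- integer(); e <- ext(f0, "t")
    repeat {
      f <- as.integer(sub("[th]$", "", e))
      if (visited[as.character(f)]) break
      visited[as.character(f)] <- TRUE
      genes <- c(genes, if (grepl("t$", e)) f else -f)
      e <- unname(nbr[other(e)])
    }
    chroms[[length(chroms) + 1L]] <- genes; circ <- c(circ, TRUE)
  }
  genome("rebuilt", chroms, circ)
}

# a small simulated dataset shared by several tests
sim_dataset <- function(taxa = 6L, genes = 50L, seed = 1L,
                        config = sim_config(n_genes = genes, seed = seed + 1L)) {
  tree <- random_tree(taxa, seed = seed)
  evolve_genomes(tree, config)
}
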