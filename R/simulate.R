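## Genome rearrangement simulator: DCJ, deletion, insertion, duplication.
##
## DCJ is implemented on gene extremities: each gene copy (instance) k has a
## tail extremity 2k-1 and a head extremity 2k (relative to the family's
## forward orientation). A genome is a set of "slots": adjacency slots pair
## two extremities, telomere slots hold one. A DCJ removes two slots and
## rejoins the freed extremities one of the alternative ways; fusion,
## fission, translocation and inversion all emerge as special cases.

## ---- instance-level structure -------------------------------------------

.gstruct <- function(g) {
  fam <- integer(); chrom_inst <- list(); m <- 0L
  for (i in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[[i]]
    chrom_inst[[i]] <- m + seq_along(ch)
    m <- m + length(ch)
    fam <- c(fam, ch)                     # signed value as placed
  }
  list(fam = fam, chrom_inst = chrom_inst, circular = g$circular)
}

## ordered slot list: per chromosome, left telomere, internal adjacencies,
## right telomere (linear) or all adjacencies including the wrap (circular)
.slots <- function(gs) {
  slots <- list()
  for (i in seq_along(gs$chrom_inst)) {
    ids <- gs$chrom_inst[[i]]
    sg <- gs$fam[ids]
    lead  <- ifelse(sg > 0L, 2L * ids - 1L, 2L * ids)
    trail <- ifelse(sg > 0L, 2L * ids, 2L * ids - 1L)
    k <- length(ids)
    if (gs$circular[i]) {
      for (j in seq_len(k))
        slots[[length(slots) + 1L]] <- c(trail[j], lead[if (j == k) 1L else j + 1L])
    } else {
      slots[[length(slots) + 1L]] <- lead[1L]
      if (k > 1L) for (j in seq_len(k - 1L))
        slots[[length(slots) + 1L]] <- c(trail[j], lead[j + 1L])
      slots[[length(slots) + 1L]] <- trail[k]
    }
  }
  slots
}

## reading of extremity e as the trailing (right) end of a signed gene
.sig_trail <- function(e, fam_abs) {
  k <- (e + 1L) %/% 2L
  if (e %% 2L == 0L) fam_abs[k] else -fam_abs[k]
}
## reading of extremity e as the leading (left) end of a signed gene
.sig_lead <- function(e, fam_abs) {
  k <- (e + 1L) %/% 2L
  if (e %% 2L == 1L) fam_abs[k] else -fam_abs[k]
}

## canonical adjacency key of a slot
.slot_key <- function(slot, fam_abs) {
  if (length(slot) == 1L)
    .adj_key(canonical_adjacency(0L, .sig_lead(slot, fam_abs)))
  else
    .adj_key(canonical_adjacency(.sig_trail(slot[1L], fam_abs),
                                 .sig_lead(slot[2L], fam_abs)))
}

## rebuild chromosomes from a slot set; deterministic order (linear
## chromosomes by smallest telomeric extremity, then circular remainders)
.rebuild <- function(name, fam_abs, slots, drop_empty = FALSE) {
  m <- length(fam_abs)
  slot_of <- integer(2L * m)
  for (s in seq_along(slots)) for (e in slots[[s]]) slot_of[e] <- s
  visited <- logical(m)
  chroms <- list(); circ <- logical()
  telo <- sort(unlist(slots[lengths(slots) == 1L], use.names = FALSE))
  for (e0 in telo) {
    if (visited[(e0 + 1L) %/% 2L]) next
    genes <- integer(); e <- e0
    repeat {
      k <- (e + 1L) %/% 2L
      visited[k] <- TRUE
      genes <- c(genes, if (e %% 2L == 1L) fam_abs[k] else -fam_abs[k])
      o <- if (e %% 2L == 1L) e + 1L else e - 1L
      s <- slot_of[o]
      if (length(slots[[s]]) == 1L) break
      e <- slots[[s]][slots[[s]] != o]
    }
    chroms[[length(chroms) + 1L]] <- genes; circ <- c(circ, FALSE)
  }
  for (k0 in seq_len(m)) {
    if (visited[k0]) next
    genes <- integer(); e <- 2L * k0 - 1L
    repeat {
      k <- (e + 1L) %/% 2L
      if (visited[k]) break
      visited[k] <- TRUE
      genes <- c(genes, if (e %% 2L == 1L) fam_abs[k] else -fam_abs[k])
      o <- if (e %% 2L == 1L) e + 1L else e - 1L
      s <- slot_of[o]
      e <- slots[[s]][slots[[s]] != o]
    }
    chroms[[length(chroms) + 1L]] <- genes; circ <- c(circ, TRUE)
  }
  genome(name, chroms, circ)
}

## DCJ by slot indices (the replayable primitive)
.apply_dcj_slots <- function(g, i, j, rejoin = 1L) {
  gs <- .gstruct(g)
  slots <- .slots(gs)
  if (i == j || i > length(slots) || j > length(slots) || i < 1L || j < 1L)
    stop("invalid slot indices")
  s1 <- slots[[i]]; s2 <- slots[[j]]
  new_slots <- if (length(s1) == 2L && length(s2) == 2L) {
    if (rejoin == 1L) list(c(s1[1L], s2[1L]), c(s1[2L], s2[2L]))
    else              list(c(s1[1L], s2[2L]), c(s1[2L], s2[1L]))
  } else if (length(s1) == 2L && length(s2) == 1L) {
    if (rejoin == 1L) list(c(s1[1L], s2[1L]), s1[2L])
    else              list(c(s1[2L], s2[1L]), s1[1L])
  } else if (length(s1) == 1L && length(s2) == 2L) {
    if (rejoin == 1L) list(c(s2[1L], s1[1L]), s2[2L])
    else              list(c(s2[2L], s1[1L]), s2[1L])
  } else {
    list(c(s1[1L], s2[1L]))                 # fusion of two telomeres
  }
  slots <- c(slots[-c(i, j)], new_slots)
  .rebuild(g$name, abs(gs$fam), slots)
}

#' Apply one double-cut-and-join operation
#'
#' Cuts the two given adjacencies/telomeres and rejoins the freed gene ends.
#' With cuts (i,j) and (k,l), \code{rejoin = 1} joins the end of i with the
#' end of k (and the start of j with the start of l); \code{rejoin = 2} joins
#' crosswise. For a telomere cut the single freed end pairs with one freed
#' end of the other cut; two telomeres fuse (rejoin ignored). Gene content is
#' never altered; inversion, translocation, fusion and fission are all
#' special cases.
#'
#' @param g A \code{go_genome}.
#' @param cut1,cut2 Adjacencies as length-2 integer vectors \code{c(i, j)}
#'   (0 = chromosome end marker), e.g. \code{c(1, 2)} or \code{c(3, 0)}.
#'   With duplicated adjacencies the first occurrence (chromosome order,
#'   left to right) is cut.
#' @param rejoin 1 or 2, selecting the rejoining (see above).
#' @return The rearranged \code{go_genome}.
#' @examples
#' g <- genome("A", list(c(1L, 2L, 3L)))
#' apply_dcj(g, c(1, 2), c(3, 0), rejoin = 1)$chromosomes[[1]]  # 1 -3 -2
#' @export
apply_dcj <- function(g, cut1, cut2, rejoin = 1L) {
  stopifnot(inherits(g, "go_genome"), rejoin %in% c(1L, 2L))
  gs <- .gstruct(g)
  slots <- .slots(gs)
  fam_abs <- abs(gs$fam)
  keys <- vapply(slots, .slot_key, "", fam_abs = fam_abs)
  find_slot <- function(cut) {
    cut <- as.integer(cut)
    if (length(cut) != 2L) stop("cuts must be length-2 signed pairs")
    k <- .adj_key(canonical_adjacency(cut[1L], cut[2L]))
    w <- which(keys == k)
    if (!length(w)) stop("adjacency (", cut[1L], ",", cut[2L],
                         ") is not present in genome '", g$name, "'")
    w[1L]
  }
  i <- find_slot(cut1)
  j <- find_slot(cut2)
  if (i == j) stop("the two cuts name the same adjacency occurrence")
  ## orient the freed extremities to follow the user's written cut direction
  orient <- function(slot, cut) {
    if (length(slot) == 1L) return(slot)
    litt <- paste(as.integer(cut), collapse = ",")
    pa <- paste(c(.sig_trail(slot[1L], fam_abs), .sig_lead(slot[2L], fam_abs)),
                collapse = ",")
    if (litt == pa) slot else c(slot[2L], slot[1L])
  }
  s1 <- orient(slots[[i]], cut1); s2 <- orient(slots[[j]], cut2)
  slots[[i]] <- s1; slots[[j]] <- s2
  ## re-dispatch through the slot primitive with oriented slots
  new_slots <- if (length(s1) == 2L && length(s2) == 2L) {
    if (rejoin == 1L) list(c(s1[1L], s2[1L]), c(s1[2L], s2[2L]))
    else              list(c(s1[1L], s2[2L]), c(s1[2L], s2[1L]))
  } else if (length(s1) == 2L) {
    if (rejoin == 1L) list(c(s1[1L], s2[1L]), s1[2L])
    else              list(c(s1[2L], s2[1L]), s1[1L])
  } else if (length(s2) == 2L) {
    if (rejoin == 1L) list(c(s2[1L], s1[1L]), s2[2L])
    else              list(c(s2[2L], s1[1L]), s2[1L])
  } else list(c(s1[1L], s2[1L]))
  slots <- c(slots[-c(i, j)], new_slots)
  .rebuild(g$name, fam_abs, slots)
}

#' Content-modifying events: deletion, insertion, duplication
#'
#' \code{apply_deletion} removes a contiguous signed segment (a
#' whole-chromosome deletion removes the chromosome). \code{apply_insertion}
#' introduces a segment of brand-new gene families (ids continue from the
#' largest family id present). \code{apply_duplication} copies an existing
#' contiguous segment, optionally inverted, into any position.
#'
#' @param g A \code{go_genome}.
#' @param chrom Chromosome index.
#' @param start 1-based start of the segment.
#' @param len Segment length in genes.
#' @param pos Insertion gap: 0 inserts at the chromosome start, k after the
#'   k-th gene.
#' @param dest_chrom,dest_pos Destination chromosome and gap for the copy.
#' @param invert Insert the copied segment reversed and strand-flipped?
#' @return The modified \code{go_genome}.
#' @export
apply_deletion <- function(g, chrom, start, len) {
  stopifnot(inherits(g, "go_genome"))
  ch <- g$chromosomes[[chrom]]
  if (start < 1L || len < 1L || start + len - 1L > length(ch))
    stop("invalid deletion coordinates")
  if (len == length(ch)) {
    if (length(g$chromosomes) == 1L)
      stop("deletion would leave genome '", g$name, "' with zero genes")
    return(genome(g$name, g$chromosomes[-chrom], g$circular[-chrom]))
  }
  g$chromosomes[[chrom]] <- ch[-(start:(start + len - 1L))]
  g
}

#' @rdname apply_deletion
#' @export
apply_insertion <- function(g, chrom, pos, len) {
  stopifnot(inherits(g, "go_genome"))
  ch <- g$chromosomes[[chrom]]
  if (pos < 0L || pos > length(ch) || len < 1L) stop("invalid insertion coordinates")
  m <- max(abs(unlist(g$chromosomes)))
  seg <- m + seq_len(len)
  g$chromosomes[[chrom]] <- append(ch, seg, after = pos)
  g
}

#' @rdname apply_deletion
#' @export
apply_duplication <- function(g, chrom, start, len, dest_chrom = chrom,
                              dest_pos = start + len - 1L, invert = FALSE) {
  stopifnot(inherits(g, "go_genome"))
  ch <- g$chromosomes[[chrom]]
  if (start < 1L || len < 1L || start + len - 1L > length(ch))
    stop("invalid duplication source")
  seg <- ch[start:(start + len - 1L)]
  if (invert) seg <- rev(-seg)
  dch <- g$chromosomes[[dest_chrom]]
  if (dest_pos < 0L || dest_pos > length(dch)) stop("invalid duplication target")
  g$chromosomes[[dest_chrom]] <- append(dch, seg, after = dest_pos)
  g
}

## dispatcher used by evolve/replay
.apply_event <- function(g, kind, args) {
  switch(kind,
    dcj = .apply_dcj_slots(g, args$i, args$j, args$rejoin),
    deletion = apply_deletion(g, args$chrom, args$start, args$len),
    insertion = {
      g2 <- apply_insertion(g, args$chrom, args$pos, args$len)
      g2
    },
    duplication = apply_duplication(g, args$chrom, args$start, args$len,
                                    args$dest_chrom, args$dest_pos, args$invert),
    stop("unknown event kind: ", kind))
}

## ---- random event sampling ----------------------------------------------

.sample_segment_len <- function(p, cap) min(1L + rgeom(1L, p), cap)

.pick_gap <- function(g) {
  ## uniform over all insertion gaps (len+1 per chromosome)
  gaps <- lengths(g$chromosomes) + 1L
  u <- sample.int(sum(gaps), 1L)
  ch <- findInterval(u - 1L, cumsum(c(0L, gaps)), rightmost.closed = TRUE)
  list(chrom = ch, pos = u - c(0L, cumsum(gaps))[ch] - 1L)
}

.random_event <- function(g, kind, seg_p) {
  ## returns list(kind, args) or NULL when the event is not applicable
  lens <- lengths(g$chromosomes)
  if (kind == "dcj") {
    sl <- .slots(.gstruct(g))
    ns <- length(sl)
    if (ns < 2L) return(NULL)
    ij <- sample.int(ns, 2L)
    both_telo <- length(sl[[ij[1L]]]) == 1L && length(sl[[ij[2L]]]) == 1L
    rejoin <- if (both_telo) 1L else sample.int(2L, 1L)
    list(kind = "dcj", args = list(i = ij[1L], j = ij[2L], rejoin = rejoin))
  } else if (kind == "deletion") {
    ch <- sample.int(length(lens), 1L, prob = lens)
    len <- .sample_segment_len(seg_p, lens[ch])
    if (sum(lens) - len < 1L)
      stop("genome annihilated by deletions; lower the deletion rate")
    start <- sample.int(lens[ch] - len + 1L, 1L)
    list(kind = "deletion", args = list(chrom = ch, start = start, len = len))
  } else if (kind == "insertion") {
    gap <- .pick_gap(g)
    len <- .sample_segment_len(seg_p, .Machine$integer.max)
    list(kind = "insertion", args = list(chrom = gap$chrom, pos = gap$pos, len = len))
  } else if (kind == "duplication") {
    ch <- sample.int(length(lens), 1L, prob = lens)
    len <- .sample_segment_len(seg_p, lens[ch])
    start <- sample.int(lens[ch] - len + 1L, 1L)
    gap <- .pick_gap(g)
    list(kind = "duplication",
         args = list(chrom = ch, start = start, len = len,
                     dest_chrom = gap$chrom, dest_pos = gap$pos,
                     invert = runif(1L) < 0.5))
  } else stop("unknown event kind: ", kind)
}

#' Exhaustive one-step DCJ loss probability
#'
#' Enumerates every one-step DCJ outcome on a single linear chromosome with
#' \code{n} genes -- all unordered pairs of its n+1 adjacencies/telomeres,
#' each with its available rejoinings -- and returns the probability that a
#' fixed internal adjacency is destroyed. Equals 2/(n+1): a uniformly chosen
#' pair includes the fixed adjacency with that probability, and no rejoining
#' of a cut pair can recreate it. This grounds the model's loss probability.
#'
#' @param n Number of genes (>= 3).
#' @return The enumerated destruction probability.
#' @export
dcj_break_probability <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 3L)
  g <- genome("g", list(seq_len(n)))
  sl <- .slots(.gstruct(g))
  S <- length(sl)
  fixed <- .adj_key(canonical_adjacency(1L, 2L))
  tot <- 0
  for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
    rejoins <- if (length(sl[[i]]) == 1L && length(sl[[j]]) == 1L) 1L else 1:2
    destroyed <- vapply(rejoins, function(r) {
      g2 <- .apply_dcj_slots(g, i, j, r)
      !(fixed %in% .adj_key(genome_adjacencies(g2)))
    }, TRUE)
    tot <- tot + mean(destroyed)
  }
  tot / choose(S, 2)
}

## ---- simulation ----------------------------------------------------------

#' Simulation configuration
#'
#' @param n_genes Gene families in the root genome.
#' @param chromosomes Number of chromosomes in the root genome.
#' @param circular Are the root chromosomes circular?
#' @param events_per_branch Fixed expected event count per branch. When
#'   \code{rate_scale} is given instead, the per-branch count is
#'   Poisson(branch length x rate_scale).
#' @param poisson Draw the per-branch count from a Poisson with mean
#'   \code{events_per_branch} (otherwise the count is fixed)?
#' @param rate_scale Optional rate tying event counts to branch lengths.
#' @param probs Event-type probabilities (dcj, deletion, insertion,
#'   duplication); must sum to 1.
#' @param seg_p Geometric parameter for indel/duplication segment lengths.
#' @param seed RNG seed (required by \code{\link{evolve_genomes}}).
#' @return A list of class \code{go_sim_config}.
#' @export
sim_config <- function(n_genes = 100L, chromosomes = 1L, circular = FALSE,
                       events_per_branch = 3, poisson = FALSE,
                       rate_scale = NULL,
                       probs = c(dcj = 0.9, deletion = 0.1 / 3,
                                 insertion = 0.1 / 3, duplication = 0.1 / 3),
                       seg_p = 0.5, seed = NULL) {
  stopifnot(n_genes >= 1L, chromosomes >= 1L, chromosomes <= n_genes,
            events_per_branch >= 0, seg_p > 0, seg_p <= 1)
  if (abs(sum(probs) - 1) > 1e-12) stop("event probabilities must sum to 1")
  if (!setequal(names(probs), c("dcj", "deletion", "insertion", "duplication")))
    stop("probs must name dcj, deletion, insertion, duplication")
  structure(list(n_genes = as.integer(n_genes),
                 chromosomes = as.integer(chromosomes),
                 circular = circular,
                 events_per_branch = events_per_branch,
                 poisson = poisson, rate_scale = rate_scale,
                 probs = probs[c("dcj", "deletion", "insertion", "duplication")],
                 seg_p = seg_p, seed = seed),
            class = "go_sim_config")
}

#' Random binary tree
#'
#' Uniform random topology by successive random attachment of each new leaf
#' to a uniformly chosen branch; branch lengths are exponential.
#'
#' @param ntaxa Number of leaves (>= 3).
#' @param seed Optional RNG seed.
#' @param mean_branch Mean of the exponential branch lengths.
#' @return A rooted binary \code{phylo} tree with tips \code{t1..tN}.
#' @export
random_tree <- function(ntaxa, seed = NULL, mean_branch = 1) {
  ntaxa <- as.integer(ntaxa)
  if (ntaxa < 3L) stop("need at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  root <- ntaxa + 1L
  parent <- c(root, root); child <- c(1L, 2L)
  nxt <- ntaxa + 2L
  for (k in 3L:ntaxa) {
    e <- sample.int(length(parent), 1L)
    m <- nxt; nxt <- nxt + 1L
    c_old <- child[e]
    child[e] <- m
    parent <- c(parent, m, m); child <- c(child, c_old, k)
  }
  tr <- structure(list(edge = cbind(parent, child),
                       tip.label = paste0("t", seq_len(ntaxa)),
                       Nnode = ntaxa - 1L,
                       edge.length = rexp(length(parent), 1 / mean_branch)),
                  class = "phylo")
  dimnames(tr$edge) <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

## preorder internal-node order (root first); used for A1.. ancestor labels
.preorder_internal <- function(tree) {
  nt <- length(tree$tip.label)
  ce <- .children_edges(tree)
  out <- integer()
  rec <- function(node) {
    if (node > nt) {
      out[length(out) + 1L] <<- node
      for (e in ce[[node]]) rec(tree$edge[e, 2L])
    }
  }
  rec(nt + 1L)
  out
}

#' Label internal nodes A1, A2, ... in preorder
#'
#' @param tree A \code{phylo} tree.
#' @param overwrite Replace existing labels?
#' @return The tree with \code{node.label} set.
#' @export
label_ancestors <- function(tree, overwrite = FALSE) {
  if (!is.null(tree$node.label) && !overwrite &&
      all(nzchar(tree$node.label))) return(tree)
  nt <- length(tree$tip.label)
  lab <- character(tree$Nnode)
  lab[.preorder_internal(tree) - nt] <- paste0("A", seq_len(tree$Nnode))
  tree$node.label <- lab
  tree
}

#' Evolve genomes along a tree
#'
#' Starts from the identity root genome (genes 1..n split contiguously into
#' the configured chromosomes) and applies, along every branch in preorder, a
#' number of random events (fixed or Poisson); each event's kind is drawn
#' from the configured distribution and DCJ operands are chosen uniformly
#' over the current adjacencies and telomeres. Fully reproducible from the
#' seed.
#'
#' @param tree A rooted \code{phylo} tree with branch lengths.
#' @param config A \code{\link{sim_config}} (its \code{seed} must be set).
#' @return A list of class \code{go_sim}: \code{leaves} and \code{ancestors}
#'   (\code{go_genomes}), \code{tree} (internal nodes labeled A1..), and
#'   \code{log} (replayable event log, one record per event).
#' @export
evolve_genomes <- function(tree, config = sim_config()) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "go_sim_config"))
  if (is.null(config$seed)) stop("simulation requires a seed in sim_config()")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  set.seed(config$seed)
  tree <- label_ancestors(tree)
  nt <- length(tree$tip.label)

  n <- config$n_genes; nc <- config$chromosomes
  breaks <- floor(seq(0L, n, length.out = nc + 1L))
  chroms <- lapply(seq_len(nc), function(i) seq.int(breaks[i] + 1L, breaks[i + 1L]))
  root_g <- genome("root", chroms, rep(config$circular, nc))

  node_name <- function(v) if (v <= nt) tree$tip.label[v] else
    tree$node.label[v - nt]

  genomes <- vector("list", nt + tree$Nnode)
  genomes[[nt + 1L]] <- root_g
  log <- list()
  ce <- .children_edges(tree)
  kinds <- names(config$probs)

  rec <- function(node) {
    for (e in ce[[node]]) {
      v <- tree$edge[e, 2L]
      g <- genomes[[node]]
      nev <- if (!is.null(config$rate_scale))
        rpois(1L, tree$edge.length[e] * config$rate_scale)
      else if (config$poisson) rpois(1L, config$events_per_branch)
      else as.integer(round(config$events_per_branch))
      k <- 0L
      while (k < nev) {
        kind <- sample(kinds, 1L, prob = config$probs)
        ev <- .random_event(g, kind, config$seg_p)
        if (is.null(ev)) next                 # inapplicable; redraw
        g <- .apply_event(g, ev$kind, ev$args)
        if (sum(lengths(g$chromosomes)) < 1L)
          stop("genome annihilated by deletions; lower the deletion rate")
        log[[length(log) + 1L]] <<- c(list(branch = node_name(v)), ev)
        k <- k + 1L
      }
      g$name <- node_name(v)
      genomes[[v]] <<- g
      if (v > nt) rec(v)
    }
  }
  rec(nt + 1L)

  leaves <- genome_set(genomes[seq_len(nt)])
  anc <- genomes[(nt + 1L):(nt + tree$Nnode)]
  for (i in seq_along(anc)) anc[[i]]$name <- tree$node.label[i]
  structure(list(leaves = leaves, ancestors = genome_set(anc),
                 tree = tree, log = log, config = config),
            class = "go_sim")
}

#' Replay an event log
#'
#' Applies the recorded events branch by branch from the root genome;
#' reproduces every node genome of the original simulation exactly.
#'
#' @param sim A \code{go_sim} result.
#' @return A list of reconstructed genomes named by node (leaves and
#'   ancestors).
#' @export
replay_events <- function(sim) {
  stopifnot(inherits(sim, "go_sim"))
  tree <- sim$tree
  nt <- length(tree$tip.label)
  ce <- .children_edges(tree)
  node_name <- function(v) if (v <= nt) tree$tip.label[v] else
    tree$node.label[v - nt]
  root_g <- sim$ancestors[[tree$node.label[1L]]]
  by_branch <- split(sim$log, vapply(sim$log, `[[`, "", "branch"))
  out <- list()
  rec <- function(node, g) {
    out[[node_name(node)]] <<- g
    for (e in ce[[node]]) {
      v <- tree$edge[e, 2L]
      gv <- g
      for (ev in by_branch[[node_name(v)]])
        gv <- .apply_event(gv, ev$kind, ev$args)
      gv$name <- node_name(v)
      rec(v, gv)
    }
  }
  ## root label is the first preorder internal label
  root <- nt + 1L
  rg <- root_g; rg$name <- node_name(root)
  rec(root, rg)
  out
}
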