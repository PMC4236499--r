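## Ancestral genome inference (the small phylogeny stage).
##
## 1. Marginal posterior of every binary character at every internal node
##    (one down pass + one up pass of conditional likelihoods).
## 2. Gene content: a family is ancestral iff its posterior presence
##    probability strictly exceeds the threshold (default 50%).
## 3. Adjacency assembly: candidate adjacencies (the encoding's columns,
##    filtered to present genes) become edges of a Travelling Salesperson
##    instance over gene extremities, with weight -ln p; per-gene head-tail
##    edges are mandatory and 2L chromosome-cap vertices yield L linear
##    chromosomes. The minimal tour decodes into the ancestral gene order.

#' Marginal posterior probabilities of ancestral states
#'
#' For each internal node and character, the posterior probability of the
#' presence state given tree, branch lengths and model, computed by combining
#' the downward conditional likelihood with the upward partial likelihood
#' (stationary prior at the root) and normalizing over the two states.
#'
#' Unrooted trees are rooted at the midpoint of the longest path first (an
#' outgroup can be enforced by supplying an already-rooted tree); by
#' reversibility the likelihood itself is root-invariant, but node identities
#' require a declared root.
#'
#' @param tree A \code{phylo} tree with branch lengths.
#' @param enc A \code{go_encoding}; taxa must match the tree's tips.
#' @param model A \code{go_model}.
#' @return A \code{go_posteriors}: list with \code{tree} (rooted, internal
#'   nodes labeled), \code{prob} (internal nodes x characters matrix of
#'   presence posteriors) and \code{meta} (the encoding's column metadata).
#' @export
marginal_posteriors <- function(tree, enc, model) {
  .check_tree_enc(tree, enc)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree <- label_ancestors(tree)
  ws <- .lik_workspace(tree, enc, model, up = TRUE)
  nt <- length(tree$tip.label)
  prob <- matrix(NA_real_, tree$Nnode, ws$C,
                 dimnames = list(tree$node.label, colnames(enc$mat)))
  for (v in (nt + 1L):(nt + tree$Nnode)) {
    w1 <- ws$U[[v]][2L, ] * ws$D[[v]][2L, ]
    w0 <- ws$U[[v]][1L, ] * ws$D[[v]][1L, ]
    prob[v - nt, ] <- w1 / (w0 + w1)
  }
  structure(list(tree = tree, prob = prob, meta = enc$meta),
            class = "go_posteriors")
}

#' @export
print.go_posteriors <- function(x, ...) {
  cat("Ancestral state posteriors:", nrow(x$prob), "internal node(s) x",
      ncol(x$prob), "characters\n")
  invisible(x)
}

#' Write per-node adjacency posteriors as TSV
#'
#' @param post A \code{go_posteriors}.
#' @param file Output path.
#' @export
write_posteriors_tsv <- function(post, file) {
  stopifnot(inherits(post, "go_posteriors"))
  df <- data.frame(node = rep(rownames(post$prob), each = ncol(post$prob)),
                   character = rep(colnames(post$prob), nrow(post$prob)),
                   kind = rep(post$meta$kind, nrow(post$prob)),
                   posterior = as.vector(t(post$prob)))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Ancestral gene content from posteriors
#'
#' A gene family is deemed present at a node iff its posterior strictly
#' exceeds the threshold. Candidate adjacencies and telomeres keep their
#' posteriors; candidates touching an absent gene are dropped (the count of
#' dropped candidates is recorded per node).
#'
#' @param post A \code{go_posteriors}.
#' @param threshold Presence probability cutoff in (0,1); default 0.5.
#' @return A \code{go_content}: per node, \code{genes} (present family ids),
#'   \code{adj} (data frame: left, right, kind, p) and \code{dropped}.
#' @export
infer_gene_content <- function(post, threshold = 0.5) {
  stopifnot(inherits(post, "go_posteriors"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  meta <- post$meta
  is_fam <- meta$kind == "gene_family"
  nodes <- lapply(rownames(post$prob), function(nd) {
    p <- post$prob[nd, ]
    genes <- meta$family[is_fam & p > threshold]
    adj <- data.frame(left = meta$left[!is_fam], right = meta$right[!is_fam],
                      kind = meta$kind[!is_fam], p = p[!is_fam],
                      stringsAsFactors = FALSE)
    touches <- function(x) x == 0L | abs(x) %in% genes
    keep <- touches(adj$left) & touches(adj$right)
    list(genes = sort(genes), adj = adj[keep, , drop = FALSE],
         dropped = sum(!keep))
  })
  structure(list(nodes = setNames(nodes, rownames(post$prob)),
                 threshold = threshold),
            class = "go_content")
}

#' Build the adjacency-assembly TSP instance for one node
#'
#' Vertices are the two extremities (tail, head) of every present gene plus
#' 2L chromosome caps, where L = max(1, round(sum of telomere posteriors /
#' 2)). A candidate adjacency with posterior p gets edge weight -ln(max(p,
#' epsilon)); any other extremity pair costs -ln(epsilon); cap-cap edges are
#' free; each gene's tail-head edge gets a large negative weight so every
#' optimal tour traverses all genes.
#'
#' @param content_node One element of \code{infer_gene_content()$nodes}.
#' @param epsilon Floor probability for non-candidate adjacencies.
#' @return A \code{go_tsp}: weight matrix \code{w}, \code{genes},
#'   \code{caps} (cap vertex indices), \code{L} and \code{labels}.
#' @export
build_tsp <- function(content_node, epsilon = 1e-6) {
  genes <- content_node$genes
  adj <- content_node$adj
  if (!length(genes)) stop("no present genes: nothing to assemble")
  stopifnot(epsilon > 0, epsilon < 1)
  G <- length(genes)
  tel_mass <- sum(adj$p[adj$kind == "telomere"])
  L <- max(1L, as.integer(floor(tel_mass / 2 + 0.5)))
  V <- 2L * G + 2L * L
  labels <- c(paste0(rep(c("t", "h"), G), rep(genes, each = 2L)),
              paste0("cap", seq_len(2L * L)))
  caps <- 2L * G + seq_len(2L * L)
  w <- matrix(-log(epsilon), V, V, dimnames = list(labels, labels))
  w[caps, caps] <- 0
  idx <- function(fam) match(fam, genes)                 # gene position
  trail_of <- function(x) if (x > 0L) 2L * idx(x) else 2L * idx(-x) - 1L
  lead_of  <- function(x) if (x > 0L) 2L * idx(x) - 1L else 2L * idx(-x)
  for (r in seq_len(nrow(adj))) {
    p <- max(adj$p[r], epsilon)
    if (adj$kind[r] == "telomere") {
      k <- if (adj$left[r] == 0L) adj$right[r] else stop("malformed telomere")
      e <- lead_of(k)
      w[caps, e] <- w[e, caps] <- -log(p)
    } else {
      a <- trail_of(adj$left[r]); b <- lead_of(adj$right[r])
      if (a == b) next                                   # needs 2 copies; skip
      w[a, b] <- w[b, a] <- -log(p)
    }
  }
  B <- sum(abs(w[upper.tri(w)])) + 1
  for (i in seq_len(G)) w[2L * i - 1L, 2L * i] <- w[2L * i, 2L * i - 1L] <- -B
  diag(w) <- 0
  structure(list(w = w, genes = genes, caps = caps, L = L, labels = labels,
                 epsilon = epsilon, B = B),
            class = "go_tsp")
}

#' Solve a TSP instance
#'
#' Exact mode runs Held-Karp dynamic programming (provably minimal tour, up
#' to 18 vertices); heuristic mode runs greedy nearest-neighbor from a seeded
#' start followed by 2-opt until no improving swap remains. \code{auto}
#' picks exact when the instance is small enough.
#'
#' @param instance A \code{go_tsp}.
#' @param mode "auto", "exact" or "heuristic".
#' @param seed Seed for the heuristic start vertex.
#' @return List with \code{tour} (vertex indices, cyclic) and \code{weight}.
#' @export
solve_tsp <- function(instance, mode = c("auto", "exact", "heuristic"),
                      seed = 1L) {
  stopifnot(inherits(instance, "go_tsp"))
  mode <- match.arg(mode)
  V <- nrow(instance$w)
  if (mode == "auto") mode <- if (V <= 18L) "exact" else "heuristic"
  if (mode == "exact") {
    if (V > 18L)
      stop("instance has ", V, " vertices; exact mode handles at most 18, ",
           "use mode = 'heuristic'")
    tour <- held_karp_cpp(instance$w)
    list(tour = as.integer(tour), weight = attr(tour, "weight"), mode = "exact")
  } else {
    set.seed(seed)
    start <- sample.int(V, 1L)
    res <- nn_two_opt_cpp(instance$w, start)
    list(tour = as.integer(res$tour), weight = res$weight, mode = "heuristic")
  }
}

#' Decode a tour into an ancestral genome
#'
#' Cuts the cyclic tour at cap vertices; every cap-to-cap path alternates
#' mandatory gene edges with adjacency edges and decodes to one linear
#' chromosome, the traversal direction of each gene fixing its sign.
#'
#' @param tour Integer vertex tour from \code{\link{solve_tsp}}.
#' @param instance The \code{go_tsp} the tour solves.
#' @param name Name for the resulting genome (typically the node label).
#' @return A \code{go_genome} with linear chromosomes.
#' @export
assemble_genome <- function(tour, instance, name = "ancestor") {
  stopifnot(inherits(instance, "go_tsp"))
  V <- nrow(instance$w)
  if (!setequal(tour, seq_len(V))) stop("tour must visit every vertex once")
  is_cap <- tour %in% instance$caps
  if (!any(is_cap)) stop("tour contains no cap vertex")
  ## rotate so the tour starts at a cap
  s <- which(is_cap)[1L]
  tour <- c(tour[s:V], tour[seq_len(s - 1L)])
  is_cap <- tour %in% instance$caps
  segs <- split(tour[!is_cap], cumsum(is_cap)[!is_cap])
  chroms <- list()
  for (seg in segs) {
    k <- length(seg)
    if (k == 0L) next
    if (k %% 2L != 0L) stop("internal error: tour breaks gene alternation")
    genes <- integer(k / 2L)
    for (i in seq_len(k / 2L)) {
      a <- seg[2L * i - 1L]; b <- seg[2L * i]
      ga <- (a + 1L) %/% 2L
      if (b != (if (a %% 2L == 1L) a + 1L else a - 1L))
        stop("internal error: tour breaks gene alternation")
      genes[i] <- if (a %% 2L == 1L) instance$genes[ga] else -instance$genes[ga]
    }
    chroms[[length(chroms) + 1L]] <- genes
  }
  if (!length(chroms)) stop("tour decodes to an empty genome")
  ## the tour direction and cut point are arbitrary; fix a reading direction
  ## (majority-positive strand, then smaller leading gene) and sort
  ## chromosomes so equal assemblies serialize identically
  chroms <- lapply(chroms, function(genes) {
    alt <- rev(-genes)
    if (sum(genes > 0L) > sum(alt > 0L)) genes
    else if (sum(genes > 0L) < sum(alt > 0L)) alt
    else if (genes[1L] <= alt[1L]) genes else alt
  })
  chroms <- chroms[order(vapply(chroms, function(g) min(abs(g)), 0))]
  genome(name, chroms, rep(FALSE, length(chroms)))
}

#' Infer ancestral genomes for every internal node
#'
#' Runs the full small-phylogeny stage: marginal posteriors, gene-content
#' thresholding, TSP construction and solution, and tour decoding, for every
#' internal node of the (rooted) tree.
#'
#' @inheritParams marginal_posteriors
#' @param threshold Gene-content posterior cutoff.
#' @param epsilon Floor probability for non-candidate adjacencies.
#' @param mode TSP mode, see \code{\link{solve_tsp}}.
#' @param seed Seed for the heuristic TSP start.
#' @return A list of class \code{go_ancestors}: \code{genomes}
#'   (\code{go_genomes}, one per internal node, named by node label),
#'   \code{posteriors}, \code{content} and the rooted labeled \code{tree}.
#' @export
infer_ancestral_genomes <- function(tree, enc, model, threshold = 0.5,
                                    epsilon = 1e-6, mode = "auto", seed = 1L) {
  post <- marginal_posteriors(tree, enc, model)
  content <- infer_gene_content(post, threshold)
  gs <- vector("list", length(content$nodes))
  for (i in seq_along(content$nodes)) {
    nd <- names(content$nodes)[i]
    inst <- build_tsp(content$nodes[[i]], epsilon)
    sol <- solve_tsp(inst, mode, seed = seed)
    gs[[i]] <- assemble_genome(sol$tour, inst, name = nd)
  }
  structure(list(genomes = genome_set(gs), posteriors = post,
                 content = content, tree = post$tree),
            class = "go_ancestors")
}

#' @export
print.go_ancestors <- function(x, ...) {
  cat("Ancestral genomes for", length(x$genomes), "internal node(s):",
      paste(names(x$genomes), collapse = ", "), "\n")
  invisible(x)
}
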