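test_that("marginal posteriors match brute-force Bayes enumeration", {
  set.seed(5)
  for (r in 1:6) {
    nt <- sample(4:6, 1)
    tr <- random_tree(nt, seed = 400 + r, mean_branch = 0.5)
    X <- matrix(rbinom(nt * 8, 1, 0.5), nt, 8,
                dimnames = list(tr$tip.label, NULL))
    enc <- enc_from_matrix(X)
    m <- adjacency_model(sample(3:12, 1))
    post <- marginal_posteriors(tr, enc, m)
    for (v in seq_len(tr$Nnode)) for (cc in 1:8) {
      expect_equal(post$prob[v, cc],
                   brute_posterior(tr, X, m, nt + v, cc), tolerance = 1e-9)
    }
    expect_true(all(post$prob >= 0 & post$prob <= 1))
  }
})

test_that("posterior degenerate and closed-form cases behave", {
  m <- adjacency_model(5)
  tr <- read_newick(text = "((A:0,B:0):0,(C:0,D:0):0);")
  X <- matrix(1L, 4, 3, dimnames = list(LETTERS[1:4], NULL))
  post <- marginal_posteriors(tr, enc_from_matrix(X), m)
  expect_true(all(post$prob == 1))

  # symmetric model, star tree, leaves {1,1,0}: presence wins but not surely
  ms <- adjacency_model(1, ratio = 1)
  star <- read_newick(text = "(A:0.3,B:0.3,C:0.3);")
  Xs <- matrix(c(1L, 1L, 0L), 3, 1, dimnames = list(c("A", "B", "C"), NULL))
  ps <- marginal_posteriors(star, enc_from_matrix(Xs), ms)
  expect_gt(ps$prob[1, 1], 0.5)
  expect_lt(ps$prob[1, 1], 1)
  # closed form: root posterior on a 3-star by direct summation
  P <- transition_matrix(ms, 0.3)
  w1 <- 0.5 * P[2, 2]^2 * P[2, 1]
  w0 <- 0.5 * P[1, 2]^2 * P[1, 1]
  expect_equal(ps$prob[1, 1], w1 / (w0 + w1), tolerance = 1e-12)

  expect_error(marginal_posteriors(ape::rtree(4, br = NULL),
                                   enc_from_matrix(matrix(0L, 4, 1,
                                     dimnames = list(paste0("t", 1:4), NULL))),
                                   m),
               "branch lengths")
})

test_that("gene content uses a strict majority of posterior mass", {
  # synthetic posterior table: 3 gene families + adjacencies among them
  key <- function(l, r) gophylo:::.adj_key(canonical_adjacency(l, r))
  cols <- c(key(1, 2), key(2, 3), key(0, 1), "g1", "g2", "g3")
  meta <- data.frame(kind = c("adjacency", "adjacency", "telomere",
                              rep("gene_family", 3)),
                     left = c(canonical_adjacency(1, 2)[1],
                              canonical_adjacency(2, 3)[1], 0L, NA, NA, NA),
                     right = c(canonical_adjacency(1, 2)[2],
                               canonical_adjacency(2, 3)[2], 1L, NA, NA, NA),
                     family = c(NA, NA, NA, 1L, 2L, 3L))
  rownames(meta) <- cols
  prob <- matrix(c(0.9, 0.9, 0.8, 0.51, 0.50, 0.49), 1,
                 dimnames = list("A1", cols))
  post <- structure(list(tree = NULL, prob = prob, meta = meta),
                    class = "go_posteriors")
  ct <- infer_gene_content(post)
  nd <- ct$nodes$A1
  expect_equal(nd$genes, 1L)                    # 0.51 in, 0.50 and 0.49 out
  # adjacency (1,2) touches absent gene 2 -> dropped; telomere of 1 kept
  expect_equal(nrow(nd$adj), 1L)
  expect_equal(nd$adj$kind, "telomere")
  expect_equal(nd$dropped, 2L)
  expect_error(infer_gene_content(post, threshold = 1), "strictly inside")
  expect_error(infer_gene_content(post, threshold = 0), "strictly inside")
})

test_that("TSP construction encodes candidates, caps and mandatory edges", {
  key <- function(l, r) canonical_adjacency(l, r)
  cn <- list(genes = c(1L, 2L, 3L),
             adj = data.frame(
               left = c(0L, -2L, -3L, 0L),
               right = c(1L, -1L, -2L, -3L),
               kind = c("telomere", "adjacency", "adjacency", "telomere"),
               p = c(1, 1, 1, 1)))
  inst <- build_tsp(cn, epsilon = 1e-6)
  expect_equal(inst$L, 1L)                      # telomere mass 2 -> one chromosome
  expect_equal(nrow(inst$w), 8L)                # 6 extremities + 2 caps
  sol <- solve_tsp(inst, "exact")
  g <- assemble_genome(sol$tour, inst, "A1")
  expect_true(genomes_identical(g, genome("x", list(c(1L, 2L, 3L)))))
  expect_equal(write_genomes(g), ">A1\n1 2 3 $\n")
  # every mandatory gene edge is in the tour
  tour <- sol$tour
  edges <- cbind(tour, c(tour[-1], tour[1]))
  for (i in 1:3)
    expect_true(any((edges[, 1] == 2 * i - 1 & edges[, 2] == 2 * i) |
                    (edges[, 1] == 2 * i & edges[, 2] == 2 * i - 1)))

  # telomere-mass rounding: total 3.7 -> two linear chromosomes
  cn2 <- list(genes = 1:2,
              adj = data.frame(left = c(0L, 0L, 0L, 0L),
                               right = c(1L, -1L, 2L, -2L),
                               kind = rep("telomere", 4),
                               p = c(1, 1, 0.9, 0.8)))
  expect_equal(build_tsp(cn2)$L, 2L)
  expect_error(build_tsp(list(genes = integer(), adj = cn$adj)),
               "no present genes")
})

test_that("conflicting candidate adjacencies resolve to the likelier one", {
  # gene 1's trailing end can host (1,2) at p=0.9 or (1,3) at p=0.6
  cn <- list(genes = c(1L, 2L, 3L),
             adj = data.frame(
               left = c(-2L, -3L),
               right = c(-1L, -1L),
               kind = c("adjacency", "adjacency"),
               p = c(0.9, 0.6)))
  inst <- build_tsp(cn, epsilon = 1e-6)
  sol <- solve_tsp(inst, "exact")
  g <- assemble_genome(sol$tour, inst, "A1")
  keys <- gophylo:::.adj_key(genome_adjacencies(g))
  expect_true(gophylo:::.adj_key(canonical_adjacency(1L, 2L)) %in% keys)
  expect_false(gophylo:::.adj_key(canonical_adjacency(1L, 3L)) %in% keys)
})

test_that("exact TSP equals brute force; heuristic never beats it", {
  # fixed 4-vertex instance checked against all three distinct tours
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1; W[1, 3] <- W[3, 1] <- 2; W[1, 4] <- W[4, 1] <- 3
  W[2, 3] <- W[3, 2] <- 4; W[2, 4] <- W[4, 2] <- 5; W[3, 4] <- W[4, 3] <- 6
  inst <- structure(list(w = W, caps = integer()), class = "go_tsp")
  expect_equal(solve_tsp(inst, "exact")$weight, brute_tsp_weight(W))

  set.seed(14)
  for (r in 1:100) {
    n <- sample(4:8, 1)
    W <- matrix(runif(n * n, 0, 10), n)
    W <- (W + t(W)) / 2; diag(W) <- 0
    inst <- structure(list(w = W, caps = integer()), class = "go_tsp")
    ex <- solve_tsp(inst, "exact")
    expect_equal(ex$weight, brute_tsp_weight(W), tolerance = 1e-9)
    he <- solve_tsp(inst, "heuristic", seed = r)
    expect_gte(he$weight, ex$weight - 1e-9)
  }
  big <- structure(list(w = matrix(0, 20, 20), caps = integer()),
                   class = "go_tsp")
  expect_error(solve_tsp(big, "exact"), "heuristic")
})

test_that("tour decoding is sign-consistent under direction reversal", {
  cn <- list(genes = c(1L, 2L, 3L),
             adj = data.frame(
               left = c(0L, -2L, -3L, 0L),
               right = c(1L, -1L, -2L, -3L),
               kind = c("telomere", "adjacency", "adjacency", "telomere"),
               p = c(1, 1, 1, 1)))
  inst <- build_tsp(cn)
  sol <- solve_tsp(inst, "exact")
  fwd <- assemble_genome(sol$tour, inst, "A1")
  rev_tour <- rev(sol$tour)
  bwd <- assemble_genome(rev_tour, inst, "A1")
  expect_true(genomes_identical(fwd, bwd))
})

test_that("identical inputs reproduce themselves at every ancestor", {
  doc <- read_genomes(text = paste0(">", c("A", "B", "C", "D"),
                                    "\n1 2 3 4 5 $\n", collapse = ""))
  enc <- encode_genomes(doc)
  m <- adjacency_model(n_families(enc))
  tr <- read_newick(text = "((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  anc <- infer_ancestral_genomes(tr, enc, m)
  for (g in anc$genomes)
    expect_true(genomes_identical(g, doc$A))
})

test_that("assembled ancestors recover most true adjacencies near the leaves", {
  hit <- 0L; tot <- 0L
  for (r in 1:3) {
    sim <- sim_dataset(taxa = 6L, genes = 60L, seed = 2500L + r,
                       config = sim_config(n_genes = 60L, seed = 2600L + r))
    enc <- encode_genomes(sim$leaves)
    m <- adjacency_model(n_families(enc))
    tt <- sim$tree; tt$edge.length <- rep(0.01, nrow(tt$edge))
    tt <- optimize_branch_lengths(tt, enc, m)
    attr(tt, "loglik") <- NULL
    anc <- infer_ancestral_genomes(tt, enc, m)
    nt <- length(tt$tip.label)
    for (v in (nt + 1L):(nt + tt$Nnode)) {
      if (!any(tt$edge[tt$edge[, 1] == v, 2] <= nt)) next
      lab <- tt$node.label[v - nt]
      truth <- unique(gophylo:::.adj_key(genome_adjacencies(sim$ancestors[[lab]])))
      got <- unique(gophylo:::.adj_key(genome_adjacencies(anc$genomes[[lab]])))
      hit <- hit + sum(truth %in% got); tot <- tot + length(truth)
    }
  }
  expect_gt(hit / tot, 0.9)
})
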