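test_that("neighbor joining reproduces three-point and additive cases", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 2))

  # additive distances from ((A,B),(C,D)) with unit branches
  t4 <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d4 <- ape::cophenetic.phylo(t4)
  tr4 <- nj_tree(d4)
  expect_equal(rf_distance(tr4, t4), 0)
  expect_lt(max(abs(ape::cophenetic.phylo(tr4)[rownames(d4), colnames(d4)] - d4)),
            1e-9)

  # ties resolve without error into some binary topology
  dt <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(dt) <- 0
  expect_silent(tt <- nj_tree(dt))
  expect_equal(length(tt$tip.label), 4L)

  bad <- d; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
  nn <- d; nn[1, 2] <- nn[2, 1] <- NA
  expect_error(nj_tree(nn), "NA")
})

test_that("ML search improves on its start and recovers simulated trees", {
  hits <- 0L
  for (r in 1:10) {
    sim <- sim_dataset(taxa = 6L, genes = 50L, seed = 500L + r,
                       config = sim_config(n_genes = 50L, seed = 600L + r))
    enc <- encode_genomes(sim$leaves)
    m <- adjacency_model(n_families(enc))
    fit <- ml_tree(enc, m)
    # hill-climbing contract: never below the optimized NJ start
    nj0 <- optimize_branch_lengths(nj_tree(ml_distance_matrix(enc, m)), enc, m)
    expect_gte(fit$loglik, attr(nj0, "loglik") - 1e-6)
    expect_true(all(diff(fit$trace) > 0))
    hits <- hits + (rf_distance(fit$tree, sim$tree) == 0L)
  }
  expect_gte(hits, 9L)
})

test_that("identical encodings force a cherry", {
  X <- rbind(A = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L),
             B = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L),
             C = c(0L, 0L, 1L, 1L, 0L, 1L, 1L, 0L),
             D = c(0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L))
  fit <- ml_tree(enc_from_matrix(X), adjacency_model(4))
  sib <- fit$tree$edge[fit$tree$edge[, 2] %in%
                         which(fit$tree$tip.label %in% c("A", "B")), 1]
  expect_equal(sib[1], sib[2])
})

test_that("search is deterministic given the input", {
  sim <- sim_dataset(taxa = 6L, genes = 40L, seed = 71L)
  enc <- encode_genomes(sim$leaves)
  m <- adjacency_model(n_families(enc))
  f1 <- ml_tree(enc, m); f2 <- ml_tree(enc, m)
  expect_identical(write_newick(f1$tree), write_newick(f2$tree))
  expect_identical(f1$loglik, f2$loglik)
})

test_that("Robinson-Foulds distance counts one-sided bipartitions", {
  t1 <- read_newick(text = "((A,B),(C,D),E);")
  expect_equal(rf_distance(t1, t1), 0)
  q1 <- read_newick(text = "((A,B),(C,D));")
  q2 <- read_newick(text = "((A,C),(B,D));")
  expect_equal(rf_distance(q1, q2), 2)
  expect_error(rf_distance(q1, read_newick(text = "((A,B),(C,E));")),
               "leaf sets")
  # independent cross-check on random 10-leaf pairs
  for (r in 1:10) {
    a <- random_tree(10, seed = 900 + r)
    b <- random_tree(10, seed = 950 + r)
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b))))
  }
})

test_that("bootstrap supports behave at the compatible-data extremes", {
  # 50 columns, all compatible with ((A,B),C,(D,E)): the AB clade, the DE
  # clade (twice, once as its complement), a constant and a singleton
  pat <- rbind(A = c(1L, 0L, 1L, 1L, 1L),
               B = c(1L, 0L, 1L, 1L, 0L),
               C = c(0L, 0L, 1L, 1L, 0L),
               D = c(0L, 1L, 0L, 1L, 0L),
               E = c(0L, 1L, 0L, 1L, 0L))
  X <- pat[, rep(1:5, each = 10L)]
  enc <- enc_from_matrix(X)
  m <- adjacency_model(5)
  bs <- bootstrap_supports(enc, m, replicates = 15L, seed = 8L)
  expect_true(all(bs$supports == 100L))
  expect_true(all(nchar(bs$tree$node.label) >= 0))

  one <- bootstrap_supports(enc, m, replicates = 1L, seed = 9L)
  expect_true(all(one$supports %in% c(0L, 100L)))

  # seed-reproducibility
  b1 <- bootstrap_supports(enc, m, replicates = 5L, seed = 33L)
  b2 <- bootstrap_supports(enc, m, replicates = 5L, seed = 33L)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  expect_error(bootstrap_supports(enc, m, replicates = 5L, seed = NULL),
               "seed")
})

test_that("once broken, adjacencies almost never re-form in simulations", {
  refm <- 0L; broken <- 0L
  for (r in 1:5) {
    sim <- sim_dataset(taxa = 8L, genes = 60L, seed = 1200L + r,
                       config = sim_config(n_genes = 60L, seed = 1300L + r))
    tr <- sim$tree
    nt <- length(tr$tip.label)
    name_of <- function(v) if (v <= nt) tr$tip.label[v] else tr$node.label[v - nt]
    gsets <- lapply(seq_len(nt + tr$Nnode), function(v) {
      nm <- name_of(v)
      g <- if (v <= nt) sim$leaves[[nm]] else sim$ancestors[[nm]]
      unique(gophylo:::.adj_key(genome_adjacencies(g)))
    })
    paths <- ape::nodepath(tr)                 # root-to-tip node paths
    for (p in paths) {
      lost <- character()
      for (i in seq_along(p)[-1]) {
        prev <- gsets[[p[i - 1]]]; cur <- gsets[[p[i]]]
        newly_lost <- setdiff(prev, cur)
        refm <- refm + sum(lost %in% cur)      # re-formed after being broken
        broken <- broken + length(newly_lost)
        lost <- union(setdiff(lost, cur), newly_lost)
      }
    }
  }
  expect_gt(broken, 50L)
  expect_lt(refm / broken, 0.05)
})
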