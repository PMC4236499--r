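test_that("two-sequence likelihood matches the direct root-sum formula", {
  m <- adjacency_model(6)
  tr <- read_newick(text = "(A:0.2,B:0.4);")
  X <- matrix(c(1L, 1L, 0L, 1L, 1L, 0L), 2, 3,
              dimnames = list(c("A", "B"), NULL))
  enc <- enc_from_matrix(X)
  ll <- tree_log_likelihood(tr, enc, m)
  direct <- 0
  for (cc in 1:3) {
    s <- 0
    for (root_state in 0:1) {
      P1 <- transition_matrix(m, 0.2); P2 <- transition_matrix(m, 0.4)
      s <- s + m$pi[root_state + 1] *
        P1[root_state + 1, X["A", cc] + 1] * P2[root_state + 1, X["B", cc] + 1]
    }
    direct <- direct + log(s)
  }
  expect_equal(ll, direct, tolerance = 1e-12)
})

test_that("zero branch lengths with identical leaves give the prior mass", {
  m <- adjacency_model(5)
  tr <- read_newick(text = "((A:0,B:0):0,(C:0,D:0):0);")
  X <- matrix(rep(c(1L, 1L, 0L, 1L), each = 4), 4, 4,
              dimnames = list(LETTERS[1:4], NULL))
  enc <- enc_from_matrix(X)
  expect_equal(tree_log_likelihood(tr, enc, m),
               sum(log(m$pi[X[1, ] + 1])), tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration over ancestral states", {
  m <- adjacency_model(10)
  set.seed(99)
  for (r in 1:8) {
    tr <- random_tree(5, seed = 300 + r, mean_branch = 0.4)
    X <- matrix(rbinom(5 * 12, 1, 0.4), 5, 12,
                dimnames = list(tr$tip.label, NULL))
    enc <- enc_from_matrix(X)
    expect_equal(tree_log_likelihood(tr, enc, m), brute_loglik(tr, X, m),
                 tolerance = 1e-9)
  }
})

test_that("log-likelihood is invariant to root placement", {
  m <- adjacency_model(8)
  tr <- random_tree(6, seed = 17, mean_branch = 0.5)
  X <- matrix(rbinom(6 * 25, 1, 0.5), 6, 25,
              dimnames = list(tr$tip.label, NULL))
  enc <- enc_from_matrix(X)
  ll0 <- tree_log_likelihood(tr, enc, m)
  un <- ape::unroot(tr)
  expect_equal(tree_log_likelihood(un, enc, m), ll0, tolerance = 1e-9)
  for (og in c("t2", "t5")) {
    rr <- ape::root(un, outgroup = og, resolve.root = TRUE)
    expect_equal(tree_log_likelihood(rr, enc, m), ll0, tolerance = 1e-9)
  }
})

test_that("a discordant leaf lowers the likelihood of a constant column", {
  m <- adjacency_model(6)
  tr <- read_newick(text = "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);")
  Xc <- matrix(1L, 4, 1, dimnames = list(LETTERS[1:4], NULL))
  Xf <- Xc; Xf["D", 1] <- 0L
  expect_lt(tree_log_likelihood(tr, enc_from_matrix(Xf), m),
            tree_log_likelihood(tr, enc_from_matrix(Xc), m))
})

test_that("taxon mismatches are reported with the offending names", {
  m <- adjacency_model(4)
  tr <- read_newick(text = "((A:1,B:1):1,Z:1);")
  X <- matrix(0L, 3, 2, dimnames = list(c("A", "B", "C"), NULL))
  expect_error(tree_log_likelihood(tr, enc_from_matrix(X), m), "Z")
  expect_error(tree_log_likelihood(tr, enc_from_matrix(X), m), "C")
})

test_that("pairwise ML distance maximizes the two-sequence likelihood", {
  m <- adjacency_model(10)
  x <- rep(1L, 100)
  expect_equal(pairwise_ml_distance(x, x, m), 0)
  set.seed(12)
  y <- x; y[sample(100, 5)] <- 0L
  d <- pairwise_ml_distance(x, y, m)
  expect_equal(d, pairwise_ml_distance(y, x, m), tolerance = 1e-10)
  # dense grid oracle
  f <- function(t) {
    P <- transition_matrix(m, t)
    sum(log(m$pi[x + 1] * P[cbind(x + 1, y + 1)]))
  }
  grid <- seq(1e-6, 1, length.out = 20000)
  expect_lt(abs(d - grid[which.max(vapply(grid, f, 0))]), 1e-4)
  # saturation returns the cap
  z <- rep(0L, 100); z[1:50] <- 1L
  w <- 1L - z
  expect_equal(pairwise_ml_distance(z, w, m, cap = 5), 5)
  expect_error(pairwise_ml_distance(integer(0), integer(0), m), "non-empty")
})

test_that("branch-length optimization is monotone and reaches a fixed point", {
  m <- adjacency_model(8)
  sim <- sim_dataset(taxa = 4L, genes = 60L, seed = 31L,
                     config = sim_config(n_genes = 60L, events_per_branch = 4,
                                         seed = 32L))
  enc <- encode_genomes(sim$leaves)
  mo <- adjacency_model(n_families(enc))
  tr <- sim$tree; tr$edge.length <- rep(0.05, nrow(tr$edge))
  ll0 <- tree_log_likelihood(tr, enc, mo)
  opt1 <- optimize_branch_lengths(tr, enc, mo)
  expect_gte(attr(opt1, "loglik"), ll0)
  opt2 <- optimize_branch_lengths(opt1, enc, mo)
  expect_lt(abs(attr(opt2, "loglik") - attr(opt1, "loglik")), 1e-3)

  # all-constant columns drive every branch to zero
  Xc <- matrix(1L, 4, 10, dimnames = list(sim$tree$tip.label, NULL))
  optc <- optimize_branch_lengths(tr, enc_from_matrix(Xc), mo)
  expect_true(all(optc$edge.length < 1e-5))
})

test_that("optimized branch lengths recover simulated divergence", {
  # fixed 4-leaf topology, characters simulated from the model itself; the
  # basal trifurcation keeps every branch identifiable under reversibility,
  # and a mild loss/gain ratio keeps enough presence mass for estimation
  m <- adjacency_model(1)
  tr <- read_newick(text = "(A:0.08,B:0.12,(C:0.1,D:0.07):0.11);")
  set.seed(77)
  nchar <- 2000L
  nt <- 4L
  E <- tr$edge
  P <- lapply(tr$edge.length, function(t) transition_matrix(m, t))
  X <- matrix(0L, nt, nchar, dimnames = list(tr$tip.label, NULL))
  po <- rev(gophylo:::.postorder_edges(tr))   # preorder
  for (cc in seq_len(nchar)) {
    st <- integer(nt + tr$Nnode)
    st[nt + 1L] <- rbinom(1, 1, m$pi[2])
    for (e in po)
      st[E[e, 2]] <- rbinom(1, 1, P[[e]][st[E[e, 1]] + 1, 2])
    X[, cc] <- st[seq_len(nt)]
  }
  tr0 <- tr; tr0$edge.length <- rep(0.05, nrow(E))
  fitted <- optimize_branch_lengths(tr0, enc_from_matrix(X), m)
  rel_err <- abs(fitted$edge.length - tr$edge.length) / tr$edge.length
  expect_lt(mean(rel_err), 0.2)
})
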