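## Reproducible simulation study: how well does the pipeline recover known
## trees and ancestors? Used by the package's validation suite; also a
## convenient template for users calibrating their own analyses.

#' Tree and ancestor recovery under simulated evolution
#'
#' For each replicate: draw a random tree, evolve genomes along it, infer the
#' phylogeny by ML from the leaf genomes alone, and score the
#' Robinson-Foulds distance to the truth. Ancestral gene orders are then
#' reconstructed on the true topology (branch lengths re-estimated by ML)
#' and, for every internal node that is a parent of at least one leaf, the
#' fraction of the true ancestor's adjacencies present in the assembled
#' ancestor is recorded.
#'
#' @param replicates Number of simulation replicates.
#' @param taxa Leaves per replicate.
#' @param seed Base seed; per-replicate seeds are derived deterministically.
#' @param config A \code{\link{sim_config}} describing the evolutionary
#'   regime (its seed field is overridden per replicate).
#' @param ancestors Also run the ancestral-reconstruction arm?
#' @return A list: \code{rf} (per-replicate RF distance),
#'   \code{tree_recovery} (fraction of replicates with RF = 0),
#'   \code{adjacency_recovery} (pooled fraction of true ancestral adjacencies
#'   recovered at leaf-adjacent nodes), and the per-replicate breakdown.
#' @export
recovery_experiment <- function(replicates = 20L, taxa = 12L, seed = 1L,
                                config = sim_config(n_genes = 100L),
                                ancestors = TRUE) {
  stopifnot(replicates >= 1L, taxa >= 4L)
  rf <- integer(replicates)
  hit <- 0; tot <- 0
  per_rep <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    tree <- random_tree(taxa, seed = seed + 7919L * r)
    config$seed <- seed + 104729L * r
    sim <- evolve_genomes(tree, config)
    enc <- encode_genomes(sim$leaves)
    model <- adjacency_model(n_families(enc))
    fit <- ml_tree(enc, model)
    rf[r] <- rf_distance(fit$tree, sim$tree)
    rh <- 0; rt <- 0
    if (ancestors) {
      tt <- sim$tree
      tt$edge.length <- rep(0.01, nrow(tt$edge))
      tt <- optimize_branch_lengths(tt, enc, model)
      attr(tt, "loglik") <- NULL
      anc <- infer_ancestral_genomes(tt, enc, model)
      nt <- length(tt$tip.label)
      for (v in (nt + 1L):(nt + tt$Nnode)) {
        if (!any(tt$edge[tt$edge[, 1L] == v, 2L] <= nt)) next
        lab <- tt$node.label[v - nt]
        truth <- unique(.adj_key(genome_adjacencies(sim$ancestors[[lab]])))
        got <- unique(.adj_key(genome_adjacencies(anc$genomes[[lab]])))
        rh <- rh + sum(truth %in% got)
        rt <- rt + length(truth)
      }
      hit <- hit + rh; tot <- tot + rt
    }
    per_rep[[r]] <- data.frame(replicate = r, rf = rf[r],
                               adj_hit = rh, adj_total = rt)
  }
  list(rf = rf,
       tree_recovery = mean(rf == 0L),
       adjacency_recovery = if (tot > 0) hit / tot else NA_real_,
       detail = do.call(rbind, per_rep))
}
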