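## File-to-file pipeline commands. Each run writes its primary outputs plus a
## run manifest (command, config, seed, input digests, version, timings).
## Given equal inputs and seed, primary outputs are byte-identical.

.manifest <- function(out_dir, command, seed, config, inputs, extra = list(),
                      t0 = NULL) {
  man <- c(list(command = command,
                version = as.character(utils::packageVersion("gophylo")),
                seed = seed,
                config = config,
                inputs = lapply(inputs, function(f)
                  list(path = f, md5 = unname(tools::md5sum(f)))),
                elapsed_sec = if (!is.null(t0))
                  round(as.numeric(Sys.time()) - t0, 3)),
           extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.prep_input <- function(input) {
  if (!file.exists(input)) stop("input file not found: ", input)
  doc <- read_genomes(input)
  if (length(doc) < 3L) stop("need at least 3 genomes, got ", length(doc))
  enc <- encode_genomes(doc)
  list(doc = doc, enc = enc, model = adjacency_model(n_families(enc)))
}

#' Reconstruct a phylogeny from a gene-order file
#'
#' Reads GRAPPA/MGR genomes, builds the binary encoding and the 2n-ratio
#' transition model, runs the ML tree search and (optionally) bootstrap, and
#' writes \code{tree.nwk} plus \code{manifest.json} into \code{out_dir}.
#'
#' @param input Path to a GRAPPA/MGR gene-order file (>= 3 genomes).
#' @param out_dir Output directory (created if missing).
#' @param bootstrap Number of bootstrap replicates (0 = off).
#' @param seed RNG seed; required when \code{bootstrap > 0}.
#' @param config A \code{\link{search_config}}.
#' @return Invisibly, the \code{go_ml_fit} with an added \code{paths} element.
#' @export
run_tree <- function(input, out_dir, bootstrap = 0L, seed = NULL,
                     config = search_config()) {
  t0 <- as.numeric(Sys.time())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- .prep_input(input)
  fit <- if (bootstrap > 0L) {
    if (is.null(seed)) stop("bootstrap requires --seed")
    bootstrap_supports(prep$enc, prep$model, replicates = bootstrap,
                       seed = seed, config = config)
  } else ml_tree(prep$enc, prep$model, config)
  tree_path <- file.path(out_dir, "tree.nwk")
  write_newick(fit$tree, tree_path)
  .manifest(out_dir, "tree", seed, c(unclass(config),
                                     list(bootstrap = bootstrap)),
            input, list(loglik = fit$loglik, loglik_trace = fit$trace,
                        n_characters = ncol(prep$enc$mat),
                        n_families = n_families(prep$enc)), t0)
  fit$paths <- c(tree = tree_path,
                 manifest = file.path(out_dir, "manifest.json"))
  invisible(fit)
}

#' Infer ancestral genomes from a gene-order file
#'
#' Uses the supplied Newick tree (or infers one by ML) and writes the
#' ancestral gene orders (\code{ancestors.mgr}, one record per internal
#' node), per-node adjacency posteriors (\code{posteriors.tsv}) and
#' \code{manifest.json} into \code{out_dir}.
#'
#' @inheritParams run_tree
#' @param tree_file Optional Newick file; its leaves must match the genome
#'   names. Branch lengths are estimated by ML when absent.
#' @param threshold Gene-content posterior cutoff.
#' @param epsilon Floor probability for non-candidate adjacencies.
#' @param mode TSP mode ("auto", "exact" or "heuristic").
#' @return Invisibly, the \code{go_ancestors} with an added \code{paths}.
#' @export
run_ancestors <- function(input, out_dir, tree_file = NULL, seed = 1L,
                          threshold = 0.5, epsilon = 1e-6, mode = "auto",
                          config = search_config()) {
  t0 <- as.numeric(Sys.time())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- .prep_input(input)
  inputs <- input
  if (is.null(tree_file)) {
    tree <- ml_tree(prep$enc, prep$model, config)$tree
  } else {
    if (!file.exists(tree_file)) stop("tree file not found: ", tree_file)
    tree <- read_newick(tree_file)
    alien <- setdiff(tree$tip.label, prep$enc$taxa)
    missing <- setdiff(prep$enc$taxa, tree$tip.label)
    if (length(alien) || length(missing))
      stop("tree/genome taxon mismatch;",
           if (length(alien)) paste0(" unknown leaves: ",
                                     paste(alien, collapse = ", ")),
           if (length(missing)) paste0(" genomes absent from tree: ",
                                       paste(missing, collapse = ", ")))
    if (is.null(tree$edge.length)) {
      tree$edge.length <- rep(0.1, nrow(tree$edge))
      tree <- optimize_branch_lengths(tree, prep$enc, prep$model,
                                      eps = config$eps, tol = config$tol,
                                      max_len = config$max_len)
      attr(tree, "loglik") <- NULL
    }
    inputs <- c(inputs, tree_file)
  }
  anc <- infer_ancestral_genomes(tree, prep$enc, prep$model,
                                 threshold = threshold, epsilon = epsilon,
                                 mode = mode, seed = seed)
  anc_path <- file.path(out_dir, "ancestors.mgr")
  post_path <- file.path(out_dir, "posteriors.tsv")
  write_genomes(anc$genomes, anc_path)
  write_posteriors_tsv(anc$posteriors, post_path)
  .manifest(out_dir, "ancestors", seed,
            list(threshold = threshold, epsilon = epsilon, mode = mode),
            inputs, list(n_internal_nodes = length(anc$genomes)), t0)
  anc$paths <- c(ancestors = anc_path, posteriors = post_path,
                 manifest = file.path(out_dir, "manifest.json"))
  invisible(anc)
}

#' Simulate a ground-truthed gene-order dataset
#'
#' Draws a random tree, evolves genomes along it under DCJ plus
#' deletion/insertion/duplication, and writes \code{genomes.mgr} (leaves),
#' \code{ancestors.mgr} (true internal genomes), \code{tree.nwk} (true tree,
#' ancestor labels A1..), \code{events.tsv} (event log) and
#' \code{manifest.json} into \code{out_dir}.
#'
#' @param out_dir Output directory.
#' @param taxa Number of leaves.
#' @param seed RNG seed (required).
#' @param config A \code{\link{sim_config}}; its seed is derived from
#'   \code{seed} when unset.
#' @param mean_branch Mean exponential branch length of the random tree.
#' @return Invisibly, the \code{go_sim} with an added \code{paths}.
#' @export
run_simulate <- function(out_dir, taxa = 6L, seed, config = sim_config(),
                         mean_branch = 1) {
  t0 <- as.numeric(Sys.time())
  if (missing(seed) || is.null(seed)) stop("simulation requires --seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- random_tree(taxa, seed = seed, mean_branch = mean_branch)
  if (is.null(config$seed)) config$seed <- seed + 1L
  sim <- evolve_genomes(tree, config)
  paths <- c(genomes = file.path(out_dir, "genomes.mgr"),
             ancestors = file.path(out_dir, "ancestors.mgr"),
             tree = file.path(out_dir, "tree.nwk"),
             events = file.path(out_dir, "events.tsv"))
  write_genomes(sim$leaves, paths["genomes"])
  write_genomes(sim$ancestors, paths["ancestors"])
  write_newick(sim$tree, paths["tree"])
  ev <- if (length(sim$log)) data.frame(
    branch = vapply(sim$log, `[[`, "", "branch"),
    kind = vapply(sim$log, `[[`, "", "kind"),
    args = vapply(sim$log, function(e)
      as.character(jsonlite::toJSON(e$args, auto_unbox = TRUE)), "")
  ) else data.frame(branch = character(), kind = character(),
                    args = character())
  utils::write.table(ev, paths["events"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .manifest(out_dir, "simulate", seed,
            c(unclass(config), list(taxa = taxa, mean_branch = mean_branch)),
            character(), list(n_events = length(sim$log)), t0)
  sim$paths <- c(paths, manifest = file.path(out_dir, "manifest.json"))
  invisible(sim)
}
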