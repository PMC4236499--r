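## Binary encoding of a genome collection (the MLWD-style pseudo-alignment).
##
## Every canonical adjacency or telomere observed in at least one input genome
## becomes one presence/absence character, in first-observation order; one
## further character per distinct gene family (|id|), ascending. Copy counts
## collapse to presence: with duplicated genes two distinct genomes can share
## an encoding, a known many-to-one limitation of this representation.

#' Encode genomes as binary presence/absence characters
#'
#' @param doc A \code{go_genomes} document with at least 3 genomes.
#' @return A \code{go_encoding}: list with \code{taxa} (genome names),
#'   \code{mat} (taxa x characters 0/1 integer matrix) and \code{meta}
#'   (data frame per column: \code{kind} in adjacency/telomere/gene_family,
#'   \code{left}, \code{right} for junction columns, \code{family} for gene
#'   columns).
#' @examples
#' doc <- read_genomes(text = ">A\n1 2 3 $\n>B\n1 -2 3 $\n>C\n1 2 3 $\n")
#' enc <- encode_genomes(doc)
#' enc$mat
#' @export
encode_genomes <- function(doc) {
  if (inherits(doc, "go_genome")) stop("need a go_genomes collection, not one genome")
  if (!inherits(doc, "go_genomes")) doc <- genome_set(doc)
  if (length(doc) < 3L) stop("need at least 3 genomes to infer a tree")

  adjs <- lapply(doc, genome_adjacencies)
  keys <- lapply(adjs, .adj_key)
  all_keys <- unique(unlist(keys, use.names = FALSE))
  fams <- lapply(doc, function(g) unique(abs(unlist(g$chromosomes))))
  all_fams <- sort(unique(unlist(fams, use.names = FALSE)))
  if (!length(all_fams)) stop("empty union of genes")

  nA <- length(all_keys); nF <- length(all_fams)
  mat <- matrix(0L, nrow = length(doc), ncol = nA + nF,
                dimnames = list(names(doc), c(all_keys, paste0("g", all_fams))))
  for (i in seq_along(doc)) {
    mat[i, match(unique(keys[[i]]), all_keys)] <- 1L
    mat[i, nA + match(fams[[i]], all_fams)] <- 1L
  }

  am <- .key_adj(all_keys)
  meta <- data.frame(
    kind = c(ifelse(am[, 1L] == 0L | am[, 2L] == 0L, "telomere", "adjacency"),
             rep("gene_family", nF)),
    left = c(am[, 1L], rep(NA_integer_, nF)),
    right = c(am[, 2L], rep(NA_integer_, nF)),
    family = c(rep(NA_integer_, nA), all_fams),
    stringsAsFactors = FALSE)
  rownames(meta) <- colnames(mat)

  structure(list(taxa = names(doc), mat = mat, meta = meta),
            class = "go_encoding")
}

#' @export
print.go_encoding <- function(x, ...) {
  cat("Binary gene-order encoding:", length(x$taxa), "taxa x",
      ncol(x$mat), "characters (",
      sum(x$meta$kind != "gene_family"), "adjacency/telomere,",
      sum(x$meta$kind == "gene_family"), "gene-family )\n")
  invisible(x)
}

#' Number of gene families in an encoding
#'
#' The model's loss/gain ratio defaults to 2n with n the number of distinct
#' gene families observed across the input genomes.
#'
#' @param enc A \code{go_encoding}.
#' @return Integer count of distinct gene families.
#' @export
n_families <- function(enc) {
  stopifnot(inherits(enc, "go_encoding"))
  sum(enc$meta$kind == "gene_family")
}

#' Export an encoding as TSV (debugging aid)
#'
#' @param enc A \code{go_encoding}.
#' @param file Output path.
#' @export
write_encoding_tsv <- function(enc, file) {
  stopifnot(inherits(enc, "go_encoding"))
  df <- data.frame(taxon = enc$taxa, enc$mat, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

## Subset/resample encoding columns (bootstrap support machinery).
.encoding_subset <- function(enc, idx) {
  structure(list(taxa = enc$taxa,
                 mat = enc$mat[, idx, drop = FALSE],
                 meta = enc$meta[idx, , drop = FALSE]),
            class = "go_encoding")
}
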