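## Adjacency and telomere semantics.
##
## An adjacency (i,j) means gene i is immediately followed by gene j; reading
## the reverse strand gives the same junction as (-j,-i), so both map to one
## canonical object. The chromosome extremity marker `o` is encoded as the
## integer 0, and a telomere (k,o) is identical to (o,-k). The canonical
## representative is the ordered form whose first element is smallest under
## the total order o < ... < -2 < -1 < 1 < 2 < ... (second element breaks ties).

.adj_rank <- function(x) ifelse(x == 0L, -Inf, as.numeric(x))
.adj_neg  <- function(x) ifelse(x == 0L, 0L, -x)

#' Canonical form of an adjacency or telomere
#'
#' @param left,right Signed gene ids (non-zero integers), with \code{0}
#'   standing for the chromosome extremity marker \code{o}. Vectorized.
#' @return An integer matrix with columns \code{left}, \code{right}, one row
#'   per input adjacency, in canonical form.
#' @examples
#' canonical_adjacency(2, -3)            # same object as (3, -2)
#' canonical_adjacency(5, 0)             # telomere, stored as (o, -5)
#' @export
canonical_adjacency <- function(left, right) {
  left <- as.integer(left); right <- as.integer(right)
  if (length(left) != length(right)) stop("left/right length mismatch")
  if (any(left == 0L & right == 0L)) stop("adjacency cannot join two extremity markers")
  if (anyNA(left) || anyNA(right)) stop("NA gene id")
  b1 <- .adj_neg(right); b2 <- .adj_neg(left)
  swap <- (.adj_rank(b1) < .adj_rank(left)) |
    (.adj_rank(b1) == .adj_rank(left) & .adj_rank(b2) < .adj_rank(right))
  out <- cbind(left = ifelse(swap, b1, left), right = ifelse(swap, b2, right))
  storage.mode(out) <- "integer"
  out
}

## "l,r" string keys for canonical adjacency rows; used as column identifiers.
.adj_key <- function(mat) paste(mat[, 1L], mat[, 2L], sep = ",")
.key_adj <- function(keys) {
  parts <- do.call(rbind, strsplit(keys, ",", fixed = TRUE))
  m <- cbind(left = as.integer(parts[, 1L]), right = as.integer(parts[, 2L]))
  m
}

#' Adjacencies and telomeres of a genome
#'
#' A linear chromosome with k genes contributes k-1 internal adjacencies and
#' 2 telomeres; a circular chromosome with k genes contributes k adjacencies
#' and no telomere. Multiplicities are kept (duplicated segments can repeat
#' an adjacency).
#'
#' @param g A \code{go_genome}.
#' @return Integer matrix of canonical (left, right) rows, one per occurrence.
#' @export
genome_adjacencies <- function(g) {
  stopifnot(inherits(g, "go_genome"))
  L <- vector("list", length(g$chromosomes))
  for (i in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[[i]]; k <- length(ch)
    if (g$circular[i]) {
      l <- ch; r <- c(ch[-1L], ch[1L])
    } else {
      l <- c(0L, ch); r <- c(ch, 0L)
    }
    L[[i]] <- canonical_adjacency(l, r)
  }
  do.call(rbind, L)
}

## Canonical form of a genome: each chromosome reduced to the lexicographically
## smaller of its two reading directions (all rotations too, if circular),
## chromosomes sorted. Makes genome identity insensitive to chromosome order
## and whole-chromosome flips.
.canon_chrom <- function(ch, circular) {
  flip <- function(v) rev(-v)
  if (!circular) {
    cand <- list(ch, flip(ch))
  } else {
    k <- length(ch)
    rots <- function(v) { vv <- c(v, v); lapply(seq_len(k), function(s) vv[s:(s + k - 1L)]) }
    cand <- c(rots(ch), rots(flip(ch)))
  }
  keys <- vapply(cand, paste, "", collapse = " ")
  cand[[order(keys)[1L]]]
}

#' Canonical representation of a genome
#'
#' Two genomes describe the same gene order iff their canonical forms are
#' identical: chromosome order, whole-chromosome flips and (for circular
#' chromosomes) rotations are quotiented out.
#'
#' @param g A \code{go_genome}.
#' @return A \code{go_genome} in canonical form.
#' @export
canonical_genome <- function(g) {
  stopifnot(inherits(g, "go_genome"))
  chs <- mapply(.canon_chrom, g$chromosomes, g$circular, SIMPLIFY = FALSE)
  key <- paste(ifelse(g$circular, "c", "l"),
               vapply(chs, paste, "", collapse = " "))
  o <- order(key)
  genome(g$name, chs[o], g$circular[o])
}

#' Test gene-order identity of two genomes
#'
#' @param a,b \code{go_genome} objects.
#' @return \code{TRUE} iff the two genomes have identical gene orders up to
#'   chromosome order, flips and rotations (names ignored).
#' @export
genomes_identical <- function(a, b) {
  ca <- canonical_genome(a); cb <- canonical_genome(b)
  identical(ca$chromosomes, cb$chromosomes) && identical(ca$circular, cb$circular)
}
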