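## Genome containers and GRAPPA/MGR text format I/O.
##
## A genome is a list of chromosomes, each a signed permutation of non-zero
## gene (synteny block) identifiers; the sign is the strand. The interchange
## format is the GRAPPA/MGR dialect: a FASTA-like ">name" header, then each
## chromosome as whitespace-separated signed integers terminated by "$"
## (linear) or "@" (circular, a common GRAPPA extension).

#' Construct a genome
#'
#' @param name Genome name (non-empty string, no whitespace).
#' @param chromosomes List of integer vectors of signed, non-zero gene ids.
#' @param circular Logical vector, one flag per chromosome (default all linear).
#' @return An object of class \code{go_genome}.
#' @examples
#' g <- genome("A", list(c(1L, -2L, 3L)))
#' genome_adjacencies(g)
#' @export
genome <- function(name, chromosomes, circular = rep(FALSE, length(chromosomes))) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name) || grepl("\\s", name))
    stop("genome name must be a single non-empty token")
  if (!is.list(chromosomes) || length(chromosomes) == 0L)
    stop("a genome needs at least one chromosome")
  chromosomes <- lapply(chromosomes, function(ch) {
    ch <- as.integer(ch)
    if (length(ch) == 0L) stop("empty chromosome in genome '", name, "'")
    if (any(ch == 0L) || anyNA(ch)) stop("gene ids must be non-zero integers")
    ch
  })
  circular <- as.logical(circular)
  if (length(circular) != length(chromosomes))
    stop("'circular' must have one flag per chromosome")
  structure(list(name = name, chromosomes = chromosomes, circular = circular),
            class = "go_genome")
}

#' @export
print.go_genome <- function(x, ...) {
  cat(">", x$name, " (", length(x$chromosomes), " chromosome(s), ",
      sum(lengths(x$chromosomes)), " genes)\n", sep = "")
  for (i in seq_along(x$chromosomes))
    cat(" ", paste(x$chromosomes[[i]], collapse = " "),
        if (x$circular[i]) "@" else "$", "\n")
  invisible(x)
}

#' Bundle genomes into a document
#'
#' @param ... \code{go_genome} objects, or a single list of them.
#' @return A named list of genomes of class \code{go_genomes}.
#' @export
genome_set <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1L]], "go_genome")) gs <- gs[[1L]]
  if (!length(gs) || !all(vapply(gs, inherits, TRUE, "go_genome")))
    stop("genome_set() expects go_genome objects")
  nm <- vapply(gs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate genome names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(setNames(gs, nm), class = "go_genomes")
}

#' @export
print.go_genomes <- function(x, ...) {
  cat("Gene-order document with", length(x), "genome(s):",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read genomes in GRAPPA/MGR format
#'
#' Parses the gene-order dialect used by GRAPPA and MGR: headers are ">"
#' followed by the genome name (first whitespace-delimited token; the rest of
#' the header line is ignored), and each chromosome is a run of signed
#' integers ended by \code{$} (linear) or \code{@} (circular). Blank lines and
#' trailing whitespace are tolerated; anything else is a loud parse error
#' naming the offending line.
#'
#' @param file Path to a file, or \code{NULL} when \code{text} is given.
#' @param text Character scalar (or vector of lines) to parse instead of a file.
#' @return A \code{go_genomes} document, records in file order.
#' @examples
#' read_genomes(text = ">A\n1 -2 $\n3 $\n>B\n-1 2 3 $\n")
#' @export
read_genomes <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    text <- readLines(file, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (length(lines) == 0L) lines <- ""

  records <- list()
  cur_name <- NULL; cur_line <- 0L
  cur_chroms <- list(); cur_circ <- logical(); buf <- integer()

  flush_record <- function() {
    if (is.null(cur_name)) return()
    if (length(buf))
      stop("chromosome content after last terminator in genome '", cur_name,
           "' (started at line ", cur_line, ")")
    if (!length(cur_chroms))
      stop("genome '", cur_name, "' (line ", cur_line, ") has zero chromosomes")
    g <- genome(cur_name, cur_chroms, cur_circ)
    if (!is.null(records[[cur_name]]))
      stop("duplicate genome name '", cur_name, "' at line ", cur_line)
    records[[cur_name]] <<- g
  }

  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*$", line)) next
    if (grepl("^>", line)) {
      flush_record()
      nm <- strsplit(trimws(sub("^>", "", line)), "\\s+")[[1L]]
      if (length(nm) == 0L || !nzchar(nm[1L]))
        stop("malformed header (empty name) at line ", ln)
      cur_name <- nm[1L]; cur_line <- ln
      cur_chroms <- list(); cur_circ <- logical(); buf <- integer()
      next
    }
    if (is.null(cur_name))
      stop("gene data before any '>' header at line ", ln)
    for (tok in strsplit(trimws(line), "\\s+")[[1L]]) {
      if (tok == "$" || tok == "@") {
        if (!length(buf)) stop("empty chromosome at line ", ln)
        cur_chroms[[length(cur_chroms) + 1L]] <- buf
        cur_circ <- c(cur_circ, tok == "@")
        buf <- integer()
      } else if (grepl("^[+-]?[0-9]+$", tok)) {
        v <- as.integer(tok)
        if (is.na(v)) stop("gene id overflow '", tok, "' at line ", ln)
        if (v == 0L) stop("gene id 0 at line ", ln)
        buf <- c(buf, v)
      } else {
        stop("invalid token '", tok, "' at line ", ln)
      }
    }
  }
  flush_record()
  if (!length(records)) stop("no genome records found")
  genome_set(records)
}

#' Write genomes in GRAPPA/MGR format
#'
#' Emits exactly the dialect accepted by \code{\link{read_genomes}}, so that
#' write/read round trips are identities.
#'
#' @param doc A \code{go_genomes} document (or a single \code{go_genome}).
#' @param file Optional path; when \code{NULL} the text is returned.
#' @return The formatted text, invisibly when written to a file.
#' @export
write_genomes <- function(doc, file = NULL) {
  if (inherits(doc, "go_genome")) doc <- genome_set(list(doc))
  if (!inherits(doc, "go_genomes")) doc <- genome_set(doc)
  out <- character()
  for (g in doc) {
    out <- c(out, paste0(">", g$name))
    for (i in seq_along(g$chromosomes))
      out <- c(out, paste0(paste(g$chromosomes[[i]], collapse = " "),
                           if (g$circular[i]) " @" else " $"))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}

#' Read and write Newick trees
#'
#' Thin wrappers over \pkg{ape}'s Newick parser/serializer. Round trips
#' preserve topology, branch lengths (10 significant digits) and node labels;
#' bootstrap supports and ancestor names travel as internal node labels.
#'
#' @param file,text As in \code{\link{read_genomes}}.
#' @return \code{read_newick}: an \pkg{ape} \code{phylo} object.
#' @export
read_newick <- function(file = NULL, text = NULL) {
  tr <- if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    ape::read.tree(file)
  } else ape::read.tree(text = text)
  if (is.null(tr)) stop("Newick parse failure")
  if (!is.null(tr$tip.label) && any(!nzchar(tr$tip.label)))
    stop("empty leaf label in Newick input")
  tr
}

#' @param tree A \code{phylo} object.
#' @param digits Significant digits for branch lengths.
#' @rdname read_newick
#' @return \code{write_newick}: the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
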