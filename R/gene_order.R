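# Signed gene orders and GRAPPA-style gene-order files.
#
# A genome is a signed permutation of 1..g: the gene order along one linear
# chromosome, the sign encoding strand. Inversions reverse a contiguous
# block and flip its signs.

#' Create a signed gene order
#'
#' @param genes integer vector; signed, nonzero, absolute values exactly
#'   `1..g` with no repeats.
#' @param name genome identifier.
#' @return a `gene_order`: an integer vector with a `name` attribute.
#' @examples
#' gene_order(c(1, -3, 2), "A")
#' @export
gene_order <- function(genes, name = "genome") {
  genes <- as.integer(genes)
  validate_genes(genes, name)
  structure(genes, name = name, class = "gene_order")
}

validate_genes <- function(genes, name) {
  if (length(genes) == 0L) stop("empty gene order in ", name)
  if (anyNA(genes)) stop("NA gene in ", name)
  if (any(genes == 0L)) stop("zero gene entry in ", name)
  tab <- tabulate(abs(genes), nbins = length(genes))
  if (any(tab > 1L)) {
    stop("duplicate gene ", which(tab > 1L)[1L], " in ", name)
  }
  if (any(tab == 0L)) {
    stop("missing gene ", which(tab == 0L)[1L], " in ", name)
  }
  invisible(genes)
}

#' @export
print.gene_order <- function(x, ...) {
  cat(">", attr(x, "name"), "\n", paste(unclass(x), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

genome_name <- function(x) attr(x, "name")

#' Apply an inversion to a gene order
#'
#' Reverses the block between the i-th and j-th genes (1-based, inclusive)
#' and flips its signs; an involution for fixed `(i, j)`.
#'
#' @param genome a [gene_order()] or plain signed integer vector.
#' @param i,j 1-based start and end positions, `1 <= i <= j <= g`.
#' @return the mutated genome, same class as the input.
#' @examples
#' apply_inversion(gene_order(1:4, "A"), 2, 3)  # 1 -3 -2 4
#' @export
apply_inversion <- function(genome, i, j) {
  g <- length(genome)
  if (i < 1L || j > g || i > j) {
    stop("inversion positions out of range: i=", i, " j=", j, " g=", g)
  }
  out <- unclass(genome)
  out[i:j] <- -rev(out[i:j])
  attributes(out) <- attributes(genome)
  out
}

#' Create a genome set
#'
#' An ordered collection of gene orders over a common gene set `1..g` with
#' unique names.
#'
#' @param genomes list of [gene_order()] objects (or a named list of
#'   integer vectors).
#' @return a `genome_set` with elements `genomes` (named list of integer
#'   vectors) and `g`.
#' @export
genome_set <- function(genomes) {
  if (length(genomes) == 0L) stop("empty genome set")
  nms <- vapply(seq_along(genomes), function(i) {
    nm <- genome_name(genomes[[i]])
    if (is.null(nm)) nm <- names(genomes)[i]
    if (is.null(nm) || is.na(nm) || nm == "") nm <- paste0("G", i)
    nm
  }, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate genome name: ", nms[duplicated(nms)][1L])
  }
  g <- length(genomes[[1L]])
  lst <- vector("list", length(genomes))
  for (i in seq_along(genomes)) {
    gi <- as.integer(unclass(genomes[[i]]))
    if (length(gi) != g) {
      stop("inconsistent gene count in ", nms[i], ": ", length(gi),
           " vs ", g)
    }
    validate_genes(gi, nms[i])
    lst[[i]] <- gi
  }
  names(lst) <- nms
  structure(list(genomes = lst, g = g), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x$genomes), "genomes,", x$g, "genes\n")
  invisible(x)
}

#' @export
length.genome_set <- function(x) length(x$genomes)

#' Read gene orders from a GRAPPA-style file
#'
#' The format alternates `>name` header lines with one or more lines of
#' whitespace-separated signed integers (the genome), until the next
#' header. All genomes must share the gene set `1..g`.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character scalar/vector holding the file content.
#' @return a [genome_set()].
#' @export
read_gene_orders <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE))
  } else {
    readLines(path, warn = FALSE)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty gene-order input")
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stop("gene-order input must start with a '>name' header")
  idx <- cumsum(hdr)
  genomes <- list()
  for (k in seq_len(max(idx))) {
    blk <- lines[idx == k]
    nm <- trimws(sub("^>", "", blk[1L]))
    if (nm == "") stop("empty genome name in header ", k)
    if (length(blk) < 2L) stop("no gene data for genome ", nm)
    toks <- unlist(strsplit(paste(blk[-1L], collapse = " "),
                            "[[:space:]]+"))
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.integer(toks))
    if (anyNA(vals)) stop("non-integer gene entry in ", nm)
    genomes[[length(genomes) + 1L]] <- gene_order(vals, nm)
  }
  genome_set(genomes)
}

#' Write gene orders to a GRAPPA-style file
#'
#' Inverse of [read_gene_orders()]; one header and one line of integers per
#' genome.
#'
#' @param set a [genome_set()].
#' @param path output file path (or connection).
#' @export
write_gene_orders <- function(set, path) {
  stopifnot(inherits(set, "genome_set"))
  lines <- unlist(lapply(names(set$genomes), function(nm) {
    c(paste0(">", nm), paste(set$genomes[[nm]], collapse = " "))
  }))
  writeLines(lines, path)
  invisible(path)
}

# fetch a genome (integer vector) by name
set_genome <- function(set, name) set$genomes[[name]]
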