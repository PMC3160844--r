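# Rearrangement distances between signed permutations.

check_pair <- function(a, b) {
  a <- as.integer(unclass(a)); b <- as.integer(unclass(b))
  if (length(a) != length(b)) stop("genomes differ in gene count")
  if (!identical(sort(abs(a)), seq_along(a)) ||
      !identical(sort(abs(b)), seq_along(b))) {
    stop("genomes are not signed permutations of the same gene set")
  }
  list(a = a, b = b)
}

#' Inversion (reversal) distance between two signed gene orders
#'
#' The minimum number of inversions transforming one genome into the
#' other, computed by the Hannenhalli-Pevzner formula on the breakpoint
#' graph: (g + 1) - cycles + hurdles + fortress.
#'
#' @param a,b gene orders over the same gene set `1..g`.
#' @return a nonnegative integer; symmetric in its arguments.
#' @examples
#' inversion_distance(gene_order(1:3), gene_order(c(-3, -2, -1)))  # 1
#' @export
inversion_distance <- function(a, b) {
  p <- check_pair(a, b)
  cpp_inv_dist(p$a, p$b)
}

#' Breakpoint distance between two signed gene orders
#'
#' The number of signed adjacencies of `a` (including the two terminal
#' adjacencies against frame markers 0 and g+1) absent from `b`, where an
#' adjacency `(x, y)` matches `(-y, -x)`.
#'
#' @inheritParams inversion_distance
#' @return a nonnegative integer.
#' @export
breakpoint_distance <- function(a, b) {
  p <- check_pair(a, b)
  cpp_breakpoint_dist(p$a, p$b)
}

#' Pairwise distance matrix for a genome set
#'
#' @param set a [genome_set()] with at least two genomes.
#' @param metric `"inversion"` (default) or `"breakpoint"`.
#' @param correction distance correction hook; only `"none"` is
#'   implemented (the identity), kept as an extension point for corrected
#'   metrics.
#' @return a symmetric integer matrix with zero diagonal and genome names
#'   as dimnames.
#' @export
pairwise_matrix <- function(set, metric = c("inversion", "breakpoint"),
                            correction = c("none")) {
  metric <- match.arg(metric)
  correction <- match.arg(correction)
  stopifnot(inherits(set, "genome_set"))
  n <- length(set$genomes)
  if (n < 2L) stop("need at least two genomes for a distance matrix")
  X <- do.call(rbind, set$genomes)
  D <- cpp_pairwise(X, metric)
  dimnames(D) <- list(names(set$genomes), names(set$genomes))
  D
}

#' Count unrooted binary tree topologies
#'
#' `(2n - 5)!!` distinct unrooted binary topologies on `n` labeled leaves;
#' 15 for five leaves and 2,027,025 for ten.
#'
#' @param n leaf count, `n >= 3`.
#' @return a positive number.
#' @export
topology_count <- function(n) {
  if (n < 3L) stop("topology_count requires n >= 3")
  if (n == 3L) return(1)
  prod(seq(3, 2 * n - 5, by = 2))
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d symmetric matrix with dimnames, as from [pairwise_matrix()].
#' @param path output file path.
#' @export
write_phylip <- function(d, path) {
  n <- nrow(d)
  lines <- c(format(n), vapply(seq_len(n), function(i) {
    paste(formatC(rownames(d)[i], width = -10),
          paste(format(d[i, ], trim = TRUE), collapse = " "))
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
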