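# Topological accuracy against model trees: internal-edge bipartitions
# with a 0.5 length threshold, FP/FN counts, and classification of disk
# decompositions as compatible / incompatible (with a merge-replay probe
# for recoverability).

#' Internal bipartitions of a tree, after contracting short edges
#'
#' Edges shorter than `length_threshold` (when lengths are present) are
#' contracted first; each remaining internal edge induces one bipartition
#' of the leaf set.
#'
#' @param tree a `labeled_tree`.
#' @param length_threshold edges shorter than this count as zero-length
#'   (default 0.5).
#' @return a character vector of canonical splits (empty for trees with
#'   fewer than 4 leaves).
#' @export
internal_bipartitions <- function(tree, length_threshold = 0.5) {
  if (sum(tree$leaf) < 4L) return(character(0))
  tr <- tree
  if (!is.null(tr$lengths)) {
    short <- which(!is.na(tr$lengths) & tr$lengths < length_threshold &
                     !tr$leaf[tr$edges[, 1L]] & !tr$leaf[tr$edges[, 2L]])
    if (length(short)) tr <- lt_contract(tr, short)$tree
  }
  unique(lt_internal_splits(tr))
}

#' False-positive / false-negative internal edges
#'
#' `FP` counts internal bipartitions of the reconstruction absent from
#' the model tree; `FN` counts internal bipartitions of the model tree
#' absent from the reconstruction. External edges never contribute.
#'
#' @param reconstructed,model trees over the same leaf names.
#' @param length_threshold passed to [internal_bipartitions()].
#' @return an `accuracy_report`: `fp`, `fn`, `n_internal_model`.
#' @export
fp_fn <- function(reconstructed, model, length_threshold = 0.5) {
  rt <- as_lt(reconstructed); mt <- as_lt(model)
  if (!setequal(leaf_names(rt), leaf_names(mt))) {
    stop("reconstruction and model must share the same leaf names")
  }
  sr <- internal_bipartitions(rt, length_threshold)
  sm <- internal_bipartitions(mt, length_threshold)
  structure(list(fp = length(setdiff(sr, sm)),
                 fn = length(setdiff(sm, sr)),
                 n_internal_model = length(sm)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("FP =", x$fp, " FN =", x$fn, " (model internal edges:",
      x$n_internal_model, ")\n")
  invisible(x)
}

#' Classify a disk decomposition against the model tree
#'
#' A decomposition is compatible when some model-tree edge separates the
#' exclusive region of one disk from the exclusive region of the other;
#' overlap genomes never affect compatibility.
#'
#' @param decomp a `disk_decomposition` (indices into `names`).
#' @param model a `model_tree` or `labeled_tree`.
#' @param names genome names positionally matching the decomposition's
#'   indices.
#' @return `"compatible"` or `"incompatible"`.
#' @export
classify_decomposition <- function(decomp, model, names = NULL) {
  mt <- if (inherits(model, "model_tree")) model$tree else as_lt(model)
  if (is.null(names)) names <- leaf_names(mt)
  ex0 <- names[setdiff(decomp$disk0, decomp$overlap)]
  ex1 <- names[setdiff(decomp$disk1, decomp$overlap)]
  if (!all(c(ex0, ex1) %in% mt$vnames[mt$leaf])) {
    stop("decomposition refers to genomes absent from the model tree")
  }
  for (k in seq_len(nrow(mt$edges))) {
    side <- lt_side_of(mt, k, mt$edges[k, 1L])
    nm <- mt$vnames[intersect(side, which(mt$leaf))]
    if ((all(ex0 %in% nm) && !any(ex1 %in% nm)) ||
        (all(ex1 %in% nm) && !any(ex0 %in% nm))) {
      return("compatible")
    }
  }
  "incompatible"
}

#' Merge-replay recoverability probe
#'
#' For an incompatible decomposition, reconstructs the correct
#' sub-topology of each disk from the model tree (induced subtree with
#' ground-truth internal genomes), replays the merge, and reports whether
#' the model topology over the parent disk is recovered. Compatible
#' decompositions are vacuously recoverable.
#'
#' @param decomp a `disk_decomposition`.
#' @param model a `model_tree` with all vertices labeled (from
#'   [evolve_genomes()]) or a fully labeled `labeled_tree`.
#' @param names genome names positionally matching the decomposition.
#' @param params [dcm_params()].
#' @return `"recoverable"` or `"irrecoverable"`.
#' @export
merge_replay <- function(decomp, model, names = NULL,
                         params = dcm_params()) {
  mt <- if (inherits(model, "model_tree")) model$tree else as_lt(model)
  if (is.null(names)) names <- leaf_names(mt)
  if (classify_decomposition(decomp, model, names) == "compatible") {
    return("recoverable")
  }
  if (any(vapply(mt$labels, is.null, logical(1)))) {
    stop("merge_replay requires ground-truth labels on the model tree")
  }
  sub0 <- model_subtree(mt, names[decomp$disk0])
  sub1 <- model_subtree(mt, names[decomp$disk1])
  ov <- names[decomp$overlap]
  st <- if (length(ov) == 0L) {
    merge_nonoverlapping(sub0, sub1, params)
  } else {
    merge_overlapping(sub0, sub1, ov, params)
  }
  target <- lt_restrict(mt, names[decomp$parent])
  tgt_splits <- sort(unique(lt_internal_splits(target)))
  cand_trees <- c(list(st$tree),
                  lapply(attr(st, "ties") %||% list(), function(s) s$tree))
  for (tr in cand_trees) {
    if (identical(sort(unique(lt_internal_splits(tr))), tgt_splits)) {
      return("recoverable")
    }
  }
  "irrecoverable"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# induced model subtree on a leaf subset, keeping ground-truth labels
model_subtree <- function(mt, keep) {
  r <- lt_restrict(mt, keep)
  attr(r, "edge_src") <- NULL
  attr(r, "vertex_src") <- NULL
  r$lengths <- NULL
  r
}
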