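#' Construct a clone tree
#'
#' A rooted tree of clones under the infinite-sites assumption: the root is
#' wild type (empty mutation set), every child's mutation set is a strict
#' superset of its parent's, and each mutation is gained on exactly one edge.
#'
#' @param mutation_sets List of character vectors, one per clone, giving the
#'   full set of mutations acquired on the path from the root. The first
#'   element must be the root (empty set).
#' @param parent Integer vector of parent indices (NA for the root).
#' @param clone_ids Optional character vector of clone identifiers.
#' @param colony_counts Optional integer vector of colonies observed per clone.
#' @return An object of class \code{clone_tree}.
#' @export
clone_tree <- function(mutation_sets, parent, clone_ids = NULL,
                       colony_counts = NULL) {
  n <- length(mutation_sets)
  stopifnot(length(parent) == n, n >= 1L)
  mutation_sets <- lapply(mutation_sets, function(s) sort(unique(as.character(s))))
  if (length(mutation_sets[[1L]]) != 0L)
    stop("clone_tree: first clone must be the wild-type root (empty set)",
         call. = FALSE)
  if (!is.na(parent[1L]))
    stop("clone_tree: root must have parent NA", call. = FALSE)
  if (is.null(clone_ids))
    clone_ids <- c("WT", if (n > 1L) paste0("C", seq_len(n - 1L)))
  gained <- vector("list", n)
  for (i in seq_len(n)[-1L]) {
    p <- parent[i]
    if (is.na(p) || p < 1L || p > n || p == i)
      stop("clone_tree: invalid parent index for clone ", i, call. = FALSE)
    if (!all(mutation_sets[[p]] %in% mutation_sets[[i]]) ||
        length(mutation_sets[[i]]) <= length(mutation_sets[[p]]))
      stop("clone_tree: clone ", i,
           " is not a strict superset of its parent", call. = FALSE)
    gained[[i]] <- setdiff(mutation_sets[[i]], mutation_sets[[p]])
  }
  all_gained <- unlist(gained)
  if (anyDuplicated(all_gained))
    stop("clone_tree: a mutation is gained on more than one edge ",
         "(infinite-sites violation)", call. = FALSE)
  structure(
    list(mutation_sets = mutation_sets,
         parent = as.integer(parent),
         clone_ids = as.character(clone_ids),
         edge_mutations = gained,
         colony_counts = colony_counts),
    class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  n <- length(x$mutation_sets)
  cat("Clone tree:", n - 1L, "mutant clone(s),",
      length(unique(unlist(x$mutation_sets))), "mutation(s)\n")
  print_node <- function(i, depth) {
    lab <- if (i == 1L) "WT (root)" else {
      gained <- paste(x$edge_mutations[[i]], collapse = "+")
      cnt <- if (!is.null(x$colony_counts))
        sprintf("  [%d colonies]", x$colony_counts[i]) else ""
      paste0(x$clone_ids[i], ": +", gained, cnt)
    }
    cat(strrep("  ", depth), lab, "\n", sep = "")
    for (ch in which(x$parent == i)) print_node(ch, depth + 1L)
  }
  print_node(1L, 0L)
  invisible(x)
}

#' @export
summary.clone_tree <- function(object, ...) {
  kids <- tabulate(object$parent[!is.na(object$parent)],
                   nbins = length(object$parent))
  out <- list(
    n_clones = length(object$mutation_sets) - 1L,
    n_mutations = length(unique(unlist(object$mutation_sets))),
    max_depth = max(vapply(object$mutation_sets, length, 1L)),
    is_chain = all(kids <= 1L),
    leaf_clones = object$clone_ids[kids == 0L]
  )
  class(out) <- "summary.clone_tree"
  out
}

#' @export
print.summary.clone_tree <- function(x, ...) {
  cat("Clone tree summary\n")
  cat("  mutant clones:  ", x$n_clones, "\n")
  cat("  mutations:      ", x$n_mutations, "\n")
  cat("  max mutations/clone:", x$max_depth, "\n")
  cat("  topology:       ", if (x$is_chain) "linear chain" else "branching", "\n")
  cat("  leaf clones:    ", paste(x$leaf_clones, collapse = ", "), "\n")
  invisible(x)
}

#' Newick rendering of a clone tree
#'
#' Internal and leaf clones are labelled by clone id; edge labels (gained
#' mutations) are appended with '+'. Usable with \pkg{ape} for plotting.
#'
#' @param x A \code{clone_tree}.
#' @return A single Newick string.
#' @export
clone_tree_newick <- function(x) {
  stopifnot(inherits(x, "clone_tree"))
  lab <- function(i) {
    if (i == 1L) return("WT")
    paste0(x$clone_ids[i], "_", paste(x$edge_mutations[[i]], collapse = "+"))
  }
  build <- function(i) {
    ch <- which(x$parent == i)
    if (length(ch) == 0L) return(lab(i))
    paste0("(", paste(vapply(ch, build, ""), collapse = ","), ")", lab(i))
  }
  paste0(build(1L), ";")
}

#' Plot a clone tree
#'
#' Uses \pkg{ape} when available; otherwise falls back to the indented text
#' rendering of \code{print}.
#'
#' @param x A \code{clone_tree}.
#' @param ... Passed to \code{ape::plot.phylo}.
#' @export
plot.clone_tree <- function(x, ...) {
  if (requireNamespace("ape", quietly = TRUE) &&
      length(x$mutation_sets) > 2L) {
    phy <- ape::read.tree(text = clone_tree_newick(x))
    ape::plot.phylo(phy, show.node.label = TRUE, ...)
  } else {
    print(x)
  }
  invisible(x)
}

#' Clones carrying a given mutation
#'
#' @param tree A \code{clone_tree}.
#' @param mutation Mutation identifier.
#' @return Integer indices of clones whose mutation set contains
#'   \code{mutation}.
#' @export
clones_with_mutation <- function(tree, mutation) {
  which(vapply(tree$mutation_sets, function(s) mutation %in% s, TRUE))
}

#' All mutation identifiers on a clone tree
#'
#' @param tree A \code{clone_tree}.
#' @return Character vector in order of first acquisition.
#' @export
tree_mutations <- function(tree) {
  unique(unlist(tree$edge_mutations))
}
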