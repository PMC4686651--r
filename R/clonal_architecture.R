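#' Enumerate subclones from a colony genotype matrix
#'
#' A subclone is a distinct non-empty mutation set observed as a colony
#' genotype. Colonies containing any nocall entry are excluded by default
#' (a nocall could flip containment relations); alternatively nocalls can
#' be treated as wildtype.
#'
#' @param matrix A \code{colony_genotype_matrix}.
#' @param nocall "exclude" (default) drops colonies with any nocall;
#'   "as_wildtype" keeps them with nocalls read as wildtype.
#' @return An object of class \code{subclone_catalog}: \code{data.frame}
#'   with columns \code{signature} (mutations joined by "+"), \code{count},
#'   \code{frequency}; attributes \code{wildtype_count},
#'   \code{n_evaluable}, \code{signatures} (list of character vectors),
#'   \code{colony_signatures} (named character vector, colony -> signature).
#' @export
enumerate_subclones <- function(matrix, nocall = c("exclude", "as_wildtype")) {
  stopifnot(inherits(matrix, "colony_genotype_matrix"))
  nocall <- match.arg(nocall)
  g <- unclass(matrix)
  if (nocall == "exclude") {
    keep <- rowSums(g == "nocall") == 0L
    g <- g[keep, , drop = FALSE]
  }
  bin <- g == "mutant"
  sigs <- apply(bin, 1L, function(r) paste(colnames(g)[r], collapse = "+"))
  wt <- sum(sigs == "")
  mut_sigs <- sigs[sigs != ""]
  tab <- table(mut_sigs)
  # order by decreasing size of the mutation set, then count, for stable output
  sig_sets <- lapply(names(tab), function(s) strsplit(s, "+", fixed = TRUE)[[1]])
  ord <- order(vapply(sig_sets, length, 1L), -as.integer(tab))
  cat_df <- data.frame(signature = names(tab)[ord],
                       count = as.integer(tab)[ord],
                       frequency = as.integer(tab)[ord] / nrow(g),
                       stringsAsFactors = FALSE)
  structure(cat_df,
            wildtype_count = wt,
            n_evaluable = nrow(g),
            signatures = sig_sets[ord],
            colony_signatures = sigs,
            class = c("subclone_catalog", "data.frame"))
}

#' @export
print.subclone_catalog <- function(x, ...) {
  cat("Subclone catalog:", nrow(x), "distinct mutant subclone(s),",
      attr(x, "wildtype_count"), "wild-type colonies,",
      attr(x, "n_evaluable"), "evaluable\n")
  print.data.frame(x)
  invisible(x)
}

#' Perfect-phylogeny compatibility of a genotype matrix
#'
#' Binary directed two-character test with known all-zero ancestral state:
#' the matrix is tree-compatible iff no pair of mutations (A, B) shows all
#' three colony patterns \{A only, B only, A and B\} (the three-gamete
#' condition). Colonies with nocall entries are excluded.
#'
#' @param matrix A \code{colony_genotype_matrix} or logical/0-1 matrix
#'   (colonies x mutations).
#' @return List with \code{compatible} (logical) and
#'   \code{violating_pair} (character length 2, first violating pair in
#'   panel order, or NULL).
#' @export
check_tree_compatibility <- function(matrix) {
  bin <- as_binary_genotypes(matrix)
  m <- ncol(bin)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        a <- bin[, i]; b <- bin[, j]
        if (any(a & !b) && any(!a & b) && any(a & b))
          return(list(compatible = FALSE,
                      violating_pair = colnames(bin)[c(i, j)]))
      }
    }
  }
  list(compatible = TRUE, violating_pair = NULL)
}

as_binary_genotypes <- function(matrix) {
  if (inherits(matrix, "colony_genotype_matrix")) {
    g <- unclass(matrix)
    keep <- rowSums(g == "nocall") == 0L
    g <- g[keep, , drop = FALSE]
    bin <- g == "mutant"
  } else {
    bin <- matrix > 0
  }
  if (is.null(colnames(bin)))
    colnames(bin) <- paste0("m", seq_len(ncol(bin)))
  bin
}

#' Infer the clone tree from a colony genotype matrix
#'
#' Builds the tree of observed genotype signatures ordered by strict set
#' containment: each clone's parent is its unique maximal proper-subset
#' signature among those observed (the wild-type root if none), and the
#' mutations gained on an edge are the set difference. Signatures that are
#' containment-incomparable become sibling branches. Unobserved
#' intermediate clones are not invented, so an edge may carry several
#' mutations. Requires tree compatibility
#' (\code{\link{check_tree_compatibility}}).
#'
#' @param matrix A \code{colony_genotype_matrix}.
#' @param nocall Passed to \code{\link{enumerate_subclones}}.
#' @return A \code{\link{clone_tree}} whose non-root nodes are the observed
#'   subclones, with per-clone colony counts.
#' @export
infer_clone_tree <- function(matrix, nocall = c("exclude", "as_wildtype")) {
  nocall <- match.arg(nocall)
  compat <- check_tree_compatibility(matrix)
  if (!compat$compatible)
    stop("infer_clone_tree: genotype matrix is not tree-compatible; ",
         "violating mutation pair: ",
         paste(compat$violating_pair, collapse = ", "), call. = FALSE)
  catalog <- enumerate_subclones(matrix, nocall)
  sets <- attr(catalog, "signatures")
  n <- length(sets)
  # nodes: 1 = root (empty), 2..n+1 = observed signatures ordered by size
  ord <- order(vapply(sets, length, 1L))
  sets <- sets[ord]
  counts <- catalog$count[ord]
  sigs <- catalog$signature[ord]
  parent <- c(NA_integer_, integer(n))
  all_sets <- c(list(character(0)), sets)
  for (i in seq_len(n)) {
    child <- sets[[i]]
    # candidate parents: observed proper subsets
    cand <- which(vapply(seq_len(i), function(j) {
      s <- all_sets[[j]]
      length(s) < length(child) && all(s %in% child)
    }, TRUE))
    sizes <- vapply(all_sets[cand], length, 1L)
    maximal <- cand[sizes == max(sizes)]
    # two incomparable maximal subsets cannot occur for a compatible matrix
    if (length(unique(lapply(all_sets[maximal], sort))) > 1L)
      stop("infer_clone_tree: ambiguous parent for subclone ", sigs[i],
           "; candidates: ",
           paste(vapply(all_sets[maximal], paste, "", collapse = "+"),
                 collapse = " | "), call. = FALSE)
    parent[i + 1L] <- maximal[1L]
  }
  clone_tree(all_sets, parent,
             clone_ids = c("WT", sigs),
             colony_counts = c(attr(catalog, "wildtype_count"), counts))
}

#' Identify founder mutations and mutually exclusive pairs
#'
#' The founder set contains every mutation called mutant in all mutant
#' colonies (evaluable entries only) — the lesion inferred to precede all
#' others. Mutual-exclusivity pairs are mutation pairs that each occur in
#' at least \code{min_count} colonies yet never co-occur.
#'
#' @param matrix A \code{colony_genotype_matrix}.
#' @param min_count Minimum per-mutation colony count for exclusivity calls.
#' @return List with \code{founder} (character vector) and
#'   \code{exclusive_pairs} (\code{data.frame} with columns
#'   \code{mutation1}, \code{mutation2}).
#' @export
identify_founder <- function(matrix, min_count = 2L) {
  stopifnot(inherits(matrix, "colony_genotype_matrix"))
  g <- unclass(matrix)
  mutant_any <- rowSums(g == "mutant") > 0L
  if (!any(mutant_any))
    return(list(founder = character(0),
                exclusive_pairs = data.frame(mutation1 = character(0),
                                             mutation2 = character(0))))
  gm <- g[mutant_any, , drop = FALSE]
  founder <- colnames(gm)[vapply(seq_len(ncol(gm)), function(j) {
    col <- gm[, j]
    eval_ <- col != "nocall"
    any(eval_) && all(col[eval_] == "mutant")
  }, TRUE)]
  bin <- g == "mutant"
  counts <- colSums(bin)
  pairs <- list()
  m <- ncol(bin)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (counts[i] >= min_count && counts[j] >= min_count &&
            !any(bin[, i] & bin[, j]))
          pairs[[length(pairs) + 1L]] <-
            data.frame(mutation1 = colnames(bin)[i],
                       mutation2 = colnames(bin)[j],
                       stringsAsFactors = FALSE)
      }
    }
  }
  ex <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(mutation1 = character(0), mutation2 = character(0))
  list(founder = founder, exclusive_pairs = ex)
}

#' Bulk-MAB hierarchy of mutations
#'
#' Orders mutations within one sample by cellular prevalence: A is placed
#' above B only when A's prevalence CI lies entirely above B's; mutations
#' with overlapping CIs stay unordered (similar burdens do not identify
#' which mutation is ancestral). A heuristic partial order, not a formal
#' test.
#'
#' @param estimates List of \code{mab_estimate} objects from one sample,
#'   heterozygosity assumed.
#' @return List with \code{above} (\code{data.frame} of ordered pairs:
#'   \code{higher}, \code{lower}) and \code{prevalence} (named vector).
#' @export
mab_hierarchy <- function(estimates) {
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, TRUE, "mab_estimate")))
  ids <- vapply(estimates, `[[`, "", "mutation_id")
  prev <- vapply(estimates, function(e) min(1, 2 * e$mab), 0)
  lo <- vapply(estimates, function(e) min(1, 2 * e$ci[1L]), 0)
  hi <- vapply(estimates, function(e) min(1, 2 * e$ci[2L]), 0)
  names(prev) <- ids
  pairs <- list()
  n <- length(ids)
  if (n >= 2L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && lo[i] > hi[j])
          pairs[[length(pairs) + 1L]] <-
            data.frame(higher = ids[i], lower = ids[j],
                       stringsAsFactors = FALSE)
      }
    }
  }
  above <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(higher = character(0), lower = character(0))
  list(above = above, prevalence = prev)
}

#' Earliest compartment of detection along the differentiation hierarchy
#'
#' Given detection flags per compartment in differentiation order (HSC at
#' the top), returns the most primitive compartment where the mutation is
#' detected. Mutations absent in HSCs but present downstream are flagged
#' progenitor-origin (a lesion acquired in a progenitor, not a stem cell).
#'
#' @param detection Named logical vector; names are compartment labels in
#'   hierarchy order, most primitive first (e.g. HSC, MPP, MLP, CMP, GMP,
#'   MEP).
#' @return List with \code{origin} (label or NA if never detected) and
#'   \code{progenitor_origin} (logical).
#' @export
assign_origin_compartment <- function(detection) {
  stopifnot(is.logical(detection), !is.null(names(detection)),
            length(detection) >= 1L)
  hit <- which(detection)
  if (length(hit) == 0L)
    return(list(origin = NA_character_, progenitor_origin = FALSE))
  origin <- names(detection)[min(hit)]
  list(origin = origin,
       progenitor_origin = !detection[[1L]] && any(detection[-1L]))
}
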