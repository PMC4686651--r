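#' Call a single-colony genotype
#'
#' A colony is called mutant for a gene when strictly more than 30 percent
#' of its sequencing reads carry the mutant allele; entries with depth below
#' \code{min_colony_depth} are nocall (a 0/0 or shallow entry must never be
#' called wild type).
#'
#' @param alt,total Alt and total read counts (vectorised).
#' @param config A \code{\link{filter_config}}.
#' @return Character vector in \{"mutant", "wildtype", "nocall"\}.
#' @export
call_colony_genotype <- function(alt, total, config = filter_config()) {
  stopifnot(all(alt >= 0), all(alt <= total))
  frac <- ifelse(total > 0, alt / total, 0)
  ifelse(total < config$min_colony_depth, "nocall",
         ifelse(frac > config$colony_mutant_threshold, "mutant", "wildtype"))
}

#' Build a colonies-by-mutations genotype matrix
#'
#' @param colony_table Long \code{data.frame} with columns \code{colony_id},
#'   \code{mutation_id}, \code{alt}, \code{total} (one row per colony and
#'   panel mutation; missing combinations become nocall).
#' @param panel Character vector of mutation identifiers defining column
#'   order; defaults to order of first appearance.
#' @param config A \code{\link{filter_config}}.
#' @return An object of class \code{colony_genotype_matrix}: a character
#'   matrix (rows = colonies sorted by identifier, columns = panel order,
#'   entries "mutant"/"wildtype"/"nocall") with attributes \code{alt_frac}
#'   and \code{depth} (numeric matrices of the same shape).
#' @export
build_genotype_matrix <- function(colony_table, panel = NULL,
                                  config = filter_config()) {
  stopifnot(is.data.frame(colony_table),
            all(c("colony_id", "mutation_id", "alt", "total") %in%
                  names(colony_table)))
  if (anyDuplicated(colony_table[, c("colony_id", "mutation_id")]))
    stop("build_genotype_matrix: duplicate colony/mutation entries",
         call. = FALSE)
  if (is.null(panel)) panel <- unique(colony_table$mutation_id)
  colonies <- sort(unique(colony_table$colony_id))
  geno <- matrix("nocall", length(colonies), length(panel),
                 dimnames = list(colonies, panel))
  frac <- matrix(NA_real_, length(colonies), length(panel),
                 dimnames = list(colonies, panel))
  depth <- matrix(0, length(colonies), length(panel),
                  dimnames = list(colonies, panel))
  keep <- colony_table$mutation_id %in% panel
  tab <- colony_table[keep, , drop = FALSE]
  idx <- cbind(match(tab$colony_id, colonies), match(tab$mutation_id, panel))
  geno[idx] <- call_colony_genotype(tab$alt, tab$total, config)
  frac[idx] <- ifelse(tab$total > 0, tab$alt / tab$total, NA_real_)
  depth[idx] <- tab$total
  structure(geno, alt_frac = frac, depth = depth,
            class = c("colony_genotype_matrix", "matrix", "array"))
}

#' @export
print.colony_genotype_matrix <- function(x, ...) {
  code <- matrix(substr(unclass(x), 1L, 1L), nrow(x), ncol(x),
                 dimnames = dimnames(x))
  cat("Colony genotype matrix:", nrow(x), "colonies x", ncol(x),
      "mutations (M = mutant, w = wildtype, . = nocall)\n")
  code[code == "m"] <- "M"
  code[code == "n"] <- "."
  print(code, quote = FALSE)
  invisible(x)
}

#' Fraction of colonies mutant for one gene
#'
#' Colonies with nocall for the mutation are excluded from the denominator.
#' The percentage is rounded half-up to the nearest integer, matching the
#' reporting granularity of published colony screens.
#'
#' @param matrix A \code{colony_genotype_matrix}.
#' @param mutation Mutation identifier (column).
#' @return List with \code{percent} (integer), \code{fraction} (raw),
#'   \code{n_mutant}, \code{n_wildtype}, \code{n_nocall}.
#' @export
colony_fraction_mutant <- function(matrix, mutation) {
  stopifnot(inherits(matrix, "colony_genotype_matrix"))
  if (!mutation %in% colnames(matrix))
    stop("colony_fraction_mutant: mutation '", mutation,
         "' not in the panel", call. = FALSE)
  col <- unclass(matrix)[, mutation]
  n_m <- sum(col == "mutant")
  n_w <- sum(col == "wildtype")
  if (n_m + n_w == 0L)
    stop("colony_fraction_mutant: no evaluable colonies for '", mutation,
         "'", call. = FALSE)
  fraction <- n_m / (n_m + n_w)
  list(percent = as.integer(floor(100 * fraction + 0.5)),
       fraction = fraction,
       n_mutant = n_m, n_wildtype = n_w,
       n_nocall = sum(col == "nocall"))
}
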