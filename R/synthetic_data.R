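#' Simulate a clone tree
#'
#' Grows a rooted clone tree under the infinite-sites assumption by adding
#' one mutation at a time. With probability \code{branching_prob} the new
#' mutation starts a branch from a uniformly chosen existing clone; otherwise
#' it extends the most recently created clone, so a branching probability of
#' 0 produces a single linear chain.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{\link{clone_tree}} with \code{config$n_mutations} mutant
#'   clones, one new mutation per edge.
#' @export
simulate_clone_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$n_mutations
  withr_seed(stage_seed(config$seed, "tree"))
  sets <- list(character(0))
  parent <- NA_integer_
  tip <- 1L
  for (i in seq_len(k)) {
    m <- paste0("m", i)
    p <- if (stats::runif(1) < config$branching_prob)
      sample.int(length(sets), 1L) else tip
    sets[[length(sets) + 1L]] <- c(sets[[p]], m)
    parent <- c(parent, p)
    tip <- length(sets)
  }
  clone_tree(sets, parent)
}

# set.seed scoped to one stage without clobbering the caller's RNG state
withr_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

#' Construct a compartment profile
#'
#' Per-clone cell fractions in one sorted haematopoietic compartment; the
#' remainder (1 minus the sum) is wild type.
#'
#' @param compartment Compartment label (e.g. "HSC", "MPP", "GMP", "MEP",
#'   "CD34", "HEC", "LTC", "TNC").
#' @param fractions Named numeric vector of clone fractions in [0, 1],
#'   names matching clone ids of the generating tree.
#' @param time_point Time-point label (default "TP1").
#' @return An object of class \code{compartment_profile}.
#' @export
compartment_profile <- function(compartment, fractions, time_point = "TP1") {
  if (length(fractions) && is.null(names(fractions)))
    stop("compartment_profile: 'fractions' must be named by clone id",
         call. = FALSE)
  if (any(fractions < 0))
    stop("compartment_profile: clone fractions must be >= 0", call. = FALSE)
  if (sum(fractions) > 1 + 1e-9)
    stop("compartment_profile: clone fractions must sum to <= 1",
         call. = FALSE)
  structure(list(compartment = compartment,
                 fractions = fractions,
                 time_point = time_point),
            class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, ...) {
  cat("Compartment", x$compartment, "at", x$time_point, "\n")
  if (length(x$fractions)) {
    for (i in seq_along(x$fractions))
      cat(sprintf("  %-8s %.3f\n", names(x$fractions)[i], x$fractions[i]))
  }
  cat(sprintf("  %-8s %.3f\n", "WT", max(0, 1 - sum(x$fractions))))
  invisible(x)
}

#' Assign clone fractions across compartments
#'
#' Draws a base set of clone fractions for the mutant clones of a tree and
#' perturbs them per compartment by multiplicative log-normal drift. With
#' \code{config$drift = 0} every compartment carries identical fractions,
#' emulating mutation burdens maintained from stem cells down the myeloid
#' hierarchy.
#'
#' @param tree A \code{\link{clone_tree}}.
#' @param compartments Character vector of compartment labels.
#' @param config A \code{\link{simulation_config}}.
#' @param time_point Time-point label for all profiles.
#' @return List of \code{\link{compartment_profile}} objects, one per
#'   compartment.
#' @export
assign_clone_fractions <- function(tree, compartments, config,
                                   time_point = "TP1") {
  stopifnot(inherits(tree, "clone_tree"), inherits(config, "simulation_config"))
  if (length(compartments) == 0L)
    stop("assign_clone_fractions: at least one compartment is required",
         call. = FALSE)
  withr_seed(stage_seed(config$seed, "fractions"))
  n <- length(tree$mutation_sets)          # incl. wild-type root
  w <- stats::rgamma(n, shape = 1.5, rate = 1)
  lapply(compartments, function(comp) {
    wc <- if (config$drift > 0)
      w * exp(config$drift * stats::rnorm(n)) else w
    fr <- wc / sum(wc)
    compartment_profile(comp,
                        stats::setNames(fr[-1L], tree$clone_ids[-1L]),
                        time_point)
  })
}

# deterministic dummy genomic coordinates for simulated mutations
mutation_coords <- function(mutation_ids) {
  i <- seq_along(mutation_ids)
  data.frame(mutation_id = mutation_ids,
             gene = toupper(mutation_ids),
             chrom = as.character((i %% 22L) + 1L),
             pos = 1000000L + i * 100000L,
             ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}

# random flank with no two adjacent identical bases (never trips the
# homopolymer filter)
random_clean_flank <- function(n, len = 6L) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    s <- sample(bases, 1L)
    for (j in seq_len(len - 1L))
      s <- paste0(s, sample(setdiff(bases, substr(s, j, j)), 1L))
    s
  }, "")
}

#' Simulate bulk allele counts for a compartment
#'
#' For each heterozygous mutation on the tree, the expected mutant allele
#' burden (MAB) is half the summed fraction of clones carrying it; read
#' counts are drawn binomially at the configured coverage with a symmetric
#' per-read error flip. The true underlying MAB of every record is carried
#' in a ground-truth side table (attribute \code{"truth"}) that analysis
#' functions never read.
#'
#' @param profile A \code{\link{compartment_profile}}.
#' @param tree The generating \code{\link{clone_tree}}.
#' @param config A \code{\link{simulation_config}}.
#' @param sample_id Sample identifier written into the records.
#' @param source_class Source class label (default "compartment").
#' @param replicate_id Replicate identifier.
#' @param experiment_id Experiment (e.g. mouse) identifier.
#' @return A variant table (\code{data.frame}, columns of
#'   \code{\link{variant_table_columns}}) with attribute \code{"truth"}.
#' @export
simulate_bulk_counts <- function(profile, tree, config,
                                 sample_id = profile$compartment,
                                 source_class = "compartment",
                                 replicate_id = "R1",
                                 experiment_id = "E1") {
  stopifnot(inherits(profile, "compartment_profile"),
            inherits(tree, "clone_tree"),
            inherits(config, "simulation_config"))
  if (config$coverage < 1L)
    stop("simulate_bulk_counts: coverage must be >= 1", call. = FALSE)
  muts <- tree_mutations(tree)
  if (!all(names(profile$fractions) %in% tree$clone_ids))
    stop("simulate_bulk_counts: profile and tree disagree on clone ids",
         call. = FALSE)
  withr_seed(stage_seed(config$seed,
                        paste0("bulk:", sample_id, ":", replicate_id)))
  e <- config$seq_error
  n <- length(muts)
  prev <- vapply(muts, function(m) {
    idx <- clones_with_mutation(tree, m)
    ids <- tree$clone_ids[idx]
    sum(profile$fractions[names(profile$fractions) %in% ids])
  }, 0)
  true_mab <- prev / 2
  p_obs <- true_mab * (1 - e) + (1 - true_mab) * e
  total <- rep(config$coverage, n)
  alt <- stats::rbinom(n, total, p_obs)
  alt_fwd <- stats::rbinom(n, alt, 0.5)
  coords <- mutation_coords(muts)
  df <- data.frame(
    row_uid = paste0(sample_id, ":", replicate_id, ":", muts),
    sample_id = sample_id,
    source_class = source_class,
    replicate_id = replicate_id,
    experiment_id = experiment_id,
    mutation_id = muts,
    gene = coords$gene,
    chrom = coords$chrom,
    pos = coords$pos,
    ref = coords$ref,
    alt = coords$alt,
    alt_reads = alt,
    total_reads = total,
    alt_fwd = alt_fwd,
    alt_rev = alt - alt_fwd,
    mean_alignment_score = 60,
    mean_base_quality = 35,
    flank_left = random_clean_flank(n),
    flank_right = random_clean_flank(n),
    wga = FALSE,
    pop_known = FALSE,
    pop_af = 0,
    dup_region = FALSE,
    known_mutation = FALSE,
    pos_bias = FALSE,
    len_bias = FALSE,
    stringsAsFactors = FALSE)
  attr(df, "truth") <- data.frame(
    row_uid = df$row_uid,
    mutation_id = muts,
    true_mab = true_mab,
    clone_prevalence = prev,
    is_artifact = FALSE,
    dropout = FALSE,
    stringsAsFactors = FALSE)
  df
}

#' Simulate single-cell colonies
#'
#' Each colony's founder clone is drawn i.i.d. from the compartment's clone
#' fractions (wild type with the residual probability); every cell of a
#' colony shares the founder genotype, so carried heterozygous mutations are
#' read at expectation 0.5 and non-carried mutations at the sequencing error
#' rate.
#'
#' @param profile A \code{\link{compartment_profile}}.
#' @param tree The generating \code{\link{clone_tree}}.
#' @param n_colonies Number of colonies (>= 1).
#' @param config A \code{\link{simulation_config}}.
#' @return Long-format \code{data.frame} with columns \code{colony_id},
#'   \code{mutation_id}, \code{alt}, \code{total}; attribute \code{"truth"}
#'   holds founder clone and genotype per colony.
#' @export
simulate_colonies <- function(profile, tree, n_colonies, config) {
  stopifnot(inherits(profile, "compartment_profile"),
            inherits(tree, "clone_tree"),
            inherits(config, "simulation_config"))
  if (n_colonies < 1L)
    stop("simulate_colonies: n_colonies must be >= 1", call. = FALSE)
  withr_seed(stage_seed(config$seed, "colonies"))
  muts <- tree_mutations(tree)
  fr <- profile$fractions
  probs <- c(fr, WT = max(0, 1 - sum(fr)))
  founder <- sample(names(probs), n_colonies, replace = TRUE, prob = probs)
  colony_ids <- sprintf("colony%03d", seq_len(n_colonies))
  e <- config$seq_error
  rows <- vector("list", n_colonies)
  genotypes <- vector("list", n_colonies)
  for (i in seq_len(n_colonies)) {
    geno <- if (founder[i] == "WT") character(0) else
      tree$mutation_sets[[match(founder[i], tree$clone_ids)]]
    genotypes[[i]] <- geno
    p <- ifelse(muts %in% geno, 0.5, e)
    total <- rep(config$coverage, length(muts))
    alt <- stats::rbinom(length(muts), total, p)
    rows[[i]] <- data.frame(colony_id = colony_ids[i],
                            mutation_id = muts,
                            alt = alt, total = total,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  attr(df, "truth") <- list(
    founder = stats::setNames(founder, colony_ids),
    genotypes = stats::setNames(genotypes, colony_ids))
  df
}

#' Inject whole-genome-amplification artifacts
#'
#' Adds spurious variant records at the configured artifact rate (a
#' configurable fraction with homopolymer flanking context of length >= 5
#' and/or positional/read-length bias flags) and applies allele dropout to
#' heterozygous records, zeroing either the alt or the ref reads. Artifact
#' records carry ground-truth labels in the \code{"truth"} attribute for
#' filter-evaluation tests; the labels are never consumed by the filters.
#'
#' @param table A variant table from \code{\link{simulate_bulk_counts}}.
#' @param config A \code{\link{simulation_config}}.
#' @return The table with injected artifacts, dropout applied, records
#'   flagged \code{wga = TRUE}, and an updated \code{"truth"} attribute.
#' @export
inject_wga_artifacts <- function(table, config) {
  stopifnot(is.data.frame(table), inherits(config, "simulation_config"))
  truth <- attr(table, "truth")
  withr_seed(stage_seed(config$seed, "wga"))
  out <- table
  out$wga <- TRUE
  n <- nrow(out)

  # allele dropout on heterozygous records
  dropped <- rep(FALSE, n)
  if (config$wga_dropout_prob > 0 && n > 0) {
    het <- out$alt_reads > 0 & out$alt_reads < out$total_reads
    hit <- het & stats::runif(n) < config$wga_dropout_prob
    if (any(hit)) {
      to_alt <- stats::runif(sum(hit)) < 0.5
      idx <- which(hit)
      lose_alt <- idx[!to_alt]
      lose_ref <- idx[to_alt]
      out$alt_reads[lose_alt] <- 0L
      out$alt_fwd[lose_alt] <- 0L
      out$alt_rev[lose_alt] <- 0L
      out$alt_reads[lose_ref] <- out$total_reads[lose_ref]
      out$alt_fwd[lose_ref] <- as.integer(round(out$total_reads[lose_ref] / 2))
      out$alt_rev[lose_ref] <- out$total_reads[lose_ref] - out$alt_fwd[lose_ref]
      dropped <- hit
    }
  }
  if (!is.null(truth)) truth$dropout <- dropped

  # spurious records
  n_art <- if (config$wga_artifact_rate > 0 && n > 0)
    stats::rbinom(1L, n, config$wga_artifact_rate) else 0L
  if (n_art > 0) {
    src <- sample.int(n, n_art, replace = TRUE)
    frac <- stats::runif(n_art, 0.02, 0.6)
    total <- out$total_reads[src]
    alt <- stats::rbinom(n_art, total, frac)
    fwd <- stats::rbinom(n_art, alt, 0.5)
    homo <- stats::runif(n_art) < config$artifact_homopolymer_frac
    bias <- stats::runif(n_art) < config$artifact_bias_frac
    art_ids <- sprintf("wga_art%03d", seq_len(n_art))
    art <- out[src, ]
    art$row_uid <- paste0(art$sample_id, ":", art$replicate_id, ":", art_ids)
    art$mutation_id <- art_ids
    art$gene <- toupper(art_ids)
    art$pos <- 50000000L + seq_len(n_art) * 1000L
    art$alt_reads <- alt
    art$total_reads <- total
    art$alt_fwd <- fwd
    art$alt_rev <- alt - fwd
    art$flank_left <- ifelse(homo, "CAAAAA", random_clean_flank(n_art))
    art$pos_bias <- bias
    art$len_bias <- bias
    art$wga <- TRUE
    out <- rbind(out, art)
    rownames(out) <- NULL
    if (!is.null(truth)) {
      truth <- rbind(truth, data.frame(
        row_uid = art$row_uid,
        mutation_id = art_ids,
        true_mab = 0,
        clone_prevalence = 0,
        is_artifact = TRUE,
        dropout = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  attr(out, "truth") <- truth
  out
}

#' Simulate a germline SNP allele-fraction profile with an optional deletion
#'
#' Generates heterozygous population SNPs along one chromosome; SNPs inside
#' the deleted interval deviate from 0.5 according to the fraction of cells
#' carrying a heterozygous deletion: the expected allele fraction becomes
#' 1/(2-f) or (1-f)/(2-f) depending on which allele is retained.
#'
#' @param n_snps Number of SNPs.
#' @param depth Read depth per SNP; counts are binomial unless
#'   \code{exact = TRUE}.
#' @param del_start,del_end SNP index range of the deletion (NULL for none).
#' @param clone_fraction Fraction of cells carrying the deletion.
#' @param chrom Chromosome label.
#' @param seed Integer seed.
#' @param exact If TRUE, fractions are set to their expectations (noise-free).
#' @return A SNP record \code{data.frame} (see
#'   \code{\link{snp_table_columns}}) with attribute \code{"truth"} giving
#'   the deleted index range and clone fraction.
#' @export
simulate_loh_profile <- function(n_snps = 200, depth = 80,
                                 del_start = NULL, del_end = NULL,
                                 clone_fraction = 1.0,
                                 chrom = "7", seed = 1L, exact = FALSE) {
  withr_seed(stage_seed(seed, "loh"))
  pos <- 100000L + seq_len(n_snps) * 50000L
  f <- clone_fraction
  expect <- rep(0.5, n_snps)
  in_del <- rep(FALSE, n_snps)
  if (!is.null(del_start) && !is.null(del_end)) {
    in_del[del_start:del_end] <- TRUE
    hi <- stats::runif(n_snps) < 0.5
    expect[in_del & hi] <- 1 / (2 - f)
    expect[in_del & !hi] <- (1 - f) / (2 - f)
  }
  if (exact) {
    alt_frac <- expect
    alt_reads <- round(expect * depth)
  } else {
    alt_reads <- stats::rbinom(n_snps, depth, expect)
    alt_frac <- alt_reads / depth
  }
  df <- data.frame(chrom = chrom, pos = pos,
                   alt_reads = alt_reads, depth = depth,
                   alt_frac = alt_frac,
                   pop_known = TRUE, pop_af = 0.3,
                   somatic = FALSE, dup_region = FALSE,
                   normal_frac = 0.5,
                   stringsAsFactors = FALSE)
  attr(df, "truth") <- list(del_start = del_start, del_end = del_end,
                            clone_fraction = clone_fraction)
  df
}
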