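#' Canonical variant-table columns
#'
#' The TSV dialect exchanged between pipeline stages: one row per variant
#' observation in one sample, with read-level evidence. Required columns
#' and their meaning:
#' \describe{
#'   \item{row_uid}{unique row identifier}
#'   \item{sample_id}{sample identifier}
#'   \item{source_class}{one of primary_CD34, HEC, LTC, CFC, compartment,
#'     normal_skin, normal_Tcell, WGA-control}
#'   \item{replicate_id, experiment_id}{replicate and experiment (mouse)}
#'   \item{mutation_id, gene, chrom, pos, ref, alt}{variant identity
#'     (pos is 1-based)}
#'   \item{alt_reads, total_reads, alt_fwd, alt_rev}{read counts; strand
#'     counts sum to alt_reads}
#'   \item{mean_alignment_score, mean_base_quality}{read-level means}
#'   \item{flank_left, flank_right}{flanking sequence, >= 5 bases each side}
#'   \item{wga}{whole-genome-amplified material flag}
#'   \item{pop_known, pop_af}{population-database membership and allele
#'     frequency}
#'   \item{dup_region, known_mutation}{genomic duplicated region flag and
#'     known-mutation override}
#'   \item{pos_bias, len_bias}{precomputed positional / read-length
#'     distribution bias flags for WGA records}
#' }
#'
#' @return Character vector of column names.
#' @export
variant_table_columns <- function() {
  c("row_uid", "sample_id", "source_class", "replicate_id", "experiment_id",
    "mutation_id", "gene", "chrom", "pos", "ref", "alt",
    "alt_reads", "total_reads", "alt_fwd", "alt_rev",
    "mean_alignment_score", "mean_base_quality",
    "flank_left", "flank_right",
    "wga", "pop_known", "pop_af", "dup_region", "known_mutation",
    "pos_bias", "len_bias")
}

#' Canonical SNP-table columns for LOH mapping
#'
#' @return Character vector: chrom, pos, alt_reads, depth, alt_frac,
#'   pop_known, pop_af, somatic, dup_region, normal_frac.
#' @export
snp_table_columns <- function() {
  c("chrom", "pos", "alt_reads", "depth", "alt_frac",
    "pop_known", "pop_af", "somatic", "dup_region", "normal_frac")
}

validate_variant_rows <- function(df) {
  reasons <- rep(NA_character_, nrow(df))
  bad_counts <- df$alt_reads < 0 | df$alt_reads > df$total_reads
  reasons[bad_counts] <- "alt_reads outside [0, total_reads]"
  bad_strand <- (df$alt_fwd + df$alt_rev) != df$alt_reads
  reasons[is.na(reasons) & bad_strand] <-
    "strand alt counts do not sum to alt_reads"
  bad_pos <- df$pos < 1
  reasons[is.na(reasons) & bad_pos] <- "position < 1"
  reasons
}

#' Read a variant table
#'
#' Reads the canonical TSV dialect or a VCF (via \pkg{vcfR}, with AD-style
#' allele depths). Rows violating record invariants (alt > total, strand
#' counts inconsistent, position < 1) are collected into a rejection
#' report, never silently dropped.
#'
#' @param path Input file.
#' @param dialect "tsv" or "vcf".
#' @param sample_id,source_class Identity fields for VCF ingestion (VCFs
#'   carry no pipeline metadata).
#' @return Validated variant \code{data.frame}; attribute
#'   \code{"rejected"} holds a \code{data.frame} of rejected rows with a
#'   \code{reason} column.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               sample_id = "sample1",
                               source_class = "primary_CD34") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("read_variant_table: file not found: ", path, call. = FALSE)
  df <- if (dialect == "tsv") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character"))
    missing <- setdiff(variant_table_columns(), names(x))
    if (length(missing))
      stop("read_variant_table: missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    x[, variant_table_columns()]
  } else {
    read_vcf_counts(path, sample_id, source_class)
  }
  reasons <- validate_variant_rows(df)
  rejected <- df[!is.na(reasons), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[!is.na(reasons)]
  out <- df[is.na(reasons), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

# map a VCF with per-sample AD fields onto the canonical variant table
read_vcf_counts <- function(path, sample_id, source_class) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_counts: package 'vcfR' is required for VCF input",
         call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1L]
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_d <- vapply(parts, function(p) as.integer(p[1L]), 0L)
  alt_d <- vapply(parts, function(p) as.integer(p[2L]), 0L)
  n <- nrow(fix)
  mut <- paste0(fix$CHROM, ":", fix$POS, fix$REF, ">", fix$ALT)
  data.frame(
    row_uid = paste0(sample_id, ":vcf:", mut),
    sample_id = sample_id,
    source_class = source_class,
    replicate_id = "R1",
    experiment_id = "E1",
    mutation_id = mut,
    gene = NA_character_,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    alt_reads = alt_d,
    total_reads = ref_d + alt_d,
    alt_fwd = as.integer(floor(alt_d / 2)),
    alt_rev = alt_d - as.integer(floor(alt_d / 2)),
    mean_alignment_score = 60,
    mean_base_quality = 35,
    flank_left = NA_character_,
    flank_right = NA_character_,
    wga = FALSE,
    pop_known = FALSE,
    pop_af = 0,
    dup_region = FALSE,
    known_mutation = FALSE,
    pos_bias = FALSE,
    len_bias = FALSE,
    stringsAsFactors = FALSE)
}

#' Write a variant table as canonical TSV
#'
#' @param records Variant \code{data.frame}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(records, path) {
  utils::write.table(records[, variant_table_columns()], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end synthetic pipeline
#'
#' Chains the stages on simulator output: simulate a clone tree and
#' compartment mixtures, draw bulk allele counts, inject WGA artifacts,
#' run the filter cascade, quantify MABs, genotype colonies, reconstruct
#' the clone tree, classify trajectories between the first two
#' compartments, and scan a synthetic chromosome for LOH. Outputs are
#' written under \code{out_dir} with a run manifest (JSON) recording the
#' tool version, config snapshot, seed, per-stage record counts, file
#' digests, and timestamps. Identical config and seed give byte-identical
#' stage outputs.
#'
#' @param sim_config A \code{\link{simulation_config}}.
#' @param filt_config A \code{\link{filter_config}}.
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   c("simulate", "filter", "mab", "colonies", "tree", "dynamics", "loh").
#' @param compartments Compartment labels to simulate.
#' @param n_colonies Colonies to simulate for genotyping.
#' @return List of stage outputs plus \code{manifest}.
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         filt_config = filter_config(),
                         out_dir = tempfile("clonarch_run"),
                         stages = c("simulate", "filter", "mab", "colonies",
                                    "tree", "dynamics", "loh"),
                         compartments = c("HSC", "MPP", "GMP", "MEP"),
                         n_colonies = 48L) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  outputs <- list()
  skipped <- setdiff(c("simulate", "filter", "mab", "colonies", "tree",
                       "dynamics", "loh"), stages)

  tree <- simulate_clone_tree(sim_config)
  profiles <- assign_clone_fractions(tree, compartments, sim_config)
  names(profiles) <- compartments

  tables <- NULL
  if ("simulate" %in% stages) {
    tables <- lapply(compartments, function(cmp)
      simulate_bulk_counts(profiles[[cmp]], tree, sim_config,
                           sample_id = cmp))
    names(tables) <- compartments
    all_tab <- do.call(rbind, tables)
    rownames(all_tab) <- NULL
    write_variant_table(all_tab, file.path(out_dir, "simulated_variants.tsv"))
    truth <- do.call(rbind, lapply(tables, attr, "truth"))
    rownames(truth) <- NULL
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         digits = NA)
    counts$simulated <- nrow(all_tab)
    outputs$variants <- all_tab
    outputs$tree_true <- tree
  }

  passed <- NULL
  if ("filter" %in% stages && !is.null(tables)) {
    all_tab <- outputs$variants
    # matched normal: wild type at every locus, same coverage
    normals <- all_tab[!duplicated(all_tab$mutation_id), , drop = FALSE]
    normals$alt_reads <- 0L
    normals$alt_fwd <- 0L
    normals$alt_rev <- 0L
    normals$source_class <- "normal_skin"
    res <- filter_cascade(all_tab, filt_config, normals = normals)
    passed <- res$passed
    write_variant_table(passed, file.path(out_dir, "passed_variants.tsv"))
    utils::write.table(res$verdicts, file.path(out_dir, "verdict_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$passed <- nrow(passed)
    outputs$verdicts <- res$verdicts
  }

  if ("mab" %in% stages && !is.null(passed)) {
    mt <- mab_table(passed, filt_config)
    utils::write.table(mt$table, file.path(out_dir, "mab_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$mab_estimates <- nrow(mt$table)
    outputs$mab <- mt$table
  }

  gmat <- NULL
  if ("colonies" %in% stages) {
    ctab <- simulate_colonies(profiles[[1L]], tree, n_colonies, sim_config)
    gmat <- build_genotype_matrix(ctab, tree_mutations(tree), filt_config)
    code <- matrix(c(mutant = "M", wildtype = "W",
                     nocall = "N")[unclass(gmat)],
                   nrow(gmat), ncol(gmat), dimnames = dimnames(gmat))
    utils::write.table(code, file.path(out_dir, "genotype_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    counts$colonies <- nrow(gmat)
    outputs$genotypes <- gmat
  }

  if ("tree" %in% stages && !is.null(gmat)) {
    compat <- check_tree_compatibility(gmat)
    if (compat$compatible) {
      inferred <- infer_clone_tree(gmat)
      jsonlite::write_json(
        list(clone_ids = inferred$clone_ids,
             parent = inferred$parent,
             edge_mutations = inferred$edge_mutations,
             colony_counts = inferred$colony_counts),
        file.path(out_dir, "clone_tree.json"), auto_unbox = FALSE,
        digits = NA)
      counts$tree_nodes <- length(inferred$clone_ids)
      outputs$tree_inferred <- inferred
    } else {
      counts$tree_nodes <- 0L
      outputs$tree_incompatible_pair <- compat$violating_pair
    }
  }

  if ("dynamics" %in% stages && !is.null(outputs$mab) &&
      length(compartments) >= 2L) {
    tab <- outputs$mab
    p1 <- tab[tab$sample_id == compartments[1L],
              c("mutation_id", "mab"), drop = FALSE]
    p2 <- tab[tab$sample_id == compartments[2L],
              c("mutation_id", "mab"), drop = FALSE]
    traj <- clone_trajectory_table(p1, p2, filt_config)
    utils::write.table(traj, file.path(out_dir, "trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$trajectories <- nrow(traj)
    outputs$trajectories <- traj
  }

  if ("loh" %in% stages) {
    snps <- simulate_loh_profile(n_snps = 150, depth = 80,
                                 del_start = 60, del_end = 100,
                                 clone_fraction = 0.9,
                                 seed = sim_config$seed)
    informative <- select_informative_snps(snps)
    prof <- allele_fraction_profile(informative, "7")
    segs <- detect_loh_segments(prof, chrom = "7")
    utils::write.table(as.data.frame(segs),
                       file.path(out_dir, "loh_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$loh_segments <- nrow(segs)
    outputs$loh <- segs
  }

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    tool = "clonarch",
    version = as.character(utils::packageVersion("clonarch")),
    seed = sim_config$seed,
    config = list(simulation = unclass(sim_config),
                  filter = unclass(filt_config)),
    stages_run = stages,
    stages_skipped = skipped,
    record_counts = counts,
    file_digests = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs$manifest <- manifest
  outputs$out_dir <- out_dir
  invisible(outputs)
}
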