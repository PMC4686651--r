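#' Simulation configuration
#'
#' Bundles every tunable of the clone-mixture simulator. Defaults reflect the
#' study conditions the analysis was designed for: heterozygous point
#' mutations on a clone tree, amplicon coverage of 800 reads, and
#' whole-genome-amplification (WGA) artifacts at rates typical of single-cell
#' WGA material.
#'
#' @param n_mutations Number of somatic mutations placed on the clone tree.
#' @param branching_prob Probability, per mutation, that it starts a new
#'   branch from a randomly chosen existing clone rather than extending the
#'   most recent clone. 0 yields a linear chain.
#' @param drift Per-compartment drift magnitude on the log scale applied to
#'   clone fractions; 0 gives identical fractions in every compartment.
#' @param coverage Target reads per amplicon (default 800, the study's
#'   reference coverage).
#' @param seq_error Per-base symmetric sequencing error rate.
#' @param wga_artifact_rate Probability per locus record that a spurious
#'   WGA-derived variant record is injected.
#' @param wga_dropout_prob Probability per heterozygous record that WGA
#'   allele dropout zeroes one allele.
#' @param artifact_homopolymer_frac Fraction of injected artifact records
#'   given a homopolymer flanking context of length >= 5.
#' @param artifact_bias_frac Fraction of injected artifact records carrying
#'   positional/read-length bias flags.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output at every stage.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_mutations = 8,
                              branching_prob = 0.4,
                              drift = 0.05,
                              coverage = 800,
                              seq_error = 0.001,
                              wga_artifact_rate = 0.02,
                              wga_dropout_prob = 0.05,
                              artifact_homopolymer_frac = 0.5,
                              artifact_bias_frac = 0.3,
                              seed = 1L) {
  cfg <- list(
    n_mutations = as.integer(n_mutations),
    branching_prob = branching_prob,
    drift = drift,
    coverage = as.integer(coverage),
    seq_error = seq_error,
    wga_artifact_rate = wga_artifact_rate,
    wga_dropout_prob = wga_dropout_prob,
    artifact_homopolymer_frac = artifact_homopolymer_frac,
    artifact_bias_frac = artifact_bias_frac,
    seed = as.integer(seed)
  )
  probs <- c("branching_prob", "seq_error", "wga_artifact_rate",
             "wga_dropout_prob", "artifact_homopolymer_frac",
             "artifact_bias_frac")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("simulation_config: '", p, "' must be a probability in [0, 1]",
           call. = FALSE)
  }
  if (cfg$n_mutations < 0L)
    stop("simulation_config: 'n_mutations' must be >= 0", call. = FALSE)
  if (cfg$coverage < 1L)
    stop("simulation_config: 'coverage' must be >= 1", call. = FALSE)
  if (cfg$drift < 0)
    stop("simulation_config: 'drift' must be >= 0", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Filter configuration
#'
#' Houses every numeric threshold of the somatic-variant filter cascade.
#' Defaults are the published operating points: somatic Fisher p < 0.01,
#' >= 3 supporting reads, normal contamination < 20 percent (skin) or
#' < 50 percent (T cells), tumour allele burden > 5 percent, mean alignment
#' score >= 10, mean base quality >= 15, fold strand bias <= 10, population
#' allele frequency <= 0.001, flanking homopolymer runs of >= 5 bases,
#' detection in >= 2 of 3 animals for WGA-heavy xenograft series, colony
#' mutant call at > 30 percent of reads, and a 1 percent MAB detection floor
#' at the 800x reference coverage. \code{min_colony_depth} is this package's
#' own guard (a low-depth colony entry must not be called wild type).
#'
#' @param somatic_p_max Maximum somatic Fisher p-value (strict <).
#' @param min_supporting_reads Minimum tumour alt reads (non-strict >=).
#' @param normal_max_fraction_skin Maximum normal alt fraction, skin-paired.
#' @param normal_max_fraction_tcell Maximum normal alt fraction, T-cell-paired.
#' @param tumour_min_burden Minimum tumour alt fraction (strict >).
#' @param min_alignment_score Minimum mean alignment score.
#' @param min_base_quality Minimum mean base quality.
#' @param max_fold_strand_bias Maximum fold strand bias (strict >10 fails).
#' @param pop_af_max Maximum population allele frequency for known variants.
#' @param homopolymer_min_run Minimum flanking homopolymer run that fails.
#' @param mds3_min_animals Minimum animals with detection for WGA-heavy series.
#' @param colony_mutant_threshold Colony mutant-call read fraction (strict >).
#' @param min_colony_depth Minimum colony depth below which entries are nocall.
#' @param detection_floor MAB detection floor at the reference coverage.
#' @param reference_coverage Reference amplicon coverage for the floor.
#' @param ci_level Confidence level for binomial intervals.
#' @param same_tolerance Absolute MAB tolerance for the "same" trajectory
#'   category.
#' @return An object of class \code{filter_config}.
#' @export
filter_config <- function(somatic_p_max = 0.01,
                          min_supporting_reads = 3L,
                          normal_max_fraction_skin = 0.20,
                          normal_max_fraction_tcell = 0.50,
                          tumour_min_burden = 0.05,
                          min_alignment_score = 10,
                          min_base_quality = 15,
                          max_fold_strand_bias = 10,
                          pop_af_max = 0.001,
                          homopolymer_min_run = 5L,
                          mds3_min_animals = 2L,
                          colony_mutant_threshold = 0.30,
                          min_colony_depth = 20L,
                          detection_floor = 0.01,
                          reference_coverage = 800L,
                          ci_level = 0.95,
                          same_tolerance = 0.05) {
  cfg <- list(
    somatic_p_max = somatic_p_max,
    min_supporting_reads = as.integer(min_supporting_reads),
    normal_max_fraction_skin = normal_max_fraction_skin,
    normal_max_fraction_tcell = normal_max_fraction_tcell,
    tumour_min_burden = tumour_min_burden,
    min_alignment_score = min_alignment_score,
    min_base_quality = min_base_quality,
    max_fold_strand_bias = max_fold_strand_bias,
    pop_af_max = pop_af_max,
    homopolymer_min_run = as.integer(homopolymer_min_run),
    mds3_min_animals = as.integer(mds3_min_animals),
    colony_mutant_threshold = colony_mutant_threshold,
    min_colony_depth = as.integer(min_colony_depth),
    detection_floor = detection_floor,
    reference_coverage = as.integer(reference_coverage),
    ci_level = ci_level,
    same_tolerance = same_tolerance
  )
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("filter_config: '", nm, "' must be a finite scalar", call. = FALSE)
    if (v < 0)
      stop("filter_config: '", nm, "' must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "filter_config")
}

#' Write a filter configuration to YAML or JSON
#'
#' @param config A \code{filter_config} or \code{simulation_config}.
#' @param path Output path; format chosen by extension (.yaml/.yml or .json).
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, c("filter_config", "simulation_config")))
  x <- unclass(config)
  x$.class <- class(config)[1L]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a filter or simulation configuration written by \code{write_config}
#'
#' Round-trips losslessly: all numeric fields are restored at full precision.
#'
#' @param path Path to a YAML or JSON config file.
#' @return The restored configuration object.
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cls <- x$.class
  x$.class <- NULL
  if (is.null(cls)) cls <- "filter_config"
  do.call(cls, x)
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Somatic-variant filter configuration\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Clone-mixture simulation configuration\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Stage-scoped seed derivation: all randomness flows from config$seed, with a
# distinct deterministic stream per pipeline stage so partial pipelines
# reproduce. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
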