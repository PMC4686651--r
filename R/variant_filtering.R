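#' Two-sided Fisher's exact somatic test
#'
#' Exact two-sided p-value for the 2x2 table of tumour alt/ref versus normal
#' alt/ref reads, computed by direct enumeration of the hypergeometric
#' outcome distribution (the sum of all outcome probabilities not exceeding
#' the observed one). Symmetric under swapping the tumour and normal rows
#' and under relabelling alt/ref.
#'
#' @param tumor_alt,tumor_ref,normal_alt,normal_ref Non-negative read counts.
#' @return p-value in [0, 1]. An all-zero table returns 1 with a warning.
#' @export
fisher_somatic_test <- function(tumor_alt, tumor_ref, normal_alt, normal_ref) {
  counts <- c(tumor_alt, tumor_ref, normal_alt, normal_ref)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("fisher_somatic_test: counts must be non-negative and finite",
         call. = FALSE)
  if (sum(counts) == 0) {
    warning("fisher_somatic_test: all-zero table, returning p = 1")
    return(1.0)
  }
  m <- tumor_alt + normal_alt          # total alt
  n <- tumor_ref + normal_ref          # total ref
  k <- tumor_alt + tumor_ref           # tumour margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tumor_alt, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1.0, p)
}

# verdict constructor: pass iff no rules fired
filter_verdict <- function(record_id, rules, stage = NA_character_) {
  structure(list(record_id = record_id,
                 pass = length(rules) == 0L,
                 rules = rules,
                 stage = if (length(rules)) stage else NA_character_),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat("Record", x$record_id, if (x$pass) "PASS" else
    paste0("FAIL [", x$stage, "]: ", paste(x$rules, collapse = ", ")), "\n")
  invisible(x)
}

#' Read-level quality filters
#'
#' Fails a record when the mean alignment score is below 10, the mean base
#' quality below 15, or the fold strand bias above 10. Fold strand bias is
#' defined as max(fwd, rev) / max(1, min(fwd, rev)) over the per-strand alt
#' read counts.
#'
#' @param record One-row variant table record (see
#'   \code{\link{variant_table_columns}}).
#' @param config A \code{\link{filter_config}}.
#' @return A \code{filter_verdict}.
#' @export
apply_read_filters <- function(record, config = filter_config()) {
  rules <- character(0)
  if (record$mean_alignment_score < config$min_alignment_score)
    rules <- c(rules, "alignment_score")
  if (record$mean_base_quality < config$min_base_quality)
    rules <- c(rules, "base_quality")
  if (fold_strand_bias(record$alt_fwd, record$alt_rev) >
      config$max_fold_strand_bias)
    rules <- c(rules, "strand_bias")
  filter_verdict(record$row_uid, rules, "read_filters")
}

#' Fold strand bias
#'
#' max(fwd, rev) / max(1, min(fwd, rev)); 0 when no alt reads.
#'
#' @param fwd,rev Per-strand alt read counts.
#' @return Numeric fold bias.
#' @export
fold_strand_bias <- function(fwd, rev) {
  pmax(fwd, rev) / pmax(1, pmin(fwd, rev))
}

#' Somatic filters against a paired normal
#'
#' Passes a record iff all of: somatic Fisher p < 0.01; tumour alt reads
#' >= 3; normal alt fraction < 20 percent (skin-paired) or < 50 percent
#' (T-cell-paired); tumour alt fraction > 5 percent; not a population
#' polymorphism (known with allele frequency > 0.001); not in a genomic
#' duplicated region unless flagged as a known mutation.
#'
#' @param record One-row tumour variant record.
#' @param normal_record One-row record for the same locus in the paired
#'   normal tissue.
#' @param config A \code{\link{filter_config}}.
#' @param normal_source "skin" or "tcell"; selects the contamination
#'   threshold.
#' @return A \code{filter_verdict}.
#' @export
pass_somatic_filters <- function(record, normal_record,
                                 config = filter_config(),
                                 normal_source = c("skin", "tcell")) {
  normal_source <- match.arg(normal_source)
  if (is.null(normal_record) ||
      (is.data.frame(normal_record) && nrow(normal_record) == 0L))
    stop("pass_somatic_filters: paired normal record required", call. = FALSE)
  rules <- character(0)
  p <- fisher_somatic_test(record$alt_reads,
                           record$total_reads - record$alt_reads,
                           normal_record$alt_reads,
                           normal_record$total_reads - normal_record$alt_reads)
  if (!(p < config$somatic_p_max)) rules <- c(rules, "somatic_p")
  if (record$alt_reads < config$min_supporting_reads)
    rules <- c(rules, "min_supporting_reads")
  normal_frac <- if (normal_record$total_reads > 0)
    normal_record$alt_reads / normal_record$total_reads else 0
  nmax <- if (normal_source == "skin") config$normal_max_fraction_skin
          else config$normal_max_fraction_tcell
  if (!(normal_frac < nmax)) rules <- c(rules, "normal_contamination")
  tumour_frac <- if (record$total_reads > 0)
    record$alt_reads / record$total_reads else 0
  if (!(tumour_frac > config$tumour_min_burden))
    rules <- c(rules, "tumour_min_burden")
  if (isTRUE(record$pop_known) && record$pop_af > config$pop_af_max)
    rules <- c(rules, "population_af")
  if (isTRUE(record$dup_region) && !isTRUE(record$known_mutation))
    rules <- c(rules, "duplicated_region")
  filter_verdict(record$row_uid, rules, "somatic_filters")
}

# longest run of one repeated base at the given end of a flank string
# end = "right": run touching the variant from the left flank
# end = "left":  run touching the variant from the right flank
adjacent_run_length <- function(flank, end = c("right", "left")) {
  end <- match.arg(end)
  if (is.na(flank) || !nzchar(flank)) return(0L)
  chars <- strsplit(flank, "")[[1]]
  if (end == "right") chars <- rev(chars)
  run <- 1L
  for (i in seq_along(chars)[-1L]) {
    if (chars[i] == chars[1L]) {
      if (i == run + 1L) run <- i else break
    } else break
  }
  run
}

#' WGA artifact filters
#'
#' For whole-genome-amplified material, fails a record when a single-base
#' run of 5 or more flanks the variant position on either side, when the
#' variant appears in the control-WGA variant set, or when positional or
#' read-length distribution bias flags are set (the bias metrics are
#' precomputed input flags).
#'
#' @param record One-row WGA variant record; flanking sequence required.
#' @param config A \code{\link{filter_config}}.
#' @param control_wga_variant_set Character vector of mutation identifiers
#'   seen in control WGA experiments.
#' @return A \code{filter_verdict}.
#' @export
wga_artifact_filters <- function(record, config = filter_config(),
                                 control_wga_variant_set = character(0)) {
  if (is.na(record$flank_left) || is.na(record$flank_right) ||
      !nzchar(record$flank_left) || !nzchar(record$flank_right))
    stop("wga_artifact_filters: flanking sequence required for WGA records",
         call. = FALSE)
  rules <- character(0)
  run <- max(adjacent_run_length(record$flank_left, "right"),
             adjacent_run_length(record$flank_right, "left"))
  if (run >= config$homopolymer_min_run) rules <- c(rules, "homopolymer")
  if (record$mutation_id %in% control_wga_variant_set)
    rules <- c(rules, "control_wga")
  if (isTRUE(record$pos_bias)) rules <- c(rules, "positional_bias")
  if (isTRUE(record$len_bias)) rules <- c(rules, "read_length_bias")
  filter_verdict(record$row_uid, rules, "wga_filters")
}

#' Xenograft (HEC) concordance rules
#'
#' A candidate mutation in human engrafted cells (HEC) passes iff it is
#' detected in more than one HEC sample, or concurrently in an HEC
#' experiment and an LTC-derived or primary CD34+ sample. Where WGA-derived
#' HEC data are involved, it also passes when found concurrently in
#' (1) WGA HEC and an independent non-WGA HEC experiment, (2) repeat WGA
#' samples from the same engraftment experiment, or (3) WGA HEC and a
#' non-WGA LTC, CD34+ or HEC sample. For WGA-heavy series across three
#' animals (\code{mds3_like = TRUE}), detection in at least
#' \code{config$mds3_min_animals} animals is additionally required.
#'
#' @param mutation Mutation identifier (used only for messages).
#' @param evidence \code{data.frame} with columns \code{experiment},
#'   \code{replicate}, \code{wga} (logical), \code{source} (one of "HEC",
#'   "LTC", "CD34"), \code{detected} (logical).
#' @param config A \code{\link{filter_config}}.
#' @param mds3_like Apply the >= 2-of-3-animals requirement.
#' @return Logical pass/fail with attribute \code{"rule"} naming the first
#'   satisfied rule (or "none").
#' @export
hec_concordance_pass <- function(mutation, evidence,
                                 config = filter_config(),
                                 mds3_like = FALSE) {
  stopifnot(is.data.frame(evidence), nrow(evidence) > 0L)
  det <- evidence[evidence$detected, , drop = FALSE]
  hec <- det[det$source == "HEC", , drop = FALSE]
  support <- det[det$source %in% c("LTC", "CD34"), , drop = FALSE]
  rule <- "none"
  pass <- FALSE
  if (nrow(hec) > 1L) {
    pass <- TRUE; rule <- "multiple_hec"
  } else if (nrow(hec) >= 1L && nrow(support) >= 1L) {
    pass <- TRUE; rule <- "hec_plus_ltc_or_cd34"
  }
  if (!pass && any(evidence$wga)) {
    wga_hec <- hec[hec$wga, , drop = FALSE]
    nonwga_hec <- hec[!hec$wga, , drop = FALSE]
    if (nrow(wga_hec) >= 1L && nrow(nonwga_hec) >= 1L &&
        length(union(wga_hec$experiment, nonwga_hec$experiment)) > 1L) {
      pass <- TRUE; rule <- "wga_plus_independent_nonwga_hec"
    } else if (any(table(wga_hec$experiment) >= 2L)) {
      pass <- TRUE; rule <- "repeat_wga_same_experiment"
    } else if (nrow(wga_hec) >= 1L &&
               any(!det$wga & det$source %in% c("LTC", "CD34", "HEC"))) {
      pass <- TRUE; rule <- "wga_plus_nonwga_support"
    }
  }
  if (mds3_like) {
    n_animals <- length(unique(hec$experiment))
    if (n_animals < config$mds3_min_animals) {
      pass <- FALSE; rule <- "mds3_min_animals"
    }
  }
  structure(pass, rule = rule)
}

#' Somatic-variant filter cascade
#'
#' Applies, in order: read-level filters, somatic filters against the paired
#' normal, WGA artifact filters for WGA-derived records, and the HEC
#' concordance rule for xenograft-derived records. One verdict is emitted
#' per record; the passed set is exactly the records with no fired rules.
#' Per-record errors (e.g. a missing paired normal) are recorded in the log
#' without aborting the batch.
#'
#' @param records Variant table (\code{data.frame}).
#' @param config A \code{\link{filter_config}}.
#' @param normals Variant table of paired-normal records matched to tumour
#'   records by \code{mutation_id}.
#' @param normal_source "skin" or "tcell".
#' @param control_wga_variant_set Mutation ids seen in control WGA runs.
#' @param hec_evidence Optional evidence \code{data.frame} (see
#'   \code{\link{hec_concordance_pass}}) with an extra \code{mutation_id}
#'   column, required to judge records with \code{source_class == "HEC"}.
#' @param mds3_like Apply the multi-animal requirement in the HEC stage.
#' @return List with \code{passed} (subset of \code{records}) and
#'   \code{verdicts} (one row per record: \code{row_uid}, \code{pass},
#'   \code{rules}, \code{stage}).
#' @export
filter_cascade <- function(records, config = filter_config(),
                           normals = NULL,
                           normal_source = c("skin", "tcell"),
                           control_wga_variant_set = character(0),
                           hec_evidence = NULL,
                           mds3_like = FALSE) {
  normal_source <- match.arg(normal_source)
  n <- nrow(records)
  if (is.null(n) || n == 0L) {
    return(list(passed = records,
                verdicts = data.frame(row_uid = character(0),
                                      pass = logical(0),
                                      rules = character(0),
                                      stage = character(0),
                                      stringsAsFactors = FALSE)))
  }
  verdicts <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    v <- apply_read_filters(rec, config)
    if (v$pass) {
      nr <- if (!is.null(normals))
        normals[normals$mutation_id == rec$mutation_id, , drop = FALSE]
      else NULL
      v2 <- tryCatch(
        pass_somatic_filters(rec, nr, config, normal_source),
        error = function(e) filter_verdict(rec$row_uid, "missing_normal",
                                           "somatic_filters"))
      v <- v2
    }
    if (v$pass && isTRUE(rec$wga)) {
      v <- tryCatch(
        wga_artifact_filters(rec, config, control_wga_variant_set),
        error = function(e) filter_verdict(rec$row_uid, "missing_flank",
                                           "wga_filters"))
    }
    if (v$pass && rec$source_class == "HEC" && !is.null(hec_evidence)) {
      ev <- hec_evidence[hec_evidence$mutation_id == rec$mutation_id,
                         , drop = FALSE]
      ok <- if (nrow(ev) > 0L)
        hec_concordance_pass(rec$mutation_id, ev, config, mds3_like)
      else FALSE
      if (!isTRUE(as.logical(ok)))
        v <- filter_verdict(rec$row_uid, "hec_concordance", "hec_concordance")
    }
    verdicts[[i]] <- data.frame(
      row_uid = rec$row_uid,
      pass = v$pass,
      rules = paste(v$rules, collapse = ","),
      stage = if (v$pass) NA_character_ else v$stage,
      stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, verdicts)
  rownames(log) <- NULL
  list(passed = records[log$pass, , drop = FALSE], verdicts = log)
}
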