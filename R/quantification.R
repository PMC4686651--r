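#' Mutant allele burden from read counts
#'
#' MAB is the proportion of sequencing reads at a locus carrying the mutant
#' allele. The confidence interval is a Wilson score interval, which behaves
#' well at small counts and near the detection floor.
#'
#' @param alt,total Alt and total read counts, \code{0 <= alt <= total},
#'   \code{total > 0}.
#' @param mutation_id,sample_id Optional identifiers carried on the result.
#' @param config A \code{\link{filter_config}} (supplies the CI level,
#'   detection floor and minimum supporting reads).
#' @return An object of class \code{mab_estimate} with fields \code{mab},
#'   \code{ci} (length 2), \code{alt}, \code{total}, \code{n_replicates},
#'   \code{detected}.
#' @export
mab_from_counts <- function(alt, total, mutation_id = NA_character_,
                            sample_id = NA_character_,
                            config = filter_config()) {
  if (total <= 0)
    stop("mab_from_counts: MAB undefined for total = 0", call. = FALSE)
  if (alt < 0 || alt > total)
    stop("mab_from_counts: need 0 <= alt <= total", call. = FALSE)
  mab <- alt / total
  ci <- wilson_interval(alt, total, config$ci_level)
  floor <- detection_limit(total, config$min_supporting_reads,
                           config$detection_floor)
  structure(list(mutation_id = mutation_id,
                 sample_id = sample_id,
                 mab = mab, ci = ci,
                 alt = alt, total = total,
                 n_replicates = 1L,
                 detected = mab >= floor && alt >= config$min_supporting_reads),
            class = "mab_estimate")
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes.
#' @param n Trials.
#' @param level Confidence level.
#' @return Numeric length-2 vector (lower, upper).
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' @export
print.mab_estimate <- function(x, ...) {
  cat(sprintf("MAB %s%s: %.3f [%.3f, %.3f] (%d/%d reads, %d replicate%s%s)\n",
              ifelse(is.na(x$mutation_id), "", paste0(x$mutation_id, " ")),
              ifelse(is.na(x$sample_id), "", paste0("in ", x$sample_id)),
              x$mab, x$ci[1], x$ci[2], round(x$alt), round(x$total),
              x$n_replicates, if (x$n_replicates > 1L) "s" else "",
              if (x$detected) "" else ", below detection floor"))
  invisible(x)
}

#' Pool replicate MAB estimates
#'
#' The pooled MAB is the unweighted mean of the replicate MABs, matching the
#' convention of averaging independent validation experiments rather than
#' pooling reads. With three or more replicates the CI comes from the
#' replicate spread (t interval); otherwise from the Wilson interval on the
#' pooled counts. Set \code{weight_by_reads = TRUE} for read-weighted
#' pooling instead.
#'
#' @param replicates List of \code{mab_estimate} objects for the same
#'   mutation.
#' @param config A \code{\link{filter_config}}.
#' @param weight_by_reads Pool reads instead of averaging replicate MABs.
#' @return A pooled \code{mab_estimate} with \code{n_replicates} recorded.
#' @export
pool_mab <- function(replicates, config = filter_config(),
                     weight_by_reads = FALSE) {
  stopifnot(length(replicates) >= 1L)
  stopifnot(all(vapply(replicates, inherits, TRUE, "mab_estimate")))
  ids <- unique(vapply(replicates, `[[`, "", "mutation_id"))
  if (length(ids[!is.na(ids)]) > 1L)
    stop("pool_mab: replicates mix mutation identifiers: ",
         paste(ids, collapse = ", "), call. = FALSE)
  mabs <- vapply(replicates, `[[`, 0, "mab")
  alt <- sum(vapply(replicates, `[[`, 0, "alt"))
  total <- sum(vapply(replicates, `[[`, 0, "total"))
  k <- length(mabs)
  mab <- if (weight_by_reads) alt / total else mean(mabs)
  ci <- if (k >= 3L && !weight_by_reads && stats::sd(mabs) > 0) {
    half <- stats::qt(1 - (1 - config$ci_level) / 2, df = k - 1L) *
      stats::sd(mabs) / sqrt(k)
    c(max(0, mab - half), min(1, mab + half))
  } else {
    wilson_interval(alt, total, config$ci_level)
  }
  floor <- detection_limit(total / k, config$min_supporting_reads,
                           config$detection_floor)
  structure(list(mutation_id = ids[1L],
                 sample_id = replicates[[1L]]$sample_id,
                 mab = mab, ci = ci,
                 alt = alt, total = total,
                 n_replicates = k,
                 detected = mab >= floor),
            class = "mab_estimate")
}

#' Convert MAB to cellular prevalence
#'
#' For a heterozygous mutation, the fraction of cells carrying the mutation
#' is twice the mutant allele burden (a MAB of 50 percent means 100 percent
#' of cells carry the mutation), capped at 1 with an over-unity flag when
#' 2*MAB exceeds 1 (possible LOH or copy-number change). Hemizygous or
#' homozygous mutations map one-to-one.
#'
#' @param mab Mutant allele burden in [0, 1].
#' @param zygosity "heterozygous" (default), "hemizygous" or "homozygous".
#' @return Cellular prevalence in [0, 1], with attribute \code{over_unity}.
#' @export
cellular_prevalence <- function(mab, zygosity = c("heterozygous",
                                                  "hemizygous",
                                                  "homozygous")) {
  zygosity <- match.arg(zygosity)
  stopifnot(all(mab >= 0 & mab <= 1))
  if (zygosity == "heterozygous") {
    over <- 2 * mab > 1
    structure(pmin(2 * mab, 1), over_unity = over)
  } else {
    structure(mab, over_unity = rep(FALSE, length(mab)))
  }
}

#' MAB detection floor at a given coverage
#'
#' The smallest MAB reliably distinguishable from noise: the larger of the
#' configured floor (1 percent, calibrated at the 800x reference coverage)
#' and the read-count floor \code{min_alt_reads / coverage}. Monotone
#' non-increasing in coverage.
#'
#' @param coverage Read depth (>= 1).
#' @param min_alt_reads Minimum alt reads for a call (default 3).
#' @param floor Configured MAB floor (default 0.01).
#' @return MAB floor in [0, 1].
#' @export
detection_limit <- function(coverage, min_alt_reads = 3, floor = 0.01) {
  if (any(coverage < 1))
    stop("detection_limit: coverage must be >= 1", call. = FALSE)
  pmax(floor, min_alt_reads / coverage)
}

#' Compare MABs across compartments
#'
#' Pairwise two-tailed two-sample t-tests between compartments; a mutation's
#' burden is reported as "maintained" between two compartments when
#' p > 0.05. Pairs where both groups have fewer than two replicates get a
#' descriptive difference and no p-value.
#'
#' @param groups Named list: compartment label -> numeric vector of
#'   replicate MABs.
#' @param alpha Significance level for the maintained call.
#' @return \code{data.frame} with one row per compartment pair: the two
#'   labels, mean difference, t statistic, p-value and \code{maintained}.
#' @export
compare_compartments <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  labs <- names(groups)
  pairs <- utils::combn(labs, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    x <- groups[[pr[1L]]]; y <- groups[[pr[2L]]]
    diff <- mean(x) - mean(y)
    if (length(x) >= 2L && length(y) >= 2L &&
        (stats::sd(x) > 0 || stats::sd(y) > 0)) {
      tt <- stats::t.test(x, y, alternative = "two.sided")
      data.frame(compartment1 = pr[1L], compartment2 = pr[2L],
                 mean_diff = diff, statistic = unname(tt$statistic),
                 p_value = tt$p.value, maintained = tt$p.value > alpha,
                 stringsAsFactors = FALSE)
    } else {
      maintained <- if (length(x) >= 2L && length(y) >= 2L && diff == 0)
        TRUE else NA
      data.frame(compartment1 = pr[1L], compartment2 = pr[2L],
                 mean_diff = diff, statistic = NA_real_,
                 p_value = if (isTRUE(maintained)) 1.0 else NA_real_,
                 maintained = maintained,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MAB table from a variant table
#'
#' Computes one \code{mab_estimate} per record of a (filtered) variant
#' table and returns both the estimates and a flat table.
#'
#' @param records Variant table.
#' @param config A \code{\link{filter_config}}.
#' @return List with \code{estimates} (list of \code{mab_estimate}) and
#'   \code{table} (\code{data.frame}: mutation_id, sample_id, replicate_id,
#'   mab, ci_lo, ci_hi, alt, total, detected).
#' @export
mab_table <- function(records, config = filter_config()) {
  ests <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    mab_from_counts(r$alt_reads, r$total_reads, r$mutation_id, r$sample_id,
                    config)
  })
  tab <- do.call(rbind, lapply(seq_along(ests), function(i) {
    e <- ests[[i]]
    data.frame(mutation_id = e$mutation_id, sample_id = e$sample_id,
               replicate_id = records$replicate_id[i],
               mab = e$mab, ci_lo = e$ci[1L], ci_hi = e$ci[2L],
               alt = e$alt, total = e$total, detected = e$detected,
               stringsAsFactors = FALSE)
  }))
  list(estimates = ests, table = tab)
}
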