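#' Classify a MAB change between paired samples
#'
#' Five exhaustive, mutually exclusive trajectory categories for a mutation
#' observed in a primary sample and a follow-up (xenograft or later time
#' point): \code{not_detected} when the follow-up MAB is below the
#' detection floor; \code{same} when the absolute change is within
#' \code{same_tolerance} (a 43 to 46 percent shift counts as unchanged);
#' otherwise \code{increased_ge2fold} / \code{decreased_ge2fold} when the
#' fold change (follow-up over primary, primary clamped at the floor)
#' reaches 2 in either direction, and \code{changed_lt2fold} otherwise.
#'
#' @param primary_mab,followup_mab MABs in [0, 1].
#' @param config A \code{\link{filter_config}} (supplies
#'   \code{detection_floor} and \code{same_tolerance}).
#' @return One of "same", "changed_lt2fold", "decreased_ge2fold",
#'   "increased_ge2fold", "not_detected".
#' @export
classify_mab_change <- function(primary_mab, followup_mab,
                                config = filter_config()) {
  stopifnot(primary_mab >= 0, primary_mab <= 1,
            followup_mab >= 0, followup_mab <= 1)
  if (followup_mab < config$detection_floor) return("not_detected")
  if (abs(followup_mab - primary_mab) <= config$same_tolerance)
    return("same")
  fold <- followup_mab / max(primary_mab, config$detection_floor)
  if (fold >= 2) return("increased_ge2fold")
  if (fold <= 0.5) return("decreased_ge2fold")
  "changed_lt2fold"
}

#' Test a MAB shift between two samples from read counts
#'
#' Two-sided Fisher's exact test on the 2x2 alt/ref table of the two
#' samples (an exact two-proportion test at amplicon depth). When replicate
#' MAB vectors are available use
#' \code{\link{test_mab_shift_replicates}} instead.
#'
#' @param alt1,total1 Counts in the first sample.
#' @param alt2,total2 Counts in the second sample.
#' @return p-value in [0, 1].
#' @export
test_mab_shift <- function(alt1, total1, alt2, total2) {
  if (total1 <= 0 || total2 <= 0)
    stop("test_mab_shift: totals must be positive", call. = FALSE)
  fisher_somatic_test(alt1, total1 - alt1, alt2, total2 - alt2)
}

#' Test a MAB shift between replicate MAB vectors
#'
#' Two-tailed two-sample t-test on replicate MABs.
#'
#' @param mabs1,mabs2 Numeric vectors of replicate MABs (length >= 2 each).
#' @return p-value in [0, 1].
#' @export
test_mab_shift_replicates <- function(mabs1, mabs2) {
  stopifnot(length(mabs1) >= 2L, length(mabs2) >= 2L)
  if (stats::sd(mabs1) == 0 && stats::sd(mabs2) == 0)
    return(if (mean(mabs1) == mean(mabs2)) 1.0 else 0.0)
  stats::t.test(mabs1, mabs2, alternative = "two.sided")$p.value
}

#' Per-mutation trajectory table for a sample pair
#'
#' Applies \code{\link{classify_mab_change}} to every mutation of a shared
#' panel. Mutations missing from the follow-up table are classified
#' \code{not_detected} with an audit note.
#'
#' @param primary \code{data.frame} with columns \code{mutation_id},
#'   \code{mab}.
#' @param followup \code{data.frame} with the same columns.
#' @param config A \code{\link{filter_config}}.
#' @return \code{data.frame}: \code{mutation_id}, \code{primary_mab},
#'   \code{followup_mab}, \code{category}, \code{note}.
#' @export
clone_trajectory_table <- function(primary, followup,
                                   config = filter_config()) {
  stopifnot(all(c("mutation_id", "mab") %in% names(primary)),
            all(c("mutation_id", "mab") %in% names(followup)))
  if (nrow(primary) == 0L)
    return(data.frame(mutation_id = character(0), primary_mab = numeric(0),
                      followup_mab = numeric(0), category = character(0),
                      note = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(primary)), function(i) {
    mut <- primary$mutation_id[i]
    p <- primary$mab[i]
    j <- match(mut, followup$mutation_id)
    if (is.na(j)) {
      data.frame(mutation_id = mut, primary_mab = p, followup_mab = NA_real_,
                 category = "not_detected",
                 note = "missing from follow-up table",
                 stringsAsFactors = FALSE)
    } else {
      f <- followup$mab[j]
      data.frame(mutation_id = mut, primary_mab = p, followup_mab = f,
                 category = classify_mab_change(p, f, config),
                 note = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# signed direction of a trajectory category: +1 growth, -1 shrink/loss,
# 0 stable or sub-2-fold change
category_direction <- function(category) {
  unname(c(same = 0, changed_lt2fold = 0, increased_ge2fold = 1,
           decreased_ge2fold = -1, not_detected = -1)[category])
}

#' Recapitulation score between two trajectory classifications
#'
#' How closely one comparison (e.g. primary vs xenograft) mirrors another
#' (e.g. time point 1 vs time point 2): the fraction of shared-panel
#' mutations with identical trajectory category, plus a direction-only
#' concordance (up / down-or-lost / stable). Symmetric in its arguments.
#'
#' @param categories1,categories2 Named character vectors of trajectory
#'   categories keyed by mutation identifier.
#' @return List with \code{concordance}, \code{direction_concordance},
#'   and \code{per_mutation} (\code{data.frame}).
#' @export
recapitulation_score <- function(categories1, categories2) {
  shared <- intersect(names(categories1), names(categories2))
  if (length(shared) == 0L)
    stop("recapitulation_score: no shared mutations", call. = FALSE)
  c1 <- categories1[shared]; c2 <- categories2[shared]
  agree <- c1 == c2
  dir_agree <- category_direction(c1) == category_direction(c2)
  list(concordance = mean(agree),
       direction_concordance = mean(dir_agree),
       per_mutation = data.frame(mutation_id = shared,
                                 category1 = unname(c1),
                                 category2 = unname(c2),
                                 agree = unname(agree),
                                 direction_agree = unname(dir_agree),
                                 stringsAsFactors = FALSE))
}

#' Infer the acquisition order of lesions from sequential samples
#'
#' A lesion precedes another when it is detected at an earlier time point.
#' Lesions first detected at the same time point are ordered by cellular
#' prevalence where their confidence intervals separate, and tied
#' otherwise (similar burdens leave the ancestry undecidable).
#'
#' @param table \code{data.frame} with columns \code{lesion}, \code{time}
#'   (sortable time-point values), \code{mab}, and optionally \code{alt},
#'   \code{total} for CI-based tie-breaking.
#' @param config A \code{\link{filter_config}} (detection floor, CI level).
#' @return \code{data.frame} ordered by inferred acquisition: \code{lesion},
#'   \code{first_detected} (time value), \code{rank} (ties share a rank).
#' @export
infer_acquisition_order <- function(table, config = filter_config()) {
  stopifnot(all(c("lesion", "time", "mab") %in% names(table)))
  det <- table[table$mab >= config$detection_floor, , drop = FALSE]
  lesions <- unique(table$lesion)
  first <- vapply(lesions, function(l) {
    tt <- det$time[det$lesion == l]
    if (length(tt) == 0L) NA_real_ else min(as.numeric(tt))
  }, 0)
  detected <- lesions[!is.na(first)]
  first <- first[!is.na(first)]
  mab_at_first <- vapply(seq_along(detected), function(i) {
    d <- table[table$lesion == detected[i] &
                 as.numeric(table$time) == first[i], , drop = FALSE]
    if (nrow(d) == 0L) 0 else max(d$mab)
  }, 0)
  ord <- order(first, -mab_at_first)
  detected <- detected[ord]; first <- first[ord]
  rank <- integer(length(detected))
  r <- 0L
  for (i in seq_along(detected)) {
    if (i == 1L) { r <- 1L; rank[i] <- r; next }
    if (first[i] > first[i - 1L]) {
      r <- r + 1L
    } else {
      # same first-detection time: separate only when prevalence CIs separate
      sep <- ci_separated(table, detected[i - 1L], detected[i],
                          first[i], config)
      if (isTRUE(sep)) r <- r + 1L
    }
    rank[i] <- r
  }
  data.frame(lesion = detected, first_detected = first, rank = rank,
             stringsAsFactors = FALSE)
}

ci_separated <- function(table, lesion_a, lesion_b, time, config) {
  row <- function(l) {
    d <- table[table$lesion == l & as.numeric(table$time) == time, ,
               drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    d[1L, ]
  }
  a <- row(lesion_a); b <- row(lesion_b)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (!all(c("alt", "total") %in% names(table)) ||
      is.na(a$alt) || is.na(b$alt)) return(FALSE)
  ci_a <- wilson_interval(a$alt, a$total, config$ci_level)
  ci_b <- wilson_interval(b$alt, b$total, config$ci_level)
  ci_a[1L] > ci_b[2L] || ci_b[1L] > ci_a[2L]
}
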