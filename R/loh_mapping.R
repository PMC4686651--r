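#' Select informative SNPs for LOH mapping
#'
#' Keeps germline polymorphisms usable for allele-balance analysis: records
#' that are population-known, not somatic, outside known genomic duplicated
#' regions, with read depth of at least \code{min_depth} (default 20), and
#' heterozygous in the paired normal (normal alt fraction within
#' [0.25, 0.75]) when a normal fraction is supplied. Output is sorted by
#' position within chromosome.
#'
#' @param records SNP record \code{data.frame} (see
#'   \code{\link{snp_table_columns}}).
#' @param min_depth Minimum read depth.
#' @return Filtered, position-sorted \code{data.frame}.
#' @export
select_informative_snps <- function(records, min_depth = 20) {
  stopifnot(is.data.frame(records))
  keep <- records$pop_known &
    !records$somatic &
    !records$dup_region &
    records$depth >= min_depth
  if ("normal_frac" %in% names(records)) {
    nf <- records$normal_frac
    keep <- keep & (is.na(nf) | (nf >= 0.25 & nf <= 0.75))
  }
  out <- records[keep, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Allele-fraction profile along one chromosome
#'
#' A pure projection of informative SNPs onto a position-ordered
#' (position, fraction) series; no smoothing.
#'
#' @param records Informative SNP records.
#' @param chromosome Chromosome label.
#' @return \code{data.frame} with columns \code{pos}, \code{frac}, sorted
#'   by position. Empty input yields an empty series with a warning.
#' @export
allele_fraction_profile <- function(records, chromosome) {
  sub <- records[records$chrom == chromosome, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("allele_fraction_profile: no informative SNPs on chromosome ",
            chromosome)
    return(data.frame(pos = integer(0), frac = numeric(0)))
  }
  sub <- sub[order(sub$pos), , drop = FALSE]
  data.frame(pos = sub$pos, frac = sub$alt_frac)
}

#' Detect LOH segments by sliding-window allele-balance shift
#'
#' Slides a window of \code{window} consecutive SNPs along the profile; a
#' window is LOH-shifted when its mean absolute deviation of the allele
#' fraction from 0.5 exceeds \code{delta}. Maximal runs of at least
#' \code{min_consecutive} shifted windows merge into segments. The fraction
#' of cells affected by a heterozygous deletion is estimated from the
#' segment's mean deviation d by inverting the allele-balance model:
#' f = 2d / (0.5 + d).
#'
#' @param profile (position, fraction) series from
#'   \code{\link{allele_fraction_profile}}.
#' @param window Window size in SNPs (default 25).
#' @param delta Mean-deviation threshold (default 0.15).
#' @param min_consecutive Minimum run of shifted windows (default 1).
#' @param chrom Chromosome label written into the segments.
#' @return \code{data.frame} of class \code{loh_segments}: \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive), \code{n_snps},
#'   \code{mean_deviation}, \code{affected_fraction}. Sorted by start,
#'   non-overlapping.
#' @export
detect_loh_segments <- function(profile, window = 25L, delta = 0.15,
                                min_consecutive = 1L, chrom = NA_character_) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 1L)
  n <- nrow(profile)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      mean_deviation = numeric(0),
                      affected_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("loh_segments", "data.frame")
  if (window > n) {
    warning("detect_loh_segments: window (", window,
            ") exceeds profile length (", n, "); no segments")
    return(empty)
  }
  dev <- abs(profile$frac - 0.5)
  # mean deviation over each window of `window` consecutive SNPs
  cs <- cumsum(c(0, dev))
  nwin <- n - window + 1L
  win_mean <- (cs[(window + 1L):(n + 1L)] - cs[1L:nwin]) / window
  shifted <- win_mean > delta
  r <- rle(shifted)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_consecutive) next
    first_win <- starts[k]
    last_win <- ends[k]
    snp_lo <- first_win
    snp_hi <- last_win + window - 1L
    # windows overlapping a deletion edge drag in balanced flanking SNPs;
    # trim the segment to SNPs whose own deviation clears the threshold
    while (snp_lo < snp_hi && dev[snp_lo] <= delta) snp_lo <- snp_lo + 1L
    while (snp_hi > snp_lo && dev[snp_hi] <= delta) snp_hi <- snp_hi - 1L
    d <- mean(dev[snp_lo:snp_hi])
    segs[[length(segs) + 1L]] <- data.frame(
      chrom = chrom,
      start = profile$pos[snp_lo],
      end = profile$pos[snp_hi],
      n_snps = snp_hi - snp_lo + 1L,
      mean_deviation = d,
      affected_fraction = min(1, 2 * d / (0.5 + d)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(segs)) do.call(rbind, segs) else empty
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("loh_segments", "data.frame")
  out
}

#' @export
print.loh_segments <- function(x, ...) {
  cat("LOH segments:", nrow(x), "segment(s)\n")
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Export LOH segments as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. Uses \pkg{rtracklayer} when available, otherwise writes the
#' three-column BED text directly.
#'
#' @param segments An \code{loh_segments} \code{data.frame}.
#' @param path Output BED path.
#' @return \code{path}, invisibly.
#' @export
loh_segments_to_bed <- function(segments, path) {
  stopifnot(is.data.frame(segments))
  if (requireNamespace("GenomicRanges", quietly = TRUE) &&
      requireNamespace("rtracklayer", quietly = TRUE) &&
      nrow(segments) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = segments$chrom,
      ranges = IRanges::IRanges(start = segments$start,
                                end = segments$end))
    rtracklayer::export(gr, path, format = "BED")
  } else {
    bed <- data.frame(chrom = segments$chrom,
                      start = segments$start - 1L,
                      end = segments$end)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
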