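# Shared fixtures: all synthetic, built in code.

# one well-formed tumour record with free overrides
make_record <- function(...) {
  rec <- data.frame(
    row_uid = "r1", sample_id = "S1", source_class = "primary_CD34",
    replicate_id = "R1", experiment_id = "E1",
    mutation_id = "SF3B1_K700E", gene = "SF3B1",
    chrom = "2", pos = 198267484L, ref = "A", alt = "G",
    alt_reads = 368L, total_reads = 800L, alt_fwd = 184L, alt_rev = 184L,
    mean_alignment_score = 60, mean_base_quality = 35,
    flank_left = "ACGTCA", flank_right = "TGCAGT",
    wga = FALSE, pop_known = FALSE, pop_af = 0,
    dup_region = FALSE, known_mutation = FALSE,
    pos_bias = FALSE, len_bias = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_normal <- function(record, alt = 0L) {
  n <- record
  n$row_uid <- paste0(record$row_uid, "_normal")
  n$source_class <- "normal_skin"
  n$alt_reads <- alt
  n$alt_fwd <- as.integer(floor(alt / 2))
  n$alt_rev <- alt - n$alt_fwd
  n
}

# colony table from explicit genotype list: counts at depth with p = 0.5
# for carried mutations and 0 otherwise (deterministic, noise-free)
make_colony_table <- function(genotypes, panel, depth = 200L) {
  do.call(rbind, lapply(names(genotypes), function(cid) {
    carried <- genotypes[[cid]]
    data.frame(colony_id = cid, mutation_id = panel,
               alt = ifelse(panel %in% carried, as.integer(depth / 2), 0L),
               total = depth, stringsAsFactors = FALSE)
  }))
}

# brute-force three-gamete oracle: scans every column pair for the
# {10, 01, 11} patterns, independent of the package implementation
brute_force_compatible <- function(bin) {
  m <- ncol(bin)
  if (m < 2L) return(TRUE)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    p10 <- p01 <- p11 <- FALSE
    for (r in seq_len(nrow(bin))) {
      if (bin[r, i] && !bin[r, j]) p10 <- TRUE
      if (!bin[r, i] && bin[r, j]) p01 <- TRUE
      if (bin[r, i] && bin[r, j]) p11 <- TRUE
    }
    if (p10 && p01 && p11) return(FALSE)
  }
  TRUE
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher
# test, written directly from the definition (no dhyper)
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, 0)
  p_obs <- prob[match(a, support)]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}
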