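test_that("Fisher somatic test matches enumeration oracle and fisher.test", {
  # identical rows carry no somatic signal
  expect_equal(fisher_somatic_test(0, 100, 0, 100), 1.0)
  expect_equal(fisher_somatic_test(5, 95, 5, 95), 1.0)
  # clear somatic signal at exome-scale counts
  expect_lt(fisher_somatic_test(10, 90, 0, 100), 0.01)
  expect_equal(fisher_somatic_test(10, 90, 0, 100),
               fisher_oracle(10, 90, 0, 100), tolerance = 1e-10)

  # dual route on random tables: own enumeration vs stats::fisher.test
  set.seed(1)
  for (i in 1:200) {
    t <- rpois(4, 8)
    p_own <- fisher_somatic_test(t[1], t[2], t[3], t[4])
    if (sum(t) == 0) next
    p_ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(p_own, p_ref, tolerance = 1e-9)
    # symmetry under swapping rows and relabelling alt/ref
    expect_equal(p_own, fisher_somatic_test(t[3], t[4], t[1], t[2]),
                 tolerance = 1e-12)
    expect_equal(p_own, fisher_somatic_test(t[2], t[1], t[4], t[3]),
                 tolerance = 1e-12)
  }

  expect_warning(p0 <- fisher_somatic_test(0, 0, 0, 0), "all-zero")
  expect_equal(p0, 1.0)
  expect_error(fisher_somatic_test(-1, 5, 5, 5), "non-negative")
})

test_that("read-level filters fire on quality, alignment and strand bias", {
  cfg <- filter_config()
  v <- apply_read_filters(make_record(mean_base_quality = 14), cfg)
  expect_false(v$pass)
  expect_true("base_quality" %in% v$rules)

  v <- apply_read_filters(make_record(alt_reads = 21L, alt_fwd = 20L,
                                      alt_rev = 1L), cfg)
  expect_false(v$pass)
  expect_true("strand_bias" %in% v$rules)
  expect_equal(fold_strand_bias(20, 1), 20)

  v <- apply_read_filters(make_record(mean_alignment_score = 9), cfg)
  expect_true("alignment_score" %in% v$rules)

  v <- apply_read_filters(make_record(alt_reads = 10L, alt_fwd = 5L,
                                      alt_rev = 5L), cfg)
  expect_true(v$pass)
  expect_length(v$rules, 0L)
})

test_that("somatic filters enforce every published threshold", {
  cfg <- filter_config()
  rec <- make_record()
  nrm <- make_normal(rec)

  expect_true(pass_somatic_filters(rec, nrm, cfg)$pass)

  v <- pass_somatic_filters(make_record(alt_reads = 2L, alt_fwd = 1L,
                                        alt_rev = 1L), nrm, cfg)
  expect_true("min_supporting_reads" %in% v$rules)

  v <- pass_somatic_filters(make_record(alt_reads = 32L, alt_fwd = 16L,
                                        alt_rev = 16L), nrm, cfg)  # 4%
  expect_true("tumour_min_burden" %in% v$rules)

  v <- pass_somatic_filters(rec, make_normal(rec, alt = 200L), cfg)  # 25%
  expect_true("normal_contamination" %in% v$rules)
  # a 25% normal is tolerable for T-cell-paired normals (<50%)
  v <- pass_somatic_filters(rec, make_normal(rec, alt = 200L), cfg,
                            normal_source = "tcell")
  expect_false("normal_contamination" %in% v$rules)

  v <- pass_somatic_filters(make_record(pop_known = TRUE, pop_af = 0.01),
                            nrm, cfg)
  expect_true("population_af" %in% v$rules)
  # known population variant at rare frequency is kept
  v <- pass_somatic_filters(make_record(pop_known = TRUE, pop_af = 0.0005),
                            nrm, cfg)
  expect_true(v$pass)

  v <- pass_somatic_filters(make_record(dup_region = TRUE), nrm, cfg)
  expect_true("duplicated_region" %in% v$rules)
  v <- pass_somatic_filters(make_record(dup_region = TRUE,
                                        known_mutation = TRUE), nrm, cfg)
  expect_false("duplicated_region" %in% v$rules)

  # weak somatic evidence: high normal-free signal needed for p < 0.01
  v <- pass_somatic_filters(make_record(alt_reads = 3L, total_reads = 40L,
                                        alt_fwd = 2L, alt_rev = 1L),
                            make_normal(make_record(total_reads = 40L)), cfg)
  expect_true("somatic_p" %in% v$rules)

  expect_error(pass_somatic_filters(rec, NULL, cfg), "normal")
})

test_that("WGA artifact filters catch homopolymers, control hits and bias", {
  cfg <- filter_config()
  # run of five As touching the variant from the left
  v <- wga_artifact_filters(make_record(wga = TRUE, flank_left = "TAAAAA"),
                            cfg)
  expect_true("homopolymer" %in% v$rules)
  # run of four: below threshold
  v <- wga_artifact_filters(make_record(wga = TRUE, flank_left = "TAAAA",
                                        flank_right = "GTGTGT"), cfg)
  expect_false("homopolymer" %in% v$rules)
  # run must touch the variant: interrupted run does not count
  v <- wga_artifact_filters(make_record(wga = TRUE, flank_left = "AAAAAT"),
                            cfg)
  expect_false("homopolymer" %in% v$rules)
  # right flank read from the variant outwards
  v <- wga_artifact_filters(make_record(wga = TRUE, flank_right = "GGGGGA"),
                            cfg)
  expect_true("homopolymer" %in% v$rules)

  v <- wga_artifact_filters(make_record(wga = TRUE), cfg,
                            control_wga_variant_set = "SF3B1_K700E")
  expect_true("control_wga" %in% v$rules)

  v <- wga_artifact_filters(make_record(wga = TRUE, pos_bias = TRUE), cfg)
  expect_true("positional_bias" %in% v$rules)

  expect_error(
    wga_artifact_filters(make_record(wga = TRUE, flank_left = NA_character_),
                         cfg),
    "flank")
})

test_that("HEC concordance implements the disjunctive pass rules", {
  cfg <- filter_config()
  ev <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(experiment = r[[1]], replicate = r[[2]],
                 wga = r[[3]], source = r[[4]], detected = r[[5]],
                 stringsAsFactors = FALSE)))
  }
  # WGA HEC in mouse A plus non-WGA HEC in mouse B
  e <- ev(list("mouseA", "r1", TRUE, "HEC", TRUE),
          list("mouseB", "r1", FALSE, "HEC", TRUE))
  expect_true(as.logical(hec_concordance_pass("m", e, cfg)))

  # single WGA HEC detection, nowhere else
  e <- ev(list("mouseA", "r1", TRUE, "HEC", TRUE),
          list("mouseB", "r1", TRUE, "HEC", FALSE))
  expect_false(as.logical(hec_concordance_pass("m", e, cfg)))

  # one HEC experiment plus LTC support
  e <- ev(list("mouseA", "r1", FALSE, "HEC", TRUE),
          list("pt", "r1", FALSE, "LTC", TRUE))
  expect_true(as.logical(hec_concordance_pass("m", e, cfg)))

  # repeat WGA replicates from the same engraftment experiment
  e <- ev(list("mouseA", "r1", TRUE, "HEC", TRUE),
          list("mouseA", "r2", TRUE, "HEC", TRUE))
  r <- hec_concordance_pass("m", e, cfg)
  expect_true(as.logical(r))

  # WGA HEC plus non-WGA CD34 support
  e <- ev(list("mouseA", "r1", TRUE, "HEC", TRUE),
          list("pt", "r1", FALSE, "CD34", TRUE))
  expect_true(as.logical(hec_concordance_pass("m", e, cfg)))

  # MDS3-like series: one of three animals is not enough
  e <- ev(list("mouseA", "r1", TRUE, "HEC", TRUE),
          list("mouseA", "r2", TRUE, "HEC", TRUE),
          list("mouseB", "r1", TRUE, "HEC", FALSE),
          list("mouseC", "r1", TRUE, "HEC", FALSE))
  expect_false(as.logical(hec_concordance_pass("m", e, cfg,
                                               mds3_like = TRUE)))
  # two of three animals passes
  e$detected[3] <- TRUE
  expect_true(as.logical(hec_concordance_pass("m", e, cfg,
                                              mds3_like = TRUE)))
})

test_that("filter cascade passes true clones and is monotone and order-free", {
  cfg <- filter_config()
  scfg <- simulation_config(n_mutations = 10, branching_prob = 0,
                            seq_error = 0.001, wga_artifact_rate = 0.5,
                            wga_dropout_prob = 0, seed = 21)
  tr <- simulate_clone_tree(scfg)
  # chain tree: early mutations reach high prevalence, late ones tail off
  prof <- compartment_profile("CD34", stats::setNames(
    rep(0.095, 10), tr$clone_ids[-1]))
  bulk <- simulate_bulk_counts(prof, tr, scfg)
  wga <- inject_wga_artifacts(bulk, scfg)
  truth <- attr(wga, "truth")
  normals <- wga[!duplicated(wga$mutation_id), , drop = FALSE]
  normals$alt_reads <- 0L; normals$alt_fwd <- 0L; normals$alt_rev <- 0L

  res <- filter_cascade(wga, cfg, normals = normals)
  # every true somatic variant with prevalence >= 12% passes
  true_ids <- truth$row_uid[!truth$is_artifact & truth$clone_prevalence >= 0.12]
  expect_true(all(res$verdicts$pass[res$verdicts$row_uid %in% true_ids]))
  # artifact pass rate is measured and bounded
  art_ids <- truth$row_uid[truth$is_artifact]
  art_pass <- mean(res$verdicts$pass[res$verdicts$row_uid %in% art_ids])
  expect_lt(art_pass, 1)

  # empty input
  empty <- filter_cascade(wga[0, ], cfg, normals = normals)
  expect_equal(nrow(empty$verdicts), 0L)

  # monotonicity: stricter burden threshold shrinks the passed set
  stricter <- filter_config(tumour_min_burden = 0.20)
  res2 <- filter_cascade(wga, stricter, normals = normals)
  expect_true(all(res2$passed$row_uid %in% res$passed$row_uid))

  # order independence: permuting the batch permutes verdicts only
  set.seed(7)
  perm <- sample(nrow(wga))
  res3 <- filter_cascade(wga[perm, ], cfg, normals = normals)
  v1 <- res$verdicts[order(res$verdicts$row_uid), ]
  v3 <- res3$verdicts[order(res3$verdicts$row_uid), ]
  rownames(v1) <- rownames(v3) <- NULL
  expect_equal(v1, v3)

  # self-consistency audit: no passed record violates any single rule
  for (uid in res$passed$row_uid) {
    rec <- res$passed[res$passed$row_uid == uid, ]
    expect_gte(rec$alt_reads, cfg$min_supporting_reads)
    expect_gt(rec$alt_reads / rec$total_reads, cfg$tumour_min_burden)
    expect_lte(fold_strand_bias(rec$alt_fwd, rec$alt_rev),
               cfg$max_fold_strand_bias)
  }
})
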