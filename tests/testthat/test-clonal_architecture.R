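test_that("subclone enumeration counts distinct mutant signatures", {
  genos <- list(c01 = "S", c02 = "S", c03 = c("S", "J"), c04 = c("S", "D"))
  gm <- build_genotype_matrix(make_colony_table(genos, c("S", "J", "D")),
                              c("S", "J", "D"))
  cat1 <- enumerate_subclones(gm)
  expect_equal(nrow(cat1), 3L)
  expect_setequal(cat1$count, c(2L, 1L, 1L))
  expect_equal(attr(cat1, "wildtype_count"), 0L)

  # all wild type: no subclones
  genos_wt <- list(c01 = character(0), c02 = character(0))
  gm_wt <- build_genotype_matrix(make_colony_table(genos_wt, "S"), "S")
  expect_equal(nrow(enumerate_subclones(gm_wt)), 0L)
  expect_equal(attr(enumerate_subclones(gm_wt), "wildtype_count"), 2L)

  # six-clone tree, every clone sampled, error 0: exactly six subclones
  cfg <- simulation_config(n_mutations = 6, branching_prob = 0.5,
                           seq_error = 0, seed = 13)
  tr <- simulate_clone_tree(cfg)
  prof <- compartment_profile("CD34", stats::setNames(
    rep(1 / 7, 6), tr$clone_ids[-1]))
  col <- simulate_colonies(prof, tr, 400, cfg)
  gm6 <- build_genotype_matrix(col, tree_mutations(tr))
  founders <- attr(col, "truth")$founder
  if (length(setdiff(tr$clone_ids[-1], founders)) == 0L)
    expect_equal(nrow(enumerate_subclones(gm6)), 6L)

  # nocall handling: excluded colonies leave the catalog
  tab <- make_colony_table(genos, c("S", "J", "D"))
  tab$alt[tab$colony_id == "c03"] <- 2L
  tab$total[tab$colony_id == "c03"] <- 5L
  gm_n <- build_genotype_matrix(tab, c("S", "J", "D"))
  expect_equal(attr(enumerate_subclones(gm_n), "n_evaluable"), 3L)
})

test_that("three-gamete compatibility test agrees with a brute-force oracle", {
  genos <- list(c1 = "S", c2 = c("S", "J"), c3 = c("S", "D"))
  gm <- build_genotype_matrix(make_colony_table(genos, c("S", "J", "D")),
                              c("S", "J", "D"))
  expect_true(check_tree_compatibility(gm)$compatible)

  bad <- rbind(A = c(1, 0), B = c(0, 1), AB = c(1, 1))
  colnames(bad) <- c("A", "B")
  r <- check_tree_compatibility(bad)
  expect_false(r$compatible)
  expect_equal(r$violating_pair, c("A", "B"))

  # random matrices up to 12 colonies x 6 mutations vs the oracle
  set.seed(5)
  for (i in 1:300) {
    nr <- sample(2:12, 1); nc <- sample(2:6, 1)
    bin <- matrix(stats::runif(nr * nc) < 0.4, nr, nc,
                  dimnames = list(NULL, paste0("g", seq_len(nc))))
    expect_equal(check_tree_compatibility(bin)$compatible,
                 brute_force_compatible(bin))
  }

  # simulator colonies at error 0 are always compatible
  for (s in 1:20) {
    cfg <- simulation_config(n_mutations = 5, branching_prob = 0.6,
                             seq_error = 0, seed = s)
    tr <- simulate_clone_tree(cfg)
    prof <- assign_clone_fractions(tr, "CD34", cfg)[[1]]
    col <- simulate_colonies(prof, tr, 25, cfg)
    gm <- build_genotype_matrix(col, tree_mutations(tr))
    expect_true(check_tree_compatibility(gm)$compatible)
  }
})

test_that("clone tree inference orders signatures by containment", {
  # mutually exclusive branches under a shared founder
  genos <- list(c1 = "S", c2 = c("S", "J"), c3 = c("S", "D"))
  gm <- build_genotype_matrix(make_colony_table(genos, c("S", "J", "D")),
                              c("S", "J", "D"))
  tr <- infer_clone_tree(gm)
  expect_equal(length(tr$mutation_sets), 4L)  # root + 3 subclones
  s_idx <- which(vapply(tr$mutation_sets, function(x)
    identical(x, "S"), TRUE))
  expect_equal(tr$parent[s_idx], 1L)
  branch_parents <- tr$parent[vapply(tr$mutation_sets, length, 1L) == 2L]
  expect_equal(branch_parents, c(s_idx, s_idx))

  # chain
  genos <- list(c1 = "S", c2 = c("S", "D"), c3 = c("S", "D", "X"))
  gm <- build_genotype_matrix(make_colony_table(genos, c("S", "D", "X")),
                              c("S", "D", "X"))
  tr <- infer_clone_tree(gm)
  depths <- vapply(tr$mutation_sets, length, 1L)
  expect_equal(sort(depths), 0:3)
  expect_true(all(tabulate(tr$parent[-1], 4) <= 1))  # linear

  # unobserved intermediates are not invented: multi-mutation edge label
  genos <- list(c1 = character(0), c2 = c("S", "D"))
  gm <- build_genotype_matrix(make_colony_table(genos, c("S", "D")),
                              c("S", "D"))
  tr <- infer_clone_tree(gm)
  expect_equal(length(tr$mutation_sets), 2L)
  expect_setequal(tr$edge_mutations[[2]], c("S", "D"))

  # incompatible matrix raises with the violating pair
  genos <- list(c1 = "A", c2 = "B", c3 = c("A", "B"))
  gm <- build_genotype_matrix(make_colony_table(genos, c("A", "B")),
                              c("A", "B"))
  expect_error(infer_clone_tree(gm), "A, B")
})

test_that("round-trip: simulated tree -> colonies -> inferred tree is exact", {
  for (s in c(3, 17, 42)) {
    cfg <- simulation_config(n_mutations = 5, branching_prob = 0.5,
                             seq_error = 0, seed = s)
    tr <- simulate_clone_tree(cfg)
    prof <- compartment_profile("CD34", stats::setNames(
      rep(0.9 / 5, 5), tr$clone_ids[-1]))
    col <- simulate_colonies(prof, tr, 500, cfg)
    founders <- attr(col, "truth")$founder
    if (length(setdiff(tr$clone_ids[-1], founders)) > 0L) next
    gm <- build_genotype_matrix(col, tree_mutations(tr))
    inf <- infer_clone_tree(gm)
    # same clone set
    key <- function(t) sort(vapply(t$mutation_sets, paste, "",
                                   collapse = "+"))
    expect_equal(key(inf), key(tr))
    # same parent relation, matched by mutation-set signature
    sig <- function(t, i) paste(t$mutation_sets[[i]], collapse = "+")
    for (i in seq_along(inf$parent)[-1]) {
      j <- which(vapply(seq_along(tr$mutation_sets), function(k)
        sig(tr, k) == sig(inf, i), TRUE))
      expect_equal(sig(tr, tr$parent[j]), sig(inf, inf$parent[i]))
    }
    # node count equals subclone count; invariants hold by construction
    expect_equal(length(inf$mutation_sets) - 1L,
                 nrow(enumerate_subclones(gm)))
  }
})

test_that("founder mutations and mutual exclusivity are identified", {
  genos <- c(stats::setNames(replicate(20, "S", simplify = FALSE),
                             sprintf("c%02d", 1:20)),
             list(c21 = c("S", "J"), c22 = c("S", "J"),
                  c23 = c("S", "D"), c24 = c("S", "D"),
                  c25 = character(0)))
  gm <- build_genotype_matrix(make_colony_table(genos, c("S", "J", "D")),
                              c("S", "J", "D"))
  r <- identify_founder(gm)
  expect_equal(r$founder, "S")
  expect_equal(nrow(r$exclusive_pairs), 1L)
  expect_setequal(unlist(r$exclusive_pairs[1, ]), c("J", "D"))

  # founder labels the edge out of the root in the inferred tree
  tr <- infer_clone_tree(gm)
  root_children <- which(tr$parent == 1L)
  expect_true(all(vapply(root_children, function(i)
    all(r$founder %in% tr$mutation_sets[[i]]), TRUE)))

  # exclusivity needs >= 2 colonies per mutation: singletons stay silent
  genos <- list(c1 = c("S", "J"), c2 = c("S", "D"), c3 = "S")
  gm <- build_genotype_matrix(make_colony_table(genos, c("S", "J", "D")),
                              c("S", "J", "D"))
  expect_equal(nrow(identify_founder(gm)$exclusive_pairs), 0L)

  # no shared mutation: empty founder set
  genos <- list(c1 = "J", c2 = "D")
  gm <- build_genotype_matrix(make_colony_table(genos, c("J", "D")),
                              c("J", "D"))
  expect_length(identify_founder(gm)$founder, 0L)
})

test_that("bulk-MAB hierarchy orders mutations only beyond CI overlap", {
  # deep counts: 70% vs 60% prevalence separate cleanly
  dn <- mab_from_counts(1750, 5000, "DNMT3A")   # MAB 0.35
  sf <- mab_from_counts(1500, 5000, "SF3B1")    # MAB 0.30
  h <- mab_hierarchy(list(sf, dn))
  expect_equal(nrow(h$above), 1L)
  expect_equal(h$above$higher, "DNMT3A")
  expect_equal(h$above$lower, "SF3B1")

  # similar burdens with overlapping CIs stay unordered
  a <- mab_from_counts(368, 800, "SF3B1")
  b <- mab_from_counts(360, 800, "TET2")
  expect_equal(nrow(mab_hierarchy(list(a, b))$above), 0L)

  # singleton
  expect_equal(nrow(mab_hierarchy(list(a))$above), 0L)
})

test_that("origin compartment is the most primitive detected one", {
  det <- c(HSC = TRUE, MPP = TRUE, GMP = TRUE, MEP = TRUE)
  r <- assign_origin_compartment(det)
  expect_equal(r$origin, "HSC")
  expect_false(r$progenitor_origin)

  det <- c(HSC = FALSE, MPP = FALSE, MLP = TRUE, CMP = FALSE, GMP = TRUE)
  r <- assign_origin_compartment(det)
  expect_equal(r$origin, "MLP")
  expect_true(r$progenitor_origin)

  r <- assign_origin_compartment(c(HSC = FALSE, MPP = FALSE))
  expect_true(is.na(r$origin))
})

test_that("clone recovery probability matches the union-miss approximation", {
  cfg0 <- simulation_config(n_mutations = 3, branching_prob = 0,
                            seq_error = 0, seed = 1)
  tr <- simulate_clone_tree(cfg0)
  fr <- c(0.4, 0.25, 0.15)
  prof <- compartment_profile("CD34", stats::setNames(fr, tr$clone_ids[-1]))
  n_col <- 15L
  all_seen <- vapply(1:300, function(s) {
    cfg <- simulation_config(n_mutations = 3, branching_prob = 0,
                             seq_error = 0, seed = s)
    col <- simulate_colonies(prof, tr, n_col, cfg)
    length(setdiff(tr$clone_ids[-1], attr(col, "truth")$founder)) == 0L
  }, TRUE)
  approx <- 1 - sum((1 - fr)^n_col)   # first-order union bound
  expect_lt(abs(mean(all_seen) - approx), 0.05)
})
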