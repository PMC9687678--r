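test_that("simulated trees are ultrametric, reproducible and labelled", {
  sim <- simulate_tree(2L, seed = 1L)
  d <- ape::node.depth.edgelength(sim$tree)
  expect_equal(d[1], d[2], tolerance = 1e-9)    # cherry: equal leaf depths

  expect_identical(simulate_tree(10L, seed = 42L)$newick,
                   simulate_tree(10L, seed = 42L)$newick)

  big <- simulate_tree(50L, seed = 3L)
  depths <- ape::node.depth.edgelength(big$tree)[1:50]
  expect_lt(max(depths) - min(depths), 1e-9)    # ultrametry
  expect_equal(big$tree$tip.label, sprintf("s%03d", 1:50))

  expect_error(simulate_tree(1L, seed = 1L), ">= 2")
})

test_that("gain/loss occurrence simulation honours its degenerate limits", {
  sim <- simulate_tree(8L, seed = 5L)
  frozen <- simulate_occurrence(sim$tree, list(
    universe_size = 50, core_size = 10, gain_rate = 0, loss_rate = 0,
    root_presence_prob = 0.5), seed = 7L)
  # zero rates: every leaf equals the root state exactly
  expect_true(all(apply(frozen, 2, function(col) length(unique(col)) == 1L)))
  expect_true(all(frozen[, attr(frozen, "core_ids")] == 1L))

  allcore <- simulate_occurrence(sim$tree, list(
    universe_size = 30, core_size = 30, gain_rate = 0.1, loss_rate = 0.2,
    root_presence_prob = 0.5), seed = 7L)
  expect_true(all(allcore == 1L))

  expect_identical(
    simulate_occurrence(sim$tree, default_sim_config(), seed = 9L),
    simulate_occurrence(sim$tree, default_sim_config(), seed = 9L))
})

test_that("equal gain and loss rates drive presence to one half on long branches", {
  # star tree with branches long enough to reach stationarity
  star <- parse_newick("(A:100,B:100,C:100,D:100,E:100);")
  occ <- simulate_occurrence(star, list(
    universe_size = 2000, core_size = 0, gain_rate = 0.5, loss_rate = 0.5,
    root_presence_prob = 0), seed = 11L)
  expect_lt(abs(mean(occ) - 0.5), 0.03)
})

test_that("ortholog layer mirrors reactions and dilutes with independent families", {
  sim <- simulate_tree(12L, seed = 6L)
  occ <- simulate_occurrence(sim$tree, list(
    universe_size = 200, core_size = 50, gain_rate = 0.105, loss_rate = 0.195,
    root_presence_prob = 0.35), seed = 8L)

  bij <- simulate_orthologs(occ, families_per_reaction = 1L,
                            n_nonmetabolic = 0L, seed = 2L)
  expect_true(all(bij$occurrence == occ))   # bijection up to column names
  Sm <- similarity_matrix(occ, "model")
  Sg <- similarity_matrix(bij$occurrence, "genotype")
  expect_equal(unclass(Sg)[1:12, 1:12], unclass(Sm)[1:12, 1:12])

  mixed <- simulate_orthologs(occ, families_per_reaction = 1L,
                              n_nonmetabolic = 500L, tree = sim$tree,
                              seed = 2L)
  expect_equal(ncol(mixed$occurrence), 200L + 500L)
  expect_equal(sum(is.na(mixed$family_map$reaction_id)), 500L)
  Sg2 <- similarity_matrix(mixed$occurrence, "genotype")
  pv <- align_layers(list(model = Sm, genotype = Sg2))
  r <- pearson_cor(pv$model, pv$genotype)$r
  expect_gt(r, 0)          # coupling survives dilution ...
  expect_lt(r, 1)          # ... but is no longer perfect

  empty <- occ[, 0, drop = FALSE]
  expect_error(simulate_orthologs(empty, seed = 1L), "no reactions")
  expect_error(simulate_orthologs(occ, n_nonmetabolic = 10L, seed = 1L),
               "tree")
})

test_that("traits are pathway-AND functions corrupted by seeded noise", {
  sim <- simulate_tree(10L, seed = 4L)
  occ <- simulate_occurrence(sim$tree, list(
    universe_size = 60, core_size = 20, gain_rate = 0.105, loss_rate = 0.195,
    root_presence_prob = 0.35), seed = 5L)
  defs <- sample_trait_definitions(colnames(occ), n_substrates = 6L,
                                   set_size = 3L, seed = 9L)

  clean <- simulate_traits(occ, defs, flip_noise = 0, missing_prob = 0,
                           seed = 1L)
  for (s in names(defs)) {
    expected <- as.numeric(rowSums(occ[, defs[[s]], drop = FALSE]) ==
                             length(defs[[s]]))
    expect_equal(unname(clean[, s]), expected)
  }

  gone <- simulate_traits(occ, defs, flip_noise = 0, missing_prob = 1,
                          seed = 1L)
  expect_true(all(is.na(gone)))
  St <- trait_similarity(gone)
  expect_true(all(is.na(St[upper.tri(St)])))

  expect_error(simulate_traits(occ, list(sub1 = "MNX:R9999"), seed = 1L),
               "unknown required reaction")
  expect_identical(simulate_traits(occ, defs, 0.3, 0.05, seed = 2L),
                   simulate_traits(occ, defs, 0.3, 0.05, seed = 2L))
})

test_that("pure label noise destroys the trait-model correlation", {
  d <- simulate_panreactome_data(100L, seed = 31L)
  noisy <- simulate_traits(d$occurrence, d$trait_defs, flip_noise = 0.5,
                           missing_prob = 0, seed = 13L)
  Sm <- similarity_matrix(d$occurrence, "model")
  St <- trait_similarity(noisy)
  pv <- align_layers(list(model = Sm, trait = St))
  expect_lt(abs(pearson_cor(pv$model, pv$trait)$r), 0.1)
})

test_that("heaps-count generation is exact when noiseless and reproducible", {
  exact <- generate_heaps_counts(2000.039, 0.1173, c(1, 50, 332))
  expect_equal(exact$pan, 2000.039 * c(1, 50, 332)^0.1173)
  flat <- generate_heaps_counts(5, 0, 1:10)
  expect_true(all(flat$pan == 5))
  expect_identical(generate_heaps_counts(10, 0.3, 1:20, 0.1, seed = 3L),
                   generate_heaps_counts(10, 0.3, 1:20, 0.1, seed = 3L))
  expect_error(generate_heaps_counts(-1, 0.5, 1:10), "positive")
})

test_that("the bundled study generator is reproducible and self-consistent", {
  d1 <- simulate_panreactome_data(20L, seed = 17L)
  d2 <- simulate_panreactome_data(20L, seed = 17L)
  expect_identical(d1$occurrence, d2$occurrence)
  expect_identical(d1$newick, d2$newick)
  expect_identical(d1$traits, d2$traits)

  expect_equal(sort(names(d1$clades)), sort(rownames(d1$occurrence)))
  expect_equal(rownames(d1$orthologs), rownames(d1$occurrence))
  expect_equal(nrow(d1$traits), 20L)
  expect_true(all(unlist(d1$trait_defs) %in% colnames(d1$occurrence)))
})
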