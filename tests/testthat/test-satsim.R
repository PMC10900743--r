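test_that("duplication-divergence cycles build monomers with full records", {
  set.seed(61)
  u <- random_dna(20)
  expect_equal(evolve_duplication_divergence(u, 0, 0.1)$sequence, u)

  ## one cycle at zero divergence and no spacer: exact tandem dimer
  r <- evolve_duplication_divergence(u, 1, 0, seed = 5, spacer_prob = 0)
  expect_equal(r$sequence, strrep(u, 2))
  expect_equal(r$record[[1]]$boundary, 20)

  ## diverged cycle: detect_period finds the unit length back
  r2 <- evolve_duplication_divergence(u, 1, 0.15, seed = 6,
                                      spacer_prob = 0)
  cand <- detect_period(r2$sequence)
  expect_true(any(abs(head(cand, 3) - 20) <= 2))

  ## same seed reproduces, different seeds differ
  expect_equal(evolve_duplication_divergence(u, 2, 0.2, seed = 7)$sequence,
               evolve_duplication_divergence(u, 2, 0.2, seed = 7)$sequence)
  expect_false(identical(
    evolve_duplication_divergence(u, 2, 0.2, seed = 7)$sequence,
    evolve_duplication_divergence(u, 2, 0.2, seed = 8)$sequence))
  expect_error(evolve_duplication_divergence(random_dna(8), 1, 0.1),
               "at least 10")
})

test_that("library evolution is seeded, tree-driven and truth-complete", {
  cfg <- sim_config(seed = 101)
  sim <- simulate_library_evolution(cfg)
  expect_setequal(names(sim$catalogs), c("Cya", "Cla", "Mni", "Ptr", "Asi"))
  expect_equal(nrow(sim$truth), 5 * cfg$n_ancestral_families)
  ## ancestry map is total: every leaf family has an ancestral id
  expect_true(all(sim$truth$ancestral_id %in%
                    seq_len(cfg$n_ancestral_families)))
  ## catalogs hold the present families (>= 3 each), ordered by
  ## decreasing true abundance
  for (sp in names(sim$catalogs)) {
    pres <- sim$truth[sim$truth$species == sp & sim$truth$present, ]
    expect_gte(nrow(pres), 3)
    expect_equal(length(sim$catalogs[[sp]]), nrow(pres))
    expect_true(all(diff(pres$abundance) <= 0))
  }
  ## determinism
  sim2 <- simulate_library_evolution(cfg)
  expect_identical(sim$truth, sim2$truth)
  expect_false(identical(
    sim$truth$abundance,
    simulate_library_evolution(sim_config(seed = 102))$truth$abundance))
  expect_error(simulate_library_evolution(sim_config(tree = "not a tree",
                                                     seed = 1)),
               "newick")
})

test_that("a no-evolution single-species run returns the ancestral library", {
  cfg <- sim_config(tree = "(Xxx:1);", subst_rate = 0, indel_ratio = 0,
                    amplification_sdlog = 0, silencing_prob = 0,
                    seed = 103)
  sim <- simulate_library_evolution(cfg)
  expect_equal(length(sim$catalogs), 1)
  ## re-running with mutation switched on but rate 0 gives identical
  ## sequences, i.e. the catalog is the root library itself
  expect_equal(sort(unique(sim$truth$ancestral_id)),
               seq_len(cfg$n_ancestral_families))
})

test_that("the long outgroup branch shares fewest similarity groups", {
  cfg <- sim_config(seed = 104, subst_rate = 0.004)
  sim <- simulate_library_evolution(cfg)
  grp <- assign_groups(sim$catalogs)
  df <- as.data.frame(grp)
  shared <- function(sp) sum(!is.na(df$group[df$species == sp]))
  caiman <- vapply(c("Cya", "Cla", "Mni"), shared, numeric(1))
  expect_lte(shared("Asi"), min(caiman))
})

test_that("genomes carry exact composition bookkeeping and seeded reads", {
  cfg <- sim_config(seed = 105, genome_length = 150000, n_pairs = 500)
  sim <- simulate_library_evolution(cfg)
  sp <- "Cya"
  g <- build_genome_and_reads(sim$catalogs[[sp]],
                              sim$truth[sim$truth$species == sp, ], cfg)
  expect_equal(nchar(g$genome), 150000)
  expect_equal(sum(g$composition$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(g$composition$nt), 150000)
  expect_length(g$genes, 3)
  expect_equal(length(g$reads), 500)
  ## byte-identical rerun
  g2 <- build_genome_and_reads(sim$catalogs[[sp]],
                               sim$truth[sim$truth$species == sp, ], cfg)
  expect_identical(g$genome, g2$genome)
  expect_identical(as.character(g$reads$read1), as.character(g2$reads$read1))

  ## n_pairs = 0: valid genome, empty read set
  cfg0 <- sim_config(seed = 105, genome_length = 150000, n_pairs = 0)
  g0 <- build_genome_and_reads(sim$catalogs[[sp]],
                               sim$truth[sim$truth$species == sp, ], cfg0)
  expect_equal(length(g0$reads), 0)
  expect_equal(nchar(g0$genome), 150000)

  ## genome shorter than the insert span is a configuration error
  cfg_bad <- sim_config(seed = 1, genome_length = 300)
  expect_error(build_genome_and_reads(sim$catalogs[[sp]],
                                      sim$truth[sim$truth$species == sp, ],
                                      cfg_bad), "insert")
})

test_that("planted abundance is recovered by masking within binomial error", {
  ## one dominant family at 2% of a small genome, clustered arrays only
  cfg <- sim_config(seed = 106, tree = "(Xxx:1);", n_ancestral_families = 3,
                    subst_rate = 0, amplification_sdlog = 0,
                    clustered_fraction = 1,
                    array_copy_range = c(50, 100),
                    array_divergence_range = c(0.02, 0.05),
                    genome_length = 300000, n_pairs = 4000)
  sim <- simulate_library_evolution(cfg)
  truth <- sim$truth
  g <- build_genome_and_reads(sim$catalogs[[1]], truth, cfg)
  ab <- mask_reads(g$reads, sim$catalogs[[1]])
  top <- truth$name[which.max(truth$abundance)]
  true_frac <- g$composition$fraction[g$composition$component == top]
  est <- ab$abundance_fraction[ab$family == top]
  se <- sqrt(true_frac * (1 - true_frac) / (2 * cfg$n_pairs))
  expect_lt(abs(est - true_frac), 3 * se + 0.1 * true_frac)
})
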