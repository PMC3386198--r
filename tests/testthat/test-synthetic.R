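test_that("sequence evolution at zero duration returns the ancestor", {
  anc <- rand_seq(500, seed = 80)
  expect_identical(evolve_sequence(anc, 0, 2.2e-9, seed = 1), anc)
  expect_identical(evolve_sequence(anc, 1e7, 0, seed = 1), anc)
})

test_that("sequence evolution is deterministic under a fixed seed", {
  anc <- rand_seq(2000, seed = 81)
  a <- evolve_sequence(anc, 5e6, 2.2e-9, seed = 99)
  b <- evolve_sequence(anc, 5e6, 2.2e-9, seed = 99)
  expect_identical(a, b)
  c <- evolve_sequence(anc, 5e6, 2.2e-9, seed = 100)
  expect_false(identical(a, c))
})

test_that("gaps and N are carried through evolution unchanged", {
  anc <- "AC-GTN"
  out <- evolve_sequence(anc, 1e8, 1e-7, seed = 3)
  v <- strsplit(out, "")[[1]]
  expect_equal(v[3], "-")
  expect_equal(v[6], "N")
})

test_that("evolution rejects negative duration, rate, kappa", {
  expect_error(evolve_sequence("ACGT", -1, 1e-9), "non-negative")
  expect_error(evolve_sequence("ACGT", 1, -1e-9), "non-negative")
  expect_error(evolve_sequence("ACGT", 1, 1e-9, kappa = 0), "positive")
})

test_that("expected K2P divergence between copies equals 2rt", {
  # 50 seeded replicate pairs, 5 kb, 9.3 My at the mammalian neutral rate:
  # mean pairwise K2P distance within 3 SE of 2 * 2.2e-9 * 9.3e6
  n_rep <- 50
  d <- with_seed_test(90, vapply(seq_len(n_rep), function(i) {
    anc <- paleofoam:::random_dna(5000)
    a <- evolve_sequence(anc, 9.3e6, 2.2e-9)
    b <- evolve_sequence(anc, 9.3e6, 2.2e-9)
    k2p_distance(count_substitutions(a, b))$d
  }, numeric(1)))
  expected <- 2 * 2.2e-9 * 9.3e6
  se <- sd(d) / sqrt(n_rep)
  expect_lt(abs(mean(d) - expected), 3 * se)
})

test_that("codivergence simulation is symmetric for equal-duration sister tips", {
  host <- parse_newick("(h1:50,h2:50);")
  sim <- simulate_codivergence(host, viral_rate = 1e-9, rate_noise_sd = 0)
  expect_equal(sim$virus_tree$edge.length[1], sim$virus_tree$edge.length[2])
})

test_that("codivergence simulation emits congruent trees, tip sequences, and truth", {
  host <- host_tree_foamy()
  sim <- simulate_codivergence(host, viral_rate = 1e-9,
                               root_seq_length = 300, seed = 91)
  expect_true(is_congruent(
    map_congruent_branches(host, sim$virus_tree, sim$tip_map)))
  expect_length(sim$tip_seqs, 6L)
  expect_true(all(nchar(sim$tip_seqs) == 300))
  # determinism
  sim2 <- simulate_codivergence(host, viral_rate = 1e-9,
                                root_seq_length = 300, seed = 91)
  expect_identical(sim$tip_seqs, sim2$tip_seqs)
  expect_error(simulate_codivergence(ape::rtree(3, br = NULL), 1e-9), "dated")
})

test_that("R² degrades monotonically with per-branch rate noise", {
  host <- host_tree_foamy()
  mean_r2 <- vapply(c(0, 0.4, 1.2), function(sd) {
    r2 <- vapply(1:30, function(i) {
      sim <- simulate_codivergence(host, 1e-9, rate_noise_sd = sd,
                                   seed = 1000 * sd + i)
      pairs <- extract_branch_pairs(
        map_congruent_branches(host, sim$virus_tree, sim$tip_map),
        host, sim$virus_tree)
      suppressWarnings(codivergence_test(pairs)$r_squared)
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("endogenization simulation is deterministic and internally consistent", {
  cfg <- sim_config(genome_length = 1500, seed = 92)
  s1 <- simulate_endogenization(cfg)
  s2 <- simulate_endogenization(cfg)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$truth$indel_events, s2$truth$indel_events)
  # truth coords describe the emitted contigs
  for (i in seq_along(s1$contigs)) {
    co <- s1$truth$coords[i, ]
    expect_equal(nchar(s1$contigs[[i]]),
                 nchar(gsub("-", "", s1$alignment[[i]])))
    expect_lte(co$element_end, nchar(s1$contigs[[i]]))
  }
  # alignment rows degap to the contigs
  expect_identical(unname(gsub("-", "", s1$alignment)), unname(s1$contigs))
})

test_that("zero-rate duplication produces identical copies dating to zero", {
  cfg <- sim_config(genome_length = 900,
                    host_neutral_rate = list(mean = 0, sd = 0),
                    indel_rate = 0, seed = 93)
  sim <- simulate_endogenization(cfg)
  expect_equal(length(unique(unname(sim$contigs))), 1L)
  age <- date_duplication_set(sim$element_alignment, n_bootstrap = 50, seed = 1)
  expect_equal(age$t_years, 0)
})

test_that("pair duplicated 9.3 My ago diverges by about 4.1% in expectation", {
  d <- vapply(1:30, function(i) {
    cfg <- sim_config(genome_length = 4000, endogenization_time = 12,
                      duplication_times = 9.3, indel_rate = 0, seed = 9300 + i)
    sim <- simulate_endogenization(cfg)
    k2p_distance(count_substitutions(sim$element_alignment[[1]],
                                     sim$element_alignment[[2]]))$d
  }, numeric(1))
  expected <- 2 * 2.2e-9 * 9.3e6
  expect_lt(abs(mean(d) - expected), 3 * sd(d) / sqrt(length(d)))
})

test_that("simulated duplicate-set truth is recovered at default thresholds", {
  sim <- simulate_endogenization(sim_config(genome_length = 1200, seed = 94))
  part <- identify_duplicate_sets(sim$contigs, sim$truth$coords)
  expect_length(part$sets, 1L)
  expect_setequal(part$sets[[1]], sim$truth$duplicate_set)
})

test_that("truth gained-stop indices are genuine stops in the decayed copies", {
  sim <- simulate_endogenization(sim_config(genome_length = 1500,
                                            indel_rate = 0, seed = 95))
  for (id in names(sim$element_alignment)) {
    s <- sim$element_alignment[[id]]
    for (ci in sim$truth$gained_stops[[id]]) {
      expect_true(substr(s, 3 * ci + 1, 3 * ci + 3) %in% c("TAA", "TAG", "TGA"))
    }
    # the ancestral ORF itself had no internal stops
    rep0 <- annotate_defects(setNames(sim$truth$ancestral_element, "anc"),
                             0, nchar(sim$truth$ancestral_element))
    expect_length(rep0$stop_positions, 0L)
  }
})

test_that("fragmentation emits overlapping sub-contigs with truth coordinates", {
  sim <- simulate_endogenization(sim_config(genome_length = 1500,
                                            n_fragments = 3, seed = 96))
  expect_false(is.null(sim$fragments))
  fc <- sim$truth$fragment_coords
  expect_equal(nrow(fc), 3L * length(sim$contigs))
  for (k in seq_len(nrow(fc))) {
    expect_identical(unname(sim$fragments[fc$fragment_id[k]]),
                     substr(sim$contigs[[fc$contig_id[k]]],
                            fc$start[k] + 1, fc$end[k]))
    expect_gte(fc$end[k] - fc$start[k], 300L)
  }
})

test_that("simulation configs validate their invariants", {
  expect_error(sim_config(endogenization_time = 10,
                          duplication_times = c(15)), "precede")
  expect_error(sim_config(indel_rate = -1), "non-negative")
  expect_error(sim_config(genome_length = 10), "short")
})
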