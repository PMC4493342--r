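small_cfg <- function(...) {
  args <- list(n_species = 5, n_individuals = c(1, 3, 4, 2, 3),
               seq_length = 300, divergence = c(0.04, 0.12),
               intra_rate = 0.003, n_unique_sites = 3, n_shared_sites = 2,
               truncate_species = 0, ambiguity_rate = 0)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("identical (config, seed) gives bit-identical FASTA output", {
  cfg <- sim_config(n_species = 4, n_individuals = c(1, 2, 3, 4),
                    seq_length = 900)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_barcode_fasta(simulate_alignment(cfg, seed = 5)$alignment, f1)
  write_barcode_fasta(simulate_alignment(cfg, seed = 5)$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed differs
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_barcode_fasta(simulate_alignment(cfg, seed = 6)$alignment, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  expect_error(simulate_alignment(cfg), "seed is required")
})

test_that("zero intraspecific rate makes conspecific records identical", {
  sim <- simulate_alignment(small_cfg(intra_rate = 0), seed = 3)
  aln <- sim$alignment
  for (sp in unique(aln$species)) {
    rows <- aln$seq[aln$species == sp, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1L)))
  }
})

test_that("with zero background divergence the diagnosis is exactly the planted sites", {
  sim <- simulate_alignment(small_cfg(divergence = c(0, 0), intra_rate = 0,
                                      n_unique_sites = 5, n_shared_sites = 0),
                            seed = 13)
  aln <- sim$alignment
  prof <- site_state_profile(aln)
  tr <- sim$truth$planted_unique
  for (sp in sim$truth$species) {
    got <- find_unique_diagnostics(prof, sp)
    want <- tr[tr$species == sp, ]
    expect_equal(got$position, sort(want$position))
    expect_equal(got$state, want$state[order(want$position)])
  }
})

test_that("planted unique sites are recovered and no false diagnostics appear", {
  for (seed in 1:20) {
    sim <- simulate_alignment(small_cfg(), seed = seed)
    aln <- sim$alignment
    prof <- site_state_profile(aln)
    tr <- sim$truth$planted_unique
    for (sp in sim$truth$species) {
      got <- find_unique_diagnostics(prof, sp)
      want <- sort(tr$position[tr$species == sp])
      expect_true(all(want %in% got$position),
                  label = sprintf("recovery seed %d species %s", seed, sp))
      # every reported site must be genuinely diagnostic by brute force
      bu <- bf_unique(aln, sp)
      expect_equal(got$position, bu$position,
                   label = sprintf("no false positives seed %d species %s",
                                   seed, sp))
    }
  }
})

test_that("planted shared sites appear with their designated sharers", {
  sim <- simulate_alignment(small_cfg(intra_rate = 0), seed = 21)
  aln <- sim$alignment
  prof <- site_state_profile(aln)
  tr <- sim$truth$planted_shared
  for (i in seq_len(nrow(tr))) {
    sh <- find_shared_diagnostics(prof, tr$species[i])
    rows <- sh[sh$position == tr$position[i], ]
    expect_gt(nrow(rows), 0)
    expect_setequal(rows$sharer, strsplit(tr$sharers[i], ";")[[1]])
    expect_true(all(rows$state == tr$state[i]))
  }
})

test_that("realized intraspecific distances match the configured rate", {
  # expected pairwise intraspecific p-distance is 2m/L minus the correction
  # for two mutations hitting the same site
  devs <- c()
  for (seed in 31:50) {
    cfg <- small_cfg(n_individuals = c(4, 4, 4, 4, 4), intra_rate = 0.005)
    sim <- simulate_alignment(cfg, seed = seed)
    m <- distance_matrix(sim$alignment, dist_config("p", NULL, 50))
    s <- species_distance_summary(m, setNames(sim$alignment$species,
                                              sim$alignment$id))
    devs <- c(devs, s$overall_intraspecific)
  }
  truth <- simulate_alignment(small_cfg(n_individuals = c(4, 4, 4, 4, 4),
                                        intra_rate = 0.005), seed = 31)$truth
  m_mut <- truth$m_intra
  n_f <- truth$n_mutable
  L <- 300
  expected <- (2 * m_mut - (4 / 3) * m_mut^2 / n_f) / L
  se <- sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs) - expected), 3 * se + 1e-4)
})

test_that("realized among-species distances track the planted expectation", {
  for (seed in c(61, 62, 63)) {
    sim <- simulate_alignment(small_cfg(), seed = seed)
    m <- distance_matrix(sim$alignment, dist_config("p", NULL, 50))
    s <- species_distance_summary(m, setNames(sim$alignment$species,
                                              sim$alignment$id))
    exp_p <- sim$truth$expected_pairwise
    rel <- abs(s$among - exp_p) / exp_p
    expect_lt(max(rel[upper.tri(rel)], na.rm = TRUE), 0.10)
  }
})

test_that("truncated species records are missing before the truncation start", {
  sim <- simulate_alignment(
    sim_config(n_species = 4, n_individuals = c(1, 2, 2, 2),
               seq_length = 1011, n_unique_sites = 3, n_shared_sites = 1,
               ambiguity_rate = 0),
    seed = 8)
  aln <- sim$alignment
  tsp <- sim$truth$truncated_species
  rows <- which(aln$species == tsp)
  expect_true(all(aln$seq[rows, 1:823] == "N"))
  expect_true(all(aln$seq[rows, 824:1011] != "N"))
  # its planted sites all lie in the observed window
  tr <- rbind(sim$truth$planted_unique[, c("species", "position")],
              sim$truth$planted_shared[, c("species", "position")])
  expect_true(all(tr$position[tr$species == tsp] >= 824))
})

test_that("ambiguity injection never touches planted sites", {
  sim <- simulate_alignment(small_cfg(ambiguity_rate = 0.02), seed = 77)
  aln <- sim$alignment
  planted <- c(sim$truth$planted_unique$position,
               sim$truth$planted_shared$position)
  amb <- c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B")
  expect_false(any(aln$seq[, planted] %in% amb))
  expect_true(any(aln$seq %in% amb))  # but injection did happen elsewhere
})

test_that("K2P and TN93 collapse toward JC69 on JC-like simulated data", {
  sim <- simulate_alignment(small_cfg(seq_length = 600), seed = 91)
  aln <- sim$alignment
  d_jc <- distance_matrix(aln, dist_config("jc69", NULL, 50))$d
  d_k2 <- distance_matrix(aln, dist_config("k2p", NULL, 50))$d
  d_tn <- distance_matrix(aln, dist_config("tn93", NULL, 50))$d
  ut <- upper.tri(d_jc)
  expect_lt(max(abs(d_k2[ut] - d_jc[ut]) / pmax(d_jc[ut], 0.01)), 0.05)
  expect_lt(max(abs(d_tn[ut] - d_jc[ut]) / pmax(d_jc[ut], 0.01)), 0.05)
})

test_that("infeasible configurations raise explicit errors", {
  expect_error(simulate_alignment(small_cfg(seq_length = 20,
                                            n_unique_sites = 3,
                                            n_shared_sites = 2),
                                  seed = 1),
               "infeasible")
  expect_error(simulate_alignment(small_cfg(divergence = c(0.7, 0.74)),
                                  seed = 1),
               "infeasible")
  expect_error(simulate_alignment(
    sim_config(n_species = 3, n_individuals = 2, seq_length = 500,
               truncate_species = 1, truncation_start = 499,
               n_unique_sites = 3, n_shared_sites = 2),
    seed = 1), "infeasible")
  expect_error(sim_config(max_sharers = 2, divergence = c(0.5, 0.2)))
})

test_that("truth serialization round-trips through JSON", {
  sim <- simulate_alignment(small_cfg(), seed = 19)
  tr <- sim$truth
  tmp <- withr::local_tempfile(fileext = ".json")
  truth_report(tr, tmp)
  back <- read_truth(tmp)
  expect_equal(back$seed, tr$seed)
  expect_equal(back$generator_version, tr$generator_version)
  expect_equal(back$species, tr$species)
  expect_equal(back$planted_unique, tr$planted_unique)
  expect_equal(back$planted_shared, tr$planted_shared)
  expect_equal(back$expected_pairwise, tr$expected_pairwise, tolerance = 1e-12)
  expect_equal(back$m_intra, tr$m_intra)
  # empty planted sets serialize to explicit empty arrays
  sim0 <- simulate_alignment(small_cfg(n_unique_sites = 0, n_shared_sites = 0),
                             seed = 2)
  js <- truth_report(sim0$truth)
  expect_match(js, '"planted_unique": \\{')
  parsed <- jsonlite::fromJSON(js)
  expect_length(parsed$planted_unique$position, 0)
})
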