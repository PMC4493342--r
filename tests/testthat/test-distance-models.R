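# Closed-form values below are evaluated independently inside the test from
# the published formulas, then compared against the implementation.

p1 <- dist_config("p", min_overlap = 1)

test_that("pairwise distances match direct closed-form evaluation", {
  for (model in c("p", "jc69", "k2p", "tn93")) {
    cfg <- dist_config(model, gamma_shape = NULL, min_overlap = 1)
    expect_identical(pairwise_distance("ACGTACGT", "ACGTACGT", cfg), 0)
  }
  expect_equal(pairwise_distance("ACGT", "ACGA", p1), 0.25)

  # JC69 at p = 0.25: d = -(3/4) ln(1 - 4p/3) = -(3/4) ln(2/3)
  a <- "AAAACCCCGGGGTTTT"
  b <- "AAAACCCCGGGTTGCA"  # 4 mismatches in 16 sites, p = 0.25
  expect_equal(pairwise_distance(a, b, dist_config("jc69", NULL, 1)),
               -0.75 * log(1 - 4 * 0.25 / 3), tolerance = 1e-12)

  # K2P with exactly 1 transition and 1 transversion in 10 sites (P = Q = 0.1):
  # d = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)
  a <- "AAAAACCCCC"
  b <- "GTAAACCCCC"  # one A->G transition, one A->T transversion
  expect_equal(pairwise_distance(a, b, dist_config("k2p", NULL, 1)),
               -0.5 * log(1 - 0.2 - 0.1) - 0.25 * log(1 - 0.2),
               tolerance = 1e-12)
})

test_that("TN93 matches its closed form with pair base frequencies", {
  set.seed(1)
  a <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  b <- a
  idx <- sample(400, 60)
  b[idx] <- sapply(a[idx], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1))
  n <- 400
  gA <- (sum(a == "A") + sum(b == "A")) / (2 * n)
  gC <- (sum(a == "C") + sum(b == "C")) / (2 * n)
  gG <- (sum(a == "G") + sum(b == "G")) / (2 * n)
  gT <- (sum(a == "T") + sum(b == "T")) / (2 * n)
  gR <- gA + gG; gY <- gC + gT
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / n
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / n
  Q <- sum(a != b) / n - P1 - P2
  k1 <- 2 * gA * gG / gR; k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  d_exp <- -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
    k3 * log(1 - Q / (2 * gR * gY))
  expect_equal(pairwise_distance(a, b, dist_config("tn93", NULL, 1)),
               d_exp, tolerance = 1e-12)
})

test_that("distances agree with ape::dist.dna on clean alignments", {
  skip_if_not_installed("ape")
  for (seed in 1:5) {
    aln <- random_alignment(seed, p_missing = 0, p_ambig = 0, n_pos = 200)
    bin <- ape::as.DNAbin(matrix(tolower(aln$seq), nrow = nrow(aln$seq)))
    # ape prints NaN/Inf for saturated pairs where we flag NA by design
    norm <- function(x) { x[!is.finite(x)] <- NA_real_; unname(x) }
    for (spec in list(c("p", "raw"), c("jc69", "JC69"),
                      c("k2p", "K80"))) {
      ours <- distance_matrix(aln, dist_config(spec[1], NULL, 1))$d
      theirs <- as.matrix(ape::dist.dna(bin, model = spec[2],
                                        pairwise.deletion = TRUE))
      expect_equal(norm(ours), norm(theirs), tolerance = 1e-9,
                   label = paste("model", spec[1], "seed", seed))
    }
    # gamma-corrected K80
    ours_g <- distance_matrix(aln, dist_config("k2p", 0.7, 1))$d
    theirs_g <- as.matrix(ape::dist.dna(bin, model = "K80", gamma = 0.7,
                                        pairwise.deletion = TRUE))
    expect_equal(norm(ours_g), norm(theirs_g), tolerance = 1e-9)
  }
  # TN93 uses pair frequencies; on 2-record alignments these equal ape's
  # whole-alignment frequencies
  for (seed in 6:10) {
    aln <- random_alignment(seed, n_species = 2, max_ind = 1,
                            p_missing = 0, p_ambig = 0, n_pos = 300)
    bin <- ape::as.DNAbin(matrix(tolower(aln$seq), nrow = 2))
    norm <- function(x) { x[!is.finite(x)] <- NA_real_; unname(x) }
    ours <- distance_matrix(aln, dist_config("tn93", NULL, 1))$d
    theirs <- as.matrix(ape::dist.dna(bin, model = "TN93",
                                      pairwise.deletion = TRUE))
    expect_equal(norm(ours), norm(theirs), tolerance = 1e-9)
    ours_g <- distance_matrix(aln, dist_config("tn93", 1.2, 1))$d
    theirs_g <- as.matrix(ape::dist.dna(bin, model = "TN93", gamma = 1.2,
                                        pairwise.deletion = TRUE))
    expect_equal(norm(ours_g), norm(theirs_g), tolerance = 1e-9)
  }
})

test_that("model ordering and gamma limits hold", {
  set.seed(4)
  a <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  av <- strsplit(a, "")[[1]]
  bv <- av; idx <- sample(300, 45)
  bv[idx] <- sapply(av[idx], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1))
  d_p <- pairwise_distance(av, bv, p1)
  d_jc <- pairwise_distance(av, bv, dist_config("jc69", NULL, 1))
  d_jc_g <- pairwise_distance(av, bv, dist_config("jc69", 1, 1))
  expect_true(d_p <= d_jc)
  expect_true(d_jc <= d_jc_g)
  # alpha -> infinity recovers the uncorrected distance
  for (model in c("jc69", "k2p", "tn93")) {
    d0 <- pairwise_distance(av, bv, dist_config(model, NULL, 1))
    dInf <- pairwise_distance(av, bv, dist_config(model, 1e6, 1))
    expect_equal(dInf, d0, tolerance = 1e-6)
    expect_true(dInf >= d0)  # monotone decrease toward the limit
  }
})

test_that("model reductions: TN93 -> K2P (uniform freqs) and K2P -> JC69 (Q = 2P)", {
  # uniform pair frequencies and equal transition classes
  a <- c(rep("A", 5), rep("C", 5), rep("G", 5), rep("T", 5))
  b <- a
  b[1] <- "G"   # A->G transition
  b[6] <- "T"   # C->T transition
  b[11] <- "C"; b[16] <- "A"  # two transversions, preserving uniform counts
  expect_equal(sum(c(a, b) == "A"), sum(c(a, b) == "C"))
  d_tn <- pairwise_distance(a, b, dist_config("tn93", NULL, 1))
  d_k2 <- pairwise_distance(a, b, dist_config("k2p", NULL, 1))
  expect_equal(d_tn, d_k2, tolerance = 1e-9)

  # Q = 2P degenerates Kimura's formula to Jukes-Cantor
  a2 <- c(rep("A", 12), rep("C", 12))
  b2 <- a2
  b2[1] <- "G"               # 1 transition
  b2[2] <- "T"; b2[13] <- "A"  # 2 transversions
  d_k2b <- pairwise_distance(a2, b2, dist_config("k2p", NULL, 1))
  d_jcb <- pairwise_distance(a2, b2, dist_config("jc69", NULL, 1))
  expect_equal(d_k2b, d_jcb, tolerance = 1e-12)
})

test_that("pairwise deletion, overlap threshold and saturation semantics", {
  # ambiguity codes and missing are excluded from the comparison
  expect_equal(pairwise_distance("ACGTN", "ACGAR", p1), 1 / 4)
  # all-missing columns never change a distance
  aln <- random_alignment(3, p_missing = 0.1)
  pad <- matrix("N", n_records(aln), 50)
  aln_pad <- barcode_alignment(cbind(aln$seq, pad), aln$id, aln$species)
  cfg <- dist_config("p", NULL, 1)
  expect_identical(distance_matrix(aln, cfg)$d, distance_matrix(aln_pad, cfg)$d,
                   ignore_attr = TRUE)
  # disjoint coverage -> undefined but symmetric
  aln2 <- toy_aln(c(paste0(strrep("A", 50), strrep("N", 50)),
                    paste0(strrep("N", 50), strrep("A", 50))),
                  c("sp1", "sp2"))
  m2 <- distance_matrix(aln2, dist_config("p", NULL, 100))
  expect_true(is.na(m2$d[1, 2]) && is.na(m2$d[2, 1]))
  expect_equal(m2$n_undefined, 1L)
  expect_equal(diag(m2$d), c(0, 0), ignore_attr = TRUE)
  # saturation: log argument <= 0 is undefined, not clamped
  sat <- pairwise_distance(strrep("A", 100), strrep("G", 100),
                           dist_config("jc69", NULL, 1))
  expect_true(is.na(sat))
  expect_error(pairwise_distance("ACGT", "ACG", p1), "alignment mismatch")
})

test_that("distance_matrix equals brute-force per-pair recomputation", {
  for (seed in 1:6) {
    aln <- random_alignment(seed, n_species = 4, max_ind = 3)
    for (model in c("p", "jc69", "k2p", "tn93")) {
      cfg <- dist_config(model, gamma_shape = if (seed %% 2) 1 else NULL,
                         min_overlap = 5)
      m <- distance_matrix(aln, cfg)$d
      n <- n_records(aln)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        expect_equal(m[i, j],
                     pairwise_distance(aln$seq[i, ], aln$seq[j, ], cfg),
                     tolerance = 1e-12,
                     label = sprintf("seed %d model %s pair %d-%d",
                                     seed, model, i, j))
      }
    }
  }
})

test_that("species summary means equal brute-force averages", {
  set.seed(9)
  aln <- random_alignment(9, n_species = 4, max_ind = 4)
  cfg <- dist_config("p", NULL, 1)
  m <- distance_matrix(aln, cfg)
  sof <- setNames(aln$species, aln$id)
  s <- species_distance_summary(m, sof)
  for (spA in s$species) {
    ri <- which(aln$species == spA)
    if (length(ri) >= 2) {
      vals <- c()
      for (i in ri) for (j in ri) if (i < j) vals <- c(vals, m$d[i, j])
      expect_equal(s$intraspecific[[spA]], mean(vals, na.rm = TRUE))
    } else {
      expect_true(is.na(s$intraspecific[[spA]]))
    }
    for (spB in s$species) {
      if (spB >= spA) next
      vals <- c()
      for (i in ri) for (j in which(aln$species == spB))
        vals <- c(vals, m$d[i, j])
      expect_equal(s$among[spA, spB], mean(vals, na.rm = TRUE))
      expect_equal(s$among[spA, spB], s$among[spB, spA])
    }
  }
  expect_equal(s$overall_intraspecific,
               mean(s$intraspecific, na.rm = TRUE))
})

test_that("two singleton species at distance d give among mean exactly d", {
  aln <- toy_aln(c("AAAAAAAAAA", "AAAAAAAAGG"), c("spA", "spB"))
  m <- distance_matrix(aln, dist_config("p", NULL, 1))
  s <- species_distance_summary(m, setNames(aln$species, aln$id))
  expect_equal(s$among["spA", "spB"], 0.2)
  expect_true(all(is.na(s$intraspecific)))
  expect_error(species_distance_summary(m, c(r01 = "spA")), "unknown species")
})

test_that("summary table formats n/a and three decimals like a divergence table", {
  aln <- toy_aln(c("AAAAAAAAAA", "AAAAAAAAGG", "AAAAAAAAGA"),
                 c("spA", "spB", "spB"))
  s <- species_distance_summary(distance_matrix(aln, dist_config("p", NULL, 1)),
                                setNames(aln$species, aln$id))
  tab <- format_species_summary(s)
  expect_equal(tab$intraspecific[tab$species == "spA"], "n/a")
  expect_equal(tab$intraspecific[tab$species == "spB"], "0.100")
  expect_equal(tab[tab$species == "spB", "1"], "0.150")
})
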