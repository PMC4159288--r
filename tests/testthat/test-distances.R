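test_that("K2P matches the closed form on canonical pairs", {
  # two transitions over 8 sites: P = 0.25, Q = 0
  d1 <- k2pDistance("AATTCCGG", "AGTTCCGA", minOverlap = 1)
  expect_equal(as.numeric(d1), -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(as.numeric(d1), 0.34657, tolerance = 1e-4)
  # one transversion over 4 sites: P = 0, Q = 0.25
  d2 <- k2pDistance("AAAA", "AACA", minOverlap = 1)
  expect_equal(as.numeric(d2), -0.5 * log(0.75) - 0.25 * log(0.5),
               tolerance = 1e-12)
  expect_equal(as.numeric(d2), 0.31714, tolerance = 1e-4)
  # identical sequences at full length
  s <- random_dna(658)
  expect_equal(as.numeric(k2pDistance(s, s)), 0)
  expect_error(k2pDistance("ACGT", "ACGTA"), "equal length")
})

test_that("pairwise deletion and undefined cells behave as specified", {
  # ambiguity codes are deleted exactly like N
  dN <- k2pDistance("ARGT", "AAGT", minOverlap = 1)
  expect_equal(attr(dN, "overlap"), 3L)
  expect_equal(as.numeric(dN), 0)
  # overlap below the floor -> undefined with reason
  dU <- k2pDistance("NNNA", "ANNN", minOverlap = 1)
  expect_true(is.na(dU))
  expect_identical(attr(dU, "reason"), "overlap")
  # saturation -> undefined, not clamped
  dS <- k2pDistance("AAAA", "GGGG", minOverlap = 1)
  expect_true(is.na(dS))
  expect_identical(attr(dS, "reason"), "saturated")
  # deleting an agreeing unambiguous site keeps d = 0 when P = Q = 0
  expect_equal(as.numeric(k2pDistance("AACGT", "NACGT", minOverlap = 1)), 0)
})

test_that("matrix engine agrees with the scalar route and an external oracle", {
  set.seed(11)
  anc <- random_dna(658)
  seqs <- setNames(c(anc, vapply(c(5, 20, 60, 120), function(n)
    mutate_seq(anc, n), character(1))), paste0("s", 1:5))
  lib <- make_lib(seqs)
  m <- pairwiseK2P(lib, minOverlap = 300)
  expect_equal(length(specimenIds(m)) * (length(specimenIds(m)) - 1) / 2, 10)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(distances(m)[i, j],
                 as.numeric(k2pDistance(seqs[i], seqs[j], minOverlap = 300)),
                 tolerance = 1e-12)
  }
  # cross-check against ape's K80 with pairwise deletion
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(distances(m)), unname(ref[names(seqs), names(seqs)]),
               tolerance = 1e-9)
  # symmetry / diagonal
  expect_identical(distances(m), t(distances(m)))
  expect_equal(unname(diag(distances(m))), rep(0, 5))
})

test_that("three identical sequences give an all-zero matrix; disjoint pairs flagged", {
  s <- random_dna(400)
  m <- pairwiseK2P(make_lib(c(a = s, b = s, c = s)), minOverlap = 300)
  expect_true(all(distances(m) == 0))
  # two sequences with no overlapping unambiguous site
  half <- 200
  sA <- paste0(random_dna(half), strrep("N", half))
  sB <- paste0(strrep("N", half), random_dna(half))
  m2 <- suppressMessages(pairwiseK2P(make_lib(c(a = sA, b = sB)),
                                     minOverlap = 1))
  expect_true(is.na(distances(m2)["a", "b"]))
  expect_equal(siteOverlap(m2)["a", "b"], 0L)
})

test_that("K2P dominates the p-distance on random pairs", {
  set.seed(23)
  for (r in 1:25) {
    a <- random_dna(658)
    b <- mutate_seq(a, sample(1:150, 1))
    d <- as.numeric(k2pDistance(a, b, minOverlap = 1))
    if (!is.na(d)) expect_gte(d, oracle_pdist(a, b) - 1e-12)
  }
})

test_that("species summaries recover planted intra/inter structure", {
  g <- generateLibrary(presetScenarios(seed = 42)$deep_split_8)
  m <- suppressMessages(pairwiseK2P(g$library))
  labs <- speciesLabels(g$library)
  s <- speciesSummaries(m, labs)
  expect_equal(nrow(s), 1L)
  expect_equal(s$max_intra, g$truth$lineages$planted_k2p_pct,
               tolerance = 0.15)   # satellites widen the MPD slightly
  expect_true(is.na(s$nn_species))  # single species: no neighbour
  expect_lte(s$mean_intra, s$max_intra)
  # invariance under specimen reordering
  set.seed(5)
  perm <- sample(length(g$library))
  m2 <- suppressMessages(pairwiseK2P(g$library[perm]))
  s2 <- speciesSummaries(m2, labs)
  expect_equal(s, s2)
  # a two-record species with identical sequences
  s0 <- speciesSummaries(
    pairwiseK2P(make_lib(c(a = random_dna(400), b = random_dna(400))[c(1, 1)] |>
                           setNames(c("a", "b")), species = rep("Gen x", 2)),
                minOverlap = 300),
    c(a = "Gen x", b = "Gen x"))
  expect_equal(s0$mean_intra, 0)
  expect_equal(s0$max_intra, 0)
})

test_that("low-divergence pair table lists planted sharing at zero", {
  g <- generateLibrary(presetScenarios(seed = 42)$haplotype_sharing)
  m <- suppressMessages(pairwiseK2P(g$library))
  labs <- speciesLabels(g$library)
  low <- lowDivergencePairs(m, labs)
  cores <- c("Nabisyn brevisyn", "Nabisyn ericetosyn", "Nabisyn rugosulus")
  zero <- low[low$min_distance == 0, ]
  core_pairs <- zero[zero$species_1 %in% cores & zero$species_2 %in% cores, ]
  expect_equal(nrow(core_pairs), 3L)   # all three core pairs at 0
  expect_true(all(low$species_1 <= low$species_2))
  expect_false(is.unsorted(low$min_distance))
  # species order in the matrix does not matter
  set.seed(9)
  m2 <- suppressMessages(pairwiseK2P(g$library[sample(length(g$library))]))
  low2 <- lowDivergencePairs(m2, labs)
  expect_equal(low, low2)
  # a planted pair at >= 5% minimum distance is absent
  far <- generateLibrary(presetScenarios(seed = 42)$clean_library)
  mf <- suppressMessages(pairwiseK2P(far$library))
  expect_equal(nrow(lowDivergencePairs(mf, speciesLabels(far$library))), 0L)
})

test_that("deep-divergence table keeps only species above the threshold", {
  summ <- data.frame(species = c("a sp", "b sp", "c sp"),
                     n_specimens = c(4L, 5L, 2L),
                     mean_intra = c(0.2, 3.1, NA),
                     max_intra = c(0.5, 23, NA))
  dd <- deepDivergenceSpecies(summ)
  expect_identical(dd$species, "b sp")
  expect_equal(nrow(deepDivergenceSpecies(summ, threshold = 25)), 0L)
})
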