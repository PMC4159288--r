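test_that("no candidate gap means a single group; planted clusters split cleanly", {
  # all distances below the prior ceiling
  set.seed(2)
  n <- 8
  d <- matrix(stats::runif(n * n, 0, 0.015), n, n)
  d <- (d + t(d)) / 2; diag(d) <- 0
  p <- abgdPartition(make_dmat(d), priorP = 0.02, gapWidthX = 1.5)
  expect_equal(length(unique(groupLabels(p))), 1L)
  # two planted clusters: intra <= 1%, inter >= 10%
  d2 <- matrix(0, 8, 8)
  intra <- matrix(stats::runif(16, 0, 0.01), 4, 4)
  intra <- (intra + t(intra)) / 2; diag(intra) <- 0
  d2[1:4, 1:4] <- intra
  intra2 <- matrix(stats::runif(16, 0, 0.01), 4, 4)
  intra2 <- (intra2 + t(intra2)) / 2; diag(intra2) <- 0
  d2[5:8, 5:8] <- intra2
  d2[1:4, 5:8] <- stats::runif(16, 0.10, 0.12)
  d2[5:8, 1:4] <- t(d2[1:4, 5:8])
  p2 <- abgdPartition(make_dmat(d2), priorP = 0.02, gapWidthX = 1.5)
  g <- groupLabels(p2)
  expect_equal(length(unique(g)), 2L)
  expect_equal(length(unique(g[1:4])), 1L)
  expect_equal(length(unique(g[5:8])), 1L)
  # fewer than 3 specimens: single flagged group
  p3 <- abgdPartition(make_dmat(d2[1:2, 1:2]), priorP = 0.01)
  expect_identical(p3@flags, "too_few")
})

test_that("recursion resolves nested clusters at successive gaps", {
  # 12 specimens: two superclusters 15% apart; one supercluster splits
  # again at ~5%; intra noise ~0.5-1%
  set.seed(6)
  blocks <- list(1:4, 5:8, 9:12)
  d <- matrix(0.15, 12, 12)
  for (b in blocks) d[b, b] <- 0.006
  d[1:4, 5:8] <- d[5:8, 1:4] <- 0.05   # the secondary split
  d <- d + matrix(stats::runif(144, 0, 0.003), 12, 12)
  d <- (d + t(d)) / 2; diag(d) <- 0
  # prior above the intra noise (~0.9%) so only the real gaps qualify
  p <- abgdPartition(make_dmat(d), priorP = 0.013, gapWidthX = 1.5)
  g <- groupLabels(p)
  expect_equal(length(unique(g)), 3L)
  for (b in blocks) expect_equal(length(unique(g[b])), 1L)
  expect_gte(p@depth, 2L)
  # with a prior above the secondary gap only the primary split remains
  p2 <- abgdPartition(make_dmat(d), priorP = 0.07, gapWidthX = 1.5)
  expect_equal(length(unique(groupLabels(p2))), 2L)
})

test_that("partitions equal the exhaustive-search oracle on small matrices", {
  set.seed(12)
  for (r in 1:20) {
    n <- sample(5:12, 1)
    k <- sample(1:3, 1)
    centers <- stats::runif(k, 0, 0.15)
    assign_c <- sample(seq_len(k), n, replace = TRUE)
    d <- matrix(0, n, n)
    for (i in 2:n) for (j in 1:(i - 1)) {
      base <- if (assign_c[i] == assign_c[j]) 0.005 else
        abs(centers[assign_c[i]] - centers[assign_c[j]]) + 0.05
      d[i, j] <- d[j, i] <- base + stats::runif(1, 0, 0.004)
    }
    prior <- stats::runif(1, 0.001, 0.1)
    xw <- stats::runif(1, 0.1, 3)
    got <- unname(groupLabels(abgdPartition(make_dmat(d), prior, xw)))
    want <- oracle_gap_partition(d, prior, xw)
    expect_identical(got, want,
                     label = sprintf("matrix %d (n=%d prior=%.4f X=%.2f)",
                                     r, n, prior, xw))
  }
})

test_that("sweep rows are monotone and the finest cell refines the rest", {
  g <- generateLibrary(presetScenarios(seed = 13)$deep_split_8)
  m <- suppressMessages(pairwiseK2P(g$library))
  labs <- speciesLabels(g$library)
  sw <- apeSweep(m, labs, nSteps = 40, nX = 5)
  # once lumped at a prior, lumped at every larger prior (fixed X)
  for (xi in seq_along(sw@gapWidths)) {
    lump <- sw@lumped[1, , xi]
    expect_true(all(diff(as.integer(lump)) >= 0))
  }
  # group counts monotone non-increasing in both grid directions
  expect_true(all(apply(sw@nGroups, 2, function(cc) all(diff(cc) <= 0))))
  expect_true(all(apply(sw@nGroups, 1, function(rr) all(diff(rr) <= 0))))
  # the (smallest prior, smallest X) partition refines every other cell
  fine <- groupLabels(abgdPartition(m, min(sw@priors), min(sw@gapWidths)))
  for (pp in sw@priors[c(1, 20, 40)]) for (xx in sw@gapWidths[c(1, 5)]) {
    coarse <- groupLabels(abgdPartition(m, pp, xx))
    tab <- table(fine, coarse)
    expect_true(all(rowSums(tab > 0) == 1))  # each fine group in one coarse
  }
})

test_that("estimator P reads the first lumped prior with censoring at the edges", {
  # structureless species (one haplotype): lumped everywhere -> censored
  # below
  set.seed(19)
  anc <- random_dna(658)
  lib <- make_lib(setNames(rep(anc, 4), paste0("s", 1:4)),
                  species = rep("Gen flat", 4))
  m <- suppressMessages(pairwiseK2P(lib))
  sw <- apeSweep(m, speciesLabels(lib), nX = 1, xMin = 0.1)
  e <- estimateP(sw)
  expect_identical(e$estimator_P, "<0.1")
  expect_identical(e$censored, "below")
  # ~23% split: never lumped in range -> censored above
  g23 <- generateLibrary(presetScenarios(seed = 19)$deep_split_23)
  m23 <- suppressMessages(pairwiseK2P(g23$library))
  e23 <- estimateP(apeSweep(m23, speciesLabels(g23$library), nX = 1,
                            xMin = 0.1))
  expect_identical(e23$estimator_P, ">10")
  # ~5% split: estimator lands within one geometric grid step
  g5 <- generateLibrary(presetScenarios(seed = 19)$deep_split_5)
  m5 <- suppressMessages(pairwiseK2P(g5$library))
  e5 <- estimateP(apeSweep(m5, speciesLabels(g5$library), nX = 1,
                           xMin = 0.1))
  planted <- g5$truth$lineages$planted_k2p_pct
  ratio <- (0.1 / 0.001)^(1 / 99)
  expect_lte(abs(log(e5$estimator_value / planted)), log(ratio) + 1e-9)
  expect_error(estimateP(sw, species = "Gen absent"), "absent")
})

test_that("sweep matrices render one row per species with monotone transitions", {
  # two invariant species (single haplotype each) plus one deep split:
  # only the deep-split row may ever show split cells
  set.seed(21)
  flatA <- random_dna(658)
  flatB <- mutate_seq(flatA, 90)
  lib23 <- generateLibrary(presetScenarios(seed = 21)$deep_split_23)$library
  lib <- make_lib(
    setNames(c(rep(flatA, 3), rep(flatB, 3),
               as.character(sequences(lib23))),
             c(paste0("a", 1:3), paste0("b", 1:3),
               paste0("c_", specimenIds(lib23)))),
    species = c(rep("Genus flatus", 3), rep("Genus planus", 3),
                specimenData(lib23)$species))
  m <- suppressMessages(pairwiseK2P(lib))
  sw <- apeSweep(m, speciesLabels(lib), nSteps = 20, nX = 2)
  mats <- renderSweepMatrix(sw, gapWidth = 0.1)
  mat <- mats[[1]]
  expect_equal(dim(mat), c(3L, 20L))
  expect_true(all(mat %in% c("lumped", "split")))
  # exactly one row (the deep-split species) contains split cells
  has_split <- apply(mat == "split", 1, any)
  expect_identical(names(which(has_split)), "Splitsyn avenius")
  # once lumped, stays lumped at larger priors
  for (r in seq_len(nrow(mat))) {
    lump <- mat[r, ] == "lumped"
    expect_true(all(diff(as.integer(lump)) >= 0))
  }
})
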