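test_that("NJ recovers the generating split of an additive matrix", {
  # 4-taxon additive matrix with split AB|CD dominating
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.02
  d["c", "d"] <- d["d", "c"] <- 0.02
  for (x in c("a", "b")) for (y in c("c", "d"))
    d[x, y] <- d[y, x] <- 0.2
  tr <- njTree(make_dmat(d, letters[1:4]))
  bip <- bipartition_matrix(tr)
  expect_true(displays_quartet(bip, "a", "b", "c", "d"))
  # 3 taxa: the unique unrooted topology
  tr3 <- njTree(make_dmat(d[1:3, 1:3], letters[1:3]))
  expect_equal(ape::Ntip(tr3), 3L)
  expect_error(njTree(make_dmat(d[1:2, 1:2], letters[1:2])), "at least 3")
})

test_that("undefined cells drop the fewest specimens and clamping removes negatives", {
  d <- matrix(0.1, 5, 5); diag(d) <- 0
  d[1, 2:5] <- d[2:5, 1] <- NA   # specimen 1 carries every undefined cell
  m <- make_dmat(d)
  expect_warning(tr <- njTree(m), "t01")
  expect_setequal(tr$tip.label, sprintf("t%02d", 2:5))
  g <- generateLibrary(presetScenarios(seed = 3)$clean_library)
  tr2 <- njTree(suppressMessages(pairwiseK2P(g$library)))
  expect_true(all(tr2$edge.length >= 0))
})

test_that("monophyly is an exact bipartition test on the unrooted tree", {
  tr <- ape::read.tree(text = "((a1,a2),(b1,(b2,c1)),c2);")
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
  rep <- monophylyReport(tr, sp)
  expect_identical(rep$status[rep$species == "A"], "monophyletic")
  expect_identical(rep$status[rep$species == "B"], "non-monophyletic")
  expect_identical(rep$status[rep$species == "C"], "non-monophyletic")
  expect_match(rep$conflicting[rep$species == "B"], "C")
  # single-specimen species are trivial; a lone species is monophyletic
  tr1 <- ape::read.tree(text = "((x1,x2),(x3,y1));")
  rep1 <- monophylyReport(tr1, c(x1 = "X", x2 = "X", x3 = "X", y1 = "Y"))
  expect_identical(rep1$status[rep1$species == "Y"], "trivial")
  expect_identical(rep1$status[rep1$species == "X"], "monophyletic")
  expect_error(monophylyReport(tr, sp[-1]), "labelled")
})

test_that("planted haplotype sharing breaks monophyly of the sharing species", {
  g <- generateLibrary(presetScenarios(seed = 42)$haplotype_sharing)
  m <- suppressMessages(pairwiseK2P(g$library))
  tr <- njTree(m)
  rep <- monophylyReport(tr, speciesLabels(g$library))
  truth <- g$truth$speciesExpectations
  for (i in seq_len(nrow(truth))) {
    obs <- rep$status[rep$species == truth$species[i]]
    if (is.na(truth$expected_monophyletic[i])) next  # tie-dependent case
    if (truth$expected_monophyletic[i])
      expect_true(obs %in% c("monophyletic", "trivial"),
                  label = truth$species[i])
    else expect_identical(obs, "non-monophyletic", label = truth$species[i])
  }
})

test_that("bootstrap supports are seeded, bounded and strong for clean splits", {
  set.seed(31)
  ancA <- random_dna(658)
  ancB <- mutate_seq(ancA, 130)   # ~20% divergence, zero intra variation
  lib <- make_lib(c(a1 = ancA, a2 = ancA, a3 = ancA,
                    b1 = ancB, b2 = ancB, b3 = ancB),
                  species = rep(c("Gen alpha", "Gen beta"), each = 3))
  tr <- suppressMessages(bootstrapSupports(lib, nReplicates = 100, seed = 7))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # the a|b bipartition exists and is supported by every replicate
  rep <- monophylyReport(tr, speciesLabels(lib))
  expect_true(all(rep$status == "monophyletic"))
  node_ab <- ape::getMRCA(tr, c("a1", "a2", "a3"))
  lab_ab <- tr$node.label[node_ab - ape::Ntip(tr)]
  if (nzchar(lab_ab)) expect_equal(as.numeric(lab_ab), 100)
  # determinism contract
  tr2 <- suppressMessages(bootstrapSupports(lib, nReplicates = 100, seed = 7))
  expect_identical(tr$node.label, tr2$node.label)
  tr3 <- suppressMessages(bootstrapSupports(lib, nReplicates = 1, seed = 7))
  sup3 <- suppressWarnings(as.numeric(tr3$node.label))
  expect_true(all(sup3[!is.na(sup3)] %in% c(0, 100)))
  expect_error(bootstrapSupports(lib, nReplicates = 10), "seed")
})

test_that("threshold clustering is single-linkage over sub-threshold pairs", {
  # chain: a-b 1%, b-c 1%, a-c 3% -> one cluster by transitivity
  d <- matrix(c(0, 0.01, 0.03,
                0.01, 0, 0.01,
                0.03, 0.01, 0) , 3, 3)
  cl <- thresholdClusters(make_dmat(d, c("a", "b", "c")), threshold = 2.2)
  expect_equal(length(unique(cl$cluster)), 1L)
  # all pairs at/above threshold -> singletons
  d2 <- matrix(0.05, 3, 3); diag(d2) <- 0
  cl2 <- thresholdClusters(make_dmat(d2, c("a", "b", "c")), threshold = 2.2)
  expect_equal(length(unique(cl2$cluster)), 3L)
  # monotone coarsening: huge threshold -> one cluster, zero -> singletons
  cl_all <- thresholdClusters(make_dmat(d2), threshold = 1e6)
  expect_equal(length(unique(cl_all$cluster)), 1L)
  cl_none <- thresholdClusters(make_dmat(d2), threshold = 0)
  expect_equal(length(unique(cl_none$cluster)), 3L)
})

test_that("clusters equal independently traversed components on random matrices", {
  set.seed(17)
  for (r in 1:5) {
    n <- 10
    d <- matrix(stats::runif(n * n, 0, 0.08), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    m <- make_dmat(d)
    cl <- thresholdClusters(m, threshold = 2.2)
    # naive BFS over the same graph
    adj <- d * 100 < 2.2; diag(adj) <- FALSE
    comp <- rep(0L, n); cid <- 0L
    for (s in seq_len(n)) {
      if (comp[s]) next
      cid <- cid + 1L; queue <- s; comp[s] <- cid
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        nb <- which(adj[u, ] & comp == 0L)
        comp[nb] <- cid; queue <- c(queue, nb)
      }
    }
    expect_equal(length(unique(cl$cluster)), cid)
    # same partition up to relabelling
    expect_equal(as.integer(factor(cl$cluster, levels = unique(cl$cluster))),
                 as.integer(factor(comp, levels = unique(comp))))
  }
})

test_that("planted deep split yields two threshold clusters", {
  g <- generateLibrary(presetScenarios(seed = 42)$deep_split_8)
  m <- suppressMessages(pairwiseK2P(g$library))
  cl <- thresholdClusters(m)
  expect_equal(length(unique(cl$cluster)), 2L)
  truth_lin <- setNames(g$truth$specimens$lineage,
                        g$truth$specimens$specimen_id)
  split_by_cluster <- split(truth_lin[cl$specimen_id], cl$cluster)
  for (grp in split_by_cluster)
    expect_equal(length(unique(grp)), 1L)  # clusters = planted lineages
})
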