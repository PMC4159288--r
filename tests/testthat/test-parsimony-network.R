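test_that("haplotype collapsing follows the ambiguity-compatibility rule", {
  lib <- make_lib(c(a = "AATA", b = "AATA", c = "AANA", d = "AAGA"))
  h <- collapseHaplotypes(lib)
  # a, b identical; c (N compatible) joins them; d differs at site 3
  expect_equal(length(h), 2L)
  expect_setequal(haplotypeMembers(h)$h1, c("a", "b", "c"))
  expect_setequal(haplotypeMembers(h)$h2, "d")
  # strict mode keeps the N variant apart
  hs <- collapseHaplotypes(lib, strict = TRUE)
  expect_equal(length(hs), 3L)
  # members partition the input specimen set
  expect_setequal(unlist(haplotypeMembers(h)), specimenIds(lib))
})

test_that("shared-plus-satellite scenario collapses to the planted haplotypes", {
  # one dominant haplotype plus satellites two and three steps out
  set.seed(41)
  h1 <- random_dna(658)
  h2 <- mutate_seq(h1, 2)
  h3 <- mutate_seq(h1, 3)
  lib <- make_lib(c(w1 = h1, w2 = h1, w3 = h1, g1 = h1, g2 = h2, g3 = h3),
                  species = c(rep("Chara weberoid", 3),
                              rep("Chara gylloid", 3)))
  ht <- collapseHaplotypes(lib)
  expect_equal(length(ht), 3L)
  expect_equal(length(haplotypeMembers(ht)$h1), 4L)  # shared across species
  sc <- ht@speciesCounts
  expect_equal(sort(sc$species[sc$haplotype == "h1"]),
               c("Chara gylloid", "Chara weberoid"))
  net <- buildNetwork(ht, connectionLimit(658, 0.95))
  expect_equal(length(subnetworks(net)), 1L)
})

test_that("connection limit matches its direct-evaluation oracle and is monotone", {
  # frozen regression constants, re-derived by the independent oracle
  expect_equal(connectionLimit(658, 0.95), oracle_parsimony_limit(658, 0.95))
  expect_equal(connectionLimit(658, 0.90), oracle_parsimony_limit(658, 0.90))
  expect_identical(connectionLimit(658, 0.95), 8L)
  expect_identical(connectionLimit(658, 0.90), 11L)
  # monotone non-decreasing in length, non-increasing in confidence
  for (conf in c(0.8, 0.9, 0.95, 0.99)) {
    lims <- vapply(c(100L, 300L, 658L, 1500L), connectionLimit, integer(1),
                   confidence = conf)
    expect_true(all(diff(lims) >= 0))
  }
  for (L in c(200L, 658L, 1200L)) {
    lims <- vapply(c(0.8, 0.9, 0.95, 0.99), function(cf)
      connectionLimit(L, cf), integer(1))
    expect_true(all(diff(lims) <= 0))
  }
  # extreme confidence shrinks the limit to its floor of one step
  expect_identical(connectionLimit(658, 0.999999), 1L)
  expect_error(connectionLimit(658, 1), "confidence")
  expect_error(connectionLimit(658, 0), "confidence")
})

test_that("network assembly inserts one node per intermediate step", {
  lib1 <- make_lib(c(a = "AAAA", b = "AAAT"))
  net1 <- buildNetwork(collapseHaplotypes(lib1), limit = 4)
  expect_equal(igraph::ecount(net1@graph), 1L)
  expect_equal(sum(igraph::V(net1@graph)$type == "inferred"), 0L)
  lib2 <- make_lib(c(a = "AAAA", b = "AATT"))
  net2 <- buildNetwork(collapseHaplotypes(lib2), limit = 4)
  expect_equal(sum(igraph::V(net2@graph)$type == "inferred"), 1L)
  expect_equal(igraph::ecount(net2@graph), 2L)
  # a pair beyond the limit stays apart and its gap is reported
  lib3 <- make_lib(c(a = "AAAAAAAA", b = "TTTTTAAA"))  # 5 steps
  net3 <- buildNetwork(collapseHaplotypes(lib3), limit = 2)
  expect_equal(length(subnetworks(net3)), 2L)
  expect_equal(subnetworkGap(net3)$min_steps, 5L)
})

test_that("planted two-lineage species gives two subnetworks until the limit reaches the gap", {
  g <- generateLibrary(presetScenarios(seed = 42)$orius)
  h <- collapseHaplotypes(g$library)
  lim95 <- connectionLimit(alignmentLength(g$library), 0.95)
  net <- buildNetwork(h, lim95)
  expect_equal(length(subnetworks(net)), 2L)
  gap <- subnetworkGap(net)
  expect_equal(gap$min_steps, g$truth$lineages$planted_steps)
  joined <- buildNetwork(h, g$truth$lineages$planted_steps)
  expect_equal(length(subnetworks(joined)), 1L)
})

test_that("path lengths dominate mutational distances; input order only relabels", {
  g <- generateLibrary(presetScenarios(seed = 8)$haplotype_sharing)
  lib <- g$library[which(specimenData(g$library)$genus == "Nabisyn")]
  h <- collapseHaplotypes(lib)
  net <- buildNetwork(h, 8)
  dg <- igraph::distances(net@graph)
  reps <- lapply(as.character(h@representatives), function(s)
    strsplit(s, "")[[1]])
  ids <- haplotypeIds(h)
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    steps <- sum(reps[[i]] != reps[[j]])
    if (is.finite(dg[ids[i], ids[j]]))
      expect_gte(dg[ids[i], ids[j]], steps)
  }
  # shuffled input: same haplotype size spectrum and subnetwork structure
  set.seed(4)
  lib2 <- lib[sample(length(lib))]
  h2 <- collapseHaplotypes(lib2)
  expect_equal(sort(vapply(haplotypeMembers(h2), length, integer(1))),
               sort(vapply(haplotypeMembers(h), length, integer(1))))
  net2 <- buildNetwork(h2, 8)
  expect_equal(length(subnetworks(net2)), length(subnetworks(net)))
})
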