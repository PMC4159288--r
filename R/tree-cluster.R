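#' @include distances.R
NULL

# Drop the fewest specimens needed (greedy by undefined-cell count) so the
# remaining distance matrix is complete. Imputation is deliberately not
# offered: inventing distances would silently bias the tree.
.completeIds <- function(d) {
  keep <- rep(TRUE, nrow(d))
  repeat {
    nan_counts <- rowSums(is.na(d[keep, keep, drop = FALSE]))
    if (all(nan_counts == 0)) break
    worst <- which(keep)[which.max(nan_counts)]
    keep[worst] <- FALSE
  }
  rownames(d)[keep]
}

# Clamp negative NJ branch estimates to zero, transferring the deficit to
# the adjacent edge toward the root of ape's internal edge table so leaf
# path lengths are approximately preserved (Kuhner-Felsenstein style).
.clampNegativeEdges <- function(phy) {
  for (pass in 1:5) {
    neg <- which(phy$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      deficit <- phy$edge.length[e]
      phy$edge.length[e] <- 0
      parent <- phy$edge[e, 1L]
      up <- which(phy$edge[, 2L] == parent)
      if (length(up) == 1L)
        phy$edge.length[up] <- phy$edge.length[up] + deficit
    }
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Neighbour-joining tree from a K2P distance matrix
#'
#' Standard Saitou-Nei neighbour joining (via [ape::nj()]) on the defined
#' part of the matrix. Specimens involved in undefined cells are dropped
#' greedily (fewest removals leaving a complete matrix) with a warning.
#' Negative branch-length estimates are clamped to zero with the deficit
#' transferred to the adjacent edge, unless `keepNegative = TRUE`.
#'
#' @param m a [K2PDistanceMatrix].
#' @param keepNegative keep negative NJ branch estimates as-is.
#' @return An unrooted `ape::phylo` tree whose tip labels are the analyzed
#'   specimen ids.
#' @export
njTree <- function(m, keepNegative = FALSE) {
  stopifnot(is(m, "K2PDistanceMatrix"))
  d <- distances(m)
  ids <- specimenIds(m)
  if (anyNA(d)) {
    keep <- .completeIds(d)
    drop <- setdiff(ids, keep)
    warning("njTree: dropping ", length(drop),
            " specimen(s) with undefined distances: ",
            paste(drop, collapse = ", "))
    d <- d[keep, keep, drop = FALSE]
  }
  if (nrow(d) < 3) stop("need at least 3 specimens with defined distances")
  phy <- ape::nj(as.dist(d))
  if (!keepNegative) phy <- .clampNegativeEdges(phy)
  phy
}

#' Bootstrap supports for the neighbour-joining tree
#'
#' Nonparametric bootstrap over alignment columns: columns are resampled
#' with replacement, the K2P matrix and NJ tree are recomputed per
#' replicate, and the support of each internal bipartition of the original
#' tree is the percentage of replicates displaying it. One root seed spawns
#' one sub-seed per replicate, so results are reproducible. Replicates
#' whose resampled matrix has undefined distances among the analyzed ids
#' are dropped and counted.
#'
#' @param lib a [BarcodeLibrary].
#' @param nReplicates number of bootstrap replicates (default 1000).
#' @param seed integer seed (mandatory).
#' @param minOverlap per-pair overlap floor, as in [pairwiseK2P()].
#' @param keepNegative passed to the per-replicate NJ (see [njTree()]).
#' @return The original NJ tree with `node.label` set to integer percent
#'   supports (root label empty), plus attributes `n_kept` and `n_dropped`.
#' @export
bootstrapSupports <- function(lib, nReplicates = 1000, seed,
                              minOverlap = 300, keepNegative = FALSE) {
  stopifnot(is(lib, "BarcodeLibrary"), nReplicates >= 1)
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  m <- pairwiseK2P(lib, minOverlap = minOverlap)
  phy <- njTree(m, keepNegative = keepNegative)
  ids <- phy$tip.label
  mat <- .seqMatrix(sequences(lib))[ids, , drop = FALSE]
  L <- ncol(mat)

  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, nReplicates)
  trees <- vector("list", nReplicates)
  dropped <- 0L
  for (r in seq_len(nReplicates)) {
    set.seed(sub_seeds[r])
    cols <- sample.int(L, L, replace = TRUE)
    k <- .k2pEngine(mat[, cols, drop = FALSE], minOverlap)
    if (anyNA(k$d)) { dropped <- dropped + 1L; next }
    tr <- ape::nj(as.dist(k$d))
    trees[[r]] <- tr
  }
  trees <- trees[!vapply(trees, is.null, logical(1))]
  kept <- length(trees)
  if (dropped > 0)
    message("bootstrapSupports: dropped ", dropped,
            " replicate(s) with undefined distances")
  if (kept == 0) stop("all bootstrap replicates were dropped")
  counts <- ape::prop.clades(phy, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / kept)
  phy$node.label <- as.character(support)
  phy$node.label[1L] <- ""  # root of ape's internal representation
  attr(phy, "n_kept") <- kept
  attr(phy, "n_dropped") <- dropped
  phy
}

# Bipartition membership matrix: one row per internal edge clade (as listed
# by ape::prop.part under ape's arbitrary rooting), columns = tips.
.cladeMatrix <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  mat <- matrix(FALSE, nrow = length(pp), ncol = length(labs),
                dimnames = list(NULL, labs))
  for (i in seq_along(pp)) mat[i, pp[[i]]] <- TRUE
  mat
}

#' Per-species monophyly report
#'
#' A species with two or more specimens is monophyletic on the unrooted
#' tree iff some edge bipartition isolates exactly its specimen set;
#' singletons are reported as `trivial`. For non-monophyletic species the
#' other species inside the smallest clade containing it are listed as the
#' conflicting set.
#'
#' Internal edges of (near-)zero length are collapsed into polytomies
#' before the test (`collapseZero`, default on): a zero-length edge
#' reflects an arbitrary resolution of identical sequences, not signal, so
#' species whose specimens share a haplotype with another species are
#' consistently read as non-monophyletic instead of depending on
#' tie-breaking.
#'
#' @param tree an unrooted `ape::phylo` whose tips are specimen ids.
#' @param species named character vector (specimen id -> species) covering
#'   every tip.
#' @param collapseZero collapse internal edges shorter than `tol` first.
#' @param tol edge-length tolerance for the collapse (default 1e-8, far
#'   below one substitution on any realistic barcode).
#' @return `data.frame` with `species`, `n`, `status` (`monophyletic`,
#'   `non-monophyletic`, `trivial`), `conflicting` (comma-separated, empty
#'   when none).
#' @export
monophylyReport <- function(tree, species, collapseZero = TRUE,
                            tol = 1e-8) {
  tips <- tree$tip.label
  if (!all(tips %in% names(species)))
    stop("every leaf must be labelled; missing: ",
         paste(setdiff(tips, names(species)), collapse = ", "))
  if (collapseZero && !is.null(tree$edge.length))
    tree <- ape::di2multi(tree, tol = tol)
  sp <- species[tips]
  cm <- .cladeMatrix(tree)
  sps <- sort(unique(unname(sp)), method = "radix")
  rows <- lapply(sps, function(s) {
    inset <- unname(sp == s)
    n <- sum(inset)
    if (n == 1L)
      return(data.frame(species = s, n = n, status = "trivial",
                        conflicting = ""))
    hit <- apply(cm, 1L, function(side) all(side == inset) ||
                                        all(side == !inset))
    # the complement of a single tip is always an (unlisted) bipartition
    # side, as is the full tip set
    if (sum(!inset) <= 1L) hit <- TRUE
    if (any(hit))
      return(data.frame(species = s, n = n, status = "monophyletic",
                        conflicting = ""))
    # smallest containing clade (consider both sides of each bipartition)
    sides <- rbind(cm, !cm)
    contains <- apply(sides, 1L, function(side) all(side[inset]))
    sizes <- rowSums(sides)
    sizes[!contains] <- NA
    best <- which.min(sizes)
    conflict <- sort(unique(unname(sp[sides[best, ] & !inset])),
                     method = "radix")
    data.frame(species = s, n = n, status = "non-monophyletic",
               conflicting = paste(conflict, collapse = ","))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Single-linkage threshold clustering (operational-taxonomic-unit proxy)
#'
#' Clusters are the connected components of the graph joining specimen
#' pairs with a defined K2P distance below `threshold` percent. This is a
#' documented single-linkage proxy for database-assigned barcode OTUs
#' (e.g. BOLD's BIN system, whose RESL algorithm is proprietary); the
#' threshold defaults to the 2.2% used for rough intra/interspecific
#' differentiation.
#'
#' @param m a [K2PDistanceMatrix].
#' @param threshold percent threshold (default 2.2).
#' @return `data.frame` with `specimen_id` and `cluster` (labels `C001`,
#'   ... ordered by first occurrence), with attribute `threshold`.
#' @export
thresholdClusters <- function(m, threshold = 2.2) {
  stopifnot(is(m, "K2PDistanceMatrix"))
  ids <- specimenIds(m)
  d <- distances(m) * 100
  adj <- !is.na(d) & d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel by first occurrence
  first <- match(unique(comp), comp)
  lab <- setNames(sprintf("C%03d", seq_along(first)), comp[first])
  res <- data.frame(specimen_id = ids,
                    cluster = unname(lab[as.character(comp)]))
  attr(res, "threshold") <- threshold
  res
}
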