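#' @include AllClasses.R
NULL

.UNAMB <- c("A", "C", "G", "T")

# Number of differing sites where both sequences are unambiguous
# (consistent with pairwise deletion in the distance module).
.mutSteps <- function(a, b) {
  use <- a %in% .UNAMB & b %in% .UNAMB
  sum(a[use] != b[use])
}

#' Collapse specimens into haplotypes
#'
#' Specimens merge into one haplotype iff their sequences are identical at
#' every site where both are unambiguous ("ambiguity-compatible" merging:
#' an N is compatible with anything). Each incoming specimen joins the
#' first existing haplotype whose representative it is compatible with, in
#' input order; the representative's ambiguous positions are resolved from
#' members as they join. Strict-identity collapsing is available via
#' `strict = TRUE`. Haplotypes are numbered `h1`, `h2`, ... by descending
#' member count, ties by first occurrence.
#'
#' @param lib a [BarcodeLibrary] holding one analysis group (a species or
#'   genus subset).
#' @param strict require exact sequence identity instead of
#'   ambiguity-compatible merging.
#' @return A [HaplotypeTable].
#' @export
collapseHaplotypes <- function(lib, strict = FALSE) {
  stopifnot(is(lib, "BarcodeLibrary"), length(lib) >= 1)
  mat <- .seqMatrix(sequences(lib))
  ids <- rownames(mat)
  sp <- speciesLabels(lib)
  reps <- list()      # representative character vectors
  members <- list()
  for (i in seq_len(nrow(mat))) {
    s <- mat[i, ]
    placed <- FALSE
    for (h in seq_along(reps)) {
      r <- reps[[h]]
      ok <- if (strict) all(r == s) else {
        use <- r %in% .UNAMB & s %in% .UNAMB
        all(r[use] == s[use])
      }
      if (ok) {
        members[[h]] <- c(members[[h]], ids[i])
        fill <- !(r %in% .UNAMB) & (s %in% .UNAMB)
        if (any(fill) && !strict) { r[fill] <- s[fill]; reps[[h]] <- r }
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- s
      members[[length(members) + 1L]] <- ids[i]
    }
  }
  sizes <- vapply(members, length, integer(1))
  ord <- order(-sizes, seq_along(sizes))  # frequency desc, then first seen
  reps <- reps[ord]; members <- members[ord]
  hids <- paste0("h", seq_along(reps))
  names(members) <- hids
  repset <- Biostrings::DNAStringSet(
    vapply(reps, paste, character(1), collapse = ""))
  names(repset) <- hids
  counts <- do.call(rbind, lapply(seq_along(hids), function(h) {
    tab <- table(sp[members[[h]]])
    data.frame(haplotype = hids[h], species = names(tab),
               n = as.integer(tab))
  }))
  rownames(counts) <- NULL
  new("HaplotypeTable", haplotypeIds = hids, representatives = repset,
      members = members, speciesCounts = counts)
}

#' Statistical parsimony connection limit
#'
#' The largest number of mutational steps j for which the estimated
#' probability of a parsimonious connection (no alignment site carrying a
#' superimposed change) is at least `confidence`. The probability is
#' computed under a finite-sites Poisson model: j observed differences over
#' `seqLength` sites imply a Jukes-Cantor-corrected per-site substitution
#' load lambda, and
#' \deqn{P(j) = \left[(1+\lambda) e^{-\lambda}\right]^{L},}
#' the probability that no site experienced two or more substitutions. The
#' limit is floored at 1 (a single step is always accepted), is monotone
#' non-decreasing in `seqLength` and non-increasing in `confidence`.
#'
#' @param seqLength number of alignment sites (>= 1).
#' @param confidence connection confidence in (0, 1); 0.95 is the
#'   conventional default.
#' @return Integer maximum number of steps.
#' @examples
#' connectionLimit(658, 0.95)
#' connectionLimit(658, 0.90)
#' @export
connectionLimit <- function(seqLength, confidence = 0.95) {
  stopifnot(seqLength >= 1)
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  limit <- 1L
  j <- 1L
  while (j < seqLength * 3 / 4) {
    p <- j / seqLength
    if (p >= 3 / 4) break
    lambda <- -0.75 * log1p(-4 * p / 3)
    logP <- seqLength * (log1p(lambda) - lambda)
    if (logP >= log(confidence)) limit <- j else break
    j <- j + 1L
  }
  max(limit, 1L)
}

#' Assemble a statistical parsimony network
#'
#' Haplotype pairs are connected in order of increasing mutational
#' distance (ties broken by higher combined haplotype frequency, then by
#' lexicographic id pair); a pair differing by k steps contributes a path
#' with k - 1 inferred intermediate nodes ("missing haplotypes"), each edge
#' representing a single mutational change. Pairs beyond `limit` steps are
#' never joined directly, so the result may consist of several
#' subnetworks. Within one distance class, every pair whose endpoints lay
#' in different components at the start of the class is connected, which
#' permits reticulations (loops) for alternative equal-length connections.
#'
#' @param h a [HaplotypeTable].
#' @param limit maximum number of mutational steps, e.g. from
#'   [connectionLimit()].
#' @return A [ParsimonyNetwork].
#' @export
buildNetwork <- function(h, limit) {
  stopifnot(is(h, "HaplotypeTable"), limit >= 1)
  limit <- as.integer(limit)
  hids <- h@haplotypeIds
  k <- length(hids)
  reps <- lapply(as.character(h@representatives), function(s)
    strsplit(s, "")[[1]])
  freq <- vapply(h@members, length, integer(1))

  D <- matrix(0L, k, k, dimnames = list(hids, hids))
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- .mutSteps(reps[[i]], reps[[j]])
    }
  }

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, k, name = hids, type = "real",
                            freq = as.integer(freq))
  inferred_n <- 0L

  if (k >= 2) {
    ut <- which(upper.tri(D), arr.ind = TRUE)
    pairs <- data.frame(i = ut[, 1], j = ut[, 2], d = D[ut])
    pairs <- pairs[pairs$d >= 1L & pairs$d <= limit, , drop = FALSE]
    pairs$f <- freq[pairs$i] + freq[pairs$j]
    pairs <- pairs[order(pairs$d, -pairs$f, hids[pairs$i], hids[pairs$j],
                         method = "radix"), , drop = FALSE]
    for (dclass in unique(pairs$d)) {
      cls <- pairs[pairs$d == dclass, , drop = FALSE]
      comp0 <- igraph::components(g)$membership
      for (r in seq_len(nrow(cls))) {
        a <- hids[cls$i[r]]; b <- hids[cls$j[r]]
        if (comp0[[a]] == comp0[[b]]) next
        steps <- cls$d[r]
        if (steps == 1L) {
          g <- igraph::add_edges(g, c(a, b))
        } else {
          mids <- paste0("i", inferred_n + seq_len(steps - 1L))
          inferred_n <- inferred_n + steps - 1L
          g <- igraph::add_vertices(g, length(mids), name = mids,
                                    type = "inferred", freq = 0L)
          chain <- c(a, rep(mids, each = 2), b)
          g <- igraph::add_edges(g, chain)
        }
      }
    }
  }
  memb <- igraph::components(g)$membership
  real <- memb[hids]
  subs <- split(names(real), unname(real))
  subs <- lapply(subs, function(x) x[order(match(x, hids))])
  # order subnetworks by their first (most frequent) haplotype
  subs <- subs[order(vapply(subs, function(x) match(x[1], hids), integer(1)))]
  names(subs) <- paste0("net", seq_along(subs))
  new("ParsimonyNetwork", graph = g, haplotypes = h,
      connectionLimit = limit, subnetworkIds = subs)
}

#' Minimum mutational gap between subnetworks
#'
#' For each pair of subnetworks, the minimum pairwise mutational difference
#' between their member haplotypes, i.e. the number of steps a connection
#' would need if the limit were raised.
#'
#' @param net a [ParsimonyNetwork] with at least two subnetworks (a single
#'   subnetwork yields an empty table).
#' @return `data.frame` with `subnetwork_1`, `subnetwork_2`, `min_steps`.
#' @export
subnetworkGap <- function(net) {
  stopifnot(is(net, "ParsimonyNetwork"))
  subs <- net@subnetworkIds
  empty <- data.frame(subnetwork_1 = character(),
                      subnetwork_2 = character(), min_steps = integer())
  if (length(subs) < 2) return(empty)
  reps <- lapply(as.character(net@haplotypes@representatives),
                 function(s) strsplit(s, "")[[1]])
  names(reps) <- net@haplotypes@haplotypeIds
  res <- list()
  nm <- names(subs)
  for (i in seq_along(subs)) for (j in seq_len(i - 1L)) {
    steps <- min(vapply(subs[[i]], function(a)
      min(vapply(subs[[j]], function(b)
        .mutSteps(reps[[a]], reps[[b]]), integer(1))), integer(1)))
    res[[length(res) + 1L]] <- data.frame(
      subnetwork_1 = nm[j], subnetwork_2 = nm[i], min_steps = steps)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a parsimony network as edge and node tables
#'
#' @param net a [ParsimonyNetwork].
#' @param edgePath,nodePath output TSV paths.
#' @return Invisibly, the two paths.
#' @export
writeNetwork <- function(net, edgePath, nodePath) {
  g <- net@graph
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2])
  v <- igraph::V(g)
  nodes <- data.frame(node = v$name, type = v$type, freq = v$freq)
  memb <- igraph::components(g)$membership
  subnet_of <- rep(names(net@subnetworkIds),
                   vapply(net@subnetworkIds, length, integer(1)))
  names(subnet_of) <- unlist(net@subnetworkIds, use.names = FALSE)
  first_real <- vapply(net@subnetworkIds, function(x) x[1], character(1))
  comp_name <- setNames(names(net@subnetworkIds), memb[first_real])
  nodes$subnetwork <- unname(comp_name[as.character(memb[nodes$node])])
  write.table(edges, edgePath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(nodes, nodePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges = edgePath, nodes = nodePath))
}

#' Write a haplotype table to TSV
#'
#' @param h a [HaplotypeTable].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeHaplotypeTable <- function(h, path) {
  df <- data.frame(
    haplotype = h@haplotypeIds,
    n = vapply(h@members, length, integer(1)),
    members = vapply(h@members, paste, character(1), collapse = ","),
    species = vapply(h@haplotypeIds, function(id) {
      sc <- h@speciesCounts[h@speciesCounts$haplotype == id, , drop = FALSE]
      paste(sprintf("%s(%d)", sc$species, sc$n), collapse = ";")
    }, character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
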