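#' @include AllGenerics.R
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' BarcodeLibrary: an aligned barcode reference library
#'
#' Holds aligned specimen sequences together with their species, genus and
#' family labels. Sequences are stored as a [Biostrings::DNAStringSet] over
#' the IUPAC DNA alphabet plus the alignment gap `-`; all sequences share one
#' alignment length (inputs are assumed pre-aligned to a common barcode
#' coordinate frame).
#'
#' @slot seqs [Biostrings::DNAStringSet], named by specimen id.
#' @slot meta `data.frame` with columns `specimen_id`, `species`, `genus`,
#'   `family`, parallel to `seqs`.
#'
#' @seealso [readBarcodeLibrary()], [generateLibrary()]
#' @export
setClass("BarcodeLibrary",
  slots = c(seqs = "DNAStringSet", meta = "data.frame"))

setValidity("BarcodeLibrary", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (!identical(nrow(object@meta), n))
    msg <- c(msg, "metadata rows must match number of sequences")
  need <- c("specimen_id", "species", "genus", "family")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste("metadata must have columns:",
                        paste(need, collapse = ", ")))
  else {
    ids <- object@meta$specimen_id
    if (anyDuplicated(ids))
      msg <- c(msg, paste("duplicate specimen_id:",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (!identical(names(object@seqs), ids))
      msg <- c(msg, "sequence names must equal metadata specimen_id, in order")
  }
  if (n > 0) {
    w <- Biostrings::width(object@seqs)
    if (length(unique(w)) != 1L)
      msg <- c(msg, "all sequences must share one alignment length (align first)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BarcodeLibrary number of records.
#' @param x a `BarcodeLibrary`.
#' @export
setMethod("length", "BarcodeLibrary", function(x) length(x@seqs))

#' @describeIn BarcodeLibrary specimen identifiers in library order.
#' @export
setMethod("specimenIds", "BarcodeLibrary", function(x) x@meta$specimen_id)

#' @describeIn BarcodeLibrary aligned sequences.
#' @export
setMethod("sequences", "BarcodeLibrary", function(x) x@seqs)

#' @describeIn BarcodeLibrary specimen metadata table.
#' @export
setMethod("specimenData", "BarcodeLibrary", function(x) x@meta)

#' @describeIn BarcodeLibrary named vector of species labels.
#' @export
setMethod("speciesLabels", "BarcodeLibrary",
  function(x) setNames(x@meta$species, x@meta$specimen_id))

#' @describeIn BarcodeLibrary subset records by index, id or logical vector.
#' @param i index, specimen-id character vector, or logical vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "BarcodeLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@meta$specimen_id)
  new("BarcodeLibrary", seqs = x@seqs[i],
      meta = x@meta[i, , drop = FALSE])
})

setMethod("show", "BarcodeLibrary", function(object) {
  n <- length(object)
  cat("BarcodeLibrary with", n, "record(s)\n")
  if (n > 0) {
    cat("  alignment length:", alignmentLength(object), "columns\n")
    cat("  species:", length(unique(object@meta$species)),
        " genera:", length(unique(object@meta$genus)),
        " families:", length(unique(object@meta$family)), "\n")
  }
})

#' Alignment length of a library
#'
#' @param lib a [BarcodeLibrary].
#' @return Integer number of alignment columns.
#' @export
alignmentLength <- function(lib) {
  stopifnot(is(lib, "BarcodeLibrary"), length(lib) > 0)
  unique(Biostrings::width(lib@seqs))
}

#' K2PDistanceMatrix: pairwise K2P distances with pairwise deletion
#'
#' Symmetric matrix of Kimura 2-parameter distances (proportions, not
#' percent). Cells are `NA` ("undefined") where the pairwise site overlap
#' fell below `minOverlap` or where the K2P logarithm argument was
#' non-positive (saturated pair); undefined cells are never clamped.
#'
#' @slot ids specimen identifiers (row/column order).
#' @slot d numeric matrix of distances; `NA` = undefined.
#' @slot overlap integer matrix of compared-site counts per pair.
#' @slot minOverlap minimum overlap required for a defined distance.
#'
#' @seealso [pairwiseK2P()]
#' @export
setClass("K2PDistanceMatrix",
  slots = c(ids = "character", d = "matrix", overlap = "matrix",
            minOverlap = "integer"))

setValidity("K2PDistanceMatrix", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (!all(dim(object@d) == n) || !all(dim(object@overlap) == n))
    msg <- c(msg, "matrix dimensions must match ids")
  else {
    if (!isTRUE(all.equal(object@d, t(object@d))))
      msg <- c(msg, "distance matrix must be symmetric")
    if (any(diag(object@d) != 0, na.rm = TRUE))
      msg <- c(msg, "diagonal must be zero")
    if (any(object@d < 0, na.rm = TRUE))
      msg <- c(msg, "distances must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn K2PDistanceMatrix specimen ids.
#' @param x a `K2PDistanceMatrix`.
#' @export
setMethod("specimenIds", "K2PDistanceMatrix", function(x) x@ids)

#' @describeIn K2PDistanceMatrix distance matrix (proportions, `NA` =
#'   undefined).
#' @export
setMethod("distances", "K2PDistanceMatrix", function(x) x@d)

#' @describeIn K2PDistanceMatrix per-pair compared-site counts.
#' @export
setMethod("siteOverlap", "K2PDistanceMatrix", function(x) x@overlap)

#' @describeIn K2PDistanceMatrix number of specimens.
#' @export
setMethod("length", "K2PDistanceMatrix", function(x) length(x@ids))

setMethod("show", "K2PDistanceMatrix", function(object) {
  n <- length(object@ids)
  up <- object@d[upper.tri(object@d)]
  cat("K2PDistanceMatrix:", n, "specimens,", length(up), "pairs\n")
  cat("  undefined pairs: ", sum(is.na(up)),
      " (min overlap ", object@minOverlap, ")\n", sep = "")
  if (any(!is.na(up)))
    cat(sprintf("  defined range: %.4f - %.4f\n",
                min(up, na.rm = TRUE), max(up, na.rm = TRUE)))
})

#' Subset a K2P distance matrix
#'
#' @param x a [K2PDistanceMatrix].
#' @param i specimen ids (character) or indices to keep.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "K2PDistanceMatrix", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("K2PDistanceMatrix", ids = x@ids[i],
      d = x@d[i, i, drop = FALSE],
      overlap = x@overlap[i, i, drop = FALSE],
      minOverlap = x@minOverlap)
})

#' HaplotypeTable: collapsed haplotypes of one analysis group
#'
#' Specimens sharing one sequence (under the chosen ambiguity rule) are
#' merged into haplotypes, numbered `h1`, `h2`, ... by descending member
#' count, ties broken by first occurrence in the input.
#'
#' @slot haplotypeIds haplotype ids, `h1`..`hk`.
#' @slot representatives [Biostrings::DNAStringSet] of representative
#'   sequences, named by haplotype id (ambiguities resolved from members
#'   where possible).
#' @slot members named list: haplotype id -> member specimen ids.
#' @slot speciesCounts `data.frame` of per-species member counts
#'   (haplotype, species, n).
#'
#' @seealso [collapseHaplotypes()]
#' @export
setClass("HaplotypeTable",
  slots = c(haplotypeIds = "character", representatives = "DNAStringSet",
            members = "list", speciesCounts = "data.frame"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  if (!identical(object@haplotypeIds, names(object@members)))
    msg <- c(msg, "members must be named by haplotypeIds")
  if (!identical(object@haplotypeIds, names(object@representatives)))
    msg <- c(msg, "representatives must be named by haplotypeIds")
  all_members <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_members))
    msg <- c(msg, "haplotype members must partition the specimen set")
  if (length(msg)) msg else TRUE
})

#' @describeIn HaplotypeTable haplotype ids.
#' @param x a `HaplotypeTable`.
#' @export
setMethod("haplotypeIds", "HaplotypeTable", function(x) x@haplotypeIds)

#' @describeIn HaplotypeTable haplotype membership list.
#' @export
setMethod("haplotypeMembers", "HaplotypeTable", function(x) x@members)

#' @describeIn HaplotypeTable number of haplotypes.
#' @export
setMethod("length", "HaplotypeTable", function(x) length(x@haplotypeIds))

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", length(object@haplotypeIds), "haplotype(s) from",
      length(unlist(object@members, use.names = FALSE)), "specimen(s)\n")
  n <- vapply(object@members, length, integer(1))
  k <- min(5L, length(n))
  if (k > 0)
    cat("  ", paste(sprintf("%s(n=%d)", names(n)[seq_len(k)], n[seq_len(k)]),
                    collapse = " "), if (length(n) > k) "..." else "", "\n")
})

#' ParsimonyNetwork: statistical parsimony haplotype network
#'
#' Haplotypes plus inferred intermediate ("missing") haplotypes connected by
#' edges each representing a single mutational change. Haplotype pairs whose
#' mutational distance exceeds the connection limit are never joined
#' directly, so the network may fall apart into subnetworks.
#'
#' @slot graph an `igraph` graph; vertex attributes `type` (`"real"` or
#'   `"inferred"`) and `freq` (member count, 0 for inferred nodes).
#' @slot haplotypes the [HaplotypeTable] the network was built from.
#' @slot connectionLimit maximum number of mutational steps joined.
#' @slot subnetworkIds list of character vectors: haplotype ids per
#'   connected component.
#'
#' @seealso [buildNetwork()], [connectionLimit()], [subnetworkGap()]
#' @export
setClass("ParsimonyNetwork",
  slots = c(graph = "ANY", haplotypes = "HaplotypeTable",
            connectionLimit = "integer", subnetworkIds = "list"))

#' @describeIn ParsimonyNetwork haplotype ids (real nodes only).
#' @param x a `ParsimonyNetwork`.
#' @export
setMethod("haplotypeIds", "ParsimonyNetwork",
  function(x) x@haplotypes@haplotypeIds)

#' @describeIn ParsimonyNetwork list of subnetwork memberships.
#' @export
setMethod("subnetworks", "ParsimonyNetwork", function(x) x@subnetworkIds)

setMethod("show", "ParsimonyNetwork", function(object) {
  g <- object@graph
  cat("ParsimonyNetwork:", sum(igraph::V(g)$type == "real"), "haplotypes,",
      sum(igraph::V(g)$type == "inferred"), "inferred intermediates,",
      igraph::ecount(g), "single-mutation edges\n")
  cat("  connection limit:", object@connectionLimit, "steps;",
      length(object@subnetworkIds), "subnetwork(s)\n")
})

#' GapPartition: one recursive barcode-gap partition
#'
#' Result of [abgdPartition()] at one (prior, gap width) setting: a group
#' label per specimen, produced by recursively splitting at the first
#' significant gap in the sorted pairwise-distance distribution.
#'
#' @slot ids specimen ids.
#' @slot groups integer group label per specimen (parallel to `ids`).
#' @slot priorP intraspecific-divergence prior (proportion).
#' @slot gapWidthX relative gap width factor.
#' @slot depth recursion depth reached.
#' @slot flags character flags (e.g. `"too_few"` for < 3 specimens).
#' @export
setClass("GapPartition",
  slots = c(ids = "character", groups = "integer", priorP = "numeric",
            gapWidthX = "numeric", depth = "integer", flags = "character"))

#' @describeIn GapPartition named integer group labels.
#' @param x a `GapPartition`.
#' @export
setMethod("groupLabels", "GapPartition",
  function(x) setNames(x@groups, x@ids))

setMethod("show", "GapPartition", function(object) {
  cat(sprintf(
    "GapPartition: %d specimens in %d group(s) (prior P = %.4g, X = %.3g, depth %d)\n",
    length(object@ids), length(unique(object@groups)),
    object@priorP, object@gapWidthX, object@depth))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' SweepResult: gap-partition exploration over a (prior, gap width) grid
#'
#' For every combination of an intraspecific-divergence prior and a relative
#' gap width, records the number of groups in the recursive partition and,
#' per species, whether all of its specimens fell into a single group
#' ("lumped") or at least two groups ("split").
#'
#' @slot priors prior grid (proportions; geometric spacing).
#' @slot gapWidths relative gap width grid (linear spacing).
#' @slot nGroups integer matrix `length(priors) x length(gapWidths)`.
#' @slot lumped logical array `species x priors x gapWidths`; `TRUE` =
#'   lumped.
#' @slot species species labels (dimension 1 of `lumped`).
#'
#' @seealso [apeSweep()], [estimateP()], [renderSweepMatrix()]
#' @export
setClass("SweepResult",
  slots = c(priors = "numeric", gapWidths = "numeric", nGroups = "matrix",
            lumped = "array", species = "character"))

setValidity("SweepResult", function(object) {
  msg <- character()
  if (!all(dim(object@nGroups) == c(length(object@priors),
                                    length(object@gapWidths))))
    msg <- c(msg, "nGroups must be priors x gapWidths")
  if (!all(dim(object@lumped) == c(length(object@species),
                                   length(object@priors),
                                   length(object@gapWidths))))
    msg <- c(msg, "lumped must be species x priors x gapWidths")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult:", length(object@priors), "priors x",
      length(object@gapWidths), "gap widths,",
      length(object@species), "species\n")
  cat(sprintf("  priors: %.4g - %.4g (geometric); gap widths: %.3g - %.3g\n",
              min(object@priors), max(object@priors),
              min(object@gapWidths), max(object@gapWidths)))
  cat("  group counts:", min(object@nGroups), "-", max(object@nGroups), "\n")
})

#' AuditReport: the full library audit
#'
#' Container for all result surfaces produced by [runAudit()]: composition
#' summary, per-species distance summaries, the low-divergence species-pair
#' table, deep-divergence tables split by threshold-cluster count, the
#' monophyly report, threshold clusters, haplotype-network summaries, the
#' divergence-estimator table, and run metadata sufficient to re-run the
#' audit bit-identically.
#'
#' @slot composition one-row `data.frame` (base frequencies, AT content,
#'   length range).
#' @slot speciesSummaries per-species distance summary table.
#' @slot lowDivergencePairs species pairs with minimum interspecific
#'   distance below the threshold.
#' @slot deepOneCluster species with max intraspecific distance above the
#'   threshold and one threshold cluster.
#' @slot deepMultiCluster species with max intraspecific distance above the
#'   threshold and two or more threshold clusters, with estimator P.
#' @slot monophyly per-species monophyly report.
#' @slot clusters specimen-to-cluster assignment.
#' @slot tree the neighbour-joining tree (`ape::phylo`), bootstrap supports
#'   as node labels when computed.
#' @slot networks per-group haplotype network summary table.
#' @slot sweep the [SweepResult] (or `NULL` if the sweep was disabled).
#' @slot estimates per-species intraspecific divergence estimator table.
#' @slot speciesAudit per-species roll-up: table membership and
#'   identification success.
#' @slot metadata list: config, seed, package/R versions, thresholds.
#' @export
setClass("AuditReport",
  slots = c(composition = "data.frame", speciesSummaries = "data.frame",
            lowDivergencePairs = "data.frame", deepOneCluster = "data.frame",
            deepMultiCluster = "data.frame", monophyly = "data.frame",
            clusters = "data.frame", tree = "ANY", networks = "data.frame",
            sweep = "ANY", estimates = "data.frame",
            speciesAudit = "data.frame", metadata = "list"))

setMethod("show", "AuditReport", function(object) {
  cat("AuditReport\n")
  cat("  species:", nrow(object@speciesAudit),
      " specimens:", nrow(object@clusters), "\n")
  cat("  low-divergence pairs:", nrow(object@lowDivergencePairs), "\n")
  cat("  deep-divergence species:", nrow(object@deepOneCluster), "+",
      nrow(object@deepMultiCluster), "(one / multiple clusters)\n")
  cat("  non-monophyletic species:",
      sum(object@monophyly$status == "non-monophyletic"), "\n")
  cat(sprintf("  identification rate: %.1f%%\n",
              object@metadata$identification_rate_pct))
})
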