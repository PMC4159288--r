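#' @include barcodeAudit-package.R
NULL

#' Specimen identifiers of an object
#'
#' @param x a [BarcodeLibrary] or [K2PDistanceMatrix].
#' @return Character vector of specimen identifiers, in object order.
#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))

#' Aligned sequences of a barcode library
#'
#' @param x a [BarcodeLibrary].
#' @return A [Biostrings::DNAStringSet] named by specimen identifier.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Specimen metadata of a barcode library
#'
#' @param x a [BarcodeLibrary].
#' @return A `data.frame` with columns `specimen_id`, `species`, `genus`,
#'   `family`, one row per specimen in library order.
#' @export
setGeneric("specimenData", function(x) standardGeneric("specimenData"))

#' Species label per specimen
#'
#' @param x a [BarcodeLibrary].
#' @return Named character vector (names = specimen ids).
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' Distance matrix accessor
#'
#' @param x a [K2PDistanceMatrix].
#' @return Numeric matrix of pairwise distances (proportions); `NA` marks
#'   undefined cells.
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' Per-pair site overlap accessor
#'
#' @param x a [K2PDistanceMatrix].
#' @return Integer matrix of the number of sites compared per pair after
#'   pairwise deletion.
#' @export
setGeneric("siteOverlap", function(x) standardGeneric("siteOverlap"))

#' Haplotype identifiers
#'
#' @param x a [HaplotypeTable] or [ParsimonyNetwork].
#' @return Character vector of haplotype ids (`h1`, `h2`, ...).
#' @export
setGeneric("haplotypeIds", function(x) standardGeneric("haplotypeIds"))

#' Haplotype membership
#'
#' @param x a [HaplotypeTable].
#' @return Named list mapping haplotype id to member specimen ids.
#' @export
setGeneric("haplotypeMembers", function(x) standardGeneric("haplotypeMembers"))

#' Subnetworks of a parsimony network
#'
#' @param x a [ParsimonyNetwork].
#' @return List of character vectors; each element holds the haplotype ids of
#'   one connected subnetwork.
#' @export
setGeneric("subnetworks", function(x) standardGeneric("subnetworks"))

#' Group labels of a gap partition
#'
#' @param x a [GapPartition].
#' @return Named integer vector mapping specimen id to group number.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
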