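#' @include AllClasses.R
NULL

.validateSeqChars <- function(chars, ids) {
  # chars: character vector of upper-cased sequences
  bad <- regexpr("[^ACGTRYSWKMBDHVN-]", chars)
  hit <- which(bad > 0)
  if (length(hit)) {
    i <- hit[1L]
    stop(sprintf(
      "illegal character '%s' in sequence of specimen '%s' at position %d",
      substr(chars[i], bad[i], bad[i]), ids[i], bad[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a barcode library from sequences and metadata
#'
#' Low-level constructor used by [readBarcodeLibrary()] and the synthetic
#' generator. Sequences are upper-cased and validated against the IUPAC DNA
#' alphabet plus `-`.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   aligned sequences (names = specimen ids).
#' @param meta `data.frame` with columns `specimen_id`, `species`, `genus`,
#'   `family`. Rows are matched to `seqs` by `specimen_id`; record order
#'   follows `seqs`.
#' @return A validated [BarcodeLibrary].
#' @export
BarcodeLibrary <- function(seqs, meta) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named by specimen id")
  seqs <- toupper(seqs)
  .validateSeqChars(seqs, names(seqs))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "genus", "family")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  meta <- meta[, need, drop = FALSE]
  for (cn in need) meta[[cn]] <- as.character(meta[[cn]])

  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate specimen_id in sequences: ", paste(dup, collapse = ", "))
  dup <- unique(meta$specimen_id[duplicated(meta$specimen_id)])
  if (length(dup))
    stop("duplicate specimen_id in metadata: ", paste(dup, collapse = ", "))

  orphan_seq <- setdiff(names(seqs), meta$specimen_id)
  orphan_meta <- setdiff(meta$specimen_id, names(seqs))
  if (length(orphan_seq) || length(orphan_meta))
    stop("sequence/metadata mismatch; FASTA-only ids: [",
         paste(orphan_seq, collapse = ", "), "]; metadata-only ids: [",
         paste(orphan_meta, collapse = ", "), "]")

  meta <- meta[match(names(seqs), meta$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("sequences have unequal lengths (", paste(sort(unique(w)),
         collapse = ", "), "); align to a common coordinate frame first")
  new("BarcodeLibrary", seqs = Biostrings::DNAStringSet(seqs), meta = meta)
}

#' Read a barcode library from FASTA plus metadata TSV
#'
#' FASTA identifiers (first whitespace-delimited token of each header) must
#' resolve 1:1 against the `specimen_id` column of the tab-separated
#' metadata table. Record order follows the FASTA file.
#'
#' @param fastaPath path to an aligned FASTA file (single-line or wrapped).
#' @param metadataPath path to a UTF-8 tab-separated table with a header
#'   row.
#' @param columns named character vector mapping the required fields
#'   `specimen_id`, `species`, `genus`, `family` to column names in the
#'   metadata file (so BOLD-style exports can be mapped without editing the
#'   file).
#' @return A validated [BarcodeLibrary].
#' @examples
#' fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' writeLines(c("specimen_id\tspecies\tgenus\tfamily",
#'              "s1\tGenus una\tGenus\tFam",
#'              "s2\tGenus una\tGenus\tFam"), tsv)
#' lib <- readBarcodeLibrary(fa, tsv)
#' @export
readBarcodeLibrary <- function(fastaPath, metadataPath,
                               columns = c(specimen_id = "specimen_id",
                                           species = "species",
                                           genus = "genus",
                                           family = "family")) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- read.delim(metadataPath, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE,
                     fileEncoding = "UTF-8")
  need <- c("specimen_id", "species", "genus", "family")
  if (!all(need %in% names(columns)))
    stop("'columns' must map all of: ", paste(need, collapse = ", "))
  miss <- setdiff(unname(columns[need]), names(meta))
  if (length(miss))
    stop("metadata file is missing column(s): ", paste(miss, collapse = ", "))
  mapped <- data.frame(specimen_id = meta[[columns[["specimen_id"]]]],
                       species = meta[[columns[["species"]]]],
                       genus = meta[[columns[["genus"]]]],
                       family = meta[[columns[["family"]]]],
                       stringsAsFactors = FALSE)
  BarcodeLibrary(as.character(seqs), mapped)
}

#' Write a barcode library to FASTA plus metadata TSV
#'
#' Inverse of [readBarcodeLibrary()]: re-reading the two files yields a
#' library with byte-identical sequences and labels.
#'
#' @param lib a [BarcodeLibrary].
#' @param fastaPath,metadataPath output paths.
#' @return Invisibly, the two paths.
#' @export
writeBarcodeLibrary <- function(lib, fastaPath, metadataPath) {
  stopifnot(is(lib, "BarcodeLibrary"))
  Biostrings::writeXStringSet(lib@seqs, fastaPath)
  write.table(lib@meta, metadataPath, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(fasta = fastaPath, metadata = metadataPath))
}

#' Informative length per record
#'
#' The number of non-gap, non-N characters per sequence. Other IUPAC
#' ambiguity codes count toward the informative length (they are real reads,
#' just uncertain ones) but are excluded from composition and from pairwise
#' distance computation.
#'
#' @param lib a [BarcodeLibrary].
#' @return Named integer vector.
#' @export
informativeLength <- function(lib) {
  stopifnot(is(lib, "BarcodeLibrary"))
  w <- Biostrings::width(lib@seqs) -
    Biostrings::letterFrequency(lib@seqs, "N")[, 1L] -
    Biostrings::letterFrequency(lib@seqs, "-")[, 1L]
  setNames(as.integer(w), specimenIds(lib))
}

#' Filter records by minimum informative length
#'
#' Keeps records whose informative base count (non-gap, non-N) is at least
#' `minBases`. The default of 401 retains fragments of more than 400 bases,
#' i.e. more than ~60% of the full 658-column barcode.
#'
#' @param lib a [BarcodeLibrary].
#' @param minBases minimum informative base count (default 401).
#' @return The filtered [BarcodeLibrary]; record order preserved. An empty
#'   result is not an error but is reported via a message.
#' @export
filterMinLength <- function(lib, minBases = 401) {
  stopifnot(is(lib, "BarcodeLibrary"), minBases >= 1)
  keep <- informativeLength(lib) >= minBases
  out <- lib[which(keep)]
  if (length(out) == 0L)
    message("filterMinLength: no records with >= ", minBases,
            " informative bases remain")
  else if (any(!keep))
    message("filterMinLength: removed ", sum(!keep), " of ", length(lib),
            " record(s) below ", minBases, " informative bases")
  out
}

#' Base composition summary
#'
#' Per-sequence A/C/G/T frequencies over unambiguous positions, combined
#' either as the unweighted mean across sequences (default; one sequence,
#' one vote) or pooled over all bases. Sequences without a single
#' unambiguous position are excluded with a warning.
#'
#' @param lib a [BarcodeLibrary].
#' @param method `"per-sequence"` (default) or `"pooled"`.
#' @return One-row `data.frame`: `freq_A`, `freq_C`, `freq_G`, `freq_T`,
#'   `at_content` (fractions), `n_sequences`, `length_min`, `length_max`
#'   (informative base counts).
#' @export
compositionSummary <- function(lib, method = c("per-sequence", "pooled")) {
  stopifnot(is(lib, "BarcodeLibrary"), length(lib) > 0)
  method <- match.arg(method)
  counts <- Biostrings::letterFrequency(lib@seqs, c("A", "C", "G", "T"))
  tot <- rowSums(counts)
  empty <- tot == 0
  if (any(empty)) {
    warning("excluding ", sum(empty),
            " sequence(s) with no unambiguous position from composition")
    counts <- counts[!empty, , drop = FALSE]
    tot <- tot[!empty]
  }
  if (nrow(counts) == 0L) stop("no sequence with unambiguous positions")
  freq <- if (method == "per-sequence") colMeans(counts / tot)
          else colSums(counts) / sum(tot)
  il <- informativeLength(lib)
  data.frame(freq_A = unname(freq["A"]), freq_C = unname(freq["C"]),
             freq_G = unname(freq["G"]), freq_T = unname(freq["T"]),
             at_content = unname(freq["A"] + freq["T"]),
             n_sequences = length(lib),
             length_min = min(il), length_max = max(il))
}
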