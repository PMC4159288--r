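#' @include AllClasses.R
NULL

# K2P closed form from transition proportion P, transversion proportion Q.
# Returns NA when either logarithm argument is non-positive (saturation).
.k2pFromPQ <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  d <- ifelse(ok,
              pmax(0, -0.5 * log(pmax(w1, 1e-300) * sqrt(pmax(w2, 1e-300)))),
              NA_real_)
  d
}

# Pairwise transition/transversion/overlap counts for a character matrix
# (rows = sequences, columns = aligned sites) via indicator cross-products.
# Sites where either sequence is not A/C/G/T are deleted pairwise.
.pairCounts <- function(mat) {
  ind <- lapply(c("A", "C", "G", "T"), function(b) (mat == b) + 0)
  names(ind) <- c("A", "C", "G", "T")
  U <- ind$A + ind$C + ind$G + ind$T
  overlap <- tcrossprod(U)
  matches <- tcrossprod(ind$A) + tcrossprod(ind$C) +
    tcrossprod(ind$G) + tcrossprod(ind$T)
  transitions <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  transversions <- overlap - matches - transitions
  list(overlap = overlap, transitions = transitions,
       transversions = transversions)
}

# Character matrix from sequences; rows named by id.
.seqMatrix <- function(seqs) {
  if (is(seqs, "XStringSet")) {
    m <- as.matrix(seqs)
  } else {
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  m
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence is not an unambiguous A/C/G/T (gaps, Ns and
#' all other IUPAC ambiguity codes) are deleted pairwise. Over the remaining
#' L sites, with transition proportion P and transversion proportion Q,
#' \deqn{d = -\tfrac12 \ln\left((1-2P-Q)\sqrt{1-2Q}\right).}
#' The distance is undefined (`NA`) when L < `minOverlap` or when either
#' logarithm argument is non-positive (saturated pair); saturated pairs are
#' never clamped.
#'
#' @param seqA,seqB equal-length aligned sequences (single strings or
#'   [Biostrings::DNAString]).
#' @param minOverlap minimum number of compared sites for a defined
#'   distance (default 300).
#' @return Distance as a proportion (`NA` if undefined), with attributes
#'   `overlap`, `P`, `Q` and, when undefined, `reason` (`"overlap"` or
#'   `"saturated"`).
#' @examples
#' k2pDistance("AATTCCGG", "AGTTCCGA", minOverlap = 1)  # 2 transitions
#' @export
k2pDistance <- function(seqA, seqB, minOverlap = 300) {
  a <- strsplit(toupper(as.character(seqA)), "")[[1]]
  b <- strsplit(toupper(as.character(seqB)), "")[[1]]
  if (length(a) != length(b))
    stop("sequences must be aligned to equal length (", length(a),
         " vs ", length(b), ")")
  bases <- c("A", "C", "G", "T")
  use <- a %in% bases & b %in% bases
  L <- sum(use)
  if (L < minOverlap)
    return(structure(NA_real_, overlap = L, P = NA_real_, Q = NA_real_,
                     reason = "overlap"))
  a <- a[use]; b <- b[use]
  diffs <- a != b
  purine <- c("A", "G")
  ts <- sum(diffs & (a %in% purine) == (b %in% purine))
  tv <- sum(diffs) - ts
  P <- ts / L; Q <- tv / L
  d <- .k2pFromPQ(P, Q)
  structure(d, overlap = L, P = P, Q = Q,
            reason = if (is.na(d)) "saturated" else NULL)
}

#' Pairwise K2P distance matrix for a library
#'
#' Computes all n(n-1)/2 pairwise K2P distances under pairwise deletion.
#' Cells with insufficient overlap or a saturated log argument are recorded
#' as undefined (`NA`); the per-pair overlap matrix is kept alongside so the
#' reason is recoverable.
#'
#' @param lib a [BarcodeLibrary] with at least two records.
#' @param minOverlap minimum compared-site count per pair (default 300).
#' @return A [K2PDistanceMatrix].
#' @export
pairwiseK2P <- function(lib, minOverlap = 300) {
  stopifnot(is(lib, "BarcodeLibrary"), length(lib) >= 2)
  mat <- .seqMatrix(sequences(lib))
  k <- .k2pEngine(mat, minOverlap)
  nun <- sum(is.na(k$d[upper.tri(k$d)]))
  if (nun > 0)
    message("pairwiseK2P: ", nun, " undefined pair(s) (overlap < ",
            minOverlap, " or saturated)")
  new("K2PDistanceMatrix", ids = rownames(mat), d = k$d,
      overlap = k$overlap, minOverlap = as.integer(minOverlap))
}

# Distance engine on a character matrix (shared with the bootstrap).
.k2pEngine <- function(mat, minOverlap) {
  pc <- .pairCounts(mat)
  O <- pc$overlap
  P <- ifelse(O > 0, pc$transitions / O, NA_real_)
  Q <- ifelse(O > 0, pc$transversions / O, NA_real_)
  d <- .k2pFromPQ(P, Q)
  d[O < minOverlap] <- NA_real_
  diag(d) <- 0
  storage.mode(O) <- "integer"
  dimnames(d) <- dimnames(O) <- list(rownames(mat), rownames(mat))
  list(d = d, overlap = O)
}

#' Per-species distance summaries
#'
#' For every species: number of specimens, mean and maximum intraspecific
#' K2P distance (the maximum is the MPD), and the nearest-neighbour species
#' with its minimum interspecific distance. Undefined pairs are skipped;
#' species whose intraspecific pairs are all undefined are flagged.
#'
#' @param m a [K2PDistanceMatrix].
#' @param species named character vector mapping every specimen id in `m`
#'   to a species label (e.g. from [speciesLabels()]).
#' @return `data.frame` with columns `species`, `n_specimens`,
#'   `mean_intra`, `max_intra`, `nn_species`, `nn_distance` (percent),
#'   `n_undefined_intra`, `all_intra_undefined`. `mean_intra`/`max_intra`
#'   are `NA` for n = 1.
#' @export
speciesSummaries <- function(m, species) {
  stopifnot(is(m, "K2PDistanceMatrix"))
  ids <- specimenIds(m)
  if (!all(ids %in% names(species)))
    stop("every specimen id must be labelled; missing: ",
         paste(setdiff(ids, names(species)), collapse = ", "))
  sp <- unname(species[ids])
  d <- distances(m) * 100  # report percent
  sps <- sort(unique(sp), method = "radix")
  out <- lapply(sps, function(s) {
    i <- which(sp == s)
    n <- length(i)
    intra <- if (n >= 2) d[i, i][upper.tri(d[i, i, drop = FALSE])] else numeric()
    inter <- d[i, -i, drop = FALSE]
    nnd <- NA_real_; nns <- NA_character_
    if (length(inter) && any(!is.na(inter))) {
      j <- which(inter == min(inter, na.rm = TRUE), arr.ind = TRUE)
      cand <- sort(unique(sp[-i][j[, 2]]), method = "radix")
      nns <- cand[1L]
      nnd <- min(inter, na.rm = TRUE)
    }
    data.frame(species = s, n_specimens = n,
               mean_intra = if (any(!is.na(intra))) mean(intra, na.rm = TRUE) else NA_real_,
               max_intra = if (any(!is.na(intra))) max(intra, na.rm = TRUE) else NA_real_,
               nn_species = nns, nn_distance = nnd,
               n_undefined_intra = sum(is.na(intra)),
               all_intra_undefined = n >= 2 && all(is.na(intra)))
  })
  res <- do.call(rbind, out)
  if (any(res$all_intra_undefined))
    message("speciesSummaries: all intraspecific pairs undefined for: ",
            paste(res$species[res$all_intra_undefined], collapse = ", "))
  rownames(res) <- NULL
  res
}

#' Species pairs with low interspecific divergence
#'
#' All unordered species pairs whose minimum pairwise interspecific K2P
#' distance is below `threshold` percent, sorted ascending by distance with
#' alphabetical tie-breaks. Pairs sharing an identical haplotype appear
#' with distance 0.
#'
#' @param m a [K2PDistanceMatrix].
#' @param species named character vector (specimen id -> species).
#' @param threshold percent threshold (default 2.2).
#' @return `data.frame` with `species_1`, `species_2` (alphabetical within
#'   pair) and `min_distance` (percent).
#' @export
lowDivergencePairs <- function(m, species, threshold = 2.2) {
  stopifnot(is(m, "K2PDistanceMatrix"))
  ids <- specimenIds(m)
  sp <- unname(species[ids])
  if (length(unique(sp)) < 2) stop("need at least two species")
  d <- distances(m) * 100
  sps <- sort(unique(sp), method = "radix")
  res <- list()
  for (i in seq_along(sps)) for (j in seq_len(i - 1L)) {
    a <- which(sp == sps[i]); b <- which(sp == sps[j])
    sub <- d[a, b, drop = FALSE]
    if (all(is.na(sub))) next
    mn <- min(sub, na.rm = TRUE)
    if (mn < threshold)
      res[[length(res) + 1L]] <- data.frame(
        species_1 = sps[j], species_2 = sps[i], min_distance = mn)
  }
  if (!length(res))
    return(data.frame(species_1 = character(), species_2 = character(),
                      min_distance = numeric()))
  res <- do.call(rbind, res)
  res <- res[order(res$min_distance, res$species_1, res$species_2,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Species with deep intraspecific divergence
#'
#' Species whose maximum intraspecific pairwise distance (MPD) exceeds
#' `threshold` percent, sorted ascending by MPD.
#'
#' @param summaries output of [speciesSummaries()].
#' @param threshold percent threshold (default 2.2).
#' @return Subset of `summaries` (columns `species`, `n_specimens`,
#'   `mean_intra`, `max_intra`), ascending by `max_intra`.
#' @export
deepDivergenceSpecies <- function(summaries, threshold = 2.2) {
  keep <- !is.na(summaries$max_intra) & summaries$max_intra > threshold
  res <- summaries[keep, c("species", "n_specimens", "mean_intra",
                           "max_intra"), drop = FALSE]
  res <- res[order(res$max_intra, res$species, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a distance matrix to TSV
#'
#' @param m a [K2PDistanceMatrix].
#' @param path output path.
#' @param format `"square"` (ids in header and first column) or `"long"`
#'   (`id_1`, `id_2`, `distance`, `overlap`; upper triangle only).
#' @return Invisibly, `path`.
#' @export
writeDistanceMatrix <- function(m, path, format = c("square", "long")) {
  stopifnot(is(m, "K2PDistanceMatrix"))
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(specimen_id = m@ids,
                     formatC(m@d, format = "f", digits = 6),
                     check.names = FALSE)
    names(df) <- c("specimen_id", m@ids)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ut <- which(upper.tri(m@d), arr.ind = TRUE)
    df <- data.frame(id_1 = m@ids[ut[, 1]], id_2 = m@ids[ut[, 2]],
                     distance = m@d[ut], overlap = m@overlap[ut])
    df <- df[order(df$id_1, df$id_2, method = "radix"), , drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
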