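#' @include distances.R
NULL

# ---- internal recursive gap engine ------------------------------------
#
# All quantities that do not depend on the prior or the gap width factor
# (sorted distances, gap widths, local scales, the single-linkage
# dendrogram, components per chosen gap) are cached per specimen subset, so
# a full (prior x gap width) sweep revisits each subset's geometry once.

.subsetKey <- function(idx) paste(idx, collapse = ",")

.subsetEntry <- function(idx, d, cache) {
  key <- .subsetKey(idx)
  e <- cache[[key]]
  if (!is.null(e)) return(e)
  sub <- d[idx, idx, drop = FALSE]
  ut <- sub[upper.tri(sub)]
  ds <- sort(ut[!is.na(ut)])
  ng <- max(length(ds) - 1L, 0L)
  if (ng > 0) {
    gaps <- ds[-1L] - ds[-length(ds)]
    uppers <- ds[-1L]
    # local scale: mean width of the other gaps in a centered rank window
    # of w = max(10, 5% of the number of distances) gaps; the candidate gap
    # itself is excluded from its own scale.
    w <- max(10L, ceiling(0.05 * length(ds)))
    half <- w %/% 2L
    cs <- cumsum(c(0, gaps))
    lo <- pmax(seq_len(ng) - half, 1L)
    hi <- pmin(seq_len(ng) + half, ng)
    tot <- cs[hi + 1L] - cs[lo]
    cnt <- hi - lo  # window size minus the candidate itself
    scales <- ifelse(cnt > 0, (tot - gaps) / cnt, 0)
  } else {
    gaps <- uppers <- scales <- numeric()
  }
  hc <- NULL
  if (length(idx) >= 3) {
    subh <- sub
    subh[is.na(subh)] <- 1e9  # undefined pairs never link
    hc <- hclust(as.dist(subh), method = "single")
  }
  e <- list(idx = idx, ds = ds, gaps = gaps, uppers = uppers,
            scales = scales, hc = hc, comps = list())
  cache[[key]] <- e
  e
}

# Components of the sub-threshold graph at the cutoff of gap `ci`
# (single-linkage dendrogram cut at height ds[ci], i.e. pairs with
# d <= lower gap endpoint are linked). Cached per (subset, gap).
.gapComponents <- function(e, ci, cache) {
  key <- .subsetKey(e$idx)
  ck <- as.character(ci)
  got <- cache[[key]]$comps[[ck]]
  if (!is.null(got)) return(got)
  memb <- cutree(e$hc, h = e$ds[ci])
  groups <- split(e$idx, memb)
  names(groups) <- NULL
  cache[[key]]$comps[[ck]] <- groups
  groups
}

.sigIdx <- function(e, xw) {
  which(e$gaps > 0 & e$gaps > xw * e$scales)
}

# Recursive partition of `idx`; returns list(groups = list of index
# vectors, depth = recursion depth reached).
.partitionRec <- function(idx, prior, xw, d, cache, depth = 1L) {
  if (length(idx) < 3)
    return(list(groups = list(idx), depth = depth))
  e <- .subsetEntry(idx, d, cache)
  cand <- .sigIdx(e, xw)
  cand <- cand[e$uppers[cand] > prior]
  for (ci in cand) {
    groups <- .gapComponents(e, ci, cache)
    if (length(groups) > 1L) {
      out <- lapply(groups, .partitionRec, prior = prior, xw = xw, d = d,
                    cache = cache, depth = depth + 1L)
      return(list(groups = do.call(c, lapply(out, `[[`, "groups")),
                  depth = max(vapply(out, `[[`, integer(1), "depth"))))
    }
  }
  list(groups = list(idx), depth = depth)
}

#' Recursive barcode-gap partition
#'
#' Re-implementation of automatic barcode gap discovery: all defined
#' pairwise distances are sorted; a gap between consecutive sorted
#' distances is *significant* when its width exceeds `gapWidthX` times the
#' local average gap width (mean of the other gaps in a centered rank
#' window of `max(10, 5%%)` of the distances), and is a *candidate* when
#' its upper endpoint exceeds the intraspecific prior `priorP` (distances
#' up to the prior are assumed intraspecific, so only gaps reaching beyond
#' it can be the barcode gap). The first candidate gap splits the set into
#' the connected components linking pairs below the gap; the procedure
#' recurses independently within each group until no significant gap
#' remains or a group has fewer than 3 specimens. With no candidate at the
#' top level the whole set is one group.
#'
#' @param m a [K2PDistanceMatrix].
#' @param priorP intraspecific-divergence prior, as a proportion in (0, 1).
#' @param gapWidthX relative gap width factor (> 0); 1.5 is the
#'   conventional default, smaller values admit smaller gaps.
#' @return A [GapPartition]. Fewer than 3 specimens give a single group
#'   flagged `"too_few"`.
#' @export
abgdPartition <- function(m, priorP, gapWidthX = 1.5) {
  stopifnot(is(m, "K2PDistanceMatrix"))
  if (!(priorP > 0 && priorP < 1)) stop("priorP must be in (0, 1)")
  if (!(gapWidthX > 0)) stop("gapWidthX must be > 0")
  ids <- specimenIds(m)
  n <- length(ids)
  if (n < 3) {
    return(new("GapPartition", ids = ids, groups = rep(1L, n),
               priorP = priorP, gapWidthX = gapWidthX, depth = 1L,
               flags = "too_few"))
  }
  cache <- new.env(parent = emptyenv())
  res <- .partitionRec(seq_len(n), priorP, gapWidthX, distances(m), cache)
  groups <- integer(n)
  for (g in seq_along(res$groups)) groups[res$groups[[g]]] <- g
  # renumber by first occurrence
  groups <- match(groups, unique(groups))
  new("GapPartition", ids = ids, groups = groups, priorP = priorP,
      gapWidthX = gapWidthX, depth = res$depth, flags = character())
}

#' Two-parameter exploration of the gap partitioner
#'
#' Runs the recursive gap partition at every combination of an
#' intraspecific-divergence prior (geometric grid over
#' `[pMin, pMax]`, matching the two orders of magnitude the prior spans)
#' and a relative gap width (linear grid over `[xMin, xMax]`). For each
#' cell the number of groups is recorded, and each species is classified
#' as *lumped* (all its specimens in a single group) or *split*.
#'
#' @param m a [K2PDistanceMatrix].
#' @param species named character vector (specimen id -> species).
#' @param pMin,pMax prior range as proportions (defaults 0.001 and 0.1).
#' @param nSteps number of prior grid points (default 100).
#' @param xMin,xMax relative gap width range (defaults 0.1 and 10).
#' @param nX number of gap width grid points (default 100).
#' @return A [SweepResult].
#' @export
apeSweep <- function(m, species, pMin = 0.001, pMax = 0.1, nSteps = 100,
                     xMin = 0.1, xMax = 10, nX = 100) {
  stopifnot(is(m, "K2PDistanceMatrix"), pMin > 0, pMax > pMin,
            xMin > 0, xMax >= xMin, nSteps >= 1, nX >= 1)
  ids <- specimenIds(m)
  if (!all(ids %in% names(species)))
    stop("every specimen id must be labelled")
  sp <- unname(species[ids])
  sps <- sort(unique(sp), method = "radix")
  spIdx <- lapply(sps, function(s) which(sp == s))
  priors <- if (nSteps == 1) pMin else
    exp(seq(log(pMin), log(pMax), length.out = nSteps))
  gws <- if (nX == 1) xMin else seq(xMin, xMax, length.out = nX)
  n <- length(ids)
  d <- distances(m)
  cache <- new.env(parent = emptyenv())
  nGroups <- matrix(NA_integer_, nSteps, nX)
  lumped <- array(NA, dim = c(length(sps), nSteps, nX),
                  dimnames = list(sps, NULL, NULL))
  for (xi in seq_along(gws)) {
    for (pi in seq_along(priors)) {
      res <- .partitionRec(seq_len(n), priors[pi], gws[xi], d, cache)
      grp <- integer(n)
      for (g in seq_along(res$groups)) grp[res$groups[[g]]] <- g
      nGroups[pi, xi] <- length(res$groups)
      for (k in seq_along(spIdx)) {
        gk <- grp[spIdx[[k]]]
        lumped[k, pi, xi] <- all(gk == gk[1L])
      }
    }
  }
  new("SweepResult", priors = priors, gapWidths = gws, nGroups = nGroups,
      lumped = lumped, species = sps)
}

#' Per-species intraspecific divergence estimator P
#'
#' The smallest grid prior (reported in percent) at which all specimens of
#' a species fall into one group of the recursive gap partition, read from
#' the sweep column whose gap width is closest to `gapWidth` (default 0.1,
#' the most permissive conventional setting). A species lumped already at
#' the smallest grid prior is censored below (`"<0.1"` with the default
#' grid); a species never lumped in range is censored above (`">10"`).
#'
#' @param sweep a [SweepResult].
#' @param species species to report (default: all in the sweep).
#' @param gapWidth requested gap width factor (default 0.1).
#' @return `data.frame` with `species`, `gap_width`, `estimator_P`
#'   (character, censoring rendered as `"<lo"`/`">hi"`), `estimator_value`
#'   (numeric percent, `NA` when censored) and `censored`
#'   (`"none"`, `"below"`, `"above"`).
#' @export
estimateP <- function(sweep, species = NULL, gapWidth = 0.1) {
  stopifnot(is(sweep, "SweepResult"))
  if (is.null(species)) species <- sweep@species
  bad <- setdiff(species, sweep@species)
  if (length(bad))
    stop("species absent from sweep: ", paste(bad, collapse = ", "))
  xi <- which.min(abs(sweep@gapWidths - gapWidth))
  lo <- sprintf("<%.4g", min(sweep@priors) * 100)
  hi <- sprintf(">%.4g", max(sweep@priors) * 100)
  rows <- lapply(species, function(s) {
    lump <- sweep@lumped[s, , xi]
    first <- if (any(lump)) which(lump)[1L] else NA_integer_
    if (is.na(first)) {
      data.frame(species = s, gap_width = sweep@gapWidths[xi],
                 estimator_P = hi, estimator_value = NA_real_,
                 censored = "above")
    } else if (first == 1L) {
      data.frame(species = s, gap_width = sweep@gapWidths[xi],
                 estimator_P = lo, estimator_value = NA_real_,
                 censored = "below")
    } else {
      v <- sweep@priors[first] * 100
      data.frame(species = s, gap_width = sweep@gapWidths[xi],
                 estimator_P = sprintf("%.2f", v), estimator_value = v,
                 censored = "none")
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Render the lumped/split sweep classification as a matrix
#'
#' One matrix per requested gap width: rows are species, columns prior
#' grid points, cells `"lumped"` or `"split"` (the red/blue cells of the
#' matrix plots).
#'
#' @param sweep a [SweepResult].
#' @param gapWidth one or more gap width values (default: smallest in the
#'   grid); each is matched to the nearest grid column.
#' @return A named list of character matrices (names = gap width values).
#' @export
renderSweepMatrix <- function(sweep, gapWidth = min(sweep@gapWidths)) {
  stopifnot(is(sweep, "SweepResult"))
  out <- lapply(gapWidth, function(g) {
    xi <- which.min(abs(sweep@gapWidths - g))
    mat <- ifelse(sweep@lumped[, , xi, drop = FALSE][, , 1], "lumped", "split")
    mat <- matrix(mat, nrow = length(sweep@species),
                  dimnames = list(sweep@species,
                                  sprintf("%.4g", sweep@priors * 100)))
    mat
  })
  names(out) <- sprintf("%.4g", sweep@gapWidths[vapply(gapWidth, function(g)
    which.min(abs(sweep@gapWidths - g)), integer(1))])
  out
}

#' Plot a sweep classification matrix
#'
#' Image plot with species on the y axis and the intraspecific divergence
#' prior on the x axis; lumped cells red, split cells blue.
#'
#' @param sweep a [SweepResult].
#' @param gapWidth gap width to display (nearest grid column).
#' @return Invisibly, the plotted matrix.
#' @export
plotSweepMatrix <- function(sweep, gapWidth = min(sweep@gapWidths)) {
  xi <- which.min(abs(sweep@gapWidths - gapWidth))
  z <- t(sweep@lumped[, , xi, drop = FALSE][, , 1] + 0)
  graphics::image(x = seq_along(sweep@priors), y = seq_along(sweep@species),
                  z = z, col = c("blue", "red"), zlim = c(0, 1),
                  xlab = "prior grid point", ylab = "", axes = FALSE,
                  main = sprintf("gap width X = %.3g", sweep@gapWidths[xi]))
  graphics::axis(1)
  graphics::axis(2, at = seq_along(sweep@species), labels = sweep@species,
                 las = 2, cex.axis = 0.6)
  invisible(z)
}

#' Write the sweep classification to TSV
#'
#' @param sweep a [SweepResult].
#' @param path output path.
#' @param gapWidth gap width column to export (nearest grid column).
#' @return Invisibly, `path`.
#' @export
writeSweepMatrix <- function(sweep, path, gapWidth = min(sweep@gapWidths)) {
  mat <- renderSweepMatrix(sweep, gapWidth)[[1]]
  df <- data.frame(species = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
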