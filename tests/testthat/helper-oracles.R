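# Independent oracles and fixture builders. Everything here is coded
# naively (per-site loops, breadth-first searches) on purpose: the oracles
# must not share code paths with the implementation they check.

# ---- K2P closed-form oracle -------------------------------------------

oracle_k2p <- function(a, b, min_overlap = 1) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(a) == length(b))
  ts <- 0L; tv <- 0L; L <- 0L
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      L <- L + 1L
      if (x != y) {
        transition <- (x == "A" && y == "G") || (x == "G" && y == "A") ||
                      (x == "C" && y == "T") || (x == "T" && y == "C")
        if (transition) ts <- ts + 1L else tv <- tv + 1L
      }
    }
  }
  if (L < min_overlap) return(NA_real_)
  P <- ts / L; Q <- tv / L
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

oracle_pdist <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[use] != b[use]) / sum(use)
}

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = "")

# mutate a fraction of sites uniformly at random (any different base)
mutate_seq <- function(s, n) {
  v <- strsplit(s, "")[[1]]
  sites <- sample(seq_along(v), n)
  for (i in sites) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# ---- fixture builders --------------------------------------------------

make_lib <- function(seqs, species = NULL, genus = NULL, family = NULL) {
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) { ids <- sprintf("s%02d", seq_len(n)); names(seqs) <- ids }
  if (is.null(species)) species <- rep("Genus una", n)
  if (is.null(genus)) genus <- vapply(strsplit(species, " "), `[[`, "", 1)
  if (is.null(family)) family <- rep("Fam", n)
  BarcodeLibrary(seqs, data.frame(specimen_id = ids, species = species,
                                  genus = genus, family = family))
}

make_dmat <- function(d, ids = NULL) {
  n <- nrow(d)
  if (is.null(ids)) ids <- sprintf("t%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  ov <- matrix(658L, n, n)
  new("K2PDistanceMatrix", ids = ids, d = d, overlap = ov,
      minOverlap = 1L)
}

# additive distance matrix from a random unrooted topology
random_additive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
}

# does `tree` display quartet ij|kl? (some bipartition separates i,j from k,l)
displays_quartet <- function(bip, i, j, k, l) {
  for (r in seq_len(nrow(bip))) {
    s <- bip[r, ]
    if ((s[i] && s[j] && !s[k] && !s[l]) ||
        (!s[i] && !s[j] && s[k] && s[l])) return(TRUE)
  }
  FALSE
}

bipartition_matrix <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  m <- matrix(FALSE, length(pp), length(labs), dimnames = list(NULL, labs))
  for (r in seq_along(pp)) m[r, pp[[r]]] <- TRUE
  m
}

# quartet topology implied by a (near-)additive matrix via the four-point
# condition: returns the pair indices grouped with the first taxon
fourpoint_split <- function(d, q) {
  i <- q[1]; j <- q[2]; k <- q[3]; l <- q[4]
  s1 <- d[i, j] + d[k, l]   # ij|kl
  s2 <- d[i, k] + d[j, l]   # ik|jl
  s3 <- d[i, l] + d[j, k]   # il|jk
  which.min(c(s1, s2, s3))
}

# ---- naive recursive gap-partition oracle ------------------------------
# Exhaustive re-statement of the partition rule with plain loops and a
# breadth-first component search (no sorting tricks, no caching).

oracle_gap_partition <- function(d, prior, xw) {
  n <- nrow(d)
  recurse <- function(idx) {
    if (length(idx) < 3) return(list(idx))
    vals <- c()
    for (a in seq_along(idx)) for (b in seq_len(a - 1L))
      if (!is.na(d[idx[a], idx[b]])) vals <- c(vals, d[idx[a], idx[b]])
    ds <- sort(vals)
    k <- length(ds)
    if (k < 2) return(list(idx))
    gaps <- diff(ds)
    w <- max(10L, ceiling(0.05 * k))
    half <- w %/% 2L
    for (gi in seq_along(gaps)) {            # every possible gap position
      if (gaps[gi] <= 0) next
      lo <- max(1L, gi - half); hi <- min(length(gaps), gi + half)
      others <- setdiff(lo:hi, gi)
      scale <- if (length(others)) mean(gaps[others]) else 0
      if (!(gaps[gi] > xw * scale)) next     # not significant
      if (!(ds[gi + 1L] > prior)) next       # below the prior ceiling
      cutoff <- ds[gi]
      # breadth-first components over pairs with d <= cutoff
      comp <- rep(0L, length(idx))
      cid <- 0L
      for (s in seq_along(idx)) {
        if (comp[s] != 0L) next
        cid <- cid + 1L
        queue <- s
        comp[s] <- cid
        while (length(queue)) {
          u <- queue[1]; queue <- queue[-1]
          for (v in seq_along(idx)) {
            duv <- d[idx[u], idx[v]]
            if (comp[v] == 0L && !is.na(duv) && duv <= cutoff) {
              comp[v] <- cid
              queue <- c(queue, v)
            }
          }
        }
      }
      if (cid > 1L) {
        out <- list()
        for (g in seq_len(cid))
          out <- c(out, recurse(idx[comp == g]))
        return(out)
      }
    }
    list(idx)
  }
  groups <- recurse(seq_len(n))
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  match(lab, unique(lab))
}

# ---- statistical-parsimony probability oracle --------------------------
# Direct evaluation: P(no site with >= 2 substitutions) under a Poisson
# per-site load lambda implied by j observed differences over L sites.

oracle_parsimony_limit <- function(L, confidence) {
  best <- 1L
  for (j in seq_len(floor(L / 2))) {
    p <- j / L
    if (p >= 0.75) break
    lambda <- -0.75 * log(1 - 4 * p / 3)
    prob <- (exp(-lambda) * (1 + lambda))^L
    if (prob >= confidence) best <- j else break
  }
  best
}
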