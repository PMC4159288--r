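#' @include library-io.R distances.R
NULL

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

#' Evolve a sequence by a fixed number of substitutions
#'
#' Applies exactly `nSubstitutions` point substitutions at distinct,
#' uniformly chosen sites of the ancestor. At each site a transition is
#' chosen over a transversion with odds `kappa : 1`; the two possible
#' transversion targets are equally likely. Draws come from R's current
#' random stream (seed upstream).
#'
#' @param ancestor a single string (or character vector of bases) over
#'   A/C/G/T.
#' @param nSubstitutions number of substituted sites (0 allowed).
#' @param kappa transition:transversion odds (default 4, typical for
#'   insect mitochondrial COI; `Inf` forces all transitions).
#' @param excludeSites site indices never substituted (used by the
#'   generator to keep within-lineage variation off the sites that define
#'   a planted lineage split, so planted divergences stay exact).
#' @return The derived sequence as a single string.
#' @export
evolveSequence <- function(ancestor, nSubstitutions, kappa = 4,
                           excludeSites = integer()) {
  a <- if (length(ancestor) > 1L) ancestor else
    strsplit(toupper(as.character(ancestor)), "")[[1]]
  if (!all(a %in% .UNAMB)) stop("ancestor must be over A/C/G/T")
  L <- length(a)
  avail <- setdiff(seq_len(L), excludeSites)
  if (nSubstitutions > length(avail))
    stop("cannot place ", nSubstitutions, " substitutions on ",
         length(avail), " available sites")
  if (nSubstitutions > 0) {
    sites <- sample(avail, nSubstitutions)
    pts <- if (is.infinite(kappa)) 1 else kappa / (kappa + 1)
    for (s in sites) {
      base <- a[s]
      a[s] <- if (stats::runif(1) < pts) .TS_PARTNER[[base]]
              else sample(.TV_PARTNERS[[base]], 1L)
    }
  }
  paste(a, collapse = "")
}

# Expected K2P distance for s planted substitutions on L sites at a given
# transition:transversion odds (one hit per site within an evolve call).
.k2pOfSteps <- function(s, L, kappa = 4) {
  pts <- if (is.infinite(kappa)) 1 else kappa / (kappa + 1)
  .k2pFromPQ(pts * s / L, (1 - pts) * s / L)
}

# Smallest substitution count whose expected K2P matches the target (%).
.stepsForK2P <- function(targetPct, L, kappa = 4) {
  target <- targetPct / 100
  smax <- floor(L * 0.7)
  ks <- .k2pOfSteps(seq_len(smax), L, kappa)
  ok <- which(!is.na(ks))
  if (!length(ok) || max(ks[ok]) < target)
    stop("target divergence of ", targetPct,
         "% is unattainable on ", L, " sites")
  which.min(abs(ks - target))
}

#' Scenario configuration for the synthetic-library generator
#'
#' One row of `speciesTable` per species, with columns:
#' `species`, `genus`, `family` (labels), `n_specimens`, `n_haplotypes`,
#' `intra_target_pct` (target maximum intraspecific K2P, percent),
#' `split_pct` (0 = no deep split, otherwise the target K2P between the
#' two planted lineages), `split_steps` (optional exact mutational step
#' count overriding `split_pct`; `NA` = derive from `split_pct`),
#' `sharing_group` (`NA` or a group id; all `core` members of one group
#' share an identical modal haplotype) and `sharing_role` (`"core"` or
#' `"satellite"`; a satellite's haplotypes sit at least one step away from
#' the shared haplotype).
#'
#' @param speciesTable species design table, see above.
#' @param alignmentLength alignment columns (default 658, the full
#'   barcode).
#' @param kappa transition:transversion odds for all evolution steps.
#' @param fracShort fraction of specimens emitted as shorter fragments
#'   (ends replaced by `-`; informative length kept at >= 410 bases).
#' @param fracAmbiguous fraction of specimens carrying 1-5 N sites.
#' @param seed integer seed (mandatory).
#' @param name scenario name.
#' @return A validated `ScenarioConfig` (list-like S4 object).
#' @export
scenarioConfig <- function(speciesTable, alignmentLength = 658, kappa = 4,
                           fracShort = 0, fracAmbiguous = 0, seed,
                           name = "custom") {
  if (missing(seed)) stop("a seed is mandatory")
  st <- as.data.frame(speciesTable, stringsAsFactors = FALSE)
  defaults <- list(n_haplotypes = 1L, intra_target_pct = 0,
                   split_pct = 0, split_steps = NA_integer_,
                   sharing_group = NA_character_, sharing_role = "core",
                   genus = NA_character_, family = NA_character_)
  for (cn in names(defaults)) if (!cn %in% names(st)) st[[cn]] <- defaults[[cn]]
  stopifnot(all(c("species", "n_specimens") %in% names(st)))
  if (anyDuplicated(st$species)) stop("duplicate species in scenario")
  if (any(st$n_specimens < 1)) stop("n_specimens must be >= 1")
  if (any(st$intra_target_pct < 0) || any(st$split_pct < 0))
    stop("divergence targets must be >= 0")
  st$genus[is.na(st$genus)] <- vapply(strsplit(st$species[is.na(st$genus)], " "),
                                      `[[`, character(1), 1L)
  st$family[is.na(st$family)] <- "FamSyn"
  grp <- st$sharing_group[!is.na(st$sharing_group)]
  if (length(grp)) {
    sizes <- table(grp)
    if (any(sizes < 2)) stop("sharing groups need at least 2 species")
  }
  new("ScenarioConfig", speciesTable = st,
      alignmentLength = as.integer(alignmentLength), kappa = kappa,
      fracShort = fracShort, fracAmbiguous = fracAmbiguous,
      seed = as.integer(seed), name = name)
}

#' @rdname scenarioConfig
#' @export
setClass("ScenarioConfig",
  slots = c(speciesTable = "data.frame", alignmentLength = "integer",
            kappa = "numeric", fracShort = "numeric",
            fracAmbiguous = "numeric", seed = "integer", name = "character"))

setMethod("show", "ScenarioConfig", function(object) {
  st <- object@speciesTable
  cat("ScenarioConfig '", object@name, "': ", nrow(st), " species, ",
      sum(st$n_specimens), " specimens, ", object@alignmentLength,
      " columns, seed ", object@seed, "\n", sep = "")
})

#' Generate a synthetic barcode library with planted structure
#'
#' Builds an aligned library whose statistical structure mirrors a real
#' COI-5P reference library: a root sequence with insect-COI base
#' composition (A 31.8%, C 18.6%, G 16.0%, T 33.6%), one ancestor per
#' species (or per sharing group), star-like intraspecific variation with
#' the ancestral haplotype as the modal one, optional deep lineage splits
#' at a planted divergence, species groups sharing an identical haplotype,
#' and optional short fragments and ambiguous sites. Deterministic per
#' seed: the same config yields byte-identical FASTA and truth table.
#'
#' @param cfg a [scenarioConfig()].
#' @return A list with elements `library` (a [BarcodeLibrary]) and `truth`
#'   (a list holding `specimens`, `lineages`, `sharing` and
#'   `speciesExpectations` tables; see the package vignette).
#' @export
generateLibrary <- function(cfg) {
  stopifnot(is(cfg, "ScenarioConfig"))
  st <- cfg@speciesTable
  L <- cfg@alignmentLength
  kappa <- cfg@kappa
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(cfg@seed)

  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(0.318, 0.186, 0.160, 0.336))

  # one ancestor per sharing group, then per non-sharing species
  groups <- unique(st$sharing_group[!is.na(st$sharing_group)])
  group_anc <- list()
  for (g in groups)
    group_anc[[g]] <- evolveSequence(root, sample(35:85, 1L), kappa)

  split_steps_of <- function(row) {
    if (!is.na(row$split_steps)) return(as.integer(row$split_steps))
    if (row$split_pct > 0) return(.stepsForK2P(row$split_pct, L, kappa))
    0L
  }

  seqs <- character(); ids <- character()
  meta <- list(); spec_truth <- list(); lin_truth <- list()
  exp_truth <- list()
  counter <- 0L

  for (r in seq_len(nrow(st))) {
    row <- st[r, ]
    ssteps <- split_steps_of(row)
    if (ssteps + 25 > floor(0.7 * L))
      stop("planted divergence too high for alignment length in species ",
           row$species)

    if (!is.na(row$sharing_group)) {
      anc <- group_anc[[row$sharing_group]]
      if (identical(row$sharing_role, "satellite"))
        anc <- evolveSequence(anc, 1L, kappa)
    } else {
      n_anc <- sample(35:85, 1L)
      if (ssteps > 0) n_anc <- max(n_anc, ssteps + 25L)
      anc <- evolveSequence(root, n_anc, kappa)
    }

    n <- row$n_specimens
    lineage_anc <- list(A = anc)
    lineage_n <- c(A = n)
    realized_split <- NA_real_
    split_sites <- integer()
    if (ssteps > 0) {
      lineage_anc$B <- evolveSequence(anc, ssteps, kappa)
      split_sites <- which(strsplit(lineage_anc$A, "")[[1]] !=
                           strsplit(lineage_anc$B, "")[[1]])
      realized_split <- 100 * as.numeric(
        k2pDistance(lineage_anc$A, lineage_anc$B, minOverlap = 1))
      if (row$split_pct > 0 &&
          abs(realized_split - row$split_pct) / row$split_pct > 0.15)
        warning("realized split ", round(realized_split, 2),
                "% deviates >15% from target in ", row$species)
      nA <- ceiling(n / 2)
      lineage_n <- c(A = nA, B = n - nA)
      lin_truth[[length(lin_truth) + 1L]] <- data.frame(
        species = row$species, lineage_a = "A", lineage_b = "B",
        planted_steps = ssteps, planted_k2p_pct = realized_split)
    }

    nh_total <- max(1L, min(row$n_haplotypes, n))
    kmax <- max(1L, round(row$intra_target_pct / 100 * L / 2))
    # distribute haplotypes over lineages proportionally to specimen counts
    nh_lin <- pmax(round(nh_total * lineage_n / sum(lineage_n)), 1L)

    for (ln in names(lineage_anc)) {
      n_l <- lineage_n[[ln]]
      if (n_l == 0L) next
      n_sat <- min(nh_lin[[ln]] - 1L, n_l - 1L)
      haps <- c(lineage_anc[[ln]],
                if (n_sat > 0)
                  vapply(seq_len(n_sat), function(i)
                    evolveSequence(lineage_anc[[ln]],
                                   sample.int(kmax, 1L), kappa,
                                   excludeSites = split_sites),
                    character(1)))
      hap_counts <- c(n_l - n_sat, rep(1L, n_sat))  # modal first
      assign_h <- rep(seq_along(haps), hap_counts)
      for (a in assign_h) {
        counter <- counter + 1L
        id <- sprintf("SYN%04d", counter)
        ids <- c(ids, id)
        seqs <- c(seqs, haps[a])
        meta[[length(meta) + 1L]] <- data.frame(
          specimen_id = id, species = row$species, genus = row$genus,
          family = row$family)
        spec_truth[[length(spec_truth) + 1L]] <- data.frame(
          specimen_id = id, species = row$species, lineage = ln)
      }
    }

    n_cores_in_group <- if (!is.na(row$sharing_group))
      sum(st$sharing_group %in% row$sharing_group &
          st$sharing_role == "core") else 0L
    shares <- !is.na(row$sharing_group) &&
      identical(row$sharing_role, "core") && n_cores_in_group >= 2
    # Core species keep specimens on a haplotype also carried by another
    # species: after collapsing zero-length tree edges those specimens sit
    # in one polytomy with the other species, so monophyly fails
    # deterministically. A satellite species sits only 1-2 steps off the
    # shared blob, where single-site homoplasy can tip the resolution
    # either way, so its monophyly is not asserted (NA).
    in_group <- !is.na(row$sharing_group)
    exp_mono <- if (!in_group) TRUE else if (shares) FALSE else NA
    exp_truth[[length(exp_truth) + 1L]] <- data.frame(
      species = row$species, n_specimens = n,
      expected_monophyletic = exp_mono,
      expected_clusters = 1L + (ssteps > 0 &&
                                !is.na(realized_split) &&
                                realized_split > 2.2),
      shares_haplotype = shares,
      expected_low_pair = in_group,
      planted_split_pct = realized_split)
  }

  names(seqs) <- ids
  # short fragments: trim ends to '-' keeping >= 410 informative bases
  if (cfg@fracShort > 0) {
    short <- which(stats::runif(length(seqs)) < cfg@fracShort)
    for (i in short) {
      target <- sample(410:(L - 1), 1L)
      cut <- L - target
      front <- sample.int(cut + 1L, 1L) - 1L
      back <- cut - front
      s <- strsplit(seqs[i], "")[[1]]
      if (front > 0) s[seq_len(front)] <- "-"
      if (back > 0) s[(L - back + 1L):L] <- "-"
      seqs[i] <- paste(s, collapse = "")
    }
  }
  if (cfg@fracAmbiguous > 0) {
    amb <- which(stats::runif(length(seqs)) < cfg@fracAmbiguous)
    for (i in amb) {
      s <- strsplit(seqs[i], "")[[1]]
      cand <- which(s != "-")
      pos <- sample(cand, min(sample.int(5L, 1L), length(cand)))
      s[pos] <- "N"
      seqs[i] <- paste(s, collapse = "")
    }
  }

  lib <- BarcodeLibrary(seqs, do.call(rbind, meta))
  truth <- list(
    specimens = {
      df <- do.call(rbind, spec_truth); rownames(df) <- NULL; df
    },
    lineages = if (length(lin_truth)) {
      df <- do.call(rbind, lin_truth); rownames(df) <- NULL; df
    } else data.frame(species = character(), lineage_a = character(),
                      lineage_b = character(), planted_steps = integer(),
                      planted_k2p_pct = numeric()),
    sharing = {
      sh <- st[!is.na(st$sharing_group),
               c("sharing_group", "species", "sharing_role")]
      rownames(sh) <- NULL
      names(sh) <- c("group", "species", "role")
      sh
    },
    speciesExpectations = {
      df <- do.call(rbind, exp_truth); rownames(df) <- NULL; df
    },
    scenario = cfg@name, seed = cfg@seed)
  list(library = lib, truth = truth)
}

#' Write a truth table to TSV and JSON
#'
#' @param truth the `truth` element of [generateLibrary()] output.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeTruthTable <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("specimens", "lineages", "sharing", "speciesExpectations"))
    write.table(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Preset synthetic scenarios
#'
#' Named scenario configurations covering the structural regimes a barcode
#' audit must detect:
#' \describe{
#'   \item{clean_library}{8 well-separated species, 5 specimens each; no
#'     planted conflicts.}
#'   \item{haplotype_sharing}{a 4-species group whose first three species
#'     share one dominant haplotype while the fourth sits at least one
#'     step away, plus a 2-species pair sharing a haplotype with two
#'     satellite haplotypes 1-3 steps out.}
#'   \item{deep_split_5 / deep_split_8 / deep_split_23}{a single species
#'     with two planted lineages at ~5%, ~8% or ~23% K2P.}
#'   \item{orius}{a single species whose two lineages sit exactly 29
#'     mutational steps apart (5 haplotypes, 10 specimens).}
#'   \item{mixed_full}{~40 species / ~160 specimens combining all regimes,
#'     with 30% shorter fragments and occasional ambiguities, for
#'     end-to-end runs.}
#' }
#'
#' @param seed integer seed stored in every config (default 42).
#' @return Named list of `ScenarioConfig` objects.
#' @export
presetScenarios <- function(seed = 42) {
  sp <- function(...) data.frame(..., stringsAsFactors = FALSE)
  # rbind with column union (missing design columns get their defaults)
  rbind2 <- function(...) {
    dfs <- list(...)
    cols <- unique(unlist(lapply(dfs, names)))
    filled <- lapply(dfs, function(d) {
      for (cn in setdiff(cols, names(d)))
        d[[cn]] <- switch(cn,
          split_steps = NA_integer_, sharing_group = NA_character_,
          sharing_role = "core", split_pct = 0, 0)
      d[, cols, drop = FALSE]
    })
    do.call(rbind, filled)
  }

  clean <- sp(species = sprintf("Genus%02d cleanus", 1:8),
              genus = sprintf("Genus%02d", 1:8),
              family = paste0("Fam", rep(1:4, each = 2)),
              n_specimens = 5L, n_haplotypes = 2L,
              intra_target_pct = rep(c(0.3, 0.8), 4), split_pct = 0)

  sharing <- rbind2(
    sp(species = paste("Nabisyn", c("rugosulus", "brevisyn", "ericetosyn",
                                    "pseudosyn")),
       genus = "Nabisyn", family = "FamN",
       n_specimens = c(6L, 11L, 5L, 11L), n_haplotypes = c(1L, 2L, 1L, 2L),
       intra_target_pct = c(0, 0.3, 0, 0.3), split_pct = 0,
       sharing_group = "share1",
       sharing_role = c("core", "core", "core", "satellite")),
    sp(species = paste("Charasyn", c("gyllenhalinus", "weberinus")),
       genus = "Charasyn", family = "FamC",
       n_specimens = c(3L, 6L), n_haplotypes = c(3L, 1L),
       intra_target_pct = c(0.8, 0), split_pct = 0,
       sharing_group = "share2", sharing_role = c("core", "core")))

  deep <- function(pct, n, nh, name) sp(
    species = name, genus = strsplit(name, " ")[[1]][1], family = "FamD",
    n_specimens = n, n_haplotypes = nh, intra_target_pct = 0.5,
    split_pct = pct)

  orius <- sp(species = "Oriusyn nigrellus", genus = "Oriusyn",
              family = "FamO", n_specimens = 10L, n_haplotypes = 5L,
              intra_target_pct = 0.5, split_pct = 0,
              split_steps = 29L)

  mixed_clean <- sp(species = sprintf("Genus%02d mixtus", 1:30),
                    genus = sprintf("Genus%02d", 1:30),
                    family = paste0("Fam", rep(1:6, 5)),
                    n_specimens = rep(c(3L, 4L, 3L), 10),
                    n_haplotypes = rep(c(1L, 2L, 3L), 10),
                    intra_target_pct = rep(c(0.2, 0.6, 1.2), 10),
                    split_pct = 0)
  mixed <- rbind2(
    mixed_clean,
    sp(species = paste("Genus31", c("primus", "secundus", "tertius",
                                    "quartus")),
       genus = "Genus31", family = "Fam7",
       n_specimens = c(5L, 6L, 8L, 6L), n_haplotypes = c(1L, 2L, 1L, 1L),
       intra_target_pct = c(0, 0.3, 0, 0), split_pct = 0,
       sharing_group = "share1",
       sharing_role = c("core", "core", "core", "satellite")),
    sp(species = paste("Genus32", c("primus", "secundus")),
       genus = "Genus32", family = "Fam7",
       n_specimens = c(3L, 6L), n_haplotypes = c(3L, 1L),
       intra_target_pct = c(0.8, 0), split_pct = 0,
       sharing_group = "share2", sharing_role = c("core", "core")),
    sp(species = "Genus33 quintus", genus = "Genus33", family = "Fam8",
       n_specimens = 8L, n_haplotypes = 3L, intra_target_pct = 0.5,
       split_pct = 5),
    sp(species = "Genus34 sextus", genus = "Genus34", family = "Fam8",
       n_specimens = 10L, n_haplotypes = 4L, intra_target_pct = 0.5,
       split_pct = 8),
    sp(species = "Genus35 septimus", genus = "Genus35", family = "Fam8",
       n_specimens = 7L, n_haplotypes = 3L, intra_target_pct = 0.4,
       split_pct = 23))

  list(
    clean_library = scenarioConfig(clean, seed = seed,
                                   name = "clean_library"),
    haplotype_sharing = scenarioConfig(sharing, seed = seed,
                                       name = "haplotype_sharing"),
    deep_split_5 = scenarioConfig(deep(5, 12L, 4L, "Splitsyn quintanus"),
                                  seed = seed, name = "deep_split_5"),
    deep_split_8 = scenarioConfig(deep(8, 10L, 4L, "Splitsyn octanus"),
                                  seed = seed, name = "deep_split_8"),
    deep_split_23 = scenarioConfig(deep(23, 7L, 3L, "Splitsyn avenius"),
                                   seed = seed, name = "deep_split_23"),
    orius = scenarioConfig(orius, seed = seed, name = "orius"),
    mixed_full = scenarioConfig(mixed, fracShort = 0.3,
                                fracAmbiguous = 0.05, seed = seed,
                                name = "mixed_full"))
}
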