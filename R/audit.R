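#' @include tree-cluster.R gap-partition.R parsimony-network.R synthetic-data.R
NULL

#' Audit configuration
#'
#' @param threshold percent K2P threshold separating "low" from "high"
#'   divergence and used for the single-linkage cluster proxy (default
#'   2.2).
#' @param minBases minimum informative length, see [filterMinLength()].
#' @param minOverlap per-pair site floor, see [pairwiseK2P()].
#' @param nBootstrap bootstrap replicates for the NJ tree (default 1000;
#'   0 disables bootstrapping).
#' @param seed integer seed governing all randomness in the audit.
#' @param sweep logical: run the (prior x gap width) exploration.
#' @param pMin,pMax,nSteps,xMin,xMax,nX sweep grids, see [apeSweep()].
#' @param estimatorGapWidth gap width at which estimator P is read
#'   (default 0.1).
#' @param networkConfidence connection confidence for haplotype networks.
#' @param networkGroups `"auto"` (genera containing a low-divergence pair
#'   or a deep-divergence species), `"none"`, or a character vector of
#'   genus names.
#' @return A named list of settings for [runAudit()].
#' @export
auditConfig <- function(threshold = 2.2, minBases = 401, minOverlap = 300,
                        nBootstrap = 1000, seed = 1, sweep = TRUE,
                        pMin = 0.001, pMax = 0.1, nSteps = 100,
                        xMin = 0.1, xMax = 10, nX = 100,
                        estimatorGapWidth = 0.1,
                        networkConfidence = 0.95,
                        networkGroups = "auto") {
  list(threshold = threshold, minBases = minBases, minOverlap = minOverlap,
       nBootstrap = nBootstrap, seed = as.integer(seed), sweep = sweep,
       pMin = pMin, pMax = pMax, nSteps = nSteps, xMin = xMin, xMax = xMax,
       nX = nX, estimatorGapWidth = estimatorGapWidth,
       networkConfidence = networkConfidence,
       networkGroups = networkGroups)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("audit stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[audit] %-22s %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full barcode-library audit
#'
#' Executes every stage in order: length filtering, composition, pairwise
#' K2P distances, per-species summaries, the low-divergence species-pair
#' table, single-linkage threshold clusters, the NJ tree with bootstrap,
#' the monophyly report, haplotype networks for flagged genera, the
#' two-parameter gap-partition sweep and the per-species divergence
#' estimator. Deterministic given (library, config).
#'
#' Species are rolled up into disjoint report tables mirroring the audit's
#' result surfaces: species with MPD above the threshold land in the
#' "deep, one cluster" or "deep, multiple clusters" table; the remaining
#' species are unremarkable. Independently, any species participating in
#' a below-threshold interspecific pair is listed in the low-divergence
#' pair table. A species counts as successfully identifiable when it is
#' not non-monophyletic on the tree and shares no threshold cluster with
#' another species.
#'
#' @param lib a [BarcodeLibrary].
#' @param config see [auditConfig()].
#' @return An [AuditReport].
#' @export
runAudit <- function(lib, config = auditConfig()) {
  stopifnot(is(lib, "BarcodeLibrary"))
  flt <- .stage("filter_min_length", filterMinLength(lib, config$minBases))
  if (length(flt) < 3) stop("fewer than 3 records after length filtering")
  comp <- .stage("composition", compositionSummary(flt))
  m <- .stage("k2p_distances",
              pairwiseK2P(flt, minOverlap = config$minOverlap))

  # complete-matrix id set shared by tree, clusters and sweep
  ids_complete <- .completeIds(distances(m))
  if (length(ids_complete) < length(flt))
    message("[audit] dropping ", length(flt) - length(ids_complete),
            " specimen(s) with undefined distances from tree/sweep stages")
  mc <- m[ids_complete]
  sub <- flt[ids_complete]
  species <- speciesLabels(flt)

  summ <- .stage("species_summaries", speciesSummaries(m, species))
  low <- if (length(unique(unname(species))) >= 2)
    .stage("low_divergence_pairs",
           lowDivergencePairs(m, species, config$threshold))
  else data.frame(species_1 = character(), species_2 = character(),
                  min_distance = numeric())
  deep <- .stage("deep_divergence",
                 deepDivergenceSpecies(summ, config$threshold))
  clus <- .stage("threshold_clusters",
                 thresholdClusters(mc, config$threshold))

  tree <- if (config$nBootstrap > 0)
    .stage("nj_bootstrap",
           bootstrapSupports(sub, nReplicates = config$nBootstrap,
                             seed = config$seed,
                             minOverlap = config$minOverlap))
  else .stage("nj_tree", njTree(mc))
  mono <- .stage("monophyly",
                 monophylyReport(tree, speciesLabels(sub)))

  sweep <- NULL
  est <- data.frame(species = character(), gap_width = numeric(),
                    estimator_P = character(), estimator_value = numeric(),
                    censored = character())
  if (isTRUE(config$sweep)) {
    sweep <- .stage("gap_sweep",
                    apeSweep(mc, species, pMin = config$pMin,
                             pMax = config$pMax, nSteps = config$nSteps,
                             xMin = config$xMin, xMax = config$xMax,
                             nX = config$nX))
    est <- .stage("estimator_P",
                  estimateP(sweep, gapWidth = config$estimatorGapWidth))
  }

  nets <- .stage("haplotype_networks",
                 .auditNetworks(sub, summ, low, config))

  # ---- species roll-up ------------------------------------------------
  meta <- specimenData(flt)
  fam_of <- setNames(meta$family, meta$species)
  clus_of <- setNames(clus$cluster, clus$specimen_id)
  sp_sub <- speciesLabels(sub)

  cluster_tab <- table(species = unname(sp_sub[names(clus_of)]),
                       cluster = unname(clus_of))
  n_clusters <- apply(cluster_tab > 0, 1L, sum)
  shared_cluster <- apply(cluster_tab > 0, 2L, sum) > 1
  sp_shares <- apply(cluster_tab[, shared_cluster, drop = FALSE] > 0, 1L,
                     any)

  all_sp <- sort(unique(unname(species)), method = "radix")
  status <- setNames(mono$status[match(all_sp, mono$species)], all_sp)
  status[is.na(status)] <- "not_in_tree"
  nclu <- setNames(as.integer(n_clusters[match(all_sp, names(n_clusters))]),
                   all_sp)
  shares <- setNames(as.logical(sp_shares[match(all_sp, names(sp_shares))]),
                     all_sp)
  mpd <- setNames(summ$max_intra[match(all_sp, summ$species)], all_sp)
  in_low <- all_sp %in% c(low$species_1, low$species_2)
  deep_sp <- !is.na(mpd) & mpd > config$threshold
  table_of <- ifelse(deep_sp & !is.na(nclu) & nclu >= 2, "deep_multi_cluster",
              ifelse(deep_sp, "deep_one_cluster", "unremarkable"))
  identified <- status != "non-monophyletic" & !is.na(shares) & !shares
  speciesAudit <- data.frame(
    species = all_sp,
    family = unname(fam_of[all_sp]),
    n_specimens = summ$n_specimens[match(all_sp, summ$species)],
    monophyly = unname(status),
    n_clusters = unname(nclu),
    shares_cluster = unname(shares),
    max_intra = unname(mpd),
    in_low_divergence_pair = in_low,
    table = unname(table_of),
    identified = unname(identified))
  speciesAudit <- speciesAudit[order(speciesAudit$family,
                                     speciesAudit$species,
                                     method = "radix"), , drop = FALSE]
  rownames(speciesAudit) <- NULL

  deep1 <- merge(deep[deep$species %in% all_sp[table_of == "deep_one_cluster"], ],
                 speciesAudit[, c("species", "family", "n_clusters")],
                 by = "species", sort = FALSE)
  deepM <- merge(deep[deep$species %in% all_sp[table_of == "deep_multi_cluster"], ],
                 speciesAudit[, c("species", "family", "n_clusters")],
                 by = "species", sort = FALSE)
  if (nrow(est)) {
    deepM <- merge(deepM, est[, c("species", "estimator_P")],
                   by = "species", all.x = TRUE, sort = FALSE)
  } else deepM$estimator_P <- NA_character_
  deepM <- deepM[order(deepM$max_intra, deepM$species, method = "radix"), ,
                 drop = FALSE]
  rownames(deepM) <- NULL

  low$family_1 <- unname(fam_of[low$species_1])

  id_rate <- 100 * mean(speciesAudit$identified, na.rm = TRUE)
  metadata <- list(
    config = config,
    seed = config$seed,
    n_input_records = length(lib),
    n_analyzed_records = length(flt),
    n_tree_records = length(sub),
    alignment_length = alignmentLength(lib),
    cluster_proxy = paste("single-linkage connected components at",
                          config$threshold,
                          "% K2P (documented OTU proxy, not BOLD RESL)"),
    identification_rate_pct = id_rate,
    package_version = as.character(packageVersion("barcodeAudit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  new("AuditReport", composition = comp, speciesSummaries = summ,
      lowDivergencePairs = low, deepOneCluster = deep1,
      deepMultiCluster = deepM, monophyly = mono, clusters = clus,
      tree = tree, networks = nets, sweep = sweep, estimates = est,
      speciesAudit = speciesAudit, metadata = metadata)
}

# Build haplotype networks for flagged genera and summarize them.
.auditNetworks <- function(sub, summ, low, config) {
  empty <- data.frame(group = character(), n_specimens = integer(),
                      n_haplotypes = integer(), n_subnetworks = integer(),
                      connection_limit = integer(), max_gap_steps = integer())
  if (identical(config$networkGroups, "none")) return(empty)
  meta <- specimenData(sub)
  genus_of <- setNames(meta$genus, meta$species)
  if (identical(config$networkGroups, "auto")) {
    flagged_sp <- unique(c(low$species_1, low$species_2,
                           summ$species[!is.na(summ$max_intra) &
                                        summ$max_intra > config$threshold]))
    genera <- sort(unique(unname(genus_of[flagged_sp])), method = "radix")
  } else genera <- config$networkGroups
  if (!length(genera)) return(empty)
  limit <- connectionLimit(alignmentLength(sub), config$networkConfidence)
  rows <- lapply(genera, function(g) {
    grp <- sub[which(meta$genus == g)]
    if (length(grp) < 2) return(NULL)
    h <- collapseHaplotypes(grp)
    net <- buildNetwork(h, limit)
    gaps <- subnetworkGap(net)
    data.frame(group = g, n_specimens = length(grp),
               n_haplotypes = length(h),
               n_subnetworks = length(subnetworks(net)),
               connection_limit = limit,
               max_gap_steps = if (nrow(gaps)) max(gaps$min_steps)
                               else NA_integer_)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write an audit report to a directory
#'
#' Emits TSV tables, the Newick tree, the sweep classification matrix at
#' the estimator gap width and a JSON metadata file. Output is a pure
#' function of (library, config): re-running writes byte-identical files.
#'
#' @param report an [AuditReport].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeAuditReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, percent_cols = character()) {
    for (cn in percent_cols) df[[cn]] <- .fmt(df[[cn]], 2)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  comp <- report@composition
  for (cn in c("freq_A", "freq_C", "freq_G", "freq_T", "at_content"))
    comp[[cn]] <- .fmt(100 * comp[[cn]], 1)
  w(comp, "composition.tsv")
  w(report@speciesSummaries, "species_summaries.tsv",
    c("mean_intra", "max_intra", "nn_distance"))
  w(report@lowDivergencePairs, "low_divergence_pairs.tsv", "min_distance")
  w(report@deepOneCluster, "deep_divergence_one_cluster.tsv",
    c("mean_intra", "max_intra"))
  w(report@deepMultiCluster, "deep_divergence_multi_cluster.tsv",
    c("mean_intra", "max_intra"))
  w(report@monophyly, "monophyly.tsv")
  clus <- report@clusters
  con <- file(file.path(dir, "clusters.tsv"), "w")
  writeLines(paste0("# ", report@metadata$cluster_proxy), con)
  write.table(clus, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  w(report@networks, "networks_summary.tsv")
  w(report@estimates, "estimator_P.tsv")
  w(report@speciesAudit, "species_audit.tsv", "max_intra")
  ape::write.tree(report@tree, file.path(dir, "tree.nwk"))
  if (!is.null(report@sweep))
    writeSweepMatrix(report@sweep, file.path(dir, "sweep_matrix.tsv"),
                     gapWidth = report@metadata$config$estimatorGapWidth)
  jsonlite::write_json(report@metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare an audit report against a generator truth table
#'
#' Checks, per species, the planted expectations the report should
#' recover: monophyly status and the number of threshold clusters. An
#' empty result means the audit matches the planted truth.
#'
#' @param report an [AuditReport].
#' @param truth the `truth` element of [generateLibrary()] output for the
#'   same library.
#' @return `data.frame` of discrepancies (`species`, `field`, `expected`,
#'   `observed`); zero rows on full agreement.
#' @export
compareToTruth <- function(report, truth) {
  exp <- truth$speciesExpectations
  aud <- report@speciesAudit
  if (!all(exp$species %in% aud$species))
    stop("report and truth describe different species sets; missing: ",
         paste(setdiff(exp$species, aud$species), collapse = ", "))
  rows <- list()
  addrow <- function(s, f, e, o)
    rows[[length(rows) + 1L]] <<- data.frame(species = s, field = f,
                                             expected = as.character(e),
                                             observed = as.character(o))
  for (i in seq_len(nrow(exp))) {
    s <- exp$species[i]
    a <- aud[aud$species == s, ]
    obs_mono <- a$monophyly != "non-monophyletic"
    if (!is.na(exp$expected_monophyletic[i]) &&
        exp$expected_monophyletic[i] != obs_mono)
      addrow(s, "monophyletic", exp$expected_monophyletic[i], obs_mono)
    if (!is.na(a$n_clusters) &&
        exp$expected_clusters[i] != a$n_clusters)
      addrow(s, "n_clusters", exp$expected_clusters[i], a$n_clusters)
    exp_low <- if ("expected_low_pair" %in% names(exp))
      exp$expected_low_pair[i] else exp$shares_haplotype[i]
    if (exp_low && !isTRUE(a$in_low_divergence_pair))
      addrow(s, "in_low_divergence_pair", TRUE, a$in_low_divergence_pair)
  }
  if (!length(rows))
    return(data.frame(species = character(), field = character(),
                      expected = character(), observed = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
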