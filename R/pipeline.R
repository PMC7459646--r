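#' Pipeline run configuration
#'
#' All thresholds of the analysis with their standard defaults: coverage
#' filter (> 10 reads, <= 99.9th percentile), DMC thresholds (q < 0.01,
#' |difference| >= 20 points), variance percentile 95 for pattern
#' exploration, t-SNE perplexity 2, and 1000 bootstrap iterations for the
#' KS enrichment test. Every value is echoed to the run manifest.
#'
#' @param minCoverage,upperPercentile coverage filter bounds.
#' @param qMax,minDiff DMC thresholds.
#' @param variancePercentile site-variance percentile for exploration.
#' @param perplexity t-SNE perplexity.
#' @param ksIter KS-boot iterations.
#' @param enrichmentRegions region scopes for enrichment (default "all";
#'   any subset of \code{c(regionLevels(), "all")}).
#' @param seed integer seed for every stochastic stage.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(minCoverage = 10, upperPercentile = 99.9,
                      qMax = 0.01, minDiff = 20, variancePercentile = 95,
                      perplexity = 2, ksIter = 1000L,
                      enrichmentRegions = "all", seed = 1L) {
  cfg <- list(minCoverage = minCoverage, upperPercentile = upperPercentile,
              qMax = qMax, minDiff = minDiff,
              variancePercentile = variancePercentile,
              perplexity = perplexity, ksIter = as.integer(ksIter),
              enrichmentRegions = enrichmentRegions, seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are \code{\link{runConfig}} arguments.
#' @return list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(runConfig)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

.contrastPairs <- function(groups) {
  idx <- utils::combn(seq_along(groups), 2)
  lapply(seq_len(ncol(idx)), function(j) {
    c(treatment = groups[max(idx[, j])], control = groups[min(idx[, j])])
  })
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> write -> read -> filter -> unite -> annotate ->
#' differential methylation -> DMC/DMG calling -> contrast overlap ->
#' global-pattern exploration -> enrichment, entirely through the on-disk
#' file formats, and writes result tables plus a manifest into
#' \code{outdir}. Rerunning with the same design and config is
#' bit-identical.
#'
#' @param design a \code{\link{simulationDesign}}.
#' @param outdir output directory.
#' @param config a \code{\link{runConfig}}.
#' @param pathways optional gene-to-pathway table; by default a synthetic
#'   map over the design's genes is generated.
#' @return invisibly, a list with the united sets, per-contrast results,
#'   DMG tables, Venn overlaps, exploration outputs, enrichment tables and
#'   the manifest path.
#' @export
runPipeline <- function(design, outdir, config = runConfig()) {
  stopifnot(inherits(design, "SimulationDesign"),
            inherits(config, "RunConfig"))
  badRegion <- setdiff(config$enrichmentRegions, c(regionLevels(), "all"))
  if (length(badRegion))
    stop("validation error: unknown region scope(s): ",
         paste(badRegion, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- c()
  note <- function(...) log <<- c(log, paste0(...))

  # stage: simulate + write
  sim <- simulateGenome(design)
  mm <- simulateMethylomes(design, sim$cpgSites)
  dataDir <- file.path(outdir, "data")
  paths <- writeSimulatedData(sim$genome, sim$geneModels, mm$calls,
                              mm$truth, dataDir)
  note("simulate: ", length(sim$cpgSites), " CpGs, ", ncol(mm$calls),
       " samples, ", nrow(mm$truth), " planted effect sites")

  # stage: read + filter
  groupsOf <- sampleGroups(mm$calls)
  names(groupsOf) <- colnames(mm$calls)
  samples <- lapply(seq_along(paths$cov), function(j) {
    s <- readBismarkCov(paths$cov[j],
                        group = groupsOf[[sub("\\.cov$", "",
                                              basename(paths$cov[j]))]])
    f <- filterByCoverage(s, config$minCoverage, config$upperPercentile)
    note("filter ", colnames(s)[1], ": ", nrow(s), " -> ", nrow(f), " sites")
    f
  })

  # stage: region map
  models <- readGeneModels(paths$gff)
  canon <- selectCanonicalIsoforms(models)
  seqlen <- Biostrings::fasta.seqlengths(paths$genome)
  map <- buildRegionMap(canon, seqlen)
  note("regions: ", length(canonicalGenes(map)), " canonical genes")

  groups <- design$groups
  sampleGroupsVec <- vapply(samples, function(s) sampleGroups(s)[1],
                            character(1))
  if (!all(groups %in% sampleGroupsVec))
    stop("validation error: group label without samples")

  # stage: per-contrast differential methylation
  contrasts <- .contrastPairs(groups)
  results <- list(); dmgs <- list()
  for (ct in contrasts) {
    nm <- paste(ct[["treatment"]], ct[["control"]], sep = ":")
    un <- uniteSamples(samples, groups = ct)
    res <- diffMeth(un, ct[["treatment"]], ct[["control"]])
    res <- callDmcs(res, config$qMax, config$minDiff)
    res <- annotateResults(res, map)
    results[[nm]] <- res
    dmgs[[nm]] <- mapDmcsToGenes(res)
    note("diffmeth ", nm, ": ", length(res@sites), " united sites, ",
         length(dmcs(res)), " DMCs, ", nrow(dmgs[[nm]]), " DMGs")
    writeResultTable(res, file.path(outdir, sprintf("diffmeth_%s.tsv",
                                                    gsub(":", "_", nm))))
    utils::write.table(dmgs[[nm]],
                       file.path(outdir, sprintf("dmg_%s.tsv",
                                                 gsub(":", "_", nm))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  venn <- list(
    body_or_promoter = overlapContrasts(lapply(dmgs, function(d) d$gene_id)),
    promoter_only = overlapContrasts(lapply(dmgs, function(d)
      d$gene_id[d$promoter])))
  for (v in names(venn))
    utils::write.table(venn[[v]],
                       file.path(outdir, sprintf("venn_%s.tsv", v)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # stage: global patterns over all groups
  unAll <- uniteSamples(samples)
  pm <- methPercent(unAll)
  hv <- selectHighVarianceSites(pm, config$variancePercentile)
  emb <- list(pca = embedSamples(pm, "pca"))
  if (ncol(pm) >= 4L && config$perplexity < (ncol(pm) - 1) / 3)
    emb$tsne <- embedSamples(hv, "tsne", perplexity = config$perplexity,
                             seed = config$seed)
  cl <- clusterSamples(pm)
  note("explore: ", nrow(pm), " united sites across all samples, ",
       nrow(hv), " high-variance sites")
  for (e in names(emb)) {
    tb <- data.frame(sample = rownames(emb[[e]]),
                     round(emb[[e]][, 1:2, drop = FALSE], 6))
    utils::write.table(tb, file.path(outdir, sprintf("embedding_%s.tsv", e)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(round(cl$correlation, 6),
                     file.path(outdir, "sample_correlation.tsv"),
                     sep = "\t", quote = FALSE)

  # stage: enrichment (per contrast, three tests)
  geneIds <- unique(S4Vectors::mcols(canonicalGenes(map))$gene_id)
  pathways <- readPathwayMap(simulatePathways(geneIds, seed = config$seed))
  enr <- list()
  for (nm in names(results)) {
    for (tst in c("ora", "wilcox", "ksboot")) {
      tb <- enrichRegions(results[[nm]], pathways, test = tst,
                          regions = config$enrichmentRegions,
                          nIter = config$ksIter, seed = config$seed)
      if (is.null(tb)) next
      tb$contrast <- nm
      enr[[paste(nm, tst)]] <- tb
      utils::write.table(
        tb, file.path(outdir, sprintf("enrich_%s_%s.tsv", tst,
                                      gsub(":", "_", nm))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- c("methylRRBS pipeline manifest",
                sprintf("package_version: %s",
                        as.character(utils::packageVersion("methylRRBS"))),
                sprintf("seed: %d", config$seed),
                sprintf("design: %s", paste(names(design), "=",
                                            vapply(design, function(v)
                                              paste(v, collapse = ","),
                                              character(1)),
                                            collapse = "; ")),
                sprintf("config: %s", paste(names(config), "=",
                                            vapply(config, function(v)
                                              paste(v, collapse = ","),
                                              character(1)),
                                            collapse = "; ")),
                log)
  manifestPath <- file.path(outdir, "manifest.txt")
  writeLines(manifest, manifestPath)

  invisible(list(results = results, dmgs = dmgs, venn = venn,
                 embeddings = emb, clustering = cl, enrichment = enr,
                 regionMap = map, truth = mm$truth, united = unAll,
                 manifest = manifestPath, outdir = outdir))
}

#' Write a per-site differential methylation table
#'
#' @param res a \linkS4class{DiffMethResult}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeResultTable <- function(res, path) {
  s <- res@sites
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(s)),
                   pos = GenomicRanges::start(s),
                   as.data.frame(S4Vectors::mcols(s)),
                   stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary tables of a pipeline run
#'
#' Report tables over a completed \code{\link{runPipeline}} result: the
#' regional distribution of united CpGs, per-region hyper/hypo DMC counts
#' per contrast, Venn overlap counts, and per-gene DMC tallies with a
#' promoter marker.
#'
#' @param run the list returned by \code{\link{runPipeline}}.
#' @return list of data.frames: \code{region_distribution},
#'   \code{dmc_by_region}, \code{venn}, \code{gene_tallies}.
#' @export
summarizeRun <- function(run) {
  rd <- lapply(names(run$results), function(nm) {
    fr <- regionDistribution(S4Vectors::mcols(run$results[[nm]]@sites)$label)
    data.frame(contrast = nm, region = names(fr), fraction = as.numeric(fr),
               stringsAsFactors = FALSE)
  })
  dmcTab <- lapply(names(run$results), function(nm) {
    mc <- S4Vectors::mcols(run$results[[nm]]@sites)
    d <- as.data.frame(mc[mc$status %in% c("hyper", "hypo"), c("label",
                                                               "status")])
    tb <- table(factor(as.character(d$label), levels = regionLevels()),
                factor(as.character(d$status), levels = c("hyper", "hypo")))
    data.frame(contrast = nm, region = rownames(tb),
               hyper = as.integer(tb[, "hyper"]),
               hypo = as.integer(tb[, "hypo"]),
               total = as.integer(rowSums(tb)), stringsAsFactors = FALSE)
  })
  tallies <- lapply(names(run$dmgs), function(nm) {
    d <- run$dmgs[[nm]]
    if (nrow(d) == 0L) return(NULL)
    # "h/H ^P"-style marker: hyper/hypo counts, ^P when promoter DMC present
    d$tally <- sprintf("%d/%d%s", d$hyper, d$hypo,
                       ifelse(d$promoter, " ^P", ""))
    cbind(contrast = nm, d)
  })
  tallies <- tallies[!vapply(tallies, is.null, TRUE)]
  list(region_distribution = do.call(rbind, rd),
       dmc_by_region = do.call(rbind, dmcTab),
       venn = run$venn,
       gene_tallies = if (length(tallies)) do.call(rbind, tallies) else NULL)
}
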