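#' Validate and normalise a gene-to-pathway mapping
#'
#' @param pathways data.frame with columns gene_id, pathway_id (and
#'   optionally pathway_name).
#' @return the data.frame, de-duplicated, with pathway_name filled in.
#' @export
readPathwayMap <- function(pathways) {
  if (is.character(pathways) && length(pathways) == 1L)
    pathways <- utils::read.table(pathways, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "pathway_id") %in% colnames(pathways)))
  if (!"pathway_name" %in% colnames(pathways))
    pathways$pathway_name <- pathways$pathway_id
  unique(pathways[, c("gene_id", "pathway_id", "pathway_name")])
}

#' Over-representation analysis of DMGs
#'
#' Hypergeometric upper-tail test per pathway: with a universe of N genes of
#' which K belong to the pathway and n are DMGs, the p-value is
#' P(X >= k) for the observed overlap k. Pathways with no member inside the
#' universe are skipped with a warning. Benjamini-Hochberg adjustment across
#' the tested pathways.
#'
#' @param dmgIds character vector of DMG gene ids (must lie in the
#'   universe).
#' @param universe character vector of all eligible gene ids (typically all
#'   genes with >= 1 united CpG).
#' @param pathways mapping as accepted by \code{\link{readPathwayMap}}.
#' @return data.frame: pathway_id, pathway_name, K, k, n, N, pvalue, padj.
#' @export
oraTest <- function(dmgIds, universe, pathways) {
  pathways <- readPathwayMap(pathways)
  universe <- unique(universe)
  dmgIds <- unique(dmgIds)
  if (!all(dmgIds %in% universe))
    stop("DMG set must be a subset of the universe")
  N <- length(universe)
  n <- length(dmgIds)
  ids <- unique(pathways$pathway_id)
  rows <- lapply(ids, function(pid) {
    members <- intersect(pathways$gene_id[pathways$pathway_id == pid],
                         universe)
    K <- length(members)
    if (K == 0L) {
      warning("pathway ", pid, " has no member in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(members, dmgIds))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid,
               pathway_name = pathways$pathway_name[
                 match(pid, pathways$pathway_id)],
               K = K, k = k, n = n, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) return(NULL)
  out$padj <- stats::p.adjust(out$pvalue, "BH")
  out
}

# Site table shared by the two distribution-based tests: one row per united
# CpG with its two pooled group means, region label and gene id.
.siteTable <- function(res) {
  mc <- S4Vectors::mcols(res@sites)
  if (!all(c("label", "gene_id") %in% colnames(mc)))
    stop("annotate the result with annotateResults() first")
  data.frame(meanTreatment = mc$meanTreatment,
             meanControl = mc$meanControl,
             meth.diff = mc$meth.diff,
             label = as.character(mc$label),
             gene_id = mc$gene_id,
             stringsAsFactors = FALSE)
}

.scopeRows <- function(st, region) {
  if (region == "all") st else st[st$label == region, , drop = FALSE]
}

#' Pathway-wise Wilcoxon signed-rank test of group methylation
#'
#' For each pathway, pairs the two pooled group methylation rates at every
#' united CpG inside the pathway's member genes (within the given region
#' scope) and applies the Wilcoxon signed-rank test. Pathways with fewer
#' than \code{minSites} usable sites, or with all-zero differences (the
#' statistic is undefined), are reported NA and excluded from the BH
#' adjustment.
#'
#' @param res an annotated \linkS4class{DiffMethResult}.
#' @param pathways mapping as accepted by \code{\link{readPathwayMap}}.
#' @param region one of \code{regionLevels()} or "all".
#' @param minSites minimum usable sites per pathway (default 5).
#' @return data.frame: pathway_id, pathway_name, region, n_sites, statistic,
#'   pvalue, padj.
#' @export
pathwayWilcoxon <- function(res, pathways, region = "all", minSites = 5L) {
  pathways <- readPathwayMap(pathways)
  st <- .scopeRows(.siteTable(res), region)
  ids <- unique(pathways$pathway_id)
  rows <- lapply(ids, function(pid) {
    genes <- pathways$gene_id[pathways$pathway_id == pid]
    sel <- !is.na(st$gene_id) & st$gene_id %in% genes
    nS <- sum(sel)
    stat <- p <- NA_real_
    if (nS >= minSites) {
      d <- st$meanTreatment[sel] - st$meanControl[sel]
      if (any(d != 0)) {
        wt <- suppressWarnings(
          stats::wilcox.test(st$meanTreatment[sel], st$meanControl[sel],
                             paired = TRUE, exact = FALSE))
        stat <- unname(wt$statistic)
        p <- wt$p.value
      }
    }
    data.frame(pathway_id = pid,
               pathway_name = pathways$pathway_name[
                 match(pid, pathways$pathway_id)],
               region = region, n_sites = nS, statistic = stat, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  ok <- !is.na(out$pvalue)
  out$padj[ok] <- stats::p.adjust(out$pvalue[ok], "BH")
  out
}

# sup-norm distance between the ECDF of x and the ECDF of the (sorted)
# background; evaluated at the jump points of both step functions
.ksStat <- function(x, bgSorted) {
  s <- sort(x)
  n <- length(s)
  m <- length(bgSorted)
  FbAt <- findInterval(s, bgSorted) / m
  FbBefore <- findInterval(s, bgSorted, left.open = TRUE) / m
  Fs <- seq_len(n) / n
  max(abs(Fs - FbAt), abs((Fs - 1 / n) - FbBefore))
}

#' Bootstrap Kolmogorov-Smirnov pathway enrichment
#'
#' Tests whether the methylation differences of the CpGs in a pathway's
#' member genes deviate from the differences of all CpGs in the same region
#' scope. The observed statistic is the sup-norm distance between the two
#' empirical CDFs; the null distribution is built by drawing, with
#' replacement, size-matched site sets from the background for
#' \code{nIter} iterations, and the p-value is
#' (1 + #\{D_boot >= D_obs\}) / (nIter + 1) (add-one estimator, so p is
#' never 0 and its attainable minimum is 1/(nIter + 1)).
#' Benjamini-Hochberg adjustment across pathways. Deterministic under
#' \code{seed}.
#'
#' @param res an annotated \linkS4class{DiffMethResult}.
#' @param pathways mapping as accepted by \code{\link{readPathwayMap}}.
#' @param region one of \code{regionLevels()} or "all".
#' @param nIter bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return data.frame: pathway_id, pathway_name, region, n_sites,
#'   statistic (D_obs), pvalue, padj.
#' @export
ksBoot <- function(res, pathways, region = "all", nIter = 1000L, seed = 1L) {
  pathways <- readPathwayMap(pathways)
  st <- .scopeRows(.siteTable(res), region)
  background <- st$meth.diff
  if (length(background) == 0L) stop("empty background for region ", region)
  bgSorted <- sort(background)
  set.seed(seed)
  ids <- unique(pathways$pathway_id)
  rows <- lapply(ids, function(pid) {
    genes <- pathways$gene_id[pathways$pathway_id == pid]
    sel <- !is.na(st$gene_id) & st$gene_id %in% genes
    nS <- sum(sel)
    if (nS == 0L) stop("empty site set for pathway ", pid)
    if (nS > length(background))
      stop("background smaller than pathway ", pid)
    dObs <- .ksStat(st$meth.diff[sel], bgSorted)
    boot <- matrix(sample(background, nS * nIter, replace = TRUE),
                   nrow = nS)
    dBoot <- apply(boot, 2, .ksStat, bgSorted = bgSorted)
    p <- (1 + sum(dBoot >= dObs)) / (nIter + 1)
    data.frame(pathway_id = pid,
               pathway_name = pathways$pathway_name[
                 match(pid, pathways$pathway_id)],
               region = region, n_sites = nS, statistic = dObs, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, "BH")
  out
}

#' Run one enrichment test over every region scope
#'
#' Applies \code{\link{oraTest}}, \code{\link{pathwayWilcoxon}} or
#' \code{\link{ksBoot}} for each region label plus "all" and binds the
#' results (BH adjustment stays within each region scope). For ORA the
#' DMG/universe pair is recomputed per scope from the annotated result.
#'
#' @param res an annotated \linkS4class{DiffMethResult} (through
#'   \code{\link{callDmcs}} for ORA).
#' @param pathways mapping as accepted by \code{\link{readPathwayMap}}.
#' @param test "ora", "wilcox" or "ksboot".
#' @param regions region scopes to run (default all labels plus "all").
#' @param nIter,seed passed to \code{\link{ksBoot}}.
#' @return data.frame of stacked per-scope results with a \code{region}
#'   column; a \code{test} column names the procedure.
#' @export
enrichRegions <- function(res, pathways, test = c("ora", "wilcox", "ksboot"),
                          regions = c(regionLevels()[-7], "all"),
                          nIter = 1000L, seed = 1L) {
  test <- match.arg(test)
  st <- .siteTable(res)
  out <- lapply(regions, function(rg) {
    if (test == "ora") {
      mc <- S4Vectors::mcols(res@sites)
      if (!"status" %in% colnames(mc)) stop("run callDmcs() first")
      rows <- .scopeRows(cbind(st, status = as.character(mc$status)), rg)
      uni <- unique(stats::na.omit(st$gene_id))
      dmg <- unique(stats::na.omit(
        rows$gene_id[rows$status %in% c("hyper", "hypo")]))
      r <- oraTest(dmg, uni, pathways)
      if (is.null(r)) return(NULL)
      r$region <- rg
      r
    } else if (test == "wilcox") {
      pathwayWilcoxon(res, pathways, region = rg)
    } else {
      # only pathways with >= 1 site in this scope are testable
      rows <- .scopeRows(st, rg)
      pw <- readPathwayMap(pathways)
      genesHere <- unique(stats::na.omit(rows$gene_id))
      pw <- pw[pw$pathway_id %in%
                 unique(pw$pathway_id[pw$gene_id %in% genesHere]), ,
               drop = FALSE]
      if (nrow(pw) == 0L || nrow(rows) == 0L) return(NULL)
      ksBoot(res, pw, region = rg, nIter = nIter, seed = seed)
    }
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(NULL)
  out$test <- test
  out
}
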