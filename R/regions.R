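#' Read gene models from GFF3
#'
#' Imports gene/mRNA/exon features and returns the transcript table used by
#' \code{\link{selectCanonicalIsoforms}}.
#'
#' @param path GFF3 file with gene, mRNA and exon features (ID/Parent
#'   attributes).
#' @return list with \code{mrna} (GRanges; mcols gene_id, tx_id) and
#'   \code{exons} (GRanges; mcols tx_id).
#' @export
readGeneModels <- function(path) {
  parseGeneModels(rtracklayer::import(path))
}

#' Extract the transcript table from GFF3-style ranges
#'
#' @param gr \code{GRanges} with mcols \code{type} (gene/mRNA/exon),
#'   \code{ID} and \code{Parent} (as written by
#'   \code{\link{simulateGenome}} or imported by rtracklayer).
#' @return list with \code{mrna} and \code{exons} as in
#'   \code{\link{readGeneModels}}.
#' @export
parseGeneModels <- function(gr) {
  type <- as.character(S4Vectors::mcols(gr)$type)
  parent <- S4Vectors::mcols(gr)$Parent
  if (is(parent, "List")) parent <- vapply(as.list(parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  parent <- as.character(parent)
  id <- as.character(S4Vectors::mcols(gr)$ID)
  mrna <- gr[type == "mRNA"]
  S4Vectors::mcols(mrna) <- S4Vectors::DataFrame(
    gene_id = parent[type == "mRNA"], tx_id = id[type == "mRNA"])
  exons <- gr[type == "exon"]
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
    tx_id = parent[type == "exon"])
  list(mrna = mrna, exons = exons)
}

#' Select one canonical isoform per gene
#'
#' For genes with multiple transcripts, keeps the one with the longest
#' transcript sequence (sum of exon widths); ties are broken by the
#' lexicographically smallest transcript id. Transcripts without exons are
#' rejected.
#'
#' @param models list as returned by \code{\link{readGeneModels}}.
#' @return list with \code{mrna} (one GRanges row per gene; mcols gene_id,
#'   tx_id, tss) and \code{exons} (GRanges of the kept transcripts).
#' @export
selectCanonicalIsoforms <- function(models) {
  mrna <- models$mrna
  exons <- models$exons
  txId <- S4Vectors::mcols(mrna)$tx_id
  exTx <- S4Vectors::mcols(exons)$tx_id
  missing <- setdiff(txId, unique(exTx))
  if (length(missing))
    stop("isoform validation error: mRNA without exons: ",
         paste(missing, collapse = ", "))
  txLen <- vapply(txId, function(t) sum(GenomicRanges::width(exons[exTx == t])),
                  numeric(1))
  geneId <- S4Vectors::mcols(mrna)$gene_id
  keep <- vapply(unique(geneId), function(g) {
    i <- which(geneId == g)
    i[order(-txLen[i], txId[i])][1]
  }, integer(1))
  mrna <- mrna[keep]
  str <- as.character(GenomicRanges::strand(mrna))
  tss <- ifelse(str == "-", GenomicRanges::end(mrna),
                GenomicRanges::start(mrna))
  S4Vectors::mcols(mrna)$tss <- as.integer(tss)
  list(mrna = mrna,
       exons = exons[exTx %in% S4Vectors::mcols(mrna)$tx_id])
}

# strand-aware interval [d1, d2] bp upstream of the TSS, clamped to the
# chromosome; returns NULL when fully outside
.upstreamTier <- function(chrom, tss, str, d1, d2, chromLen) {
  if (str == "-") { s <- tss + d1; e <- tss + d2 } else {
    s <- tss - d2; e <- tss - d1
  }
  s <- max(1L, s); e <- min(chromLen, e)
  if (s > e) return(NULL)
  c(s, e)
}

#' Build the labeled region map from canonical gene models
#'
#' Lays out, per gene and strand-aware: exons; introns (mRNA minus exons);
#' promoter tiers P250 (1-250 bp), P1K (251-1000 bp) and P6K (1001-6000 bp)
#' upstream of the TSS; and flanks (6001-10000 bp upstream of the TSS plus
#' 10 kb downstream of the mRNA 3' end). Regions are truncated at chromosome
#' ends. Everything not covered is intergenic by default at annotation time.
#'
#' @param canonical list from \code{\link{selectCanonicalIsoforms}}.
#' @param seqinfo a \code{Seqinfo} (or named vector of chromosome lengths).
#' @return A \linkS4class{RegionMap}.
#' @export
buildRegionMap <- function(canonical, seqinfo) {
  if (!is(seqinfo, "Seqinfo"))
    seqinfo <- GenomeInfoDb::Seqinfo(seqnames = names(seqinfo),
                                     seqlengths = unname(seqinfo))
  mrna <- canonical$mrna
  exons <- canonical$exons
  lens <- GenomeInfoDb::seqlengths(seqinfo)
  rows <- list()
  addRow <- function(chrom, s, e, label, gene) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = s, end = e, label = label, gene_id = gene,
      stringsAsFactors = FALSE)
  }
  exTx <- S4Vectors::mcols(exons)$tx_id
  for (i in seq_along(mrna)) {
    g <- S4Vectors::mcols(mrna)$gene_id[i]
    tx <- S4Vectors::mcols(mrna)$tx_id[i]
    chrom <- as.character(GenomicRanges::seqnames(mrna))[i]
    chromLen <- lens[[chrom]]
    str <- as.character(GenomicRanges::strand(mrna))[i]
    tss <- S4Vectors::mcols(mrna)$tss[i]
    if (tss < 1L || tss > chromLen)
      stop("validation error: TSS of ", g, " outside chromosome bounds")
    ms <- GenomicRanges::start(mrna)[i]; me <- GenomicRanges::end(mrna)[i]
    ex <- exons[exTx == tx]
    ex <- GenomicRanges::reduce(ex, ignore.strand = TRUE)
    for (j in seq_along(ex))
      addRow(chrom, GenomicRanges::start(ex)[j], GenomicRanges::end(ex)[j],
             "exon", g)
    # introns: gaps between exons inside the mRNA
    intr <- GenomicRanges::setdiff(
      GenomicRanges::GRanges(chrom, IRanges::IRanges(ms, me)),
      GenomicRanges::GRanges(chrom, IRanges::ranges(ex)),
      ignore.strand = TRUE)
    for (j in seq_along(intr))
      addRow(chrom, GenomicRanges::start(intr)[j],
             GenomicRanges::end(intr)[j], "intron", g)
    tiers <- list(P250 = c(1L, 250L), P1K = c(251L, 1000L),
                  P6K = c(1001L, 6000L), flanks = c(6001L, 10000L))
    for (lab in names(tiers)) {
      iv <- .upstreamTier(chrom, tss, str, tiers[[lab]][1], tiers[[lab]][2],
                          chromLen)
      if (!is.null(iv)) addRow(chrom, iv[1], iv[2], lab, g)
    }
    # downstream flank: 10 kb past the mRNA 3' end
    if (str == "-") { s <- ms - 10000L; e <- ms - 1L } else {
      s <- me + 1L; e <- me + 10000L
    }
    s <- max(1L, s); e <- min(chromLen, e)
    if (s <= e) addRow(chrom, s, e, "flanks", g)
  }
  if (length(rows)) {
    df <- do.call(rbind, rows)
    regions <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end), seqinfo = seqinfo)
    S4Vectors::mcols(regions)$label <-
      factor(df$label, levels = regionLevels())
    S4Vectors::mcols(regions)$gene_id <- df$gene_id
  } else {
    regions <- GenomicRanges::GRanges(seqinfo = seqinfo)
    S4Vectors::mcols(regions)$label <-
      factor(character(0), levels = regionLevels())
    S4Vectors::mcols(regions)$gene_id <- character(0)
  }
  new("RegionMap", regions = regions, genes = mrna)
}

#' Annotate CpG sites with a unique region label
#'
#' Assigns every site exactly one label under the precedence
#' exon > intron > P250 > P1K > P6K > flanks > intergenic; when a site falls
#' in regions of several genes the highest-precedence label wins, and within
#' equal precedence the lexicographically smallest gene id is reported.
#' Overlap is strand-agnostic: a CpG's label does not depend on which strand
#' its call came from.
#'
#' @param sites \code{GRanges} of CpG positions.
#' @param map a \linkS4class{RegionMap}.
#' @return \code{sites} with added mcols \code{label} (factor over
#'   \code{regionLevels()}) and \code{gene_id} (NA for intergenic sites).
#' @export
annotateCpGs <- function(sites, map) {
  known <- GenomeInfoDb::seqlevels(GenomeInfoDb::seqinfo(regionRanges(map)))
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(sites))), known)
  if (length(bad))
    stop("lookup error: unknown chromosome(s): ", paste(bad, collapse = ", "))
  lab <- factor(rep("intergenic", length(sites)), levels = regionLevels())
  gid <- rep(NA_character_, length(sites))
  regions <- regionRanges(map)
  if (length(regions) && length(sites)) {
    ov <- GenomicRanges::findOverlaps(sites, regions, ignore.strand = TRUE)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      rk <- as.integer(S4Vectors::mcols(regions)$label[s])
      gg <- S4Vectors::mcols(regions)$gene_id[s]
      o <- order(q, rk, gg)
      first <- !duplicated(q[o])
      lab[q[o][first]] <- S4Vectors::mcols(regions)$label[s[o][first]]
      gid[q[o][first]] <- gg[o][first]
    }
  }
  out <- sites
  S4Vectors::mcols(out)$label <- lab
  S4Vectors::mcols(out)$gene_id <- gid
  out
}

#' Regional distribution of a labeled site set
#'
#' @param labels factor (or character) of region labels, e.g. the
#'   \code{label} mcol produced by \code{\link{annotateCpGs}}.
#' @return named numeric vector of fractions over \code{regionLevels()},
#'   summing to 1.
#' @export
regionDistribution <- function(labels) {
  if (length(labels) == 0L) stop("empty site set")
  tb <- table(factor(as.character(labels), levels = regionLevels()))
  fr <- as.numeric(tb) / length(labels)
  names(fr) <- names(tb)
  fr
}

#' Attach region labels and gene ids to a differential result
#'
#' @param res a \linkS4class{DiffMethResult}.
#' @param map a \linkS4class{RegionMap}.
#' @return the result with \code{label} and \code{gene_id} mcols added.
#' @export
annotateResults <- function(res, map) {
  ann <- annotateCpGs(GenomicRanges::granges(res@sites), map)
  S4Vectors::mcols(res@sites)$label <- S4Vectors::mcols(ann)$label
  S4Vectors::mcols(res@sites)$gene_id <- S4Vectors::mcols(ann)$gene_id
  res
}
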