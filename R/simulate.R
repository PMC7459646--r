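#' Simulation design for synthetic RRBS data
#'
#' Bundles every parameter of the synthetic-data generator: a toy genome
#' (random sequence, so CpGs arise at natural dinucleotide frequency), gene
#' models with overlapping isoforms, and group-structured beta-binomial
#' methylation counts with planted differential methylation. Defaults mirror
#' a three-diet contrast design: groups NC (control), SS and SO with four
#' replicate samples each and ~30x mean CpG coverage.
#'
#' @param nChromosomes number of toy chromosomes.
#' @param chromLength length of each chromosome (bp).
#' @param nGenes number of genes to place across the genome.
#' @param groups group labels; the first is the control.
#' @param samplesPerGroup replicate samples per group (>= 1).
#' @param meanCoverage mean per-CpG read coverage (negative binomial mean).
#' @param coverageDispersion negative-binomial dispersion of coverage
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson coverage.
#' @param baselineMethAlpha,baselineMethBeta Beta shape parameters of the
#'   per-site baseline methylation level; the default (0.8, 0.8) is bimodal,
#'   as CpG methylation in vertebrate genomes typically is.
#' @param withinGroupOverdispersion beta-binomial intra-class correlation rho
#'   in [0, 1); 0 (the default) recovers binomial counts, the sampling model
#'   the per-site likelihood-ratio test assumes.
#' @param nEffectSites number of CpGs given a planted group difference.
#' @param effectSize planted difference in percentage points, in (0, 100].
#' @param seed integer seed governing all randomness of the generator.
#' @return A validated list of class \code{SimulationDesign}.
#' @export
#' @examples
#' d <- simulationDesign(nGenes = 5, chromLength = 2e4, nEffectSites = 10)
#' d$groups
simulationDesign <- function(nChromosomes = 2L, chromLength = 1e5L,
                             nGenes = 40L,
                             groups = c("NC", "SS", "SO"),
                             samplesPerGroup = 4L,
                             meanCoverage = 30,
                             coverageDispersion = 0.2,
                             baselineMethAlpha = 0.8,
                             baselineMethBeta = 0.8,
                             withinGroupOverdispersion = 0,
                             nEffectSites = 500L,
                             effectSize = 30,
                             seed = 1L) {
  d <- list(nChromosomes = as.integer(nChromosomes),
            chromLength = as.integer(chromLength),
            nGenes = as.integer(nGenes),
            groups = as.character(groups),
            samplesPerGroup = as.integer(samplesPerGroup),
            meanCoverage = meanCoverage,
            coverageDispersion = coverageDispersion,
            baselineMethAlpha = baselineMethAlpha,
            baselineMethBeta = baselineMethBeta,
            withinGroupOverdispersion = withinGroupOverdispersion,
            nEffectSites = as.integer(nEffectSites),
            effectSize = effectSize,
            seed = as.integer(seed))
  class(d) <- "SimulationDesign"
  validateDesign(d)
  d
}

validateDesign <- function(d) {
  stopifnot(inherits(d, "SimulationDesign"))
  if (d$nChromosomes < 1L || d$chromLength < 100L)
    stop("design error: need >= 1 chromosome of >= 100 bp")
  if (d$nGenes < 0L) stop("design error: nGenes must be non-negative")
  if (d$samplesPerGroup < 1L)
    stop("design error: samplesPerGroup must be >= 1")
  if (length(d$groups) < 2L || anyDuplicated(d$groups))
    stop("design error: need >= 2 distinct group labels")
  if (d$meanCoverage <= 0 || d$coverageDispersion < 0)
    stop("design error: coverage parameters must be positive")
  if (d$baselineMethAlpha <= 0 || d$baselineMethBeta <= 0)
    stop("design error: Beta shape parameters must be positive")
  rho <- d$withinGroupOverdispersion
  if (rho < 0 || rho >= 1)
    stop("design error: withinGroupOverdispersion must be in [0, 1)")
  if (d$effectSize <= 0 || d$effectSize > 100)
    stop("design error: effectSize must be in (0, 100]")
  if (d$nEffectSites < 0L)
    stop("design error: nEffectSites must be non-negative")
  invisible(TRUE)
}

#' Generate a toy genome with gene models and CpG map
#'
#' Draws random chromosome sequences (uniform base composition, so CpG
#' dinucleotides occur at ~1/16 density), places non-overlapping genes on
#' random strands, gives roughly a quarter of them a second, overlapping
#' isoform of different length (to exercise canonical-isoform selection),
#' splits each mRNA into exons, and records every CpG position (the C of
#' each CG dinucleotide on the plus strand).
#'
#' @param design a \code{\link{simulationDesign}}.
#' @return A list with elements \code{genome} (\code{DNAStringSet}),
#'   \code{geneModels} (GFF3-style \code{GRanges} with gene/mRNA/exon rows),
#'   and \code{cpgSites} (width-1 \code{GRanges}).
#' @export
simulateGenome <- function(design) {
  validateDesign(design)
  set.seed(design$seed)
  chromNames <- sprintf("chr%d", seq_len(design$nChromosomes))
  seqs <- Biostrings::DNAStringSet(vapply(chromNames, function(nm) {
    paste(sample(c("A", "C", "G", "T"), design$chromLength, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(seqs) <- chromNames
  sinfo <- GenomeInfoDb::Seqinfo(seqnames = chromNames,
                                 seqlengths = rep(design$chromLength,
                                                  design$nChromosomes))

  geneModels <- placeGenes(design, sinfo)
  cpg <- locateCpGs(seqs, sinfo)
  list(genome = seqs, geneModels = geneModels, cpgSites = cpg)
}

# Non-overlapping gene placement; ~25% of genes get a second overlapping
# isoform with a different transcript length.
placeGenes <- function(design, sinfo) {
  if (design$nGenes == 0L)
    return(GenomicRanges::GRanges(seqinfo = sinfo))
  # genes need room: span up to 8 kb plus spacing
  maxSpan <- 8000L
  perChrom <- ceiling(design$nGenes / design$nChromosomes)
  slot <- design$chromLength %/% perChrom
  if (slot < maxSpan + 200L)
    stop("sizing error: chromLength too small to host ", design$nGenes,
         " genes (need ~", perChrom * (maxSpan + 200L), " bp per chromosome)")
  rows <- list()
  gi <- 0L
  for (ci in seq_len(design$nChromosomes)) {
    nHere <- min(perChrom, design$nGenes - (ci - 1L) * perChrom)
    if (nHere <= 0L) break
    for (k in seq_len(nHere)) {
      gi <- gi + 1L
      lo <- (k - 1L) * slot + 100L
      len <- sample(2000:6000, 1L)
      gstart <- lo + sample.int(max(1L, slot - len - 200L), 1L)
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("gene%03d", gi)
      txs <- list(c(gstart, gstart + len - 1L))
      if (stats::runif(1) < 0.25) {  # overlapping second isoform
        shift <- sample(100:800, 1L)
        len2 <- sample(1500:6000, 1L)
        s2 <- max(lo, gstart + shift)
        txs <- c(txs, list(c(s2, min(s2 + len2 - 1L, k * slot + 50L,
                                     design$chromLength - 50L))))
      }
      for (ti in seq_along(txs)) {
        tstart <- txs[[ti]][1]; tend <- txs[[ti]][2]
        if (tend - tstart < 400L) tend <- tstart + 400L
        tid <- sprintf("%s.t%d", gid, ti)
        ex <- makeExons(tstart, tend)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = GenomeInfoDb::seqnames(sinfo)[ci],
          start = c(tstart, tstart, ex$start),
          end = c(tend, tend, ex$end),
          strand = strand,
          type = c("gene", "mRNA", rep("exon", nrow(ex))),
          ID = c(if (ti == 1L) gid else NA_character_, tid,
                 sprintf("%s.e%d", tid, seq_len(nrow(ex)))),
          Parent = c(NA_character_, gid, rep(tid, nrow(ex))),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- df[!(df$type == "gene" & is.na(df$ID)), ]  # one gene row per gene
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand, seqinfo = sinfo)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr
}

# Split a transcript into 2-5 exons anchored at both transcript ends.
makeExons <- function(tstart, tend) {
  len <- tend - tstart + 1L
  nEx <- sample(2:5, 1L)
  # 2*nEx - 1 alternating exon/intron segments, each >= 50 bp
  nSeg <- 2L * nEx - 1L
  if (len < nSeg * 50L) nEx <- max(1L, len %/% 150L)
  nSeg <- 2L * nEx - 1L
  if (nEx == 1L) return(data.frame(start = tstart, end = tend))
  cuts <- sort(sample(seq(tstart + 50L, tend - 50L), nSeg - 1L))
  bounds <- c(tstart - 1L, cuts, tend)
  segStart <- bounds[-length(bounds)] + 1L
  segEnd <- bounds[-1]
  keep <- seq(1L, nSeg, by = 2L)
  data.frame(start = segStart[keep], end = segEnd[keep])
}

locateCpGs <- function(seqs, sinfo) {
  hits <- lapply(names(seqs), function(nm) {
    m <- Biostrings::matchPattern("CG", seqs[[nm]])
    if (length(m) == 0L) return(NULL)
    GenomicRanges::GRanges(nm, IRanges::IRanges(Biostrings::start(m),
                                                width = 1L),
                           strand = "+", seqinfo = sinfo)
  })
  cpg <- do.call(c, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(cpg)) GenomicRanges::GRanges(seqinfo = sinfo) else cpg
}

#' Simulate per-sample methylomes with planted effects
#'
#' For every CpG a baseline methylation level pi is drawn from
#' Beta(alpha, beta). \code{nEffectSites} randomly chosen sites get a planted
#' group difference: a non-control group (assigned round-robin) is shifted by
#' +/- \code{effectSize} percentage points, hyper/hypo balanced; if the
#' preferred direction would push the level outside [0, 1] (clipping the
#' realized difference), the direction is reflected so the planted difference
#' is always attained. Coverage is negative binomial; methylated counts are
#' beta-binomial with intra-class correlation rho
#' (\code{withinGroupOverdispersion}; rho = 0 gives binomial).
#'
#' @param design a \code{\link{simulationDesign}}.
#' @param cpgSites width-1 \code{GRanges} of CpG positions (from
#'   \code{\link{simulateGenome}}).
#' @param seed optional seed overriding \code{design$seed}.
#' @return A list with \code{calls} (a single multi-sample
#'   \linkS4class{MethylCallSet}), and \code{truth} (data.frame of planted
#'   sites: chrom, pos, group, contrasts, direction, planted_diff).
#' @export
simulateMethylomes <- function(design, cpgSites, seed = design$seed) {
  validateDesign(design)
  n <- length(cpgSites)
  if (n == 0L) stop("cpgSites is empty")
  if (design$nEffectSites > n)
    stop("design error: nEffectSites exceeds number of CpG sites")
  set.seed(seed)

  groups <- design$groups
  control <- groups[1]
  treatments <- groups[-1]
  pi0 <- stats::rbeta(n, design$baselineMethAlpha, design$baselineMethBeta)
  pi0 <- pmin(pmax(pi0, 1e-4), 1 - 1e-4)

  piMat <- matrix(pi0, nrow = n, ncol = length(groups),
                  dimnames = list(NULL, groups))
  truth <- data.frame(chrom = character(0), pos = integer(0),
                      group = character(0), contrasts = character(0),
                      direction = character(0), planted_diff = numeric(0))
  if (design$nEffectSites > 0L) {
    idx <- sort(sample.int(n, design$nEffectSites))
    tgt <- treatments[(seq_along(idx) - 1L) %% length(treatments) + 1L]
    dirs <- rep(c(1, -1), length.out = length(idx))
    eff <- design$effectSize / 100
    base <- pi0[idx]
    shifted <- base + dirs * eff
    flip <- shifted < 0 | shifted > 1
    dirs[flip] <- -dirs[flip]
    shifted <- base + dirs * eff
    shifted <- pmin(pmax(shifted, 0), 1)   # only reachable if effectSize>50
    for (g in treatments) {
      sel <- tgt == g
      piMat[idx[sel], g] <- shifted[sel]
    }
    # a site shifted in group g separates g from the control and from every
    # other treatment; contrasts named treatment:control with the group later
    # in `groups` as treatment (e.g. SO:SS)
    contrastName <- function(a, b) {
      ord <- match(c(a, b), groups)
      paste(c(a, b)[order(-ord)], collapse = ":")
    }
    ctr <- vapply(tgt, function(g) {
      others <- setdiff(treatments, g)
      paste(c(contrastName(g, control),
              vapply(others, contrastName, character(1), b = g)),
            collapse = ";")
    }, character(1))
    truth <- data.frame(chrom = as.character(GenomicRanges::seqnames(cpgSites)[idx]),
                        pos = GenomicRanges::start(cpgSites)[idx],
                        group = tgt,
                        contrasts = ctr,
                        direction = ifelse(dirs > 0, "hyper", "hypo"),
                        planted_diff = dirs * design$effectSize,
                        stringsAsFactors = FALSE)
  }

  nSamp <- length(groups) * design$samplesPerGroup
  sampleGroup <- rep(groups, each = design$samplesPerGroup)
  sampleIds <- sprintf("%s_%d", sampleGroup,
                       rep(seq_len(design$samplesPerGroup), length(groups)))
  cov <- matrix(0L, n, nSamp)
  met <- matrix(0L, n, nSamp)
  rho <- design$withinGroupOverdispersion
  for (j in seq_len(nSamp)) {
    mu <- design$meanCoverage
    cv <- if (design$coverageDispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / design$coverageDispersion)
    else stats::rpois(n, mu)
    p <- piMat[, sampleGroup[j]]
    if (rho > 0) {
      a <- p * (1 - rho) / rho
      b <- (1 - p) * (1 - rho) / rho
      p <- stats::rbeta(n, a, b)
    }
    cov[, j] <- cv
    met[, j] <- stats::rbinom(n, cv, p)
  }
  calls <- MethylCallSet(cpgSites, cov, met, sampleIds, sampleGroup)
  list(calls = calls, truth = truth)
}

#' Simulate a gene-to-pathway membership table
#'
#' Random gene-set assignment used to exercise the enrichment procedures on
#' synthetic data; every pathway draws its members uniformly from the gene
#' universe.
#'
#' @param geneIds character vector of gene identifiers (the universe).
#' @param nPathways number of pathways.
#' @param sizeRange inclusive range of pathway sizes.
#' @param seed integer seed.
#' @return data.frame with columns gene_id, pathway_id, pathway_name.
#' @export
simulatePathways <- function(geneIds, nPathways = 20L, sizeRange = c(5L, 15L),
                             seed = 1L) {
  set.seed(seed)
  sizeRange <- pmin(sizeRange, length(geneIds))
  rows <- lapply(seq_len(nPathways), function(i) {
    sz <- sample(seq(sizeRange[1], sizeRange[2]), 1L)
    data.frame(gene_id = sample(geneIds, sz),
               pathway_id = sprintf("pw%03d", i),
               pathway_name = sprintf("synthetic pathway %d", i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write simulated data to disk
#'
#' Exports the toy genome as FASTA, gene models as GFF3, one Bismark-dialect
#' coverage file per sample, and the planted-effect truth table as TSV.
#'
#' @param genome \code{DNAStringSet}.
#' @param geneModels GFF3-style \code{GRanges} (from
#'   \code{\link{simulateGenome}}).
#' @param calls a \linkS4class{MethylCallSet}.
#' @param truth truth-table data.frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of written paths.
#' @export
writeSimulatedData <- function(genome, geneModels, calls, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fa)
  gff <- file.path(dir, "genes.gff3")
  exportGeneModels(geneModels, gff)
  covFiles <- vapply(seq_len(ncol(calls)), function(j) {
    f <- file.path(dir, sprintf("%s.cov", colnames(calls)[j]))
    writeBismarkCov(calls[, j], f)
    f
  }, character(1))
  tt <- file.path(dir, "truth.tsv")
  utils::write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genome = fa, gff = gff, cov = covFiles, truth = tt))
}

# GFF3 writer: plain text, stable column order (rtracklayer's importer reads
# it back; writing by hand keeps attribute order deterministic for hashing).
exportGeneModels <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  attr <- ifelse(mc$Parent == "",
                 sprintf("ID=%s", mc$ID),
                 sprintf("ID=%s;Parent=%s", mc$ID, mc$Parent))
  lines <- sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(GenomicRanges::seqnames(gr)), mc$type,
                   GenomicRanges::start(gr), GenomicRanges::end(gr),
                   as.character(GenomicRanges::strand(gr)), attr)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
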