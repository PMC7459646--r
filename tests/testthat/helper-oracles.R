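# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval machinery: scalar arithmetic, double loops,
# base-R set operations.

# closed-form 2x2 G statistic from pooled counts
gStatOracle <- function(mA, cA, mB, cB) {
  o <- c(mA, cA - mA, mB, cB - mB)
  rowTot <- c(cA, cB)
  colTot <- c(mA + mB, cA + cB - mA - mB)
  n <- cA + cB
  e <- c(rowTot[1] * colTot / n, rowTot[2] * colTot / n)
  2 * sum(ifelse(o == 0, 0, o * log(o / e)))
}

# per-gene label intervals from canonical models, by scalar arithmetic
oracleGeneIntervals <- function(canon, chromLens) {
  mrna <- canon$mrna
  exons <- canon$exons
  out <- list()
  for (i in seq_along(mrna)) {
    g <- S4Vectors::mcols(mrna)$gene_id[i]
    tx <- S4Vectors::mcols(mrna)$tx_id[i]
    chrom <- as.character(GenomicRanges::seqnames(mrna))[i]
    L <- chromLens[[chrom]]
    minus <- as.character(GenomicRanges::strand(mrna))[i] == "-"
    ms <- GenomicRanges::start(mrna)[i]
    me <- GenomicRanges::end(mrna)[i]
    tss <- if (minus) me else ms
    ex <- exons[S4Vectors::mcols(exons)$tx_id == tx]
    exIv <- cbind(GenomicRanges::start(ex), GenomicRanges::end(ex))
    # introns: positions in [ms, me] not in any exon
    inExon <- rep(FALSE, me - ms + 1)
    for (j in seq_len(nrow(exIv))) {
      a <- max(ms, exIv[j, 1]); b <- min(me, exIv[j, 2])
      if (a <= b) inExon[(a:b) - ms + 1] <- TRUE
    }
    r <- rle(inExon)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    inIv <- cbind(starts[!r$values] + ms - 1, ends[!r$values] + ms - 1)
    tier <- function(d1, d2) {
      if (minus) c(tss + d1, tss + d2) else c(tss - d2, tss - d1)
    }
    clamp <- function(iv) {
      iv[1] <- max(1, iv[1]); iv[2] <- min(L, iv[2])
      if (iv[1] > iv[2]) NULL else iv
    }
    down <- if (minus) c(ms - 10000, ms - 1) else c(me + 1, me + 10000)
    ivs <- list(exon = exIv, intron = inIv,
                P250 = rbind(clamp(tier(1, 250))),
                P1K = rbind(clamp(tier(251, 1000))),
                P6K = rbind(clamp(tier(1001, 6000))),
                flanks = rbind(clamp(tier(6001, 10000)), clamp(down)))
    out[[length(out) + 1]] <- list(gene = g, chrom = chrom, ivs = ivs)
  }
  out
}

# all-overlaps + precedence label per site
oracleAnnotate <- function(chrom, pos, geneIvs) {
  levs <- c("exon", "intron", "P250", "P1K", "P6K", "flanks", "intergenic")
  vapply(seq_along(pos), function(k) {
    best <- 7L
    for (gi in geneIvs) {
      if (gi$chrom != chrom[k]) next
      for (lab in seq_len(6)) {
        iv <- gi$ivs[[lab]]
        if (is.null(iv) || nrow(iv) == 0) next
        for (j in seq_len(nrow(iv)))
          if (pos[k] >= iv[j, 1] && pos[k] <= iv[j, 2]) best <- min(best, lab)
      }
    }
    levs[best]
  }, character(1))
}

# small united MethylCallSet built directly from matrices
makeUnited <- function(cov, met, groups, chrom = "chr1") {
  n <- nrow(cov)
  sites <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(seq_len(n) * 10, width = 1))
  ids <- sprintf("%s_%d", groups, stats::ave(seq_along(groups), groups,
                                             FUN = seq_along))
  MethylCallSet(sites, cov, met, ids, groups)
}

# simulate a two-group 4v4 contrast at the stated coverage and test every
# site with complete coverage; returns the DiffMethResult plus the truth
simulateContrast <- function(nSites = 10000, coverage = 30, nEffect = 0,
                             effectSize = 30, seed = 1) {
  d <- simulationDesign(groups = c("NC", "SS"), samplesPerGroup = 4,
                        meanCoverage = coverage, nEffectSites = nEffect,
                        effectSize = effectSize, seed = seed)
  sites <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq_len(nSites) * 10,
                                                   width = 1))
  mm <- simulateMethylomes(d, sites, seed = seed)
  testable <- rowSums(methCoverage(mm$calls) == 0) == 0
  list(result = diffMeth(mm$calls[testable, ], "SS", "NC"),
       truth = mm$truth, nTested = sum(testable))
}
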