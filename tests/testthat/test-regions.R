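# hand-built transcript table: one helper shared by these tests
mkModels <- function(df, exonsDf) {
  mrna <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
  S4Vectors::mcols(mrna) <- S4Vectors::DataFrame(gene_id = df$gene,
                                                 tx_id = df$tx)
  ex <- GenomicRanges::GRanges(exonsDf$chrom,
                               IRanges::IRanges(exonsDf$start, exonsDf$end),
                               strand = exonsDf$strand)
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(tx_id = exonsDf$tx)
  list(mrna = mrna, exons = ex)
}

fullExon <- function(df) data.frame(chrom = df$chrom, start = df$start,
                                    end = df$end, strand = df$strand,
                                    tx = df$tx)

test_that("canonical isoform selection keeps the longest transcript", {
  df <- data.frame(chrom = "chr1", start = c(1000, 1200, 5000),
                   end = c(1899, 2399, 5800), strand = "+",
                   gene = c("gA", "gA", "gB"),
                   tx = c("gA.t1", "gA.t2", "gB.t1"))
  m <- mkModels(df, fullExon(df))
  canon <- selectCanonicalIsoforms(m)
  expect_equal(S4Vectors::mcols(canon$mrna)$tx_id, c("gA.t2", "gB.t1"))
  # single-isoform gene passes through unchanged
  expect_equal(GenomicRanges::start(canon$mrna[2]), 5000L)
  # transcript without exons is rejected
  m2 <- mkModels(df, fullExon(df)[-1, ])
  expect_error(selectCanonicalIsoforms(m2), "without exons")
})

test_that("canonical selection matches the argmax-length oracle on random genes", {
  set.seed(31)
  rows <- list(); exrows <- list()
  for (g in 1:50) {
    nIso <- sample(2:4, 1)
    base <- g * 20000
    for (t in seq_len(nIso)) {
      s <- base + sample(0:500, 1)
      e <- s + sample(500:5000, 1)
      tx <- sprintf("g%02d.t%d", g, t)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chr1", start = s, end = e, strand = "+",
        gene = sprintf("g%02d", g), tx = tx)
      # two exons covering part of the transcript
      mid <- s + (e - s) %/% 2
      exrows[[length(exrows) + 1]] <- data.frame(
        chrom = "chr1", start = c(s, mid + 100), end = c(mid - 100, e),
        strand = "+", tx = tx)
    }
  }
  df <- do.call(rbind, rows); exdf <- do.call(rbind, exrows)
  canon <- selectCanonicalIsoforms(mkModels(df, exdf))
  # oracle: per gene, argmax of summed exon widths, ties to smallest tx id
  txLen <- tapply(exdf$end - exdf$start + 1, exdf$tx, sum)
  oracle <- vapply(split(df, df$gene), function(d) {
    len <- txLen[d$tx]
    d$tx[order(-len, d$tx)][1]
  }, character(1))
  expect_setequal(S4Vectors::mcols(canon$mrna)$tx_id, unname(oracle))
})

test_that("promoter tiers sit upstream of the TSS with strand symmetry and clipping", {
  df <- data.frame(chrom = "chr1", start = c(10001, 30001, 101),
                   end = c(12000, 32000, 1500), strand = c("+", "-", "+"),
                   gene = c("gP", "gM", "gEdge"),
                   tx = c("gP.t1", "gM.t1", "gEdge.t1"))
  canon <- selectCanonicalIsoforms(mkModels(df, fullExon(df)))
  map <- buildRegionMap(canon, c(chr1 = 50000L))
  r <- regionRanges(map)
  lab <- S4Vectors::mcols(r)$label
  gid <- S4Vectors::mcols(r)$gene_id
  iv <- function(g, l) {
    i <- which(gid == g & lab == l)
    cbind(GenomicRanges::start(r)[i], GenomicRanges::end(r)[i])
  }
  # plus strand, TSS at 10001: P250 covers [9751, 10000]
  expect_equal(iv("gP", "P250"), cbind(9751L, 10000L))
  expect_equal(iv("gP", "P1K"), cbind(9001L, 9750L))
  expect_equal(iv("gP", "P6K"), cbind(4001L, 9000L))
  # flanks: 6001-10000 upstream plus 10 kb downstream of the 3' end
  expect_equal(iv("gP", "flanks")[order(iv("gP", "flanks")[, 1]), ],
               rbind(c(1L, 4000L), c(12001L, 22000L)))
  # minus strand, TSS at 32000: tiers mirror to the right
  expect_equal(iv("gM", "P250"), cbind(32001L, 32250L))
  expect_equal(iv("gM", "P1K"), cbind(32251L, 33000L))
  expect_equal(iv("gM", "P6K"), cbind(33001L, 38000L))
  # gene near the chromosome start: clipped at 1, P6K partially present
  expect_equal(unname(iv("gEdge", "P250")), cbind(1L, 100L))
  expect_equal(nrow(iv("gEdge", "P1K")), 0L)
  # TSS outside bounds errors
  bad <- canon
  S4Vectors::mcols(bad$mrna)$tss[1] <- 60000L
  expect_error(buildRegionMap(bad, c(chr1 = 50000L)), "outside chromosome")
})

test_that("precedence gives a single label with exon winning over promoters", {
  # gene A exon overlapping gene B's P250
  df <- data.frame(chrom = "chr1", start = c(5000, 10200), end = c(9900, 12000),
                   strand = "+", gene = c("gA", "gB"),
                   tx = c("gA.t1", "gB.t1"))
  canon <- selectCanonicalIsoforms(mkModels(df, fullExon(df)))
  map <- buildRegionMap(canon, c(chr1 = 60000L))
  # site 9960 is in gA's exon (5000-9900)? no - pick inside both:
  # gB P250 = [9950, 10199]; gA exon = [5000, 9900]; overlap needs a site in
  # gA exon AND gB P250 -> extend gA to 10000
  df$end[1] <- 10000
  canon <- selectCanonicalIsoforms(mkModels(df, fullExon(df)))
  map <- buildRegionMap(canon, c(chr1 = 60000L))
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9980, 9980))
  ann <- annotateCpGs(site, map)
  expect_equal(as.character(S4Vectors::mcols(ann)$label), "exon")
  expect_equal(S4Vectors::mcols(ann)$gene_id, "gA")
  # a site 12 kb from every gene is intergenic
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(40000, 40000))
  expect_equal(as.character(S4Vectors::mcols(annotateCpGs(far, map))$label),
               "intergenic")
  # unknown chromosome errors
  expect_error(annotateCpGs(GenomicRanges::GRanges("chrX",
                                                   IRanges::IRanges(1, 1)),
                            map), "unknown chromosome")
})

test_that("annotation equals the brute-force all-overlaps oracle", {
  for (seed in c(101, 202)) {
    d <- simulationDesign(nChromosomes = 2, chromLength = 5e4, nGenes = 8,
                          seed = seed)
    sim <- simulateGenome(d)
    canon <- selectCanonicalIsoforms(parseGeneModels(sim$geneModels))
    lens <- stats::setNames(rep(d$chromLength, d$nChromosomes),
                            paste0("chr", 1:d$nChromosomes))
    map <- buildRegionMap(canon, lens)
    set.seed(seed)
    chrom <- sample(names(lens), 2000, replace = TRUE)
    pos <- sample(d$chromLength, 2000, replace = TRUE)
    sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    ann <- annotateCpGs(sites, map)
    oracle <- oracleAnnotate(chrom, pos, oracleGeneIntervals(canon, lens))
    expect_identical(as.character(S4Vectors::mcols(ann)$label), oracle)
    # idempotence: re-annotating changes nothing
    ann2 <- annotateCpGs(GenomicRanges::granges(ann), map)
    expect_identical(S4Vectors::mcols(ann2)$label,
                     S4Vectors::mcols(ann)$label)
  }
})

test_that("region fractions partition the site set", {
  labs <- c(rep("exon", 3), rep("intergenic", 5), "P250", "flanks")
  fr <- regionDistribution(labs)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(unname(fr["exon"]), 0.3)
  # scale invariance under duplication
  expect_equal(regionDistribution(rep(labs, 3)), fr)
  # all intergenic
  fr2 <- regionDistribution(rep("intergenic", 7))
  expect_equal(unname(fr2["intergenic"]), 1)
  expect_equal(sum(fr2[names(fr2) != "intergenic"]), 0)
  expect_error(regionDistribution(character(0)), "empty")
})

test_that("labels are invariant under genome mirroring", {
  df <- data.frame(chrom = "chr1", start = c(12000, 30000),
                   end = c(15000, 34000), strand = c("+", "-"),
                   gene = c("gA", "gB"), tx = c("gA.t1", "gB.t1"))
  L <- 50000L
  canon <- selectCanonicalIsoforms(mkModels(df, fullExon(df)))
  map <- buildRegionMap(canon, c(chr1 = L))
  pos <- seq(1L, L, by = 97L)
  ann <- annotateCpGs(GenomicRanges::GRanges("chr1",
                                             IRanges::IRanges(pos, pos)), map)
  # mirrored genome: coordinates reflected, strands flipped
  dfm <- data.frame(chrom = "chr1", start = L - df$end + 1L,
                    end = L - df$start + 1L,
                    strand = ifelse(df$strand == "+", "-", "+"),
                    gene = df$gene, tx = df$tx)
  canonM <- selectCanonicalIsoforms(mkModels(dfm, fullExon(dfm)))
  mapM <- buildRegionMap(canonM, c(chr1 = L))
  posM <- L - pos + 1L
  annM <- annotateCpGs(GenomicRanges::GRanges("chr1",
                                              IRanges::IRanges(posM, posM)),
                       mapM)
  expect_identical(as.character(S4Vectors::mcols(ann)$label),
                   as.character(S4Vectors::mcols(annM)$label))
})
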