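test_that("per-site test: direct arithmetic and degenerate cases", {
  # identical pooled proportions: zero difference, p ~ 1
  r0 <- perSiteTest(c(10, 10), c(20, 20), c(5, 15), c(10, 30))
  expect_equal(r0$meth.diff, 0)
  expect_equal(r0$pvalue, 1, tolerance = 1e-9)
  # strong difference: 40/50 vs 10/50 pooled
  r1 <- perSiteTest(40, 50, 10, 50)
  expect_equal(r1$meth.diff, 60)
  expect_lt(r1$pvalue, 1e-8)
  expect_equal(r1$statistic, gStatOracle(40, 50, 10, 50), tolerance = 1e-8)
  # boundary table triggers the flagged continuity correction
  rb <- perSiteTest(0, 30, 12, 30)
  expect_true(rb$corrected)
  expect_true(is.finite(rb$statistic))
})

test_that("glm likelihood-ratio equals the closed-form G statistic", {
  set.seed(12)
  for (i in 1:300) {
    cA <- sample(20:80, 1); cB <- sample(20:80, 1)
    mA <- min(max(rbinom(1, cA, runif(1, 0.15, 0.85)), 1), cA - 1)
    mB <- min(max(rbinom(1, cB, runif(1, 0.15, 0.85)), 1), cB - 1)
    r <- perSiteTest(mA, cA, mB, cB)
    expect_equal(r$statistic, gStatOracle(mA, cA, mB, cB), tolerance = 1e-8)
  }
})

test_that("vectorized contrast agrees with the per-site glm route", {
  set.seed(13)
  n <- 200
  cov <- matrix(sample(15:60, n * 8, replace = TRUE), n, 8)
  met <- matrix(rbinom(n * 8, as.vector(cov), runif(n * 8, 0.1, 0.9)), n, 8)
  un <- makeUnited(cov, met, rep(c("NC", "SS"), each = 4))
  res <- diffMeth(un, "SS", "NC")
  mc <- S4Vectors::mcols(resultSites(res))
  idx <- sample(n, 40)
  for (i in idx) {
    r <- perSiteTest(met[i, 5:8], cov[i, 5:8], met[i, 1:4], cov[i, 1:4])
    expect_equal(mc$pvalue[i], r$pvalue, tolerance = 1e-8)
    expect_equal(mc$meth.diff[i], r$meth.diff, tolerance = 1e-10)
  }
})

test_that("swapping treatment and control negates differences and swaps status", {
  set.seed(14)
  n <- 500
  cov <- matrix(sample(20:50, n * 8, replace = TRUE), n, 8)
  p <- rep(runif(n, 0.1, 0.9), 8)
  met <- matrix(rbinom(n * 8, as.vector(cov), p), n, 8)
  un <- makeUnited(cov, met, rep(c("NC", "SS"), each = 4))
  a <- callDmcs(diffMeth(un, "SS", "NC"), qMax = 0.2, minDiff = 5)
  b <- callDmcs(diffMeth(un, "NC", "SS"), qMax = 0.2, minDiff = 5)
  ma <- S4Vectors::mcols(resultSites(a)); mb <- S4Vectors::mcols(resultSites(b))
  expect_equal(mb$meth.diff, -ma$meth.diff)
  expect_equal(mb$pvalue, ma$pvalue)
  expect_equal(mb$qvalue, ma$qvalue)
  swap <- c(hyper = "hypo", hypo = "hyper", ns = "ns")
  expect_identical(as.character(mb$status),
                   unname(swap[as.character(ma$status)]))
})

test_that("DMC thresholds follow the q < 0.01 and |diff| >= 20 rule exactly", {
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:4 * 100, width = 1))
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    meanTreatment = c(50, 50, 80, 25), meanControl = c(25, 30.1, 20, 50),
    meth.diff = c(25, 19.9, 60, -25),
    statistic = NA_real_, pvalue = c(0.001, 0.001, 0.01, 0.001),
    qvalue = c(0.005, 0.005, 0.02, 0.005), corrected = FALSE)
  res <- callDmcs(DiffMethResult(sites, "SS", "NC"))
  st <- as.character(S4Vectors::mcols(resultSites(res))$status)
  expect_identical(st, c("hyper", "ns", "ns", "hypo"))
  expect_equal(length(dmcs(res)), 2L)
})

test_that("gene mapping tallies DMCs by sub-region and flags promoters", {
  sites <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1:6 * 50, width = 1))
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    meanTreatment = 50, meanControl = 20, meth.diff = c(30, 30, -30, 30, 30, -30),
    statistic = NA_real_, pvalue = 1e-5, qvalue = c(1e-4, 1e-4, 1e-4, 1e-4, 0.5, 1e-4),
    corrected = FALSE,
    label = factor(c("P250", "exon", "intron", "intergenic", "exon", "flanks"),
                   levels = regionLevels()),
    gene_id = c("g1", "g2", "g2", NA, "g3", "g4"))
  res <- callDmcs(DiffMethResult(sites, "SS", "NC"))
  tab <- mapDmcsToGenes(res)
  expect_setequal(tab$gene_id, c("g1", "g2"))      # g3 ns, g4 flank-only
  g1 <- tab[tab$gene_id == "g1", ]
  expect_equal(g1$P250, 1L); expect_true(g1$promoter)
  expect_equal(g1$hyper, 1L); expect_equal(g1$hypo, 0L)
  g2 <- tab[tab$gene_id == "g2", ]
  expect_equal(g2$exon + g2$intron, 2L); expect_false(g2$promoter)
  # only intergenic DMCs: no DMGs
  s2 <- sites
  S4Vectors::mcols(s2)$label <- factor("intergenic", levels = regionLevels())
  S4Vectors::mcols(s2)$gene_id <- NA_character_
  expect_equal(nrow(mapDmcsToGenes(callDmcs(DiffMethResult(s2, "SS", "NC")))),
               0L)
})

test_that("per-gene tallies equal a brute-force group-by of the DMC table", {
  set.seed(15)
  n <- 400
  labels <- sample(regionLevels(), n, replace = TRUE)
  genes <- ifelse(labels == "intergenic", NA,
                  sprintf("g%02d", sample(1:25, n, replace = TRUE)))
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:n * 10, width = 1))
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    meanTreatment = 50, meanControl = 20,
    meth.diff = sample(c(-30, 30, 5), n, replace = TRUE),
    statistic = NA_real_, pvalue = 1e-5,
    qvalue = sample(c(1e-4, 0.5), n, replace = TRUE), corrected = FALSE,
    label = factor(labels, levels = regionLevels()), gene_id = genes)
  res <- callDmcs(DiffMethResult(sites, "SS", "NC"))
  tab <- mapDmcsToGenes(res)
  # oracle: plain data.frame aggregation
  mc <- as.data.frame(S4Vectors::mcols(resultSites(res)))
  dmc <- mc[mc$status != "ns" & !is.na(mc$gene_id) &
              mc$label != "intergenic", ]
  for (g in unique(dmc$gene_id)) {
    d <- dmc[dmc$gene_id == g, ]
    inBodyProm <- sum(d$label %in% c("exon", "intron", "P250", "P1K", "P6K"))
    row <- tab[tab$gene_id == g, ]
    if (inBodyProm == 0) { expect_equal(nrow(row), 0L); next }
    expect_equal(row$hyper, sum(d$status == "hyper"))
    expect_equal(row$hypo, sum(d$status == "hypo"))
    for (rg in c("exon", "intron", "P250", "P1K", "P6K", "flanks"))
      expect_equal(row[[rg]], sum(d$label == rg))
  }
  # bookkeeping: hyper + hypo = total per sub-region
  byRegion <- table(dmc$label, dmc$status)
  expect_equal(unname(rowSums(byRegion[, c("hyper", "hypo")])),
               as.vector(table(factor(dmc$label,
                                      levels = rownames(byRegion)))))
})

test_that("contrast overlaps equal brute-force set algebra", {
  expect_equal(sum(overlapContrasts(list(a = c("x", "y"),
                                         b = c("z")))$count), 3)
  idSets <- list(a = letters[1:10], b = letters[6:15], c = letters[c(1, 8:12)])
  ov <- overlapContrasts(idSets)
  # every cell checked against direct set operations
  for (i in seq_len(nrow(ov))) {
    inSets <- names(idSets)[unlist(ov[i, names(idSets)])]
    outSets <- setdiff(names(idSets), inSets)
    members <- Reduce(intersect, idSets[inSets])
    for (o in outSets) members <- setdiff(members, idSets[[o]])
    expect_equal(ov$count[i], length(members))
  }
  expect_equal(unname(attr(ov, "totals")), c(10L, 10L, 6L))
  # identical sets collapse to one cell
  same <- overlapContrasts(list(a = letters[1:5], b = letters[1:5]))
  expect_equal(same$count, 5)
  expect_true(all(unlist(same[, c("a", "b")])))
})
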