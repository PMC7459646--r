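# binomial log-likelihood kernel, 0*log(0) treated as 0
.llBinom <- function(m, c) {
  p <- m / c
  t1 <- ifelse(m == 0, 0, m * log(p))
  t2 <- ifelse(c - m == 0, 0, (c - m) * log(1 - p))
  t1 + t2
}

# LRT (deviance) statistic of group vs intercept-only binomial model from
# pooled group counts; equals the 2x2 G statistic. Boundary tables (a group
# at 0% or 100%) get a 0.5 continuity correction, flagged.
.pooledLRT <- function(mA, cA, mB, cB) {
  corrected <- mA == 0 | mA == cA | mB == 0 | mB == cB
  mA2 <- ifelse(corrected, mA + 0.5, mA)
  cA2 <- ifelse(corrected, cA + 1, cA)
  mB2 <- ifelse(corrected, mB + 0.5, mB)
  cB2 <- ifelse(corrected, cB + 1, cB)
  g <- 2 * (.llBinom(mA2, cA2) + .llBinom(mB2, cB2) -
              .llBinom(mA2 + mB2, cA2 + cB2))
  g <- pmax(g, 0)
  list(statistic = g,
       pvalue = stats::pchisq(g, df = 1, lower.tail = FALSE),
       corrected = corrected)
}

#' Single-site differential methylation test via logistic regression
#'
#' Fits a binomial logistic regression of (methylated, unmethylated) counts
#' on the group indicator with \code{stats::glm} and tests the group effect
#' by the likelihood-ratio (deviance) chi-square with 1 df. The methylation
#' difference is the difference of count-pooled group percentages
#' (treatment - control). When a pooled group sits at 0% or 100%
#' (separation), the test is recomputed on the 0.5-continuity-corrected
#' pooled 2x2 table and flagged.
#'
#' @param methTreatment,covTreatment methylated and total counts per
#'   treatment replicate.
#' @param methControl,covControl same for the control group.
#' @return list: \code{meth.diff} (points), \code{statistic}, \code{pvalue},
#'   \code{corrected}.
#' @export
#' @examples
#' perSiteTest(c(38, 42), c(50, 50), c(11, 9), c(50, 50))
perSiteTest <- function(methTreatment, covTreatment,
                        methControl, covControl) {
  stopifnot(length(methTreatment) == length(covTreatment),
            length(methControl) == length(covControl),
            all(covTreatment > 0), all(covControl > 0),
            all(methTreatment >= 0 & methTreatment <= covTreatment),
            all(methControl >= 0 & methControl <= covControl))
  mT <- sum(methTreatment); cT <- sum(covTreatment)
  mC <- sum(methControl); cC <- sum(covControl)
  delta <- 100 * (mT / cT - mC / cC)
  boundary <- mT == 0 || mT == cT || mC == 0 || mC == cC
  if (boundary) {
    r <- .pooledLRT(mT, cT, mC, cC)
    return(list(meth.diff = delta, statistic = r$statistic,
                pvalue = r$pvalue, corrected = TRUE))
  }
  meth <- c(methTreatment, methControl)
  cov <- c(covTreatment, covControl)
  grp <- factor(c(rep("T", length(methTreatment)),
                  rep("C", length(methControl))), levels = c("C", "T"))
  fit <- stats::glm(cbind(meth, cov - meth) ~ grp, family = stats::binomial())
  fit0 <- stats::glm(cbind(meth, cov - meth) ~ 1, family = stats::binomial())
  g <- fit0$deviance - fit$deviance
  list(meth.diff = delta, statistic = g,
       pvalue = stats::pchisq(g, df = 1, lower.tail = FALSE),
       corrected = FALSE)
}

#' Per-CpG differential methylation over a united contrast
#'
#' For every united site, pools counts within each group, computes the
#' methylation difference in percentage points (treatment - control) and a
#' likelihood-ratio chi-square p-value from the binomial logistic regression
#' of methylation state on group (computed in its closed pooled form, which
#' is identical to the \code{glm} fit - see \code{\link{perSiteTest}}), then
#' converts p-values to SLIM q-values.
#'
#' @param united a multi-sample \linkS4class{MethylCallSet} from
#'   \code{\link{uniteSamples}} containing both groups.
#' @param treatment,control group labels.
#' @return A \linkS4class{DiffMethResult}.
#' @export
diffMeth <- function(united, treatment, control) {
  grp <- sampleGroups(united)
  if (!treatment %in% grp || !control %in% grp)
    stop("treatment/control label not present among samples")
  iT <- grp == treatment
  iC <- grp == control
  cv <- methCoverage(united)
  mt <- methCounts(united)
  if (any(cv[, iT | iC] == 0))
    stop("zero coverage at a united site; filter before uniting")
  mT <- rowSums(mt[, iT, drop = FALSE]); cT <- rowSums(cv[, iT, drop = FALSE])
  mC <- rowSums(mt[, iC, drop = FALSE]); cC <- rowSums(cv[, iC, drop = FALSE])
  r <- .pooledLRT(mT, cT, mC, cC)
  sl <- slimQvalues(r$pvalue)
  sites <- GenomicRanges::granges(SummarizedExperiment::rowRanges(united))
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    meanTreatment = 100 * mT / cT,
    meanControl = 100 * mC / cC,
    meth.diff = 100 * (mT / cT - mC / cC),
    statistic = r$statistic,
    pvalue = r$pvalue,
    qvalue = sl$qvalues,
    corrected = r$corrected)
  DiffMethResult(sites, treatment, control, sl$pi0)
}

#' Call differentially methylated cytosines
#'
#' A site is a DMC iff q-value < \code{qMax} and |methylation difference| >=
#' \code{minDiff} percentage points; hypermethylated if the difference is
#' positive, hypomethylated if negative, otherwise "ns".
#'
#' @param res a \linkS4class{DiffMethResult}.
#' @param qMax q-value threshold (default 0.01, strict).
#' @param minDiff minimum absolute difference in points (default 20,
#'   inclusive).
#' @return the result with a \code{status} mcol set and the thresholds
#'   recorded in the object metadata of its sites.
#' @export
callDmcs <- function(res, qMax = 0.01, minDiff = 20) {
  mc <- S4Vectors::mcols(res@sites)
  isDmc <- mc$qvalue < qMax & abs(mc$meth.diff) >= minDiff
  status <- ifelse(!isDmc, "ns", ifelse(mc$meth.diff > 0, "hyper", "hypo"))
  S4Vectors::mcols(res@sites)$status <-
    factor(status, levels = c("hyper", "hypo", "ns"))
  S4Vectors::metadata(res@sites)$qMax <- qMax
  S4Vectors::metadata(res@sites)$minDiff <- minDiff
  validObject(res)
  res
}

#' Tally DMCs per gene and call differentially methylated genes
#'
#' A gene is a DMG when it carries at least one DMC in its gene body (exon
#' or intron) or promoter (P250, P1K or P6K). Flank DMCs are tallied per
#' gene for reporting but do not by themselves create a DMG; intergenic DMCs
#' map to no gene.
#'
#' @param res a \linkS4class{DiffMethResult} that has been through
#'   \code{\link{callDmcs}} and \code{\link{annotateResults}}.
#' @return data.frame: gene_id, one DMC-count column per sub-region (exon,
#'   intron, P250, P1K, P6K, flanks), hyper, hypo, and logical
#'   \code{promoter} (>= 1 promoter DMC).
#' @export
mapDmcsToGenes <- function(res) {
  mc <- S4Vectors::mcols(res@sites)
  if (!all(c("status", "label", "gene_id") %in% colnames(mc)))
    stop("run callDmcs() and annotateResults() first")
  d <- as.data.frame(mc[mc$status %in% c("hyper", "hypo"), ,
                        drop = FALSE])
  d <- d[!is.na(d$gene_id) & d$label != "intergenic", , drop = FALSE]
  if (any(is.na(d$label))) stop("DMC with unknown label")
  subRegions <- c("exon", "intron", "P250", "P1K", "P6K", "flanks")
  if (nrow(d) == 0L) {
    out <- data.frame(gene_id = character(0))
    for (r in subRegions) out[[r]] <- integer(0)
    out$hyper <- integer(0); out$hypo <- integer(0)
    out$promoter <- logical(0)
    return(out)
  }
  genes <- sort(unique(d$gene_id))
  tab <- table(factor(d$gene_id, levels = genes),
               factor(as.character(d$label), levels = subRegions))
  st <- table(factor(d$gene_id, levels = genes),
              factor(as.character(d$status), levels = c("hyper", "hypo")))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (r in subRegions) out[[r]] <- as.integer(tab[, r])
  out$hyper <- as.integer(st[, "hyper"])
  out$hypo <- as.integer(st[, "hypo"])
  out$promoter <- (out$P250 + out$P1K + out$P6K) >= 1L
  body <- out$exon + out$intron
  out[body + out$P250 + out$P1K + out$P6K >= 1L, , drop = FALSE]
}

#' Venn overlap of DMG sets across contrasts
#'
#' @param dmgSets named list (>= 2) of gene-id character vectors.
#' @return data.frame with one row per non-empty membership pattern:
#'   logical columns per set plus \code{count}, and attribute
#'   \code{"totals"} with per-set sizes.
#' @export
overlapContrasts <- function(dmgSets) {
  stopifnot(length(dmgSets) >= 2L, !is.null(names(dmgSets)))
  all <- sort(unique(unlist(dmgSets)))
  if (length(all) == 0L) {
    out <- as.data.frame(matrix(logical(0), 0, length(dmgSets),
                                dimnames = list(NULL, names(dmgSets))))
    out$count <- integer(0)
    attr(out, "totals") <- vapply(dmgSets, length, integer(1))
    return(out)
  }
  member <- vapply(dmgSets, function(s) all %in% s, logical(length(all)))
  member <- matrix(member, ncol = length(dmgSets),
                   dimnames = list(NULL, names(dmgSets)))
  pat <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- unique(pat)
  out <- do.call(rbind, lapply(pats, function(p) {
    flags <- strsplit(p, "", fixed = TRUE)[[1]] == "1"
    df <- as.data.frame(as.list(flags))
    names(df) <- names(dmgSets)
    df$count <- sum(pat == p)
    df
  }))
  out <- out[do.call(order, c(as.list(out[names(dmgSets)]),
                              decreasing = TRUE)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "totals") <- vapply(dmgSets, function(s) length(unique(s)),
                                integer(1))
  out
}
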