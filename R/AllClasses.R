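#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels Seqinfo seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

#' Region labels in precedence order
#'
#' The unique per-CpG annotation vocabulary. When a CpG falls in regions of
#' several genes (or several regions of one gene), the earliest label in this
#' vector wins: exon > intron > P250 > P1K > P6K > flanks > intergenic.
#' P250/P1K/P6K are the promoter tiers 1-250, 251-1000 and 1001-6000 bp
#' upstream of the TSS; flanks are 6001-10000 bp upstream of the TSS plus
#' 10 kb downstream of the mRNA 3' end.
#'
#' @return Character vector of the seven labels, highest precedence first.
#' @export
#' @examples
#' regionLevels()
regionLevels <- function() {
  c("exon", "intron", "P250", "P1K", "P6K", "flanks", "intergenic")
}

#' MethylCallSet: CpG methylation counts over samples
#'
#' A \linkS4class{RangedSummarizedExperiment} holding per-CpG bisulfite
#' counts: assays \code{coverage} (total reads) and \code{methylated}
#' (methylated reads), one column per sample, with \code{colData} columns
#' \code{sample} and \code{group}. Rows are CpG positions (width-1
#' \code{GRanges}, the C of the CpG on the indexed strand).
#'
#' @slot .. inherits all slots from RangedSummarizedExperiment.
#' @export
setClass("MethylCallSet", contains = "RangedSummarizedExperiment")

setValidity("MethylCallSet", function(object) {
  msg <- NULL
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("coverage", "methylated") %in% an))
    msg <- c(msg, "assays must include 'coverage' and 'methylated'")
  else {
    cv <- SummarizedExperiment::assay(object, "coverage")
    mt <- SummarizedExperiment::assay(object, "methylated")
    if (any(cv < 0) || any(mt < 0))
      msg <- c(msg, "counts must be non-negative")
    if (any(mt > cv))
      msg <- c(msg, "methylated count exceeds coverage at some site")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample", "group") %in% colnames(cd)))
    msg <- c(msg, "colData must carry 'sample' and 'group'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MethylCallSet
#'
#' @param sites \code{GRanges} of CpG positions (width 1).
#' @param coverage,methylated integer matrices, sites x samples.
#' @param sample character vector of sample identifiers.
#' @param group character vector of group labels, parallel to \code{sample}.
#' @return A \linkS4class{MethylCallSet}.
#' @export
MethylCallSet <- function(sites, coverage, methylated, sample, group) {
  coverage <- as.matrix(coverage)
  methylated <- as.matrix(methylated)
  storage.mode(coverage) <- "integer"
  storage.mode(methylated) <- "integer"
  colnames(coverage) <- sample
  colnames(methylated) <- sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(coverage = coverage, methylated = methylated),
    rowRanges = sites,
    colData = S4Vectors::DataFrame(sample = sample, group = group,
                                   row.names = sample))
  new("MethylCallSet", se)
}

#' @describeIn MethylCallSet coverage matrix accessor.
#' @param x a MethylCallSet.
#' @export
methCoverage <- function(x) SummarizedExperiment::assay(x, "coverage")

#' @describeIn MethylCallSet methylated-count matrix accessor.
#' @export
methCounts <- function(x) SummarizedExperiment::assay(x, "methylated")

#' @describeIn MethylCallSet percent-methylation matrix (100 * M / coverage).
#' @export
methPercent <- function(x) {
  cv <- methCoverage(x)
  100 * methCounts(x) / ifelse(cv == 0, NA_integer_, cv)
}

#' @describeIn MethylCallSet group label per sample.
#' @export
sampleGroups <- function(x) {
  as.character(SummarizedExperiment::colData(x)$group)
}

setMethod("show", "MethylCallSet", function(object) {
  cat("MethylCallSet with", nrow(object), "CpG sites x",
      ncol(object), "samples\n")
  grp <- table(sampleGroups(object))
  cat("  groups:", paste(sprintf("%s(%d)", names(grp), grp), collapse = ", "),
      "\n")
})

#' RegionMap: precedence-annotated genomic regions
#'
#' Holds the labeled region intervals derived from canonical gene models
#' (exon, intron, promoter tiers P250/P1K/P6K, flanks) together with the
#' canonical models themselves. Used by \code{\link{annotateCpGs}} to assign
#' every CpG exactly one label under the precedence
#' exon > intron > P250 > P1K > P6K > flanks > intergenic.
#'
#' @slot regions \code{GRanges} with mcols \code{label} (factor over
#'   \code{regionLevels()}) and \code{gene_id}.
#' @slot genes \code{GRanges} of canonical mRNA extents with mcols
#'   \code{gene_id}, \code{tx_id} and \code{tss} (TSS coordinate, 1-based).
#' @export
setClass("RegionMap",
         representation(regions = "GRanges", genes = "GRanges"))

setValidity("RegionMap", function(object) {
  msg <- NULL
  mc <- S4Vectors::mcols(object@regions)
  if (!all(c("label", "gene_id") %in% colnames(mc)))
    msg <- c(msg, "regions must carry mcols 'label' and 'gene_id'")
  else if (!all(as.character(mc$label) %in% regionLevels()))
    msg <- c(msg, "unknown region label")
  if (length(object@genes) &&
      !all(c("gene_id", "tx_id", "tss") %in%
           colnames(S4Vectors::mcols(object@genes))))
    msg <- c(msg, "genes must carry mcols 'gene_id', 'tx_id', 'tss'")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RegionMap", function(object) {
  cat("RegionMap:", length(object@genes), "canonical genes,",
      length(object@regions), "labeled intervals\n")
  tb <- table(factor(S4Vectors::mcols(object@regions)$label,
                     levels = regionLevels()))
  cat("  ", paste(sprintf("%s:%d", names(tb), tb), collapse = " "), "\n")
})

#' @describeIn RegionMap the labeled region intervals.
#' @param x a RegionMap.
#' @export
regionRanges <- function(x) x@regions

#' @describeIn RegionMap the canonical gene models.
#' @export
canonicalGenes <- function(x) x@genes

#' DiffMethResult: per-CpG differential methylation results
#'
#' One record per united CpG for a two-group contrast: pooled group
#' methylation means, difference in percentage points (treatment - control),
#' likelihood-ratio p-value, SLIM q-value, and (after
#' \code{\link{callDmcs}}) a hyper/hypo/ns status; region label and gene id
#' are added by \code{\link{annotateResults}}.
#'
#' @slot sites \code{GRanges} with mcols \code{meanTreatment},
#'   \code{meanControl} (percent), \code{meth.diff} (points),
#'   \code{statistic}, \code{pvalue}, \code{qvalue}, \code{corrected}
#'   (continuity-correction flag), and optionally \code{status},
#'   \code{label}, \code{gene_id}.
#' @slot treatment,control group labels of the contrast.
#' @slot pi0 SLIM estimate of the null proportion.
#' @export
setClass("DiffMethResult",
         representation(sites = "GRanges", treatment = "character",
                        control = "character", pi0 = "numeric"))

setValidity("DiffMethResult", function(object) {
  msg <- NULL
  mc <- S4Vectors::mcols(object@sites)
  need <- c("meanTreatment", "meanControl", "meth.diff", "pvalue", "qvalue")
  if (!all(need %in% colnames(mc)))
    msg <- c(msg, paste("sites must carry mcols:", paste(need, collapse = ", ")))
  else {
    if (any(abs(mc$meth.diff) > 100 + 1e-9))
      msg <- c(msg, "meth.diff outside [-100, 100]")
    if (any(mc$qvalue < 0 | mc$qvalue > 1))
      msg <- c(msg, "qvalue outside [0, 1]")
    if ("status" %in% colnames(mc)) {
      st <- as.character(mc$status)
      if (any(st == "hyper" & mc$meth.diff <= 0) ||
          any(st == "hypo" & mc$meth.diff >= 0))
        msg <- c(msg, "status sign inconsistent with meth.diff")
    }
  }
  if (length(object@treatment) != 1L || length(object@control) != 1L)
    msg <- c(msg, "treatment and control must be single labels")
  if (is.null(msg)) TRUE else msg
})

#' Construct a DiffMethResult
#'
#' Normally produced by \code{\link{diffMeth}}; the constructor is exported
#' so result tables from other tools can be re-threshold with
#' \code{\link{callDmcs}}.
#'
#' @param sites \code{GRanges} with the result mcols (see class docs).
#' @param treatment,control contrast group labels.
#' @param pi0 SLIM null-proportion estimate (NA if unknown).
#' @return A \linkS4class{DiffMethResult}.
#' @export
DiffMethResult <- function(sites, treatment, control, pi0 = NA_real_) {
  new("DiffMethResult", sites = sites, treatment = treatment,
      control = control, pi0 = pi0)
}

setMethod("show", "DiffMethResult", function(object) {
  cat("DiffMethResult:", object@treatment, "vs", object@control,
      "(control),", length(object@sites), "sites\n")
  if (!is.na(object@pi0)) cat("  SLIM pi0 =", format(object@pi0, digits = 4), "\n")
  mc <- S4Vectors::mcols(object@sites)
  if ("status" %in% colnames(mc)) {
    tb <- table(factor(mc$status, levels = c("hyper", "hypo", "ns")))
    cat("  DMCs: hyper", tb[["hyper"]], "/ hypo", tb[["hypo"]], "\n")
  }
})

#' @describeIn DiffMethResult result GRanges accessor.
#' @param x a DiffMethResult.
#' @export
resultSites <- function(x) x@sites

#' @describeIn DiffMethResult SLIM pi0 accessor.
#' @export
slimPi0Estimate <- function(x) x@pi0

#' @describeIn DiffMethResult contrast labels, c(treatment, control).
#' @export
contrastLabels <- function(x) c(treatment = x@treatment, control = x@control)

#' @describeIn DiffMethResult subset of sites called DMC (requires
#'   \code{\link{callDmcs}} first).
#' @export
dmcs <- function(x) {
  mc <- S4Vectors::mcols(x@sites)
  if (!"status" %in% colnames(mc))
    stop("no DMC status yet; run callDmcs() first")
  x@sites[mc$status %in% c("hyper", "hypo")]
}
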