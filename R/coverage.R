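#' Read a Bismark coverage file
#'
#' Parses the Bismark \code{.cov} dialect (tab-separated: chrom, start, end,
#' percent methylation, count methylated, count unmethylated; 1-based
#' inclusive coordinates). The reported percentage is cross-checked against
#' the counts; a deviation beyond 0.5 percentage points raises a warning.
#' The format carries no strand, so sites are imported unstranded.
#'
#' @param path path to a \code{.cov} file (may be empty).
#' @param sample sample identifier; defaults to the file base name.
#' @param group group label for the sample.
#' @return A single-sample \linkS4class{MethylCallSet}.
#' @export
readBismarkCov <- function(path, sample = sub("\\.cov$", "", basename(path)),
                           group = NA_character_) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "pct",
                                    "meth", "unmeth"),
                      colClasses = c("character", "integer", "integer",
                                     "numeric", "integer", "integer")),
    error = function(e) {
      if (file.exists(path) && file.size(path) == 0)
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), pct = numeric(0),
                          meth = integer(0), unmeth = integer(0)))
      # re-read line-wise to report the offending line
      ln <- readLines(path)
      for (i in seq_along(ln)) {
        f <- strsplit(ln[i], "\t", fixed = TRUE)[[1]]
        if (length(f) != 6L || anyNA(suppressWarnings(as.numeric(f[2:6]))))
          stop("malformed coverage row at line ", i, " of ", path)
      }
      stop("cannot parse ", path, ": ", conditionMessage(e))
    })
  coverage <- df$meth + df$unmeth
  if (any(df$meth < 0 | df$unmeth < 0))
    stop("negative counts in ", path)
  if (nrow(df)) {
    computed <- 100 * df$meth / ifelse(coverage == 0, NA, coverage)
    off <- abs(computed - df$pct) > 0.5
    if (any(off, na.rm = TRUE))
      warning(sum(off, na.rm = TRUE), " rows in ", path,
              " report a %methylation differing from the counts by > 0.5")
  }
  sites <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$start, df$start))
  MethylCallSet(sites, matrix(coverage, ncol = 1),
                matrix(df$meth, ncol = 1), sample, group)
}

#' Write a Bismark coverage file
#'
#' @param calls a single-sample \linkS4class{MethylCallSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeBismarkCov <- function(calls, path) {
  stopifnot(ncol(calls) == 1L)
  cv <- methCoverage(calls)[, 1]
  mt <- methCounts(calls)[, 1]
  pct <- ifelse(cv == 0, 0, 100 * mt / cv)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   as.character(GenomicRanges::seqnames(calls)),
                   GenomicRanges::start(calls), GenomicRanges::start(calls),
                   formatC(pct, format = "fg", digits = 10),
                   mt, cv - mt)
  writeLines(lines, path)
  invisible(path)
}

#' Per-sample coverage filtering
#'
#' Removes sites whose read coverage is less than or equal to
#' \code{minCoverage} or strictly above the sample's own
#' \code{upperPercentile}-th coverage percentile (linear-interpolation
#' percentile on the raw, unfiltered coverage distribution; both bounds are
#' evaluated on that same distribution).
#'
#' @param calls a \linkS4class{MethylCallSet} (each sample filtered on its
#'   own distribution; multi-sample objects are reduced to the intersection
#'   of per-sample retained sites).
#' @param minCoverage exclusive lower bound (default 10: coverage <= 10 is
#'   removed).
#' @param upperPercentile percentile (0-100] for the upper cut, default 99.9.
#' @return A \linkS4class{MethylCallSet} restricted to retained sites.
#' @export
filterByCoverage <- function(calls, minCoverage = 10, upperPercentile = 99.9) {
  if (nrow(calls) == 0L) return(calls)
  cv <- methCoverage(calls)
  keep <- rep(TRUE, nrow(calls))
  for (j in seq_len(ncol(cv))) {
    hi <- stats::quantile(cv[, j], upperPercentile / 100, type = 7,
                          names = FALSE)
    keep <- keep & cv[, j] > minCoverage & cv[, j] <= hi
  }
  if (!any(keep))
    warning("coverage filter removed every site")
  calls[keep, ]
}

#' Unite CpG sites across the samples of a contrast
#'
#' Intersects the (already filtered) site lists of every sample in the two
#' groups: a site is retained only if it has counts in all samples, the
#' prerequisite for per-site testing. Per-sample counts are preserved.
#'
#' @param callList list of single-sample \linkS4class{MethylCallSet}s.
#' @param groups optional character pair; restrict to samples of these
#'   groups (default: use all samples given).
#' @return A multi-sample \linkS4class{MethylCallSet} over the united sites.
#' @export
uniteSamples <- function(callList, groups = NULL) {
  stopifnot(length(callList) >= 1L)
  if (!is.null(groups)) {
    gl <- vapply(callList, function(x) sampleGroups(x)[1], character(1))
    callList <- callList[gl %in% groups]
    if (!all(groups %in% gl))
      stop("no samples for group(s): ",
           paste(setdiff(groups, gl), collapse = ", "))
  }
  keys <- lapply(callList, function(x)
    paste(GenomicRanges::seqnames(x), GenomicRanges::start(x),
          GenomicRanges::strand(x)))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L)
    stop("no CpG site is covered in every sample; ",
         "consider a lower coverage threshold")
  idx1 <- match(common, keys[[1]])
  sites <- GenomicRanges::granges(SummarizedExperiment::rowRanges(
    callList[[1]]))[idx1]
  ord <- GenomicRanges::order(sites)
  sites <- sites[ord]
  common <- common[ord]
  cov <- vapply(seq_along(callList), function(i) {
    methCoverage(callList[[i]])[match(common, keys[[i]]), 1]
  }, integer(length(common)))
  met <- vapply(seq_along(callList), function(i) {
    methCounts(callList[[i]])[match(common, keys[[i]]), 1]
  }, integer(length(common)))
  cov <- matrix(cov, ncol = length(callList))
  met <- matrix(met, ncol = length(callList))
  MethylCallSet(sites, cov, met,
                vapply(callList, function(x) colnames(x)[1], character(1)),
                vapply(callList, function(x) sampleGroups(x)[1], character(1)))
}

#' Filter FASTQ reads by restriction-digestion signature
#'
#' RRBS fragments start at an MspI (C^CGG) or TaqI (T^CGA) cut site, so a
#' genuine read begins with CGG or CGA; after bisulfite conversion an
#' unmethylated leading C reads as T, giving the accepted 5' signatures
#' {CGG, TGG, CGA, TGA}. Reads longer than \code{maxLen} are truncated to
#' \code{maxLen} (default 50 bp) before the signature test.
#'
#' @param infile input FASTQ path.
#' @param outfile output FASTQ path.
#' @param maxLen trim length in bp.
#' @param signatures accepted 5' trinucleotides.
#' @return invisibly, a named integer vector (read, kept).
#' @export
filterReadsByDigestion <- function(infile, outfile, maxLen = 50L,
                                   signatures = c("CGG", "TGG", "CGA", "TGA")) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(infile, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ ", infile, ": ",
                             conditionMessage(e)))
  quals <- S4Vectors::mcols(reads)$qualities
  w <- pmin(Biostrings::width(reads), maxLen)
  reads <- Biostrings::subseq(reads, 1L, w)
  quals <- Biostrings::subseq(quals, 1L, w)
  lead <- as.character(Biostrings::subseq(reads, 1L,
                                          pmin(Biostrings::width(reads), 3L)))
  keep <- lead %in% signatures
  Biostrings::writeXStringSet(reads[keep], outfile, format = "fastq",
                              qualities = quals[keep])
  invisible(c(read = length(reads), kept = sum(keep)))
}
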