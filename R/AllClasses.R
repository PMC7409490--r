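#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

#' Per-CpG bisulfite call set
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one row per CpG site
#' (width-1 ranges, 1-based) and one column per sample, with integer assays
#' \code{methylated} and \code{total} (read counts supporting the methylated
#' state and overall coverage).  \code{colData(x)$group} carries the sample to
#' subgroup map; a group named \code{"control"} must be present.
#'
#' @slot .
#'   Inherits all slots from \code{RangedSummarizedExperiment}.
#' @seealso \code{\link{MethylCallSet}} (constructor),
#'   \code{\link{filterCpGs}}, \code{\link{assembleRegions}}
#' @export
setClass("MethylCallSet",
         contains = "RangedSummarizedExperiment")

setValidity("MethylCallSet", function(object) {
  msg <- character()
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("methylated", "total") %in% an)) {
    msg <- c(msg, "assays 'methylated' and 'total' are required")
  } else {
    m <- SummarizedExperiment::assay(object, "methylated")
    tot <- SummarizedExperiment::assay(object, "total")
    if (any(m < 0) || any(tot < m)) {
      msg <- c(msg, "counts must satisfy total >= methylated >= 0")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must have a 'group' column")
  } else if (ncol(object) > 0L && !"control" %in% cd$group) {
    msg <- c(msg, "at least one sample must belong to group 'control'")
  }
  if (nrow(object) > 1L) {
    gr <- SummarizedExperiment::rowRanges(object)
    ord <- order(as.factor(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))
    if (!identical(ord, seq_len(nrow(object)))) {
      msg <- c(msg, "CpG sites must be sorted by chromosome and position")
    }
    if (anyDuplicated(paste(GenomicRanges::seqnames(gr),
                            GenomicRanges::start(gr)))) {
      msg <- c(msg, "duplicate CpG positions")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Region-level methylation set
#'
#' A \linkS4class{RangedSummarizedExperiment} with one row per assembled
#' multi-CpG region.  Assays: \code{pct} (per-sample region methylation in
#' percent, 100 * sum(methylated) / sum(total) over member CpGs),
#' \code{methylated} and \code{total} (summed counts).  \code{rowData} holds
#' \code{n_cpgs}; \code{colData$group} as in \linkS4class{MethylCallSet}.
#'
#' @seealso \code{\link{assembleRegions}}, \code{\link{callDMRs}}
#' @export
setClass("MethylRegionSet",
         contains = "RangedSummarizedExperiment")

setValidity("MethylRegionSet", function(object) {
  msg <- character()
  an <- names(SummarizedExperiment::assays(object))
  if (!"pct" %in% an) {
    msg <- c(msg, "assay 'pct' is required")
  } else {
    p <- SummarizedExperiment::assay(object, "pct")
    if (any(p < 0 | p > 100, na.rm = TRUE)) {
      msg <- c(msg, "'pct' values must lie in [0, 100]")
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"n_cpgs" %in% colnames(rd)) {
    msg <- c(msg, "rowData must have 'n_cpgs'")
  } else if (nrow(object) > 0L && any(rd$n_cpgs < 1L)) {
    msg <- c(msg, "'n_cpgs' must be >= 1")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must have a 'group' column")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylCallSet
#'
#' @param chrom character vector of chromosome names, one per CpG.
#' @param pos integer vector of 1-based CpG positions.
#' @param methylated,total integer matrices (CpG x sample) of methylated and
#'   total read counts; column names are sample ids.
#' @param sampleGroups named character vector mapping sample id to group
#'   label; must contain at least one \code{"control"}.
#' @return A \linkS4class{MethylCallSet}.
#' @examples
#' mcs <- MethylCallSet(
#'   chrom = c("chr1", "chr1"), pos = c(100L, 150L),
#'   methylated = matrix(c(5L, 3L, 2L, 8L), 2,
#'                       dimnames = list(NULL, c("s1", "s2"))),
#'   total = matrix(10L, 2, 2, dimnames = list(NULL, c("s1", "s2"))),
#'   sampleGroups = c(s1 = "control", s2 = "tumor"))
#' methLevel(mcs)
#' @export
MethylCallSet <- function(chrom, pos, methylated, total, sampleGroups) {
  methylated <- as.matrix(methylated)
  total <- as.matrix(total)
  if (is.null(colnames(methylated))) colnames(methylated) <- names(sampleGroups)
  if (is.null(colnames(total))) colnames(total) <- names(sampleGroups)
  samples <- colnames(total)
  if (!all(samples %in% names(sampleGroups))) {
    stop("every sample column needs an entry in 'sampleGroups'")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  ord <- order(as.factor(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  gr <- gr[ord]
  methylated <- methylated[ord, , drop = FALSE]
  total <- total[ord, , drop = FALSE]
  cd <- S4Vectors::DataFrame(group = unname(sampleGroups[samples]),
                             row.names = samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(methylated = methylated, total = total),
    rowRanges = gr, colData = cd)
  methods::new("MethylCallSet", se)
}

#' Construct a MethylRegionSet from parallel matrices
#'
#' Mostly used internally by \code{\link{assembleRegions}} and in tests that
#' need regions with hand-designed methylation levels.
#'
#' @param regions a \code{GRanges} of region intervals.
#' @param pct numeric matrix (region x sample) of percent methylation.
#' @param nCpgs integer vector of member-CpG counts.
#' @param sampleGroups named character vector sample -> group.
#' @param methylated,total optional summed count matrices.
#' @return A \linkS4class{MethylRegionSet}.
#' @export
MethylRegionSet <- function(regions, pct, nCpgs, sampleGroups,
                            methylated = NULL, total = NULL) {
  pct <- as.matrix(pct)
  samples <- colnames(pct)
  if (is.null(samples)) {
    samples <- names(sampleGroups)
    colnames(pct) <- samples
  }
  assays <- list(pct = pct)
  if (!is.null(methylated)) assays$methylated <- as.matrix(methylated)
  if (!is.null(total)) assays$total <- as.matrix(total)
  mcols(regions)$n_cpgs <- as.integer(nCpgs)
  cd <- S4Vectors::DataFrame(group = unname(sampleGroups[samples]),
                             row.names = samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = regions, colData = cd)
  methods::new("MethylRegionSet", se)
}

setMethod("show", "MethylCallSet", function(object) {
  grp <- table(SummarizedExperiment::colData(object)$group)
  cat("MethylCallSet with", nrow(object), "CpG sites x",
      ncol(object), "samples\n")
  cat("groups:", paste(sprintf("%s(%d)", names(grp), grp), collapse = ", "),
      "\n")
  invisible(NULL)
})

setMethod("show", "MethylRegionSet", function(object) {
  cat("MethylRegionSet with", nrow(object), "regions x",
      ncol(object), "samples\n")
  if (nrow(object) > 0L) {
    cat("CpGs per region:",
        paste(range(SummarizedExperiment::rowData(object)$n_cpgs),
              collapse = "-"), "\n")
  }
  invisible(NULL)
})
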