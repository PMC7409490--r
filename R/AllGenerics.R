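#' Sample-to-group map
#'
#' @param x a \linkS4class{MethylCallSet} or \linkS4class{MethylRegionSet}.
#' @return Named character vector, sample id to group label.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Methylated read counts
#' @param x a \linkS4class{MethylCallSet}.
#' @return Integer matrix, CpG x sample.
#' @export
setGeneric("methReads", function(x) standardGeneric("methReads"))

#' Total read counts (coverage)
#' @param x a \linkS4class{MethylCallSet}.
#' @return Integer matrix, CpG x sample.
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' Percent methylation
#'
#' For a call set, per-CpG percent methylation (100 * methylated / total);
#' for a region set, the per-sample region percentages.
#' @param x a \linkS4class{MethylCallSet} or \linkS4class{MethylRegionSet}.
#' @return Numeric matrix in [0, 100].
#' @export
setGeneric("methLevel", function(x) standardGeneric("methLevel"))

#' Number of CpG sites per region
#' @param x a \linkS4class{MethylRegionSet}.
#' @return Integer vector.
#' @export
setGeneric("nCpGs", function(x) standardGeneric("nCpGs"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(as.character(cd$group), rownames(cd))
})

#' @rdname methReads
#' @export
setMethod("methReads", "MethylCallSet", function(x) {
  SummarizedExperiment::assay(x, "methylated")
})

#' @rdname totalReads
#' @export
setMethod("totalReads", "MethylCallSet", function(x) {
  SummarizedExperiment::assay(x, "total")
})

#' @rdname methLevel
#' @export
setMethod("methLevel", "MethylCallSet", function(x) {
  100 * methReads(x) / pmax(totalReads(x), 1L)
})

#' @rdname methLevel
#' @export
setMethod("methLevel", "MethylRegionSet", function(x) {
  SummarizedExperiment::assay(x, "pct")
})

#' @rdname nCpGs
#' @export
setMethod("nCpGs", "MethylRegionSet", function(x) {
  as.integer(SummarizedExperiment::rowData(x)$n_cpgs)
})
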