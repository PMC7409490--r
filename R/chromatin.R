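# Chromatin context: DMR-peak overlap (>50 bp rule), per-mark composition
# by compartment and direction, SE/CTCF-DMR sets, and average-linkage
# clustering of SE/CTCF-DMR methylation profiles into modules.

#' Overlap DMRs with a peak set
#'
#' Emits every (DMR, peak) pair with a positive intersection; a pair
#' qualifies when the overlap is at least \code{minOverlap} bp (default 51,
#' i.e. the strict ">50 bp" rule).  Output is ordered by DMR then peak
#' start, deterministically.
#'
#' @param dmrs \code{GRanges} with mcols \code{dmr_id}.
#' @param peaks \code{GRanges} of intervals for one mark
#'   (\code{metadata(peaks)$mark} used as the label if set).
#' @param minOverlap minimum qualifying overlap in bp.
#' @param mark optional mark label overriding the metadata.
#' @return data.frame: dmr_id, mark, peak_chrom, peak_start, peak_end,
#'   overlap_length, qualifies.
#' @export
overlapDMRsPeaks <- function(dmrs, peaks, minOverlap = 51L, mark = NULL) {
  if (is.null(mark)) mark <- S4Vectors::metadata(peaks)$mark
  if (is.null(mark)) mark <- NA_character_
  if (length(dmrs) && length(peaks) &&
      !any(as.character(seqnames(dmrs)) %in%
             as.character(seqnames(peaks)))) {
    warning(sprintf(
      "no shared chromosome names between DMRs (%s...) and peaks (%s...)",
      as.character(seqnames(dmrs))[1], as.character(seqnames(peaks))[1]))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(dmrs, peaks))
  if (!length(hits)) {
    return(data.frame(dmr_id = character(), mark = character(),
                      peak_chrom = character(), peak_start = integer(),
                      peak_end = integer(), overlap_length = integer(),
                      qualifies = logical()))
  }
  q <- queryHits(hits)
  s <- subjectHits(hits)
  ov <- width(pintersect(granges(dmrs)[q], granges(peaks)[s]))
  out <- data.frame(dmr_id = mcols(dmrs)$dmr_id[q], mark = mark,
                    peak_chrom = as.character(seqnames(peaks))[s],
                    peak_start = start(peaks)[s],
                    peak_end = end(peaks)[s],
                    overlap_length = ov,
                    qualifies = ov >= minOverlap)
  out[order(out$dmr_id, out$peak_start), , drop = FALSE]
}

#' Mark composition by compartment and DMR direction
#'
#' For every (compartment, direction, mark) cell: the fraction of DMRs in
#' that compartment/direction with at least one qualifying overlap of the
#' mark.  A DMR may carry several marks, so rows are not a partition.
#' Cells with no DMR get a missing fraction, not zero.
#'
#' @param overlaps named list of \code{\link{overlapDMRsPeaks}} outputs,
#'   one per mark (names are the mark labels).
#' @param annotated annotated DMR \code{GRanges} with mcols \code{dmr_id},
#'   \code{compartment}, \code{direction}.
#' @return data.frame: compartment, direction, mark, n_dmrs, n_overlapping,
#'   fraction.
#' @export
markComposition <- function(overlaps, annotated) {
  meta <- data.frame(dmr_id = mcols(annotated)$dmr_id,
                     compartment = mcols(annotated)$compartment,
                     direction = mcols(annotated)$direction)
  cells <- expand.grid(compartment = c("promoter", "body", "intergenic"),
                       direction = c("hyper", "hypo"),
                       mark = names(overlaps), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    members <- meta$dmr_id[meta$compartment == cell$compartment &
                             meta$direction == cell$direction]
    ov <- overlaps[[cell$mark]]
    hit_ids <- unique(ov$dmr_id[ov$qualifies])
    n <- length(members)
    k <- sum(members %in% hit_ids)
    data.frame(cell, n_dmrs = n, n_overlapping = k,
               fraction = if (n) k / n else NA_real_)
  })
  do.call(rbind, res)
}

#' Super-enhancer and CTCF overlap with DMRs
#'
#' A DMR is an SE-DMR (resp. CTCF-DMR) when it has a qualifying (>50 bp by
#' default) overlap with the SE (resp. CTCF) interval set.  Both
#' denominators of the composition are reported: the hypo/hyper split of
#' the overlapping DMRs, and the fraction of peaks touched by a DMR of each
#' direction.
#'
#' @param annotated annotated DMR \code{GRanges} with \code{dmr_id} and
#'   \code{direction} mcols.
#' @param sePeaks,ctcfPeaks \code{GRanges} interval sets.
#' @param minOverlap minimum qualifying overlap in bp (default 51).
#' @return list with elements \code{se} and \code{ctcf}, each a list:
#'   \code{dmr_ids}, \code{n}, \code{fraction_hypo}, \code{fraction_hyper}
#'   (over overlapping DMRs), \code{peak_fraction_hypo},
#'   \code{peak_fraction_hyper} (over peaks).
#' @export
seCtcfOverlap <- function(annotated, sePeaks, ctcfPeaks, minOverlap = 51L) {
  one <- function(peaks, label) {
    ov <- overlapDMRsPeaks(annotated, peaks, minOverlap, mark = label)
    ids <- unique(ov$dmr_id[ov$qualifies])
    dirs <- mcols(annotated)$direction[match(ids, mcols(annotated)$dmr_id)]
    n <- length(ids)
    # peak-denominator: which peaks carry a qualifying hypo/hyper DMR
    ovq <- ov[ov$qualifies, , drop = FALSE]
    ovq$direction <- mcols(annotated)$direction[
      match(ovq$dmr_id, mcols(annotated)$dmr_id)]
    pk <- paste(ovq$peak_chrom, ovq$peak_start, ovq$peak_end)
    np <- length(peaks)
    list(dmr_ids = ids, n = n,
         fraction_hypo = if (n) mean(dirs == "hypo") else NA_real_,
         fraction_hyper = if (n) mean(dirs == "hyper") else NA_real_,
         peak_fraction_hypo = if (np)
           length(unique(pk[ovq$direction == "hypo"])) / np else NA_real_,
         peak_fraction_hyper = if (np)
           length(unique(pk[ovq$direction == "hyper"])) / np else NA_real_)
  }
  list(se = one(sePeaks, "SE"), ctcf = one(ctcfPeaks, "CTCF"))
}

#' Cluster SE/CTCF-DMR methylation profiles into modules
#'
#' Agglomerative average-linkage clustering on Euclidean distances between
#' per-DMR methylation vectors, cut into \code{k} modules (default 3).
#'
#' @param pct numeric matrix, DMRs x samples, percent methylation; rownames
#'   are DMR ids.
#' @param k number of modules.
#' @return Named integer vector: DMR id -> module label in 1..k.
#' @export
clusterSEModules <- function(pct, k = 3L) {
  if (nrow(pct) < 2L) stop("need >= 2 DMRs to cluster", call. = FALSE)
  if (k > nrow(pct)) {
    stop(sprintf("k = %d exceeds the %d DMRs", k, nrow(pct)), call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(pct, method = "euclidean"),
                      method = "average")
  stats::cutree(hc, k = k)
}
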