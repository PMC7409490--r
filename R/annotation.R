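# Compartment annotation: promoter / gene-body / intergenic assignment
# relative to the nearest TSS, and the relative-distance statistic D.

#' Promoter and gene-body intervals for gene models
#'
#' Strand-aware: the promoter spans \code{upstream} bp upstream through
#' \code{downstream} bp downstream of the TSS (default 5 kb / 200 bp); the
#' gene body runs from the promoter end to the transcript 3' end.  The
#' promoter is clipped at position 1; the body is empty (zero width) when
#' the gene is shorter than \code{downstream}.
#'
#' @param genes \code{GRanges} of gene models with mcols \code{gene_id}.
#' @param upstream,downstream promoter extent in bp relative to the TSS.
#' @return list with parallel \code{GRanges} \code{promoter} and
#'   \code{body} (zero-width body ranges mark promoter-only genes).
#' @export
buildCompartments <- function(genes, upstream = 5000L, downstream = 200L) {
  if (!length(genes)) {
    return(list(promoter = GenomicRanges::GRanges(),
                body = GenomicRanges::GRanges()))
  }
  plus <- as.character(strand(genes)) != "-"
  tss <- tssOf(genes)
  g_start <- start(genes)
  g_end <- end(genes)
  p_start <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  p_end <- ifelse(plus, tss + downstream - 1L, tss + upstream)
  p_start <- pmax(1L, p_start)
  # body: from the promoter end to the 3' end, possibly empty
  b_start <- ifelse(plus, tss + downstream, g_start)
  b_end <- ifelse(plus, g_end, tss - downstream)
  empty <- b_start > b_end
  b_width <- ifelse(empty, 0L, b_end - b_start + 1L)
  b_start[empty] <- pmax(1L, b_end[empty] + 1L)
  chrom <- as.character(seqnames(genes))
  ids <- mcols(genes)$gene_id
  list(promoter = GenomicRanges::GRanges(chrom,
                                         IRanges::IRanges(p_start, p_end),
                                         gene_id = ids),
       body = GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(b_start,
                                                      width = b_width),
                                     gene_id = ids))
}

#' Relative distance D of a DMR from the TSS
#'
#' D = |end base of DMR - TSS| / gene length x 100, where the "end base" is
#' the DMR boundary furthest downstream in the direction of transcription
#' (the right edge for + genes, the left edge for - genes).  D is 0 for a
#' DMR ending exactly at the TSS and may exceed 100 for regions beyond one
#' gene length.
#'
#' @param dmrs \code{GRanges} of DMRs.
#' @param genes parallel \code{GRanges} of the genes each DMR is measured
#'   against (recycled if length 1).
#' @return Numeric vector of D values (percent of gene length).
#' @export
relativeDistance <- function(dmrs, genes) {
  if (length(genes) == 1L && length(dmrs) > 1L) {
    genes <- rep(genes, length(dmrs))
  }
  stopifnot(length(dmrs) == length(genes))
  plus <- as.character(strand(genes)) != "-"
  tss <- tssOf(genes)
  end_base <- ifelse(plus, end(dmrs), start(dmrs))
  100 * abs(end_base - tss) / width(genes)
}

#' Annotate DMRs with compartment, nearest gene and relative distance
#'
#' The nearest gene is the one whose TSS is closest to the DMR midpoint on
#' the same chromosome (distance ties broken by lexicographic gene id).
#' The DMR is a promoter DMR if it overlaps that gene's promoter interval
#' by >= 1 bp, else a body DMR if it overlaps the gene body, else
#' intergenic (promoter wins over body for straddling DMRs).  D is reported
#' for promoter/body DMRs and missing for intergenic ones.
#'
#' @param dmrs \code{GRanges} of DMRs (e.g. from \code{\link{callDMRs}}).
#' @param genes \code{GRanges} of gene models with mcols \code{gene_id}.
#' @param upstream,downstream promoter definition, see
#'   \code{\link{buildCompartments}}.
#' @return The input \code{GRanges} with added mcols: \code{gene_id}
#'   (nearest gene, NA when the chromosome has no genes),
#'   \code{compartment}, \code{distance_to_tss} (signed bp from TSS to DMR
#'   midpoint, positive downstream of transcription) and
#'   \code{relative_distance_d}.
#' @export
annotateDMRs <- function(dmrs, genes, upstream = 5000L, downstream = 200L) {
  n <- length(dmrs)
  gene_id <- rep(NA_character_, n)
  compartment <- rep("intergenic", n)
  dist_tss <- rep(NA_real_, n)
  dval <- rep(NA_real_, n)
  if (n && length(genes)) {
    comp <- buildCompartments(genes, upstream, downstream)
    mid <- floor((start(dmrs) + end(dmrs)) / 2)
    d_chrom <- as.character(seqnames(dmrs))
    g_chrom <- as.character(seqnames(genes))
    for (ch in unique(d_chrom)) {
      di <- which(d_chrom == ch)
      gi <- which(g_chrom == ch)
      if (!length(gi)) next
      # columns ordered by gene_id so that "first" tie-break on equal
      # distance is the lexicographic winner
      gi <- gi[order(mcols(genes)$gene_id[gi])]
      tss <- tssOf(genes[gi])
      dmat <- abs(outer(mid[di], tss, "-"))
      j <- max.col(-dmat, ties.method = "first")
      sel <- gi[j]
      gene_id[di] <- mcols(genes)$gene_id[sel]
      plus <- as.character(strand(genes[sel])) != "-"
      dist_tss[di] <- ifelse(plus, mid[di] - tss[j], tss[j] - mid[di])
      # promoter precedence, then body, else intergenic (parallel >=1 bp
      # overlap; chromosomes already match through the nearest gene)
      pairOv <- function(a, b) {
        pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L >= 1L
      }
      pmatch_ <- comp$promoter[match(gene_id[di],
                                     mcols(comp$promoter)$gene_id)]
      bmatch <- comp$body[match(gene_id[di], mcols(comp$body)$gene_id)]
      ov_p <- pairOv(dmrs[di], pmatch_)
      ov_b <- width(bmatch) > 0 & pairOv(dmrs[di], bmatch)
      compartment[di][ov_b] <- "body"
      compartment[di][ov_p] <- "promoter"
      has <- compartment[di] != "intergenic"
      if (any(has)) {
        dval[di][has] <- relativeDistance(
          dmrs[di][has], genes[sel][has])
      }
    }
  }
  mcols(dmrs)$gene_id <- gene_id
  mcols(dmrs)$compartment <- compartment
  mcols(dmrs)$distance_to_tss <- dist_tss
  mcols(dmrs)$relative_distance_d <- dval
  dmrs
}
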