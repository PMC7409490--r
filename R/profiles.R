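# Dataset-level summaries and unsupervised structure: top-variable feature
# selection, hierarchical clustering of samples, PCA, subgroup composition
# and the Mann-Whitney comparison used for everything that is not the DMR
# ANOVA.

#' Select the top-variable features
#'
#' Features are ranked by across-sample variance (descending), ties broken
#' by feature id, and the top \code{ceiling(fraction * n)} retained.
#' Features with any missing value are dropped before ranking.
#'
#' @param x numeric matrix, features x samples, with rownames.
#' @param fraction fraction of features to keep, in (0, 1] (default 0.05,
#'   the usual "top 5% most variable" selection).
#' @return The row-subset matrix, in rank order.
#' @export
topVariable <- function(x, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  }
  x <- x[stats::complete.cases(x), , drop = FALSE]
  v <- apply(x, 1, stats::var)
  ord <- order(-v, rownames(x))
  n_keep <- ceiling(fraction * nrow(x))
  x[ord[seq_len(n_keep)], , drop = FALSE]
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns on Euclidean distances
#' (complete linkage by default, the \code{hclust} default).
#'
#' @param x numeric matrix, features x samples.
#' @param k cut height in number of clusters.
#' @param linkage linkage method passed to \code{stats::hclust}.
#' @return list: \code{hclust} (the tree) and \code{labels} (named cluster
#'   membership from \code{cutree}).
#' @export
hierarchicalCluster <- function(x, k = 2L, linkage = "complete") {
  if (ncol(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (k > ncol(x)) stop("k exceeds the number of samples", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(x), method = "euclidean"),
                      method = linkage)
  list(hclust = hc, labels = stats::cutree(hc, k = k))
}

#' PCA of a methylation matrix
#'
#' Centered (not scaled) principal components of the samples, with a fixed
#' sign convention: each component is flipped so its largest-magnitude
#' loading is positive.
#'
#' @param x numeric matrix, features x samples.
#' @return list: \code{scores} (samples x PCs), \code{explained}
#'   (fraction of variance per PC).
#' @export
pcaMethylation <- function(x) {
  if (ncol(x) < 2L || nrow(x) < 2L) {
    stop("need >= 2 samples and >= 2 features", call. = FALSE)
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained = expl[seq_len(ncol(scores))])
}

#' Subgroup summary of called, annotated DMRs
#'
#' Per subgroup: DMR count, hyper/hypo fractions, compartment fractions,
#' and the median methylation per compartment (control vs subgroup), i.e.
#' the numbers behind compartment boxplots and hyper-fraction barplots.
#'
#' @param annotatedBySubgroup named list of annotated DMR \code{GRanges},
#'   one per subgroup.
#' @return data.frame with one row per subgroup; empty subgroups yield NA
#'   fields.
#' @export
subgroupSummary <- function(annotatedBySubgroup) {
  rows <- lapply(names(annotatedBySubgroup), function(sg) {
    a <- annotatedBySubgroup[[sg]]
    n <- length(a)
    if (!n) {
      return(data.frame(subgroup = sg, n_dmrs = 0L,
                        fraction_hyper = NA_real_, fraction_hypo = NA_real_,
                        fraction_promoter = NA_real_,
                        fraction_body = NA_real_,
                        fraction_intergenic = NA_real_,
                        median_mdm_promoter = NA_real_,
                        median_mdm_body = NA_real_,
                        median_mdm_intergenic = NA_real_))
    }
    dirs <- mcols(a)$direction
    comp <- mcols(a)$compartment
    mdm <- mcols(a)$group_mdm
    med <- function(c) if (any(comp == c)) stats::median(mdm[comp == c])
      else NA_real_
    data.frame(subgroup = sg, n_dmrs = n,
               fraction_hyper = mean(dirs == "hyper"),
               fraction_hypo = mean(dirs == "hypo"),
               fraction_promoter = mean(comp == "promoter"),
               fraction_body = mean(comp == "body"),
               fraction_intergenic = mean(comp == "intergenic"),
               median_mdm_promoter = med("promoter"),
               median_mdm_body = med("body"),
               median_mdm_intergenic = med("intergenic"))
  })
  do.call(rbind, rows)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact p-value for small untied samples, normal approximation with tie
#' correction otherwise (the \code{stats::wilcox.test} policy).
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list: \code{U} (statistic for the first sample) and
#'   \code{p.value}.
#' @export
mannWhitney <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p.value = min(wt$p.value, 1))
}
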