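# Methylation-expression integration: two-fold expression calls, the
# mixed-direction exclusion, GEM quadrant classification, the
# methylation-expression r-squared, and cohort-level GEM summaries.

GEM_PATTERNS <- data.frame(
  compartment = c("promoter", "promoter", "body", "body"),
  direction = c("hypo", "hyper", "hyper", "hypo"),
  expression = c("overexpressed", "under-expressed", "overexpressed",
                 "under-expressed"),
  quadrant = c("promoter_hypo_over", "promoter_hyper_under",
               "body_hyper_over", "body_hypo_under"))

#' Classify genes by two-fold expression change
#'
#' Group means are taken on the log2 scale (so the fold change is the
#' geometric-mean ratio): a gene is overexpressed when log2FC >= 1,
#' under-expressed when log2FC <= -1 (for the default two-fold cutoff), and
#' unchanged otherwise.
#'
#' @param expr numeric matrix, genes x samples, log2 scale.
#' @param sampleGroups named character vector sample -> group.
#' @param controlGroup,testGroup the contrast.
#' @param minFold linear fold-change cutoff (default 2).
#' @return data.frame: gene_id, control_mean, group_mean, log2fc, class.
#' @export
callExpression <- function(expr, sampleGroups, controlGroup = "control",
                           testGroup, minFold = 2) {
  gv <- sampleGroups[colnames(expr)]
  ctrl <- which(gv == controlGroup)
  grp <- which(gv == testGroup)
  if (!length(ctrl) || !length(grp)) {
    stop("both groups need >= 1 sample", call. = FALSE)
  }
  cm <- rowMeans(expr[, ctrl, drop = FALSE])
  gm <- rowMeans(expr[, grp, drop = FALSE])
  lfc <- gm - cm
  thr <- log2(minFold)
  cls <- ifelse(lfc >= thr, "overexpressed",
                ifelse(lfc <= -thr, "under-expressed", "unchanged"))
  data.frame(gene_id = rownames(expr), control_mean = cm, group_mean = gm,
             log2fc = lfc, class = cls, row.names = NULL)
}

#' Mixed-direction exclusion
#'
#' A gene is excluded when, within the \emph{same} compartment (promoter or
#' body), it carries at least one hyper- and one hypomethylated DMR.  A mix
#' across compartments (e.g. promoter hypo + body hyper) does not exclude.
#'
#' @param annotated \code{GRanges} of annotated DMRs
#'   (\code{\link{annotateDMRs}} output).
#' @return Character vector of excluded gene ids.
#' @export
excludedGenes <- function(annotated) {
  df <- as.data.frame(mcols(annotated))
  df <- df[df$compartment %in% c("promoter", "body") & !is.na(df$gene_id), ]
  if (!nrow(df)) return(character())
  key <- paste(df$gene_id, df$compartment)
  mixed <- tapply(df$direction, key, function(d) {
    any(d == "hyper") && any(d == "hypo")
  })
  unique(sub(" .*", "", names(mixed)[mixed]))
}

#' Squared methylation-expression correlation
#'
#' Squared Pearson correlation between per-sample region methylation and
#' log2 expression, computed over tumor samples only (controls excluded by
#' the caller).  Returns NA when either vector is constant.
#'
#' @param meth,expr paired numeric vectors (>= 3 samples).
#' @return r-squared in [0, 1], or NA.
#' @export
methylationExpressionR2 <- function(meth, expr) {
  if (length(meth) != length(expr) || length(meth) < 3L) {
    stop("need >= 3 paired samples", call. = FALSE)
  }
  if (stats::sd(meth) == 0 || stats::sd(expr) == 0) return(NA_real_)
  stats::cor(meth, expr)^2
}

#' Classify genes whose expression correlates with methylation (GEMs)
#'
#' Intersects annotated DMR direction/compartment with the two-fold
#' expression classes.  A gene is a GEM when it matches one of the four
#' canonical patterns: promoter hypo & overexpressed, promoter hyper &
#' under-expressed, body hyper & overexpressed, body hypo &
#' under-expressed.  Genes failing the mixed-direction exclusion are
#' removed first.  A gene matching both a promoter and a body pattern is
#' reported once, promoter pattern primary, with the secondary pattern in
#' \code{secondary_quadrant}.  r-squared between the per-sample methylation
#' of the strongest supporting DMR and expression over tumor (non-control)
#' samples is reported when per-sample data are available, but is not a
#' membership gate unless \code{r2Gate} is set.
#'
#' @param annotated annotated DMR \code{GRanges}; per-sample percentages
#'   are read from \code{metadata(annotated)$pct} when present.
#' @param exprCalls data.frame from \code{\link{callExpression}}.
#' @param expr optional expression matrix for r-squared.
#' @param sampleGroups named sample -> group vector (needed with
#'   \code{expr}).
#' @param controlGroup control label excluded from the correlation.
#' @param r2Gate optional minimum r-squared for GEM membership (default
#'   NULL, off; the r-squared is descriptive only).
#' @return data.frame: gene_id, quadrant, secondary_quadrant, n_dmrs,
#'   mean_delta, log2fc, r_squared.
#' @export
classifyGEMs <- function(annotated, exprCalls, expr = NULL,
                         sampleGroups = NULL, controlGroup = "control",
                         r2Gate = NULL) {
  df <- as.data.frame(mcols(annotated))
  df$row <- seq_len(nrow(df))
  df <- df[df$compartment %in% c("promoter", "body") & !is.na(df$gene_id), ]
  excl <- excludedGenes(annotated)
  df <- df[!df$gene_id %in% excl, ]
  if (!nrow(df)) {
    return(data.frame(gene_id = character(), quadrant = character(),
                      secondary_quadrant = character(), n_dmrs = integer(),
                      mean_delta = numeric(), log2fc = numeric(),
                      r_squared = numeric()))
  }
  cls <- stats::setNames(exprCalls$class, exprCalls$gene_id)
  lfc <- stats::setNames(exprCalls$log2fc, exprCalls$gene_id)
  pct <- S4Vectors::metadata(annotated)$pct
  out <- list()
  for (g in unique(df$gene_id)) {
    if (!g %in% names(cls)) next  # gene absent from expression matrix
    gdf <- df[df$gene_id == g, ]
    hits <- character()
    for (k in seq_len(nrow(GEM_PATTERNS))) {
      pat <- GEM_PATTERNS[k, ]
      if (cls[g] == pat$expression &&
          any(gdf$compartment == pat$compartment &
                gdf$direction == pat$direction)) {
        hits <- c(hits, pat$quadrant)
      }
    }
    if (!length(hits)) next
    primary <- hits[order(!grepl("^promoter", hits))][1]
    pcomp <- if (grepl("^promoter", primary)) "promoter" else "body"
    support <- gdf[gdf$compartment == pcomp, ]
    r2 <- NA_real_
    if (!is.null(pct) && !is.null(expr) && !is.null(sampleGroups) &&
        g %in% rownames(expr)) {
      best <- support$row[which.max(abs(support$delta))]
      tumor <- names(sampleGroups)[sampleGroups != controlGroup]
      tumor <- intersect(tumor, intersect(colnames(pct), colnames(expr)))
      if (length(tumor) >= 3L) {
        r2 <- methylationExpressionR2(pct[best, tumor], expr[g, tumor])
      }
    }
    if (!is.null(r2Gate) && (is.na(r2) || r2 <= r2Gate)) next
    out[[g]] <- data.frame(
      gene_id = g, quadrant = primary,
      secondary_quadrant = if (length(hits) > 1L) hits[hits != primary][1]
        else NA_character_,
      n_dmrs = nrow(gdf), mean_delta = mean(support$delta),
      log2fc = unname(lfc[g]), r_squared = r2)
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), quadrant = character(),
                      secondary_quadrant = character(), n_dmrs = integer(),
                      mean_delta = numeric(), log2fc = numeric(),
                      r_squared = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' GEM summary: fraction of differentially expressed genes that are GEMs
#'
#' @param gems data.frame from \code{\link{classifyGEMs}}.
#' @param exprCalls data.frame from \code{\link{callExpression}} for the
#'   same contrast.
#' @return list: \code{n_de} (genes >= 2-fold either way), \code{n_gem},
#'   \code{fraction} (NA when no DE genes), \code{quadrant_counts} (each
#'   gene counted once by primary quadrant), \code{n_over}, \code{n_under}.
#' @export
gemSummary <- function(gems, exprCalls) {
  de <- exprCalls$gene_id[exprCalls$class != "unchanged"]
  qc <- table(factor(gems$quadrant, levels = GEM_PATTERNS$quadrant))
  list(n_de = length(de), n_gem = nrow(gems),
       fraction = if (length(de)) nrow(gems) / length(de) else NA_real_,
       quadrant_counts = qc,
       n_over = sum(gems$quadrant %in% c("promoter_hypo_over",
                                         "body_hyper_over")),
       n_under = sum(gems$quadrant %in% c("promoter_hyper_under",
                                          "body_hypo_under")))
}
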