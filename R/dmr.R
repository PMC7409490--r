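# DMR calling from CpG call tables: coverage filter, gap-bounded region
# assembly, methylation-band filter, two-way ANOVA on per-sample per-CpG
# percentages, BH correction, and the delta/direction gates.  DMC calling
# from array beta tables uses the delta-beta + diffscore decision rule.

#' Discard CpGs under-covered in any sample
#'
#' A CpG survives only if its total read count is at least \code{minReads}
#' in \emph{every} sample (default 10, the usual RRBS cutoff).
#'
#' @param calls a \linkS4class{MethylCallSet}.
#' @param minReads minimum coverage required in each sample.
#' @return The filtered \linkS4class{MethylCallSet}.
#' @export
filterCpGs <- function(calls, minReads = 10L) {
  if (ncol(calls) == 0L) stop("call set has no samples", call. = FALSE)
  assertScalarNumber(minReads, "minReads", 1)
  keep <- rowSums(totalReads(calls) >= minReads) == ncol(calls)
  calls[keep, ]
}

#' Assemble multi-CpG regions from filtered calls
#'
#' Builds maximal runs of CpGs whose inter-CpG gap is at most \code{maxGap},
#' split greedily so that no region spans more than \code{maxSpan} bp, and
#' drops runs with fewer than \code{minCpgs} sites.  Defaults echo the
#' MspI-fragment scale of RRBS libraries.  Per-sample region methylation is
#' the pooled percentage 100 * sum(methylated) / sum(total) over member
#' CpGs.
#'
#' @param calls a filtered \linkS4class{MethylCallSet}.
#' @param maxGap maximum distance (bp) between neighbouring CpGs of a region.
#' @param minCpgs minimum CpG sites per region (default 2).
#' @param maxSpan maximum region span in bp.
#' @return A \linkS4class{MethylRegionSet}.
#' @export
assembleRegions <- function(calls, maxGap = 200L, minCpgs = 2L,
                            maxSpan = 220L) {
  if (maxGap <= 0) stop("'maxGap' must be positive", call. = FALSE)
  if (minCpgs < 1) stop("'minCpgs' must be >= 1", call. = FALSE)
  gr <- rowRanges(calls)
  n <- length(gr)
  groupsv <- sampleGroups(calls)
  if (n == 0L) {
    return(MethylRegionSet(GenomicRanges::GRanges(),
                           pct = matrix(numeric(), 0, ncol(calls),
                                        dimnames = list(NULL,
                                                        colnames(calls))),
                           nCpgs = integer(), sampleGroups = groupsv))
  }
  chrom <- as.character(seqnames(gr))
  pos <- start(gr)
  # greedy left-to-right: break on chromosome change, gap > maxGap, or span
  # about to exceed maxSpan
  region_idx <- integer(n)
  cur <- 1L
  region_idx[1] <- 1L
  anchor <- pos[1]
  for (i in seq_len(n)[-1]) {
    new_chrom <- chrom[i] != chrom[i - 1L]
    if (new_chrom || pos[i] - pos[i - 1L] > maxGap ||
        pos[i] - anchor > maxSpan) {
      cur <- cur + 1L
      anchor <- pos[i]
    }
    region_idx[i] <- cur
  }
  cnt <- tabulate(region_idx)
  keep_region <- which(cnt >= minCpgs)
  if (!length(keep_region)) {
    return(MethylRegionSet(GenomicRanges::GRanges(),
                           pct = matrix(numeric(), 0, ncol(calls),
                                        dimnames = list(NULL,
                                                        colnames(calls))),
                           nCpgs = integer(), sampleGroups = groupsv))
  }
  keep_cpg <- region_idx %in% keep_region
  ridx <- match(region_idx[keep_cpg], keep_region)
  m <- methReads(calls)[keep_cpg, , drop = FALSE]
  tot <- totalReads(calls)[keep_cpg, , drop = FALSE]
  msum <- rowsum(m, ridx)
  tsum <- rowsum(tot, ridx)
  rownames(msum) <- rownames(tsum) <- NULL
  pct <- 100 * msum / pmax(tsum, 1L)
  first <- !duplicated(ridx)
  last <- !duplicated(ridx, fromLast = TRUE)
  regions <- GenomicRanges::GRanges(chrom[keep_cpg][first],
                                    IRanges::IRanges(pos[keep_cpg][first],
                                                     pos[keep_cpg][last]))
  rs <- MethylRegionSet(regions, pct = pct, nCpgs = cnt[keep_region],
                        sampleGroups = groupsv, methylated = msum,
                        total = tsum)
  S4Vectors::metadata(rs)$cpg_region_index <- ridx
  S4Vectors::metadata(rs)$cpg_calls <- calls[keep_cpg, ]
  rs
}

#' @noRd
groupMeanMatrix <- function(regions, groups = NULL) {
  pct <- methLevel(regions)
  gv <- sampleGroups(regions)
  if (is.null(groups)) groups <- unique(gv)
  vapply(groups, function(g) {
    rowMeans(pct[, gv == g, drop = FALSE])
  }, numeric(nrow(pct)))
}

#' Methylation-band qualification filter
#'
#' A region qualifies only if the mean methylation of \emph{both} the
#' control and the test group lies in [lower, midLow] or [midHigh, upper]
#' percent — i.e. is not above 80, not below 20, and not strictly between
#' 40 and 60 (outer boundaries closed, middle band open).
#'
#' @param regions a \linkS4class{MethylRegionSet}.
#' @param controlGroup,testGroup group labels.
#' @param lower,upper,midLow,midHigh band boundaries in percent.
#' @return Logical vector, one keep/drop flag per region.
#' @export
bandFilter <- function(regions, controlGroup = "control", testGroup,
                       lower = 20, upper = 80, midLow = 40, midHigh = 60) {
  gm <- groupMeanMatrix(regions, c(controlGroup, testGroup))
  inBand <- function(m) m >= lower & m <= upper & !(m > midLow & m < midHigh)
  inBand(gm[, 1]) & inBand(gm[, 2])
}

#' Closed-form two-way additive ANOVA for one region
#'
#' Factors are sample group and CpG position, no interaction.  Assumes the
#' complete design the coverage filter guarantees (every retained CpG is
#' observed in every sample), in which the two factors are orthogonal and
#' the group main-effect sum of squares has closed form.  Returns NA when
#' the residual variance is zero (degenerate region, excluded from calling).
#'
#' @param pct numeric matrix, CpG x sample, percent methylation.
#' @param groups character vector of group labels, one per column.
#' @return Group main-effect p-value, or NA for degenerate input.
#' @export
anovaGroupP <- function(pct, groups) {
  m <- nrow(pct)
  ns <- ncol(pct)
  if (m < 2L || length(unique(groups)) < 2L) return(NA_real_)
  if (any(table(groups) < 2L)) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  gbar <- mean(pct)
  ss_tot <- sum((pct - gbar)^2)
  pos_means <- rowMeans(pct)
  ss_pos <- ns * sum((pos_means - gbar)^2)
  gl <- unique(groups)
  ng <- lengths(split(seq_along(groups), groups))[gl]
  gmeans <- vapply(gl, function(g) mean(pct[, groups == g, drop = FALSE]),
                   numeric(1))
  ss_grp <- m * sum(ng * (gmeans - gbar)^2)
  df_grp <- length(gl) - 1L
  df_res <- m * ns - 1L - (m - 1L) - df_grp
  ss_res <- ss_tot - ss_pos - ss_grp
  if (df_res <= 0L || ss_res <= 1e-10 * max(ss_tot, 1)) return(NA_real_)
  f <- (ss_grp / df_grp) / (ss_res / df_res)
  stats::pf(f, df_grp, df_res, lower.tail = FALSE)
}

#' Group main-effect p-values for every region
#'
#' Runs the two-way (group x CpG position) additive ANOVA per region on the
#' per-sample per-CpG methylation percentages and returns the group
#' main-effect p-value.  Regions whose assembly metadata is missing (e.g.
#' hand-built region sets without CpG-level data) are not supported here;
#' use \code{\link{anovaGroupP}} directly.
#'
#' @param regions a \linkS4class{MethylRegionSet} from
#'   \code{\link{assembleRegions}}.
#' @param controlGroup,testGroup the two groups compared; other samples are
#'   ignored.
#' @return Numeric vector of p-values (NA for degenerate regions).
#' @export
testDifferential <- function(regions, controlGroup = "control", testGroup) {
  calls <- S4Vectors::metadata(regions)$cpg_calls
  ridx <- S4Vectors::metadata(regions)$cpg_region_index
  if (is.null(calls)) {
    stop("region set lacks CpG-level data; build it with assembleRegions()",
         call. = FALSE)
  }
  gv <- sampleGroups(calls)
  use <- gv %in% c(controlGroup, testGroup)
  if (!any(gv[use] == controlGroup) || !any(gv[use] == testGroup)) {
    stop(sprintf("unknown group label '%s' or '%s'", controlGroup,
                 testGroup), call. = FALSE)
  }
  pct_all <- 100 * methReads(calls)[, use, drop = FALSE] /
    pmax(totalReads(calls)[, use, drop = FALSE], 1L)
  groups <- gv[use]
  vapply(seq_len(nrow(regions)), function(r) {
    anovaGroupP(pct_all[ridx == r, , drop = FALSE], groups)
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}, kept as the
#' package's single named FDR step.
#'
#' @param p numeric vector of p-values in [0, 1]; NAs propagate.
#' @return q-values (monotone in p-value rank, q >= p).
#' @export
adjustFDR <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated regions
#'
#' Applies, in order: the methylation-band filter (optional), the per-region
#' two-way ANOVA, BH correction over all tested regions of this contrast
#' (one FDR family per subgroup-vs-control comparison), and the
#' delta/significance gates: a region is a DMR iff
#' |group mean - control mean| >= \code{minDelta} percentage points and
#' q < \code{alpha}.  Direction is the sign of the delta.  Median DMR
#' methylation (MDM, the per-group median of per-sample region percentages)
#' is reported alongside the means.
#'
#' @param regions a \linkS4class{MethylRegionSet} from
#'   \code{\link{assembleRegions}}.
#' @param controlGroup,testGroup the contrast.
#' @param minDelta minimum absolute group-mean difference in percentage
#'   points (default 10).
#' @param alpha FDR threshold (default 0.05).
#' @param band apply the band filter (default TRUE)?
#' @param ... band boundaries passed to \code{\link{bandFilter}}.
#' @return A \code{GRanges} of called DMRs with mcols: \code{dmr_id},
#'   \code{n_cpgs}, \code{control_mean}, \code{group_mean}, \code{delta},
#'   \code{direction}, \code{control_mdm}, \code{group_mdm}, \code{p_value},
#'   \code{q_value}, and the \code{pct} per-sample matrix retained in
#'   \code{metadata(x)$pct} for downstream correlation.
#' @export
callDMRs <- function(regions, controlGroup = "control", testGroup,
                     minDelta = 10, alpha = 0.05, band = TRUE, ...) {
  gv <- sampleGroups(regions)
  if (!controlGroup %in% gv || !testGroup %in% gv) {
    stop(sprintf("unknown group label '%s' or '%s'", controlGroup,
                 testGroup), call. = FALSE)
  }
  keep <- if (band) {
    bandFilter(regions, controlGroup, testGroup, ...)
  } else rep(TRUE, nrow(regions))
  # carry the assembly metadata through the subset
  sub <- regions[keep, ]
  S4Vectors::metadata(sub)$cpg_calls <- S4Vectors::metadata(regions)$cpg_calls
  old_idx <- S4Vectors::metadata(regions)$cpg_region_index
  if (!is.null(old_idx)) {
    sel <- which(keep)
    keep_cpg <- old_idx %in% sel
    S4Vectors::metadata(sub)$cpg_region_index <-
      match(old_idx[keep_cpg], sel)
    S4Vectors::metadata(sub)$cpg_calls <-
      S4Vectors::metadata(regions)$cpg_calls[keep_cpg, ]
  }
  if (nrow(sub) == 0L) return(emptyDmrGRanges())
  p <- testDifferential(sub, controlGroup, testGroup)
  tested <- !is.na(p)
  q <- rep(NA_real_, length(p))
  q[tested] <- adjustFDR(p[tested])
  gm <- groupMeanMatrix(sub, c(controlGroup, testGroup))
  delta <- gm[, 2] - gm[, 1]
  pct <- methLevel(sub)
  gvs <- sampleGroups(sub)
  mdm_c <- unname(apply(pct[, gvs == controlGroup, drop = FALSE], 1,
                        stats::median))
  mdm_g <- unname(apply(pct[, gvs == testGroup, drop = FALSE], 1,
                        stats::median))
  called <- tested & abs(delta) >= minDelta & q < alpha
  if (!any(called)) return(emptyDmrGRanges())
  out <- granges(rowRanges(sub))[called]
  mcols(out) <- S4Vectors::DataFrame(
    dmr_id = sprintf("dmr%05d", seq_len(sum(called))),
    n_cpgs = nCpGs(sub)[called],
    control_mean = gm[called, 1],
    group_mean = gm[called, 2],
    delta = delta[called],
    direction = ifelse(delta[called] > 0, "hyper", "hypo"),
    control_mdm = mdm_c[called],
    group_mdm = mdm_g[called],
    p_value = p[called],
    q_value = q[called])
  S4Vectors::metadata(out)$pct <- pct[called, , drop = FALSE]
  S4Vectors::metadata(out)$contrast <- c(control = controlGroup,
                                         group = testGroup)
  out
}

#' @noRd
emptyDmrGRanges <- function() {
  out <- GenomicRanges::GRanges()
  mcols(out) <- S4Vectors::DataFrame(
    dmr_id = character(), n_cpgs = integer(), control_mean = numeric(),
    group_mean = numeric(), delta = numeric(), direction = character(),
    control_mdm = numeric(), group_mdm = numeric(), p_value = numeric(),
    q_value = numeric())
  out
}

#' Diffscore mapping from a p-value
#'
#' Signed score on the +/- 10*log10 scale: 10 * sign(delta-beta) *
#' (-log10 p), so |score| = 13.01 corresponds to p = 0.05.
#'
#' @param p p-value(s).
#' @param deltaBeta signed beta difference(s).
#' @return Signed diffscore(s).
#' @export
diffscore <- function(p, deltaBeta) {
  10 * sign(deltaBeta) * (-log10(p))
}

#' Call differentially methylated cytosines from an array beta table
#'
#' Per probe, the group difference in mean beta and a two-sided
#' Mann-Whitney U p-value across per-sample betas are computed; the p-value
#' is mapped to the signed diffscore scale.  A probe is called iff
#' |delta beta| > \code{minDelta} and |diffscore| > \code{minDiffscore}
#' (13 being equivalent to adjusted p = 0.05).
#'
#' @param betas list as from \code{\link{readBetaTable}}: \code{probes}
#'   data.frame and \code{beta} matrix (probes x samples).
#' @param sampleGroups named character vector sample -> group.
#' @param controlGroup,testGroup the contrast; each needs >= 2 samples.
#' @param minDelta beta-difference gate (default 0.1, strict).
#' @param minDiffscore diffscore gate (default 13, strict).
#' @param all return all probes (with a \code{called} flag) instead of only
#'   the called ones.
#' @return data.frame with probe, chrom, pos, mean_beta_control,
#'   mean_beta_group, delta_beta, p_value, diffscore, called.
#' @export
callDMCs <- function(betas, sampleGroups, controlGroup = "control",
                     testGroup, minDelta = 0.1, minDiffscore = 13,
                     all = FALSE) {
  beta <- betas$beta
  gv <- sampleGroups[colnames(beta)]
  ctrl <- which(gv == controlGroup)
  grp <- which(gv == testGroup)
  if (length(ctrl) < 2L || length(grp) < 2L) {
    stop("each group needs >= 2 samples for DMC calling", call. = FALSE)
  }
  mb_c <- rowMeans(beta[, ctrl, drop = FALSE])
  mb_g <- rowMeans(beta[, grp, drop = FALSE])
  db <- mb_g - mb_c
  p <- vapply(seq_len(nrow(beta)), function(i) {
    if (db[i] == 0 && all(beta[i, grp] == beta[i, ctrl][1])) return(1)
    mannWhitney(beta[i, grp], beta[i, ctrl])$p.value
  }, numeric(1))
  ds <- diffscore(p, db)
  called <- abs(db) > minDelta & abs(ds) > minDiffscore
  out <- data.frame(probe = betas$probes$probe, chrom = betas$probes$chrom,
                    pos = betas$probes$pos, mean_beta_control = mb_c,
                    mean_beta_group = mb_g, delta_beta = db, p_value = p,
                    diffscore = ds, called = called,
                    row.names = NULL)
  if (all) out else out[out$called, , drop = FALSE]
}
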