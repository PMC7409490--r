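# Shared fixtures and independent-oracle utilities.

# Adjusted Rand index between two partitions (closed form over the
# contingency table); used to score recovered cluster structure.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(tab)
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Build a MethylCallSet whose assembled regions have (approximately) the
# requested per-group mean methylation: nCpg CpGs per region spaced 50 bp,
# fixed total coverage, methylated counts drawn binomially around the
# given group percentages.
makeRegionCalls <- function(controlPct, groupPct, nCpg = 4L, nPer = 3L,
                            coverage = 100L, seed = 1, noise = TRUE) {
  stopifnot(length(controlPct) == length(groupPct))
  nreg <- length(controlPct)
  samples <- c(sprintf("c%d", seq_len(nPer)), sprintf("t%d", seq_len(nPer)))
  groups <- stats::setNames(rep(c("control", "tumor"), each = nPer), samples)
  pos <- as.vector(vapply(seq_len(nreg), function(r) {
    (r - 1L) * 10000L + 50L * seq_len(nCpg)
  }, integer(nCpg)))
  n <- nreg * nCpg
  tot <- matrix(coverage, n, length(samples),
                dimnames = list(NULL, samples))
  p <- cbind(matrix(rep(controlPct, each = nCpg) / 100, n, nPer),
             matrix(rep(groupPct, each = nCpg) / 100, n, nPer))
  meth <- if (noise) {
    withr::with_seed(seed, matrix(rbinom(n * length(samples), coverage, p),
                                  n, length(samples)))
  } else {
    round(p * coverage)
  }
  storage.mode(meth) <- "integer"
  MethylCallSet(chrom = rep("chr1", n), pos = pos, methylated = meth,
                total = tot, sampleGroups = groups)
}

# Independent rule-by-rule DMR-calling oracle: recomputes group means, the
# band rule, an lm-based two-way ANOVA, hand-rolled BH, and the delta gate,
# entirely outside the package's code path.
oracleCallDMRs <- function(regions, controlGroup = "control",
                           testGroup = "tumor", minDelta = 10,
                           alpha = 0.05, band = TRUE) {
  calls <- S4Vectors::metadata(regions)$cpg_region_index
  cpgs <- S4Vectors::metadata(regions)$cpg_calls
  pct <- methLevel(regions)
  gv <- sampleGroups(regions)
  cm <- rowMeans(pct[, gv == controlGroup, drop = FALSE])
  gm <- rowMeans(pct[, gv == testGroup, drop = FALSE])
  keep_band <- if (band) {
    inb <- function(m) m >= 20 & m <= 80 & !(m > 40 & m < 60)
    inb(cm) & inb(gm)
  } else rep(TRUE, nrow(regions))
  cpg_pct <- 100 * methReads(cpgs) / pmax(totalReads(cpgs), 1L)
  use <- sampleGroups(cpgs) %in% c(controlGroup, testGroup)
  p <- rep(NA_real_, nrow(regions))
  for (r in which(keep_band)) {
    y <- cpg_pct[calls == r, use, drop = FALSE]
    if (stats::sd(y) < 1e-8) next
    df <- data.frame(y = as.vector(y),
                     pos = factor(rep(seq_len(nrow(y)), ncol(y))),
                     g = factor(rep(sampleGroups(cpgs)[use],
                                    each = nrow(y))))
    fit <- stats::anova(stats::lm(y ~ pos + g, df))
    if (is.na(fit["g", "Pr(>F)"])) next
    p[r] <- fit["g", "Pr(>F)"]
  }
  # hand BH over the tested family
  tested <- which(!is.na(p))
  q <- rep(NA_real_, length(p))
  if (length(tested)) {
    pt <- p[tested]
    m <- length(pt)
    o <- order(pt)
    qq <- pt[o] * m / seq_len(m)
    qq <- rev(cummin(rev(qq)))
    qq <- pmin(qq, 1)
    q[tested[o]] <- qq
  }
  called <- !is.na(q) & abs(gm - cm) >= minDelta & q < alpha
  data.frame(region = seq_len(nrow(regions)), control_mean = cm,
             group_mean = gm, delta = gm - cm, p = p, q = q,
             called = called)
}

# Brute-force all-pairs interval overlap oracle (1-based closed GRanges).
oracleOverlaps <- function(dmrs, peaks, minOverlap = 51L) {
  out <- list()
  for (i in seq_along(dmrs)) {
    for (j in seq_along(peaks)) {
      if (as.character(GenomicRanges::seqnames(dmrs))[i] !=
          as.character(GenomicRanges::seqnames(peaks))[j]) next
      ov <- min(GenomicRanges::end(dmrs)[i], GenomicRanges::end(peaks)[j]) -
        max(GenomicRanges::start(dmrs)[i],
            GenomicRanges::start(peaks)[j]) + 1L
      if (ov > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          dmr_id = S4Vectors::mcols(dmrs)$dmr_id[i],
          peak_start = GenomicRanges::start(peaks)[j],
          overlap_length = ov, qualifies = ov >= minOverlap)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(dmr_id = character(), peak_start = integer(),
                      overlap_length = integer(), qualifies = logical()))
  }
  res <- do.call(rbind, out)
  res[order(res$dmr_id, res$peak_start), , drop = FALSE]
}

# Small default simulation shared by several tests.
tinyConfig <- function(seed = 11, ...) {
  simConfig(seed = seed, n_genes = 15L, n_intergenic_regions = 30L, ...)
}
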