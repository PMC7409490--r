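# DMR/DMC calling: each qualification rule against its stated behaviour,
# the closed-form ANOVA against lm, BH by hand, gate monotonicity and
# order stability.

test_that("coverage filter requires the minimum in every sample", {
  mk <- function(totals) {
    MethylCallSet(chrom = "chr1", pos = 100L,
                  methylated = matrix(0L, 1, 3,
                                      dimnames = list(NULL,
                                                      c("a", "b", "c"))),
                  total = matrix(as.integer(totals), 1, 3,
                                 dimnames = list(NULL, c("a", "b", "c"))),
                  sampleGroups = c(a = "control", b = "tumor", c = "tumor"))
  }
  expect_identical(nrow(filterCpGs(mk(c(10, 10, 10)), 10)), 1L)
  expect_identical(nrow(filterCpGs(mk(c(10, 9, 10)), 10)), 0L)
  # minReads = 1 on all-covered data is the identity
  cs <- mk(c(3, 1, 7))
  expect_identical(nrow(filterCpGs(cs, 1)), 1L)
  expect_error(filterCpGs(cs[, 0], 10), "no samples")
})

test_that("region assembly follows the gap rule and pools counts", {
  groups <- c(s1 = "control", s2 = "tumor")
  mk <- function(pos, meth, tot) {
    MethylCallSet(chrom = rep("chr1", length(pos)), pos = pos,
                  methylated = matrix(as.integer(meth), length(pos), 2,
                                      dimnames = list(NULL, names(groups))),
                  total = matrix(as.integer(tot), length(pos), 2,
                                 dimnames = list(NULL, names(groups))),
                  sampleGroups = groups)
  }
  # CpGs at 100,150,600 with max_gap 200: {100,150} kept, singleton dropped
  rs <- assembleRegions(mk(c(100L, 150L, 600L), 5, 10), maxGap = 200)
  expect_identical(nrow(rs), 1L)
  expect_identical(start(rowRanges(rs)), 100L)
  expect_identical(end(rowRanges(rs)), 150L)
  expect_identical(nCpGs(rs), 2L)
  # single CpG: nothing survives minCpgs = 2
  expect_identical(nrow(assembleRegions(mk(400L, 5, 10))), 0L)
  # pooled percentage: (5+5)/(10+10) = 50%
  expect_equal(unname(methLevel(rs)[1, ]), c(50, 50))
  # a run longer than maxSpan is split
  pos <- seq(1000L, by = 50L, length.out = 10L)
  rs2 <- assembleRegions(mk(pos, 5, 10), maxGap = 200, maxSpan = 220)
  expect_gt(nrow(rs2), 1L)
  expect_true(all(width(rowRanges(rs2)) <= 221))
  expect_identical(sum(nCpGs(rs2)), 10L)
  expect_error(assembleRegions(mk(400L, 5, 10), maxGap = 0), "positive")
})

test_that("band filter keeps only means in [20,40] u [60,80], both groups", {
  cases <- rbind(
    c(27, 39, TRUE),   # both in [20,40]
    c(85, 70, FALSE),  # control > 80
    c(40, 60, TRUE),   # boundaries of the middle band are inclusive
    c(20, 80, TRUE),   # outer boundaries inclusive
    c(41, 70, FALSE),  # middle band is open
    c(59.9, 61, FALSE),
    c(30, 19, FALSE),  # group below 20
    c(65, 75, TRUE))
  calls <- makeRegionCalls(cases[, 1], cases[, 2], noise = FALSE,
                           coverage = 1000L)
  rs <- assembleRegions(calls, maxGap = 500, maxSpan = 500)
  expect_identical(nrow(rs), nrow(cases))
  expect_identical(bandFilter(rs, "control", "tumor"),
                   as.logical(cases[, 3]))
})

test_that("closed-form two-way ANOVA matches the lm route", {
  set.seed(101)
  for (rep in 1:20) {
    m <- sample(2:6, 1)
    npc <- sample(2:5, 1)
    npt <- sample(2:5, 1)
    pct <- matrix(rnorm(m * (npc + npt), 50, 8), m)
    groups <- rep(c("control", "tumor"), c(npc, npt))
    p1 <- anovaGroupP(pct, groups)
    df <- data.frame(y = as.vector(pct),
                     pos = factor(rep(seq_len(m), npc + npt)),
                     g = factor(rep(groups, each = m)))
    p2 <- stats::anova(stats::lm(y ~ pos + g, df))["g", "Pr(>F)"]
    expect_equal(p1, p2, tolerance = 1e-10)
  }
  # strong separation: 30 vs 70 with sd 5 at n = 5/group
  set.seed(5)
  pct <- cbind(matrix(rnorm(20, 30, 5), 4), matrix(rnorm(20, 70, 5), 4))
  expect_lt(anovaGroupP(pct, rep(c("control", "tumor"), each = 5)), 1e-3)
  # degenerate: no variance anywhere -> NA sentinel
  expect_true(is.na(anovaGroupP(matrix(50, 4, 10),
                                rep(c("control", "tumor"), each = 5))))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjustFDR(0.04), 0.04)
  expect_equal(adjustFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustFDR(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.09, 0.7)
  # hand step-up
  q <- rev(cummin(rev(p * 6 / seq_len(6))))
  expect_equal(adjustFDR(p), q)
  expect_true(all(adjustFDR(p) >= p))
  expect_error(adjustFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("callDMRs applies delta, FDR and band gates as one rule set", {
  set.seed(7)
  # 12 regions: clear hyper (25->39), sub-threshold (30->39.9 approx),
  # nulls at 30, and band-violating (50->64)
  ctrl <- c(25, 30, rep(30, 8), 50, 70)
  grp <- c(39, 39.9, rep(30, 8), 64, 84)
  calls <- makeRegionCalls(ctrl, grp, nPer = 5, coverage = 200, seed = 42)
  rs <- assembleRegions(calls, maxGap = 500, maxSpan = 500)
  dmrs <- callDMRs(rs, "control", "tumor", minDelta = 10, alpha = 0.05)
  # regions were laid down 10 kb apart, so start position identifies them
  called_starts <- start(dmrs)
  called_idx <- floor(called_starts / 10000) + 1
  expect_true(1 %in% called_idx)        # 25 -> 39: called hyper
  expect_false(2 %in% called_idx)       # delta below 10 points
  expect_true(all(mcols(dmrs)$direction == "hyper"))
  expect_true(all(abs(mcols(dmrs)$delta) >= 10))
  expect_true(all(mcols(dmrs)$q_value < 0.05))
  # band-violating regions (indices 11, 12) are never called
  expect_false(any(called_starts > 10000 * 10))

  # MDM equals the direct per-sample median
  pct <- methLevel(rs)
  gv <- sampleGroups(rs)
  idx <- match(paste0("chr1:", start(dmrs)), paste0("chr1:", start(rowRanges(rs))))
  for (k in seq_along(dmrs)) {
    expect_equal(mcols(dmrs)$control_mdm[k],
                 stats::median(pct[idx[k], gv == "control"]))
    expect_equal(mcols(dmrs)$group_mdm[k],
                 stats::median(pct[idx[k], gv == "tumor"]))
  }
  expect_error(callDMRs(rs, "control", "nope"), "unknown group")
})

test_that("gate order is stable and gates are monotone", {
  set.seed(19)
  ctrl <- runif(40, 22, 38)
  grp <- ctrl + sample(c(0, 8, 12, 15), 40, replace = TRUE) *
    sample(c(-1, 1), 40, replace = TRUE)
  grp <- pmin(pmax(grp, 21), 79)
  calls <- makeRegionCalls(ctrl, grp, nPer = 5, coverage = 150, seed = 3)
  rs <- assembleRegions(calls, maxGap = 500, maxSpan = 500)

  oracle <- oracleCallDMRs(rs, minDelta = 10, alpha = 0.05, band = TRUE)
  dmrs <- callDMRs(rs, "control", "tumor", minDelta = 10, alpha = 0.05)
  expect_identical(length(dmrs), sum(oracle$called))
  expect_equal(sort(start(dmrs)),
               sort(start(rowRanges(rs))[oracle$called]))

  # monotonicity: stricter delta or alpha never adds a call
  d20 <- callDMRs(rs, "control", "tumor", minDelta = 20)
  expect_true(all(start(d20) %in% start(dmrs)))
  a01 <- callDMRs(rs, "control", "tumor", alpha = 0.01)
  expect_true(all(start(a01) %in% start(dmrs)))
})

test_that("DMC calling implements the delta-beta/diffscore rule", {
  # diffscore closed form: p = 0.05 -> |score| = 13.0103 passes the gate
  expect_equal(abs(diffscore(0.05, 0.3)), 10 * log10(20), tolerance = 1e-9)
  expect_gt(abs(diffscore(0.05, 0.3)), 13)

  set.seed(31)
  ns <- 6
  groups <- stats::setNames(rep(c("control", "tumor"), each = ns),
                            c(sprintf("c%d", 1:ns), sprintf("t%d", 1:ns)))
  beta <- rbind(
    strong = c(rnorm(ns, 0.30, 0.02), rnorm(ns, 0.55, 0.02)),
    small_delta = c(rnorm(ns, 0.30, 0.02), rnorm(ns, 0.39, 0.02)),
    null = rep(0.40, 2 * ns))
  beta <- pmin(pmax(beta, 0), 1)
  colnames(beta) <- names(groups)
  betas <- list(probes = data.frame(probe = rownames(beta),
                                    chrom = "chr1", pos = c(100L, 200L, 300L)),
                beta = beta)
  res <- callDMCs(betas, groups, "control", "tumor", all = TRUE)
  expect_true(res$called[1])
  expect_false(res$called[2])   # delta gate: |0.09| < 0.1
  expect_false(res$called[3])   # identical betas
  expect_equal(res$delta_beta[3], 0)
  called <- callDMCs(betas, groups, "control", "tumor")
  expect_identical(called$probe, "strong")

  expect_error(callDMCs(betas, c(c1 = "control", t1 = "tumor",
                                 t2 = "tumor"), "control", "tumor"),
               ">= 2 samples")
})

test_that("type-I error of the region test is nominal on null data", {
  # 400 null regions under the test's own model (no sample jitter)
  cfg <- simConfig(seed = 23, n_genes = 0L, n_intergenic_regions = 400L,
                   n_chromosomes = 2L, jitter_concentration = Inf)
  co <- simulateCohort(cfg)
  rs <- assembleRegions(filterCpGs(co$calls, 10), maxGap = 200,
                        maxSpan = 220)
  p <- testDifferential(rs, "control", "tumor")
  frac <- mean(p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 0.03)  # loose at n=400; tight case in acceptance
})
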