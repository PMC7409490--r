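# Synthetic-data generator: determinism, planted structure, sampling
# distributions, and truth-table consistency.

test_that("genome generation is deterministic and respects the layout", {
  cfg <- simConfig(seed = 5, n_genes = 50L, n_intergenic_regions = 20L,
                   n_chromosomes = 2L, chrom_length = 1e6)
  g1 <- generateGenome(cfg)
  g2 <- generateGenome(cfg)
  expect_identical(g1, g2)

  # 50 gene intervals pairwise disjoint (brute force)
  genes <- g1$genes
  expect_length(genes, 50L)
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i >= j) next
      same_chrom <- as.character(seqnames(genes))[i] ==
        as.character(seqnames(genes))[j]
      if (same_chrom) {
        disjoint <- end(genes)[i] < start(genes)[j] ||
          end(genes)[j] < start(genes)[i]
        expect_true(disjoint)
      }
    }
  }
  # every gene has a promoter and a body candidate region
  rg <- as.data.frame(mcols(g1$regions))
  per_gene <- table(rg$gene_id[!is.na(rg$gene_id)],
                    rg$compartment[!is.na(rg$gene_id)])
  expect_true(all(per_gene[, "promoter"] >= 1))
  expect_true(all(per_gene[, "body"] >= 1))
  # CpG positions strictly increasing per chromosome
  cp <- split(start(g1$cpgs), as.character(seqnames(g1$cpgs)))
  for (v in cp) expect_true(all(diff(v) > 0))
})

test_that("empty genome and sizing errors behave as specified", {
  cfg <- simConfig(n_genes = 0L, n_intergenic_regions = 0L)
  g <- generateGenome(cfg)
  expect_length(g$genes, 0L)
  expect_length(g$cpgs, 0L)
  expect_error(generateGenome(simConfig(n_genes = 100L, n_chromosomes = 1L,
                                        chrom_length = 5e4)),
               "do not fit")
})

test_that("methylation counts follow the configured sampling model", {
  # coverage: mean total within +/-2 of the NB mean over >= 1e4 CpGs
  cfg <- simConfig(seed = 7, n_genes = 0L, n_intergenic_regions = 2000L,
                   n_chromosomes = 4L, chrom_length = 2e6,
                   coverage_mean = 30,
                   n_samples_per_group = c(control = 2L, tumor = 2L))
  g <- generateGenome(cfg)
  tr <- plantTruth(cfg, g)
  calls <- generateMethylation(cfg, g, tr)
  expect_gte(nrow(calls), 1e4)
  expect_lt(abs(mean(totalReads(calls)) - 30), 2)

  # planted hyper region at baseline 0.30 + 0.20: target-group mean within
  # +/-3 points of 50%
  cfg2 <- simConfig(seed = 8, n_genes = 0L, n_intergenic_regions = 300L,
                    baseline_methylation = 0.30,
                    planted_dmrs = plantedDmrs(50, direction = "hyper",
                                               delta = 0.20),
                    coverage_mean = 50,
                    n_samples_per_group = c(control = 10L, tumor = 10L))
  g2 <- generateGenome(cfg2)
  tr2 <- plantTruth(cfg2, g2)
  calls2 <- generateMethylation(cfg2, g2, tr2)
  gv <- sampleGroups(calls2)
  in_planted <- IRanges::overlapsAny(
    rowRanges(calls2),
    GenomicRanges::GRanges(tr2$planted_regions$chrom,
                           IRanges::IRanges(tr2$planted_regions$start,
                                            tr2$planted_regions$end)))
  pct <- 100 * methReads(calls2) / totalReads(calls2)
  tumor_mean <- mean(pct[in_planted, gv == "tumor"])
  ctrl_mean <- mean(pct[in_planted, gv == "control"])
  expect_lt(abs(tumor_mean - 50), 3)
  expect_lt(abs(ctrl_mean - 30), 3)

  # null case: no plantings, group mean difference < 2 points
  expect_lt(abs(mean(pct[!in_planted, gv == "tumor"]) -
                  mean(pct[!in_planted, gv == "control"])), 2)

  # delta pushing probability out of [0,1] is a config error
  expect_error(simConfig(baseline_methylation = 0.9,
                         planted_dmrs = plantedDmrs(1, direction = "hyper",
                                                    delta = 0.2)),
               "outside")
})

test_that("expression carries the planted GEM effects and nothing else", {
  cfg <- simConfig(seed = 9, n_genes = 60L, n_intergenic_regions = 0L,
                   chrom_length = 2e6,
                   planted_gems = plantedGems(5, log2_effect = 2),
                   n_samples_per_group = c(control = 10L, tumor = 10L))
  g <- generateGenome(cfg)
  tr <- plantTruth(cfg, g)
  e1 <- generateExpression(cfg, g, tr)
  e2 <- generateExpression(cfg, g, tr)
  expect_identical(e1, e2)

  gv <- sub("_\\d+$", "", colnames(e1))
  diff <- rowMeans(e1[, gv == "tumor"]) - rowMeans(e1[, gv == "control"])
  tg <- tr$planted_gems
  # sign consistency per quadrant and recovery within the CLT bound
  for (k in seq_len(nrow(tg))) {
    expected <- tg$log2_effect[k]
    expect_lt(abs(diff[tg$gene_id[k]] - expected), 0.3)
    exp_sign <- if (tg$quadrant[k] %in% c("promoter_hypo_over",
                                          "body_hyper_over")) 1 else -1
    expect_identical(sign(expected), exp_sign)
  }
  # non-GEM genes: no planted signal; 2-fold exceedances at noise level
  null_diff <- diff[setdiff(names(diff), tg$gene_id)]
  expect_lt(mean(abs(null_diff) >= 1), 0.01)
})

test_that("peak generation honours coupling probabilities and bounds", {
  mkcfg <- function(p, nbg = 0L, seed = 13) {
    simConfig(seed = seed, n_genes = 0L, n_intergenic_regions = 150L,
              planted_dmrs = plantedDmrs(100, direction = "hypo",
                                         delta = 0.2),
              peak_coupling = data.frame(mark = "H3K27me3",
                                         dmr_direction = "hypo",
                                         probability = p),
              background_peaks_per_mark = nbg)
  }
  cfg <- mkcfg(1)
  g <- generateGenome(cfg)
  tr <- plantTruth(cfg, g)
  pk <- generatePeaks(cfg, g, tr)
  planted <- GenomicRanges::GRanges(tr$planted_regions$chrom,
                                    IRanges::IRanges(tr$planted_regions$start,
                                                     tr$planted_regions$end))
  # probability 1: every planted hypo region has a >50 bp overlap
  hits <- GenomicRanges::findOverlaps(planted, pk$peaks$H3K27me3,
                                      minoverlap = 51L)
  expect_setequal(S4Vectors::queryHits(hits), seq_along(planted))
  # all peaks within chromosome bounds
  expect_true(all(start(pk$peaks$H3K27me3) >= 1))
  expect_true(all(end(pk$peaks$H3K27me3) <= cfg$chrom_length))

  # probability 0, no background: empty set
  cfg0 <- mkcfg(0)
  pk0 <- generatePeaks(cfg0, generateGenome(cfg0),
                       plantTruth(cfg0, generateGenome(cfg0)))
  expect_length(pk0$peaks$H3K27me3, 0L)

  # probability 0.8 over 100 planted regions: binomial 95% band 80 +/- 8
  cfg8 <- mkcfg(0.8)
  g8 <- generateGenome(cfg8)
  tr8 <- plantTruth(cfg8, g8)
  pk8 <- generatePeaks(cfg8, g8, tr8)
  expect_lt(abs(nrow(pk8$couplings) - 80), 8.1)

  expect_error(simConfig(peak_coupling = data.frame(
    mark = "x", dmr_direction = "hypo", probability = 1.2)), "outside")
})

test_that("truth table is internally consistent with the genome", {
  cfg <- tinyConfig(planted_dmrs = plantedDmrs(5, compartment = "body",
                                               delta = 0.15),
                    planted_gems = plantedGems(2))
  co <- simulateCohort(cfg)
  tr <- co$truth
  expect_false(anyDuplicated(tr$planted_regions$region_id) > 0)
  # every planted region resolves to a genome candidate interval
  expect_true(all(tr$planted_regions$region_id %in%
                    mcols(co$genome$regions)$region_id))
  # every planted GEM references a planted region in the quadrant's
  # compartment
  for (k in seq_len(nrow(tr$planted_gems))) {
    row <- tr$planted_gems[k, ]
    reg <- tr$planted_regions[tr$planted_regions$region_id == row$region_id, ]
    expect_identical(nrow(reg), 1L)
    comp <- if (grepl("^promoter", row$quadrant)) "promoter" else "body"
    expect_identical(reg$compartment, comp)
    expect_identical(reg$gene_id, row$gene_id)
  }
  # intervals lie within declared chromosome bounds
  expect_true(all(tr$planted_regions$start >= 1 &
                    tr$planted_regions$end <= cfg$chrom_length))
})

test_that("an identical config reproduces byte-identical files", {
  cfg <- tinyConfig(planted_gems = plantedGems(1),
                    peak_coupling = data.frame(mark = "SE",
                                               dmr_direction = "hyper",
                                               probability = 0.5),
                    planted_dmrs = plantedDmrs(4))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSimulation(simulateCohort(cfg), d1)
  writeSimulation(simulateCohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})
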