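# GEM classification: expression calls, mixed-direction exclusion, the
# four quadrant patterns, r-squared, and cohort summaries.

# build an annotated-DMR GRanges by hand
mkAnnotated <- function(gene_id, compartment, direction, delta = 20,
                        pct = NULL) {
  n <- length(gene_id)
  gr <- GRanges(rep("chr1", n),
                IRanges(seq(1000, by = 1000, length.out = n),
                        width = rep(200, n)))
  mcols(gr) <- S4Vectors::DataFrame(
    dmr_id = sprintf("d%03d", seq_len(n)), gene_id = gene_id,
    compartment = compartment, direction = direction,
    delta = ifelse(direction == "hyper", abs(delta), -abs(delta)))
  if (!is.null(pct)) S4Vectors::metadata(gr)$pct <- pct
  gr
}

mkExprCalls <- function(gene_id, class, log2fc = NULL) {
  if (is.null(log2fc)) {
    log2fc <- ifelse(class == "overexpressed", 2,
                     ifelse(class == "under-expressed", -2, 0))
  }
  data.frame(gene_id = gene_id, control_mean = 8, group_mean = 8 + log2fc,
             log2fc = log2fc, class = class)
}

test_that("expression calls apply the two-fold rule on log2 means", {
  groups <- c(c1 = "control", c2 = "control", t1 = "tumor", t2 = "tumor")
  expr <- rbind(up = c(5, 5, 7, 7),        # log2FC = 2
                flat = c(5, 5, 5.9, 5.9),  # |FC| < 2-fold
                down = c(8, 8, 6.5, 6.5))  # log2FC = -1.5
  colnames(expr) <- names(groups)
  ec <- callExpression(expr, groups, "control", "tumor")
  expect_identical(ec$class, c("overexpressed", "unchanged",
                               "under-expressed"))
  expect_equal(ec$log2fc, c(2, 0.9, -1.5))
  # boundary: exactly two-fold is called
  expr2 <- rbind(edge = c(5, 5, 6, 6))
  colnames(expr2) <- names(groups)
  expect_identical(callExpression(expr2, groups, "control",
                                  "tumor")$class, "overexpressed")
})

test_that("a planted ARID5A-like effect is recovered within 0.3 log2", {
  # the maf-subgroup exemplar: 5.74-fold overexpression = 2.52 on log2
  cfg <- simConfig(seed = 21, n_genes = 40L, n_intergenic_regions = 0L,
                   chrom_length = 2e6,
                   planted_gems = data.frame(quadrant = "promoter_hypo_over",
                                             log2_effect = log2(5.74),
                                             target_group = "tumor"),
                   n_samples_per_group = c(control = 10L, tumor = 10L))
  co <- simulateCohort(cfg)
  groups <- sampleGroups(co$calls)
  ec <- callExpression(co$expression, groups, "control", "tumor")
  gid <- co$truth$planted_gems$gene_id
  row <- ec[ec$gene_id == gid, ]
  expect_identical(row$class, "overexpressed")
  expect_lt(abs(row$log2fc - log2(5.74)), 0.3)
})

test_that("mixed-direction exclusion works within, not across, compartments", {
  # promoter hyper + hypo on the same gene: excluded
  a1 <- mkAnnotated(c("g1", "g1"), c("promoter", "promoter"),
                    c("hyper", "hypo"))
  expect_identical(excludedGenes(a1), "g1")
  # promoter hypo + body hyper: kept
  a2 <- mkAnnotated(c("g1", "g1"), c("promoter", "body"),
                    c("hypo", "hyper"))
  expect_identical(excludedGenes(a2), character())
  # no DMRs: vacuously kept
  expect_identical(excludedGenes(mkAnnotated(character(), character(),
                                             character())), character())
})

test_that("the four canonical quadrants classify and anti-canonical do not", {
  cases <- list(
    list(comp = "promoter", dir = "hypo", cls = "overexpressed",
         quadrant = "promoter_hypo_over"),
    list(comp = "promoter", dir = "hyper", cls = "under-expressed",
         quadrant = "promoter_hyper_under"),
    list(comp = "body", dir = "hyper", cls = "overexpressed",
         quadrant = "body_hyper_over"),     # the DSG2/SORT1 pattern
    list(comp = "body", dir = "hypo", cls = "under-expressed",
         quadrant = "body_hypo_under"),     # the RFTN1 pattern
    list(comp = "promoter", dir = "hypo", cls = "under-expressed",
         quadrant = NULL),                  # anti-canonical
    list(comp = "body", dir = "hyper", cls = "under-expressed",
         quadrant = NULL))
  for (cs in cases) {
    ann <- mkAnnotated("g1", cs$comp, cs$dir)
    gems <- classifyGEMs(ann, mkExprCalls("g1", cs$cls))
    if (is.null(cs$quadrant)) {
      expect_identical(nrow(gems), 0L)
    } else {
      expect_identical(gems$quadrant, cs$quadrant)
    }
  }
})

test_that("exclusion precedes classification and promoter is primary", {
  # a clean body_hyper_over GEM ...
  ann <- mkAnnotated(c("g1", "g1"), c("body", "body"), c("hyper", "hyper"))
  ec <- mkExprCalls("g1", "overexpressed")
  expect_identical(classifyGEMs(ann, ec)$quadrant, "body_hyper_over")
  # ... vanishes when a contradictory promoter pair is injected
  ann2 <- mkAnnotated(c("g1", "g1", "g1", "g1"),
                      c("body", "body", "promoter", "promoter"),
                      c("hyper", "hyper", "hyper", "hypo"))
  expect_identical(nrow(classifyGEMs(ann2, ec)), 0L)
  # promoter + body double match: promoter primary, body secondary
  ann3 <- mkAnnotated(c("g1", "g1"), c("promoter", "body"),
                      c("hypo", "hyper"))
  gems <- classifyGEMs(ann3, ec)
  expect_identical(gems$quadrant, "promoter_hypo_over")
  expect_identical(gems$secondary_quadrant, "body_hyper_over")
})

test_that("emitted GEMs never violate their quadrant (property)", {
  set.seed(3)
  for (rep in 1:20) {
    n <- 30
    ann <- mkAnnotated(sample(sprintf("g%d", 1:10), n, TRUE),
                       sample(c("promoter", "body"), n, TRUE),
                       sample(c("hyper", "hypo"), n, TRUE))
    genes <- unique(mcols(ann)$gene_id)
    ec <- mkExprCalls(genes, sample(c("overexpressed", "under-expressed",
                                      "unchanged"), length(genes), TRUE))
    gems <- classifyGEMs(ann, ec)
    for (k in seq_len(nrow(gems))) {
      g <- gems$gene_id[k]
      quad <- gems$quadrant[k]
      comp <- if (grepl("^promoter", quad)) "promoter" else "body"
      dir <- if (grepl("hyper", quad)) "hyper" else "hypo"
      cls <- if (grepl("over$", quad)) "overexpressed" else "under-expressed"
      sub <- mcols(ann)[mcols(ann)$gene_id == g, ]
      expect_true(any(sub$compartment == comp & sub$direction == dir))
      expect_identical(ec$class[ec$gene_id == g], cls)
      expect_false(g %in% excludedGenes(ann))
    }
  }
})

test_that("r-squared behaves at its anchors and under planted correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(methylationExpressionR2(x, 2 * x + 3), 1)
  y <- c(1, -1, 2, -2, 0)  # orthogonal to x after centering? make it so
  y <- y - mean(y)
  y <- y - sum(y * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  expect_lt(methylationExpressionR2(x, y), 1e-20)
  expect_true(is.na(methylationExpressionR2(rep(1, 5), x)))
  expect_error(methylationExpressionR2(1:2, 1:2), ">= 3")

  # E[r^2] at rho = 0.7, n = 10: approx rho^2 = 0.49 over 200 draws
  set.seed(12)
  r2 <- replicate(200, {
    n <- 10
    m <- rnorm(n)
    e <- 0.7 * m + sqrt(1 - 0.49) * rnorm(n)
    methylationExpressionR2(m, e)
  })
  expect_lt(abs(mean(r2) - 0.49), 0.05)
})

test_that("gem summary counts genes once and tracks planted ratios", {
  ec <- mkExprCalls(sprintf("g%d", 1:50),
                    rep(c("overexpressed", "under-expressed"), 25))
  expect_equal(gemSummary(data.frame(gene_id = character(),
                                     quadrant = character()), ec)$fraction,
               0)
  gems <- data.frame(gene_id = sprintf("g%d", 1:20),
                     quadrant = rep(c("promoter_hypo_over",
                                      "body_hyper_over",
                                      "promoter_hyper_under",
                                      "body_hypo_under"), c(8, 6, 3, 3)))
  gs <- gemSummary(gems, ec)
  expect_equal(gs$fraction, 0.4)
  expect_identical(sum(gs$quadrant_counts), 20L)
  # over-expressed GEMs about twice the under-expressed, as planted
  expect_equal(gs$n_over / gs$n_under, 14 / 6)
  # zero DE genes: fraction missing
  ec0 <- mkExprCalls("g1", "unchanged")
  expect_true(is.na(gemSummary(gems[0, ], ec0)$fraction))
})
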