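# End-to-end orchestration: simulate (or ingest) -> call DMRs per subgroup
# -> annotate -> GEMs -> chromatin overlap -> profiles, with a manifest
# recording config, per-stage row counts, wall-clock and output checksums.

#' Pipeline run configuration
#'
#' Bundles the analysis thresholds (defaults are the study's stated values:
#' 10-read coverage, >= 2 CpGs, 10-point delta at FDR 0.05, 2-fold
#' expression, >50 bp overlap, top 5% most variable) with either a
#' simulation config or an input directory.
#'
#' @param sim a \code{\link{simConfig}} (simulate-then-analyze mode), or
#'   NULL to read inputs from \code{inputDir}.
#' @param inputDir directory holding \code{coverage/*.cov},
#'   \code{samples.tsv}, \code{genes.refflat}, \code{expression.tsv} and
#'   \code{peaks_<mark>.bed} files (the layout \code{\link{writeSimulation}}
#'   emits).
#' @param controlGroup control label.
#' @param minReads,minCpgs,maxGap,maxSpan,minDelta,alpha,minFold,minOverlap,
#'   topFraction,cutK,modulesK stage thresholds.
#' @param bandFilter apply the methylation-band qualification filter.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(sim = simConfig(), inputDir = NULL,
                      controlGroup = "control", minReads = 10L,
                      minCpgs = 2L, maxGap = 200L, maxSpan = 220L,
                      minDelta = 10, alpha = 0.05, minFold = 2,
                      minOverlap = 51L, topFraction = 0.05, cutK = 2L,
                      modulesK = 3L, bandFilter = TRUE) {
  for (nm in c("minReads", "minCpgs", "maxGap", "maxSpan", "minDelta",
               "alpha", "minFold", "minOverlap", "topFraction")) {
    assertScalarNumber(get(nm), nm, .Machine$double.eps)
  }
  structure(list(sim = sim, inputDir = inputDir,
                 controlGroup = controlGroup, minReads = minReads,
                 minCpgs = minCpgs, maxGap = maxGap, maxSpan = maxSpan,
                 minDelta = minDelta, alpha = alpha, minFold = minFold,
                 minOverlap = minOverlap, topFraction = topFraction,
                 cutK = cutK, modulesK = modulesK, bandFilter = bandFilter),
            class = "RunConfig")
}

#' @noRd
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' @noRd
dmrTable <- function(annotated) {
  data.frame(chrom = as.character(seqnames(annotated)),
             start = start(annotated) - 1L, end = end(annotated),
             as.data.frame(mcols(annotated)), check.names = FALSE)
}

#' Run the full pipeline
#'
#' Stages run in dependency order; any stage failure aborts with the stage
#' named.  Rerunning with an identical configuration reproduces identical
#' output checksums (the manifest itself, which carries wall-clock times,
#' is excluded from checksumming).
#'
#' @param config a \code{\link{runConfig}}.
#' @param outdir output directory.
#' @param verbose narrate per-stage counts.
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, outdir, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  timings <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  # -- simulate or locate inputs ------------------------------------------
  if (!is.null(config$sim)) {
    indir <- file.path(outdir, "sim")
    stage("simulate", {
      cohort <- simulateCohort(config$sim)
      writeSimulation(cohort, indir)
    })
  } else {
    indir <- config$inputDir
    if (is.null(indir)) {
      stop("pipeline stage 'inputs' failed: neither sim nor inputDir given",
           call. = FALSE)
    }
  }

  # -- ingest --------------------------------------------------------------
  calls <- stage("read-coverage", {
    covdir <- file.path(indir, "coverage")
    files <- list.files(covdir, pattern = "\\.cov(\\.gz)?$",
                        full.names = TRUE)
    if (!length(files)) {
      stop(sprintf("no coverage files under %s", covdir))
    }
    groups <- readSampleGroups(file.path(indir, "samples.tsv"))
    names(files) <- sub("\\.cov(\\.gz)?$", "", basename(files))
    readMethylCallSet(files[names(files) %in% names(groups)], groups)
  })
  counts$cpgs_raw <- nrow(calls)
  say("read %d CpG sites x %d samples", nrow(calls), ncol(calls))

  genes_path <- file.path(indir, "genes.refflat")
  genes <- if (file.exists(genes_path)) {
    stage("read-genes", readGeneModels(genes_path))
  } else GenomicRanges::GRanges(gene_id = character())
  expr_path <- file.path(indir, "expression.tsv")
  expr <- if (file.exists(expr_path)) {
    stage("read-expression", readExpressionMatrix(expr_path))
  } else NULL
  peak_files <- list.files(indir, pattern = "^peaks_.*\\.bed$",
                           full.names = TRUE)
  peaks <- stage("read-peaks", {
    pl <- lapply(peak_files, function(f) {
      readBed(f, mark = sub("^peaks_(.*)\\.bed$", "\\1", basename(f)))
    })
    names(pl) <- sub("^peaks_(.*)\\.bed$", "\\1", basename(peak_files))
    pl
  })

  # -- call DMRs per subgroup ---------------------------------------------
  groups <- sampleGroups(calls)
  subgroups <- setdiff(unique(groups), config$controlGroup)
  filtered <- stage("filter-cpgs", filterCpGs(calls, config$minReads))
  counts$cpgs_filtered <- nrow(filtered)
  say("%d CpG sites pass the %d-read coverage filter", nrow(filtered),
      config$minReads)
  regions <- stage("assemble-regions",
                   assembleRegions(filtered, maxGap = config$maxGap,
                                   minCpgs = config$minCpgs,
                                   maxSpan = config$maxSpan))
  counts$regions <- nrow(regions)
  say("%d regions assembled", nrow(regions))

  outfiles <- character()
  annotated_list <- list()
  gem_summaries <- list()
  for (sg in subgroups) {
    dmrs <- stage(paste0("call-dmrs-", sg),
                  callDMRs(regions, config$controlGroup, sg,
                           minDelta = config$minDelta,
                           alpha = config$alpha, band = config$bandFilter))
    counts[[paste0("dmrs_", sg)]] <- length(dmrs)
    say("%s: %d DMRs", sg, length(dmrs))
    ann <- stage(paste0("annotate-", sg), annotateDMRs(dmrs, genes))
    S4Vectors::metadata(ann)$pct <- S4Vectors::metadata(dmrs)$pct
    annotated_list[[sg]] <- ann
    f <- file.path(outdir, sprintf("dmrs_%s.tsv", sg))
    writeTsv(dmrTable(ann), f)
    outfiles <- c(outfiles, f)

    if (!is.null(expr)) {
      ec <- stage(paste0("call-expression-", sg),
                  callExpression(expr, groups, config$controlGroup, sg,
                                 minFold = config$minFold))
      gems <- stage(paste0("call-gems-", sg),
                    classifyGEMs(ann, ec, expr = expr,
                                 sampleGroups = groups,
                                 controlGroup = config$controlGroup))
      counts[[paste0("gems_", sg)]] <- nrow(gems)
      say("%s: %d GEMs among %d DE genes", sg, nrow(gems),
          sum(ec$class != "unchanged"))
      f <- file.path(outdir, sprintf("gems_%s.tsv", sg))
      writeTsv(gems, f)
      outfiles <- c(outfiles, f)
      gs <- gemSummary(gems, ec)
      gem_summaries[[sg]] <- list(n_de = gs$n_de, n_gem = gs$n_gem,
                                  fraction = gs$fraction,
                                  quadrant_counts = as.list(gs$quadrant_counts),
                                  n_over = gs$n_over, n_under = gs$n_under)
    }
  }

  # -- chromatin context ---------------------------------------------------
  marks <- setdiff(names(peaks), c("SE", "CTCF"))
  if (length(annotated_list) && length(peaks)) {
    for (sg in names(annotated_list)) {
      ann <- annotated_list[[sg]]
      if (!length(ann)) next
      if (length(marks)) {
        ovl <- stage(paste0("overlap-", sg), {
          lapply(peaks[marks], function(p) {
            overlapDMRsPeaks(ann, p, minOverlap = config$minOverlap)
          })
        })
        comp <- markComposition(ovl, ann)
        f <- file.path(outdir, sprintf("mark_composition_%s.tsv", sg))
        writeTsv(comp, f)
        outfiles <- c(outfiles, f)
      }
      if (all(c("SE", "CTCF") %in% names(peaks))) {
        sc <- stage(paste0("se-ctcf-", sg),
                    seCtcfOverlap(ann, peaks$SE, peaks$CTCF,
                                  minOverlap = config$minOverlap))
        counts[[paste0("se_dmrs_", sg)]] <- sc$se$n
        counts[[paste0("ctcf_dmrs_", sg)]] <- sc$ctcf$n
        pct <- S4Vectors::metadata(ann)$pct
        mod_ids <- union(sc$se$dmr_ids, sc$ctcf$dmr_ids)
        if (length(mod_ids) >= max(2L, config$modulesK)) {
          rows <- match(mod_ids, mcols(ann)$dmr_id)
          mpct <- pct[rows, , drop = FALSE]
          rownames(mpct) <- mod_ids
          mods <- clusterSEModules(mpct, k = config$modulesK)
          f <- file.path(outdir, sprintf("se_modules_%s.tsv", sg))
          writeTsv(data.frame(dmr_id = names(mods), module = unname(mods)),
                   f)
          outfiles <- c(outfiles, f)
        }
      }
    }
  }

  # -- profiles ------------------------------------------------------------
  if (nrow(regions) >= 20L) {
    prof <- stage("profiles", {
      pct <- methLevel(regions)
      rownames(pct) <- sprintf("r%06d", seq_len(nrow(pct)))
      top <- topVariable(pct, config$topFraction)
      hc <- hierarchicalCluster(top, k = min(config$cutK, ncol(top)))
      pca <- pcaMethylation(top)
      list(top = top, hc = hc, pca = pca)
    })
    counts$top_features <- nrow(prof$top)
    f <- file.path(outdir, "top_variable.tsv")
    writeTsv(data.frame(feature = rownames(prof$top), prof$top,
                        check.names = FALSE), f)
    outfiles <- c(outfiles, f)
    f <- file.path(outdir, "pca_scores.tsv")
    writeTsv(data.frame(sample = rownames(prof$pca$scores),
                        prof$pca$scores[, seq_len(min(5,
                          ncol(prof$pca$scores))), drop = FALSE],
                        check.names = FALSE), f)
    outfiles <- c(outfiles, f)
    f <- file.path(outdir, "sample_clusters.tsv")
    writeTsv(data.frame(sample = names(prof$hc$labels),
                        cluster = unname(prof$hc$labels)), f)
    outfiles <- c(outfiles, f)
  }
  if (length(annotated_list)) {
    f <- file.path(outdir, "subgroup_summary.tsv")
    writeTsv(subgroupSummary(annotated_list), f)
    outfiles <- c(outfiles, f)
  }
  if (length(gem_summaries)) {
    f <- file.path(outdir, "gem_summary.json")
    jsonlite::write_json(gem_summaries, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outfiles <- c(outfiles, f)
  }

  # -- manifest ------------------------------------------------------------
  sim_files <- if (!is.null(config$sim)) {
    list.files(file.path(outdir, "sim"), recursive = TRUE,
               full.names = TRUE)
  } else character()
  all_files <- c(sim_files, outfiles)
  manifest <- list(
    package_version = as.character(utils::packageVersion("methylGEM")),
    config = config[setdiff(names(config), "sim")],
    sim_seed = if (!is.null(config$sim)) config$sim$seed else NULL,
    stage_counts = counts,
    stage_seconds = timings,
    files = lapply(stats::setNames(all_files,
                                   sub(paste0("^", outdir, "/?"), "",
                                       all_files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Full-scale example cohort configuration
#'
#' The package's reference synthetic cohort: about 5 x 10^4 CpG sites over
#' 1,000 genes on four chromosomes, 12 samples in three tumor subgroups
#' plus controls, hypomethylation-skewed planted DMRs (70% hypo, echoing
#' the hypomethylation-dominant epigenome the pipeline is designed to
#' summarize), 10 planted GEMs per quadrant, and chromatin couplings
#' placing repressive H3K27me3 peaks preferentially over hypomethylated
#' regions and SE/CTCF intervals with hypo-skewed coupling.
#'
#' @param seed RNG seed.
#' @return A \code{\link{simConfig}} object.
#' @export
exampleCohortConfig <- function(seed = 1L) {
  planted <- rbind(
    plantedDmrs(35, compartment = "intergenic", direction = "hypo",
                delta = 0.20, target_group = "sub1"),
    plantedDmrs(15, compartment = "intergenic", direction = "hyper",
                delta = 0.20, target_group = "sub1"),
    plantedDmrs(20, compartment = "body", direction = "hypo",
                delta = 0.20, target_group = "sub2"),
    plantedDmrs(10, compartment = "body", direction = "hyper",
                delta = 0.20, target_group = "sub2"),
    plantedDmrs(15, compartment = "promoter", direction = "hypo",
                delta = 0.20, target_group = "sub3"),
    plantedDmrs(5, compartment = "promoter", direction = "hyper",
                delta = 0.20, target_group = "sub3"))
  simConfig(
    seed = seed, n_chromosomes = 4L, chrom_length = 8e6, n_genes = 1000L,
    n_intergenic_regions = 8000L,
    n_samples_per_group = c(control = 3L, sub1 = 3L, sub2 = 3L, sub3 = 3L),
    planted_dmrs = planted,
    planted_gems = plantedGems(10, log2_effect = 2, target_group = "sub1"),
    peak_coupling = data.frame(
      mark = c("H3K27me3", "H3K4me3", "SE", "SE", "CTCF", "CTCF"),
      dmr_direction = c("hypo", "hyper", "hypo", "hyper", "hypo", "hyper"),
      probability = c(0.80, 0.60, 0.65, 0.35, 0.82, 0.18)),
    background_peaks_per_mark = 100L)
}
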