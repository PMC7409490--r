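# Synthetic cohort generator: coupled methylation / expression / chromatin
# interval data with a planted truth table, emulating the statistical
# structure an RRBS-based subgroup comparison assumes (group-wise mean
# methylation shifts at multi-CpG regions, binomial read sampling with
# negative-binomial coverage, promoter-inverse / body-positive
# methylation-expression coupling, and peak placement coupled to DMR
# direction).

GEM_QUADRANTS <- c("promoter_hypo_over", "promoter_hyper_under",
                   "body_hyper_over", "body_hypo_under")

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort generator.
#' Defaults describe a small but realistic RRBS-like cohort: 30x mean
#' coverage with moderate negative-binomial overdispersion, a 30% baseline
#' methylation level, 5-vs-5 sample groups, multi-CpG regions of 4-7 CpGs
#' spaced 20-30 bp (MspI-fragment scale), Gaussian log2 expression noise of
#' 0.5, and a small Beta-distributed per-sample jitter (concentration 300,
#' i.e. about 2.5 percentage points at a 30% level) so groups have genuine
#' within-group variance.
#'
#' @param seed integer RNG seed; every generator op derives its stream from
#'   it, so a fixed config is fully deterministic.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes number of non-overlapping single-transcript genes.
#' @param gene_length_range bp range of gene lengths.
#' @param n_cpg_per_region_range CpGs per candidate region.
#' @param cpg_spacing_range bp between neighbouring CpGs of a region.
#' @param n_intergenic_regions candidate regions placed away from genes.
#' @param n_samples_per_group named integer vector, group -> sample count;
#'   must contain a group named \code{"control"}.
#' @param baseline_methylation background methylation proportion in [0, 1].
#' @param planted_dmrs data.frame with columns \code{compartment}
#'   (promoter/body/intergenic), \code{direction} (hyper/hypo), \code{delta}
#'   (positive proportion shift) and \code{target_group}; one row per
#'   planted region. See \code{\link{plantedDmrs}}.
#' @param planted_gems data.frame with columns \code{quadrant} (one of
#'   promoter_hypo_over, promoter_hyper_under, body_hyper_over,
#'   body_hypo_under), \code{log2_effect} (positive magnitude) and
#'   \code{target_group}. See \code{\link{plantedGems}}.
#' @param gem_methylation_delta methylation shift planted at GEM regions.
#' @param coverage_mean,coverage_dispersion negative-binomial read depth per
#'   CpG (mean and dispersion = 1/size), floored at 1 read.
#' @param jitter_concentration Beta concentration of the per-sample,
#'   per-region methylation jitter around the group mean; \code{Inf}
#'   disables jitter (pure binomial sampling).
#' @param expression_sd Gaussian noise sd on the log2 expression scale.
#' @param expression_baseline_mean,expression_baseline_sd distribution of
#'   per-gene baseline log2 expression.
#' @param peak_coupling data.frame with columns \code{mark},
#'   \code{dmr_direction} and \code{probability}: each planted region of
#'   that direction receives a qualifying (>50 bp) peak of that mark with
#'   the stated probability.
#' @param background_peaks_per_mark uniformly placed background peaks.
#' @param peak_extension_range bp extension of coupled peaks beyond the
#'   region boundaries.
#' @param background_peak_width_range bp width of background peaks.
#' @return A validated list of class \code{SimulationConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, n_genes = 10, n_intergenic_regions = 20)
#' cohort <- simulateCohort(cfg)
#' cohort$calls
#' @export
simConfig <- function(seed = 1L,
                      n_chromosomes = 2L,
                      chrom_length = 1e6,
                      n_genes = 50L,
                      gene_length_range = c(3000L, 10000L),
                      n_cpg_per_region_range = c(4L, 7L),
                      cpg_spacing_range = c(20L, 30L),
                      n_intergenic_regions = 100L,
                      n_samples_per_group = c(control = 5L, tumor = 5L),
                      baseline_methylation = 0.30,
                      planted_dmrs = plantedDmrs(0),
                      planted_gems = plantedGems(0),
                      gem_methylation_delta = 0.20,
                      coverage_mean = 30,
                      coverage_dispersion = 0.1,
                      jitter_concentration = 300,
                      expression_sd = 0.5,
                      expression_baseline_mean = 8,
                      expression_baseline_sd = 2,
                      peak_coupling = NULL,
                      background_peaks_per_mark = 20L,
                      peak_extension_range = c(60L, 300L),
                      background_peak_width_range = c(500L, 2000L)) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              n_cpg_per_region_range = as.integer(n_cpg_per_region_range),
              cpg_spacing_range = as.integer(cpg_spacing_range),
              n_intergenic_regions = as.integer(n_intergenic_regions),
              n_samples_per_group = n_samples_per_group,
              baseline_methylation = baseline_methylation,
              planted_dmrs = planted_dmrs,
              planted_gems = planted_gems,
              gem_methylation_delta = gem_methylation_delta,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              jitter_concentration = jitter_concentration,
              expression_sd = expression_sd,
              expression_baseline_mean = expression_baseline_mean,
              expression_baseline_sd = expression_baseline_sd,
              peak_coupling = peak_coupling,
              background_peaks_per_mark = as.integer(background_peaks_per_mark),
              peak_extension_range = as.numeric(peak_extension_range),
              background_peak_width_range =
                as.numeric(background_peak_width_range))
  class(cfg) <- "SimulationConfig"
  validateSimConfig(cfg)
  cfg
}

#' Convenience constructor for planted-DMR tables
#'
#' @param n number of planted regions (arguments are recycled to length n).
#' @param compartment,direction,delta,target_group per-region columns.
#' @return data.frame suitable for \code{simConfig(planted_dmrs = )}.
#' @export
plantedDmrs <- function(n, compartment = "intergenic", direction = "hyper",
                        delta = 0.20, target_group = "tumor") {
  if (n == 0L) {
    return(data.frame(compartment = character(), direction = character(),
                      delta = numeric(), target_group = character()))
  }
  data.frame(compartment = rep_len(compartment, n),
             direction = rep_len(direction, n),
             delta = rep_len(delta, n),
             target_group = rep_len(target_group, n))
}

#' Convenience constructor for planted-GEM tables
#'
#' @param n_per_quadrant planted GEMs in each of the four canonical
#'   methylation-expression quadrants.
#' @param log2_effect magnitude of the planted log2 expression shift.
#' @param target_group tumor group carrying the shift.
#' @return data.frame suitable for \code{simConfig(planted_gems = )}.
#' @export
plantedGems <- function(n_per_quadrant, log2_effect = 2, target_group = "tumor") {
  if (n_per_quadrant == 0L) {
    return(data.frame(quadrant = character(), log2_effect = numeric(),
                      target_group = character()))
  }
  data.frame(quadrant = rep(GEM_QUADRANTS, each = n_per_quadrant),
             log2_effect = log2_effect,
             target_group = target_group)
}

#' @noRd
validateSimConfig <- function(cfg) {
  assertScalarNumber(cfg$baseline_methylation, "baseline_methylation", 0, 1)
  assertScalarNumber(cfg$coverage_mean, "coverage_mean", 1)
  assertScalarNumber(cfg$coverage_dispersion, "coverage_dispersion",
                     .Machine$double.eps)
  if (cfg$n_genes < 0L || cfg$n_intergenic_regions < 0L ||
      cfg$n_chromosomes < 1L) {
    stop("counts must be non-negative (>=1 chromosome)", call. = FALSE)
  }
  nspg <- cfg$n_samples_per_group
  if (is.null(names(nspg)) || !"control" %in% names(nspg)) {
    stop("n_samples_per_group must be named and include 'control'",
         call. = FALSE)
  }
  if (any(nspg < 1L)) stop("sample counts must be positive", call. = FALSE)
  pd <- cfg$planted_dmrs
  if (nrow(pd)) {
    if (!all(pd$direction %in% c("hyper", "hypo"))) {
      stop("planted_dmrs$direction must be 'hyper' or 'hypo'", call. = FALSE)
    }
    if (!all(pd$compartment %in% c("promoter", "body", "intergenic"))) {
      stop("unknown planted_dmrs$compartment", call. = FALSE)
    }
    if (any(pd$delta < 0 | pd$delta > 1)) {
      stop("planted_dmrs$delta must be proportions in [0, 1]", call. = FALSE)
    }
    shifted <- cfg$baseline_methylation +
      ifelse(pd$direction == "hyper", pd$delta, -pd$delta)
    if (any(shifted < 0 | shifted > 1)) {
      stop("planted delta pushes methylation probability outside [0, 1]",
           call. = FALSE)
    }
    if (!all(pd$target_group %in% names(nspg))) {
      stop("planted_dmrs$target_group not in n_samples_per_group",
           call. = FALSE)
    }
  }
  pg <- cfg$planted_gems
  if (nrow(pg)) {
    if (!all(pg$quadrant %in% GEM_QUADRANTS)) {
      stop("unknown planted_gems$quadrant", call. = FALSE)
    }
    if (!all(pg$target_group %in% names(nspg))) {
      stop("planted_gems$target_group not in n_samples_per_group",
           call. = FALSE)
    }
    gdir <- ifelse(grepl("hyper", pg$quadrant), 1, -1)
    shifted <- cfg$baseline_methylation + gdir * cfg$gem_methylation_delta
    if (any(shifted < 0 | shifted > 1)) {
      stop("gem_methylation_delta pushes probability outside [0, 1]",
           call. = FALSE)
    }
  }
  pc <- cfg$peak_coupling
  if (!is.null(pc) && nrow(pc)) {
    if (any(pc$probability < 0 | pc$probability > 1)) {
      stop("peak coupling probability outside [0, 1]", call. = FALSE)
    }
    if (!all(pc$dmr_direction %in% c("hyper", "hypo"))) {
      stop("peak_coupling$dmr_direction must be 'hyper' or 'hypo'",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Deterministic sample naming for a configuration
#' @noRd
simSampleNames <- function(cfg) {
  nspg <- cfg$n_samples_per_group
  groups <- rep(names(nspg), nspg)
  ids <- unlist(lapply(nspg, seq_len), use.names = FALSE)
  stats::setNames(groups, sprintf("%s_%d", groups, ids))
}

#' Generate the synthetic genome: gene models and CpG position map
#'
#' Places non-overlapping single-transcript genes on the configured
#' chromosomes, then lays down candidate multi-CpG regions: one in each
#' gene's promoter, one in each gene body, plus intergenic regions placed
#' away from any gene or promoter footprint.  CpG positions are strictly
#' increasing per chromosome and the whole layout is deterministic for a
#' fixed seed.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A list of class \code{SimulatedGenome} with elements
#'   \code{genes} (GRanges, mcols \code{gene_id}), \code{regions}
#'   (candidate-region GRanges, mcols \code{region_id}, \code{compartment},
#'   \code{gene_id}) and \code{cpgs} (width-1 GRanges, mcols
#'   \code{region_id}).
#' @export
generateGenome <- function(config) {
  validateSimConfig(config)
  withSeed(config$seed, {
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    genes <- GenomicRanges::GRanges()
    if (config$n_genes > 0L) {
      per_chrom <- tabulate(rep_len(seq_len(config$n_chromosomes),
                                    config$n_genes),
                            nbins = config$n_chromosomes)
      glist <- vector("list", config$n_chromosomes)
      gi <- 0L
      for (ci in seq_len(config$n_chromosomes)) {
        k <- per_chrom[ci]
        if (k == 0L) next
        lens <- sample(seq(config$gene_length_range[1],
                           config$gene_length_range[2]), k, replace = TRUE)
        # gaps exceed twice the promoter extent, so neighbouring promoter
        # windows (and their CpG clusters) can never collide
        gaps <- sample(11000:16000, k, replace = TRUE)
        starts <- 10000 + cumsum(gaps) + cumsum(c(0, utils::head(lens, -1)))
        ends <- starts + lens - 1
        if (max(ends) > config$chrom_length - 6000) {
          stop(sprintf(paste0("genes do not fit on chromosome %s: layout ",
                              "needs %d bp but chrom_length is %d"),
                       chroms[ci], max(ends) + 6000,
                       as.integer(config$chrom_length)), call. = FALSE)
        }
        strand <- sample(c("+", "-"), k, replace = TRUE)
        glist[[ci]] <- GenomicRanges::GRanges(
          chroms[ci], IRanges::IRanges(starts, ends), strand = strand,
          gene_id = sprintf("gene%04d", gi + seq_len(k)))
        gi <- gi + k
      }
      genes <- suppressWarnings(
        do.call(c, glist[!vapply(glist, is.null, logical(1))]))
    }

    region_chrom <- character()
    region_start <- integer()
    region_comp <- character()
    region_gene <- character()
    placeCluster <- function(lo, hi) {
      # returns a feasible cluster start, or NA
      max_span <- (max(config$n_cpg_per_region_range) - 1L) *
        max(config$cpg_spacing_range)
      room <- hi - max_span - 1L - lo
      if (room < 1L) return(NA_integer_)
      lo + sample.int(room, 1L)
    }
    if (length(genes)) {
      comp <- buildCompartments(genes)
      for (i in seq_along(genes)) {
        pr <- comp$promoter[i]
        bd <- comp$body[i]
        ps <- placeCluster(GenomicRanges::start(pr) + 50L,
                           GenomicRanges::end(pr) - 50L)
        # body clusters sit in the 5' half of the body, where CpG-dense
        # MspI fragments concentrate (first exon / CpG-island shores)
        bs <- if (GenomicRanges::width(bd) > 0) {
          half <- GenomicRanges::width(bd) %/% 2L
          if (as.character(GenomicRanges::strand(genes)[i]) != "-") {
            placeCluster(GenomicRanges::start(bd) + 10L,
                         GenomicRanges::start(bd) + half)
          } else {
            placeCluster(GenomicRanges::end(bd) - half,
                         GenomicRanges::end(bd) - 10L)
          }
        } else NA_integer_
        if (is.na(ps) || is.na(bs)) {
          stop(sprintf(paste0("gene %s too short for candidate regions; ",
                              "increase gene_length_range"),
                       mcols(genes)$gene_id[i]), call. = FALSE)
        }
        region_chrom <- c(region_chrom,
                          rep(as.character(GenomicRanges::seqnames(genes)[i]),
                              2L))
        region_start <- c(region_start, ps, bs)
        region_comp <- c(region_comp, "promoter", "body")
        region_gene <- c(region_gene, rep(mcols(genes)$gene_id[i], 2L))
      }
    }
    if (config$n_intergenic_regions > 0L) {
      # disjoint 1 kb slots guarantee clusters never collide or chain
      # across the maxGap assembly rule; slots touching a gene or its
      # promoter footprint are excluded
      excl <- if (length(genes)) {
        GenomicRanges::reduce(suppressWarnings(GenomicRanges::resize(
          genes, GenomicRanges::width(genes) + 11000L, fix = "center")))
      } else GenomicRanges::GRanges()
      slot_width <- 1000L
      slot_list <- lapply(chroms, function(ch) {
        starts <- seq(501L, as.integer(config$chrom_length) - slot_width,
                      by = slot_width)
        GenomicRanges::GRanges(ch, IRanges::IRanges(starts,
                                                    width = slot_width))
      })
      slots <- suppressWarnings(do.call(c, slot_list))
      if (length(excl)) {
        slots <- slots[!IRanges::overlapsAny(slots, excl)]
      }
      if (length(slots) < config$n_intergenic_regions) {
        stop("could not place intergenic regions; genome too crowded",
             call. = FALSE)
      }
      pick <- sort(sample(seq_along(slots), config$n_intergenic_regions))
      chosen <- slots[pick]
      region_chrom <- c(region_chrom,
                        as.character(GenomicRanges::seqnames(chosen)))
      region_start <- c(region_start, GenomicRanges::start(chosen) + 100L)
      region_comp <- c(region_comp,
                       rep("intergenic", length(chosen)))
      region_gene <- c(region_gene, rep(NA_character_, length(chosen)))
    }

    n_regions <- length(region_start)
    if (n_regions == 0L) {
      return(structure(list(genes = genes,
                            regions = GenomicRanges::GRanges(),
                            cpgs = GenomicRanges::GRanges(),
                            chromosomes = stats::setNames(
                              rep(config$chrom_length, length(chroms)),
                              chroms)),
                       class = "SimulatedGenome"))
    }
    n_cpg <- sample(seq(config$n_cpg_per_region_range[1],
                        config$n_cpg_per_region_range[2]),
                    n_regions, replace = TRUE)
    cpg_pos <- vector("list", n_regions)
    region_end <- integer(n_regions)
    for (r in seq_len(n_regions)) {
      gaps <- sample(seq(config$cpg_spacing_range[1],
                         config$cpg_spacing_range[2]),
                     n_cpg[r] - 1L, replace = TRUE)
      pos <- region_start[r] + c(0L, cumsum(gaps))
      cpg_pos[[r]] <- pos
      region_end[r] <- pos[n_cpg[r]]
    }
    regions <- GenomicRanges::GRanges(
      region_chrom, IRanges::IRanges(region_start, region_end),
      region_id = sprintf("region%05d", seq_len(n_regions)),
      compartment = region_comp, gene_id = region_gene,
      n_cpgs = n_cpg)
    cpgs <- GenomicRanges::GRanges(
      rep(region_chrom, n_cpg),
      IRanges::IRanges(unlist(cpg_pos), width = 1L),
      region_id = rep(mcols(regions)$region_id, n_cpg))
    ord <- order(as.factor(GenomicRanges::seqnames(cpgs)),
                 GenomicRanges::start(cpgs))
    cpgs <- cpgs[ord]
    structure(list(genes = genes, regions = regions, cpgs = cpgs,
                   chromosomes = stats::setNames(
                     rep(config$chrom_length, length(chroms)), chroms)),
              class = "SimulatedGenome")
  })
}

#' Assign planted DMRs and GEMs to candidate regions
#'
#' Draws, deterministically for the configured seed, which candidate regions
#' carry the configured methylation shifts and which genes are planted GEMs,
#' and returns the ground-truth table the recovery tests score against.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param genome result of \code{\link{generateGenome}}.
#' @return A list of class \code{TruthTable} with data.frames
#'   \code{planted_regions} (region_id, chrom, start, end, compartment,
#'   direction, delta on the proportion scale signed by direction,
#'   target_group, gene_id) and \code{planted_gems} (gene_id, quadrant,
#'   log2_effect signed by expression direction, target_group, region_id).
#' @export
plantTruth <- function(config, genome) {
  validateSimConfig(config)
  withSeed(config$seed + 1L, {
    rg <- genome$regions
    used <- logical(length(rg))
    used_genes <- character()
    rows_r <- list()
    rows_g <- list()

    pickRegion <- function(compartment, exclude_genes = character()) {
      idx <- which(!used & mcols(rg)$compartment == compartment &
                     !(mcols(rg)$gene_id %in% exclude_genes))
      if (!length(idx)) {
        stop(sprintf("not enough free candidate regions in compartment '%s'",
                     compartment), call. = FALSE)
      }
      if (length(idx) == 1L) idx else sample(idx, 1L)
    }

    pg <- config$planted_gems
    if (nrow(pg)) {
      if (!length(genome$genes)) {
        stop("planted GEMs require genes in the genome", call. = FALSE)
      }
      for (i in seq_len(nrow(pg))) {
        comp <- if (grepl("^promoter", pg$quadrant[i])) "promoter" else "body"
        meth_dir <- if (grepl("hyper", pg$quadrant[i])) "hyper" else "hypo"
        expr_sign <- if (grepl("over$", pg$quadrant[i])) 1 else -1
        idx <- which(!used & mcols(rg)$compartment == comp &
                       !(mcols(rg)$gene_id %in% used_genes) &
                       !is.na(mcols(rg)$gene_id))
        if (!length(idx)) {
          stop("not enough free genes for planted GEMs", call. = FALSE)
        }
        j <- if (length(idx) == 1L) idx else sample(idx, 1L)
        used[j] <- TRUE
        gene <- mcols(rg)$gene_id[j]
        used_genes <- c(used_genes, gene)
        sdelta <- config$gem_methylation_delta *
          (if (meth_dir == "hyper") 1 else -1)
        rows_r[[length(rows_r) + 1L]] <- data.frame(
          region_id = mcols(rg)$region_id[j],
          chrom = as.character(GenomicRanges::seqnames(rg)[j]),
          start = GenomicRanges::start(rg)[j],
          end = GenomicRanges::end(rg)[j],
          compartment = comp, direction = meth_dir, delta = sdelta,
          target_group = pg$target_group[i], gene_id = gene)
        rows_g[[length(rows_g) + 1L]] <- data.frame(
          gene_id = gene, quadrant = pg$quadrant[i],
          log2_effect = expr_sign * pg$log2_effect[i],
          target_group = pg$target_group[i],
          region_id = mcols(rg)$region_id[j])
      }
    }

    pd <- config$planted_dmrs
    if (nrow(pd)) {
      for (i in seq_len(nrow(pd))) {
        j <- pickRegion(pd$compartment[i], exclude_genes = used_genes)
        used[j] <- TRUE
        sdelta <- pd$delta[i] * (if (pd$direction[i] == "hyper") 1 else -1)
        rows_r[[length(rows_r) + 1L]] <- data.frame(
          region_id = mcols(rg)$region_id[j],
          chrom = as.character(GenomicRanges::seqnames(rg)[j]),
          start = GenomicRanges::start(rg)[j],
          end = GenomicRanges::end(rg)[j],
          compartment = pd$compartment[i], direction = pd$direction[i],
          delta = sdelta, target_group = pd$target_group[i],
          gene_id = mcols(rg)$gene_id[j])
      }
    }

    planted_regions <- if (length(rows_r)) do.call(rbind, rows_r) else
      data.frame(region_id = character(), chrom = character(),
                 start = integer(), end = integer(),
                 compartment = character(), direction = character(),
                 delta = numeric(), target_group = character(),
                 gene_id = character())
    planted_gems <- if (length(rows_g)) do.call(rbind, rows_g) else
      data.frame(gene_id = character(), quadrant = character(),
                 log2_effect = numeric(), target_group = character(),
                 region_id = character())
    if (anyDuplicated(planted_regions$region_id)) {
      stop("internal error: duplicate planted region ids", call. = FALSE)
    }
    structure(list(planted_regions = planted_regions,
                   planted_gems = planted_gems,
                   peak_couplings = data.frame(mark = character(),
                                               region_id = character())),
              class = "TruthTable")
  })
}

#' Simulate per-CpG bisulfite calls for the whole cohort
#'
#' Per CpG and sample, total read count is negative-binomial (configured
#' mean and dispersion, floored at one read) and the methylated count is
#' binomial.  The success probability is the baseline methylation level,
#' shifted by the planted signed delta inside planted regions for samples
#' of the target group, with optional Beta-distributed per-sample,
#' per-region jitter around the group mean.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param genome result of \code{\link{generateGenome}}.
#' @param truth result of \code{\link{plantTruth}}.
#' @return A \linkS4class{MethylCallSet}.
#' @export
generateMethylation <- function(config, genome, truth) {
  validateSimConfig(config)
  groups <- simSampleNames(config)
  samples <- names(groups)
  n_cpg <- length(genome$cpgs)
  region_ids <- mcols(genome$regions)$region_id
  cpg_region <- match(mcols(genome$cpgs)$region_id, region_ids)
  n_regions <- length(region_ids)

  # region x sample matrix of true group-level proportions
  p_group <- matrix(config$baseline_methylation, n_regions, length(samples),
                    dimnames = list(region_ids, samples))
  tr <- truth$planted_regions
  if (nrow(tr)) {
    ri <- match(tr$region_id, region_ids)
    if (anyNA(ri)) {
      stop("truth references region ids absent from the genome",
           call. = FALSE)
    }
    for (k in seq_len(nrow(tr))) {
      tgt <- groups == tr$target_group[k]
      p_group[ri[k], tgt] <- p_group[ri[k], tgt] + tr$delta[k]
    }
  }
  if (any(p_group < 0 | p_group > 1)) {
    stop("planted delta pushes methylation probability outside [0, 1]",
         call. = FALSE)
  }

  withSeed(config$seed + 2L, {
    # per-sample Beta jitter around the group-level proportion
    p_sample <- p_group
    conc <- config$jitter_concentration
    if (is.finite(conc)) {
      inner <- p_group > 0 & p_group < 1
      p_sample[inner] <- stats::rbeta(sum(inner),
                                      conc * p_group[inner],
                                      conc * (1 - p_group[inner]))
    }
    size <- 1 / config$coverage_dispersion
    meth <- tot <- matrix(0L, n_cpg, length(samples),
                          dimnames = list(NULL, samples))
    for (s in seq_along(samples)) {
      totals <- as.integer(pmax(1, stats::rnbinom(n_cpg,
                                                  mu = config$coverage_mean,
                                                  size = size)))
      prob <- p_sample[cpg_region, s]
      meth[, s] <- stats::rbinom(n_cpg, totals, prob)
      tot[, s] <- totals
    }
    MethylCallSet(chrom = as.character(GenomicRanges::seqnames(genome$cpgs)),
                  pos = GenomicRanges::start(genome$cpgs),
                  methylated = meth, total = tot, sampleGroups = groups)
  })
}

#' Simulate the log2 expression matrix
#'
#' Planted GEM genes carry a group log2 shift equal to the signed planted
#' effect (promoter-hypo and body-hyper GEMs are overexpressed,
#' promoter-hyper and body-hypo GEMs under-expressed) plus Gaussian noise;
#' all other genes have zero expected group difference.
#'
#' @inheritParams generateMethylation
#' @return Numeric matrix, genes x samples, log2 scale.
#' @export
generateExpression <- function(config, genome, truth) {
  validateSimConfig(config)
  groups <- simSampleNames(config)
  samples <- names(groups)
  gene_ids <- if (length(genome$genes)) mcols(genome$genes)$gene_id else
    character()
  tg <- truth$planted_gems
  if (nrow(tg) && !all(tg$gene_id %in% gene_ids)) {
    stop("planted GEM references a gene absent from the genome",
         call. = FALSE)
  }
  withSeed(config$seed + 3L, {
    base <- stats::rnorm(length(gene_ids), config$expression_baseline_mean,
                         config$expression_baseline_sd)
    expr <- matrix(rep(base, length(samples)), ncol = length(samples),
                   dimnames = list(gene_ids, samples))
    if (nrow(tg)) {
      gi <- match(tg$gene_id, gene_ids)
      for (k in seq_len(nrow(tg))) {
        tgt <- groups == tg$target_group[k]
        expr[gi[k], tgt] <- expr[gi[k], tgt] + tg$log2_effect[k]
      }
    }
    expr + matrix(stats::rnorm(length(expr), 0, config$expression_sd),
                  nrow = nrow(expr), ncol = ncol(expr))
  })
}

#' Simulate chromatin interval sets coupled to planted regions
#'
#' For every configured (mark, direction, probability) coupling, each
#' planted region of that direction receives, with the stated probability,
#' a peak that fully covers it (so the overlap is the region width, by
#' construction >50 bp).  Background peaks are placed uniformly.
#'
#' @inheritParams generateMethylation
#' @return list with \code{peaks} (named list of GRanges per mark) and
#'   \code{couplings} (data.frame mark, region_id of realized couplings).
#' @export
generatePeaks <- function(config, genome, truth) {
  validateSimConfig(config)
  pc <- config$peak_coupling
  if (is.null(pc) || !nrow(pc)) {
    return(list(peaks = list(),
                couplings = data.frame(mark = character(),
                                       region_id = character())))
  }
  chrom_len <- genome$chromosomes
  tr <- truth$planted_regions
  withSeed(config$seed + 4L, {
    peaks <- list()
    coup <- list()
    for (mark in unique(pc$mark)) {
      gr_list <- list()
      for (i in which(pc$mark == mark)) {
        cand <- tr[tr$direction == pc$dmr_direction[i], , drop = FALSE]
        if (nrow(cand)) {
          hit <- stats::runif(nrow(cand)) < pc$probability[i]
          if (any(hit)) {
            cand <- cand[hit, , drop = FALSE]
            ext1 <- sample(seq(config$peak_extension_range[1],
                               config$peak_extension_range[2]),
                           nrow(cand), replace = TRUE)
            ext2 <- sample(seq(config$peak_extension_range[1],
                               config$peak_extension_range[2]),
                           nrow(cand), replace = TRUE)
            st <- pmax(1L, cand$start - ext1)
            en <- pmin(as.integer(chrom_len[cand$chrom]), cand$end + ext2)
            gr_list[[length(gr_list) + 1L]] <-
              GenomicRanges::GRanges(cand$chrom, IRanges::IRanges(st, en))
            coup[[length(coup) + 1L]] <-
              data.frame(mark = mark, region_id = cand$region_id)
          }
        }
      }
      nbg <- config$background_peaks_per_mark
      if (nbg > 0L) {
        bw <- sample(seq(config$background_peak_width_range[1],
                         config$background_peak_width_range[2]),
                     nbg, replace = TRUE)
        bchrom <- sample(names(chrom_len), nbg, replace = TRUE)
        bst <- vapply(seq_len(nbg), function(j) {
          sample.int(as.integer(chrom_len[bchrom[j]] - bw[j] - 1L), 1L)
        }, integer(1))
        gr_list[[length(gr_list) + 1L]] <-
          GenomicRanges::GRanges(bchrom, IRanges::IRanges(bst,
                                                          width = bw))
      }
      gr <- if (length(gr_list)) suppressWarnings(do.call(c, gr_list)) else
        GenomicRanges::GRanges()
      # lexicographic order matches what readBed() restores
      gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr), GenomicRanges::end(gr))]
      peaks[[mark]] <- gr
    }
    couplings <- if (length(coup)) do.call(rbind, coup) else
      data.frame(mark = character(), region_id = character())
    list(peaks = peaks, couplings = couplings)
  })
}

#' Simulate a complete cohort
#'
#' Runs \code{\link{generateGenome}}, \code{\link{plantTruth}},
#' \code{\link{generateMethylation}}, \code{\link{generateExpression}} and
#' \code{\link{generatePeaks}} under one configuration.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return list of class \code{SimulatedCohort} with elements \code{config},
#'   \code{genome}, \code{truth} (including realized peak couplings),
#'   \code{calls}, \code{expression} and \code{peaks}.
#' @export
simulateCohort <- function(config) {
  genome <- generateGenome(config)
  truth <- plantTruth(config, genome)
  calls <- generateMethylation(config, genome, truth)
  expr <- generateExpression(config, genome, truth)
  pk <- generatePeaks(config, genome, truth)
  truth$peak_couplings <- pk$couplings
  structure(list(config = config, genome = genome, truth = truth,
                 calls = calls, expression = expr, peaks = pk$peaks),
            class = "SimulatedCohort")
}

#' Write a simulated cohort to disk in the pipeline's external formats
#'
#' Emits Bismark-coverage-style TSVs (one per sample), a refFlat gene-model
#' file, a log2 expression TSV, a sample-group map, BED files per chromatin
#' mark, and plain-text truth tables.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the character vector of files written.
#' @export
writeSimulation <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  calls <- cohort$calls
  covdir <- file.path(dir, "coverage")
  dir.create(covdir, showWarnings = FALSE)
  for (s in colnames(calls)) {
    f <- file.path(covdir, paste0(s, ".cov"))
    writeBismarkCoverage(calls, s, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "samples.tsv")
  writeSampleGroups(sampleGroups(calls), f)
  files <- c(files, f)
  if (length(cohort$genome$genes)) {
    f <- file.path(dir, "genes.refflat")
    writeGeneModels(cohort$genome$genes, f)
    files <- c(files, f)
  }
  if (nrow(cohort$expression)) {
    f <- file.path(dir, "expression.tsv")
    writeExpressionMatrix(cohort$expression, f)
    files <- c(files, f)
  }
  for (mark in names(cohort$peaks)) {
    f <- file.path(dir, paste0("peaks_", mark, ".bed"))
    writeBed(cohort$peaks[[mark]], f)
    files <- c(files, f)
  }
  tr <- cohort$truth
  f <- file.path(dir, "truth_regions.tsv")
  utils::write.table(tr$planted_regions, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth_gems.tsv")
  utils::write.table(tr$planted_gems, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  if (nrow(tr$peak_couplings)) {
    f <- file.path(dir, "truth_peaks.tsv")
    utils::write.table(tr$peak_couplings, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
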