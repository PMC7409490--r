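# Readers and writers for the external formats the pipeline touches:
# Bismark-style coverage TSV, BED3+, refFlat gene models, expression TSV,
# array beta tables and sample-group maps.  All readers validate and fail
# with file/line context rather than silently coercing; all paths are
# gzip-transparent (".gz" suffix).  BED files are 0-based half-open on disk
# and converted to the GRanges 1-based closed convention on ingest.

#' Read a Bismark-style coverage file for one sample
#'
#' Expects the six-column format \code{chrom, start(1-based), end,
#' methylation_percent, count_methylated, count_unmethylated}.  The
#' percentage column is ignored in favor of the counts.
#'
#' @param path file path (may be gzip-compressed).
#' @param sample sample id attached to the result.
#' @return data.frame with columns \code{chrom}, \code{pos},
#'   \code{methylated}, \code{total} and attribute \code{sample}.
#' @export
readBismarkCoverage <- function(path, sample) {
  con <- openInput(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      methylated = integer(), total = integer())
    attr(out, "sample") <- sample
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1]
    parseError(path, bad,
               sprintf("expected 6 tab-separated columns, found %d", nf[bad]))
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 5]))
  unmeth <- suppressWarnings(as.integer(m[, 6]))
  for (col in list(list(v = pos, what = "position", raw = m[, 2]),
                   list(v = meth, what = "methylated count", raw = m[, 5]),
                   list(v = unmeth, what = "unmethylated count",
                        raw = m[, 6]))) {
    if (anyNA(col$v)) {
      bad <- which(is.na(col$v))[1]
      parseError(path, bad, sprintf("non-integer %s '%s'", col$what,
                                    col$raw[bad]))
    }
  }
  if (any(meth < 0L | unmeth < 0L)) {
    bad <- which(meth < 0L | unmeth < 0L)[1]
    parseError(path, bad, "negative read count")
  }
  out <- data.frame(chrom = m[, 1], pos = pos, methylated = meth,
                    total = meth + unmeth)
  attr(out, "sample") <- sample
  out
}

#' Write one sample of a call set as a Bismark-style coverage file
#'
#' @param calls a \linkS4class{MethylCallSet}.
#' @param sample sample id (a column of \code{calls}).
#' @param path output path (".gz" compresses). CpGs with zero coverage in
#'   this sample are omitted, as a real coverage file has no such rows.
#' @export
writeBismarkCoverage <- function(calls, sample, path) {
  m <- methReads(calls)[, sample]
  tot <- totalReads(calls)[, sample]
  keep <- tot > 0L
  gr <- rowRanges(calls)[keep]
  m <- m[keep]
  tot <- tot[keep]
  pct <- formatC(100 * m / tot, format = "f", digits = 6)
  con <- openOutput(path)
  on.exit(close(con))
  writeLines(paste(as.character(seqnames(gr)), start(gr), start(gr), pct,
                   m, tot - m, sep = "\t"), con)
  invisible(path)
}

#' Assemble a MethylCallSet from per-sample coverage files
#'
#' CpG sites are the union over samples; a site absent from a sample gets
#' zero counts there (and is later removed by the coverage filter).
#'
#' @param paths named character vector, sample id -> coverage file path.
#' @param sampleGroups named character vector, sample id -> group label.
#' @return A \linkS4class{MethylCallSet}.
#' @export
readMethylCallSet <- function(paths, sampleGroups) {
  if (is.null(names(paths))) stop("'paths' must be named by sample id")
  tabs <- lapply(names(paths), function(s) readBismarkCoverage(paths[[s]], s))
  names(tabs) <- names(paths)
  key <- unique(do.call(rbind, lapply(tabs, function(t) t[c("chrom", "pos")])))
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  id <- paste(key$chrom, key$pos)
  n <- nrow(key)
  meth <- tot <- matrix(0L, n, length(paths),
                        dimnames = list(NULL, names(paths)))
  for (s in names(paths)) {
    t <- tabs[[s]]
    i <- match(paste(t$chrom, t$pos), id)
    meth[i, s] <- t$methylated
    tot[i, s] <- t$total
  }
  MethylCallSet(chrom = key$chrom, pos = key$pos, methylated = meth,
                total = tot, sampleGroups = sampleGroups)
}

#' Read a BED file of chromatin intervals
#'
#' @param path BED3+ file, 0-based half-open; extra columns are ignored.
#' @param mark label attached to the set (e.g. "H3K27me3", "SE", "CTCF").
#' @return A sorted \code{GRanges} (1-based closed) with
#'   \code{metadata(x)$mark} set.
#' @export
readBed <- function(path, mark = NA_character_) {
  con <- openInput(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$mark <- mark
    return(gr)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1]
    parseError(path, bad, "BED needs at least 3 columns")
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  s0 <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
  if (anyNA(s0) || anyNA(e0)) {
    bad <- which(is.na(s0) | is.na(e0))[1]
    parseError(path, bad, "non-numeric BED coordinates")
  }
  if (any(s0 >= e0)) {
    bad <- which(s0 >= e0)[1]
    parseError(path, bad,
               sprintf("start (%d) must be < end (%d)", s0[bad], e0[bad]))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0))
  gr <- gr[order(chrom, s0, e0)]
  S4Vectors::metadata(gr)$mark <- mark
  gr
}

#' Write a GRanges as BED3
#' @param gr a \code{GRanges} (1-based closed; written 0-based half-open).
#' @param path output path (".gz" compresses).
#' @export
writeBed <- function(gr, path) {
  con <- openOutput(path)
  on.exit(close(con))
  if (length(gr)) {
    writeLines(paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read refFlat-style gene models
#'
#' Expects columns \code{gene_id, chrom, strand, txStart, txEnd} with
#' txStart/txEnd 0-based half-open as in the refFlat standard; one
#' pre-collapsed transcript per gene (multi-isoform input is rejected as a
#' duplicate gene id).
#'
#' @param path file path.
#' @return \code{GRanges} (1-based closed) with mcols \code{gene_id}; the
#'   TSS is the start for + genes and the end for - genes (see
#'   \code{\link{tssOf}}).
#' @export
readGeneModels <- function(path) {
  con <- openInput(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) return(GenomicRanges::GRanges(gene_id = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5L)) {
    bad <- which(nf < 5L)[1]
    parseError(path, bad, "refFlat needs gene, chrom, strand, txStart, txEnd")
  }
  gene <- vapply(parts, `[`, character(1), 1L)
  chrom <- vapply(parts, `[`, character(1), 2L)
  strand <- vapply(parts, `[`, character(1), 3L)
  s0 <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 4L)))
  e0 <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 5L)))
  if (any(!strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1]
    parseError(path, bad, sprintf("unknown strand symbol '%s'", strand[bad]))
  }
  if (anyNA(s0) || anyNA(e0) || any(s0 >= e0)) {
    bad <- which(is.na(s0) | is.na(e0) | s0 >= e0)[1]
    parseError(path, bad, "invalid txStart/txEnd")
  }
  if (anyDuplicated(gene)) {
    dup <- gene[duplicated(gene)][1]
    stop(sprintf("%s: duplicate gene_id '%s' (one transcript per gene)",
                 path, dup), call. = FALSE)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0),
                         strand = strand, gene_id = gene)
}

#' Write gene models as refFlat-style TSV
#' @param genes \code{GRanges} with mcols \code{gene_id}.
#' @param path output path.
#' @export
writeGeneModels <- function(genes, path) {
  con <- openOutput(path)
  on.exit(close(con))
  if (length(genes)) {
    writeLines(paste(mcols(genes)$gene_id, as.character(seqnames(genes)),
                     as.character(strand(genes)), start(genes) - 1L,
                     end(genes), sep = "\t"), con)
  }
  invisible(path)
}

#' Strand-aware transcription start sites
#'
#' @param genes \code{GRanges} of gene models.
#' @return Integer vector of 1-based TSS positions (start for +, end for -).
#' @export
tssOf <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' Read a log2 expression matrix (genes x samples TSV, header = samples)
#' @param path file path.
#' @return numeric matrix with gene ids as rownames.
#' @export
readExpressionMatrix <- function(path) {
  con <- openInput(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric expression values", path),
                           call. = FALSE)
  if (any(!is.finite(m))) {
    stop(sprintf("%s: non-finite expression values", path), call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop(sprintf("%s: duplicate gene ids", path), call. = FALSE)
  }
  m
}

#' Write a log2 expression matrix
#' @param m numeric matrix, genes x samples.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(m, path) {
  con <- openOutput(path)
  on.exit(close(con))
  utils::write.table(data.frame(gene_id = rownames(m), m,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an array-style beta-value table
#'
#' Expects a header line \code{probe, chrom, pos, <sample...>} with beta
#' values in [0, 1].
#'
#' @param path file path.
#' @return list with \code{probes} (data.frame probe, chrom, pos) and
#'   \code{beta} (numeric matrix probes x samples, rownames = probe ids).
#' @export
readBetaTable <- function(path) {
  con <- openInput(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) {
    stop(sprintf("%s: beta table needs probe, chrom, pos + >=1 sample", path),
         call. = FALSE)
  }
  if (anyDuplicated(df[[1]])) {
    stop(sprintf("%s: duplicate probe id '%s'", path,
                 df[[1]][duplicated(df[[1]])][1]), call. = FALSE)
  }
  beta <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(beta) <- df[[1]]
  if (!is.numeric(beta) || any(is.na(beta)) ||
      any(beta < 0 | beta > 1)) {
    stop(sprintf("%s: beta values must be numeric in [0, 1]", path),
         call. = FALSE)
  }
  list(probes = data.frame(probe = df[[1]], chrom = df[[2]],
                           pos = as.integer(df[[3]])),
       beta = beta)
}

#' Write a beta-value table
#' @param betas list as returned by \code{\link{readBetaTable}}.
#' @param path output path.
#' @export
writeBetaTable <- function(betas, path) {
  con <- openOutput(path)
  on.exit(close(con))
  df <- data.frame(probe = betas$probes$probe, chrom = betas$probes$chrom,
                   pos = betas$probes$pos, betas$beta, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-group map (two-column TSV: sample, group)
#' @param path file path.
#' @return named character vector sample -> group.
#' @export
readSampleGroups <- function(path) {
  con <- openInput(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(df))) {
    stop(sprintf("%s: needs columns 'sample' and 'group'", path),
         call. = FALSE)
  }
  stats::setNames(df$group, df$sample)
}

#' Write a sample-group map
#' @param groups named character vector sample -> group.
#' @param path output path.
#' @export
writeSampleGroups <- function(groups, path) {
  con <- openOutput(path)
  on.exit(close(con))
  utils::write.table(data.frame(sample = names(groups),
                                group = unname(groups)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
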