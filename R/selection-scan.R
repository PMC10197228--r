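#' Composite selection score
#'
#' Each statistic column is converted to fractional ranks `rank/(n+1)`
#' (average ranks on ties, missing windows excluded from rank fractions),
#' probit-transformed to z scores, and averaged across statistics. The mean
#' z is rescaled by `sqrt(k)` so that the null reference is standard normal;
#' `p = 1 - pnorm(zbar * sqrt(k))` and `CSS = -log10(p)`. Columns must be
#' oriented so that larger values mean stronger selection (pass absolute
#' omega/Rsb).
#'
#' @param stats data.frame (or `GRanges` mcols) holding the statistic columns
#' @param statistics column names to combine
#' @return data.frame with per-statistic fractional ranks and z, `meanZ`,
#'   `p`, `css` (NA for windows missing any statistic)
#' @export
cssScore <- function(stats, statistics = c("fst", "absOmega", "absRsb")) {
  if (inherits(stats, "GRanges")) stats <- as.data.frame(mcols(stats))
  .assert(all(statistics %in% names(stats)),
          "missing statistic columns: ",
          paste(setdiff(statistics, names(stats)), collapse = ", "))
  x <- stats[, statistics, drop = FALSE]
  complete <- complete.cases(x)
  .assert(sum(complete) >= 10,
          "need at least 10 windows with all statistics non-missing")
  k <- length(statistics)
  out <- data.frame(row.names = seq_len(nrow(x)))
  zs <- matrix(NA_real_, nrow(x), k)
  for (i in seq_len(k)) {
    col <- x[[i]]
    if (length(unique(col[complete])) == 1L)
      warning("statistic '", statistics[i], "' is constant; all ranks tied")
    r <- rep(NA_real_, nrow(x))
    r[complete] <- rank(col[complete], ties.method = "average") /
      (sum(complete) + 1)
    zs[, i] <- qnorm(r)
    out[[paste0("rank_", statistics[i])]] <- r
    out[[paste0("z_", statistics[i])]] <- zs[, i]
  }
  meanZ <- rowMeans(zs)
  p <- 1 - pnorm(meanZ * sqrt(k))
  out$meanZ <- meanZ
  out$p <- p
  out$css <- -log10(p)
  out
}

#' Call positively selected regions from windowed statistics
#'
#' A window qualifies when its FST is at or above the `percentile` quantile
#' and both `|omega|` and `|Rsb|` are at or above the same quantile of their
#' absolute values (quantiles taken genome-wide over non-missing windows).
#' Qualifying windows are assigned to the A side when `omega < 0` and
#' `rsb > 0` (diversity reduced and haplotypes extended in population A) and
#' to the B side for the opposite signs; windows with discordant signs are
#' discarded and counted. Overlapping or abutting windows of the same side
#' are merged into maximal regions.
#'
#' @param win `GRanges` from [windowStats()] with mcols `fst`, `omega`,
#'   `rsbMean`
#' @param percentile quantile cut (default 0.95)
#' @param maxGap merge windows separated by at most this many bp (default 0,
#'   i.e. only overlapping/abutting windows merge)
#' @return list with `A` and `B` (`GRanges` of regions with mcols `nWindows`,
#'   `meanFst`, `meanOmega`, `meanRsb`), `discordant` (window count) and
#'   `cutoffs`
#' @export
callPsrs <- function(win, percentile = 0.95, maxGap = 0L) {
  .assert(length(win) >= 20, "fewer than 20 windows; percentile rule unstable")
  fst <- mcols(win)$fst
  om <- mcols(win)$omega
  rsb <- mcols(win)$rsbMean
  qf <- quantile(fst, percentile, na.rm = TRUE, names = FALSE)
  qo <- quantile(abs(om), percentile, na.rm = TRUE, names = FALSE)
  qr <- quantile(abs(rsb), percentile, na.rm = TRUE, names = FALSE)
  qual <- !is.na(fst) & !is.na(om) & !is.na(rsb) &
    fst >= qf & abs(om) >= qo & abs(rsb) >= qr
  sideA <- qual & om < 0 & rsb > 0
  sideB <- qual & om > 0 & rsb < 0
  nDisc <- sum(qual & !sideA & !sideB)
  mergeSide <- function(sel) {
    if (!any(sel)) return(GRanges())
    reg <- GenomicRanges::reduce(win[sel], min.gapwidth = maxGap + 1L)
    ov <- GenomicRanges::findOverlaps(win[sel], reg)
    sh <- S4Vectors::subjectHits(ov); qh <- S4Vectors::queryHits(ov)
    mcols(reg)$nWindows <- as.integer(table(factor(sh, seq_along(reg))))
    mcols(reg)$meanFst <- as.numeric(tapply(fst[sel][qh], sh, mean))
    mcols(reg)$meanOmega <- as.numeric(tapply(om[sel][qh], sh, mean))
    mcols(reg)$meanRsb <- as.numeric(tapply(rsb[sel][qh], sh, mean))
    reg
  }
  list(A = mergeSide(sideA), B = mergeSide(sideB), discordant = nDisc,
       cutoffs = c(fst = qf, absOmega = qo, absRsb = qr))
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene` features only.
#'
#' @param path GFF3 file
#' @return `GRanges` with mcol `gene_id`
#' @export
readGeneModels <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[g$type == "gene"]
  id <- if (!is.null(g$ID)) g$ID else g$gene_id
  out <- GRanges(seqnames(g), ranges(g), strand = GenomicRanges::strand(g))
  mcols(out)$gene_id <- as.character(id)
  out
}

#' Positively selected genes: genes overlapping any region
#'
#' A gene qualifies when its body intersects a region by at least 1 bp
#' (1-based inclusive coordinates on both sides).
#'
#' @param regions `GRanges` of selected regions
#' @param genes `GRanges` with mcol `gene_id` (see [readGeneModels()])
#' @return character vector of gene ids
#' @export
callPsgs <- function(regions, genes) {
  if (length(regions) == 0L || length(genes) == 0L) return(character())
  hit <- IRanges::overlapsAny(genes, regions, minoverlap = 1L)
  unique(mcols(genes)$gene_id[hit])
}

#' Distance from SNPs to the nearest selected region
#'
#' 0 when the SNP lies inside a region, otherwise the base-pair gap to the
#' closest region boundary on the same chromosome (a SNP 1 bp left of a
#' region start has distance 1); NA when the chromosome carries no region.
#'
#' @param snps `GRanges` of SNP positions (width 1)
#' @param regions `GRanges` of regions
#' @return numeric vector of distances (bp)
#' @export
snpRegionDistance <- function(snps, regions) {
  out <- rep(NA_real_, length(snps))
  chS <- as.character(seqnames(snps))
  chR <- as.character(seqnames(regions))
  for (c1 in unique(chS)) {
    ri <- which(chR == c1)
    if (!length(ri)) next
    si <- which(chS == c1)
    s <- start(regions)[ri]; e <- end(regions)[ri]
    for (ii in si) {
      p <- start(snps)[ii]
      inside <- any(p >= s & p <= e)
      out[ii] <- if (inside) 0 else min(pmin(abs(s - p), abs(p - e)))
    }
  }
  out
}

#' Contrast selection-strength statistics between A-side and B-side regions
#'
#' One-way ANOVA comparing, across windows inside A-side vs B-side regions,
#' the composite selection score, FST, absolute omega, absolute Rsb and
#' Tajima's D in the region's target population.
#'
#' @param win `GRanges` from [windowStats()]
#' @param regionsA,regionsB region `GRanges` from [callPsrs()]
#' @param css optional per-window CSS vector (computed via [cssScore()] when
#'   omitted)
#' @return data.frame with `statistic`, `meanA`, `meanB`, `F`, `p`
#' @export
comparePsrStrength <- function(win, regionsA, regionsB, css = NULL) {
  inA <- IRanges::overlapsAny(win, regionsA)
  inB <- IRanges::overlapsAny(win, regionsB) & !inA
  .assert(sum(inA) >= 2 && sum(inB) >= 2,
          "need at least 2 windows inside each region set")
  if (is.null(css)) {
    df <- as.data.frame(mcols(win))
    df$absOmega <- abs(df$omega); df$absRsb <- abs(df$rsbMean)
    css <- cssScore(df)$css
  }
  m <- mcols(win)
  vals <- list(css = css, fst = m$fst, absOmega = abs(m$omega),
               absRsb = abs(m$rsbMean),
               tajd = ifelse(inA, m$tajdA, m$tajdB))
  grp <- factor(ifelse(inA, "A", ifelse(inB, "B", NA)))
  out <- lapply(names(vals), function(nm) {
    y <- vals[[nm]][!is.na(grp)]
    g <- grp[!is.na(grp)]
    ok <- !is.na(y)
    if (length(unique(y[ok])) < 2L) {
      warning("statistic '", nm, "' constant; ANOVA undefined")
      return(data.frame(statistic = nm, meanA = NA, meanB = NA,
                        F = NA_real_, p = NA_real_))
    }
    fit <- aov(y[ok] ~ g[ok])
    sm <- summary(fit)[[1]]
    data.frame(statistic = nm,
               meanA = mean(y[ok][g[ok] == "A"]),
               meanB = mean(y[ok][g[ok] == "B"]),
               F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1])
  })
  do.call(rbind, out)
}

#' Export regions as BED (0-based half-open) and TSV (1-based inclusive)
#'
#' @param regions `GRanges`
#' @param bedPath,tsvPath output paths (either may be NULL)
#' @export
writeRegions <- function(regions, bedPath = NULL, tsvPath = NULL) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions), end = end(regions),
                   as.data.frame(mcols(regions)))
  if (!is.null(bedPath)) {
    bed <- df
    bed$start <- bed$start - 1L
    write.table(bed, bedPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsvPath))
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
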