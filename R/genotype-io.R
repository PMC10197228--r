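#' Read a sample-to-population map
#'
#' TSV with header columns `sample`, `site`, `population`.
#'
#' @param path file path
#' @return data.frame with those three columns
#' @export
readPopMap <- function(path) {
  pm <- read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("sample", "site", "population") %in% names(pm)),
          "population map needs columns sample, site, population: ", path)
  pm$sample <- as.character(pm$sample)
  pm
}

#' Read genotypes from a VCF into a HaplotypeSet
#'
#' Biallelic SNP records are kept; multiallelic or non-SNP records are
#' skipped with a warning (the number skipped is stored in the object's
#' `skipped` attribute). Phased GT fields (`0|1`) are split into two
#' haplotype rows per sample; unphased (`0/1`) input is accepted but the
#' object is flagged unphased and haplotype-based statistics will refuse it.
#'
#' @param path VCF file (v4.x, plain text or bgzipped)
#' @param popMap data.frame from [readPopMap()]; every VCF sample must appear
#' @param verbose log record counts
#' @return a [HaplotypeSet-class]
#' @export
readVcfGenotypes <- function(path, popMap, verbose = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("empty VCF: ", path)
  fix <- v@fix
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  missing <- setdiff(samples, popMap$sample)
  if (length(missing))
    stop("samples absent from population map: ", paste(missing, collapse = ", "))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  nSkip <- sum(!keep)
  if (nSkip > 0)
    warning(nSkip, " multiallelic/non-SNP record(s) skipped")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic SNP records in VCF: ", path)

  # GT is the first colon-separated field
  gtOnly <- sub(":.*$", "", gt[, -1L, drop = FALSE])
  a1 <- substr(gtOnly, 1L, 1L)
  sep <- substr(gtOnly, 2L, 2L)
  a2 <- substr(gtOnly, 3L, 3L)
  toInt <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out[!(a %in% c("0", "1"))] <- NA_integer_
    out
  }
  m1 <- matrix(toInt(a1), nrow = nrow(gtOnly))
  m2 <- matrix(toInt(a2), nrow = nrow(gtOnly))
  phased <- all(sep[!is.na(m1)] == "|")

  L <- nrow(fix); N <- length(samples)
  al <- matrix(NA_integer_, nrow = 2L * N, ncol = L)
  al[seq(1L, 2L * N, by = 2L), ] <- t(m1)
  al[seq(2L, 2L * N, by = 2L), ] <- t(m2)

  variants <- GRanges(fix[, "CHROM"],
                      IRanges(as.integer(fix[, "POS"]), width = 1L),
                      ref = ref[keep], alt = alt[keep],
                      id = fix[, "ID"])
  hap <- HaplotypeSet(al, variants, samples, phased,
                      popMap[match(samples, popMap$sample), , drop = FALSE])
  attr(hap, "skipped") <- nSkip
  .msg(verbose, "read ", L, " SNPs x ", N, " samples (skipped ", nSkip, ")")
  hap
}

#' Write a HaplotypeSet back to a plain-text VCF
#'
#' Round-trips the GT fields of biallelic records written by
#' [readVcfGenotypes()] or the synthetic-data generator.
#'
#' @param hap a [HaplotypeSet-class]
#' @param path output path
#' @export
writeVcfGenotypes <- function(hap, path) {
  v <- variants(hap)
  al <- alleles(hap)
  sep <- if (isPhased(hap)) "|" else "/"
  a <- matrix(as.character(al), nrow = nrow(al))
  a[is.na(a)] <- "."
  odd <- a[seq(1L, nrow(a), by = 2L), , drop = FALSE]
  evn <- a[seq(2L, nrow(a), by = 2L), , drop = FALSE]
  gt <- matrix(paste0(odd, sep, evn), nrow = nrow(odd))  # N x L
  id <- if (!is.null(mcols(v)$id)) mcols(v)$id else rep(".", length(v))
  id[is.na(id)] <- "."
  body <- cbind(as.character(seqnames(v)), start(v), id,
                mcols(v)$ref, mcols(v)$alt, ".", "PASS", ".", "GT", t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds(hap)), collapse = "\t")), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

# r^2 between two dosage vectors; monomorphic or degenerate -> 0
.r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(0)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(0)
  cor(x, y)^2
}

#' LD pruning of SNPs in sliding windows
#'
#' Greedy window-based pruning on genotype dosages: within each window of
#' `windowSnps` SNPs (advanced by `stepSnps`), for any pair with
#' `r^2 > r2Max` the later-position SNP is removed. Passes repeat until no
#' SNP is removed, which makes the operation idempotent. Monomorphic SNPs
#' have undefined r^2, treated as 0 (never pruned for LD). Defaults mirror a
#' `--indep-pairwise 5 1 0.9` setting. Apply per population and intersect
#' (see [prunedIntersection()]) when a single set is wanted for structure
#' analyses.
#'
#' @param hap a [HaplotypeSet-class] (subset to one population for
#'   per-population pruning)
#' @param windowSnps window width in SNP count
#' @param stepSnps window step in SNP count
#' @param r2Max maximum squared correlation tolerated within a window
#' @return sorted integer vector of retained SNP indices
#' @export
ldPrune <- function(hap, windowSnps = 5L, stepSnps = 1L, r2Max = 0.9) {
  dos <- .dosage(alleles(hap))
  L <- ncol(dos)
  keep <- rep(TRUE, L)
  repeat {
    removed <- FALSE
    idx <- which(keep)
    if (length(idx) < 2L) break
    starts <- seq(1L, max(1L, length(idx) - 1L), by = stepSnps)
    for (s in starts) {
      win <- idx[s:min(s + windowSnps - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      for (ii in seq_len(length(win) - 1L)) {
        i <- win[ii]
        if (!keep[i]) next
        for (jj in (ii + 1L):length(win)) {
          j <- win[jj]
          if (!keep[j]) next
          if (.r2(dos[, i], dos[, j]) > r2Max) {
            keep[j] <- FALSE  # keep the earlier-position SNP
            removed <- TRUE
          }
        }
      }
    }
    if (!removed) break
  }
  which(keep)
}

#' Per-population pruned sets and their intersection
#'
#' @inheritParams ldPrune
#' @return list with per-population retained index vectors and `intersection`
#' @export
prunedIntersection <- function(hap, windowSnps = 5L, stepSnps = 1L, r2Max = 0.9) {
  pops <- unique(popMap(hap)$population)
  sets <- lapply(pops, function(p) {
    idx <- which(popMap(hap)$population == p)
    ldPrune(hap[idx, ], windowSnps, stepSnps, r2Max)
  })
  names(sets) <- pops
  sets$intersection <- Reduce(intersect, sets)
  sets
}

#' Write retained SNP indices as a BED-like TSV
#'
#' @param hap a [HaplotypeSet-class]
#' @param indices retained SNP indices (e.g. from [ldPrune()])
#' @param path output path
#' @export
writeSnpIndexBed <- function(hap, indices, path) {
  v <- variants(hap)[indices]
  df <- data.frame(chrom = as.character(seqnames(v)),
                   start = start(v) - 1L, end = start(v), index = indices)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-population diversity indices
#'
#' For every population: observed heterozygosity Ho (fraction of
#' heterozygous genotypes per SNP, averaged), gene diversity Hs (unbiased
#' expected heterozygosity `2p(1-p) n/(n-1)` with `n` the non-missing
#' haplotype count, averaged), the inbreeding coefficient Fis (per-SNP
#' `1 - Ho/Hs` averaged over polymorphic SNPs) and, when a window
#' specification is supplied, the mean windowed Tajima's D.
#'
#' @param hap a [HaplotypeSet-class]
#' @param windows optional [windowSpec()] for the Tajima's D column
#' @return data.frame with one row per population: `population`, `Ho`, `Hs`,
#'   `Fis`, `meanTajimaD`
#' @export
diversityIndices <- function(hap, windows = NULL) {
  pm <- popMap(hap)
  pops <- unique(pm$population)
  out <- lapply(pops, function(p) {
    idx <- which(pm$population == p)
    if (length(idx) < 2L)
      stop("population '", p, "' has fewer than 2 samples; Hs undefined")
    sub <- alleles(hap)[popHapRows(hap, p), , drop = FALSE]
    dos <- .dosage(sub)
    nGeno <- colSums(!is.na(dos))
    ho <- ifelse(nGeno > 0, colSums(dos == 1L, na.rm = TRUE) / nGeno, NA_real_)
    nh <- colSums(!is.na(sub))
    pfreq <- .colFreq(sub)
    hs <- ifelse(nh > 1L, 2 * pfreq * (1 - pfreq) * nh / (nh - 1), NA_real_)
    poly <- !is.na(hs) & hs > 0 & !is.na(ho)
    fis <- if (any(poly)) mean(1 - ho[poly] / hs[poly]) else NA_real_
    td <- NA_real_
    if (!is.null(windows)) {
      wt <- windowedTajimaD(hap, p, windows)
      td <- mean(wt$tajd, na.rm = TRUE)
    }
    data.frame(population = p, Ho = mean(ho, na.rm = TRUE),
               Hs = mean(hs, na.rm = TRUE), Fis = fis, meanTajimaD = td)
  })
  do.call(rbind, out)
}

#' Principal components of the genotype matrix
#'
#' Dosages are centered at `2p` and scaled by `sqrt(p(1-p))` (missing
#' dosages replaced by the SNP mean before scaling); scores come from the
#' eigendecomposition of the sample covariance matrix. Run on an LD-pruned
#' SNP set for structure analysis.
#'
#' @param hap a [HaplotypeSet-class]
#' @param nComponents number of components to return
#' @return list with `scores` (N x nComponents, rownames = sample ids) and
#'   `explained` (variance fractions, non-increasing)
#' @export
pcaCoords <- function(hap, nComponents = 2L) {
  dos <- .dosage(alleles(hap))
  N <- nrow(dos)
  .assert(nComponents <= min(N, ncol(dos)),
          "more components requested than min(samples, SNPs)")
  p <- colMeans(dos, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  dos <- dos[, keep, drop = FALSE]
  p <- p[keep]
  if (!ncol(dos)) stop("all SNPs monomorphic; PCA undefined")
  z <- sweep(dos, 2L, 2 * p)
  z[is.na(z)] <- 0
  z <- sweep(z, 2L, sqrt(p * (1 - p)), "/")
  cv <- tcrossprod(z) / ncol(z)
  if (max(abs(cv)) < 1e-12) stop("zero genotypic variance; PCA undefined")
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  scores <- eg$vectors[, seq_len(nComponents), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(nComponents)]), nComponents)
  rownames(scores) <- sampleIds(hap)
  colnames(scores) <- paste0("PC", seq_len(nComponents))
  list(scores = scores, explained = ev[seq_len(nComponents)] / sum(ev))
}
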