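#' Sliding-window specification
#'
#' @param size window size in bp (default 50 kb)
#' @param step window step in bp (default 10 kb)
#' @return list of class `windowSpec`
#' @export
windowSpec <- function(size = 50000L, step = 10000L) {
  .assert(size > 0 && step > 0, "window size and step must be positive")
  .assert(step <= size, "window step must not exceed window size")
  structure(list(size = as.integer(size), step = as.integer(step)),
            class = "windowSpec")
}

#' Tile chromosomes with sliding windows
#'
#' Windows are anchored at position 1 of each chromosome; the final partial
#' window is retained when it is at least `step` bp long.
#'
#' @param chromLengths named integer vector of chromosome lengths
#' @param windows a [windowSpec()]
#' @return `GRanges` of windows
#' @export
makeWindows <- function(chromLengths, windows = windowSpec()) {
  out <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    starts <- seq(1L, len, by = windows$step)
    ends <- pmin(starts + windows$size - 1L, len)
    keep <- (ends - starts + 1L) >= windows$step
    data.frame(chrom = ch, start = starts[keep], end = ends[keep])
  })
  df <- do.call(rbind, out)
  GRanges(df$chrom, IRanges(df$start, df$end))
}

# chromosome lengths implied by the variant coordinates
.chromLengthsFromVariants <- function(hap) {
  v <- variants(hap)
  tapply(start(v), as.character(seqnames(v)), max)
}

#' Weir & Cockerham (1984) per-SNP variance components and FST
#'
#' Two-population method-of-moments estimator. Per SNP the among-population
#' (`a`), among-individual (`b`) and within-individual (`c`) variance
#' components are returned; per-SNP FST is `a / (a + b + c)`. SNPs that are
#' monomorphic across both populations, or observed in fewer than two
#' diploid samples in either population, get zero/NA components and are
#' excluded from windowed ratio-of-sums.
#'
#' @param hap a [HaplotypeSet-class]
#' @param popA,popB population labels in `popMap(hap)`
#' @param by group samples by `"population"` or `"site"`
#' @return data.frame with columns `a`, `b`, `c`, `fst` (one row per SNP)
#' @export
wcFstComponents <- function(hap, popA, popB, by = "population") {
  alA <- alleles(hap)[popHapRows(hap, popA, by), , drop = FALSE]
  alB <- alleles(hap)[popHapRows(hap, popB, by), , drop = FALSE]
  dosA <- .dosage(alA); dosB <- .dosage(alB)
  n1 <- colSums(!is.na(dosA)); n2 <- colSums(!is.na(dosB))
  p1 <- colMeans(dosA, na.rm = TRUE) / 2
  p2 <- colMeans(dosB, na.rm = TRUE) / 2
  h1 <- colSums(dosA == 1L, na.rm = TRUE) / n1
  h2 <- colSums(dosB == 1L, na.rm = TRUE) / n2

  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  usable <- n1 >= 2 & n2 >= 2
  mono <- pbar == 0 | pbar == 1
  a[!usable | mono] <- 0; b[!usable | mono] <- 0; cc[!usable | mono] <- 0
  denom <- a + b + cc
  fst <- ifelse(denom > 0, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, fst = fst)
}

# map SNPs to windows; returns Hits-like data.frame(snp, window)
.snpWindowMap <- function(hap, win) {
  ov <- GenomicRanges::findOverlaps(variants(hap), win)
  data.frame(snp = S4Vectors::queryHits(ov), window = S4Vectors::subjectHits(ov))
}

#' Windowed Weir-Cockerham FST (ratio of sums)
#'
#' @inheritParams wcFstComponents
#' @param windows a [windowSpec()]
#' @param chromLengths optional named lengths; inferred from variants if NULL
#' @return `GRanges` of windows with mcols `nSnps` and `fst`
#' @export
windowedFst <- function(hap, popA, popB, windows = windowSpec(),
                        chromLengths = NULL) {
  if (is.null(chromLengths)) chromLengths <- .chromLengthsFromVariants(hap)
  win <- makeWindows(chromLengths, windows)
  comp <- wcFstComponents(hap, popA, popB)
  mp <- .snpWindowMap(hap, win)
  aSum <- tapply(comp$a[mp$snp], mp$window, sum)
  dSum <- tapply((comp$a + comp$b + comp$c)[mp$snp], mp$window, sum)
  nPoly <- tapply(!is.na(comp$fst[mp$snp]), mp$window, sum)
  fst <- rep(NA_real_, length(win)); n <- rep(0L, length(win))
  i <- as.integer(names(aSum))
  fst[i] <- ifelse(dSum > 0, aSum / dSum, NA_real_)
  n[i] <- as.integer(nPoly)
  mcols(win)$nSnps <- n
  mcols(win)$fst <- fst
  win
}

# per-SNP pi (expected heterozygosity with sample-size correction)
.perSnpPi <- function(al) {
  n <- colSums(!is.na(al))
  p <- .colFreq(al)
  ifelse(n > 1, 2 * p * (1 - p) * n / (n - 1), 0)
}

#' Windowed nucleotide diversity
#'
#' Per-SNP `pi = 2p(1-p) n/(n-1)` (n = non-missing haplotype count) summed in
#' each window and divided by the window span; windows without SNPs get 0.
#'
#' @inheritParams windowedFst
#' @param pop population label
#' @return `GRanges` of windows with mcols `nSnps` and `pi` (per bp)
#' @export
windowedPi <- function(hap, pop, windows = windowSpec(), chromLengths = NULL) {
  if (is.null(chromLengths)) chromLengths <- .chromLengthsFromVariants(hap)
  win <- makeWindows(chromLengths, windows)
  al <- alleles(hap)[popHapRows(hap, pop), , drop = FALSE]
  pi <- .perSnpPi(al)
  mp <- .snpWindowMap(hap, win)
  s <- tapply(pi[mp$snp], mp$window, sum)
  cnt <- tapply(mp$snp, mp$window, length)
  v <- rep(0, length(win)); n <- rep(0L, length(win))
  i <- as.integer(names(s))
  v[i] <- s; n[i] <- as.integer(cnt)
  mcols(win)$nSnps <- n
  mcols(win)$pi <- v / width(win)
  win
}

#' log2 ratio of windowed nucleotide diversity
#'
#' `omega = log2(piA / piB)`; windows where either diversity is 0 are
#' undefined (NA) and excluded from downstream percentile ranking.
#'
#' @param piA,piB `GRanges` from [windowedPi()] on the same window grid
#' @return numeric vector of per-window omega
#' @export
omegaStat <- function(piA, piB) {
  .assert(length(piA) == length(piB) &&
            all(start(piA) == start(piB)) &&
            all(as.character(seqnames(piA)) == as.character(seqnames(piB))),
          "window grids differ between the two pi tracks")
  a <- mcols(piA)$pi; b <- mcols(piB)$pi
  ifelse(a > 0 & b > 0, log2(a / b), NA_real_)
}

# Tajima (1989) constants for n haplotypes
.tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Standard D from the number of segregating sites and the mean number of
#' pairwise differences per window; windows with no segregating site are NA.
#' Requires at least 4 haplotypes in the population.
#'
#' @inheritParams windowedPi
#' @return data.frame with `chrom`, `start`, `end`, `nSnps`, `tajd`
#' @export
windowedTajimaD <- function(hap, pop, windows = windowSpec(),
                            chromLengths = NULL) {
  if (is.null(chromLengths)) chromLengths <- .chromLengthsFromVariants(hap)
  win <- makeWindows(chromLengths, windows)
  al <- alleles(hap)[popHapRows(hap, pop), , drop = FALSE]
  nHap <- round(mean(colSums(!is.na(al))))
  .assert(nHap >= 4, "Tajima's D needs at least 4 haplotypes")
  k <- .tajimaConstants(nHap)
  p <- .colFreq(al)
  seg <- !is.na(p) & p > 0 & p < 1
  piCnt <- .perSnpPi(al)  # mean pairwise differences per SNP
  mp <- .snpWindowMap(hap, win)
  S <- tapply(seg[mp$snp], mp$window, sum)
  piSum <- tapply(piCnt[mp$snp], mp$window, sum)
  d <- rep(NA_real_, length(win)); n <- rep(0L, length(win))
  i <- as.integer(names(S))
  Sv <- as.numeric(S); piv <- as.numeric(piSum)
  dv <- ifelse(Sv > 0,
               (piv - Sv / k$a1) / sqrt(k$e1 * Sv + k$e2 * Sv * (Sv - 1)),
               NA_real_)
  d[i] <- dv; n[i] <- as.integer(S)
  data.frame(chrom = as.character(seqnames(win)), start = start(win),
             end = end(win), nSnps = n, tajd = d)
}

# EHH of one carrier group as it extends; g = current group codes
.groupEhh <- function(g, n) {
  if (n < 2L) return(0)
  tab <- tabulate(g)
  sum(tab * (tab - 1) / 2) / (n * (n - 1) / 2)
}

# refine haplotype groups by the alleles at the next SNP (NA -> own code 2)
.refineGroups <- function(g, alCol) {
  alCol[is.na(alCol)] <- 2L
  key <- g * 3L + alCol
  match(key, unique(key))
}

#' Extended haplotype homozygosity profile around a focal SNP
#'
#' EHH at flanking SNP x is the probability that two randomly drawn carriers
#' of the focal allele are identical over all SNPs between the focal SNP and
#' x. EHH equals 1 at the focal SNP and is non-increasing with distance.
#'
#' @param hap a phased [HaplotypeSet-class], typically subset to one
#'   population
#' @param focal SNP index (column of the allele matrix)
#' @param allele focal allele, 0 or 1
#' @param pop optional population label to restrict to
#' @return data.frame with `index`, `pos`, `ehh` for the focal chromosome
#' @export
ehhProfile <- function(hap, focal, allele, pop = NULL) {
  .assert(isPhased(hap), "EHH requires phased haplotypes")
  al <- alleles(hap)
  if (!is.null(pop)) al <- al[popHapRows(hap, pop), , drop = FALSE]
  v <- variants(hap)
  ch <- as.character(seqnames(v))
  onChrom <- which(ch == ch[focal])
  carriers <- which(!is.na(al[, focal]) & al[, focal] == allele)
  .assert(length(carriers) >= 2, "focal allele carried by fewer than 2 haplotypes")
  n <- length(carriers)
  sub <- al[carriers, onChrom, drop = FALSE]
  fIdx <- match(focal, onChrom)
  ehh <- rep(NA_real_, length(onChrom))
  ehh[fIdx] <- 1
  for (dir in c(-1L, 1L)) {
    g <- rep(1L, n)
    j <- fIdx + dir
    while (j >= 1L && j <= length(onChrom)) {
      g <- .refineGroups(g, sub[, j])
      ehh[j] <- .groupEhh(g, n)
      j <- j + dir
    }
  }
  data.frame(index = onChrom, pos = start(v)[onChrom], ehh = ehh)
}

# iES (trapezoid integral of EHHS over bp) for every SNP of one population
# al: nHap x L (one chromosome, complete-ish), pos: positions
.iesScanChrom <- function(al, pos, cutoff) {
  L <- ncol(al)
  ies <- numeric(L)
  alc <- al
  alc[is.na(alc)] <- 2L
  for (s in seq_len(L)) {
    foc <- al[, s]
    idx0 <- which(!is.na(foc) & foc == 0L)
    idx1 <- which(!is.na(foc) & foc == 1L)
    nTot <- length(idx0) + length(idx1)
    if (nTot < 2L) { ies[s] <- 0; next }
    f0 <- length(idx0) / nTot
    f1 <- length(idx1) / nTot
    total <- 0
    for (dir in c(-1L, 1L)) {
      e <- 1
      prevPos <- pos[s]
      g0 <- rep(1L, length(idx0)); g1 <- rep(1L, length(idx1))
      j <- s + dir
      while (j >= 1L && j <= L) {
        if (length(idx0) >= 2L) g0 <- .refineGroups(g0, alc[idx0, j])
        if (length(idx1) >= 2L) g1 <- .refineGroups(g1, alc[idx1, j])
        ej <- f0 * .groupEhh(g0, length(idx0)) +
          f1 * .groupEhh(g1, length(idx1))
        total <- total + 0.5 * (e + ej) * abs(pos[j] - prevPos)
        if (ej < cutoff) break
        e <- ej
        prevPos <- pos[j]
        j <- j + dir
      }
    }
    ies[s] <- total
  }
  ies
}

#' Cross-population haplotype-length contrast (Rsb)
#'
#' For every SNP the site-EHH (EHHS, the allele-frequency-weighted average of
#' per-allele EHH) is integrated over physical position away from the focal
#' SNP until it falls below `cutoff`, giving iES per population. The log
#' ratio `ln(iES_A / iES_B)` is standardized genome-wide (median or mean
#' centering, SD scaling) and averaged within sliding windows. Positive
#' values indicate longer haplotypes (more recent sweep) in population A.
#'
#' @inheritParams windowedFst
#' @param cutoff EHHS level at which integration stops (default 0.05)
#' @param center `"median"` (default) or `"mean"` centering for
#'   standardization
#' @return list with `perSnp` (data.frame: chrom, pos, lnRatio, rsb) and
#'   `windows` (`GRanges` with mcols `nSnps`, `rsbMean`)
#' @export
rsbScan <- function(hap, popA, popB, windows = windowSpec(),
                    chromLengths = NULL, cutoff = 0.05,
                    center = c("median", "mean")) {
  .assert(isPhased(hap), "Rsb requires phased haplotypes")
  center <- match.arg(center)
  if (is.null(chromLengths)) chromLengths <- .chromLengthsFromVariants(hap)
  v <- variants(hap)
  ch <- as.character(seqnames(v))
  alA <- alleles(hap)[popHapRows(hap, popA), , drop = FALSE]
  alB <- alleles(hap)[popHapRows(hap, popB), , drop = FALSE]
  iesA <- numeric(length(v)); iesB <- numeric(length(v))
  for (c1 in unique(ch)) {
    sel <- which(ch == c1)
    iesA[sel] <- .iesScanChrom(alA[, sel, drop = FALSE], start(v)[sel], cutoff)
    iesB[sel] <- .iesScanChrom(alB[, sel, drop = FALSE], start(v)[sel], cutoff)
  }
  ok <- iesA > 0 & iesB > 0
  lnRatio <- rep(NA_real_, length(v))
  lnRatio[ok] <- log(iesA[ok] / iesB[ok])
  ctr <- if (center == "median") median(lnRatio[ok]) else mean(lnRatio[ok])
  sdv <- sd(lnRatio[ok])
  rsb <- (lnRatio - ctr) / sdv
  win <- makeWindows(chromLengths, windows)
  mp <- .snpWindowMap(hap, win)
  keep <- !is.na(rsb[mp$snp])
  m <- tapply(rsb[mp$snp][keep], mp$window[keep], mean)
  cnt <- tapply(mp$snp[keep], mp$window[keep], length)
  rm_ <- rep(NA_real_, length(win)); n <- rep(0L, length(win))
  i <- as.integer(names(m))
  rm_[i] <- m; n[i] <- as.integer(cnt)
  mcols(win)$nSnps <- n
  mcols(win)$rsbMean <- rm_
  list(perSnp = data.frame(chrom = ch, pos = start(v),
                           lnRatio = lnRatio, rsb = rsb),
       windows = win)
}

#' Assemble the per-window statistic table
#'
#' Runs windowed FST, per-population nucleotide diversity, their log2 ratio,
#' Tajima's D in both populations, and the windowed Rsb mean, on one shared
#' window grid. Population A is conventionally the high-latitude group, so
#' a sweep in A shows `omega < 0` and `rsb > 0`.
#'
#' @inheritParams windowedFst
#' @param rsbCutoff EHHS integration cutoff for [rsbScan()]
#' @return `GRanges` with mcols `nSnps`, `fst`, `piA`, `piB`, `omega`,
#'   `rsbMean`, `tajdA`, `tajdB`
#' @export
windowStats <- function(hap, popA, popB, windows = windowSpec(),
                        chromLengths = NULL, rsbCutoff = 0.05) {
  if (is.null(chromLengths)) chromLengths <- .chromLengthsFromVariants(hap)
  fstW <- windowedFst(hap, popA, popB, windows, chromLengths)
  piA <- windowedPi(hap, popA, windows, chromLengths)
  piB <- windowedPi(hap, popB, windows, chromLengths)
  om <- omegaStat(piA, piB)
  tdA <- windowedTajimaD(hap, popA, windows, chromLengths)
  tdB <- windowedTajimaD(hap, popB, windows, chromLengths)
  rsb <- rsbScan(hap, popA, popB, windows, chromLengths, rsbCutoff)
  out <- fstW
  mcols(out)$piA <- mcols(piA)$pi
  mcols(out)$piB <- mcols(piB)$pi
  mcols(out)$omega <- om
  mcols(out)$rsbMean <- mcols(rsb$windows)$rsbMean
  mcols(out)$tajdA <- tdA$tajd
  mcols(out)$tajdB <- tdB$tajd
  out
}

#' Write a window statistic table as TSV
#'
#' @param win `GRanges` from [windowStats()]
#' @param path output path
#' @export
writeWindowStats <- function(win, path) {
  df <- data.frame(chrom = as.character(seqnames(win)),
                   start = start(win), end = end(win),
                   as.data.frame(mcols(win)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
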