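popHap <- function(alA, alB, pos = NULL, chrom = "chr1") {
  nA <- nrow(alA) / 2; nB <- nrow(alB) / 2
  pm <- data.frame(sample = paste0("s", seq_len(nA + nB)),
                   site = rep(c("a", "b"), c(nA, nB)),
                   population = rep(c("A", "B"), c(nA, nB)))
  if (is.null(pos)) pos <- seq_len(ncol(alA)) * 100L
  HaplotypeSet(rbind(alA, alB),
               data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
               pm$sample, TRUE, pm)
}

test_that("Weir-Cockerham FST: fixation, no differentiation, oracle agreement", {
  # complete fixation: FST = 1
  hap <- popHap(matrix(0L, 20, 3), matrix(1L, 20, 3))
  comp <- wcFstComponents(hap, "A", "B")
  expect_equal(comp$fst, rep(1, 3))
  # equal allele frequencies, equal sizes: FST ~ 0 (may be slightly negative)
  set.seed(12)
  alA <- matrix(rbinom(40 * 20, 1L, rep(runif(20, .2, .8), each = 40)), 40)
  hap2 <- popHap(alA, alA[sample(40), ])
  f2 <- wcFstComponents(hap2, "A", "B")$fst
  expect_lt(abs(mean(f2, na.rm = TRUE)), 0.05)
  # random fixtures match the independently coded ANOVA oracle
  for (seed in 1:5) {
    set.seed(seed)
    alA <- matrix(rbinom(6 * 4, 1L, 0.5), 6)
    alB <- matrix(rbinom(6 * 4, 1L, 0.3), 6)
    hap3 <- popHap(alA, alB)
    got <- wcFstComponents(hap3, "A", "B")
    want <- oracleWcFst(selscape:::.dosage(alA), selscape:::.dosage(alB))
    poly <- !is.na(want[, "fst"]) & !is.na(got$fst)
    expect_equal(got$a[poly], unname(want[poly, "a"]), tolerance = 1e-10)
    expect_equal(got$b[poly], unname(want[poly, "b"]), tolerance = 1e-10)
    expect_equal(got$c[poly], unname(want[poly, "c"]), tolerance = 1e-10)
    expect_equal(got$fst[poly], unname(want[poly, "fst"]), tolerance = 1e-10)
  }
})

test_that("windowed FST is a ratio of sums within [-0.1, 1] and matches the
           per-SNP value for single-SNP windows", {
  hap <- randomHapFixture(20, 50, seed = 14)
  win <- windowedFst(hap, "P1", "P2", windowSpec(1000, 1000))
  expect_true(all(is.na(mcols(win)$fst) |
                    (mcols(win)$fst >= -0.1 & mcols(win)$fst <= 1)))
  comp <- wcFstComponents(hap, "P1", "P2")
  one <- which(mcols(win)$nSnps == 1)
  if (length(one)) {
    ov <- GenomicRanges::findOverlaps(variants(hap), win[one])
    expect_equal(mcols(win)$fst[one][S4Vectors::subjectHits(ov)],
                 comp$fst[S4Vectors::queryHits(ov)])
  }
})

test_that("windowed pi matches the forced single-SNP value and the all-pairs oracle", {
  # one SNP at p = 0.5 with 2 haplotypes in a 50 kb window: pi = 1/50000
  al <- matrix(c(0L, 1L), nrow = 2)
  pm <- data.frame(sample = "s1", site = "x", population = "P")
  hap <- HaplotypeSet(al, data.frame(chrom = "c", pos = 100L,
                                     ref = "A", alt = "T"),
                      pm$sample, TRUE, pm)
  w <- windowedPi(hap, "P", windowSpec(50000, 50000),
                  chromLengths = c(c = 50000L))
  expect_equal(mcols(w)$pi, 1 / 50000)
  # monomorphic window = 0
  al2 <- matrix(1L, 2, 1)
  hap2 <- HaplotypeSet(al2, data.frame(chrom = "c", pos = 100L,
                                       ref = "A", alt = "T"),
                       pm$sample, TRUE, pm)
  w2 <- windowedPi(hap2, "P", windowSpec(50000, 50000),
                   chromLengths = c(c = 50000L))
  expect_equal(mcols(w2)$pi, 0)
  # 20-haplotype window equals mean pairwise difference count / span
  hap3 <- randomHapFixture(10, 30, seed = 15, nPop = 1)
  span <- 30000L
  w3 <- windowedPi(hap3, "P1", windowSpec(span, span),
                   chromLengths = c(chr1 = span))
  expect_equal(mcols(w3)$pi[1],
               oraclePairwisePi(alleles(hap3)) / span, tolerance = 1e-12)
})

test_that("omega follows the log2 convention and window-grid checks", {
  hap <- randomHapFixture(10, 30, seed = 16, nPop = 2)
  pA <- windowedPi(hap, "P1", windowSpec(10000, 10000))
  pB <- windowedPi(hap, "P2", windowSpec(10000, 10000))
  om <- omegaStat(pA, pA)
  expect_true(all(om[mcols(pA)$pi > 0] == 0))
  doubled <- pA
  mcols(doubled)$pi <- mcols(pA)$pi * 2
  expect_true(all(omegaStat(doubled, pA)[mcols(pA)$pi > 0] == 1))
  zero <- pB
  mcols(zero)$pi <- 0
  expect_true(all(is.na(omegaStat(pA, zero))))
  short <- pB[1]
  expect_error(omegaStat(pA, short), "grid")
})

test_that("Tajima's D matches the textbook oracle and sign conventions", {
  # S = 0 window is missing
  al0 <- matrix(0L, 10, 5)
  pm <- data.frame(sample = paste0("s", 1:5), site = "x", population = "P")
  hap0 <- HaplotypeSet(al0, data.frame(chrom = "c", pos = 1:5 * 10L,
                                       ref = "A", alt = "T"),
                       pm$sample, TRUE, pm)
  w0 <- windowedTajimaD(hap0, "P", windowSpec(1000, 1000),
                        chromLengths = c(c = 1000L))
  expect_true(all(is.na(w0$tajd)))
  # random windows match the independent implementation to 1e-10
  for (seed in 20 + 1:5) {
    set.seed(seed)
    al <- matrix(rbinom(10 * 15, 1L, rep(runif(15, .1, .9), each = 10)), 10)
    hap <- HaplotypeSet(al, data.frame(chrom = "c", pos = 1:15 * 10L,
                                       ref = "A", alt = "T"),
                        pm$sample, TRUE, pm)
    w <- windowedTajimaD(hap, "P", windowSpec(1000, 1000),
                         chromLengths = c(c = 1000L))
    expect_equal(w$tajd, oracleTajimaD(al), tolerance = 1e-10)
  }
  # singletons only: D < 0
  alS <- matrix(0L, 10, 8)
  alS[cbind(1:8, 1:8)] <- 1L
  hapS <- HaplotypeSet(alS, data.frame(chrom = "c", pos = 1:8 * 10L,
                                       ref = "A", alt = "T"),
                       pm$sample, TRUE, pm)
  wS <- windowedTajimaD(hapS, "P", windowSpec(1000, 1000),
                        chromLengths = c(c = 1000L))
  expect_lt(wS$tajd, 0)
  expect_equal(wS$tajd, oracleTajimaD(alS), tolerance = 1e-10)
})

test_that("EHH: definition at focal, hand example 7/15, monotone decay, oracle", {
  # 6 carriers splitting 4/2 at the first flanking SNP: EHH = 7/15
  al <- matrix(0L, 6, 3)
  al[, 2] <- 1L                     # focal SNP: all six carry allele 1
  al[1:4, 3] <- 0L; al[5:6, 3] <- 1L
  al[, 1] <- c(0L, 0L, 0L, 0L, 0L, 0L)
  pm <- data.frame(sample = paste0("s", 1:3), site = "x", population = "P")
  hap <- HaplotypeSet(al, data.frame(chrom = "c", pos = c(50L, 100L, 150L),
                                     ref = "A", alt = "T"),
                      pm$sample, TRUE, pm)
  prof <- ehhProfile(hap, 2L, 1L)
  expect_equal(prof$ehh[2], 1)                       # EHH(focal) = 1
  expect_equal(prof$ehh[3], 7 / 15)                  # (C(4,2)+C(2,2))/C(6,2)
  expect_equal(prof$ehh[1], 1)                       # all identical left
  # all carriers identical across a window: EHH = 1 everywhere
  alI <- matrix(1L, 6, 4)
  hapI <- HaplotypeSet(alI, data.frame(chrom = "c", pos = 1:4 * 10L,
                                       ref = "A", alt = "T"),
                       pm$sample, TRUE, pm)
  profI <- ehhProfile(hapI, 2L, 1L)
  expect_true(all(profI$ehh == 1))
  # monotone non-increasing away from the focal SNP + enumeration oracle
  for (seed in 31:35) {
    set.seed(seed)
    alR <- matrix(rbinom(12 * 9, 1L, 0.5), 12)
    alR[, 5] <- rep(c(0L, 1L), 6)
    pmR <- data.frame(sample = paste0("s", 1:6), site = "x", population = "P")
    hapR <- HaplotypeSet(alR, data.frame(chrom = "c", pos = 1:9 * 10L,
                                         ref = "A", alt = "T"),
                         pmR$sample, TRUE, pmR)
    pr <- ehhProfile(hapR, 5L, 1L)
    expect_true(all(diff(pr$ehh[5:9]) <= 1e-12))
    expect_true(all(diff(rev(pr$ehh[1:5])) <= 1e-12))
    for (x in c(2L, 4L, 7L, 9L))
      expect_equal(pr$ehh[x], oracleEhh(alR, 5L, 1L, x), tolerance = 1e-12)
  }
  expect_error(ehhProfile(hap, 1L, 1L), "fewer than 2")
})

test_that("Rsb is antisymmetric, centered, and flags a planted sweep", {
  hap <- randomHapFixture(20, 200, seed = 41, nPop = 2)
  ws <- windowSpec(5000, 5000)
  t0 <- Sys.time()
  r1 <- rsbScan(hap, "P1", "P2", ws)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 5)  # 200-SNP two-population fixture completes fast
  r2 <- rsbScan(hap, "P2", "P1", ws)
  ok <- !is.na(r1$perSnp$lnRatio)
  expect_equal(r1$perSnp$lnRatio[ok], -r2$perSnp$lnRatio[ok], tolerance = 1e-12)
  expect_equal(median(r1$perSnp$rsb, na.rm = TRUE), 0, tolerance = 1e-9)

  # a planted sweep (long shared haplotypes in P1) lands in the upper tail
  al <- alleles(hap)
  sweepCols <- 90:110
  rowsP1 <- selscape:::popHapRows(hap, "P1")
  core <- al[rowsP1[1], sweepCols]
  for (h in rowsP1[-1]) al[h, sweepCols] <- core
  hapS <- HaplotypeSet(al, data.frame(chrom = "chr1",
                                      pos = start(variants(hap)),
                                      ref = "A", alt = "T"),
                       sampleIds(hap), TRUE, popMap(hap))
  rS <- rsbScan(hapS, "P1", "P2", ws)
  center <- start(variants(hapS))[100]
  ctrWin <- which(start(rS$windows) <= center & end(rS$windows) >= center)
  q90 <- quantile(mcols(rS$windows)$rsbMean, 0.9, na.rm = TRUE)
  expect_gt(max(mcols(rS$windows)$rsbMean[ctrWin]), 0)
  expect_gte(max(mcols(rS$windows)$rsbMean[ctrWin]), q90)
})

test_that("pi and Tajima's D are invariant under sample reordering", {
  hap <- randomHapFixture(12, 40, seed = 51, nPop = 1)
  perm <- sample(nSamples(hap))
  hapP <- hap[perm, ]
  w1 <- windowedPi(hap, "P1", windowSpec(5000, 5000))
  w2 <- windowedPi(hapP, "P1", windowSpec(5000, 5000))
  expect_equal(mcols(w1)$pi, mcols(w2)$pi)
  t1 <- windowedTajimaD(hap, "P1", windowSpec(5000, 5000))
  t2 <- windowedTajimaD(hapP, "P1", windowSpec(5000, 5000))
  expect_equal(t1$tajd, t2$tajd)
})

test_that("window grid anchors at 1 and keeps partial windows >= step", {
  w <- makeWindows(c(chr1 = 73000L), windowSpec(50000, 10000))
  expect_equal(start(w)[1], 1L)
  expect_true(all(width(w) >= 10000))
  expect_equal(max(end(w)), 73000L)
  expect_error(windowSpec(1000, 2000), "step")
})
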