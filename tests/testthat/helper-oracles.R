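# Independent brute-force oracles, coded from the textbook definitions and
# kept deliberately separate from the package's vectorized implementations.

# Weir & Cockerham variance components through the nested ANOVA layout:
# alleles nested in individuals nested in populations.
oracleWcFst <- function(dosA, dosB) {
  perSnp <- function(dA, dB) {
    dA <- dA[!is.na(dA)]; dB <- dB[!is.na(dB)]
    groups <- list(dA, dB)
    r <- 2
    nI <- vapply(groups, length, 0L)
    nTot <- sum(nI)
    yBarI <- vapply(groups, function(g) mean(g) / 2, 0)
    yBar <- sum(unlist(groups)) / (2 * nTot)
    ssg <- sum(vapply(groups, function(g) sum(g == 1) * 0.5, 0))
    ssi <- 2 * sum(unlist(mapply(function(g, yb) (g / 2 - yb)^2,
                                 groups, yBarI, SIMPLIFY = FALSE)))
    ssp <- sum(2 * nI * (yBarI - yBar)^2)
    msg <- ssg / nTot
    msi <- ssi / (nTot - r)
    msp <- ssp / (r - 1)
    nc <- (nTot - sum(nI^2) / nTot) / (r - 1)
    a <- (msp - msi) / (2 * nc)
    b <- (msi - msg) / 2
    cc <- msg
    c(a = a, b = b, c = cc,
      fst = if (a + b + cc > 0) a / (a + b + cc) else NA_real_)
  }
  t(vapply(seq_len(ncol(dosA)), function(s) perSnp(dosA[, s], dosB[, s]),
           numeric(4)))
}

# mean pairwise difference count between haplotypes, by explicit all-pairs
# comparison
oraclePairwisePi <- function(al) {
  n <- nrow(al)
  tot <- 0; npair <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(al[i, ]) & !is.na(al[j, ])
      # per-site pairwise diff scaled to full comparison (no-missing fixtures
      # pass ok everywhere)
      tot <- tot + sum(al[i, ok] != al[j, ok])
      npair <- npair + 1
    }
  }
  tot / npair
}

# Tajima's D from the 1989 formulas, coded with explicit loops
oracleTajimaD <- function(al) {
  n <- nrow(al)
  p <- colMeans(al)
  S <- sum(p > 0 & p < 1)
  if (S == 0) return(NA_real_)
  k <- oraclePairwisePi(al)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# EHH by string enumeration of extended haplotypes
oracleEhh <- function(al, focal, allele, x) {
  carriers <- which(al[, focal] == allele)
  n <- length(carriers)
  span <- min(focal, x):max(focal, x)
  words <- apply(al[carriers, span, drop = FALSE], 1, paste, collapse = "")
  tab <- table(words)
  sum(choose(tab, 2)) / choose(n, 2)
}

# spherical law of cosines (alternative great-circle route)
oracleGreatCircle <- function(lat1, lon1, lat2, lon2, R = 6371.393) {
  toRad <- pi / 180
  cosv <- sin(lat1 * toRad) * sin(lat2 * toRad) +
    cos(lat1 * toRad) * cos(lat2 * toRad) * cos((lon2 - lon1) * toRad)
  R * acos(pmin(1, pmax(-1, cosv)))
}

# random small haplotype fixture (no missing data)
randomHapFixture <- function(nSamples, nSnps, seed, nPop = 2) {
  set.seed(seed)
  al <- matrix(rbinom(2 * nSamples * nSnps, 1L,
                      rep(runif(nSnps, 0.1, 0.9), each = 2 * nSamples)),
               nrow = 2 * nSamples)
  pos <- sort(sample.int(nSnps * 1000L, nSnps))
  pops <- rep(paste0("P", seq_len(nPop)), length.out = nSamples)
  pm <- data.frame(sample = paste0("s", seq_len(nSamples)),
                   site = pops, population = pops)
  HaplotypeSet(al, data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T"),
               pm$sample, TRUE, pm)
}
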