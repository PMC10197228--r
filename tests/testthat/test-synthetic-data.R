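test_that("neutral simulation: homogenizing and drift limits, determinism", {
  # m = 0.5, large N, long T: adjacent demes nearly identical
  cfgH <- simConfig(nDemes = 4, samplesPerDeme = 10, nChrom = 1,
                    chromLengthBp = 1e5, nSnps = 400, migrationRate = 0.5,
                    demeSize = 500, generations = 200, sweeps = "none",
                    envLoci = data.frame(snp = integer(), slope = numeric()),
                    sstYears = 2, seed = 31)
  simH <- simulateNeutral(cfgH)
  pm <- data.frame(sample = paste0("s", seq_along(simH$demeOfSample)),
                   site = paste0("d", simH$demeOfSample),
                   population = paste0("d", simH$demeOfSample))
  hapH <- HaplotypeSet(simH$haplotypes, simH$variants, pm$sample, TRUE, pm)
  fstH <- pairwiseFst(hapH, by = "population")
  expect_lt(abs(fstH["d1", "d2"]), 0.01)

  # m = 0, N = 50, T = 200: mean per-SNP FST near the drift expectation
  # 1 - exp(-T/2N), cross-checked against an independent Wright-Fisher
  # two-deme simulation of the same depth
  cfgD <- simConfig(nDemes = 2, samplesPerDeme = 25, nChrom = 1,
                    chromLengthBp = 1e5, nSnps = 600, migrationRate = 0,
                    demeSize = 50, generations = 200, sweeps = "none",
                    envLoci = data.frame(snp = integer(), slope = numeric()),
                    sstYears = 2, seed = 32)
  simD <- simulateNeutral(cfgD)
  pmD <- data.frame(sample = paste0("s", seq_along(simD$demeOfSample)),
                    site = paste0("d", simD$demeOfSample),
                    population = paste0("d", simD$demeOfSample))
  hapD <- HaplotypeSet(simD$haplotypes, simD$variants, pmD$sample, TRUE, pmD)
  comp <- wcFstComponents(hapD, "d1", "d2")
  fstD <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  expected <- 1 - exp(-200 / (2 * 50))
  # independent WF oracle at the frequency level
  set.seed(33)
  oracleFst <- mean(replicate(5, {
    p0 <- pmin(pmax(rbeta(500, 0.8, 0.8), 0.02), 0.98)
    p1 <- p0; p2 <- p0
    for (g in 1:200) {
      p1 <- rbinom(500, 100, p1) / 100
      p2 <- rbinom(500, 100, p2) / 100
    }
    num <- (p1 - p2)^2
    den <- (p1 + p2) * (2 - p1 - p2) / 2
    sum(num[den > 0]) / sum(den[den > 0] + num[den > 0] / 2)
  }))
  expect_gt(fstD, 0.5 * expected)
  expect_lt(fstD, 1.5 * expected)
  expect_gt(fstD, 0.5 * oracleFst)
  expect_lt(fstD, 1.6 * oracleFst)

  # determinism: same seed, byte-identical bundle
  d1 <- tempfile(); d2 <- tempfile()
  emitBundle(smallSimConfig(seed = 99), d1)
  emitBundle(smallSimConfig(seed = 99), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("sweep planting: limiting case, diversity loss, non-target demes untouched", {
  cfg <- smallSimConfig(seed = 41, sweeps = "none")
  sim <- simulateNeutral(cfg)
  demeOfHap <- rep(sim$demeOfSample, each = 2L)
  v <- sim$variants
  onCh <- which(v$chrom == "chr1")
  sel <- onCh[abs(v$pos[onCh] - 5e5) <= 50000]
  # q0 = 1, r -> Inf: all target haplotypes identical, pi = 0 inside
  set.seed(42)
  hap1 <- plantSweep(sim$haplotypes, demeOfHap, targetDemes = c(5, 6),
                     snpSel = sel, pos = v$pos[sel], centerBp = 5e5,
                     q0 = 1, decayBp = Inf, freqRow = sim$freq)
  target <- which(demeOfHap %in% c(5, 6))
  expect_equal(nrow(unique(hap1[target, sel])), 1L)
  # non-target demes unchanged
  expect_identical(hap1[-target, ], sim$haplotypes[-target, ])
  # q0 < 1: pi drops in the planted interval vs the neutral original
  set.seed(43)
  hap2 <- plantSweep(sim$haplotypes, demeOfHap, c(5, 6), sel, v$pos[sel],
                     5e5, q0 = 0.9, decayBp = 50000, freqRow = sim$freq)
  piBefore <- mean(selscape:::.perSnpPi(sim$haplotypes[target, sel]))
  piAfter <- mean(selscape:::.perSnpPi(hap2[target, sel]))
  expect_lt(piAfter, piBefore)
  expect_error(plantSweep(sim$haplotypes, demeOfHap, c(5), sel[1:12],
                          v$pos[sel[1:12]], 5e5, q0 = 0.05, decayBp = 1e4,
                          freqRow = sim$freq), "no detectable sweep")
})

test_that("planted intervals lose diversity in most replicates", {
  drops <- replicate(20, {
    cfg <- smallSimConfig(seed = sample.int(1e6, 1), sweeps = "none")
    sim <- simulateNeutral(cfg)
    demeOfHap <- rep(sim$demeOfSample, each = 2L)
    v <- sim$variants
    onCh <- which(v$chrom == "chr1")
    sel <- onCh[abs(v$pos[onCh] - 3e5) <= 40000]
    neut <- onCh[abs(v$pos[onCh] - 7e5) <= 40000]
    hapS <- plantSweep(sim$haplotypes, demeOfHap, c(5, 6), sel, v$pos[sel],
                       3e5, 0.9, 50000, sim$freq)
    target <- which(demeOfHap %in% c(5, 6))
    mean(selscape:::.perSnpPi(hapS[target, sel])) <
      mean(selscape:::.perSnpPi(hapS[target, neut]))
  })
  expect_gte(mean(drops), 0.95)
})

test_that("environment generator: gradients, winter/summer asymmetry, coast", {
  cfg <- simConfig(nDemes = 10, sstYears = 8, seed = 51)
  env <- makeEnvironment(cfg)
  expect_true(all(diff(env$sites$lat) > 0))
  expect_true(all(diff(env$sites$coastPos) > 0))
  cl <- env$env
  expect_true(all(cl$sstMin <= cl$sstMed & cl$sstMed <= cl$sstMax))
  # winter spread across demes exceeds summer spread
  expect_gt(diff(range(cl$sstMin)), diff(range(cl$sstMax)))
  # D_lat strictly increasing with deme separation from site 1
  dl <- latitudeDistance(env$sites$lat[1], env$sites$lat)
  expect_true(all(diff(dl) > 0))
  # all three geographic distances computable and monotone-ish in separation
  dm <- coastlineDistanceMatrix(env$sites$lat, env$sites$lon, env$grid)
  expect_true(all(diff(dm[1, ]) > 0))
})

test_that("emitted bundle loads cleanly and is consistent with its truth table", {
  cfg <- smallSimConfig(seed = 61)
  dir <- tempfile()
  b <- emitBundle(cfg, dir)
  expect_true(all(file.exists(unlist(b$paths))))
  pm <- readPopMap(file.path(dir, "popmap.tsv"))
  expect_silent(hap <- readVcfGenotypes(file.path(dir, "genotypes.vcf"), pm))
  expect_identical(alleles(hap), alleles(b$hap))
  tr <- readSimTruth(file.path(dir, "truth.json"))
  expect_true(all(tr$sweeps$startBp >= 1 &
                    tr$sweeps$endBp <= cfg$chromLengthBp))
  # a gene sits inside every sweep and background genes exist
  genes <- readGeneModels(file.path(dir, "genes.gff3"))
  sw <- GRanges(paste0("chr", tr$sweeps$chrom),
                IRanges(tr$sweeps$startBp, tr$sweeps$endBp))
  inside <- IRanges::overlapsAny(sw, genes, type = "within")
  covered <- vapply(seq_along(sw), function(i)
    any(start(genes) >= start(sw)[i] & end(genes) <= end(sw)[i] &
          as.character(seqnames(genes)) == as.character(seqnames(sw))[i]),
    TRUE)
  expect_true(all(covered))
  expect_gte(sum(grepl("^bggene", mcols(genes)$gene_id)), 10)
})

test_that("generated FST increases with deme separation on average", {
  cfg <- smallSimConfig(seed = 71, sweeps = "none")
  sim <- simulateNeutral(cfg)
  pm <- data.frame(sample = paste0("s", seq_along(sim$demeOfSample)),
                   site = paste0("d", sim$demeOfSample),
                   population = paste0("d", sim$demeOfSample))
  hap <- HaplotypeSet(sim$haplotypes, sim$variants, pm$sample, TRUE, pm)
  fst <- pairwiseFst(hap, by = "site")
  sep <- abs(outer(1:6, 1:6, "-"))
  ut <- upper.tri(fst)
  expect_gt(cor(fst[ut], sep[ut], method = "spearman"), 0.7)
})
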