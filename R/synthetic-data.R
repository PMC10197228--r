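#' Simulation configuration for the synthetic study system
#'
#' Describes a one-dimensional stepping-stone system of demes sampled along
#' a latitudinal sea-surface-temperature gradient, with planted hard sweeps
#' and environment-correlated loci. Defaults give 12 demes of 5 diploid
#' samples (grouped into 3 populations of 4 demes), 4 chromosomes of 5 Mb
#' carrying 40,000 SNPs, and 10 sweeps per extreme population.
#'
#' @param nDemes number of demes (= sampling sites) along the coast
#' @param samplesPerDeme diploid samples per deme
#' @param nChrom,chromLengthBp chromosome count and length
#' @param nSnps total SNP count (split evenly across chromosomes)
#' @param migrationRate symmetric nearest-neighbour migration rate m
#' @param demeSize diploid deme size N (drift intensity; haplotype pool 2N)
#' @param generations forward generations of binomial drift
#' @param sweeps data.frame of sweep specs: `chrom` (index), `centerBp`,
#'   `halfWidthBp`, `side` ("A" = northern population, "B" = southern),
#'   `q0` (carrier fraction), `decayBp` (identity-decay scale r). NULL for
#'   the default layout, `none` for none.
#' @param envLoci data.frame of environment-associated loci: `snp` (index)
#'   and `slope` (frequency range across the standardized SST_max gradient);
#'   NULL for the default 5 loci
#' @param latRange latitude span of the demes (degrees N, south to north)
#' @param lonBase baseline longitude (degrees E)
#' @param sstYears years of daily SST to emit
#' @param cellKm coast raster cell size (km)
#' @param seed RNG seed; the whole bundle is a deterministic function of it
#' @return list of class `simConfig`
#' @export
simConfig <- function(nDemes = 12L, samplesPerDeme = 5L, nChrom = 4L,
                      chromLengthBp = 5e6, nSnps = 40000L,
                      migrationRate = 0.1, demeSize = 50L,
                      generations = 150L, sweeps = NULL, envLoci = NULL,
                      latRange = c(21, 39), lonBase = 112, sstYears = 40L,
                      cellKm = 10, seed = 1L) {
  .assert(migrationRate >= 0 && migrationRate <= 0.5,
          "migration rate must lie in [0, 0.5]")
  if (is.null(sweeps)) {
    # 5 sweeps per chromosome, alternating sides (10 + 10 at the 4-chromosome
    # default); centers sit at fixed genome fractions so any chromosome
    # length gets a valid layout
    centers <- seq(0.14, 0.86, length.out = 5) * chromLengthBp
    sweeps <- do.call(rbind, lapply(seq_len(nChrom), function(ch) {
      side <- if (ch %% 2L == 1L) c("A", "B", "A", "B", "A")
              else c("B", "A", "B", "A", "B")
      data.frame(chrom = ch, centerBp = centers, halfWidthBp = 25000,
                 side = side, q0 = 0.9, decayBp = 50000)
    }))
  } else if (identical(sweeps, "none")) {
    sweeps <- data.frame(chrom = integer(), centerBp = numeric(),
                         halfWidthBp = numeric(), side = character(),
                         q0 = numeric(), decayBp = numeric())
  }
  .assert(all(sweeps$centerBp - sweeps$halfWidthBp >= 1) &&
            all(sweeps$centerBp + sweeps$halfWidthBp <= chromLengthBp),
          "sweep intervals must lie within chromosome bounds")
  .assert(all(sweeps$q0 > 0 & sweeps$q0 <= 1), "q0 must lie in (0, 1]")
  if (is.null(envLoci)) {
    envLoci <- data.frame(snp = round(seq(0.11, 0.91, length.out = 5) * nSnps),
                          slope = 0.85)
  }
  structure(list(nDemes = as.integer(nDemes),
                 samplesPerDeme = as.integer(samplesPerDeme),
                 nChrom = as.integer(nChrom), chromLengthBp = chromLengthBp,
                 nSnps = as.integer(nSnps), migrationRate = migrationRate,
                 demeSize = as.integer(demeSize),
                 generations = as.integer(generations),
                 sweeps = sweeps, envLoci = envLoci, latRange = latRange,
                 lonBase = lonBase, sstYears = as.integer(sstYears),
                 cellKm = cellKm, seed = as.integer(seed)),
            class = "simConfig")
}

# deme -> population labels: thirds along the gradient; population A (BH-like)
# is the northern third (highest deme indices), B (BB-like) the southern.
.demePopulations <- function(nDemes) {
  third <- ceiling(nDemes / 3)
  pop <- rep("IM", nDemes)
  pop[seq_len(third)] <- "BB"
  pop[(nDemes - third + 1):nDemes] <- "BH"
  pop
}

#' Neutral stepping-stone forward simulation
#'
#' Ancestral frequencies are drawn from Beta(0.8, 0.8) clamped to
#' (0.02, 0.98), then drift for `generations` generations of binomial
#' sampling (2N draws per deme) with symmetric nearest-neighbour migration.
#' Sampled haplotypes are copied from a per-deme pool of 2N haplotypes,
#' which induces background identity between samples that share a pool
#' haplotype.
#'
#' @param config a [simConfig()]
#' @return list with `freq` (deme x SNP final frequencies), `haplotypes`
#'   (2 * total samples x SNP 0/1 matrix, demes in order), `demeOfSample`,
#'   `variants` (data.frame chrom/pos/ref/alt)
#' @export
simulateNeutral <- function(config) {
  set.seed(config$seed)
  D <- config$nDemes; L <- config$nSnps
  N2 <- 2L * config$demeSize
  m <- config$migrationRate
  p0 <- pmin(pmax(rbeta(L, 0.8, 0.8), 0.02), 0.98)
  freq <- matrix(rep(p0, each = D), nrow = D)
  for (g in seq_len(config$generations)) {
    if (D > 1L && m > 0) {
      up <- freq[c(2:D, D), , drop = FALSE]
      dn <- freq[c(1, 1:(D - 1)), , drop = FALSE]
      freq <- (1 - m) * freq + (m / 2) * (up + dn)
    }
    freq <- matrix(rbinom(D * L, N2, as.vector(freq)) / N2, nrow = D)
  }
  # env-correlated loci: overwrite final frequencies with a latitudinal cline
  lat <- seq(config$latRange[1], config$latRange[2], length.out = D)
  grad <- (lat - mean(lat)) / (diff(range(lat)) / 2)  # -1 .. 1
  for (r in seq_len(nrow(config$envLoci))) {
    s <- config$envLoci$snp[r]
    half <- config$envLoci$slope[r] / 2
    freq[, s] <- pmin(pmax(0.5 + half * grad, 0.02), 0.98)
  }
  # sample haplotypes through per-deme pools of 2N haplotypes
  nPerDeme <- 2L * config$samplesPerDeme
  hap <- matrix(0L, nrow = D * nPerDeme, ncol = L)
  for (d in seq_len(D)) {
    pool <- matrix(rbinom(N2 * L, 1L, rep(freq[d, ], each = N2)),
                   nrow = N2)
    rows <- sample.int(N2, nPerDeme, replace = FALSE)
    hap[(d - 1L) * nPerDeme + seq_len(nPerDeme), ] <- pool[rows, ]
    rm(pool)
  }
  perChrom <- L / config$nChrom
  .assert(perChrom == floor(perChrom), "nSnps must be divisible by nChrom")
  posAll <- unlist(lapply(seq_len(config$nChrom), function(ch) {
    sort(sample.int(config$chromLengthBp - 2L, perChrom)) + 1L
  }))
  variants <- data.frame(chrom = rep(paste0("chr", seq_len(config$nChrom)),
                                     each = perChrom),
                         pos = posAll,
                         ref = "A", alt = "T")
  list(freq = freq, haplotypes = hap,
       demeOfSample = rep(seq_len(D), each = config$samplesPerDeme),
       variants = variants)
}

#' Plant a hard sweep into target-deme haplotypes
#'
#' In the target demes a fraction `q0` of haplotypes is replaced by copies
#' of one randomly chosen core haplotype; each copied site keeps the core
#' allele with probability `exp(-d / r)` (d = distance from the sweep
#' center) and is otherwise redrawn from the deme frequency, so haplotype
#' identity and diversity loss decay away from the center.
#'
#' @param hap haplotype matrix (rows = haplotypes of all demes, in deme order)
#' @param demeOfHap deme index per haplotype row
#' @param targetDemes deme indices carrying the sweep
#' @param snpSel SNP column indices on the sweep chromosome
#' @param pos bp positions of those SNPs
#' @param centerBp sweep center
#' @param q0 carrier fraction
#' @param decayBp identity-decay scale r
#' @param freqRow per-deme frequency rows (deme x SNP, for redraws)
#' @param qByDeme optional per-deme carrier fractions (named by deme index or
#'   a vector over all demes); overrides `q0`/`targetDemes` to plant a graded,
#'   environment-driven sweep whose strength follows a cline
#' @return modified haplotype matrix
#' @export
plantSweep <- function(hap, demeOfHap, targetDemes, snpSel, pos, centerBp,
                       q0, decayBp, freqRow, qByDeme = NULL) {
  demes <- sort(unique(demeOfHap))
  qd <- setNames(rep(0, length(demes)), demes)
  if (is.null(qByDeme)) {
    qd[as.character(targetDemes)] <- q0
  } else {
    qd[as.character(seq_along(qByDeme))] <- qByDeme
  }
  totCarrier <- sum(vapply(demes, function(d)
    round(qd[as.character(d)] * sum(demeOfHap == d)), 0))
  .assert(totCarrier >= 2, "carrier fraction x haplotype count < 2: no detectable sweep")
  active <- which(demeOfHap %in% demes[qd[as.character(demes)] > 0])
  core <- hap[sample(active, 1L), snpSel]
  keepProb <- exp(-abs(pos - centerBp) / decayBp)
  for (d in demes) {
    qdd <- qd[as.character(d)]
    if (qdd <= 0) next
    rows <- which(demeOfHap == d)
    carriers <- sample(rows, round(qdd * length(rows)))
    for (h in carriers) {
      keep <- runif(length(snpSel)) < keepProb
      redraw <- rbinom(length(snpSel), 1L, freqRow[d, snpSel])
      hap[h, snpSel] <- ifelse(keep, core, redraw)
    }
  }
  hap
}

#' Synthetic coastal environment: site coordinates, daily SST, coast raster
#'
#' Demes sit on a wiggly coastline polyline with monotone latitude. Daily
#' SST follows a seasonal sinusoid whose mean decreases and whose amplitude
#' increases with latitude, so the winter (annual-minimum) spread across
#' sites exceeds the summer (annual-maximum) spread — the asymmetry typical
#' of the north-west Pacific margin. Per-site offsets add local, gradient-
#' independent variation, and the coast raster is a water corridor along the
#' polyline.
#'
#' @param config a [simConfig()]
#' @return list with `sites` (site/lat/lon + coastPos km), `sst` (long
#'   data.frame site/date/sst), `env` (per-site climatology), `grid`
#'   (a [coastGrid()])
#' @export
makeEnvironment <- function(config) {
  set.seed(config$seed + 1L)
  D <- config$nDemes
  lat <- seq(config$latRange[1], config$latRange[2], length.out = D)
  # coastline wiggle: longitude excursions make D_csl exceed D_lat
  lon <- config$lonBase + 3 * sin(seq(0, 2.5 * pi, length.out = D)) +
    seq(0, 5, length.out = D)
  sites <- data.frame(site = paste0("S", sprintf("%02d", seq_len(D))),
                      lat = lat, lon = lon)

  meanSst <- 21.5 - (7 / 18) * (lat - 21) + rnorm(D, 0, 0.5)
  ampSst <- 6.5 + (6 / 18) * (lat - 21) + rnorm(D, 0, 0.4)
  dates <- seq(as.Date("1971-01-01"), by = "day",
               length.out = ceiling(config$sstYears * 365.25))
  t <- as.numeric(dates - dates[1])
  sst <- do.call(rbind, lapply(seq_len(D), function(d) {
    vals <- meanSst[d] - ampSst[d] * cos(2 * pi * (t - 30) / 365.25) +
      rnorm(length(t), 0, 0.8)
    data.frame(site = sites$site[d], date = dates, sst = vals)
  }))
  env <- do.call(rbind, lapply(split(sst, sst$site), function(s)
    as.data.frame(as.list(sstClimatology(s$date, s$sst)))))
  env <- data.frame(site = rownames(env), env, row.names = NULL)

  # coast corridor raster along the site polyline
  kmPerDeg <- 2 * pi * EARTH_RADIUS_KM / 360
  lat0 <- min(lat) - 1; lon0 <- min(lon) - 1
  latRef <- mean(lat)
  x <- (lon - lon0) * kmPerDeg * cos(latRef * pi / 180)
  y <- (lat - lat0) * kmPerDeg
  cell <- config$cellKm
  nr <- ceiling(max(y) / cell) + 3L
  ncl <- ceiling(max(x) / cell) + 3L
  mask <- matrix(FALSE, nr, ncl)
  for (d in seq_len(D - 1L)) {
    nstep <- 200L
    xs <- seq(x[d], x[d + 1], length.out = nstep)
    ys <- seq(y[d], y[d + 1], length.out = nstep)
    r <- pmin(pmax(1L, as.integer(floor(ys / cell)) + 1L), nr)
    c2 <- pmin(pmax(1L, as.integer(floor(xs / cell)) + 1L), ncl)
    for (k in seq_len(nstep)) {
      rr <- max(1L, r[k] - 1L):min(nr, r[k] + 1L)
      cc <- max(1L, c2[k] - 1L):min(ncl, c2[k] + 1L)
      mask[rr, cc] <- TRUE
    }
  }
  grid <- coastGrid(mask, cell, lat0, lon0, latRef)
  # arc-length position of each site along the coast polyline (km)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  sites$coastPos <- c(0, cumsum(seg))
  list(sites = sites, sst = sst, env = env, grid = grid)
}

#' Generate the full synthetic input bundle
#'
#' Runs the neutral simulation, plants the configured sweeps and
#' environmental clines, generates the coastal environment, and writes every
#' file the analysis modules read: phased VCF, population map TSV, site TSV,
#' per-site daily SST CSV, coast raster, GFF3 gene models (one gene inside
#' each sweep plus a neutral background set), and a JSON truth table.
#'
#' @param config a [simConfig()]
#' @param dir output directory (created if needed)
#' @return invisible list: `paths` (emitted files), `truth`, `hap`
#'   (the in-memory [HaplotypeSet-class]) and `env`
#' @export
emitBundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateNeutral(config)
  pops <- .demePopulations(config$nDemes)
  env <- makeEnvironment(config)

  # plant sweeps (RNG continues from simulateNeutral/makeEnvironment seeds)
  set.seed(config$seed + 2L)
  demeOfHap <- rep(sim$demeOfSample, each = 2L)
  targetA <- which(pops == "BH"); targetB <- which(pops == "BB")
  v <- sim$variants
  sweeps <- config$sweeps
  if (nrow(sweeps)) {
    # environment-driven sweeps: carrier fraction follows the (realized)
    # winter-SST cline instead of a population block
    sstOrd <- env$env$sstMin[match(env$sites$site, env$env$site)]
    cline01 <- (rank(sstOrd) - 1) / (length(sstOrd) - 1)
    for (r in seq_len(nrow(sweeps))) {
      chromName <- paste0("chr", sweeps$chrom[r])
      onCh <- which(v$chrom == chromName)
      sel <- onCh[abs(v$pos[onCh] - sweeps$centerBp[r]) <=
                    3 * sweeps$decayBp[r] + sweeps$halfWidthBp[r]]
      .assert(length(sel) >= 10, "sweep interval contains fewer than 10 SNPs")
      target <- if (sweeps$side[r] == "A") targetA else targetB
      qBy <- NULL
      if (isTRUE(sweeps$envDriven[r])) {
        qBy <- if (sweeps$side[r] == "A") sweeps$q0[r] * (1 - cline01)
               else sweeps$q0[r] * cline01
      }
      sim$haplotypes <- plantSweep(sim$haplotypes, demeOfHap, target, sel,
                                   v$pos[sel], sweeps$centerBp[r],
                                   sweeps$q0[r], sweeps$decayBp[r], sim$freq,
                                   qByDeme = qBy)
    }
  }

  D <- config$nDemes
  sampleIds <- paste0(rep(env$sites$site, each = config$samplesPerDeme), "_",
                      sequence(rep(config$samplesPerDeme, D)))
  popMap <- data.frame(sample = sampleIds,
                       site = rep(env$sites$site, each = config$samplesPerDeme),
                       population = rep(pops, each = config$samplesPerDeme))
  hap <- HaplotypeSet(sim$haplotypes, v, sampleIds, TRUE, popMap)

  # gene models: one 10 kb gene centered in each sweep + neutral background
  geneRows <- list()
  if (nrow(sweeps)) {
    for (r in seq_len(nrow(sweeps))) {
      geneRows[[length(geneRows) + 1L]] <- data.frame(
        chrom = paste0("chr", sweeps$chrom[r]),
        start = sweeps$centerBp[r] - 5000, end = sweeps$centerBp[r] + 5000,
        id = sprintf("sweepgene_%02d", r), strand = "+")
    }
  }
  nNeutralGenes <- max(10L, 3L * config$nChrom)
  for (g in seq_len(nNeutralGenes)) {
    ch <- ((g - 1L) %% config$nChrom) + 1L
    st <- 150000 + (g - 1L) %/% config$nChrom * 950000
    ok <- !nrow(sweeps) ||
      all(sweeps$chrom != ch |
            abs(sweeps$centerBp - (st + 5000)) > sweeps$halfWidthBp + 120000)
    if (!ok) st <- st + 450000
    geneRows[[length(geneRows) + 1L]] <- data.frame(
      chrom = paste0("chr", ch), start = st, end = st + 10000,
      id = sprintf("bggene_%02d", g), strand = "-")
  }
  genes <- do.call(rbind, geneRows)

  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    popmap = file.path(dir, "popmap.tsv"),
    sites = file.path(dir, "sites.tsv"),
    sst = file.path(dir, "sst_daily.csv"),
    coast = file.path(dir, "coast_grid.txt"),
    gff = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.json")
  )
  writeVcfGenotypes(hap, paths$vcf)
  write.table(popMap, paths$popmap, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(env$sites, paths$sites, sep = "\t", quote = FALSE,
              row.names = FALSE)
  utils::write.csv(env$sst, paths$sst, row.names = FALSE, quote = FALSE)
  writeCoastGrid(env$grid, paths$coast)
  gffLines <- c("##gff-version 3",
                sprintf("%s\tselscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        genes$chrom, as.integer(genes$start),
                        as.integer(genes$end), genes$strand, genes$id))
  writeLines(gffLines, paths$gff)

  truth <- list(
    sweeps = cbind(sweeps,
                   startBp = sweeps$centerBp - sweeps$halfWidthBp,
                   endBp = sweeps$centerBp + sweeps$halfWidthBp),
    envLoci = data.frame(config$envLoci,
                         chrom = v$chrom[config$envLoci$snp],
                         pos = v$pos[config$envLoci$snp]),
    demeFreqEnvLoci = sim$freq[, config$envLoci$snp, drop = FALSE],
    populations = data.frame(site = env$sites$site, population = pops),
    seed = config$seed
  )
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  invisible(list(paths = paths, truth = truth, hap = hap, env = env))
}

#' Read the truth table emitted by [emitBundle()]
#'
#' @param path truth.json path
#' @return list with `sweeps`, `envLoci`, `populations` data.frames
#' @export
readSimTruth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$sweeps <- as.data.frame(tr$sweeps)
  tr$envLoci <- as.data.frame(tr$envLoci)
  tr$populations <- as.data.frame(tr$populations)
  tr
}
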