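#' Default pipeline configuration
#'
#' Nested keys mirror the stage modules: `window` (size/step), `psr`
#' (percentile, maxGap), `gea` (bfThresholdDb, rdaAlpha, geneRadiusBp),
#' `ibdibe` (gdmPerm, bootstraps), `sim` (arguments to [simConfig()]).
#' Values supplied in `override` replace defaults key by key.
#'
#' @param override named list of overrides (possibly nested)
#' @return validated config list
#' @export
pipelineConfig <- function(override = list()) {
  cfg <- list(
    window = list(size = 50000, step = 10000),
    psr = list(percentile = 0.95, maxGap = 0),
    gea = list(bfThresholdDb = 20, rdaAlpha = 0.001, geneRadiusBp = 5000),
    ibdibe = list(gdmPerm = 200, bootstraps = 200),
    sim = list(),
    seed = 1L
  )
  mergeInto <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(over[[k]]) && is.list(base[[k]]))
        mergeInto(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- mergeInto(cfg, override)
  .assert(cfg$psr$percentile > 0 && cfg$psr$percentile < 1,
          "psr.percentile must lie in (0, 1)")
  .assert(cfg$window$step <= cfg$window$size && cfg$window$size > 0,
          "window step must be positive and <= size")
  .assert(cfg$gea$rdaAlpha > 0 && cfg$gea$rdaAlpha < 1,
          "gea.rdaAlpha must lie in (0, 1)")
  cfg
}

# load the bundle files of a simulate stage
.loadBundle <- function(dir) {
  pm <- readPopMap(file.path(dir, "popmap.tsv"))
  hap <- readVcfGenotypes(file.path(dir, "genotypes.vcf"), pm)
  sites <- read.delim(file.path(dir, "sites.tsv"), stringsAsFactors = FALSE)
  sst <- readSstSeries(file.path(dir, "sst_daily.csv"))
  grid <- readCoastGrid(file.path(dir, "coast_grid.txt"))
  genes <- readGeneModels(file.path(dir, "genes.gff3"))
  env <- do.call(rbind, lapply(split(sst, sst$site), function(s)
    as.data.frame(as.list(sstClimatology(s$date, s$sst)))))
  env <- data.frame(site = rownames(env), env, row.names = NULL)
  list(hap = hap, sites = sites, env = env, grid = grid, genes = genes)
}

#' Run the analysis pipeline
#'
#' Stages communicate only through files under `outdir`: `simulate` writes
#' the synthetic bundle, `scan` the window statistics / CSS / PSR / PSG
#' tables, `gea` the candidate-SNP table, `ibdibe` the site-pair fits, and
#' `report` one aggregated JSON (including planted-sweep recall whenever a
#' truth table is present). `all` runs everything in order. Reruns with the
#' same config and seed produce identical artifacts.
#'
#' @param stage one of `"simulate"`, `"scan"`, `"gea"`, `"ibdibe"`,
#'   `"report"`, `"all"`
#' @param outdir output directory
#' @param config overrides merged by [pipelineConfig()]; alternatively a YAML
#'   file path
#' @param verbose log stage progress
#' @return invisible list of in-memory stage results
#' @export
runPipeline <- function(stage = c("all", "simulate", "scan", "gea", "ibdibe",
                                  "report"),
                        outdir, config = list(), verbose = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- pipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(outdir, "config.json")
  jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA)
  bundleDir <- file.path(outdir, "bundle")
  res <- list(config = cfg)
  stages <- if (stage == "all")
    c("simulate", "scan", "gea", "ibdibe", "report") else stage

  if ("simulate" %in% stages) {
    .msg(verbose, "stage simulate")
    sc <- do.call(simConfig, c(cfg$sim, list(seed = cfg$seed)))
    res$bundle <- emitBundle(sc, bundleDir)
  }
  needData <- any(c("scan", "gea", "ibdibe") %in% stages)
  if (needData) {
    .assert(file.exists(file.path(bundleDir, "genotypes.vcf")),
            "missing input: ", file.path(bundleDir, "genotypes.vcf"))
    dat <- .loadBundle(bundleDir)
  }

  if ("scan" %in% stages) {
    .msg(verbose, "stage scan")
    ws <- windowSpec(cfg$window$size, cfg$window$step)
    win <- windowStats(dat$hap, "BH", "BB", ws)
    df <- as.data.frame(mcols(win))
    df$absOmega <- abs(df$omega); df$absRsb <- abs(df$rsbMean)
    css <- cssScore(df)
    mcols(win)$css <- css$css
    psr <- callPsrs(win, cfg$psr$percentile, cfg$psr$maxGap)
    psgA <- callPsgs(psr$A, dat$genes)
    psgB <- callPsgs(psr$B, dat$genes)
    writeWindowStats(win, file.path(outdir, "windows.tsv"))
    writeRegions(psr$A, file.path(outdir, "psr_A.bed"),
                 file.path(outdir, "psr_A.tsv"))
    writeRegions(psr$B, file.path(outdir, "psr_B.bed"),
                 file.path(outdir, "psr_B.tsv"))
    writeLines(psgA, file.path(outdir, "psg_A.txt"))
    writeLines(psgB, file.path(outdir, "psg_B.txt"))
    anova <- tryCatch(comparePsrStrength(win, psr$A, psr$B, css = css$css),
                      error = function(e) NULL)
    if (!is.null(anova))
      write.table(anova, file.path(outdir, "psr_anova.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    res$scan <- list(windows = win, psr = psr, psgA = psgA, psgB = psgB,
                     anova = anova)
  }

  if ("gea" %in% stages) {
    .msg(verbose, "stage gea")
    fr <- popFreqs(dat$hap, by = "site")
    om <- popCovariance(fr$freq)
    envOrd <- dat$env[match(rownames(fr$freq), dat$env$site), ]
    bf <- cbind(sstMax = bayesFactor(fr$freq, envOrd$sstMax, om),
                sstMin = bayesFactor(fr$freq, envOrd$sstMin, om))
    perSample <- dat$env[match(popMap(dat$hap)$site, dat$env$site),
                         c("sstMax", "sstMin")]
    rda <- rdaOutliers(dat$hap, perSample)
    cand <- intersectCandidates(bf, rda$p, cfg$gea$bfThresholdDb,
                                cfg$gea$rdaAlpha)
    v <- variants(dat$hap)
    tab <- data.frame(chrom = as.character(seqnames(v)), pos = start(v),
                      bfSstMax = bf[, 1], bfSstMin = bf[, 2],
                      rdaP = rda$p, cand)
    write.table(tab, file.path(outdir, "gea_candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    nearGenes <- genesNearSnps(v[cand$candidate], dat$genes,
                               cfg$gea$geneRadiusBp)
    writeLines(nearGenes, file.path(outdir, "gea_genes.txt"))
    res$gea <- list(table = tab, genes = nearGenes)
  }

  if ("ibdibe" %in% stages) {
    .msg(verbose, "stage ibdibe")
    set.seed(cfg$seed + 11L)
    pairs <- pairPredictors(dat$sites, dat$env, dat$grid)
    fst <- pairwiseFst(dat$hap, by = "site")
    pairs <- addGdist(pairs, fst)
    write.table(pairs, file.path(outdir, "site_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    preds <- c("dGcc", "dCsl", "dLat", "dSstMax", "dSstMed", "dSstMin")
    ols <- lapply(preds, function(p) singleFactorOls(pairs, p))
    names(ols) <- preds
    olsTab <- data.frame(predictor = preds,
                         r2 = vapply(ols, `[[`, 0, "r2"),
                         adjR2 = vapply(ols, `[[`, 0, "adjR2"),
                         p = vapply(ols, `[[`, 0, "modelP"),
                         logLik = vapply(ols, `[[`, 0, "logLik"),
                         aic = vapply(ols, `[[`, 0, "aic"),
                         bic = vapply(ols, `[[`, 0, "bic"))
    write.table(olsTab, file.path(outdir, "ols_single_factor.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rls <- rlsFit(pairs, preds)
    comm <- commonalityAnalysis(pairs, preds, nBoot = cfg$ibdibe$bootstraps)
    siteData <- data.frame(site = dat$sites$site,
                           coastPos = dat$sites$coastPos,
                           latKm = latitudeDistance(0, dat$sites$lat),
                           sstMax = dat$env$sstMax[
                             match(dat$sites$site, dat$env$site)],
                           sstMed = dat$env$sstMed[
                             match(dat$sites$site, dat$env$site)],
                           sstMin = dat$env$sstMin[
                             match(dat$sites$site, dat$env$site)])
    gdmPreds <- c("coastPos", "latKm", "sstMax", "sstMed", "sstMin")
    gdm <- gdmFit(siteData, pairs, gdmPreds, nPerm = cfg$ibdibe$gdmPerm)
    contrast <- NULL
    psrA <- file.path(outdir, "psr_A.tsv")
    if (file.exists(psrA)) {
      regs <- .readRegionsTsv(psrA)
      regsB <- .readRegionsTsv(file.path(outdir, "psr_B.tsv"))
      allRegs <- suppressWarnings(c(regs, regsB))
      if (length(allRegs) > 0)
        contrast <- gdmRegionContrast(dat$hap, allRegs, siteData, gdmPreds)
    }
    jsonlite::write_json(
      list(gdm = list(devExplained = gdm$devExplained,
                      maxHeight = as.list(gdm$maxHeight),
                      importance = as.list(gdm$importance),
                      permP = as.list(gdm$permP)),
           rls = list(lasso = rls$lasso$coefficients,
                      elasticNet = rls$elasticNet$coefficients),
           commonality = comm$stats,
           contrast = if (!is.null(contrast)) list(
                        psrMaxHeight = as.list(contrast$psr$maxHeight),
                        nonPsrMaxHeight = as.list(contrast$nonPsr$maxHeight))),
      file.path(outdir, "ibdibe.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns")
    res$ibdibe <- list(pairs = pairs, ols = ols, rls = rls,
                       commonality = comm, gdm = gdm, contrast = contrast)
  }

  if ("report" %in% stages) {
    .msg(verbose, "stage report")
    res$report <- .buildReport(outdir, bundleDir)
    jsonlite::write_json(res$report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

.readRegionsTsv <- function(path) {
  if (!file.exists(path)) return(GRanges())
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(GRanges())
  GRanges(df$chrom, IRanges(df$start, df$end))
}

# recall / side accuracy of called regions against the planted truth
.sweepRecovery <- function(truth, regionsA, regionsB) {
  sw <- truth$sweeps
  gr <- GRanges(paste0("chr", sw$chrom), IRanges(sw$startBp, sw$endBp))
  hitA <- IRanges::overlapsAny(gr, regionsA)
  hitB <- IRanges::overlapsAny(gr, regionsB)
  isA <- sw$side == "A"
  recallA <- mean(hitA[isA])
  recallB <- mean(hitB[!isA])
  # side accuracy: called regions overlapping a planted sweep must match side
  regSide <- c(rep("A", length(regionsA)), rep("B", length(regionsB)))
  regs <- suppressWarnings(c(regionsA, regionsB))
  ov <- GenomicRanges::findOverlaps(regs, gr)
  ok <- regSide[S4Vectors::queryHits(ov)] == sw$side[S4Vectors::subjectHits(ov)]
  list(recallA = recallA, recallB = recallB,
       sideAccuracy = if (length(ok)) mean(ok) else NA_real_,
       nRegionsA = length(regionsA), nRegionsB = length(regionsB))
}

.buildReport <- function(outdir, bundleDir) {
  rep <- list()
  truthPath <- file.path(bundleDir, "truth.json")
  regsA <- .readRegionsTsv(file.path(outdir, "psr_A.tsv"))
  regsB <- .readRegionsTsv(file.path(outdir, "psr_B.tsv"))
  if (file.exists(truthPath) && (length(regsA) || length(regsB))) {
    truth <- readSimTruth(truthPath)
    rep$sweepRecovery <- .sweepRecovery(truth, regsA, regsB)
    psgA <- readLines(file.path(outdir, "psg_A.txt"))
    psgB <- readLines(file.path(outdir, "psg_B.txt"))
    sweepGenes <- sprintf("sweepgene_%02d", seq_len(nrow(truth$sweeps)))
    recovered <- IRanges::overlapsAny(
      GRanges(paste0("chr", truth$sweeps$chrom),
              IRanges(truth$sweeps$startBp, truth$sweeps$endBp)),
      suppressWarnings(c(regsA, regsB)))
    rep$psgRecall <- if (any(recovered))
      mean(sweepGenes[recovered] %in% c(psgA, psgB)) else NA_real_
  }
  geaPath <- file.path(outdir, "gea_candidates.tsv")
  if (file.exists(geaPath)) {
    gea <- read.delim(geaPath)
    rep$gea <- list(nCandidates = sum(gea$candidate),
                    nBfHits = sum(gea$bfHit), nRdaHits = sum(gea$rdaHit))
  }
  ibPath <- file.path(outdir, "ibdibe.json")
  if (file.exists(ibPath))
    rep$ibdibe <- jsonlite::read_json(ibPath, simplifyVector = TRUE)
  winPath <- file.path(outdir, "windows.tsv")
  if (file.exists(winPath)) {
    w <- read.delim(winPath)
    rep$scan <- list(nWindows = nrow(w),
                     meanFst = mean(w$fst, na.rm = TRUE),
                     meanPiA = mean(w$piA), meanPiB = mean(w$piB))
  }
  rep$provenance <- list(
    configMd5 = unname(tools::md5sum(file.path(outdir, "config.json"))),
    package = as.character(utils::packageVersion("selscape")))
  rep
}
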