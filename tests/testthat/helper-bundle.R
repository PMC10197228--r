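# Shared end-to-end fixture: the default synthetic bundle (12 demes x 5
# samples, 4 x 5 Mb, 40k SNPs, 10 + 10 planted sweeps) run through the whole
# pipeline once and cached for the session; several recovery tests read it.
.bundleCache <- new.env(parent = emptyenv())

defaultBundleRun <- function() {
  if (is.null(.bundleCache$run)) {
    dir <- file.path(tempdir(), "selscape-default-bundle")
    .bundleCache$run <- runPipeline("all", outdir = dir,
                                    config = list(seed = 101L))
    .bundleCache$dir <- dir
    .bundleCache$truth <- readSimTruth(file.path(dir, "bundle", "truth.json"))
  }
  list(res = .bundleCache$run, dir = .bundleCache$dir,
       truth = .bundleCache$truth)
}

# same scale but with environment-driven (graded) sweeps: carrier fraction
# follows the winter-SST cline, the condition under which selected regions
# carry an expanded environmental signal
envBundleRun <- function() {
  if (is.null(.bundleCache$envRun)) {
    dir <- file.path(tempdir(), "selscape-env-bundle")
    sweeps <- do.call(rbind, lapply(1:4, function(ch) {
      side <- if (ch %% 2 == 1) c("A", "B", "A", "B", "A")
              else c("B", "A", "B", "A", "B")
      data.frame(chrom = ch,
                 centerBp = seq(0.14, 0.86, length.out = 5) * 5e6,
                 halfWidthBp = 25000, side = side, q0 = 0.9,
                 decayBp = 50000, envDriven = TRUE)
    }))
    .bundleCache$envRun <- runPipeline("all", outdir = dir,
                                       config = list(seed = 202L,
                                                     sim = list(sweeps = sweeps)))
  }
  .bundleCache$envRun
}

# small, fast bundle for plumbing tests
smallSimConfig <- function(seed = 7L, sweeps = NULL) {
  if (is.null(sweeps))
    sweeps <- data.frame(chrom = c(1, 2), centerBp = 5e5, halfWidthBp = 25000,
                         side = c("A", "B"), q0 = 0.9, decayBp = 50000)
  simConfig(nDemes = 6, samplesPerDeme = 5, nChrom = 2, chromLengthBp = 1e6,
            nSnps = 2000, sweeps = sweeps,
            envLoci = data.frame(snp = c(500, 1500), slope = 0.85),
            sstYears = 3, seed = seed)
}
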