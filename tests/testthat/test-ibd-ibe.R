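# shared toy pair table: n sites on a line with two informative predictors
linePairs <- function(S, seed, noise = 0.05) {
  set.seed(seed)
  sd0 <- data.frame(site = sprintf("S%02d", 1:S),
                    coastPos = sort(runif(S, 0, 1000)),
                    sstMin = sort(runif(S, 2, 15)) + rnorm(S, 0, 0.5))
  idx <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  pairs <- data.frame(site1 = sd0$site[idx[, 1]], site2 = sd0$site[idx[, 2]])
  pairs$dCsl <- abs(sd0$coastPos[idx[, 1]] - sd0$coastPos[idx[, 2]])
  pairs$dSstMin <- abs(sd0$sstMin[idx[, 1]] - sd0$sstMin[idx[, 2]])
  list(siteData = sd0, pairs = pairs, idx = idx)
}

test_that("linearized genetic distance follows FST/(1-FST) and is monotone", {
  expect_equal(linearizedGdist(0), 0)
  expect_equal(linearizedGdist(0.5), 1)
  x <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(linearizedGdist(x)) > 0))
  expect_error(linearizedGdist(1), "infinite")
})

test_that("single-factor OLS: exact fit, null calibration, IC closed forms", {
  lp <- linePairs(10, seed = 91)
  pairs <- lp$pairs
  pairs$gdist <- 0.3 + 0.002 * pairs$dCsl
  fit <- singleFactorOls(pairs, "dCsl")
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(fit$sse, 1e-20)
  # AIC/BIC match the closed forms 2k - 2ll and k ln n - 2ll
  pairs$gdist <- 0.3 + 0.002 * pairs$dCsl + rnorm(nrow(pairs), 0, 0.1)
  fit2 <- singleFactorOls(pairs, "dCsl")
  lmfit <- lm(gdist ~ dCsl, data = pairs)
  ll <- as.numeric(logLik(lmfit))
  expect_equal(fit2$logLik, ll, tolerance = 1e-8)
  expect_equal(fit2$aic, 2 * 3 - 2 * ll, tolerance = 1e-8)
  expect_equal(fit2$bic, 3 * log(nrow(pairs)) - 2 * ll, tolerance = 1e-8)
  expect_lte(fit2$adjR2, fit2$r2)
  # independent predictor: p roughly uniform over replicates
  set.seed(92)
  ps <- replicate(100, {
    pr <- pairs
    pr$gdist <- rnorm(nrow(pr))
    singleFactorOls(pr, "dCsl")$modelP
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(singleFactorOls(transform(pairs, flat = 1), "flat"),
               "zero-variance")
  # AIC ordering of nested models agrees with the likelihood-ratio direction
  set.seed(190)
  for (k in 1:10) {
    pr <- pairs
    pr$gdist <- 0.002 * pr$dCsl + rnorm(nrow(pr), 0, 0.15)
    m0 <- lm(gdist ~ 1, data = pr)
    m1 <- lm(gdist ~ dCsl, data = pr)
    lrt <- anova(m0, m1)$`Pr(>F)`[2]
    fit <- singleFactorOls(pr, "dCsl")
    aic0 <- 2 * 2 - 2 * as.numeric(logLik(m0))
    if (lrt < 0.05) expect_lt(fit$aic, aic0)
  }
})

test_that("regularized regression keeps the generating predictor and honours defaults", {
  expect_equal(formals(rlsFit)$alphaMix, 0.5)
  # response generated from dCsl only; 5 noise predictors partly collinear
  okSel <- 0; okBoth <- 0
  reps <- 25
  for (k in seq_len(reps)) {
    set.seed(400 + k)
    n <- 91
    x1 <- runif(n, 0, 1)
    X <- cbind(dGcc = x1 + rnorm(n, 0, 0.3), dCsl = x1,
               dLat = x1 + rnorm(n, 0, 0.4),
               dSstMax = rnorm(n), dSstMed = rnorm(n), dSstMin = rnorm(n))
    pairs <- as.data.frame(X)
    pairs$gdist <- 2 * x1 + rnorm(n, 0, 0.3)
    fit <- rlsFit(pairs, colnames(X))
    co <- fit$elasticNet$coefficients
    if (co$estimate[co$term == "dCsl"] != 0) okSel <- okSel + 1
  }
  expect_gte(okSel / reps, 0.8)
  # two orthogonal predictors with equal effects are both retained
  set.seed(93)
  n <- 91
  Xo <- qr.Q(qr(matrix(rnorm(n * 2), n)))
  pairs2 <- data.frame(a = Xo[, 1], b = Xo[, 2])
  pairs2$gdist <- Xo[, 1] + Xo[, 2] + rnorm(n, 0, 0.05)
  fit2 <- rlsFit(pairs2, c("a", "b"))
  expect_setequal(fit2$lasso$survivors, c("a", "b"))
  # degenerate: pure-noise response with near-zero-signal predictors can
  # drop everything -> named error
  pairs3 <- data.frame(a = rep(c(0, 1), 10), b = rep(c(0, 1), each = 10))
  pairs3$gdist <- 0.0001 * rnorm(20)
  expect_error(
    tryCatch(rlsFit(pairs3, c("a", "b")), error = function(e) stop(e)),
    "no informative|singular|fewer", class = "error")
})

test_that("I-spline basis is monotone, bounded and hits 0/1 at the end knots", {
  k <- c(0, 3, 10)
  x <- seq(-1, 11, by = 0.01)
  B <- isplineBasis(x, k)
  expect_true(all(B >= 0 & B <= 1))
  expect_true(all(apply(B, 2, function(col) all(diff(col) >= -1e-12))))
  expect_equal(unname(isplineBasis(0, k)[1, ]), c(0, 0, 0))
  expect_equal(unname(isplineBasis(10, k)[1, ]), c(1, 1, 1))
})

test_that("GDM: link identity on zero differences, self-recovery, monotone surface", {
  lp <- linePairs(12, seed = 94)
  # zero predictor differences: constant fitted dissimilarity 1 - exp(-b0)
  sdc <- lp$siteData
  sdc$coastPos <- 5
  prs <- lp$pairs
  prs$gdist <- 0.4
  suppressWarnings(expect_error(gdmFit(sdc, prs, c("coastPos")), "no usable"))
  # noise-free response generated from a GDM with known splines
  sd0 <- lp$siteData
  kcs <- c(min(sd0$coastPos), median(sd0$coastPos), max(sd0$coastPos))
  kss <- c(min(sd0$sstMin), median(sd0$sstMin), max(sd0$sstMin))
  i <- lp$idx[, 1]; j <- lp$idx[, 2]
  eta <- 0.05 +
    abs(isplineBasis(sd0$coastPos, kcs)[i, ] -
          isplineBasis(sd0$coastPos, kcs)[j, ]) %*% c(0.9, 0.5, 0.2) +
    abs(isplineBasis(sd0$sstMin, kss)[i, ] -
          isplineBasis(sd0$sstMin, kss)[j, ]) %*% c(0.1, 0.2, 0.1)
  pairs <- lp$pairs
  pairs$gdist <- as.numeric(1 - exp(-eta))
  fit <- gdmFit(sd0, pairs, c("coastPos", "sstMin"), nPerm = 30)
  expect_gt(fit$devExplained, 99)
  expect_gt(fit$maxHeight["coastPos"], fit$maxHeight["sstMin"])
  expect_true(all(fit$coefficients >= 0))
  expect_true(all(fit$fitted >= 0 & fit$fitted < 1))
  # fitted dissimilarity never decreases along any predictor difference
  curves <- gdmSplineCurves(fit)
  for (p in unique(curves$predictor))
    expect_true(all(diff(curves$y[curves$predictor == p]) >= -1e-9))
  # null predictor: permutation p above 0.05 most of the time
  set.seed(95)
  hits <- replicate(12, {
    sdN <- sd0
    sdN$junk <- rnorm(nrow(sdN))
    fitN <- gdmFit(sdN, pairs, c("coastPos", "junk"), nPerm = 60)
    fitN$permP["junk"] > 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("commonality analysis: identities, single-predictor edge case, CIs", {
  lp <- linePairs(10, seed = 96)
  pairs <- lp$pairs
  set.seed(97)
  pairs$dJunk <- rnorm(nrow(pairs))
  pairs$gdist <- 0.002 * pairs$dCsl + 0.05 * pairs$dSstMin +
    rnorm(nrow(pairs), 0, 0.1)
  cm <- commonalityAnalysis(pairs, c("dCsl", "dSstMin", "dJunk"), nBoot = 0)
  expect_equal(sum(cm$components), cm$r2, tolerance = 1e-8)
  expect_equal(sum(cm$stats$relativeWeight), cm$r2, tolerance = 1e-8)
  expect_equal(cm$stats$unique + cm$stats$common,
               cm$stats$sqStructureCoef * cm$r2, tolerance = 1e-6)
  # single predictor: squared structure coefficient = 1
  cm1 <- commonalityAnalysis(pairs, "dCsl", nBoot = 0)
  expect_equal(cm1$stats$sqStructureCoef, 1, tolerance = 1e-10)
  # orthogonal predictors with equal effects: relative weights within CI,
  # pairwise difference CI covers 0
  set.seed(98)
  n <- 60
  Xo <- qr.Q(qr(matrix(rnorm(n * 2), n))) * sqrt(n)
  po <- data.frame(site1 = sprintf("a%02d", rep(1:12, 5))[1:n],
                   site2 = sprintf("b%02d", rep(1:12, each = 5))[1:n],
                   u = Xo[, 1], v = Xo[, 2])
  po$gdist <- Xo[, 1] + Xo[, 2] + rnorm(n, 0, 0.4)
  cmo <- commonalityAnalysis(po, c("u", "v"), nBoot = 150)
  expect_true(cmo$ci$relativeWeight["u", 1] <= cmo$stats$relativeWeight[2] &&
                cmo$stats$relativeWeight[2] <= cmo$ci$relativeWeight["u", 2])
  # perfectly collinear predictors are rejected
  bad <- pairs
  bad$dup <- 2 * bad$dCsl
  expect_error(commonalityAnalysis(bad, c("dCsl", "dup"), nBoot = 0),
               "perfectly correlated")
})

test_that("pairwise FST feeds gdist and region contrast splits behave", {
  cfg <- smallSimConfig(seed = 17)
  dir <- tempfile()
  b <- emitBundle(cfg, dir)
  hap <- b$hap
  fst <- pairwiseFst(hap, by = "population")
  expect_true(all(diag(fst) == 0))
  expect_equal(fst, t(fst))
  # stepping-stone layout: extremes more differentiated than neighbours
  expect_gt(fst["BH", "BB"], fst["BH", "IM"])
  expect_gt(fst["BH", "BB"], fst["IM", "BB"])
  # region contrast returns two fits; whole-genome regions equal the full fit
  sites <- b$env$sites
  envdf <- b$env$env
  siteData <- data.frame(site = sites$site, coastPos = sites$coastPos,
                         sstMin = envdf$sstMin[match(sites$site, envdf$site)])
  whole <- GRanges(c("chr1", "chr2"), IRanges(1, cfg$chromLengthBp))
  expect_error(gdmRegionContrast(hap, GRanges(), siteData,
                                 c("coastPos", "sstMin")), "empty region")
  tr <- b$truth
  regs <- GRanges(paste0("chr", tr$sweeps$chrom),
                  IRanges(tr$sweeps$startBp, tr$sweeps$endBp))
  ct <- gdmRegionContrast(hap, regs, siteData, c("coastPos", "sstMin"))
  expect_s3_class(ct$psr, "gdmFit")
  expect_s3_class(ct$nonPsr, "gdmFit")
  expect_true(all(ct$psr$fitted >= 0 & ct$psr$fitted < 1))
})
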