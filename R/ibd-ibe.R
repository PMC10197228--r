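#' Linearized genetic distance
#'
#' `FST / (1 - FST)`, applied elementwise.
#'
#' @param fst FST value(s) in `[0, 1)`
#' @return linearized distance(s)
#' @export
linearizedGdist <- function(fst) {
  .assert(all(is.na(fst) | fst < 1), "FST = 1 gives infinite distance")
  fst / (1 - fst)
}

#' Pairwise FST between sites (or populations)
#'
#' Weir-Cockerham ratio-of-sums FST computed within each chromosome and
#' averaged across chromosomes weighted by polymorphic SNP count.
#'
#' @param hap a [HaplotypeSet-class]
#' @param by `"site"` or `"population"`
#' @param snpSubset optional SNP index vector restricting the computation
#' @return symmetric matrix of FST values
#' @export
pairwiseFst <- function(hap, by = c("site", "population"), snpSubset = NULL) {
  by <- match.arg(by)
  groups <- unique(popMap(hap)[[by]])
  ch <- as.character(seqnames(variants(hap)))
  sel <- if (is.null(snpSubset)) seq_along(ch) else sort(snpSubset)
  out <- matrix(0, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_len(length(groups) - 1L)) {
    for (j in (i + 1L):length(groups)) {
      comp <- wcFstComponents(hap, groups[i], groups[j], by)
      a <- comp$a[sel]; d <- (comp$a + comp$b + comp$c)[sel]
      poly <- !is.na(comp$fst[sel])
      chs <- ch[sel]
      aSum <- tapply(a, chs, sum); dSum <- tapply(d, chs, sum)
      w <- tapply(poly, chs, sum)
      ok <- dSum > 0 & w > 0
      fst <- sum((aSum[ok] / dSum[ok]) * w[ok]) / sum(w[ok])
      out[i, j] <- out[j, i] <- fst
    }
  }
  out
}

#' Attach linearized genetic distance to a pair-predictor table
#'
#' @param pairs data.frame from [pairPredictors()]
#' @param fstMatrix site-by-site FST matrix from [pairwiseFst()]
#' @return `pairs` with a `gdist` column
#' @export
addGdist <- function(pairs, fstMatrix) {
  pairs$gdist <- linearizedGdist(
    fstMatrix[cbind(as.character(pairs$site1), as.character(pairs$site2))])
  pairs
}

# Gaussian log-likelihood / information criteria from residuals; k counts
# all estimated parameters including the error variance
.gaussIc <- function(resid, k) {
  n <- length(resid)
  rss <- sum(resid^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  list(logLik = ll, aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
       sse = rss)
}

#' Single-factor OLS of genetic distance on one predictor
#'
#' @param pairs site-pair table with a `gdist` column
#' @param predictor one predictor column name
#' @return list of class `fitReport`: `coefficients` (term/estimate/se/t/p),
#'   `r2`, `adjR2`, `logLik`, `aic`, `bic`, `modelP`, `n`
#' @export
singleFactorOls <- function(pairs, predictor) {
  x <- pairs[[predictor]]
  .assert(!is.null(x), "no such predictor column: ", predictor)
  .assert(nrow(pairs) >= 4, "need at least 4 site pairs")
  .assert(var(x) > 0, "zero-variance predictor: ", predictor)
  fit <- lm(pairs$gdist ~ x)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = c("(Intercept)", predictor), co)
  rownames(co) <- NULL
  ic <- .gaussIc(residuals(fit), k = 3)  # intercept, slope, sigma
  fp <- sm$fstatistic
  structure(list(coefficients = co, r2 = sm$r.squared,
                 adjR2 = sm$adj.r.squared, logLik = ic$logLik,
                 aic = ic$aic, bic = ic$bic, sse = ic$sse,
                 modelP = unname(pf(fp[1], fp[2], fp[3], lower.tail = FALSE)),
                 n = nrow(pairs)),
            class = "fitReport")
}

#' @export
print.fitReport <- function(x, ...) {
  cat(sprintf("fitReport: n=%d R2=%.3f adjR2=%.3f AIC=%.2f BIC=%.2f p=%.3g\n",
              x$n, x$r2, x$adjR2, x$aic, x$bic, x$modelP))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# post-selection coefficient table: penalized estimates, OLS-refit SE/t/p for
# survivors, zero/one rows for dropped predictors
.rlsReport <- function(coefPen, survivors, X, y, predictors) {
  co <- data.frame(term = c("(Intercept)", predictors),
                   estimate = 0, se = NA_real_, t = 0, p = 1)
  co$estimate[1] <- coefPen[1]
  co$estimate[match(names(coefPen)[-1], co$term)] <- coefPen[-1]
  if (length(survivors)) {
    refit <- lm(y ~ X[, survivors, drop = FALSE])
    sm <- summary(refit)$coefficients
    rows <- match(survivors, co$term)
    co$se[1] <- sm[1, 2]; co$t[1] <- sm[1, 3]; co$p[1] <- sm[1, 4]
    co$se[rows] <- sm[-1, 2]; co$t[rows] <- sm[-1, 3]; co$p[rows] <- sm[-1, 4]
  }
  # SE for dropped predictors: from single-variable refits (descriptive only)
  dropped <- setdiff(predictors, survivors)
  for (d in dropped) {
    smd <- summary(lm(y ~ X[, d]))$coefficients
    co$se[match(d, co$term)] <- smd[2, 2]
  }
  fitted <- cbind(1, X) %*% c(co$estimate[1], co$estimate[-1])
  resid <- y - fitted
  ic <- .gaussIc(resid, k = length(survivors) + 2)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(coefficients = co, r2 = r2, sse = ic$sse, logLik = ic$logLik,
       aic = ic$aic, bic = ic$bic, survivors = survivors)
}

#' Regularized least-squares dissection of IBD/IBE predictors
#'
#' Stage 1 discards unimportant predictors with a cross-validated LASSO;
#' stage 2 fits an elastic net (mixing parameter `alphaMix`, default 0.5) on
#' the survivors. Predictors are z-scored and the response centered.
#' Coefficient SE/t/p follow the post-selection OLS-refit convention
#' (dropped predictors get coefficient 0 and p 1). Fold assignment for
#' cross-validation is deterministic given the RNG state; set a seed for
#' reproducibility.
#'
#' @param pairs site-pair table with `gdist`
#' @param predictors predictor column names
#' @param alphaMix elastic-net mixing parameter for stage 2
#' @param nfolds cross-validation folds
#' @return list with `lasso` and `elasticNet` fit reports
#' @export
rlsFit <- function(pairs, predictors = c("dGcc", "dCsl", "dLat",
                                         "dSstMax", "dSstMed", "dSstMin"),
                   alphaMix = 0.5, nfolds = 5L) {
  X <- scale(as.matrix(pairs[, predictors, drop = FALSE]))
  colnames(X) <- predictors
  y <- pairs$gdist - mean(pairs$gdist)
  n <- length(y)
  foldid <- rep_len(seq_len(nfolds), n)[sample.int(n)]
  cv1 <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid)
  b1 <- coef(cv1, s = "lambda.min")
  keep <- rownames(b1)[-1][as.numeric(b1)[-1] != 0]
  if (!length(keep)) stop("no informative predictor survives the LASSO stage")
  co1 <- setNames(as.numeric(b1), rownames(b1))
  lasso <- .rlsReport(co1[c("(Intercept)", keep)], keep, X, y, predictors)

  if (length(keep) >= 2L) {
    cv2 <- glmnet::cv.glmnet(X[, keep, drop = FALSE], y, alpha = alphaMix,
                             foldid = foldid)
    b2 <- coef(cv2, s = "lambda.min")
    co2 <- setNames(as.numeric(b2), rownames(b2))
  } else {
    # a single survivor cannot be cross-validated by the elastic net;
    # the penalty-free limit (OLS) is the stage-2 fit
    ols <- lm(y ~ X[, keep])
    co2 <- setNames(as.numeric(coef(ols)), c("(Intercept)", keep))
  }
  keep2 <- keep[co2[keep] != 0]
  enet <- .rlsReport(co2, keep2, X, y, predictors)
  list(lasso = lasso, elasticNet = enet)
}

#' Monotone I-spline basis (order 2, knots at min/median/max)
#'
#' Three integrated M-spline basis functions, each rising from 0 at the
#' first knot to 1 at the last.
#'
#' @param x values to evaluate
#' @param knots length-3 ascending knot vector
#' @return length(x) x 3 matrix
#' @export
isplineBasis <- function(x, knots) {
  q1 <- knots[1]; q2 <- knots[2]; q3 <- knots[3]
  x <- pmin(pmax(x, q1), q3)
  i1 <- ifelse(x >= q2, 1, 1 - (q2 - x)^2 / (q2 - q1)^2)
  i2 <- ifelse(x <= q2,
               (x - q1)^2 / ((q3 - q1) * (q2 - q1)),
               1 - (q3 - x)^2 / ((q3 - q1) * (q3 - q2)))
  i3 <- ifelse(x <= q2, 0, (x - q2)^2 / (q3 - q2)^2)
  cbind(i1, i2, i3)
}

# build |I(x_i) - I(x_j)| design for one predictor
.gdmPairBasis <- function(siteVals, i, j, knots) {
  bi <- isplineBasis(siteVals[i], knots)
  bj <- isplineBasis(siteVals[j], knots)
  abs(bi - bj)
}

# Gauss-Newton NNLS fit of d = 1 - exp(-(X %*% beta)) with beta >= 0;
# X includes the intercept column
.gdmNnls <- function(X, d, tol = 1e-8, maxIter = 100L) {
  beta <- rep(0, ncol(X))
  beta[1] <- max(1e-3, -log(1 - min(mean(d), 0.99)))
  sseOld <- Inf
  for (it in seq_len(maxIter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 - exp(-eta)
    w <- exp(-eta)                    # d mu / d eta
    J <- X * w
    z <- J %*% beta + (d - mu)
    sol <- pracma::lsqnonneg(J, as.numeric(z))
    beta <- sol$x
    sse <- sum((d - (1 - exp(-as.numeric(X %*% beta))))^2)
    if (abs(sseOld - sse) < tol) break
    sseOld <- sse
  }
  if (!all(is.finite(beta))) stop("NNLS failure in GDM fit")
  list(beta = beta, sse = sse)
}

#' Generalized dissimilarity model with monotone I-splines
#'
#' Pairwise dissimilarity is modelled as `d = 1 - exp(-eta)` with
#' `eta = b0 + sum_j beta_j |I_j(x_site1) - I_j(x_site2)|`, three I-spline
#' basis functions per predictor (knots at the min/median/max of site
#' values) and all coefficients constrained non-negative; fitting is by
#' Gauss-Newton iterated non-negative least squares on the link scale.
#' The response is rescaled by `1/(1.01 max)` before the exponential link
#' (recorded in `scaleFactor`). Predictor importance is the mean percentage
#' decrease in deviance explained when that predictor's site values are
#' permuted across sites; its p-value is the fraction of permutations whose
#' deviance explained is at least the observed one.
#'
#' @param siteData data.frame with `site` and one column per predictor
#'   (site-level values)
#' @param pairs data.frame with `site1`, `site2`, `gdist`
#' @param predictors predictor column names in `siteData`
#' @param nPerm matrix permutations for importance/p (default 5000)
#' @return list of class `gdmFit`: `intercept`, `coefficients` (predictor x 3
#'   matrix), `maxHeight`, `devExplained` (percent), `importance`, `permP`,
#'   `knots`, `scaleFactor`, `fitted`, `response`
#' @export
gdmFit <- function(siteData, pairs, predictors, nPerm = 5000L) {
  keep <- predictors[vapply(predictors, function(p)
    var(siteData[[p]]) > 0, TRUE)]
  if (length(keep) < length(predictors))
    warning("constant predictor(s) dropped: ",
            paste(setdiff(predictors, keep), collapse = ", "))
  predictors <- keep
  .assert(length(predictors) >= 1, "no usable predictor")
  i <- match(pairs$site1, siteData$site)
  j <- match(pairs$site2, siteData$site)
  .assert(!anyNA(i) && !anyNA(j), "pair sites missing from siteData")
  scaleFactor <- 1 / (1.01 * max(pairs$gdist))
  d <- pairs$gdist * scaleFactor
  knots <- lapply(predictors, function(p) {
    v <- siteData[[p]]
    c(min(v), median(v), max(v))
  })
  names(knots) <- predictors
  design <- function(siteVals) {
    cols <- lapply(predictors, function(p)
      .gdmPairBasis(siteVals[[p]], i, j, knots[[p]]))
    cbind(1, do.call(cbind, cols))
  }
  devExp <- function(X) {
    fit <- .gdmNnls(X, d)
    null <- .gdmNnls(matrix(1, length(d), 1L), d)
    list(fit = fit, dev = 100 * (1 - fit$sse / null$sse))
  }
  X <- design(siteData[predictors])
  full <- devExp(X)
  beta <- full$fit$beta
  coefs <- matrix(beta[-1], nrow = length(predictors), byrow = TRUE,
                  dimnames = list(predictors, paste0("I", 1:3)))
  importance <- permP <- setNames(rep(NA_real_, length(predictors)), predictors)
  if (nPerm > 0) {
    S <- nrow(siteData)
    for (p in predictors) {
      devs <- vapply(seq_len(nPerm), function(k) {
        sd2 <- siteData[predictors]
        sd2[[p]] <- sd2[[p]][sample.int(S)]
        devExp(design(sd2))$dev
      }, 0)
      importance[p] <- mean(pmax(0, 100 * (full$dev - devs) /
                                   max(full$dev, 1e-12)))
      permP[p] <- mean(devs >= full$dev)
    }
  }
  structure(list(intercept = beta[1], coefficients = coefs,
                 maxHeight = rowSums(coefs), devExplained = full$dev,
                 importance = importance, permP = permP, knots = knots,
                 scaleFactor = scaleFactor,
                 fitted = 1 - exp(-as.numeric(X %*% beta)), response = d,
                 predictors = predictors),
            class = "gdmFit")
}

#' @export
print.gdmFit <- function(x, ...) {
  cat(sprintf("gdmFit: %d predictors, deviance explained %.1f%%\n",
              length(x$predictors), x$devExplained))
  print(data.frame(maxHeight = x$maxHeight, importance = x$importance,
                   permP = x$permP), digits = 3)
  invisible(x)
}

#' Extract fitted I-spline curves
#'
#' @param fit a [gdmFit()] result
#' @param n points per predictor
#' @return data.frame with `predictor`, `x`, `y` (partial link-scale effect)
#' @export
gdmSplineCurves <- function(fit, n = 200L) {
  out <- lapply(fit$predictors, function(p) {
    k <- fit$knots[[p]]
    x <- seq(k[1], k[3], length.out = n)
    y <- as.numeric(isplineBasis(x, k) %*% fit$coefficients[p, ])
    data.frame(predictor = p, x = x, y = y)
  })
  do.call(rbind, out)
}

#' GDMs restricted to selected vs unselected genome divisions
#'
#' Recomputes per-site-pair FST by ratio-of-sums over SNPs inside the
#' selected regions and over SNPs outside them, linearizes each, and fits a
#' GDM per division with the same site-level predictors.
#'
#' @param hap a [HaplotypeSet-class]
#' @param regions `GRanges` of selected regions (combine A and B sides)
#' @param siteData site-level predictor data.frame (see [gdmFit()])
#' @param predictors predictor column names
#' @param nPerm permutations passed to [gdmFit()]
#' @return list with `psr` and `nonPsr` gdmFit objects
#' @export
gdmRegionContrast <- function(hap, regions, siteData, predictors,
                              nPerm = 0L) {
  .assert(length(regions) > 0, "empty region list")
  inPsr <- IRanges::overlapsAny(variants(hap), regions)
  .assert(sum(inPsr) >= 5 && sum(!inPsr) >= 5,
          "a genome division has fewer than 5 SNPs")
  fitDivision <- function(sel) {
    fst <- pairwiseFst(hap, by = "site", snpSubset = which(sel))
    sites <- unique(popMap(hap)$site)
    S <- length(sites)
    idx <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
    prs <- data.frame(site1 = sites[idx[, 1]], site2 = sites[idx[, 2]])
    prs$gdist <- linearizedGdist(fst[cbind(prs$site1, prs$site2)])
    gdmFit(siteData, prs, predictors, nPerm = nPerm)
  }
  list(psr = fitDivision(inPsr), nonPsr = fitDivision(!inPsr))
}

# all-subsets R^2 over predictors; returns named vector keyed by
# comma-separated sorted indices
.allSubsetsR2 <- function(X, y) {
  p <- ncol(X)
  out <- numeric(0)
  for (m in seq_len(2^p - 1)) {
    sel <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    fit <- lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    out[paste(sel, collapse = ",")] <- r2
  }
  out
}

# commonality coefficient C(S) = -sum_{T subseteq S} (-1)^|T| R2((V \ S) u T)
.commonalityComponents <- function(r2sub, p) {
  key <- function(s) paste(sort(s), collapse = ",")
  R2 <- function(s) if (!length(s)) 0 else r2sub[[key(s)]]
  subsets <- lapply(seq_len(2^p - 1), function(m)
    which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  comp <- vapply(subsets, function(S) {
    rest <- setdiff(seq_len(p), S)
    tot <- 0
    for (m in 0:(2^length(S) - 1)) {
      Tset <- S[bitwAnd(m, 2^(seq_along(S) - 1)) > 0]
      tot <- tot + (-1)^length(Tset) * R2(union(rest, Tset))
    }
    -tot
  }, 0)
  names(comp) <- vapply(subsets, key, "")
  comp
}

# Johnson's relative weights from standardized X and y
.relativeWeights <- function(Xs, ys) {
  n <- nrow(Xs)
  sv <- svd(Xs)
  Z <- sqrt(n - 1) * sv$u %*% t(sv$v)
  Lam <- sv$v %*% diag(sv$d, length(sv$d)) %*% t(sv$v) / sqrt(n - 1)
  b <- as.numeric(crossprod(Z, ys)) / (n - 1)
  rw <- as.numeric(Lam^2 %*% b^2)
  names(rw) <- colnames(Xs)
  rw
}

# one full set of commonality/weights statistics
.commonalityStats <- function(pairs, predictors) {
  X <- as.matrix(pairs[, predictors, drop = FALSE])
  y <- pairs$gdist
  cc <- suppressWarnings(cor(X))
  off <- abs(cc[upper.tri(cc)])
  if (any(!is.finite(off)) || any(off >= 1 - 1e-12))
    stop("predictors perfectly correlated; commonality undefined")
  Xs <- scale(X); ys <- as.numeric(scale(y))
  fit <- lm.fit(cbind(1, Xs), ys)
  yhat <- ys - fit$residuals
  r2 <- 1 - sum(fit$residuals^2) / sum((ys - mean(ys))^2)
  beta <- fit$coefficients[-1]
  structCoef <- as.numeric(cor(X, yhat))
  rXY <- as.numeric(cor(X, y))
  comp <- .commonalityComponents(.allSubsetsR2(Xs, ys), length(predictors))
  unique_ <- comp[vapply(seq_along(predictors), function(i)
    as.character(i), "")]
  common <- vapply(seq_along(predictors), function(i) {
    inS <- vapply(strsplit(names(comp), ","), function(s)
      as.character(i) %in% s && length(s) > 1, TRUE)
    sum(comp[inS])
  }, 0)
  rw <- .relativeWeights(Xs, ys)
  data.frame(predictor = predictors, beta = as.numeric(beta),
             structureCoef = structCoef, sqStructureCoef = structCoef^2,
             pratt = as.numeric(beta) * rXY,
             unique = as.numeric(unique_), common = common,
             relativeWeight = as.numeric(rw), r2 = r2)
}

#' Commonality analysis and relative weights of IBD/IBE predictors
#'
#' All-subsets decomposition of the regression R^2 into unique and common
#' components, plus standardized betas, structure coefficients, Pratt
#' measures and Johnson relative weights, with percentile bootstrap
#' confidence intervals obtained by resampling sites (the pair table is
#' rebuilt from the distinct resampled sites each draw).
#'
#' @param pairs site-pair table with `gdist`, `site1`, `site2`
#' @param predictors predictor column names
#' @param nBoot bootstrap draws (default 5000; 0 skips CIs)
#' @param level CI level
#' @return list of class `commonalityReport`: `stats` (per-predictor table),
#'   `components` (all 2^p - 1 commonality components), `r2`,
#'   `sqStructDiff` / `relWeightDiff` (pairwise difference matrices), `ci`
#' @export
commonalityAnalysis <- function(pairs, predictors = c("dGcc", "dCsl", "dLat",
                                                      "dSstMax", "dSstMed",
                                                      "dSstMin"),
                                nBoot = 5000L, level = 0.95) {
  .assert(nrow(pairs) >= length(predictors) + 2,
          "need at least p + 2 site pairs")
  st <- .commonalityStats(pairs, predictors)
  comp <- .commonalityComponents(
    .allSubsetsR2(scale(as.matrix(pairs[, predictors])),
                  as.numeric(scale(pairs$gdist))), length(predictors))
  diffMat <- function(v) outer(v, v, "-")
  sqd <- diffMat(st$sqStructureCoef); rwd <- diffMat(st$relativeWeight)
  dimnames(sqd) <- dimnames(rwd) <- list(predictors, predictors)
  ci <- NULL
  if (nBoot > 0) {
    sites <- unique(c(as.character(pairs$site1), as.character(pairs$site2)))
    draws <- vector("list", nBoot)
    b <- 1L
    tries <- 0L
    maxTries <- 100L * nBoot
    while (b <= nBoot && tries < maxTries) {
      tries <- tries + 1L
      pick <- unique(sample(sites, length(sites), replace = TRUE))
      sub <- pairs[pairs$site1 %in% pick & pairs$site2 %in% pick, ]
      if (length(pick) < length(predictors) + 2 ||
          nrow(sub) < length(predictors) + 2) next
      res <- tryCatch(.commonalityStats(sub, predictors), error = function(e) NULL)
      if (is.null(res)) next
      draws[[b]] <- res
      b <- b + 1L
    }
    draws <- draws[!vapply(draws, is.null, TRUE)]
    if (length(draws) < nBoot)
      warning("only ", length(draws), " of ", nBoot,
              " site-bootstrap draws were feasible")
    if (!length(draws)) {
      out <- structure(list(stats = st, components = comp, r2 = st$r2[1],
                            sqStructDiff = sqd, relWeightDiff = rwd,
                            ci = NULL),
                       class = "commonalityReport")
      return(out)
    }
    al <- (1 - level) / 2
    ciFor <- function(col) {
      m <- vapply(draws, function(d) d[[col]], numeric(length(predictors)))
      t(apply(m, 1L, quantile, probs = c(al, 1 - al)))
    }
    ci <- lapply(c(beta = "beta", sqStructureCoef = "sqStructureCoef",
                   relativeWeight = "relativeWeight", unique = "unique"),
                 ciFor)
    for (nm in names(ci)) dimnames(ci[[nm]])[[1]] <- predictors
  }
  structure(list(stats = st, components = comp, r2 = st$r2[1],
                 sqStructDiff = sqd, relWeightDiff = rwd, ci = ci),
            class = "commonalityReport")
}

#' @export
print.commonalityReport <- function(x, ...) {
  cat(sprintf("commonalityReport: R2 = %.3f\n", x$r2))
  print(x$stats[, c("predictor", "beta", "sqStructureCoef", "unique",
                    "common", "relativeWeight")], digits = 3)
  invisible(x)
}
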