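#' Per-population (or per-site) allele frequencies
#'
#' @param hap a [HaplotypeSet-class]
#' @param by group samples by `"site"` or `"population"`
#' @return list with `freq` (P x L matrix) and `n` (non-missing haplotype
#'   counts, P x L)
#' @export
popFreqs <- function(hap, by = c("site", "population")) {
  by <- match.arg(by)
  groups <- unique(popMap(hap)[[by]])
  al <- alleles(hap)
  fr <- t(vapply(groups, function(g) {
    .colFreq(al[popHapRows(hap, g, by), , drop = FALSE])
  }, numeric(nSites(hap))))
  n <- t(vapply(groups, function(g) {
    colSums(!is.na(al[popHapRows(hap, g, by), , drop = FALSE]))
  }, numeric(nSites(hap))))
  rownames(fr) <- rownames(n) <- groups
  list(freq = fr, n = n)
}

#' Population covariance matrix from standardized allele frequencies
#'
#' Frequencies are centered at the across-population mean and scaled by
#' `sqrt(pbar (1 - pbar))` per SNP; the P x P matrix is the sample
#' covariance of those standardized vectors across SNPs. SNPs monomorphic
#' across all populations are dropped.
#'
#' @param freq P x L allele-frequency matrix
#' @return symmetric positive semi-definite P x P matrix
#' @export
popCovariance <- function(freq) {
  pbar <- colMeans(freq, na.rm = TRUE)
  keep <- !is.na(pbar) & pbar > 0 & pbar < 1
  .assert(sum(keep) >= 10 * nrow(freq),
          "need at least 10 x P polymorphic SNPs to estimate the covariance")
  x <- sweep(freq[, keep, drop = FALSE], 2L, pbar[keep])
  x <- sweep(x, 2L, sqrt(pbar[keep] * (1 - pbar[keep])), "/")
  om <- tcrossprod(x) / (ncol(x) - 1)
  (om + t(om)) / 2
}

# Omega^(-1/2) via symmetric eigendecomposition with ridge regularization
.whitener <- function(omega, ridge = 1e-8) {
  eg <- eigen((omega + t(omega)) / 2, symmetric = TRUE)
  lam <- eg$values + ridge * max(eg$values)
  if (any(lam <= 0)) stop("population covariance singular after regularization")
  eg$vectors %*% diag(1 / sqrt(lam), length(lam)) %*% t(eg$vectors)
}

#' Covariate association Bayes factors (deciban) per SNP
#'
#' Standardized allele frequencies and the (z-scored) covariate are whitened
#' by the inverse square root of the population covariance matrix, removing
#' shared drift; per SNP a linear model with the covariate is compared to an
#' intercept-only model through the BIC approximation
#' `BF = exp((BIC0 - BIC1)/2)`, reported as `10 log10(BF)` dB. The decisive
#' evidence rule used downstream is strict: `BF > 20 dB`. An externally
#' computed BF table can be supplied instead wherever a dB column is
#' consumed.
#'
#' @param freq P x L allele-frequency matrix
#' @param covariate per-population covariate values (length P)
#' @param omega P x P covariance from [popCovariance()]
#' @param ridge relative ridge added to the covariance spectrum
#' @return numeric vector of per-SNP BF in dB (NA for SNPs monomorphic
#'   across populations)
#' @export
bayesFactor <- function(freq, covariate, omega = popCovariance(freq),
                        ridge = 1e-8) {
  P <- nrow(freq)
  .assert(length(covariate) == P, "covariate length must equal population count")
  W <- .whitener(omega, ridge)
  pbar <- colMeans(freq, na.rm = TRUE)
  poly <- !is.na(pbar) & pbar > 0 & pbar < 1
  x <- sweep(freq, 2L, pbar)
  x <- sweep(x, 2L, sqrt(pmax(pbar * (1 - pbar), 1e-12)), "/")
  Y <- W %*% x                                  # P x L whitened
  cz <- as.numeric(scale(covariate))
  X1 <- cbind(W %*% rep(1, P), W %*% cz)        # whitened intercept + covariate
  X0 <- X1[, 1, drop = FALSE]
  rss <- function(X) {
    Q <- qr.Q(qr(X))
    colSums((Y - Q %*% (t(Q) %*% Y))^2)
  }
  rss0 <- rss(X0); rss1 <- rss(X1)
  dBic <- P * log(pmax(rss0, 1e-300) / pmax(rss1, 1e-300)) - log(P)
  db <- 10 * (dBic / 2) / log(10)
  db[!poly] <- NA_real_
  db
}

#' Redundancy-analysis outlier scan
#'
#' Centered dosages are regressed on the (centered) environmental covariates;
#' the SVD of the fitted matrix yields the constrained axes. Each SNP's
#' loadings on the retained axes are z-standardized per axis, summed as
#' squares, and referred to a chi-square distribution with one degree of
#' freedom per retained axis.
#'
#' @param dosage N x L genotype dosage matrix (or a [HaplotypeSet-class])
#' @param env N x C matrix/data.frame of per-sample covariates (site values
#'   broadcast to samples)
#' @param nAxes retained constrained axes (default: number of covariates)
#' @return data.frame with per-SNP `stat` and `p`; loadings in attribute
#'   `loadings`
#' @export
rdaOutliers <- function(dosage, env, nAxes = NULL) {
  if (is(dosage, "HaplotypeSet")) dosage <- .dosage(alleles(dosage))
  env <- as.matrix(env)
  .assert(nrow(env) == nrow(dosage), "env rows must match samples")
  cc <- cor(env)
  off <- abs(cc[upper.tri(cc)])
  if (any(off > 1 - 1e-12)) {
    idx <- which(upper.tri(cc), arr.ind = TRUE)[which.max(off), ]
    stop("covariates collinear to machine precision: ",
         colnames(env)[idx[1]], " ~ ", colnames(env)[idx[2]])
  }
  if (is.null(nAxes)) nAxes <- ncol(env)
  Y <- scale(dosage, center = TRUE, scale = FALSE)
  Y[is.na(Y)] <- 0
  X <- scale(env, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X))
  TY <- t(Q) %*% Y                       # k x L; SVD(QTY) = SVD(fitted)
  sv <- svd(TY, nu = 0, nv = min(nAxes, nrow(TY)))
  load <- sv$v                           # L x axes SNP loadings
  z <- scale(load)
  stat <- rowSums(z^2)
  data.frame(stat = stat, p = pchisq(stat, df = ncol(z), lower.tail = FALSE)) ->
    out
  attr(out, "loadings") <- load
  out
}

#' Intersect Bayes-factor and RDA outliers into candidate SNPs
#'
#' A SNP is a candidate when its BF exceeds 20 dB (strict) for at least one
#' covariate and its RDA p-value is below `rdaAlpha`. Tags record which
#' covariate(s) drove the BF hit.
#'
#' @param bfDb L x C matrix of BF (dB), one column per covariate (colnames
#'   used as tags)
#' @param rdaP per-SNP RDA p-values
#' @param bfThresholdDb decisive-evidence threshold (default 20 dB, strict >)
#' @param rdaAlpha RDA p-value cutoff (default 0.001)
#' @return data.frame with `bfHit`, `rdaHit`, `candidate`, `tag`
#' @export
intersectCandidates <- function(bfDb, rdaP, bfThresholdDb = 20,
                                rdaAlpha = 0.001) {
  bfDb <- as.matrix(bfDb)
  .assert(nrow(bfDb) == length(rdaP), "BF table and RDA p length differ")
  hits <- !is.na(bfDb) & bfDb > bfThresholdDb
  bfHit <- rowSums(hits) > 0
  rdaHit <- !is.na(rdaP) & rdaP < rdaAlpha
  tag <- apply(hits, 1L, function(h) paste(colnames(bfDb)[h], collapse = "+"))
  tag[!bfHit] <- ""
  data.frame(bfHit = bfHit, rdaHit = rdaHit,
             candidate = bfHit & rdaHit, tag = tag)
}

#' Genes within a radius of candidate SNPs
#'
#' A gene qualifies when the distance from its body to any candidate SNP is
#' at most `radius` bp (0 when the SNP lies inside the gene); the bound is
#' inclusive.
#'
#' @param snps `GRanges` of candidate SNP positions
#' @param genes `GRanges` with mcol `gene_id`
#' @param radius bp (default 5000)
#' @return character vector of gene ids
#' @export
genesNearSnps <- function(snps, genes, radius = 5000) {
  if (length(snps) == 0L || length(genes) == 0L) return(character())
  out <- character()
  chS <- as.character(seqnames(snps))
  chG <- as.character(seqnames(genes))
  for (g in seq_along(genes)) {
    p <- start(snps)[chS == chG[g]]
    if (!length(p)) next
    s <- start(genes)[g]; e <- end(genes)[g]
    d <- ifelse(p >= s & p <= e, 0, pmin(abs(s - p), abs(p - e)))
    if (min(d) <= radius) out <- c(out, mcols(genes)$gene_id[g])
  }
  unique(out)
}
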