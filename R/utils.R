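# Internal helpers shared across modules.

#' @importFrom stats qnorm pnorm sd median var cor lm aov coef pf pchisq
#'   quantile rbinom rbeta rnorm runif complete.cases anova residuals
#'   setNames lm.fit
#' @importFrom utils read.delim write.table head tail
NULL

# fractional ranks rank/(n+1) with average ranks for ties, NA kept as NA
fractionalRank <- function(x) {
  ok <- !is.na(x)
  r <- rep(NA_real_, length(x))
  r[ok] <- rank(x[ok], ties.method = "average") / (sum(ok) + 1)
  r
}

# allele frequency of the "1" allele per column of a haplotype row subset
.colFreq <- function(mat) {
  n <- colSums(!is.na(mat))
  cs <- colSums(mat, na.rm = TRUE)
  ifelse(n > 0, cs / n, NA_real_)
}

# diploid dosage matrix (N x L) from a 2N x L haplotype matrix; NA if either
# haplotype missing
.dosage <- function(al) {
  odd <- al[seq(1L, nrow(al), by = 2L), , drop = FALSE]
  evn <- al[seq(2L, nrow(al), by = 2L), , drop = FALSE]
  odd + evn
}

.assert <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
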