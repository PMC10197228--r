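#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width ranges mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Phased (or unphased) haplotype data with variant coordinates
#'
#' `HaplotypeSet` is the central genotype container: a `(2 * n samples) x L`
#' integer matrix of 0/1 alleles (NA for missing calls), one pair of rows per
#' diploid sample, together with the biallelic variant coordinates as a
#' [GenomicRanges::GRanges] and a sample-to-site/population map. All windowed
#' statistics, haplotype-homozygosity scans and allele-frequency summaries in
#' the package start from this object.
#'
#' @slot alleles integer matrix of dim `(2N, L)` with values in `{0, 1, NA}`;
#'   rows `2i - 1` and `2i` are the two haplotypes of sample `i`.
#' @slot variants `GRanges` of length `L` (width-1 SNP positions, 1-based)
#'   with metadata columns `ref`, `alt` and optional `id`.
#' @slot sampleIds character vector of length `N`.
#' @slot phased single logical; haplotype-based statistics (EHH, Rsb) refuse
#'   unphased input.
#' @slot popMap `data.frame` with columns `sample`, `site`, `population`,
#'   one row per sample in `sampleIds` order.
#'
#' @export
setClass("HaplotypeSet",
  representation(
    alleles   = "matrix",
    variants  = "GRanges",
    sampleIds = "character",
    phased    = "logical",
    popMap    = "data.frame"
  )
)

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  al <- object@alleles
  if (nrow(al) %% 2L != 0L)
    msg <- c(msg, "allele matrix must have an even number of rows (2 per sample)")
  if (nrow(al) != 2L * length(object@sampleIds))
    msg <- c(msg, "allele rows must equal 2 * number of samples")
  if (ncol(al) != length(object@variants))
    msg <- c(msg, "allele columns must match number of variants")
  vals <- al[!is.na(al)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "alleles must be coded 0/1 (NA for missing)")
  if (ncol(al) > 0L && any(colSums(!is.na(al)) == 0L))
    msg <- c(msg, "every variant must have at least one non-missing call")
  if (length(object@phased) != 1L)
    msg <- c(msg, "phased must be a single logical")
  pm <- object@popMap
  if (!all(c("sample", "site", "population") %in% names(pm)))
    msg <- c(msg, "popMap needs columns sample, site, population")
  else if (!setequal(pm$sample, object@sampleIds) ||
           nrow(pm) != length(object@sampleIds))
    msg <- c(msg, "popMap must map every sample exactly once")
  # positions strictly increasing within each chromosome
  if (length(object@variants) > 1L) {
    ch <- as.character(seqnames(object@variants))
    ps <- start(object@variants)
    bad <- ch[-1L] == ch[-length(ch)] & diff(ps) <= 0
    if (any(bad))
      msg <- c(msg, "variant positions must be strictly increasing within chromosomes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeSet
#'
#' @param alleles 0/1/NA matrix, two rows per sample.
#' @param variants `GRanges` of SNP positions with `ref`/`alt` metadata
#'   columns, or a data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param sampleIds character vector of sample names.
#' @param phased logical flag; `TRUE` when GT fields were phased (`|`).
#' @param popMap data.frame with columns `sample`, `site`, `population`.
#' @return A [HaplotypeSet-class] object.
#' @export
HaplotypeSet <- function(alleles, variants, sampleIds, phased, popMap) {
  if (is.data.frame(variants)) {
    variants <- GRanges(variants$chrom,
                        IRanges(variants$pos, width = 1L),
                        ref = variants$ref, alt = variants$alt)
  }
  storage.mode(alleles) <- "integer"
  popMap <- popMap[match(sampleIds, popMap$sample), , drop = FALSE]
  rownames(popMap) <- NULL
  new("HaplotypeSet", alleles = alleles, variants = variants,
      sampleIds = as.character(sampleIds), phased = isTRUE(phased),
      popMap = popMap)
}

#' @describeIn HaplotypeSet-class number of diploid samples
#' @param x,object a `HaplotypeSet`
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname HaplotypeSet-class
#' @export
setMethod("nSamples", "HaplotypeSet", function(x) length(x@sampleIds))

#' @describeIn HaplotypeSet-class number of variant sites
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname HaplotypeSet-class
#' @export
setMethod("nSites", "HaplotypeSet", function(x) length(x@variants))

#' @describeIn HaplotypeSet-class the 2N x L allele matrix
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname HaplotypeSet-class
#' @export
setMethod("alleles", "HaplotypeSet", function(x) x@alleles)

#' @describeIn HaplotypeSet-class variant coordinates as `GRanges`
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname HaplotypeSet-class
#' @export
setMethod("variants", "HaplotypeSet", function(x) x@variants)

#' @describeIn HaplotypeSet-class sample identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname HaplotypeSet-class
#' @export
setMethod("sampleIds", "HaplotypeSet", function(x) x@sampleIds)

#' @describeIn HaplotypeSet-class sample/site/population map
#' @export
setGeneric("popMap", function(x) standardGeneric("popMap"))

#' @rdname HaplotypeSet-class
#' @export
setMethod("popMap", "HaplotypeSet", function(x) x@popMap)

#' @describeIn HaplotypeSet-class whether the genotypes were phased
#' @export
setGeneric("isPhased", function(x) standardGeneric("isPhased"))

#' @rdname HaplotypeSet-class
#' @export
setMethod("isPhased", "HaplotypeSet", function(x) x@phased)

#' Subset a HaplotypeSet
#'
#' `i` selects samples (by index or id), `j` selects variant sites.
#'
#' @param x a `HaplotypeSet`
#' @param i sample index or sample id vector
#' @param j variant index vector
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@sampleIds)
  if (is.character(i)) i <- match(i, x@sampleIds)
  if (missing(j)) j <- seq_along(x@variants)
  hapRows <- as.vector(rbind(2L * i - 1L, 2L * i))
  HaplotypeSet(x@alleles[hapRows, j, drop = FALSE],
               x@variants[j],
               x@sampleIds[i], x@phased,
               x@popMap[i, , drop = FALSE])
})

setMethod("show", "HaplotypeSet", function(object) {
  pm <- object@popMap
  cat("HaplotypeSet:", length(object@sampleIds), "samples x",
      length(object@variants), "SNPs",
      if (object@phased) "(phased)" else "(unphased)", "\n")
  cat("  chromosomes:",
      paste(unique(as.character(seqnames(object@variants))), collapse = ", "), "\n")
  cat("  populations:",
      paste(sprintf("%s(%d)", names(table(pm$population)), table(pm$population)),
            collapse = " "), "\n")
  miss <- mean(is.na(object@alleles))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
})

#' Haplotype rows belonging to one population (or site)
#'
#' @param hap a `HaplotypeSet`
#' @param pop population label
#' @param by `"population"` or `"site"`
#' @return integer vector of haplotype row indices into `alleles(hap)`
#' @export
popHapRows <- function(hap, pop, by = c("population", "site")) {
  by <- match.arg(by)
  idx <- which(popMap(hap)[[by]] == pop)
  if (!length(idx)) stop("no samples with ", by, " label '", pop, "'")
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}
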