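#' Accessors for GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class].
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @return \code{dosages()}: integer matrix (sites x samples) of ALT dosages.
#' @export
dosages <- function(x) assay(x, "dosage")

#' @rdname genotype-accessors
#' @return \code{sampleIds()}: character vector of sample names.
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname genotype-accessors
#' @return \code{populations()}: named character vector, population per sample.
#' @export
populations <- function(x) {
  p <- as.character(colData(x)$population)
  names(p) <- colnames(x)
  p
}

#' @rdname genotype-accessors
#' @return \code{outgroupSamples()}: names of designated outgroup samples.
#' @export
outgroupSamples <- function(x) x@outgroup

#' @rdname genotype-accessors
#' @return \code{ancestralAlleles()}: per-site "ref"/"alt"/"unknown" calls.
#' @export
ancestralAlleles <- function(x) mcols(rowRanges(x))$ancestral

#' @rdname genotype-accessors
#' @return \code{siteInfo()}: data.frame of site coordinates, alleles and
#'   INFO annotations.
#' @export
siteInfo <- function(x) {
  rr <- rowRanges(x)
  cbind(data.frame(chrom = as.character(seqnames(rr)), pos = start(rr)),
        as.data.frame(mcols(rr)))
}

#' Derived-allele dosages
#'
#' Re-expresses the ALT-dosage matrix on the derived-allele scale using the
#' per-site ancestral calls set by [polarizeByOutgroup()]: where the ALT
#' allele is ancestral, dosage d becomes 2 - d. Sites with unknown ancestry
#' yield NA rows.
#'
#' @param x a [GenotypeMatrix-class].
#' @return integer matrix, sites x samples, derived dosages.
#' @export
derivedDosages <- function(x) {
  d <- dosages(x)
  anc <- ancestralAlleles(x)
  flip <- anc == "alt"
  d[flip, ] <- 2L - d[flip, , drop = FALSE]
  d[anc == "unknown", ] <- NA_integer_
  d
}

#' Samples belonging to a population
#' @param x a [GenotypeMatrix-class].
#' @param pop population label, or a vector of sample names (returned as-is
#'   after checking presence) for singleton "populations".
#' @return character vector of sample names.
#' @export
popSamples <- function(x, pop) {
  if (all(pop %in% colnames(x)) && !all(pop %in% populations(x)))
    return(pop)
  s <- colnames(x)[populations(x) %in% pop]
  if (!length(s)) stop("no samples in population '", paste(pop, collapse = ","), "'")
  s
}

#' Per-population derived (or ALT) allele frequencies
#'
#' @param x a [GenotypeMatrix-class].
#' @param pop population label or sample-name vector.
#' @param derived use derived dosages (requires polarization) rather than
#'   ALT dosages.
#' @return list with \code{freq} (per-site frequency, NA where no calls),
#'   \code{n} (called allele copies per site).
#' @export
popFreq <- function(x, pop, derived = FALSE) {
  d <- if (derived) derivedDosages(x) else dosages(x)
  d <- d[, popSamples(x, pop), drop = FALSE]
  n <- 2L * rowSums(!is.na(d))
  cnt <- rowSums(d, na.rm = TRUE)
  list(freq = ifelse(n > 0, cnt / n, NA_real_), n = n)
}

#' Subset sites of a GenotypeMatrix by logical or integer index
#' @param x a [GenotypeMatrix-class].
#' @param i row (site) index.
#' @return a [GenotypeMatrix-class] with the selected sites.
#' @export
subsetSites <- function(x, i) x[i, ]
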