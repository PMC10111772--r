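#' Polarize sites by an outgroup sample
#'
#' Sets the per-site ancestral-allele call from the genotype of a
#' designated outgroup individual (e.g. a domestic cat genotyped against
#' the focal reference): where the outgroup is homozygous reference the
#' ancestral allele is \code{ref}, homozygous alternate \code{alt};
#' heterozygous or missing outgroup genotypes leave the site
#' \code{unknown}. Derived dosages are then available via
#' [derivedDosages()] as the dosage of the non-ancestral allele.
#'
#' @param x a [GenotypeMatrix-class].
#' @param outgroup outgroup sample name; defaults to the first sample in
#'   \code{outgroupSamples(x)}.
#' @return \code{x} with updated ancestral calls and \code{outgroup} slot.
#' @export
polarizeByOutgroup <- function(x, outgroup = NULL) {
  if (is.null(outgroup)) {
    if (!length(outgroupSamples(x)))
      stop("no outgroup sample designated")
    outgroup <- outgroupSamples(x)[1L]
  }
  if (!outgroup %in% colnames(x))
    stop("outgroup sample '", outgroup, "' not present")
  d <- dosages(x)[, outgroup]
  anc <- rep("unknown", nrow(x))
  anc[!is.na(d) & d == 0L] <- "ref"
  anc[!is.na(d) & d == 2L] <- "alt"
  rr <- rowRanges(x)
  mcols(rr)$ancestral <- anc
  SummarizedExperiment::rowRanges(x) <- rr
  x@outgroup <- union(outgroup, x@outgroup)
  validObject(x)
  x
}
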