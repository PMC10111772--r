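#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays
NULL

#' GenotypeMatrix: multi-sample biallelic SNP genotypes
#'
#' The central container of the package. A \code{GenotypeMatrix} extends
#' \code{RangedSummarizedExperiment}: rows are biallelic SNP sites (a
#' \code{GRanges} with one-bp ranges carrying REF/ALT alleles, site-level
#' INFO annotations and the ancestral-allele call), columns are samples
#' (with their population labels and outgroup flags), and the
#' \code{"dosage"} assay holds the ALT-allele dosage per site and sample
#' (\code{0}, \code{1}, \code{2}, or \code{NA} for a missing call).
#'
#' Sites are kept sorted by (chromosome, position) with no duplicates;
#' the validity method enforces this together with the allele and dosage
#' invariants, so every downstream statistic can rely on them.
#'
#' @slot outgroup character vector of sample names designated as outgroup.
#'
#' @seealso [GenotypeMatrix()] for the constructor, [readVCF()],
#'   [applySiteFilters()], [polarizeByOutgroup()].
#' @export
setClass("GenotypeMatrix",
  contains = "RangedSummarizedExperiment",
  representation(outgroup = "character")
)

.validGenotypeMatrix <- function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rr <- rowRanges(object)
  if (nrow(object) > 0L) {
    m <- mcols(rr)
    need <- c("ref", "alt", "ancestral")
    miss <- setdiff(need, colnames(m))
    if (length(miss))
      msg <- c(msg, paste("rowRanges lack columns:", paste(miss, collapse = ", ")))
    else {
      ok <- m$ref %in% c("A", "C", "G", "T") & m$alt %in% c("A", "C", "G", "T")
      if (!all(ok)) msg <- c(msg, "REF and ALT must be single bases A/C/G/T")
      if (any(m$ref == m$alt)) msg <- c(msg, "REF and ALT must differ")
      if (!all(m$ancestral %in% c("ref", "alt", "unknown")))
        msg <- c(msg, "ancestral must be 'ref', 'alt' or 'unknown'")
    }
    key <- paste(as.character(seqnames(rr)), start(rr))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate sites (chrom, pos)")
    o <- order(as.character(seqnames(rr)), start(rr))
    if (!identical(o, seq_along(key))) msg <- c(msg, "sites must be sorted by (chrom, pos)")
  }
  cd <- colData(object)
  if (!"population" %in% colnames(cd))
    msg <- c(msg, "colData must carry a 'population' column")
  if (length(object@outgroup) &&
      !all(object@outgroup %in% colnames(object)))
    msg <- c(msg, "outgroup samples must be present among samples")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix, sites x samples, values 0/1/2/NA (ALT
#'   dosage). Row order must follow (chrom, pos); the constructor sorts.
#' @param chrom,pos chromosome id and 1-based position per site.
#' @param ref,alt single-base REF and ALT alleles per site.
#' @param samples sample identifiers (defaults to dosage column names).
#' @param populations population label per sample (single label recycled).
#' @param outgroup character vector of outgroup sample names (may be empty).
#' @param info optional \code{DataFrame}/data.frame of site-level INFO
#'   annotations (QD, FS, MQ, QUAL, DP, MQRankSum, ReadPosRankSum, ...).
#' @param ancestral ancestral-allele call per site: "ref", "alt" or
#'   "unknown" (default).
#' @param depth optional per-genotype depth matrix, same shape as dosage.
#' @param seqlengths optional named vector of chromosome lengths (bp),
#'   stored in \code{metadata()$seqlengths} and used as the default
#'   genome denominator for F_ROH.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 0L), 2, 2), chrom = "chr1",
#'                      pos = c(100, 200), ref = c("A", "C"), alt = c("G", "T"),
#'                      samples = c("s1", "s2"))
#' dosages(gm)
#' @export
GenotypeMatrix <- function(dosage, chrom, pos, ref, alt,
                           samples = colnames(dosage),
                           populations = "pop1",
                           outgroup = character(),
                           info = NULL,
                           ancestral = "unknown",
                           depth = NULL,
                           seqlengths = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n_sites <- nrow(dosage)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(dosage)))
  chrom <- rep_len(as.character(chrom), n_sites)
  pos <- rep_len(as.integer(pos), n_sites)
  ancestral <- rep_len(ancestral, n_sites)
  o <- order(chrom, pos)
  rr <- GRanges(chrom[o], IRanges(pos[o], width = 1L))
  ref <- rep_len(as.character(ref), n_sites)
  alt <- rep_len(as.character(alt), n_sites)
  mc <- DataFrame(ref = ref[o], alt = alt[o], ancestral = ancestral[o])
  if (!is.null(info)) {
    info <- as(info, "DataFrame")
    mc <- cbind(mc, info[o, , drop = FALSE])
  }
  mcols(rr) <- mc
  populations <- rep_len(populations, length(samples))
  cd <- DataFrame(population = populations, row.names = samples)
  asy <- list(dosage = dosage[o, , drop = FALSE])
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    asy$depth <- depth[o, , drop = FALSE]
  }
  asy <- lapply(asy, function(m) {
    dimnames(m) <- list(NULL, samples)
    m
  })
  se <- SummarizedExperiment(assays = asy, rowRanges = rr, colData = cd)
  obj <- new("GenotypeMatrix", se, outgroup = as.character(outgroup))
  if (!is.null(seqlengths)) metadata(obj)$seqlengths <- seqlengths
  validObject(obj)
  obj
}

#' @describeIn GenotypeMatrix compact display.
#' @param object a GenotypeMatrix.
#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object), "sites x", ncol(object), "samples\n")
  pops <- table(colData(object)$population)
  cat("  populations:",
      paste(names(pops), "(", as.integer(pops), ")", collapse = ", "), "\n")
  if (length(object@outgroup))
    cat("  outgroup:", paste(object@outgroup, collapse = ", "), "\n")
  anc <- mcols(rowRanges(object))$ancestral
  if (!is.null(anc))
    cat("  polarized sites:", sum(anc != "unknown"), "/", nrow(object), "\n")
  invisible(object)
})
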