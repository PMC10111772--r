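# small builders used across the suite

# GenotypeMatrix from a sites x samples dosage matrix on one chromosome
makeGM <- function(dosage, pos = NULL, chrom = "chr1", populations = "pop1",
                   samples = NULL, outgroup = character(),
                   ancestral = "unknown", chrom_len = NULL, info = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(pos)) pos <- seq_len(nrow(dosage)) * 100L
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(dosage)))
  if (is.null(chrom_len)) chrom_len <- max(pos) + 100
  sl <- stats::setNames(rep(chrom_len, length(unique(chrom))), unique(chrom))
  GenotypeMatrix(dosage, chrom = chrom, pos = pos,
                 ref = "A", alt = "G", samples = samples,
                 populations = populations, outgroup = outgroup,
                 ancestral = ancestral, info = info, seqlengths = sl)
}

# write a small VCF text file and return its path
writeToyVCF <- function(body_lines, samples = c("s1", "s2", "s3"),
                        extra_header = character()) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           extra_header,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body_lines), path)
  path
}
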