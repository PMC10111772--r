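#' @importFrom utils read.table write.table
NULL

.read_lines_any <- function(path, n = -1L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, n = n)
}

# cheap structural validation so parse errors can name the offending line
.validate_vcf_lines <- function(path) {
  lines <- .read_lines_any(path)
  body <- which(!startsWith(lines, "#"))
  if (!length(body)) stop("malformed VCF '", path, "': no data lines")
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 8L]
  if (length(bad))
    stop("malformed VCF '", path, "': line ", bad[1L],
         " has fewer than 8 tab-separated fields")
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("malformed VCF '", path, "': missing #CHROM header")
  invisible(TRUE)
}

#' Read a multi-sample VCF into a GenotypeMatrix
#'
#' Reads VCF 4.x (plain or gzipped) and retains biallelic SNP records only:
#' multiallelic records, indels and multi-nucleotide polymorphisms are
#' dropped and counted. Half-calls (e.g. \code{./1}) are treated as missing
#' and phased separators are normalised to unphased. Site-level INFO
#' annotations QD, FS, MQ, DP, MQRankSum and ReadPosRankSum plus QUAL are
#' carried into the site metadata when present; per-genotype DP becomes the
#' \code{"depth"} assay.
#'
#' @param path VCF file path.
#' @param populationSpec optional data.frame with columns \code{sample} and
#'   \code{population} (see [readPopulationMap()]); samples listed but
#'   absent from the file raise a configuration error, and the matrix is
#'   restricted to the listed samples.
#' @param outgroup optional character vector of outgroup sample names.
#' @return a [GenotypeMatrix-class]; the number of non-biallelic-SNP records
#'   dropped is available as \code{metadata(x)$dropped_records}.
#' @export
readVCF <- function(path, populationSpec = NULL, outgroup = character()) {
  .validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  bases <- c("A", "C", "G", "T")
  keep <- fix[, "REF"] %in% bases & fix[, "ALT"] %in% bases
  dropped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNP records in '", path, "'")
  gt <- v@gt[keep, -1L, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  fmt <- v@gt[keep, 1L]

  gt_field <- function(m, fmt, field) {
    idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) match(field, f), integer(1))
    out <- matrix(NA_character_, nrow(m), ncol(m), dimnames = dimnames(m))
    for (i in unique(idx[!is.na(idx)])) {
      rows <- which(idx == i)
      part <- vapply(strsplit(m[rows, , drop = FALSE], ":", fixed = TRUE),
                     function(x) if (length(x) >= i) x[[i]] else NA_character_,
                     character(1))
      out[rows, ] <- part
    }
    out
  }
  gts <- gt_field(gt, fmt, "GT")
  gts <- gsub("|", "/", gts, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow(gts), ncol(gts))
  dosage[gts %in% "0/0"] <- 0L
  dosage[gts %in% c("0/1", "1/0")] <- 1L
  dosage[gts %in% "1/1"] <- 2L
  colnames(dosage) <- colnames(gt)

  dp <- NULL
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(matrix(as.numeric(gt_field(gt, fmt, "DP")),
                                  nrow(gt), ncol(gt), dimnames = dimnames(gt)))
  }

  info_num <- function(field) {
    m <- regmatches(fix[, "INFO"],
                    regexpr(paste0("(^|;)", field, "=[^;]*"), fix[, "INFO"]))
    out <- rep(NA_real_, nrow(fix))
    hit <- grepl(paste0("(^|;)", field, "="), fix[, "INFO"])
    out[hit] <- suppressWarnings(as.numeric(sub(paste0(".*", field, "="), "", m)))
    out
  }
  info <- DataFrame(QD = info_num("QD"), FS = info_num("FS"),
                    MQ = info_num("MQ"),
                    QUAL = suppressWarnings(as.numeric(fix[, "QUAL"])),
                    DP = info_num("DP"),
                    MQRankSum = info_num("MQRankSum"),
                    ReadPosRankSum = info_num("ReadPosRankSum"))
  aa <- regmatches(fix[, "INFO"],
                   regexpr("(^|;)AA=[ACGT]", fix[, "INFO"]))
  anc <- rep("unknown", nrow(fix))
  hit <- grepl("(^|;)AA=[ACGT]", fix[, "INFO"])
  if (any(hit)) {
    aa_base <- sub(".*AA=", "", aa)
    anc[hit] <- ifelse(aa_base == fix[hit, "REF"], "ref",
                       ifelse(aa_base == fix[hit, "ALT"], "alt", "unknown"))
  }

  samples <- colnames(dosage)
  pops <- rep("pop1", length(samples))
  if (!is.null(populationSpec)) {
    missing <- setdiff(populationSpec$sample, samples)
    if (length(missing))
      stop("samples in population map absent from VCF: ",
           paste(missing, collapse = ", "))
    sel <- match(populationSpec$sample, samples)
    dosage <- dosage[, sel, drop = FALSE]
    if (!is.null(dp)) dp <- dp[, sel, drop = FALSE]
    samples <- populationSpec$sample
    pops <- populationSpec$population
    if (!is.null(populationSpec$outgroup))
      outgroup <- union(outgroup, populationSpec$sample[populationSpec$outgroup])
  }

  seqlen <- NULL
  meta_lines <- v@meta
  ctg <- grep("^##contig=", meta_lines, value = TRUE)
  if (length(ctg)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
    if (!anyNA(lens)) seqlen <- stats::setNames(lens, ids)
  }

  gm <- GenotypeMatrix(dosage,
                       chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       samples = samples, populations = pops,
                       outgroup = outgroup, info = info, ancestral = anc,
                       depth = dp, seqlengths = seqlen)
  metadata(gm)$dropped_records <- dropped
  gm
}

#' Write a GenotypeMatrix as VCF 4.2
#'
#' Emits plain-text VCF with the site INFO annotations (QD, FS, MQ, DP,
#' MQRankSum, ReadPosRankSum), the ancestral allele as an \code{AA} tag when
#' known, contig lengths from \code{metadata()$seqlengths}, and GT (plus DP
#' when a depth assay is present) per sample.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVCF <- function(x, path) {
  rr <- rowRanges(x)
  m <- mcols(rr)
  info_fields <- intersect(c("QD", "FS", "MQ", "DP", "MQRankSum", "ReadPosRankSum"),
                           colnames(m))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=CaptivePopGen")
  sl <- metadata(x)$seqlengths
  if (!is.null(sl))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(sl), as.integer(sl)))
  hdr <- c(hdr,
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   info_fields, info_fields),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  has_depth <- "depth" %in% names(assays(x))
  if (has_depth)
    hdr <- c(hdr, "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", colnames(x)), collapse = "\t"))

  fmt_num <- function(v) ifelse(is.na(v), NA, format(v, trim = TRUE, digits = 6,
                                                     scientific = FALSE))
  info_mat <- vapply(info_fields, function(f) {
    val <- fmt_num(as.numeric(m[[f]]))
    ifelse(is.na(val), NA_character_, paste0(f, "=", val))
  }, character(nrow(x)))
  if (is.null(dim(info_mat)))
    info_mat <- matrix(info_mat, nrow = nrow(x))
  aa <- ifelse(m$ancestral == "ref", paste0("AA=", m$ref),
               ifelse(m$ancestral == "alt", paste0("AA=", m$alt), NA))
  info_mat <- cbind(info_mat, aa)
  info_str <- apply(info_mat, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ";") else "."
  })
  qual <- if ("QUAL" %in% colnames(m))
    ifelse(is.na(m$QUAL), ".", fmt_num(as.numeric(m$QUAL))) else "."

  d <- dosages(x)
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 2L] <- "1/1"
  fmt_col <- "GT"
  if (has_depth) {
    dp <- assay(x, "depth")
    dps <- ifelse(is.na(dp), ".", format(dp, trim = TRUE))
    gt <- matrix(paste(gt, dps, sep = ":"), nrow(d), ncol(d))
    fmt_col <- "GT:DP"
  }
  body <- paste(as.character(seqnames(rr)), start(rr), ".", m$ref, m$alt,
                qual, "PASS", info_str, fmt_col,
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Tab-separated, two or three columns: sample, population and optionally a
#' logical outgroup flag. A header line is detected and skipped.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{sample}, \code{population} and
#'   (if present) \code{outgroup}.
#' @export
readPopulationMap <- function(path) {
  first <- .read_lines_any(path, n = 1L)
  header <- grepl("^sample\\b", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = header,
                   stringsAsFactors = FALSE)
  colnames(df)[1:2] <- c("sample", "population")
  if (ncol(df) >= 3) {
    colnames(df)[3] <- "outgroup"
    df$outgroup <- as.logical(df$outgroup)
  }
  df
}

#' Read assembly-gap intervals from BED
#'
#' @param path BED path (0-based half-open, as emitted by assembly QC tools).
#' @return a \code{GRanges} of gaps (1-based closed, as used internally).
#' @export
readGapsBed <- function(path) rtracklayer::import(path, format = "BED")

#' Derive assembly-gap intervals from a reference FASTA
#'
#' Runs of \code{N} in the reference are treated as gaps.
#'
#' @param fasta path to a FASTA file, or a \code{DNAStringSet}.
#' @return a \code{GRanges} of N-runs.
#' @export
gapsFromFasta <- function(fasta) {
  seqs <- if (is(fasta, "DNAStringSet")) fasta else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  grl <- lapply(seq_along(seqs), function(i) {
    hits <- Biostrings::matchPattern("N", seqs[[i]])
    if (!length(hits)) return(GRanges())
    GenomicRanges::reduce(GRanges(names(seqs)[i],
                                  IRanges(Biostrings::start(hits),
                                          Biostrings::end(hits))))
  })
  do.call(c, grl)
}
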