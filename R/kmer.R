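#' Exact k-mer histogram of a read set
#'
#' Counts canonical (strand-collapsed) k-mers exactly — suitable for toy
#' to moderately sized inputs — and tabulates the depth distribution:
#' how many distinct k-mer species occur at each depth. The peak depth
#' is the modal depth, by default excluding the depth-1 class that is
#' dominated by sequencing-error k-mers.
#'
#' @param reads FASTA/FASTQ path, a \code{DNAStringSet}, or a character
#'   vector of sequences.
#' @param k odd k-mer length (default 17).
#' @param canonical collapse each k-mer with its reverse complement.
#' @param exclude_depth1 exclude depth 1 from peak finding.
#' @return list: \code{histogram} (data.frame depth, n_kmers),
#'   \code{total_kmers} (total occurrences), \code{peak_depth},
#'   \code{k}, \code{n_short_reads} (reads shorter than k, skipped).
#' @export
kmerHistogram <- function(reads, k = 17L, canonical = TRUE,
                          exclude_depth1 = TRUE) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    first <- .read_lines_any(reads, n = 1L)
    fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  seqs <- toupper(as.character(reads))
  stopifnot(k >= 1)
  short <- nchar(seqs) < k
  n_short <- sum(short)
  seqs <- seqs[!short]
  if (!length(seqs)) stop("no reads of length >= k")
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  tab <- table(kmers)
  if (canonical) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(names(tab))))
    canon <- pmin(names(tab), rc)
    counts <- tapply(as.integer(tab), canon, sum)
  } else counts <- as.integer(tab)
  depth_tab <- table(counts)
  hist <- data.frame(depth = as.integer(names(depth_tab)),
                     n_kmers = as.integer(depth_tab))
  hist <- hist[order(hist$depth), ]
  total <- sum(as.numeric(hist$depth) * hist$n_kmers)
  peak_rows <- if (exclude_depth1) hist[hist$depth > 1L, ] else hist
  peak <- if (nrow(peak_rows)) peak_rows$depth[which.max(peak_rows$n_kmers)]
          else hist$depth[which.max(hist$n_kmers)]
  list(histogram = hist, total_kmers = total, peak_depth = peak, k = k,
       n_short_reads = n_short)
}

#' Genome-size estimate from a k-mer histogram
#'
#' Genome size (bp) = total k-mer count / peak depth.
#'
#' @param total_kmers total number of k-mer occurrences.
#' @param peak_depth modal k-mer depth (> 0).
#' @return genome size in bp.
#' @examples
#' estimateGenomeSize(61791522108, 25) / 1e6  # ~2471.66 Mb
#' @export
estimateGenomeSize <- function(total_kmers, peak_depth) {
  if (is.list(total_kmers)) {
    peak_depth <- total_kmers$peak_depth
    total_kmers <- total_kmers$total_kmers
  }
  if (is.null(peak_depth) || is.na(peak_depth) || peak_depth <= 0)
    stop("peak depth must be positive")
  total_kmers / peak_depth
}
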