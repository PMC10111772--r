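#' Run-of-homozygosity detector parameters
#'
#' Defaults reproduce the widely used sliding-window detector settings:
#' 100-SNP scanning windows allowing at most 2 heterozygous and 5 missing
#' calls, SNP hit-rate threshold 0.05, and final segments requiring at
#' least 100 SNPs, 100 kb, one SNP per 10 kb on average, and no
#' inter-SNP gap over 100 kb.
#'
#' @param window_snp scanning-window size in SNPs.
#' @param window_het maximum heterozygous calls for a homozygous window.
#' @param window_missing maximum missing calls for a homozygous window.
#' @param min_snp minimum SNPs per emitted segment.
#' @param min_kb minimum segment length (kb).
#' @param density_kb maximum average kb per SNP within a segment.
#' @param max_gap_kb split runs at inter-SNP gaps over this many kb.
#' @param hit_threshold minimum fraction of homozygous windows covering a
#'   SNP for it to enter a run.
#' @return a \code{ROHParams} list.
#' @export
rohParams <- function(window_snp = 100L, window_het = 2L,
                      window_missing = 5L, min_snp = 100L, min_kb = 100,
                      density_kb = 10, max_gap_kb = 100,
                      hit_threshold = 0.05) {
  p <- list(window_snp = as.integer(window_snp),
            window_het = as.integer(window_het),
            window_missing = as.integer(window_missing),
            min_snp = as.integer(min_snp), min_kb = min_kb,
            density_kb = density_kb, max_gap_kb = max_gap_kb,
            hit_threshold = hit_threshold)
  stopifnot(all(unlist(p[c(1, 4:7)]) > 0), hit_threshold > 0,
            hit_threshold <= 1)
  p
}

.roh_class <- function(len) {
  cut(len, c(-Inf, 1e6, 2e6, Inf),
      labels = c("100kb-1Mb", "1-2Mb", ">2Mb"), right = FALSE)
}

# rolling sum over windows of k consecutive entries
.rollsum <- function(v, k) {
  cs <- c(0, cumsum(v))
  cs[(k + 1):length(cs)] - cs[seq_len(length(cs) - k)]
}

#' Detect runs of homozygosity for one sample
#'
#' Sliding-window scan: per chromosome, every \code{window_snp}-SNP
#' window is scored homozygous when it contains at most
#' \code{window_het} heterozygous and \code{window_missing} missing
#' calls; each SNP's hit rate is the proportion of windows actually
#' containing it (fewer near chromosome ends) that are homozygous. SNPs
#' at or above the hit-rate threshold form candidate runs, runs are split
#' at inter-SNP gaps over \code{max_gap_kb}, and runs passing the SNP
#' count, length and density constraints are emitted. Chromosomes with
#' fewer SNPs than the window yield no calls (logged).
#'
#' @param x a [GenotypeMatrix-class] (sites sorted per chromosome).
#' @param sample sample name.
#' @param p a [rohParams()].
#' @return data.frame of segments: sample, chrom, start, end, n_snps,
#'   length (= end - start + 1), class.
#' @export
detectROH <- function(x, sample, p = rohParams()) {
  d_all <- dosages(x)[, sample]
  rr <- rowRanges(x)
  chrom <- as.character(seqnames(rr)); posv <- start(rr)
  segs <- list()
  for (cc in unique(chrom)) {
    sel <- which(chrom == cc)
    if (length(sel) < p$window_snp) {
      message("chromosome ", cc, " has fewer than ", p$window_snp,
              " SNPs; no ROH calls there")
      next
    }
    d <- d_all[sel]; pos <- posv[sel]
    n <- length(d)
    het <- !is.na(d) & d == 1L
    mis <- is.na(d)
    k <- p$window_snp
    hom_win <- .rollsum(het, k) <= p$window_het &
      .rollsum(mis, k) <= p$window_missing
    nwin <- n - k + 1L
    cumhom <- c(0, cumsum(hom_win))
    i <- seq_len(n)
    lo <- pmax(1L, i - k + 1L)
    hi <- pmin(nwin, i)
    hits <- cumhom[hi + 1L] - cumhom[lo]
    cover <- hi - lo + 1L
    eligible <- hits / cover >= p$hit_threshold
    # maximal runs of eligible SNPs, split at large gaps
    brk <- c(0, diff(pos) > p$max_gap_kb * 1000)
    grp <- cumsum(!eligible | brk == 1)
    runs <- split(i[eligible], grp[eligible])
    for (r in runs) {
      if (length(r) < p$min_snp) next
      len <- pos[r[length(r)]] - pos[r[1]] + 1
      if (len < p$min_kb * 1000) next
      if (len / length(r) > p$density_kb * 1000) next
      segs[[length(segs) + 1L]] <-
        data.frame(sample = sample, chrom = cc, start = pos[r[1]],
                   end = pos[r[length(r)]], n_snps = length(r),
                   length = len, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs)
         else data.frame(sample = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         n_snps = integer(), length = numeric())
  out$class <- .roh_class(out$length)
  out
}

#' Genomic inbreeding from ROH (F_ROH)
#'
#' Fraction of the genome covered by ROH segments at or above a length
#' threshold.
#'
#' @param segments data.frame from [detectROH()] (one sample).
#' @param genome_length genome denominator in bp (e.g. the summed contig
#'   lengths of the callset, or a fixed assembly size for comparability).
#' @param min_length minimum segment length in bp (default 100 kb).
#' @return F_ROH in [0, 1].
#' @export
fRoh <- function(segments, genome_length, min_length = 1e5) {
  stopifnot(genome_length > 0)
  sum(segments$length[segments$length >= min_length]) / genome_length
}

#' Excess-homozygosity inbreeding coefficient (F_H)
#'
#' F_H = (O_hom - E_hom) / (N - E_hom) for an individual, where O_hom is
#' its observed homozygous-site count over called sites, N the called
#' count, and E_hom the Hardy-Weinberg expectation
#' sum over sites of (1 - 2 p (1 - p) n/(n-1)) with p the cohort allele
#' frequency and n the cohort's called allele copies at the site.
#'
#' @param x a [GenotypeMatrix-class].
#' @param samples sample(s) to evaluate (default: all non-outgroup).
#' @param cohort samples defining allele frequencies (default: all
#'   non-outgroup samples).
#' @return named numeric vector of F_H (NA when nothing is called).
#' @export
fH <- function(x, samples = NULL, cohort = NULL) {
  if (is.null(samples)) samples <- setdiff(colnames(x), outgroupSamples(x))
  if (is.null(cohort)) cohort <- setdiff(colnames(x), outgroupSamples(x))
  dc <- dosages(x)[, cohort, drop = FALSE]
  n <- 2 * rowSums(!is.na(dc))
  pfreq <- ifelse(n > 0, rowSums(dc, na.rm = TRUE) / n, NA)
  usable <- n >= 2
  e_site <- 1 - 2 * pfreq * (1 - pfreq) * n / (n - 1)
  d <- dosages(x)[, samples, drop = FALSE]
  out <- vapply(seq_along(samples), function(k) {
    called <- !is.na(d[, k]) & usable
    N <- sum(called)
    if (N == 0) return(NA_real_)
    e <- sum(e_site[called])
    o <- sum(d[called, k] != 1L)
    if (N - e == 0) return(NA_real_)
    (o - e) / (N - e)
  }, numeric(1))
  setNames(out, samples)
}

#' Per-sample inbreeding summary table
#'
#' Runs [detectROH()] for each sample and tabulates F_H, F_ROH at the
#' 100 kb / 1 Mb / 2 Mb thresholds, and ROH counts and summed lengths
#' per length class.
#'
#' @param x a [GenotypeMatrix-class].
#' @param p a [rohParams()].
#' @param genome_length genome denominator (default: summed contig
#'   lengths from the VCF header / simulator metadata).
#' @param samples samples to include (default: all non-outgroup).
#' @return data.frame, one row per sample.
#' @export
inbreedingTable <- function(x, p = rohParams(), genome_length = NULL,
                            samples = NULL) {
  if (is.null(samples)) samples <- setdiff(colnames(x), outgroupSamples(x))
  if (is.null(genome_length)) {
    sl <- metadata(x)$seqlengths
    if (is.null(sl)) stop("no contig lengths available; supply genome_length")
    genome_length <- sum(sl)
  }
  fh <- fH(x, samples)
  rows <- lapply(samples, function(s) {
    seg <- detectROH(x, s, p)
    cls <- table(seg$class)
    lens <- tapply(seg$length, seg$class, sum, default = 0)
    data.frame(sample = s, F_H = fh[[s]],
               F_ROH_100kb = fRoh(seg, genome_length, 1e5),
               F_ROH_1Mb = fRoh(seg, genome_length, 1e6),
               F_ROH_2Mb = fRoh(seg, genome_length, 2e6),
               n_roh_100kb_1Mb = as.integer(cls[["100kb-1Mb"]]),
               n_roh_1_2Mb = as.integer(cls[["1-2Mb"]]),
               n_roh_gt2Mb = as.integer(cls[[">2Mb"]]),
               sum_len_100kb_1Mb = as.numeric(lens[["100kb-1Mb"]]),
               sum_len_1_2Mb = as.numeric(lens[["1-2Mb"]]),
               sum_len_gt2Mb = as.numeric(lens[[">2Mb"]]),
               genome_length = genome_length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- p
  out
}
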