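#' Sliding-window specification
#'
#' @param window window length in bp (default 20 kb).
#' @param step step in bp (default 10 kb); must not exceed \code{window}.
#' @return a \code{WindowSpec} list.
#' @export
windowSpec <- function(window = 20000L, step = 10000L) {
  stopifnot(window > 0, step > 0, step <= window)
  structure(list(window = as.numeric(window), step = as.numeric(step)),
            class = "WindowSpec")
}

.chrom_lengths <- function(x) {
  sl <- metadata(x)$seqlengths
  rr <- rowRanges(x)
  chroms <- unique(as.character(seqnames(rr)))
  if (!is.null(sl) && all(chroms %in% names(sl)))
    return(sl[chroms])
  setNames(vapply(chroms, function(cc)
    max(start(rr)[as.character(seqnames(rr)) == cc]), numeric(1)), chroms)
}

# windows tile from position 0; trailing partial windows keep true span
.windows_for <- function(chrom_len, w) {
  starts <- seq(0, max(0, chrom_len - 1), by = w$step)
  ends <- pmin(starts + w$window, chrom_len)
  data.frame(start = starts, end = ends, span = ends - starts)
}

# per-site summaries within one population: called copies n, alt count j
.pop_site_counts <- function(x, pop) {
  d <- dosages(x)[, popSamples(x, pop), drop = FALSE]
  list(n = 2L * rowSums(!is.na(d)), j = rowSums(d, na.rm = TRUE))
}

.window_table <- function(x, persite, seg, w, denom_callable = FALSE) {
  rr <- rowRanges(x)
  chrom <- as.character(seqnames(rr))
  pos <- start(rr)
  lens <- .chrom_lengths(x)
  out <- lapply(names(lens), function(cc) {
    sel <- which(chrom == cc)
    p <- pos[sel]
    v <- persite[sel]
    s <- seg[sel]
    cum_v <- c(0, cumsum(v))
    cum_s <- c(0, cumsum(s))
    win <- .windows_for(lens[[cc]], w)
    hi <- findInterval(win$end, p)
    lo <- findInterval(win$start, p)
    win$S <- as.integer(cum_s[hi + 1] - cum_s[lo + 1])
    win$n_sites <- hi - lo
    win$value <- (cum_v[hi + 1] - cum_v[lo + 1]) /
      (if (denom_callable) pmax(win$n_sites, 1) else win$span)
    cbind(chrom = cc, win)
  })
  tab <- do.call(rbind, out)
  attr(tab, "genome_mean") <- sum(persite) / sum(lens)
  tab
}

#' Observed heterozygosity per individual
#'
#' Proportion of heterozygous genotypes among an individual's non-missing
#' genotype calls; optionally per bp given a callable genome length.
#'
#' @param x a [GenotypeMatrix-class].
#' @param samples sample name(s); default all.
#' @param callable_length optional callable genome length (bp); when given,
#'   heterozygous-site counts are divided by it instead of the called-site
#'   count.
#' @return named numeric vector (NA where a sample has no called sites).
#' @export
individualHeterozygosity <- function(x, samples = NULL,
                                     callable_length = NULL) {
  if (is.null(samples)) samples <- colnames(x)
  d <- dosages(x)[, samples, drop = FALSE]
  het <- colSums(d == 1L, na.rm = TRUE)
  called <- colSums(!is.na(d))
  out <- if (is.null(callable_length)) ifelse(called > 0, het / called, NA_real_)
         else het / callable_length
  setNames(out, samples)
}

#' Windowed nucleotide diversity (pi)
#'
#' Unbiased per-site pairwise diversity pi_i = 2 j (n - j) / (n (n - 1))
#' with j the alternate-allele count and n the called allele copies at the
#' site, summed per window and divided by the window span in bp (or by the
#' used-site count with \code{denom = "sites"}).
#'
#' @param x a [GenotypeMatrix-class].
#' @param pop population label (or sample-name vector).
#' @param w a [windowSpec()].
#' @param denom \code{"span"} (default) or \code{"sites"}.
#' @return data.frame per window (chrom, start, end, span, S, n_sites,
#'   value = pi); \code{attr(, "genome_mean")} holds the step-independent
#'   genome-wide mean (total per-site pi over total genome length).
#' @export
windowedPi <- function(x, pop, w = windowSpec(), denom = c("span", "sites")) {
  denom <- match.arg(denom)
  cnt <- .pop_site_counts(x, pop)
  n <- cnt$n; j <- cnt$j
  ok <- n >= 2
  pi_i <- numeric(length(n))
  pi_i[ok] <- 2 * j[ok] * (n[ok] - j[ok]) / (n[ok] * (n[ok] - 1))
  seg <- ok & j > 0 & j < n
  tab <- .window_table(x, pi_i, seg, w, denom_callable = denom == "sites")
  names(tab)[names(tab) == "value"] <- "pi"
  tab
}

#' Windowed Watterson's theta
#'
#' theta_w = S / (a_n * span) with a_n the harmonic number of (called
#' allele copies - 1). Sites whose called copy number deviates from others
#' contribute 1/a_{n_i} each, summed per window, so varying missingness is
#' handled per site.
#'
#' @inheritParams windowedPi
#' @return data.frame as [windowedPi()] with \code{value = theta_w}.
#' @export
windowedThetaW <- function(x, pop, w = windowSpec(),
                           denom = c("span", "sites")) {
  denom <- match.arg(denom)
  cnt <- .pop_site_counts(x, pop)
  n <- cnt$n; j <- cnt$j
  seg <- n >= 2 & j > 0 & j < n
  a_n <- numeric(length(n))
  a_n[seg] <- vapply(n[seg], function(k) sum(1 / seq_len(k - 1)), numeric(1))
  v <- numeric(length(n))
  v[seg] <- 1 / a_n[seg]
  tab <- .window_table(x, v, seg, w, denom_callable = denom == "sites")
  names(tab)[names(tab) == "value"] <- "theta_w"
  tab
}

# Weir & Cockerham (1984) two-population variance components per site
.wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise FST between two populations
#'
#' Weir-Cockerham (1984) variance components a (among populations), b, c
#' per site; window and genome-wide FST are the "weighted" ratio of
#' averages sum(a) / sum(a + b + c). The mean of per-site ratios is also
#' reported. A Hudson-style estimator (Bhatia et al. 2013 "ratio of
#' averages") is available for sensitivity.
#'
#' @param x a [GenotypeMatrix-class].
#' @param popA,popB population labels.
#' @param w a [windowSpec()].
#' @param estimator \code{"wc"} (default) or \code{"hudson"}.
#' @return list: \code{windows} (per-window data.frame with \code{fst}),
#'   \code{fst} (genome-wide weighted), \code{fst_mean_ratio} (mean of
#'   per-site ratios), \code{sd} (SD of per-window weighted values).
#'   All are NA when every site is monomorphic across both populations.
#' @export
pairwiseFst <- function(x, popA, popB, w = windowSpec(),
                        estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  dA <- dosages(x)[, popSamples(x, popA), drop = FALSE]
  dB <- dosages(x)[, popSamples(x, popB), drop = FALSE]
  n1 <- rowSums(!is.na(dA)); n2 <- rowSums(!is.na(dB))
  ok <- n1 >= 1 & n2 >= 1
  p1 <- ifelse(ok, rowSums(dA, na.rm = TRUE) / (2 * n1), NA)
  p2 <- ifelse(ok, rowSums(dB, na.rm = TRUE) / (2 * n2), NA)
  if (estimator == "wc") {
    h1 <- ifelse(ok, rowSums(dA == 1L, na.rm = TRUE) / n1, NA)
    h2 <- ifelse(ok, rowSums(dB == 1L, na.rm = TRUE) / n2, NA)
    num <- den <- numeric(nrow(x))
    use <- ok & (n1 + n2) > 2
    comp <- .wc_components(n1[use], n2[use], p1[use], p2[use], h1[use], h2[use])
    num[use] <- comp$a
    den[use] <- comp$a + comp$b + comp$c
  } else {
    c1 <- 2 * n1; c2 <- 2 * n2
    use <- ok & c1 >= 2 & c2 >= 2
    num <- den <- numeric(nrow(x))
    num[use] <- (p1[use] - p2[use])^2 -
      p1[use] * (1 - p1[use]) / (c1[use] - 1) -
      p2[use] * (1 - p2[use]) / (c2[use] - 1)
    den[use] <- p1[use] * (1 - p2[use]) + p2[use] * (1 - p1[use])
  }
  rr <- rowRanges(x)
  chrom <- as.character(seqnames(rr)); pos <- start(rr)
  lens <- .chrom_lengths(x)
  wins <- do.call(rbind, lapply(names(lens), function(cc) {
    sel <- which(chrom == cc)
    cn <- c(0, cumsum(num[sel])); cd <- c(0, cumsum(den[sel]))
    win <- .windows_for(lens[[cc]], w)
    hi <- findInterval(win$end, pos[sel]); lo <- findInterval(win$start, pos[sel])
    wn <- cn[hi + 1] - cn[lo + 1]; wd <- cd[hi + 1] - cd[lo + 1]
    win$n_sites <- hi - lo
    win$fst <- ifelse(wd > 0, wn / wd, NA_real_)
    cbind(chrom = cc, win)
  }))
  tot_den <- sum(den)
  ratio_sites <- den > 0
  list(windows = wins,
       fst = if (tot_den > 0) sum(num) / tot_den else NA_real_,
       fst_mean_ratio = if (any(ratio_sites))
         mean(num[ratio_sites] / den[ratio_sites]) else NA_real_,
       sd = stats::sd(wins$fst, na.rm = TRUE))
}

#' All-pairs FST matrix
#'
#' Genome-wide weighted FST above the diagonal, SD of per-window values
#' below, mirroring the conventional supplementary-table layout.
#'
#' @param x a [GenotypeMatrix-class].
#' @param w a [windowSpec()].
#' @param pops populations to include (default: all non-outgroup).
#' @param estimator passed to [pairwiseFst()].
#' @return square numeric matrix.
#' @export
fstMatrix <- function(x, w = windowSpec(), pops = NULL,
                      estimator = "wc") {
  if (is.null(pops))
    pops <- setdiff(unique(populations(x)),
                    unique(populations(x)[outgroupSamples(x)]))
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  diag(m) <- 0
  for (i in seq_along(pops)) for (j in seq_along(pops)) if (i < j) {
    f <- pairwiseFst(x, pops[i], pops[j], w, estimator)
    m[i, j] <- f$fst
    m[j, i] <- f$sd
  }
  m
}
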