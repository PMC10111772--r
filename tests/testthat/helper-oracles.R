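# independent brute-force oracle: explicit window enumeration with plain
# loops, structured differently from the detector's cumulative-sum scan
roh_oracle <- function(d, pos, p = rohParams()) {
  n <- length(d)
  if (n < p$window_snp) return(NULL)
  k <- p$window_snp
  nwin <- n - k + 1L
  hom_win <- logical(nwin)
  for (w in seq_len(nwin)) {
    win <- d[w:(w + k - 1L)]
    hom_win[w] <- sum(win == 1L, na.rm = TRUE) <= p$window_het &&
      sum(is.na(win)) <= p$window_missing
  }
  elig <- logical(n)
  for (i in seq_len(n)) {
    ws <- max(1L, i - k + 1L):min(nwin, i)
    elig[i] <- mean(hom_win[ws]) >= p$hit_threshold
  }
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!elig[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && elig[j + 1L] &&
           (pos[j + 1L] - pos[j]) <= p$max_gap_kb * 1000) j <- j + 1L
    len <- pos[j] - pos[i] + 1
    nsnp <- j - i + 1L
    if (nsnp >= p$min_snp && len >= p$min_kb * 1000 &&
        len / nsnp <= p$density_kb * 1000)
      segs[[length(segs) + 1L]] <- c(start = pos[i], end = pos[j],
                                     n_snps = nsnp)
    i <- j + 1L
  }
  if (!length(segs)) NULL else do.call(rbind, segs)
}

# heterozygous background with an optional planted homozygous tract
plant_sample <- function(n_snps, chrom_len, tract = NULL, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n_snps))
  d <- sample(c(0L, 1L, 2L), n_snps, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  if (!is.null(tract)) {
    inside <- pos >= tract[1] & pos <= tract[2]
    d[inside] <- sample(c(0L, 2L), sum(inside), replace = TRUE)
  }
  list(d = d, pos = pos)
}

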