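#' Identity-by-state and p-distance matrices
#'
#' For a biallelic site with ALT dosages d_i, d_j the shared-allele
#' identity of a sample pair is (2 - |d_i - d_j|) / 2, averaged over
#' co-called sites; the IBS distance is one minus that identity and the
#' p-distance is |d_i - d_j| / 2 averaged the same way, so the two are
#' equal by construction.
#'
#' @param x a [GenotypeMatrix-class].
#' @return symmetric distance matrix with zero diagonal; entries are NA
#'   for pairs with no co-called sites.
#' @export
ibsMatrix <- function(x) {
  d <- dosages(x)
  n <- ncol(d)
  if (n < 2) stop("need at least 2 samples")
  m <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cc <- !is.na(d[, i]) & !is.na(d[, j])
    m[i, j] <- m[j, i] <-
      if (!any(cc)) NA_real_ else mean(abs(d[cc, i] - d[cc, j]) / 2)
  }
  m
}

#' @rdname ibsMatrix
#' @export
pDistanceMatrix <- function(x) ibsMatrix(x)

# unbiased estimator of p^a * q^b from x successes among X allele draws
.mono <- function(xs, X, a, b) {
  num <- rep(1, length(xs))
  for (k in seq_len(a) - 1L) num <- num * (xs - k)
  for (k in seq_len(b) - 1L) num <- num * (X - xs - k)
  den <- rep(1, length(xs))
  for (k in seq_len(a + b) - 1L) den <- den * (X - k)
  num / den
}

#' Method-of-moments IBD estimation (Z0, Z1, Z2, PI_HAT)
#'
#' PLINK-style moment estimator: per pair, observed IBS-state counts over
#' co-called sites are equated with their expectations given IBD state,
#' where the expectations use finite-sample-unbiased estimates of the
#' allele-frequency monomials computed from the whole sample set. The
#' solved Z are bounded to [0, 1] and renormalised;
#' PI_HAT = Z1/2 + Z2. Pairs with PI_HAT at or above \code{min_pi} are
#' flagged (mirroring a \code{--min} reporting threshold), and pairs with
#' fewer than 50 informative sites are flagged low-confidence.
#'
#' @param x a [GenotypeMatrix-class].
#' @param min_pi reporting-flag threshold on PI_HAT (default 0.05).
#' @param freq_pop optional population label: estimate allele frequencies
#'   from that population only instead of the full sample set.
#' @return data.frame per pair: id1, id2, n_sites, Z0, Z1, Z2, PI_HAT,
#'   flagged, low_confidence.
#' @export
ibdMoments <- function(x, min_pi = 0.05, freq_pop = NULL) {
  d <- dosages(x)
  n <- ncol(d)
  if (n < 2) stop("need at least 2 samples")
  fd <- if (is.null(freq_pop)) d else d[, popSamples(x, freq_pop), drop = FALSE]
  X <- 2 * rowSums(!is.na(fd))
  xs <- rowSums(fd, na.rm = TRUE)
  ok <- X >= 4 & xs > 0 & xs < X   # polymorphic, enough copies for corrections
  # per-site expectations given IBD state (bias-corrected)
  e00 <- 2 * .mono(xs, X, 2, 2)
  e01 <- 4 * .mono(xs, X, 3, 1) + 4 * .mono(xs, X, 1, 3)
  e02 <- .mono(xs, X, 4, 0) + .mono(xs, X, 0, 4) + 4 * .mono(xs, X, 2, 2)
  e11 <- 2 * .mono(xs, X, 2, 1) + 2 * .mono(xs, X, 1, 2)
  e12 <- .mono(xs, X, 3, 0) + .mono(xs, X, 0, 3) +
    .mono(xs, X, 2, 1) + .mono(xs, X, 1, 2)
  pairs <- t(utils::combn(n, 2))
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    cc <- ok & !is.na(d[, i]) & !is.na(d[, j])
    ad <- abs(d[cc, i] - d[cc, j])
    ibs0 <- sum(ad == 2)
    ibs1 <- sum(ad == 1)
    ibs2 <- sum(ad == 0)
    E00 <- sum(e00[cc]); E01 <- sum(e01[cc]); E02 <- sum(e02[cc])
    E11 <- sum(e11[cc]); E12 <- sum(e12[cc]); E22 <- sum(cc)
    z0 <- if (E00 > 0) ibs0 / E00 else 0
    z1 <- if (E11 > 0) (ibs1 - z0 * E01) / E11 else 0
    z2 <- if (E22 > 0) (ibs2 - z0 * E02 - z1 * E12) / E22 else 0
    z <- pmin(pmax(c(z0, z1, z2), 0), 1)
    if (sum(z) > 0) z <- z / sum(z) else z <- c(1, 0, 0)
    data.frame(id1 = colnames(d)[i], id2 = colnames(d)[j],
               n_sites = sum(cc), Z0 = z[1], Z1 = z[2], Z2 = z[3],
               PI_HAT = z[2] / 2 + z[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$flagged <- out$PI_HAT >= min_pi
  out$low_confidence <- out$n_sites < 50
  out
}

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per site, sites are centred by twice
#' the allele frequency and scaled by sqrt(2 p (1 - p)), and the sample
#' covariance (genetic relationship) matrix is eigendecomposed.
#' Coordinates are the unit-norm eigenvectors; deterministic up to sign.
#'
#' @param x a [GenotypeMatrix-class].
#' @param k number of components.
#' @param samples samples to include (default: all non-outgroup).
#' @return list: \code{coords} (samples x k matrix), \code{explained}
#'   (fraction of total variance per component).
#' @export
genotypePCA <- function(x, k = 2L, samples = NULL) {
  if (is.null(samples)) samples <- setdiff(colnames(x), outgroupSamples(x))
  d <- dosages(x)[, samples, drop = FALSE]
  p <- rowMeans(d, na.rm = TRUE) / 2
  variable <- !is.na(p) & p > 0 & p < 1
  if (!any(variable)) stop("no variable sites for PCA")
  d <- d[variable, , drop = FALSE]
  p <- p[variable]
  m <- d - 2 * p
  m[is.na(m)] <- 0
  m <- m / sqrt(2 * p * (1 - p))
  grm <- crossprod(m) / nrow(m)
  eg <- eigen(grm, symmetric = TRUE)
  k <- min(k, ncol(grm))
  coords <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(coords) <- samples
  colnames(coords) <- paste0("PC", seq_len(k))
  pos <- pmax(eg$values, 0)
  list(coords = coords, explained = pos[seq_len(k)] / sum(pos))
}
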