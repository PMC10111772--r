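#' @importFrom stats pnorm p.adjust
NULL

# delete-one block jackknife of a ratio statistic.
# num, den: per-site vectors already restricted to informative sites.
.block_jackknife_ratio <- function(num, den, block_size) {
  n <- length(num)
  if (n == 0 || sum(den) == 0)
    return(list(est = NA_real_, se = NA_real_, n_blocks = 0L))
  est <- sum(num) / sum(den)
  blocks <- ceiling(seq_len(n) / block_size)
  g <- max(blocks)
  if (g < 2) return(list(est = est, se = NA_real_, n_blocks = g))
  bn <- tapply(num, blocks, sum)
  bd <- tapply(den, blocks, sum)
  loo <- (sum(bn) - bn) / (sum(bd) - bd)
  loo <- loo[is.finite(loo)]
  g <- length(loo)
  if (g < 2) return(list(est = est, se = NA_real_, n_blocks = g))
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  list(est = est, se = se, n_blocks = g)
}

.derived_freqs <- function(x, pops) {
  anc <- ancestralAlleles(x)
  if (all(anc == "unknown"))
    stop("sites are not polarized; run polarizeByOutgroup() first")
  lapply(pops, function(p) popFreq(x, p, derived = TRUE)$freq)
}

#' Patterson's D statistic (ABBA-BABA test)
#'
#' Frequency-based D for the quartet (P1, P2; P3, Outgroup): with
#' per-population derived-allele frequencies p1..p4 at each polarized
#' site, ABBA = (1-p1) p2 p3 (1-p4) and BABA = p1 (1-p2) p3 (1-p4);
#' D = sum(ABBA - BABA) / sum(ABBA + BABA). The standard error comes
#' from a delete-one block jackknife over consecutive blocks of
#' informative polymorphic sites, and Z = D / SE. |Z| > 3 is the
#' conventional significance flag.
#'
#' @param x a polarized [GenotypeMatrix-class].
#' @param p1,p2,p3 ingroup population labels (or sample-name vectors for
#'   singleton populations).
#' @param outgroup outgroup population label (or sample names).
#' @param block_size jackknife block size in polymorphic sites.
#' @return data.frame row: P1, P2, P3, O, ABBA, BABA, D, SE, Z,
#'   n_blocks, n_sites, significant.
#' @export
dStatistic <- function(x, p1, p2, p3, outgroup, block_size = 1000L) {
  fr <- .derived_freqs(x, list(p1, p2, p3, outgroup))
  ok <- Reduce(`&`, lapply(fr, function(f) !is.na(f)))
  f1 <- fr[[1]][ok]; f2 <- fr[[2]][ok]; f3 <- fr[[3]][ok]; f4 <- fr[[4]][ok]
  abba <- (1 - f1) * f2 * f3 * (1 - f4)
  baba <- f1 * (1 - f2) * f3 * (1 - f4)
  info <- abba + baba > 0
  jk <- .block_jackknife_ratio((abba - baba)[info], (abba + baba)[info],
                               block_size)
  d <- jk$est
  z <- if (!is.na(jk$se) && jk$se > 0) d / jk$se else NA_real_
  data.frame(P1 = paste(p1, collapse = ","), P2 = paste(p2, collapse = ","),
             P3 = paste(p3, collapse = ","), O = paste(outgroup, collapse = ","),
             ABBA = sum(abba), BABA = sum(baba), D = d, SE = jk$se, Z = z,
             n_blocks = jk$n_blocks, n_sites = sum(info),
             significant = !is.na(z) && abs(z) > 3,
             stringsAsFactors = FALSE)
}

#' f4 statistic
#'
#' f4(W, X; Y, Z) = sum over polarized sites of (pW - pX)(pY - pZ), with
#' per-population derived-allele frequencies.
#'
#' @param x a polarized [GenotypeMatrix-class].
#' @param w,xx,y,z population labels or sample-name vectors.
#' @return the f4 sum (a number).
#' @export
f4Statistic <- function(x, w, xx, y, z) {
  fr <- .derived_freqs(x, list(w, xx, y, z))
  ok <- Reduce(`&`, lapply(fr, function(f) !is.na(f)))
  sum((fr[[1]][ok] - fr[[2]][ok]) * (fr[[3]][ok] - fr[[4]][ok]))
}

#' f4-ratio admixture proportion
#'
#' alpha = f4(A, O; X, C) / f4(A, O; B, C) for a target X admixed
#' between a donor clade (represented by B, with A a second, more
#' distant representative of the same clade) and the sister lineage of
#' C. Jackknifed over consecutive site blocks as in [dStatistic()];
#' the raw (unclamped) alpha is reported with a flag when it falls
#' outside [0, 1].
#'
#' @param x a polarized [GenotypeMatrix-class].
#' @param A donor-clade outer representative.
#' @param B donor population (numerator test branch uses X in its place).
#' @param X target population or focal sample name(s).
#' @param C sister population of X's unadmixed ancestry.
#' @param outgroup outgroup label or samples.
#' @param block_size jackknife block size (sites).
#' @return data.frame row: A, B, X, C, O, alpha, SE, Z, p, n_blocks,
#'   outside_unit.
#' @export
f4Ratio <- function(x, A, B, X, C, outgroup, block_size = 1000L) {
  fr <- .derived_freqs(x, list(A, B, X, C, outgroup))
  ok <- Reduce(`&`, lapply(fr, function(f) !is.na(f)))
  fA <- fr[[1]][ok]; fB <- fr[[2]][ok]; fX <- fr[[3]][ok]
  fC <- fr[[4]][ok]; fO <- fr[[5]][ok]
  num <- (fA - fO) * (fX - fC)
  den <- (fA - fO) * (fB - fC)
  info <- num != 0 | den != 0
  if (!any(info) || abs(sum(den)) < .Machine$double.eps)
    return(data.frame(A = paste(A, collapse = ","), B = paste(B, collapse = ","),
                      X = paste(X, collapse = ","), C = paste(C, collapse = ","),
                      O = paste(outgroup, collapse = ","),
                      alpha = NA_real_, SE = NA_real_, Z = NA_real_,
                      p = NA_real_, n_blocks = 0L, outside_unit = NA,
                      stringsAsFactors = FALSE))
  jk <- .block_jackknife_ratio(num[info], den[info], block_size)
  z <- if (!is.na(jk$se) && jk$se > 0) jk$est / jk$se else NA_real_
  data.frame(A = paste(A, collapse = ","), B = paste(B, collapse = ","),
             X = paste(X, collapse = ","), C = paste(C, collapse = ","),
             O = paste(outgroup, collapse = ","),
             alpha = jk$est, SE = jk$se, Z = z,
             p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
             n_blocks = jk$n_blocks,
             outside_unit = !is.na(jk$est) && (jk$est < 0 || jk$est > 1),
             stringsAsFactors = FALSE)
}

#' Per-individual mean introgression ratios
#'
#' Runs [f4Ratio()] for every (focal sample, donor) combination described
#' by the quartet configuration, treating each focal sample as a
#' singleton population, adjusts p-values by Benjamini-Hochberg across
#' all tests, and summarises the retained (q < fdr) admixture
#' proportions per focal sample. Three summaries are emitted, since
#' "mean ratio" can average over retained tests, over all tests, or over
#' per-donor means.
#'
#' @param x a polarized [GenotypeMatrix-class].
#' @param focal character vector of focal sample names.
#' @param quartets data.frame with columns \code{donor}, \code{A}
#'   (donor-clade outer representative) and \code{C} (sister of the
#'   focal lineage); one f4-ratio is run per focal sample and row with
#'   B = donor and X = the focal sample.
#' @param outgroup outgroup population or samples.
#' @param fdr false-discovery-rate level for retaining tests (1 keeps
#'   all).
#' @param block_size jackknife block size.
#' @return list: \code{tests} (all f4-ratio rows with q-values),
#'   \code{per_donor} (focal x donor mean retained alpha with n),
#'   \code{per_focal} (mean_retained, mean_all, mean_of_donor_means,
#'   n_retained per focal sample).
#' @export
perIndividualMeanIntrogression <- function(x, focal, quartets, outgroup,
                                           fdr = 0.05, block_size = 1000L) {
  rows <- list()
  for (f in focal) for (k in seq_len(nrow(quartets))) {
    r <- f4Ratio(x, A = quartets$A[k], B = quartets$donor[k], X = f,
                 C = quartets$C[k], outgroup = outgroup,
                 block_size = block_size)
    r$focal <- f
    r$donor <- quartets$donor[k]
    rows[[length(rows) + 1L]] <- r
  }
  tests <- do.call(rbind, rows)
  tests$q <- p.adjust(tests$p, method = "BH")
  tests$retained <- !is.na(tests$q) & tests$q < fdr
  per_donor <- do.call(rbind, lapply(
    split(tests, list(tests$focal, tests$donor), drop = TRUE),
    function(df) data.frame(focal = df$focal[1], donor = df$donor[1],
                            mean_alpha = if (any(df$retained))
                              mean(df$alpha[df$retained]) else 0,
                            n_retained = sum(df$retained))))
  rownames(per_donor) <- NULL
  per_focal <- do.call(rbind, lapply(split(tests, tests$focal), function(df) {
    pd <- per_donor[per_donor$focal == df$focal[1], ]
    data.frame(focal = df$focal[1],
               mean_retained = if (any(df$retained))
                 mean(df$alpha[df$retained]) else 0,
               mean_all = mean(df$alpha, na.rm = TRUE),
               mean_of_donor_means = mean(pd$mean_alpha),
               n_retained = sum(df$retained))
  }))
  rownames(per_focal) <- NULL
  list(tests = tests, per_donor = per_donor, per_focal = per_focal)
}

#' Read a quartet configuration TSV
#'
#' Tab-separated with header columns \code{donor}, \code{A}, \code{C}.
#' @param path file path.
#' @return data.frame.
#' @export
readQuartets <- function(path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
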