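#' Fast frequency-level site simulators
#'
#' Companions to the forward simulator for large-site calibration
#' studies: instead of evolving haplotypes, each site's population
#' allele frequencies are drawn from hierarchical Balding-Nichols beta
#' drift along a fixed population tree, and diploid genotypes are then
#' binomially sampled. This gives exchangeable, LD-free sites — exactly
#' the regime in which jackknife calibration of D and f4 statistics is
#' interpretable — at tens of thousands of sites per second.
#'
#' \code{simulateQuartetSites} generates the asymmetric quartet
#' (((P1, P2), P3), O) with an optional introgression pulse of fraction
#' \code{f} from P3 into P2 (frequency-level admixture).
#'
#' \code{simulateF4Sites} generates ((A, B), (X0, C)) plus outgroup O,
#' with X an admixed population drawing a fraction \code{alpha} of its
#' ancestry from a sister lineage of B (sharing the A+B clade branch)
#' and 1 - alpha from X0 (sister of C), so the f4-ratio
#' f4(A,O;X,C) / f4(A,O;B,C) recovers alpha in expectation.
#'
#' Default drift depths mirror the study system: the two focal sister
#' populations are recently separated captive lineages (short terminal
#' branches), the donor is a deeply diverged subspecies (long terminal
#' branch), and the outgroup is a distant species at which most sites
#' are effectively fixed for the ancestral allele.
#'
#' @param n_sites number of sites.
#' @param n_per_pop diploid samples per population.
#' @param f,alpha admixture fraction.
#' @param F_branch Balding-Nichols drift (FST-like) on the focal sister
#'   populations' terminal branches.
#' @param F_donor drift on the donor population's terminal branch.
#' @param F_shared drift on the shared internal branch.
#' @param F_stem drift on the ingroup stem branch.
#' @param F_out drift on the outgroup branch.
#' @param seed integer seed.
#' @return a polarized [GenotypeMatrix-class] (the truth ancestral
#'   allele is REF; the outgroup population is \code{"O"}, sampled and
#'   designated, with ancestral calls already set from the truth so the
#'   statistics can be used directly).
#' @name site-simulators
NULL

.bn_drift <- function(p, F) {
  if (F <= 0) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  stats::rbeta(length(p), a, b)
}

.freqs_to_gm <- function(freqs, n_per_pop, og_pop = "O") {
  pops <- names(freqs)
  n_sites <- length(freqs[[1]])
  dos <- do.call(cbind, lapply(pops, function(p) {
    matrix(rbinom(n_sites * n_per_pop, 2L, rep(freqs[[p]], n_per_pop)),
           n_sites, n_per_pop)
  }))
  samples <- unlist(lapply(pops, function(p) paste0(p, "_", seq_len(n_per_pop))))
  poplab <- rep(pops, each = n_per_pop)
  og <- samples[poplab == og_pop]
  GenotypeMatrix(dos, chrom = "chr1", pos = seq_len(n_sites) * 100L,
                 ref = "A", alt = "G", samples = samples,
                 populations = poplab, outgroup = og,
                 ancestral = "ref",
                 seqlengths = c(chr1 = (n_sites + 1) * 100))
}

#' @rdname site-simulators
#' @export
simulateQuartetSites <- function(n_sites = 50000L, n_per_pop = 5L, f = 0,
                                 F_branch = 0.02, F_donor = 0.3,
                                 F_shared = 0.1, F_stem = 0.05,
                                 F_out = 0.8, seed = 1L) {
  set.seed(seed)
  p0 <- runif(n_sites, 0.05, 0.95)
  pO <- .bn_drift(p0, F_out)
  p_in <- .bn_drift(p0, F_stem)
  p12 <- .bn_drift(p_in, F_shared)
  p1 <- .bn_drift(p12, F_branch)
  p2 <- .bn_drift(p12, F_branch)
  p3 <- .bn_drift(p_in, F_donor)
  if (f > 0) p2 <- (1 - f) * p2 + f * p3
  .freqs_to_gm(list(P1 = p1, P2 = p2, P3 = p3, O = pO), n_per_pop)
}

#' @rdname site-simulators
#' @export
simulateF4Sites <- function(n_sites = 50000L, n_per_pop = 5L, alpha = 0.1,
                            F_branch = 0.05, F_shared = 0.2,
                            F_stem = 0.05, F_out = 0.8, seed = 1L) {
  set.seed(seed)
  p0 <- runif(n_sites, 0.05, 0.95)
  pO <- .bn_drift(p0, F_out)
  p1 <- .bn_drift(p0, F_stem)
  pAB <- .bn_drift(p1, F_shared)     # donor clade
  pA <- .bn_drift(pAB, F_branch)
  pB <- .bn_drift(pAB, F_branch)
  pBsrc <- .bn_drift(pAB, F_branch)  # unsampled donor lineage
  pXC <- .bn_drift(p1, F_shared)
  pC <- .bn_drift(pXC, F_branch)
  pX0 <- .bn_drift(pXC, F_branch)
  pX <- alpha * pBsrc + (1 - alpha) * pX0
  pX <- .bn_drift(pX, 0.005)         # light post-admixture drift
  .freqs_to_gm(list(A = pA, B = pB, X = pX, C = pC, O = pO), n_per_pop)
}

#' Simulate unstructured Hardy-Weinberg genotypes
#'
#' One panmictic population: per-site allele frequencies uniform on
#' (0.05, 0.95), genotypes Binomial(2, p). Used for null calibration of
#' F_H and pairwise IBD.
#'
#' @param n_sites,n_samples dimensions.
#' @param seed integer seed.
#' @return a [GenotypeMatrix-class].
#' @export
simulateHWESites <- function(n_sites = 10000L, n_samples = 20L, seed = 1L) {
  set.seed(seed)
  p <- runif(n_sites, 0.05, 0.95)
  dos <- matrix(rbinom(n_sites * n_samples, 2L, rep(p, n_samples)),
                n_sites, n_samples)
  GenotypeMatrix(dos, chrom = "chr1", pos = seq_len(n_sites) * 100L,
                 ref = "A", alt = "G",
                 samples = paste0("s", seq_len(n_samples)),
                 populations = "pop1", ancestral = "ref",
                 seqlengths = c(chr1 = (n_sites + 1) * 100))
}
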