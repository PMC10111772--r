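#' @importFrom stats t.test
NULL

.SEVERITY <- c(HIGH = 3L, MODERATE = 2L, LOW = 1L)

#' Classify coding effects of SNPs
#'
#' A minimal codon-level effect classifier over CDS gene models:
#' reference and alternate codons are translated under the standard
#' genetic code with strand-aware complementing, and each coding SNP is
#' assigned HIGH (stop-gain, stop-loss, start-loss, or splice-site
#' disruption within \code{splice_bp} of an intron boundary), MODERATE
#' (missense) or LOW (synonymous). When several transcripts overlap a
#' site the most severe effect wins. Sites outside CDS and splice
#' regions are "noncoding"; sites whose REF allele contradicts the
#' reference sequence are warned about and excluded ("mismatch").
#'
#' @param x a [GenotypeMatrix-class].
#' @param gff path to a GFF3 file (or a \code{GRanges}) with CDS
#'   features carrying transcript Parent/ID attributes, strand and phase.
#' @param reference path to the reference FASTA (or a
#'   \code{DNAStringSet}).
#' @param splice_bp intronic bases adjacent to each CDS junction treated
#'   as splice sites (default 2).
#' @return character vector per site: "HIGH", "MODERATE", "LOW",
#'   "noncoding" or "mismatch".
#' @export
classifyEffects <- function(x, gff, reference, splice_bp = 2L) {
  gr <- if (is(gff, "GRanges")) gff else rtracklayer::import(gff)
  seqs <- if (is(reference, "DNAStringSet")) reference
          else Biostrings::readDNAStringSet(reference)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  cds <- gr[gr$type == "CDS"]
  tx_id <- if (!is.null(cds$Parent) && any(lengths(cds$Parent) > 0))
    vapply(as.list(cds$Parent), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  else as.character(cds$ID)
  rr <- rowRanges(x)
  chrom <- as.character(seqnames(rr)); pos <- start(rr)
  m <- mcols(rr)
  sev <- rep(0L, nrow(x))      # 0 = noncoding
  mismatch <- rep(FALSE, nrow(x))
  code <- Biostrings::GENETIC_CODE

  for (tx in unique(tx_id)) {
    part <- cds[tx_id == tx]
    strand_tx <- as.character(GenomicRanges::strand(part))[1]
    ord <- order(start(part))
    part <- part[ord]
    chr <- as.character(seqnames(part))[1]
    if (!chr %in% names(seqs)) next
    chrseq <- seqs[[chr]]
    # spliced CDS sequence in transcript orientation
    pieces <- lapply(seq_along(part), function(i)
      as.character(Biostrings::subseq(chrseq, start(part)[i], end(part)[i])))
    cds_seq <- paste(pieces, collapse = "")
    if (strand_tx == "-")
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
    # genomic position -> CDS coordinate
    widths <- end(part) - start(part) + 1L
    offs <- cumsum(c(0L, widths))[seq_along(part)]
    total <- sum(widths)
    # splice regions: splice_bp intronic bases flanking internal junctions
    if (length(part) > 1 && splice_bp > 0) {
      ints_start <- end(part)[-length(part)] + 1L
      ints_end <- start(part)[-1] - 1L
      for (iv in seq_along(ints_start)) {
        if (ints_end[iv] < ints_start[iv]) next
        sp <- which(chrom == chr &
                      ((pos >= ints_start[iv] &
                          pos <= min(ints_start[iv] + splice_bp - 1L, ints_end[iv])) |
                         (pos <= ints_end[iv] &
                            pos >= max(ints_end[iv] - splice_bp + 1L, ints_start[iv]))))
        sev[sp] <- pmax(sev[sp], 3L)
      }
    }
    hits <- which(chrom == chr & pos >= min(start(part)) & pos <= max(end(part)))
    for (si in hits) {
      piece <- which(pos[si] >= start(part) & pos[si] <= end(part))
      if (!length(piece)) next
      p_cds <- offs[piece] + (pos[si] - start(part)[piece]) + 1L
      if (strand_tx == "-") p_cds <- total - p_cds + 1L
      ref_tx <- m$ref[si]; alt_tx <- m$alt[si]
      if (strand_tx == "-") {
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        ref_tx <- comp[[ref_tx]]; alt_tx <- comp[[alt_tx]]
      }
      if (substr(cds_seq, p_cds, p_cds) != ref_tx) {
        mismatch[si] <- TRUE
        next
      }
      codon_i <- (p_cds - 1L) %/% 3L
      cs <- codon_i * 3L + 1L
      if (cs + 2L > total) next   # trailing partial codon
      ref_codon <- substr(cds_seq, cs, cs + 2L)
      alt_codon <- ref_codon
      substr(alt_codon, p_cds - cs + 1L, p_cds - cs + 1L) <- alt_tx
      ref_aa <- code[[ref_codon]]
      alt_aa <- code[[alt_codon]]
      eff <- if (ref_aa != "*" && alt_aa == "*") 3L          # stop-gain
        else if (ref_aa == "*" && alt_aa != "*") 3L          # stop-loss
        else if (codon_i == 0L && ref_codon == "ATG" &&
                 alt_codon != "ATG") 3L                      # start-loss
        else if (ref_aa != alt_aa) 2L                        # missense
        else 1L                                              # synonymous
      sev[si] <- max(sev[si], eff)
    }
  }
  out <- rep("noncoding", nrow(x))
  out[sev == 1L] <- "LOW"
  out[sev == 2L] <- "MODERATE"
  out[sev == 3L] <- "HIGH"
  if (any(mismatch & sev == 0L)) {
    warning(sum(mismatch & sev == 0L),
            " site(s) mismatch the reference sequence; excluded")
    out[mismatch & sev == 0L] <- "mismatch"
  }
  out
}

#' Impact-stratified mutation-load table
#'
#' Per sample and impact category, counts of homozygous-derived
#' (derived dosage 2) and heterozygous (dosage 1) genotypes over
#' polarized sites, the homozygote proportion hom / (hom + het),
#' population means, and Welch t-tests comparing per-individual
#' homozygote counts between populations within each category.
#'
#' @param x a polarized [GenotypeMatrix-class].
#' @param categories per-site category vector from [classifyEffects()]
#'   (or the simulator truth); only HIGH/MODERATE/LOW sites enter.
#' @param samples samples to tabulate (default: all non-outgroup).
#' @return list: \code{individuals} (sample x category counts and
#'   proportions), \code{population_means}, \code{tests} (pairwise Welch
#'   t-tests on homozygote counts per category).
#' @export
loadTable <- function(x, categories, samples = NULL) {
  if (is.null(samples)) samples <- setdiff(colnames(x), outgroupSamples(x))
  dd <- derivedDosages(x)[, samples, drop = FALSE]
  known <- ancestralAlleles(x) != "unknown"
  cats <- c("HIGH", "MODERATE", "LOW")
  rows <- list()
  for (cat in cats) {
    sel <- known & categories == cat
    hom <- colSums(dd[sel, , drop = FALSE] == 2L, na.rm = TRUE)
    het <- colSums(dd[sel, , drop = FALSE] == 1L, na.rm = TRUE)
    rows[[cat]] <- data.frame(sample = samples,
                              population = populations(x)[samples],
                              category = cat, hom = hom, het = het,
                              prop_hom = ifelse(hom + het > 0,
                                                hom / (hom + het), NA_real_),
                              stringsAsFactors = FALSE)
  }
  ind <- do.call(rbind, rows)
  rownames(ind) <- NULL
  pm <- stats::aggregate(cbind(hom, het, prop_hom) ~ population + category,
                         data = ind, FUN = mean, na.action = stats::na.omit)
  pops <- unique(ind$population)
  tests <- list()
  if (length(pops) > 1) {
    for (cat in cats) for (i in seq_along(pops)) for (j in seq_along(pops)) {
      if (i >= j) next
      a <- ind$hom[ind$category == cat & ind$population == pops[i]]
      b <- ind$hom[ind$category == cat & ind$population == pops[j]]
      if (length(a) < 2 || length(b) < 2 ||
          (stats::var(a) == 0 && stats::var(b) == 0)) next
      tt <- t.test(a, b)
      tests[[length(tests) + 1L]] <-
        data.frame(category = cat, popA = pops[i], popB = pops[j],
                   mean_hom_A = mean(a), mean_hom_B = mean(b),
                   t = unname(tt$statistic), p = tt$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  list(individuals = ind, population_means = pm,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' Unfolded site-frequency spectrum per impact category
#'
#' Derived-allele counts across polymorphic sites of a population, per
#' impact category. Sites whose called allele copies deviate from the
#' target are projected down by the hypergeometric expectation
#' (fractional counts) or excluded, per flag. Fixed-ancestral and
#' fixed-derived classes are excluded from the polymorphic spectrum. A
#' binned view summarises derived counts at or above \code{bin_from}
#' as the mean number of sites per allele-count class within
#' consecutive intervals of \code{bin_width}.
#'
#' @param x a polarized [GenotypeMatrix-class].
#' @param categories per-site category vector; use \code{NULL} for a
#'   single spectrum over all polarized sites.
#' @param pop population label or sample names.
#' @param project_n target allele copies (default: maximum observed);
#'   with \code{deviating = "project"} smaller-sample sites contribute
#'   hypergeometric expected fractions, larger are downsampled the same
#'   way.
#' @param deviating \code{"project"} (default) or \code{"exclude"}.
#' @param bin_from,bin_width binned-view parameters.
#' @return list with \code{spectrum} (data.frame category, count, sites)
#'   and \code{binned} (category, interval, mean_sites).
#' @export
sfsSpectrum <- function(x, categories = NULL, pop,
                        project_n = NULL,
                        deviating = c("project", "exclude"),
                        bin_from = 10L, bin_width = 5L) {
  deviating <- match.arg(deviating)
  dd <- derivedDosages(x)[, popSamples(x, pop), drop = FALSE]
  n_i <- 2L * rowSums(!is.na(dd))
  j_i <- rowSums(dd, na.rm = TRUE)
  if (is.null(categories)) categories <- rep("ALL", nrow(x))
  known <- ancestralAlleles(x) != "unknown" & n_i >= 2
  if (is.null(project_n)) {
    # modal called copy number; only larger samples can be projected down
    tab <- table(n_i[known])
    project_n <- as.integer(names(tab)[which.max(tab)])
  }
  cats <- setdiff(unique(categories[known]), c("noncoding", "mismatch"))
  spec <- list()
  for (cat in cats) {
    sel <- which(known & categories == cat & j_i > 0 & j_i < n_i)
    counts <- numeric(project_n - 1L)
    for (si in sel) {
      n <- n_i[si]; j <- j_i[si]
      if (n == project_n) {
        counts[j] <- counts[j] + 1
      } else if (deviating == "project" && n > project_n) {
        kk <- seq_len(project_n - 1L)
        w <- stats::dhyper(kk, j, n - j, project_n)
        counts <- counts + w   # polymorphic classes only
      }                        # n < project_n cannot be projected: excluded
    }
    spec[[cat]] <- data.frame(category = cat, count = seq_len(project_n - 1L),
                              sites = counts, stringsAsFactors = FALSE)
  }
  spectrum <- do.call(rbind, spec)
  rownames(spectrum) <- NULL
  binned <- do.call(rbind, lapply(split(spectrum, spectrum$category),
    function(df) {
      lowp <- df[df$count < bin_from, ]
      lo <- data.frame(category = df$category[1],
                       interval = as.character(lowp$count),
                       mean_sites = lowp$sites)
      hip <- df[df$count >= bin_from, ]
      if (nrow(hip)) {
        grp <- (hip$count - bin_from) %/% bin_width
        hi <- do.call(rbind, lapply(split(hip, grp), function(g)
          data.frame(category = g$category[1],
                     interval = paste0(min(g$count), "-", max(g$count)),
                     mean_sites = mean(g$sites))))
        rbind(lo, hi)
      } else lo
    }))
  rownames(binned) <- NULL
  list(spectrum = spectrum, binned = binned,
       n = project_n)
}

#' Rxy relative mutation load
#'
#' For a mutation category with derived frequencies d^X, d^Y in
#' populations X and Y over the category's polarized sites,
#' L(X not Y) = sum d^X (1 - d^Y) and L(Y not X) = sum d^Y (1 - d^X);
#' Rxy = L(X not Y) / L(Y not X). Rxy < 1 indicates a relative deficit
#' of derived alleles of that category in X. A delete-one chromosome
#' jackknife gives the confidence interval; optionally the ratio is
#' normalised by the same ratio computed on a neutral reference
#' category's sites.
#'
#' @param x a polarized [GenotypeMatrix-class].
#' @param categories per-site category vector.
#' @param category category to evaluate (e.g. "HIGH").
#' @param popX,popY population labels or sample-name vectors.
#' @param normalize_by optional neutral category (e.g. "LOW") used to
#'   normalise Rxy (off by default).
#' @param conf confidence level for the jackknife CI.
#' @return data.frame row: category, LXnotY, LYnotX, Rxy, ci_lo, ci_hi,
#'   n_sites.
#' @export
rxy <- function(x, categories, category, popX, popY, normalize_by = NULL,
                conf = 0.95) {
  ratio_for <- function(sel) {
    fX <- popFreq(x, popX, derived = TRUE)$freq[sel]
    fY <- popFreq(x, popY, derived = TRUE)$freq[sel]
    ok <- !is.na(fX) & !is.na(fY)
    list(num = fX[ok] * (1 - fY[ok]), den = fY[ok] * (1 - fX[ok]),
         chrom = as.character(seqnames(rowRanges(x)))[sel][ok])
  }
  known <- ancestralAlleles(x) != "unknown"
  sel <- which(known & categories == category)
  if (!length(sel)) stop("no polarized sites in category '", category, "'")
  r <- ratio_for(sel)
  if (sum(r$den) == 0)
    return(data.frame(category = category, LXnotY = sum(r$num), LYnotX = 0,
                      Rxy = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      n_sites = length(r$num)))
  est <- sum(r$num) / sum(r$den)
  norm <- 1
  if (!is.null(normalize_by)) {
    seln <- which(known & categories == normalize_by)
    rn <- ratio_for(seln)
    norm <- sum(rn$num) / sum(rn$den)
    est <- est / norm
  }
  chroms <- unique(r$chrom)
  ci <- c(NA_real_, NA_real_)
  if (length(chroms) >= 2) {
    loo <- vapply(chroms, function(cc) {
      keep <- r$chrom != cc
      (sum(r$num[keep]) / sum(r$den[keep])) / norm
    }, numeric(1))
    g <- length(loo)
    se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
    zq <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- c(est - zq * se, est + zq * se)
  }
  data.frame(category = category, LXnotY = sum(r$num), LYnotX = sum(r$den),
             Rxy = est, ci_lo = ci[1], ci_hi = ci[2],
             n_sites = length(r$num), stringsAsFactors = FALSE)
}
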