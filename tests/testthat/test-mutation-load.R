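# toy genome: chrA carries a two-exon plus-strand gene
#   CDS = ATG CAA CTT GAA | CCC GGG TAC TAA  (exon1 11-22, intron 23-40,
#   exon2 41-52)
toy_reference <- function() {
  filler <- function(n) paste(rep("T", n), collapse = "")
  chrA <- paste0(filler(10), "ATGCAACTTGAA", filler(18), "CCCGGGTACTAA",
                 filler(48))
  Biostrings::DNAStringSet(c(chrA = chrA))
}

toy_gff <- function() {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrA\ttoy\tCDS\t11\t22\t.\t+\t0\tID=cds1;Parent=tx1",
               "chrA\ttoy\tCDS\t41\t52\t.\t+\t0\tID=cds2;Parent=tx1"), path)
  path
}

test_that("codon effects are classified per the genetic code", {
  ref <- toy_reference()
  gff <- toy_gff()
  sites <- data.frame(
    pos = c(14L, 19L, 21L, 13L, 24L, 30L, 5L),
    ref = c("C", "T", "A", "G", "T", "T", "T"),
    alt = c("T", "C", "T", "A", "G", "G", "G"))
  # CAA->TAA stop-gain; CTT->CTC synonymous; GAA->GTA missense;
  # ATG->ATA start-loss; intron+2 splice; mid-intron; intergenic
  gm <- GenotypeMatrix(matrix(1L, nrow(sites), 2), chrom = "chrA",
                       pos = sites$pos, ref = sites$ref, alt = sites$alt,
                       samples = c("a", "b"))
  got <- classifyEffects(gm, gff, ref)
  # sites are stored sorted by position: 5, 13, 14, 19, 21, 24, 30
  expect_equal(got, c("noncoding", "HIGH", "HIGH", "LOW", "MODERATE",
                      "HIGH", "noncoding"))
})

test_that("reference-mismatching sites are warned about and excluded", {
  gm <- GenotypeMatrix(matrix(1L, 1, 2), chrom = "chrA", pos = 12L,
                       ref = "C", alt = "A", samples = c("a", "b"))
  expect_warning(got <- classifyEffects(gm, toy_gff(), toy_reference()),
                 "mismatch")
  expect_equal(got, "mismatch")
})

test_that("minus-strand genes classify like their reverse-complement construction", {
  # plus-strand gene: CDS ATGGAACTTTAA at 11-22 of chrP
  filler <- function(n) paste(rep("A", n), collapse = "")
  cds <- "ATGGAACTTTGA"
  chrP <- paste0(filler(10), cds, filler(10))
  # minus-strand twin: genomic sequence is the reverse complement
  chrM <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chrP)))
  ref <- Biostrings::DNAStringSet(c(chrP = chrP, chrM = chrM))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrP\ttoy\tCDS\t11\t22\t.\t+\t0\tID=c1;Parent=txP",
               "chrM\ttoy\tCDS\t11\t22\t.\t-\t0\tID=c2;Parent=txM"), gff)
  # plus: position 16 is codon 2 base 3 (GAA -> GAG, synonymous)
  # minus twin position: 32 - 16 + 1 = 17? chrM has length 32; genomic
  # coordinate of transcript position 16 is 32 - 16 + 1 = 17, alleles
  # complemented (A->T on transcript means T->A... transcript A->G is
  # genomic T->C on the minus strand)
  gmP <- GenotypeMatrix(matrix(1L, 1, 2), chrom = "chrP", pos = 16L,
                        ref = "A", alt = "G", samples = c("a", "b"))
  gmM <- GenotypeMatrix(matrix(1L, 1, 2), chrom = "chrM", pos = 17L,
                        ref = "T", alt = "C", samples = c("a", "b"))
  expect_equal(classifyEffects(gmP, gff, ref)[1], "LOW")
  expect_equal(classifyEffects(gmM, gff, ref)[1],
               classifyEffects(gmP, gff, ref)[1])
  # and a missense pair: codon 2 base 1 G->C (GAA -> CAA)
  gmP2 <- GenotypeMatrix(matrix(1L, 1, 2), chrom = "chrP", pos = 14L,
                         ref = "G", alt = "C", samples = c("a", "b"))
  gmM2 <- GenotypeMatrix(matrix(1L, 1, 2), chrom = "chrM", pos = 19L,
                         ref = "C", alt = "G", samples = c("a", "b"))
  expect_equal(classifyEffects(gmP2, gff, ref)[1], "MODERATE")
  expect_equal(classifyEffects(gmM2, gff, ref)[1], "MODERATE")
})

test_that("classifier agrees with a naive independent translation oracle", {
  set.seed(77)
  n_genes <- 20L
  gene_len <- 30L   # 10 codons
  spacer <- 20L
  aa_chars <- Biostrings::GENETIC_CODE
  make_cds <- function() {
    repeat {
      body <- paste(sample(c("A", "C", "G", "T"), gene_len - 6, TRUE),
                    collapse = "")
      cds <- paste0("ATG", body, "TAA")
      codons <- substring(cds, seq(1, gene_len, 3), seq(3, gene_len, 3))
      if (!any(aa_chars[codons[-length(codons)]] == "*")) return(cds)
    }
  }
  genes <- replicate(n_genes, make_cds())
  starts <- spacer + (seq_len(n_genes) - 1L) * (gene_len + spacer) + 1L
  chrom_seq <- paste(rep("A", spacer), collapse = "")
  for (g in genes)
    chrom_seq <- paste0(chrom_seq, g, paste(rep("A", spacer), collapse = ""))
  ref <- Biostrings::DNAStringSet(c(chrZ = chrom_seq))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("chrZ\ttoy\tCDS\t%d\t%d\t.\t+\t0\tID=g%d;Parent=t%d",
                       starts, starts + gene_len - 1L, seq_len(n_genes),
                       seq_len(n_genes))), gff)
  # random SNPs inside CDS
  pos <- sort(unlist(lapply(starts, function(s) s + sample(0:(gene_len - 1), 6))))
  refb <- substring(chrom_seq, pos, pos)
  altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                 character(1))
  gm <- GenotypeMatrix(matrix(1L, length(pos), 2), chrom = "chrZ", pos = pos,
                       ref = refb, alt = altb, samples = c("a", "b"))
  got <- classifyEffects(gm, gff, ref)
  # oracle: locate gene arithmetically, translate both codons directly
  oracle <- vapply(seq_along(pos), function(i) {
    gi <- findInterval(pos[i], starts)
    off <- pos[i] - starts[gi]            # 0-based within CDS
    cod <- off %/% 3L
    cds <- genes[gi]
    codon <- substring(cds, cod * 3 + 1, cod * 3 + 3)
    alt_codon <- codon
    substring(alt_codon, off %% 3L + 1, off %% 3L + 1) <- altb[i]
    a1 <- aa_chars[codon]; a2 <- aa_chars[alt_codon]
    if (a1 != "*" && a2 == "*") "HIGH"
    else if (a1 == "*" && a2 != "*") "HIGH"
    else if (cod == 0L && codon == "ATG" && alt_codon != "ATG") "HIGH"
    else if (a1 != a2) "MODERATE" else "LOW"
  }, character(1))
  expect_equal(got, unname(oracle))
})

test_that("the load table counts derived homozygotes and heterozygotes", {
  # 4 HIGH sites; sample a: dosages 2,1,1,0 -> hom 1, het 2, prop 1/3
  d <- cbind(a = c(2L, 1L, 1L, 0L), b = c(0L, 0L, 0L, 0L))
  gm <- makeGM(d, samples = c("a", "b"), populations = c("p1", "p2"),
               ancestral = "ref")
  lt <- loadTable(gm, rep("HIGH", 4))
  ra <- lt$individuals[lt$individuals$sample == "a" &
                         lt$individuals$category == "HIGH", ]
  expect_equal(ra$hom, 1L)
  expect_equal(ra$het, 2L)
  expect_equal(ra$prop_hom, 1 / 3)
  rb <- lt$individuals[lt$individuals$sample == "b" &
                         lt$individuals$category == "HIGH", ]
  expect_equal(rb$hom + rb$het, 0L)   # all-ancestral sample

  # categories partition the derived-carrying genotypes
  set.seed(10)
  d2 <- matrix(sample(0:2, 300, TRUE), 100, 3)
  cats <- sample(c("HIGH", "MODERATE", "LOW"), 100, TRUE)
  gm2 <- makeGM(d2, ancestral = "ref")
  lt2 <- loadTable(gm2, cats)
  per_sample <- tapply(lt2$individuals$hom + lt2$individuals$het,
                       lt2$individuals$sample, sum)
  carries <- colSums(d2 >= 1)
  expect_equal(as.integer(per_sample[colnames(dosages(gm2))]),
               unname(carries))
})

test_that("the unfolded SFS counts polymorphic derived classes", {
  # 4 diploids, derived counts {1, 1, 2}, plus one fixed-derived site
  d <- rbind(c(1L, 0L, 0L, 0L),
             c(0L, 0L, 1L, 0L),
             c(1L, 1L, 0L, 0L),
             c(2L, 2L, 2L, 2L))
  gm <- makeGM(d, ancestral = "ref")
  sf <- sfsSpectrum(gm, NULL, "pop1")
  spec <- sf$spectrum
  expect_equal(spec$sites[spec$count == 1], 2)
  expect_equal(spec$sites[spec$count == 2], 1)
  expect_equal(sum(spec$sites), 3)   # fixed-derived class excluded
  expect_equal(sf$n, 8L)

  # neutral simulation follows the theta/i expectation
  set.seed(55)
  theta_site <- 2
  n <- 20L
  counts <- unlist(lapply(seq_len(n - 1), function(i)
    rep(i, rpois(1, theta_site * 4000 / i))))
  dd <- matrix(0L, length(counts), n / 2)
  for (j in seq_along(counts)) {
    copies <- sample.int(n, counts[j])
    for (cp in copies) {
      ind <- (cp + 1L) %/% 2L
      dd[j, ind] <- dd[j, ind] + 1L
    }
  }
  gmn <- makeGM(dd, pos = seq_len(nrow(dd)) * 10L, ancestral = "ref")
  sfn <- sfsSpectrum(gmn, NULL, "pop1")$spectrum
  expected <- theta_site * 4000 / sfn$count
  expect_lt(max(abs(sfn$sites - expected) / expected), 0.25)

  # binned view: counts >= 10 summarised as means per interval
  expect_true(any(grepl("-", sfsSpectrum(gmn, NULL, "pop1",
                                         bin_from = 10)$binned$interval)))
})

test_that("Rxy evaluates its closed form and is exactly reciprocal", {
  # d^X = (0.5, 0.2), d^Y = (0.1, 0.4) over two HIGH sites
  X <- rbind(c(2L, 2L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L, 0L))  # 5/10, 2/10
  Y <- rbind(c(1L, 0L, 0L, 0L, 0L), c(2L, 1L, 1L, 0L, 0L))  # 1/10, 4/10
  gm <- makeGM(cbind(X, Y), populations = rep(c("X", "Y"), each = 5),
               ancestral = "ref")
  cats <- rep("HIGH", 2)
  r <- rxy(gm, cats, "HIGH", "X", "Y")
  expect_equal(r$LXnotY, 0.5 * 0.9 + 0.2 * 0.6, tolerance = 1e-12)
  expect_equal(r$LYnotX, 0.1 * 0.5 + 0.4 * 0.8, tolerance = 1e-12)
  expect_equal(r$Rxy, 0.57 / 0.37, tolerance = 1e-12)
  r_rev <- rxy(gm, cats, "HIGH", "Y", "X")
  expect_equal(r$Rxy * r_rev$Rxy, 1, tolerance = 1e-14)

  # identical frequency vectors give exactly 1
  gm_same <- makeGM(cbind(X, X), populations = rep(c("X", "Y"), each = 5),
                    ancestral = "ref")
  expect_equal(rxy(gm_same, cats, "HIGH", "X", "Y")$Rxy, 1, tolerance = 1e-14)
})

test_that("selection against homozygotes leaves the purging signature", {
  # founder-exposed recessives in X are purged relative to the
  # unbottlenecked Y; the load comparison reads the standing variants
  cfg <- simulationConfig(
    chrom_lengths = stats::setNames(rep(2e5, 4), paste0("chr", 1:4)),
    mu = 0.002 / (4 * 40), recomb = 0.002 / (4 * 40),
    init_size = 40L, n_generations = 20L,
    classes = data.frame(category = c("HIGH", "LOW"),
                         fraction = c(0.05, 0.05),
                         s = c(0.9, 0), h = c(0, 0.5)),
    events = list(evSplit(1L, "anc", "outgroup", 3L),
                  evSplit(2L, "anc", "Y", 25L),
                  evFounder(2L, "anc", "X", 2L, 4L, size = 10L),
                  evResize(3L, "anc", 0L)),
    outgroup_pop = "outgroup",
    compute_fp = FALSE, missing_rate = 0, seed = 88L)
  sim <- simulate(cfg)
  gm <- polarizeByOutgroup(sim$genotypes)
  cats <- sim$truth$sites$category
  cats[sim$truth$sites$origin_gen >= 2L] <- "noncoding"
  lt <- loadTable(gm, cats, samples = popSamples(gm, "X"))
  pm <- lt$population_means
  expect_lt(pm$prop_hom[pm$category == "HIGH"],
            pm$prop_hom[pm$category == "LOW"])
  r_high <- rxy(gm, cats, "HIGH", "X", "Y")
  r_low <- rxy(gm, cats, "LOW", "X", "Y")
  expect_lt(r_high$Rxy, 1)
  expect_lt(abs(r_low$Rxy - 1), 0.35)
  expect_lt(r_high$Rxy, r_low$Rxy)
})
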