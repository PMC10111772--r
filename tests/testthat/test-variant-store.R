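vcf_line <- function(chrom, pos, ref, alt, info, gts, qual = "100") {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", info, "GT", gts),
        collapse = "\t")
}

test_that("readVCF keeps biallelic SNPs and drops multiallelics, MNPs, indels", {
  body <- c(
    vcf_line("chr1", 100, "A", "G", "QD=20", c("0/0", "0/1", "1/1")),
    vcf_line("chr1", 200, "C", "T", "QD=20", c("0/0", "0/0", "0/1")),
    vcf_line("chr1", 300, "G", "A,T", "QD=20", c("0/1", "0/2", "1/2")),  # multiallelic
    vcf_line("chr1", 400, "AT", "A", "QD=20", c("0/0", "0/1", "1/1")),   # indel
    vcf_line("chr1", 500, "T", "C", "QD=20", c("./1", "1|1", "./.")),    # half/phased/missing
    vcf_line("chr1", 600, "G", "C", "QD=20", c("0/1", "0/0", "0/0")),
    vcf_line("chr1", 700, "A", "T", "QD=20", c("1/1", "0/1", "0/0"))
  )
  gm <- readVCF(writeToyVCF(body))
  expect_s4_class(gm, "GenotypeMatrix")
  expect_equal(dim(gm), c(5L, 3L))
  expect_equal(S4Vectors::metadata(gm)$dropped_records, 2L)
  d <- dosages(gm)
  # half-call missing, phased normalised, ./. missing
  expect_true(is.na(d[3, 1]))
  expect_equal(unname(d[3, 2]), 2L)
  expect_true(is.na(d[3, 3]))
  expect_equal(unname(d[1, ]), c(0L, 1L, 2L))
})

test_that("population map restricts and validates samples", {
  body <- vcf_line("chr1", 100, "A", "G", "QD=20", c("0/0", "0/1", "1/1"))
  path <- writeToyVCF(body)
  spec <- data.frame(sample = c("s3", "s1"), population = c("b", "a"))
  gm <- readVCF(path, spec)
  expect_equal(colnames(gm), c("s3", "s1"))
  expect_equal(unname(populations(gm)), c("b", "a"))
  bad <- data.frame(sample = "nope", population = "a")
  expect_error(readVCF(path, bad), "nope")
})

test_that("malformed VCF errors name the offending line", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t100\t.\tA\tG\t50\tPASS\tQD=20\tGT\t0/1",
               "chr1 broken line"), path)
  expect_error(readVCF(path), "line 4")
})

test_that("write -> read round trip preserves the dosage matrix exactly", {
  cfg <- simulationConfig(chrom_lengths = c(chr1 = 1e5), mu = 1e-5,
                          init_size = 20L, n_generations = 3L,
                          events = list(evSplit(1L, "anc", "outgroup", 3L)),
                          outgroup_pop = "outgroup", compute_fp = FALSE,
                          seed = 11L)
  gm <- simulate(cfg)$genotypes
  path <- tempfile(fileext = ".vcf")
  writeVCF(gm, path)
  gm2 <- readVCF(path)
  d1 <- dosages(gm); d2 <- dosages(gm2)
  expect_identical(dim(d1), dim(d2))
  expect_identical(is.na(d1), is.na(d2))
  expect_true(all(d1 == d2, na.rm = TRUE))
  expect_identical(colnames(gm), colnames(gm2))
})

test_that("hard filters remove failing sites and report counts that add up", {
  n <- 10L
  info <- S4Vectors::DataFrame(QD = rep(20, n), FS = rep(1, n),
                               MQ = rep(55, n), QUAL = rep(100, n),
                               DP = rep(40, n), MQRankSum = rep(0, n),
                               ReadPosRankSum = rep(0, n))
  d <- matrix(1L, n, 4)
  gm <- makeGM(d, info = info)
  res <- applySiteFilters(gm, filterConfig())
  expect_equal(nrow(res$genotypes), n)   # everything passes

  info$QD[3] <- 1.5                      # below the QD >= 2 threshold
  info$FS[5] <- 70                       # above the FS <= 60 threshold
  gm <- makeGM(d, info = info)
  res <- applySiteFilters(gm, filterConfig())
  expect_equal(nrow(res$genotypes), n - 2L)
  rep_tab <- res$report
  expect_equal(rep_tab$removed[rep_tab$rule == "QD"], 1L)
  expect_equal(rep_tab$removed[rep_tab$rule == "FS"], 1L)
  expect_equal(rep_tab$removed[rep_tab$rule == "input_sites"] -
                 rep_tab$removed[rep_tab$rule == "removed_total"],
               rep_tab$removed[rep_tab$rule == "output_sites"])
})

test_that("overall-depth bounds, missingness and gap proximity follow the configured thresholds", {
  n <- 8L
  info <- S4Vectors::DataFrame(QD = rep(20, n), FS = rep(1, n), MQ = rep(55, n),
                               QUAL = rep(100, n),
                               DP = c(40, 40, 40, 40, 40, 40, 5, 200),
                               MQRankSum = rep(0, n), ReadPosRankSum = rep(0, n))
  # mean DP = 55.6; bounds (18.5, 166.9): sites with DP 5 and 200 fail
  d <- matrix(0L, n, 10)
  d[2, 1:2] <- NA                        # 20% missing at site 2
  pos <- c(100, 200, 300, 400, 1006, 1004, 2000, 3000)
  gaps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1000))
  gm <- makeGM(d, pos = pos, info = info, chrom_len = 5000)
  res <- applySiteFilters(gm, filterConfig(), gaps = gaps)
  out_pos <- siteInfo(res$genotypes)$pos
  expect_false(200 %in% out_pos)         # missingness 0.2 >= 0.10
  expect_false(2000 %in% out_pos)        # low overall depth
  expect_false(3000 %in% out_pos)        # high overall depth
  expect_false(1004 %in% out_pos)        # 4 bp from gap end: removed
  expect_true(1006 %in% out_pos)         # 6 bp from gap end: kept
})

test_that("filtering is idempotent", {
  set.seed(42)
  n <- 50L
  info <- S4Vectors::DataFrame(QD = runif(n, 0, 40), FS = rexp(n, 1 / 20),
                               MQ = rnorm(n, 50, 10), QUAL = runif(n, 0, 200),
                               DP = rpois(n, 40),
                               MQRankSum = rnorm(n, 0, 6),
                               ReadPosRankSum = rnorm(n, 0, 4))
  d <- matrix(sample(c(0L, 1L, 2L, NA), n * 6, replace = TRUE,
                     prob = c(0.4, 0.3, 0.25, 0.05)), n, 6)
  gm <- makeGM(d, info = info)
  r1 <- applySiteFilters(gm, filterConfig())
  r2 <- applySiteFilters(r1$genotypes, filterConfig())
  expect_equal(nrow(r2$genotypes), nrow(r1$genotypes))
  expect_identical(dosages(r2$genotypes), dosages(r1$genotypes))
})

test_that("filters with absent INFO annotations are skipped, not fatal", {
  d <- matrix(1L, 5, 3)
  gm <- makeGM(d)   # no INFO at all beyond NA columns
  res <- suppressMessages(applySiteFilters(gm, filterConfig()))
  expect_equal(nrow(res$genotypes), 5L)
  expect_true(all(res$report$skipped[res$report$rule %in%
                                       c("QD", "FS", "MQ")]))
})

test_that("outgroup polarization sets ancestral calls and derived dosages", {
  # sites: outgroup 0/0, 1/1, 0/1, ./.
  d <- cbind(ing1 = c(0L, 0L, 2L, 1L), ing2 = c(1L, 2L, 0L, 0L),
             out = c(0L, 2L, 1L, NA))
  gm <- makeGM(d, samples = c("ing1", "ing2", "out"),
               populations = c("p", "p", "og"), outgroup = "out")
  gm <- polarizeByOutgroup(gm, "out")
  expect_equal(ancestralAlleles(gm), c("ref", "alt", "unknown", "unknown"))
  dd <- derivedDosages(gm)
  expect_equal(unname(dd[1, "ing1"]), 0L)
  expect_equal(unname(dd[2, "ing1"]), 2L)   # outgroup 1/1: ingroup 0/0 has derived dosage 2
  expect_true(all(is.na(dd[3:4, ])))
})

test_that("re-polarizing with a swapped outgroup genotype flips derived dosage", {
  set.seed(1)
  n <- 30L
  ing <- matrix(sample(0:2, n * 4, replace = TRUE), n, 4)
  og1 <- sample(c(0L, 2L), n, replace = TRUE)
  d1 <- cbind(ing, og = og1)
  d2 <- cbind(ing, og = 2L - og1)
  g1 <- polarizeByOutgroup(makeGM(d1, outgroup = "s5"), "s5")
  g2 <- polarizeByOutgroup(makeGM(d2, outgroup = "s5"), "s5")
  expect_true(all(derivedDosages(g1)[, 1:4] + derivedDosages(g2)[, 1:4] == 2L))
})

test_that("polarization recovers simulator truth where the outgroup is ancestral", {
  cfg <- simulationConfig(chrom_lengths = c(chr1 = 1e5), mu = 1e-5,
                          init_size = 20L, n_generations = 4L,
                          events = list(evSplit(1L, "anc", "outgroup", 4L)),
                          outgroup_pop = "outgroup", compute_fp = FALSE,
                          seed = 5L)
  sim <- simulate(cfg)
  gm <- polarizeByOutgroup(sim$genotypes)
  truth <- sim$truth$sites
  anc <- ancestralAlleles(gm)
  og <- dosages(sim$genotypes)[, outgroupSamples(gm)[1]]
  # where the outgroup is homozygous for the truly ancestral allele, the
  # polarized call must equal the truth at every site
  og_anc_hom <- (truth$ancestral == "ref" & !is.na(og) & og == 0L) |
    (truth$ancestral == "alt" & !is.na(og) & og == 2L)
  expect_true(all(anc[og_anc_hom] == truth$ancestral[og_anc_hom]))
  # outgroup-het/missing sites stay unknown
  expect_true(all(anc[is.na(og) | og == 1L] == "unknown"))
})
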