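neutral_cfg <- function(seed, N = 30L, L = 2e5, theta = 0.0012, gens = 4L)
  simulationConfig(chrom_lengths = c(chr1 = L), mu = theta / (4 * N),
                   init_size = N, n_generations = gens,
                   classes = data.frame(category = character(),
                                        fraction = numeric(), s = numeric(),
                                        h = numeric()),
                   compute_fp = FALSE, missing_rate = 0, seed = seed)

test_that("simulation is a deterministic function of (config, seed)", {
  a <- simulate(neutral_cfg(3L))
  b <- simulate(neutral_cfg(3L))
  expect_identical(dosages(a$genotypes), dosages(b$genotypes))
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$truth$sites, b$truth$sites)
  c_ <- simulate(neutral_cfg(4L))
  expect_false(identical(dosages(a$genotypes), dosages(c_$genotypes)))
})

test_that("neutral equilibrium diversity matches the coalescent expectation", {
  theta <- 0.0012
  pis <- vapply(1:30, function(s) {
    gm <- simulate(neutral_cfg(100L + s))$genotypes
    attr(windowedPi(gm, "anc"), "genome_mean")
  }, numeric(1))
  expect_lt(abs(mean(pis) - theta) / theta, 0.15)
  # theta_w agrees with pi in expectation at equilibrium (Tajima's D ~ 0)
  gm <- simulate(neutral_cfg(999L, gens = 3L))$genotypes
  tw <- attr(windowedThetaW(gm, "anc"), "genome_mean")
  pi <- attr(windowedPi(gm, "anc"), "genome_mean")
  expect_lt(abs(tw - pi) / pi, 0.35)
})

test_that("neutral diversity agrees with an independent coalescent simulator", {
  # msprime (python) as external oracle for E[pi] under the same theta
  theta <- 0.0012
  script <- paste(
    "import msprime, numpy as np",
    "vals = []",
    "for seed in range(1, 201):",
    "    ts = msprime.sim_ancestry(samples=30, population_size=30,",
    "        sequence_length=200000, recombination_rate=1e-8,",
    "        random_seed=seed)",
    "    mts = msprime.sim_mutations(ts, rate=1e-5, random_seed=seed)",
    "    vals.append(mts.diversity())",
    "print(np.mean(vals))", sep = "\n")
  out <- system2("python", "-", stdout = TRUE, input = script)
  oracle <- as.numeric(utils::tail(out, 1))
  expect_true(is.finite(oracle))
  pis <- vapply(1:20, function(s) {
    gm <- simulate(neutral_cfg(300L + s))$genotypes
    attr(windowedPi(gm, "anc"), "genome_mean")
  }, numeric(1))
  expect_lt(abs(mean(pis) - oracle) / oracle, 0.15)
})

test_that("allele-frequency drift variance matches p(1-p)/2N per generation", {
  N <- 50L
  p0 <- 0.5
  freqs <- vapply(1:200, function(s) {
    cfg <- simulationConfig(chrom_lengths = c(chr1 = 1e4), mu = 0,
                            init_size = N, n_generations = 1L,
                            standing_sites = data.frame(chrom = "chr1",
                                                        pos = 5000L,
                                                        count = N),
                            compute_fp = FALSE, missing_rate = 0, seed = s)
    gm <- simulate(cfg)$genotypes
    popFreq(gm, "anc")$freq[1]
  }, numeric(1))
  expected <- p0 * (1 - p0) / (2 * N)
  expect_lt(abs(var(freqs) - expected) / expected, 0.35)
  expect_lt(abs(mean(freqs) - p0), 0.02)
})

test_that("recessive lethals never appear homozygous in adults", {
  cfg <- simulationConfig(chrom_lengths = c(chr1 = 1e5), mu = 2e-5,
                          init_size = 30L, n_generations = 6L,
                          classes = data.frame(category = "HIGH",
                                               fraction = 0.2, s = 1, h = 0),
                          compute_fp = FALSE, missing_rate = 0, seed = 21L)
  sim <- simulate(cfg)
  truth <- sim$truth$sites
  d <- dosages(sim$genotypes)
  # derived dosage on the truth scale
  dd <- d
  flip <- truth$ancestral == "alt"
  dd[flip, ] <- 2L - dd[flip, , drop = FALSE]
  lethal <- truth$category == "HIGH"
  expect_gt(sum(lethal), 0)
  expect_true(all(dd[lethal, ] < 2L, na.rm = TRUE))
})

test_that("a single introgression pulse leaves ancestry fraction f in expectation", {
  f <- 0.2
  fracs <- vapply(1:20, function(s) {
    cfg <- simulationConfig(chrom_lengths = c(chr1 = 5e4), mu = 1e-5,
                            init_size = 30L, n_generations = 4L,
                            events = list(evSplit(1L, "anc", "B", 20L),
                                          evResize(2L, "anc", 15L),
                                          evPulse(3L, "anc", "B", f)),
                            classes = data.frame(category = character(),
                                                 fraction = numeric(),
                                                 s = numeric(), h = numeric()),
                            compute_fp = FALSE, missing_rate = 0,
                            seed = 500L + s)
    tr <- simulate(cfg)$truth$individuals
    mean(tr$anc[tr$population == "B"])
  }, numeric(1))
  expect_lt(abs(mean(fracs) - f), 0.06)
})

test_that("a founder event inflates long runs of homozygosity", {
  base <- function(founder, seed) {
    ev <- if (founder)
      list(evFounder(2L, "anc", "cap", 2L, 4L, size = 6L),
           evResize(3L, "anc", 0L), evResize(6L, "cap", 16L))
    else
      list(evSplit(2L, "anc", "cap", 24L), evResize(3L, "anc", 0L))
    simulationConfig(chrom_lengths = c(chr1 = 2.5e6, chr2 = 2.5e6),
                     mu = 2.5e-6, init_size = 25L, n_generations = 12L,
                     classes = data.frame(category = character(),
                                          fraction = numeric(), s = numeric(),
                                          h = numeric()),
                     events = ev, sample_pops = "cap",
                     compute_fp = FALSE, missing_rate = 0, seed = seed)
  }
  long_roh_per_ind <- function(cfg) {
    gm <- simulate(cfg)$genotypes
    segs <- do.call(rbind, lapply(colnames(gm), function(s) detectROH(gm, s)))
    sum(segs$length[segs$length > 1e6]) / ncol(gm)
  }
  with_f <- long_roh_per_ind(base(TRUE, 7L))
  without <- long_roh_per_ind(base(FALSE, 7L))
  expect_gt(with_f, without)
})

test_that("Wright's pedigree F matches classic values and a recursive oracle", {
  ped <- data.frame(id = c("a", "b", "x", "y", "z", "w"),
                    sire = c(NA, NA, "a", "a", "x", "x"),
                    dam = c(NA, NA, "b", "b", "y", "z"),
                    generation = c(0, 0, 1, 1, 2, 3))
  expect_equal(pedigreeInbreeding(ped, "x"), c(x = 0))         # unrelated parents
  expect_equal(pedigreeInbreeding(ped, "z"), c(z = 0.25))      # full sibs
  # parent x offspring mating: w = x (sire) x z (daughter of x)
  expect_equal(pedigreeInbreeding(ped, "w"), c(w = 0.25 + 0.25 / 2))

  po <- data.frame(id = c("m", "f", "d", "e"),
                   sire = c(NA, NA, "m", "m"),
                   dam = c(NA, NA, "f", "d"),
                   generation = c(0, 0, 1, 2))
  expect_equal(pedigreeInbreeding(po, "e"), c(e = 0.25))       # parent-offspring

  # independent oracle: tabular additive-relationship method on a
  # 4-generation pedigree
  set.seed(9)
  ids <- paste0("p", 1:14)
  ped4 <- data.frame(id = ids,
                     sire = c(rep(NA, 4), "p1", "p1", "p3", "p5", "p5", "p7",
                              "p8", "p8", "p10", "p11"),
                     dam = c(rep(NA, 4), "p2", "p2", "p4", "p6", "p6", "p9",
                             "p9", "p9", "p12", "p13"),
                     generation = c(0, 0, 0, 0, 1, 1, 1, 2, 2, 3, 3, 3, 4, 5))
  # oracle: build the numerator relationship matrix A row by row
  A <- matrix(0, 14, 14, dimnames = list(ids, ids))
  for (i in seq_len(14)) {
    s <- match(ped4$sire[i], ids); dd <- match(ped4$dam[i], ids)
    for (j in seq_len(i - 1))
      A[i, j] <- A[j, i] <- 0.5 * ((if (is.na(s)) 0 else A[j, s]) +
                                     (if (is.na(dd)) 0 else A[j, dd]))
    A[i, i] <- 1 + (if (is.na(s) || is.na(dd)) 0 else 0.5 * A[s, dd])
  }
  oracle_F <- diag(A) - 1
  got <- pedigreeInbreeding(ped4, ids)
  expect_equal(unname(got), unname(oracle_F), tolerance = 1e-12)
})

test_that("invalid pedigrees and impossible demography fail loudly", {
  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = c(NA, NA),
                    generation = c(0, 0))
  expect_error(pedigreeInbreeding(cyc, "a"), "pedigree")
  # lethal overload: every mutation recessive-lethal at huge rate, tiny pop
  cfg <- simulationConfig(chrom_lengths = c(chr1 = 1e4), mu = 0,
                          init_size = 4L, n_generations = 2L,
                          standing_sites = data.frame(chrom = "chr1",
                                                      pos = c(3000, 6000),
                                                      count = 8,
                                                      category = "HIGH",
                                                      s = 1, h = 1),
                          compute_fp = FALSE, seed = 2L)
  expect_error(simulate(cfg), "simulation failure")
})
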