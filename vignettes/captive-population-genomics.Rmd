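---
title: "Methods: population genomics of captive founder populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of captive founder populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

CaptivePopGen analyses multi-sample SNP data from small, founder-derived
populations — the situation of captive breeding programs descended from a
handful of wild-caught animals — and ships a forward simulator that
generates fully ground-truthed inputs for every analysis stage. This
vignette explains the models, the parameter choices and their defaults,
the numerical decisions, and what the simulation-based tests do and do
not establish about real data.

## The data model

The central object is the `GenotypeMatrix`, a
`RangedSummarizedExperiment` whose rows are biallelic SNPs (a `GRanges`
with REF/ALT alleles, the GATK-style INFO annotations QD, FS, MQ, QUAL,
DP, MQRankSum and ReadPosRankSum, and an ancestral-allele call), whose
columns are samples with population labels, and whose `"dosage"` assay
holds ALT-allele dosages 0/1/2 with `NA` for missing calls. Sites are
kept sorted with no duplicates; every statistic relies on those
invariants. Internally intervals are handled by `IRanges`/`GenomicRanges`
(1-based closed at the user surface, matching VCF).

## Site filtering

`applySiteFilters()` applies the standard hard filters for short-read
SNP callsets: QD < 2, FS > 60, MQ < 40, QUAL < 30, DP < 4,
MQRankSum < −12.5, ReadPosRankSum < −8, plus three callset-level rules —
per-site total depth outside (1/3×, 3×) of the callset mean, more than
10% missing genotype calls at a site, and proximity within 5 bp of an
assembly gap. Two readings of the missing-data rule are possible
("unobserved variant allele" could denote missing calls or a
minor-allele constraint); the missing-call-rate reading is implemented,
as it is the conventional per-site QC step. The depth rule likewise
could use summed or mean per-genotype depth; summed DP is used. A filter
whose annotation is absent is skipped with a message, never fatal, so
partially annotated callsets remain usable. The absolute depth bounds
actually applied are stored in the object's metadata and reused on
re-application, which makes filtering idempotent by construction.

## Polarization

`polarizeByOutgroup()` sets the ancestral allele from the genotype of a
designated outgroup individual: homozygous-reference means the reference
allele is ancestral, homozygous-alternate the alternate; heterozygous or
missing outgroup calls leave the site unpolarized and excluded from
derived-allele analyses. Note what this cannot do: where the outgroup
itself carries the derived allele (shared ancestral polymorphism, or a
substitution on the outgroup branch) the call is wrong, and the
simulator reproduces exactly this error mode — concordance with the
simulated truth is 100% only at sites where the outgroup genotype is
homozygous for the truly ancestral allele.

## Diversity

Windowed nucleotide diversity uses the unbiased per-site form
$\pi_i = 2 j_i (n_i - j_i) / (n_i (n_i - 1))$ with $j_i$ the alternate
allele count among $n_i$ called copies, summed over 20-kb windows
sliding in 10-kb steps (defaults) and divided by the window span in bp.
Watterson's estimator divides the segregating-site count by the harmonic
number $a_{n-1}$, per site, so missingness-induced variation in $n$ is
handled exactly. The full window span is the default denominator — the
convention of common windowed-diversity tools — with a called-sites
denominator available by flag. Windows tile from coordinate 0; trailing
partial windows report their true span. A step-independent genome-wide
mean (total per-site diversity over total genome length) is attached to
each table, because means over overlapping windows depend weakly on the
step through edge effects.

FST uses the Weir–Cockerham (1984) variance components, with windowed
and genome-wide values formed as ratios of sums ("weighted") and the
mean of per-site ratios also reported; the Hudson estimator is available
as a sensitivity option since citations of "the pairwise fixation index"
do not pin down the estimator. Negative estimates are reported as
computed, never clamped.

## Relatedness and phylogeny

Identity-by-state uses the shared-allele convention for biallelic
dosages, $(2 - |d_i - d_j|)/2$ averaged over co-called sites, so IBS
distance and p-distance coincide by construction. The
method-of-moments IBD estimator follows the PLINK construction:
per-site IBS-state expectations given IBD state are computed from
finite-sample-unbiased estimates of the allele-frequency monomials
(falling-factorial corrections), the moment equations are solved for
Z0/Z1/Z2, and the estimates are bounded to [0, 1] and renormalised;
PI_HAT = Z1/2 + Z2. Frequencies are taken from the full sample set by
default (the realistic situation when subspecies panels are pooled),
with a per-population option. PCA mean-imputes missing dosages, centres
by twice the allele frequency, scales by $\sqrt{2p(1-p)}$, and
eigendecomposes the genetic relationship matrix; coordinates are
deterministic up to sign.

Neighbor joining is delegated to `ape::nj` (the standard
implementation), followed by a clamping pass that moves each negative
branch's deficit onto its sibling edge — path lengths are preserved
where possible and no negative lengths are displayed. Bootstrap support
resamples sites with replacement (blocks of consecutive sites
optionally, for linkage robustness), rebuilds the distance matrix and
tree per replicate, and counts bipartitions with `ape::prop.clades`.

## Runs of homozygosity and inbreeding

`detectROH()` reimplements the PLINK sliding-window scan: 100-SNP
windows allowing at most 2 heterozygous and 5 missing calls; each SNP's
hit rate is the homozygous fraction of the windows that actually contain
it (SNPs near chromosome ends are covered by fewer windows and are
scored over those); SNPs at hit rate ≥ 0.05 (the emulated tool's
default, recorded in output metadata) form candidate runs, split at
inter-SNP gaps over 100 kb, and runs pass only with ≥ 100 SNPs,
≥ 100 kb, and at most 10 kb per SNP on average. No segment-level
heterozygote cap is applied beyond the window rule, matching the
emulated tool's documented behaviour. The test suite holds the detector
to exact agreement with a brute-force window-enumeration oracle on
randomly generated chromosomes.

F_ROH is the summed segment length at or above a threshold divided by a
genome denominator — by default the summed contig lengths of the
callset, configurable to a fixed assembly size for comparability.
Because the interesting biology lives in the length classes (recent
inbreeding makes long ROH), F_ROH is always reported at 100 kb, 1 Mb and
2 Mb. F_H is the excess-homozygosity coefficient
$(O_{hom} - E_{hom})/(N - E_{hom})$ with the Hardy–Weinberg expectation
computed from cohort frequencies with the $n/(n-1)$ small-sample
correction. Wright's pedigree coefficient F_p is computed by the
recursive kinship algorithm with founders assumed unrelated.

## Introgression

Patterson's D uses population derived-allele frequencies:
ABBA$_i = (1-p_1)p_2p_3(1-p_4)$, BABA$_i = p_1(1-p_2)p_3(1-p_4)$,
$D = \sum(\mathrm{ABBA}-\mathrm{BABA}) / \sum(\mathrm{ABBA}+\mathrm{BABA})$,
with a delete-one block jackknife over consecutive blocks of 1000
informative sites (no block size is standard; 1000 SNPs is the common
default and is configurable) and the conventional |Z| > 3 flag. The
f4-ratio estimates an admixture proportion as
$\alpha = f_4(A,O;X,C)/f_4(A,O;B,C)$ where B is the donor, A a second
more distant representative of the donor clade, and C the sister of the
target's unadmixed ancestry; quartets are supplied as configuration
because the appropriate (A, C) choices depend on the phylogeny at hand.
Per-individual summaries treat each focal sample as a singleton
population, adjust p-values by Benjamini–Hochberg (the natural reading
of an "FDR < 0.05" rule), and report three means — over retained tests,
over all tests, and over per-donor means — since "mean introgression
ratio" does not single one out.

## Mutation load and purging

The effect classifier is deliberately minimal: codon-level annotation
over CDS gene models, strand-aware, with HIGH = stop-gain, stop-loss,
start-loss or splice-site disruption (±2 bp of an intron boundary),
MODERATE = missense, LOW = synonymous, and "most severe effect wins"
across overlapping transcripts. Non-coding effects are excluded rather
than modelled, because the load analysis is confined to potential coding
regions. Load tables count homozygous-derived and heterozygous genotypes
per sample and category, with Welch's unequal-variance t-test — the safe default when group
sizes and variances differ — for between-population comparisons of
homozygote counts.

Rxy compares the derived-allele burden of a category between two
populations, $R_{xy} = \sum_i d_i^X(1-d_i^Y) \,/\, \sum_i d_i^Y(1-d_i^X)$;
values below 1 indicate a relative deficit in X. The identity
$R_{xy}(X,Y)\,R_{xy}(Y,X) = 1$ holds exactly and is asserted in tests. A
delete-one-chromosome jackknife provides the confidence interval, and an
optional normalisation by the same ratio on a neutral category (off by
default, since it is not always used in published applications) is
available. The unfolded SFS is reported per category, with
small-sample sites projected down by the hypergeometric expectation to
the modal copy number (or excluded, by flag), and a binned view that
summarises derived counts of 10 and above as mean site counts per
interval.

## The forward simulator

`simulate()` runs discrete-generation, two-sex, diploid Wright–Fisher
reproduction with multiplicative viability selection (heterozygote
$1-hs$, homozygote $1-s$), Poisson mutation under an infinite-sites
approximation, uniform crossover recombination, and demographic events:
population splits, founder events that move a chosen number of males and
females into a new breeding pool (the captive-founding situation),
resizes, and single-generation introgression pulses. Pedigree, per-site
impact class and selection coefficients, per-individual ancestry
fractions, and each variant's generation of origin are recorded as
ground truth. An optional "studbook" mating mode avoids full-sib
pairings when alternatives exist, mimicking managed breeding. Output is
a deterministic function of (configuration, seed).

Three initialisation/scaling decisions deserve explanation:

- **Equilibrium initialisation.** Standing variation is seeded from the
  neutral mutation–drift spectrum (site count at derived copy number
  $i$ ~ Poisson($\theta L/i$)) rather than burned in, so a scenario
  starts at realistic diversity in seconds. Carriers are assigned to
  haplotypes at random, so initial linkage disequilibrium is absent —
  adequate for frequency-based statistics, conservative for
  haplotype-length ones (ROH analyses in the tests always include
  post-initialisation generations that create real IBD structure).
- **Deleterious standing variants are seeded rare** (copy numbers drawn
  from a 1/i distribution capped at 5% frequency), approximating
  mutation–selection balance; the neutral spectrum would load the
  population with common recessive lethals it could never have carried.
- **Consistent rescaling.** Default scenarios use small chromosomes
  (hundreds of kb) and 2N of at most a few hundred, with the mutation
  rate raised so the compound parameter $4N\mu$ matches a realistic
  per-site diversity (e.g. 0.002). The recombination rate is raised by
  the same factor in the presets, keeping $\rho/\theta$ near 1. This
  matters: with physical per-bp recombination on a toy chromosome,
  linked recessives form non-recombining blocks and selection against
  homozygotes maintains them as balanced haplotypes
  (pseudo-overdominance) instead of purging them — a real phenomenon,
  but not the regime the scaled-down scenarios are meant to emulate.
  The biological point estimates behind the scaling (mutation rate
  3.5e-9 per bp per generation, 5-year generations) are carried as
  metadata.

`captiveDemography()` packages the study conditions at desk scale: an
ancestral population, a deep-splitting outgroup lineage, several
diverged wild subspecies populations, a severe founder event (2 males +
4 females) establishing a captive population that grows and splits into
two semi-isolated lineages, and a rare introgression pulse into one
lineage. No published demographic parameters exist for the captive
system beyond the mutation rate and generation time, so the preset's
sizes and times are illustrative, chosen to reproduce the qualitative
regime (founder inbreeding, moderate retained diversity, detectable
introgression) rather than calibrated values.

The frequency-level generators (`simulateQuartetSites`,
`simulateF4Sites`, `simulateHWESites`) complement the forward simulator
for large-site calibration studies: hierarchical Balding–Nichols drift
along a fixed tree, then binomial genotype sampling. Sites are
exchangeable and LD-free — precisely the regime in which block-jackknife
calibration is interpretable — and tens of thousands of sites are
generated per second. Their default drift depths mirror the study
system: recently separated focal lineages (F ≈ 0.02), deeply diverged
donor subspecies (F ≈ 0.3), and a distant outgroup (F ≈ 0.8, mostly
fixed ancestral).

## What the tests show (problem sizes, and limits)

The suite runs at fixed problem sizes chosen so the full set completes
in minutes: formula oracles on ≤ 20-site toys at 1e-10; ROH
detector–oracle equivalence on ~100 random chromosomes of 2000–5000
SNPs; D-statistic null calibration on 200 replicates of 50,000 sites
(|Z| > 3 observed in ≤ 2%); f4-ratio recovery of pulse fractions
0.02–0.2 within ±0.03 over 50 replicates; parent–offspring PI_HAT
within 0.05 of 1/2; and a purging scenario — a 2-male/4-female founder
event followed by ~18 generations at 2N = 20, with recessive
strongly-deleterious (s = 0.9, h = 0) and neutral site classes — in
which the homozygote proportion of the deleterious class falls below the
neutral class in every replicate and Rxy(HIGH) < 1 against the
unbottlenecked sister population in ≥ 90% of replicates, with Rxy(LOW)
centred at 1. The purging comparison reads the standing (pre-split)
variants from the simulator truth: at desk scale the rescaled mutation
rate injects new private variants orders of magnitude faster, relative
to the standing load, than a real genome does over a century of
captivity, and the shared standing load is what the statistic is built
to compare.

These are validations of the estimators under the generators'
assumptions — free recombination or rescaled linkage, Balding–Nichols
drift, binomial sampling, clean biallelic genotypes. Passing them does
not certify behaviour under batch effects, genotyping error correlated
with depth, reference bias, or mis-specified quartets; those must be
judged on real data.

## Degenerate inputs and numerical conventions

Monomorphic windows report zero diversity; windows with no informative
sites report FST as missing rather than 0; sample pairs with no
co-called sites get missing distances; D with zero pattern sums and
f4-ratios with vanishing denominators are reported undefined rather than
fabricated; α outside [0, 1] is reported raw with a flag. Jackknife
standard errors require at least two blocks. All statistics are plain
double-precision sums — at these problem sizes compensated summation is
unnecessary — and everything downstream of a seed is deterministic,
including the pipeline driver, which derives per-stage seeds from the
top-level seed by a fixed rule so stages can be re-run in isolation.
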