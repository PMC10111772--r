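#' Run configuration for the end-to-end pipeline
#'
#' @param vcf,population_map input VCF and sample-population TSV paths
#'   (ignored when \code{simulation} is given).
#' @param simulation a [simulationConfig()]; when supplied the pipeline
#'   starts by simulating its own input and uses the simulator truth for
#'   site categories and polarization checks.
#' @param gff,fasta gene models and reference for effect classification
#'   (optional; simulator truth categories are used when simulating).
#' @param quartets data.frame or TSV path for f4-ratio quartets
#'   (columns donor, A, C); optional.
#' @param gaps BED path or \code{GRanges} of assembly gaps (optional).
#' @param stages stages to run, in dependency order. \code{"load"},
#'   \code{"sfs"}, \code{"rxy"} and \code{"dstat"} require
#'   \code{"polarize"}.
#' @param out_dir output directory.
#' @param filter,window,roh stage parameter blocks.
#' @param block_size jackknife block size (sites).
#' @param fdr FDR level for introgression summaries.
#' @param seed top-level seed; per-stage seeds are derived from it by a
#'   fixed rule so stages are individually reproducible.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(vcf = NULL, population_map = NULL, simulation = NULL,
                      gff = NULL, fasta = NULL, quartets = NULL, gaps = NULL,
                      stages = c("filter", "polarize", "diversity", "fst",
                                 "relatedness", "pca", "nj", "roh",
                                 "dstat", "load", "sfs", "rxy"),
                      out_dir = tempfile("run"),
                      filter = filterConfig(), window = windowSpec(),
                      roh = rohParams(), block_size = 1000L, fdr = 0.05,
                      seed = 1L) {
  if (is.null(simulation)) {
    if (is.null(vcf)) stop("either a VCF or a simulation config is required")
    for (f in c(vcf, population_map))
      if (!is.null(f) && !file.exists(f)) stop("input file missing: ", f)
  }
  needs_pol <- intersect(stages, c("dstat", "load", "sfs", "rxy"))
  if (length(needs_pol) && !"polarize" %in% stages)
    stop("stage(s) ", paste(needs_pol, collapse = ", "),
         " require the 'polarize' stage")
  structure(as.list(environment()), class = "RunConfig")
}

.stage_seed <- function(seed, idx) (as.integer(seed) * 1009L + idx * 7919L) %%
  2147483647L

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate/read ->
#' filter -> polarize -> statistics), writes each stage's tables under
#' \code{out_dir}, and records a manifest (inputs, parameters, seed,
#' per-stage row counts). Outputs are a deterministic function of
#' (config, seed).
#'
#' @param cfg a [runConfig()].
#' @return invisible list of in-memory stage results (also on disk).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list(seed = cfg$seed, stages = list())
  note <- function(stage, rows) manifest$stages[[stage]] <<- list(rows = rows)
  tsv <- function(df, name) write.table(df, file.path(cfg$out_dir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    sim_cfg <- cfg$simulation
    sim_cfg$seed <- .stage_seed(cfg$seed, 1L)
    sim <- simulate(sim_cfg)
    gm <- sim$genotypes
    truth <- sim$truth
    writeSimulation(sim, file.path(cfg$out_dir, "sim"))
    note("simulate", nrow(gm))
    res$simulation <- sim
  } else {
    spec <- if (!is.null(cfg$population_map))
      readPopulationMap(cfg$population_map) else NULL
    gm <- readVCF(cfg$vcf, spec)
    note("read", nrow(gm))
  }
  pops <- setdiff(unique(populations(gm)),
                  unique(populations(gm)[outgroupSamples(gm)]))

  if ("filter" %in% cfg$stages) {
    gaps <- cfg$gaps
    if (is.character(gaps)) gaps <- readGapsBed(gaps)
    fl <- applySiteFilters(gm, cfg$filter, gaps)
    gm <- fl$genotypes
    tsv(fl$report, "filter_report.tsv")
    note("filter", nrow(gm))
    res$filter_report <- fl$report
    if (!is.null(truth)) {
      key <- paste(truth$sites$chrom, truth$sites$pos)
      si <- siteInfo(gm)
      truth$sites <- truth$sites[match(paste(si$chrom, si$pos), key), ]
    }
  }
  if ("polarize" %in% cfg$stages) {
    gm <- polarizeByOutgroup(gm)
    note("polarize", sum(ancestralAlleles(gm) != "unknown"))
  }
  res$genotypes <- gm

  if ("diversity" %in% cfg$stages) {
    het <- individualHeterozygosity(gm)
    tsv(data.frame(sample = names(het), heterozygosity = het),
        "heterozygosity.tsv")
    div <- do.call(rbind, lapply(pops, function(p) {
      pi_t <- windowedPi(gm, p, cfg$window)
      tw <- windowedThetaW(gm, p, cfg$window)
      cbind(population = p, pi_t[c("chrom", "start", "end", "S")],
            pi = pi_t$pi, theta_w = tw$theta_w)
    }))
    tsv(div, "diversity_windows.tsv")
    note("diversity", nrow(div))
    res$heterozygosity <- het
    res$diversity <- div
  }
  if ("fst" %in% cfg$stages && length(pops) > 1) {
    fm <- fstMatrix(gm, cfg$window, pops)
    write.table(fm, file.path(cfg$out_dir, "fst_matrix.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    note("fst", nrow(fm))
    res$fst <- fm
  }
  if ("relatedness" %in% cfg$stages) {
    ibd <- ibdMoments(gm)
    tsv(ibd, "ibd.tsv")
    dm <- pDistanceMatrix(gm)
    write.table(dm, file.path(cfg$out_dir, "p_distance.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    note("relatedness", nrow(ibd))
    res$ibd <- ibd
    res$p_distance <- dm
  }
  if ("pca" %in% cfg$stages && ncol(gm) > 2) {
    pca <- genotypePCA(gm)
    tsv(cbind(sample = rownames(pca$coords), as.data.frame(pca$coords)),
        "pca.tsv")
    note("pca", nrow(pca$coords))
    res$pca <- pca
  }
  if ("nj" %in% cfg$stages && ncol(gm) >= 3) {
    set.seed(.stage_seed(cfg$seed, 2L))
    og <- if (length(outgroupSamples(gm))) outgroupSamples(gm)[1] else NULL
    bs <- bootstrapSupport(gm, n_reps = 100L,
                           seed = .stage_seed(cfg$seed, 3L), outgroup = og)
    writeNewick(bs$tree, file.path(cfg$out_dir, "nj_tree.nwk"))
    note("nj", length(bs$tree$tip.label))
    res$tree <- bs
  }
  if ("roh" %in% cfg$stages) {
    inb <- inbreedingTable(gm, cfg$roh)
    tsv(inb, "inbreeding.tsv")
    note("roh", nrow(inb))
    res$inbreeding <- inb
  }
  if ("dstat" %in% cfg$stages && length(pops) >= 3 &&
      length(outgroupSamples(gm))) {
    og <- outgroupSamples(gm)
    combos <- utils::combn(pops, 3)
    dd <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k)
      dStatistic(gm, combos[1, k], combos[2, k], combos[3, k], og,
                 cfg$block_size)))
    tsv(dd, "dstat.tsv")
    note("dstat", nrow(dd))
    res$dstat <- dd
  }
  categories <- NULL
  if (!is.null(truth)) categories <- truth$sites$category
  else if (!is.null(cfg$gff) && !is.null(cfg$fasta))
    categories <- classifyEffects(gm, cfg$gff, cfg$fasta)
  if (!is.null(categories)) {
    categories[categories == "NEUTRAL"] <- "noncoding"
    if ("load" %in% cfg$stages) {
      lt <- loadTable(gm, categories)
      tsv(lt$individuals, "load_individuals.tsv")
      tsv(lt$population_means, "load_population_means.tsv")
      note("load", nrow(lt$individuals))
      res$load <- lt
    }
    if ("sfs" %in% cfg$stages) {
      sf <- lapply(pops, function(p) sfsSpectrum(gm, categories, p))
      names(sf) <- pops
      tsv(do.call(rbind, lapply(pops, function(p)
        cbind(population = p, sf[[p]]$spectrum))), "sfs.tsv")
      note("sfs", sum(vapply(sf, function(s) nrow(s$spectrum), integer(1))))
      res$sfs <- sf
    }
    if ("rxy" %in% cfg$stages && length(pops) > 1) {
      prs <- utils::combn(pops, 2)
      rx <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k)
        do.call(rbind, lapply(intersect(c("HIGH", "MODERATE", "LOW"),
                                        unique(categories)), function(cat)
          cbind(popX = prs[1, k], popY = prs[2, k],
                rxy(gm, categories, cat, prs[1, k], prs[2, k]))))))
      tsv(rx, "rxy.tsv")
      note("rxy", nrow(rx))
      res$rxy <- rx
    }
  }
  manifest$parameters <- list(filter = unclass(cfg$filter),
                              window = unclass(cfg$window),
                              roh = unclass(cfg$roh),
                              block_size = cfg$block_size, fdr = cfg$fdr)
  manifest$inputs <- list(vcf = cfg$vcf, population_map = cfg$population_map,
                          simulated = !is.null(cfg$simulation))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$manifest <- manifest
  invisible(res)
}

#' Aggregate a pipeline run into one summary bundle
#'
#' Collects per-population means (heterozygosity, genome-wide pi, FST
#' matrix, F_H / F_ROH, load table, Rxy) into a single list, written both
#' as TSV files and one JSON carrying identical numbers.
#'
#' @param res result list of [runPipeline()].
#' @param out_dir directory for \code{summary.json} /
#'   \code{summary_*.tsv} (default: skip writing).
#' @return the summary list.
#' @export
summaryReport <- function(res, out_dir = NULL) {
  gm <- res$genotypes
  popv <- populations(gm)
  summ <- list()
  if (!is.null(res$heterozygosity)) {
    het <- res$heterozygosity
    summ$heterozygosity <-
      vapply(split(het, popv[names(het)]), mean, numeric(1), USE.NAMES = TRUE)
  }
  if (!is.null(res$diversity))
    summ$mean_pi <- vapply(split(res$diversity$pi, res$diversity$population),
                           mean, numeric(1))
  if (!is.null(res$fst)) summ$fst <- res$fst
  if (!is.null(res$inbreeding)) {
    inb <- res$inbreeding
    summ$inbreeding <- do.call(rbind, lapply(split(inb, popv[inb$sample]),
      function(df) data.frame(population = popv[df$sample[1]],
                              F_H = mean(df$F_H),
                              F_ROH_100kb = mean(df$F_ROH_100kb),
                              F_ROH_1Mb = mean(df$F_ROH_1Mb),
                              F_ROH_2Mb = mean(df$F_ROH_2Mb))))
    rownames(summ$inbreeding) <- NULL
  }
  if (!is.null(res$load)) summ$load <- res$load$population_means
  if (!is.null(res$rxy)) summ$rxy <- res$rxy
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(summ)) {
      obj <- summ[[nm]]
      if (is.matrix(obj))
        write.table(obj, file.path(out_dir, paste0("summary_", nm, ".tsv")),
                    sep = "\t", quote = FALSE, col.names = NA)
      else if (is.data.frame(obj))
        write.table(obj, file.path(out_dir, paste0("summary_", nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      else
        write.table(data.frame(population = names(obj), value = obj),
                    file.path(out_dir, paste0("summary_", nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    json_ready <- lapply(summ, function(x)
      if (is.numeric(x) && !is.matrix(x) && !is.null(names(x))) as.list(x)
      else x)
    jsonlite::write_json(json_ready, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  summ
}
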