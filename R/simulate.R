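#' @importFrom stats rbinom rpois runif rnorm rexp setNames
NULL

#' Demographic events for the forward simulator
#'
#' Events are applied at the start of the stated generation, before that
#' generation's offspring are bred.
#'
#' \describe{
#'   \item{evSplit}{a new population \code{child} of \code{size} diploids is
#'     bred from the parent pool of \code{parent} (a population split).}
#'   \item{evFounder}{a founder event: \code{n_males} + \code{n_females}
#'     adults are drawn from \code{source} and become the only breeders of
#'     the new population \code{child} (they leave the source pool).}
#'   \item{evResize}{\code{pop} breeds \code{size} offspring from this
#'     generation on.}
#'   \item{evPulse}{in this generation only, each offspring of
#'     \code{target} draws both parents from \code{source} with
#'     probability \code{f} (an introgression pulse).}
#' }
#'
#' @param gen generation (1-based) at which the event fires.
#' @param parent,child,source,target,pop population labels.
#' @param size diploid population size.
#' @param n_males,n_females founder counts by sex.
#' @param f pulse admixture fraction in [0, 1].
#' @return an event list consumed by [simulate()].
#' @name sim-events
NULL

#' @rdname sim-events
#' @export
evSplit <- function(gen, parent, child, size)
  list(type = "split", gen = gen, parent = parent, child = child, size = size)

#' @rdname sim-events
#' @export
evFounder <- function(gen, source, child, n_males = 2L, n_females = 4L,
                      size = NULL)
  list(type = "founder", gen = gen, source = source, child = child,
       n_males = n_males, n_females = n_females,
       size = if (is.null(size)) n_males + n_females else size)

#' @rdname sim-events
#' @export
evResize <- function(gen, pop, size)
  list(type = "resize", gen = gen, pop = pop, size = size)

#' @rdname sim-events
#' @export
evPulse <- function(gen, source, target, f) {
  stopifnot(f >= 0, f <= 1)
  list(type = "pulse", gen = gen, source = source, target = target, f = f)
}

#' Configuration for the forward Wright-Fisher simulator
#'
#' Defaults describe a deliberately scaled-down diploid system (small
#' chromosomes, 2N at most a few hundred, mutation rate rescaled upward so
#' that the per-site scaled diversity 4*N*mu matches a realistic value)
#' so that whole scenarios run in seconds; the compound parameters
#' 4*N*mu and the selection intensities are what the statistics respond
#' to, not their factors. The biological per-generation point estimates
#' (mu = 3.5e-9/bp, generation time 5 years) are kept as metadata.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param mu per-bp per-generation mutation rate.
#' @param recomb per-bp per-generation recombination rate.
#' @param classes data.frame with columns \code{category}, \code{fraction},
#'   \code{s}, \code{h}: fraction of new mutations falling in each impact
#'   category, their selection coefficient and dominance; remaining
#'   mutations are neutral non-coding. Fitness is multiplicative:
#'   heterozygote 1-hs, homozygote 1-s.
#' @param init_size diploid size of the initial population.
#' @param init_pop label of the initial population.
#' @param init \code{"equilibrium"} seeds standing variation from the
#'   neutral frequency spectrum expected at mutation-drift balance (site
#'   count with derived count i ~ Poisson(theta*L/i)); \code{"empty"}
#'   starts without variation.
#' @param standing_sites optional data.frame (chrom, pos, count, category,
#'   s, h) of exact standing variants to seed (e.g. for drift studies with
#'   \code{mu = 0}).
#' @param events list of [sim-events].
#' @param n_generations number of bred generations.
#' @param selection_pops populations in which viability selection acts;
#'   \code{NULL} means all.
#' @param mating \code{"random"} or \code{"studbook"} (full-sib matings
#'   avoided when alternatives exist, mimicking managed breeding).
#' @param sample_pops populations sampled into the output VCF (default:
#'   all populations alive at the end).
#' @param outgroup_pop population providing the outgroup sample(s).
#' @param n_outgroup_samples how many outgroup individuals to emit.
#' @param missing_rate per-genotype missing-call rate in the output.
#' @param mean_depth mean per-genotype sequencing depth for the synthetic
#'   DP values.
#' @param ref_ancestral_prob probability that the VCF REF allele is the
#'   ancestral allele at a site (the rest are reported swapped, exercising
#'   polarization).
#' @param generation_time years per generation (metadata only).
#' @param compute_fp compute the pedigree inbreeding coefficient F_p for
#'   each sampled individual (Wright's path counting).
#' @param seed integer random seed; simulation output is a deterministic
#'   function of (config, seed).
#' @return a \code{SimulationConfig} list.
#' @export
simulationConfig <- function(chrom_lengths = c(chr1 = 5e5, chr2 = 5e5),
                             mu = 3.5e-9,
                             recomb = 1e-8,
                             classes = data.frame(
                               category = c("HIGH", "MODERATE", "LOW"),
                               fraction = c(0.002, 0.02, 0.05),
                               s = c(0.5, 0.05, 0.0),
                               h = c(0.0, 0.25, 0.5)),
                             init_size = 50L,
                             init_pop = "anc",
                             init = c("equilibrium", "empty"),
                             standing_sites = NULL,
                             events = list(),
                             n_generations = 10L,
                             selection_pops = NULL,
                             mating = c("random", "studbook"),
                             sample_pops = NULL,
                             outgroup_pop = NULL,
                             n_outgroup_samples = 1L,
                             missing_rate = 0.02,
                             mean_depth = 15,
                             ref_ancestral_prob = 0.7,
                             generation_time = 5,
                             compute_fp = TRUE,
                             seed = 1L) {
  init <- match.arg(init)
  mating <- match.arg(mating)
  stopifnot(sum(classes$fraction) <= 1, all(classes$fraction >= 0),
            init_size >= 1, all(chrom_lengths >= 1), mu >= 0, recomb >= 0)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Scaled-down captive founder demography preset
#'
#' A ready-made [simulationConfig()] emulating the study system at desk
#' scale: an ancestral population with a deep-splitting outgroup lineage,
#' several diverged subspecies populations, a severe founder event (2
#' males + 4 females) establishing a captive population that then grows
#' and splits into two semi-isolated captive lineages, and a rare
#' introgression pulse from one subspecies into one lineage.
#'
#' @param theta target per-site scaled diversity 4*N*mu of the ancestral
#'   population (sets the rescaled mutation rate).
#' @param n_subspecies number of diverged wild populations besides the
#'   focal one.
#' @param pulse_f introgression pulse fraction (0 disables the pulse).
#' @param founder run the founder event (set \code{FALSE} for a matched
#'   no-founder control).
#' @param n_generations total bred generations.
#' @param chrom_lengths chromosome lengths (bp).
#' @param seed random seed.
#' @param ... further arguments passed to [simulationConfig()].
#' @return a \code{SimulationConfig}.
#' @export
captiveDemography <- function(theta = 0.002, n_subspecies = 5L,
                              pulse_f = 0.05, founder = TRUE,
                              n_generations = 20L,
                              chrom_lengths = c(chr1 = 5e5, chr2 = 5e5),
                              seed = 1L, ...) {
  N0 <- 40L
  mu <- theta / (4 * N0)
  subs <- paste0("wild", seq_len(n_subspecies))
  ev <- list(evSplit(1L, "anc", "outgroup", 4L))
  for (i in seq_len(n_subspecies))
    ev <- c(ev, list(evSplit(2L + (i - 1L) %% 3L, "anc", subs[i], 12L)))
  ev <- c(ev, list(evSplit(4L, "anc", "focal_wild", 16L),
                   evResize(5L, "anc", 0L)))
  if (founder) {
    fg <- min(10L, n_generations - 6L)
    ev <- c(ev, list(
      evFounder(fg, "focal_wild", "captive", n_males = 2L, n_females = 4L,
                size = 12L),
      evResize(fg + 2L, "captive", 20L),
      evSplit(fg + 3L, "captive", "lineage2", 10L),
      evResize(fg + 3L, "captive", 10L)))
    if (pulse_f > 0)
      ev <- c(ev, list(evPulse(fg + 4L, subs[1L], "lineage2", pulse_f)))
  }
  # recombination rescaled with mu so rho/theta keeps a realistic ratio
  simulationConfig(chrom_lengths = chrom_lengths, mu = mu, recomb = mu,
                   init_size = N0, events = ev,
                   n_generations = n_generations,
                   outgroup_pop = "outgroup",
                   sample_pops = NULL, seed = seed, ...)
}

.unit_ancestry <- function(pops, pop) {
  v <- setNames(numeric(length(pops)), pops)
  v[pop] <- 1
  v
}

#' Run the forward Wright-Fisher simulation
#'
#' Discrete generations of diploid, two-sex Wright-Fisher reproduction
#' with multiplicative viability selection (heterozygote 1-hs, homozygote
#' 1-s per deleterious site), Poisson mutation under an infinite-sites
#' approximation, uniform crossover recombination, demographic events
#' (splits, founder events, resizes, introgression pulses) and full
#' pedigree/ancestry tracking. Deterministic given the config seed.
#'
#' @param cfg a [simulationConfig()] or [captiveDemography()] preset.
#' @return list with elements:
#' \describe{
#'   \item{genotypes}{a [GenotypeMatrix-class] of the sampled individuals
#'     (final generation of each sampled population plus the outgroup),
#'     with synthetic INFO annotations, per-genotype depths, contig
#'     lengths, and unpolarized ancestral calls.}
#'   \item{pedigree}{data.frame (id, sire, dam, sex, generation,
#'     population) over every individual ever bred.}
#'   \item{truth}{list of \code{sites} (chrom, pos, ancestral, category,
#'     s, h, origin_gen -- the generation the variant arose, 0 for
#'     standing variation) and \code{individuals} (id, population, F_p,
#'     one ancestry column per population) ground truth.}
#' }
#' @export
simulate <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  chroms <- names(cfg$chrom_lengths)
  clen <- as.numeric(cfg$chrom_lengths)
  G_total <- sum(clen)

  ## --- site registry -------------------------------------------------
  site_chrom <- integer(0)   # index into chroms
  site_pos <- integer(0)
  site_cat <- character(0)
  site_s <- numeric(0)
  site_h <- numeric(0)
  site_key <- character(0)
  site_origin <- integer(0)   # generation the variant arose (0 = standing)

  draw_classes <- function(k) {
    cats <- c(cfg$classes$category, "NEUTRAL")
    prob <- c(cfg$classes$fraction, 1 - sum(cfg$classes$fraction))
    idx <- sample.int(length(cats), k, replace = TRUE, prob = prob)
    list(category = cats[idx],
         s = c(cfg$classes$s, 0)[idx],
         h = c(cfg$classes$h, 0.5)[idx])
  }

  ## --- initial population -------------------------------------------
  N0 <- cfg$init_size
  nhap0 <- 2L * N0
  if (!is.null(cfg$standing_sites)) {
    ss <- cfg$standing_sites
    L0 <- nrow(ss)
    site_chrom <- match(as.character(ss$chrom), chroms)
    site_pos <- as.integer(ss$pos)
    site_cat <- if ("category" %in% names(ss)) as.character(ss$category)
                else rep("NEUTRAL", L0)
    site_s <- if ("s" %in% names(ss)) ss$s else rep(0, L0)
    site_h <- if ("h" %in% names(ss)) ss$h else rep(0.5, L0)
    H <- matrix(0L, nhap0, L0)
    for (j in seq_len(L0))
      H[sample.int(nhap0, min(ss$count[j], nhap0)), j] <- 1L
  } else if (cfg$init == "equilibrium" && cfg$mu > 0) {
    thetaL <- 4 * N0 * cfg$mu * G_total
    counts <- integer(0)
    for (i in seq_len(nhap0 - 1L)) {
      k <- rpois(1L, thetaL / i)
      counts <- c(counts, rep(i, k))
    }
    L0 <- length(counts)
    site_chrom <- sample.int(length(chroms), L0, replace = TRUE,
                             prob = clen / G_total)
    site_pos <- as.integer(ceiling(runif(L0) * clen[site_chrom]))
    cl <- draw_classes(L0)
    site_cat <- cl$category; site_s <- cl$s; site_h <- cl$h
    dup <- duplicated(paste(site_chrom, site_pos))
    if (any(dup)) {
      keep <- !dup
      site_chrom <- site_chrom[keep]; site_pos <- site_pos[keep]
      site_cat <- site_cat[keep]; site_s <- site_s[keep]; site_h <- site_h[keep]
      counts <- counts[keep]; L0 <- length(counts)
    }
    # standing deleterious variants are held rare, approximating
    # mutation-selection balance (the neutral SFS would load the
    # population with common homozygous lethals it could never carry)
    del <- which(site_s > 0)
    if (length(del)) {
      cap <- max(1L, floor(0.05 * nhap0))
      wts <- 1 / seq_len(cap)
      counts[del] <- sample.int(cap, length(del), replace = TRUE,
                                prob = wts / sum(wts))
    }
    H <- matrix(0L, nhap0, L0)
    for (j in seq_len(L0))
      H[sample.int(nhap0, counts[j]), j] <- 1L
  } else {
    H <- matrix(0L, nhap0, 0L)
  }
  site_key <- paste(site_chrom, site_pos)
  site_origin <- integer(length(site_pos))

  ## --- individuals ---------------------------------------------------
  next_id <- 1L
  new_ids <- function(k) {
    ids <- sprintf("i%05d", next_id + seq_len(k) - 1L)
    next_id <<- next_id + k
    ids
  }
  all_pops <- cfg$init_pop
  ind <- data.frame(id = new_ids(N0),
                    sex = rep_len(c("M", "F"), N0),
                    pop = cfg$init_pop,
                    stringsAsFactors = FALSE)
  ancestry <- matrix(1, N0, 1, dimnames = list(NULL, cfg$init_pop))
  ped <- data.frame(id = ind$id, sire = NA_character_, dam = NA_character_,
                    sex = ind$sex, generation = 0L, population = cfg$init_pop,
                    stringsAsFactors = FALSE)
  pop_size <- setNames(N0, cfg$init_pop)
  # parent pool per pop: indices into current `ind`
  pools <- list()
  pools[[cfg$init_pop]] <- seq_len(N0)
  pop_created_gen <- setNames(0L, cfg$init_pop)

  sel_active <- function(pop) is.null(cfg$selection_pops) ||
    pop %in% cfg$selection_pops

  chrom_sites <- split(seq_along(site_chrom), factor(site_chrom,
                                                     levels = seq_along(chroms)))

  gamete <- function(r1, r2) {
    L <- length(site_pos)
    if (L == 0L) return(integer(0))
    g <- integer(L)
    for (ci in seq_along(chroms)) {
      idx <- chrom_sites[[ci]]
      if (!length(idx)) next
      ncx <- rpois(1L, cfg$recomb * clen[ci])
      if (ncx > 0L) {
        cuts <- sort(runif(ncx) * clen[ci])
        par <- (rbinom(1L, 1L, 0.5) + findInterval(site_pos[idx], cuts)) %% 2L
        from2 <- idx[par == 1L]
        from1 <- idx[par == 0L]
        g[from1] <- H[r1, from1]
        g[from2] <- H[r2, from2]
      } else {
        r <- if (rbinom(1L, 1L, 0.5) == 0L) r1 else r2
        g[idx] <- H[r, idx]
      }
    }
    g
  }

  muL <- cfg$mu * G_total

  ## --- generations ---------------------------------------------------
  for (gen in seq_len(cfg$n_generations)) {
    evs <- Filter(function(e) e$gen == gen, cfg$events)
    pulses <- list()
    for (e in evs) {
      if (e$type == "resize") pop_size[e$pop] <- e$size
      else if (e$type == "split") {
        if (is.null(pools[[e$parent]]))
          stop("split parent '", e$parent, "' has no breeding pool at generation ", gen)
        pools[[e$child]] <- pools[[e$parent]]
        pop_size[e$child] <- e$size
        all_pops <- union(all_pops, e$child)
        pop_created_gen[e$child] <- gen
      } else if (e$type == "founder") {
        src <- pools[[e$source]]
        if (is.null(src)) stop("founder source '", e$source, "' missing")
        males <- src[ind$sex[src] == "M"]
        females <- src[ind$sex[src] == "F"]
        if (length(males) < e$n_males || length(females) < e$n_females)
          stop("simulation failure: not enough founders of each sex in '",
               e$source, "' at generation ", gen)
        chosen <- c(sample(males, e$n_males), sample(females, e$n_females))
        pools[[e$child]] <- chosen
        pools[[e$source]] <- setdiff(src, chosen)
        pop_size[e$child] <- e$size
        all_pops <- union(all_pops, e$child)
        pop_created_gen[e$child] <- gen
      } else if (e$type == "pulse") {
        pulses[[e$target]] <- e
      }
    }
    if (ncol(ancestry) < length(all_pops)) {
      add <- setdiff(all_pops, colnames(ancestry))
      ancestry <- cbind(ancestry,
                        matrix(0, nrow(ancestry), length(add),
                               dimnames = list(NULL, add)))
    }

    active <- names(pop_size)[pop_size > 0]
    kid_rows <- list(); kid_meta <- list(); kid_anc <- list()
    kid_newmut <- list()   # per accepted gamete: class draws
    sel_cols <- which(site_s > 0)

    for (p in active) {
      pool <- pools[[p]]
      if (is.null(pool) || !length(pool))
        stop("simulation failure: population '", p,
             "' has no breeding pool at generation ", gen)
      males <- pool[ind$sex[pool] == "M"]
      females <- pool[ind$sex[pool] == "F"]
      if (!length(males) || !length(females))
        stop("simulation failure: population '", p,
             "' lacks one sex at generation ", gen)
      pe <- pulses[[p]]
      smales <- sfemales <- NULL
      if (!is.null(pe)) {
        spool <- pools[[pe$source]]
        smales <- spool[ind$sex[spool] == "M"]
        sfemales <- spool[ind$sex[spool] == "F"]
      }
      n_target <- pop_size[p]
      accepted <- 0L
      tries <- 0L
      g1s <- vector("list", n_target); g2s <- vector("list", n_target)
      sire_v <- character(n_target); dam_v <- character(n_target)
      sex_v <- character(n_target); mig_v <- logical(n_target)
      anc_rows <- matrix(0, n_target, ncol(ancestry),
                         dimnames = list(NULL, colnames(ancestry)))
      nm1 <- vector("list", n_target); nm2 <- vector("list", n_target)
      while (accepted < n_target) {
        tries <- tries + 1L
        if (tries > 500L * n_target)
          stop("simulation failure: population '", p,
               "' cannot maintain size ", n_target, " at generation ", gen,
               " (selection load too high)")
        migrant <- !is.null(pe) && runif(1) < pe$f &&
          length(smales) && length(sfemales)
        if (migrant) {
          si <- if (length(smales) == 1L) smales else sample(smales, 1L)
          di <- if (length(sfemales) == 1L) sfemales else sample(sfemales, 1L)
        } else {
          si <- if (length(males) == 1L) males else sample(males, 1L)
          di <- if (length(females) == 1L) females else sample(females, 1L)
        }
        if (cfg$mating == "studbook" && length(males) > 1L) {
          sib_try <- 0L
          while (sib_try < 20L && .full_sibs(ped, ind$id[si], ind$id[di])) {
            si <- if (length(males) == 1L) males else sample(males, 1L)
            di <- if (length(females) == 1L) females else sample(females, 1L)
            sib_try <- sib_try + 1L
          }
        }
        g1 <- gamete(2L * si - 1L, 2L * si)
        g2 <- gamete(2L * di - 1L, 2L * di)
        k1 <- rpois(1L, muL); k2 <- rpois(1L, muL)
        c1 <- if (k1) draw_classes(k1) else NULL
        c2 <- if (k2) draw_classes(k2) else NULL
        if (sel_active(p)) {
          logw <- 0
          if (length(sel_cols)) {
            dsel <- g1[sel_cols] + g2[sel_cols]
            het <- dsel == 1L; hom <- dsel == 2L
            if (any(hom) && any(site_s[sel_cols][hom] >= 1)) logw <- -Inf
            else logw <- sum(log1p(-site_h[sel_cols][het] * site_s[sel_cols][het])) +
                sum(log1p(-site_s[sel_cols][hom]))
          }
          for (cc in list(c1, c2)) if (!is.null(cc)) {
            dd <- cc$s > 0
            logw <- logw + sum(log1p(-cc$h[dd] * cc$s[dd]))
          }
          if (is.finite(logw)) w <- exp(logw) else w <- 0
          if (runif(1) >= w) next
        }
        accepted <- accepted + 1L
        g1s[[accepted]] <- g1; g2s[[accepted]] <- g2
        nm1[accepted] <- list(c1); nm2[accepted] <- list(c2)
        sire_v[accepted] <- ind$id[si]
        dam_v[accepted] <- ind$id[di]
        sex_v[accepted] <- if (runif(1) < 0.5) "M" else "F"
        mig_v[accepted] <- migrant
        if (pop_created_gen[p] == gen && !migrant)
          anc_rows[accepted, ] <- .unit_ancestry(colnames(ancestry), p)
        else
          anc_rows[accepted, ] <- (ancestry[si, ] + ancestry[di, ]) / 2
      }
      # guard against a single-sex generation
      if (n_target >= 2L && length(unique(sex_v)) == 1L)
        sex_v[1L] <- setdiff(c("M", "F"), sex_v[1L])
      kid_rows[[p]] <- list(g1 = g1s, g2 = g2s)
      kid_meta[[p]] <- data.frame(sire = sire_v, dam = dam_v, sex = sex_v,
                                  migrant = mig_v, pop = p,
                                  stringsAsFactors = FALSE)
      kid_anc[[p]] <- anc_rows
      kid_newmut[[p]] <- list(nm1 = nm1, nm2 = nm2)
    }

    ## assemble next generation
    metas <- do.call(rbind, kid_meta)
    n_kids <- nrow(metas)
    L_old <- length(site_pos)
    Hn <- matrix(0L, 2L * n_kids, L_old)
    row <- 0L
    mut_specs <- list()  # (hap_row, category, s, h)
    for (p in names(kid_rows)) {
      kr <- kid_rows[[p]]; km <- kid_newmut[[p]]
      for (k in seq_along(kr$g1)) {
        if (is.null(kr$g1[[k]])) next
        Hn[row + 1L, ] <- kr$g1[[k]]
        Hn[row + 2L, ] <- kr$g2[[k]]
        if (!is.null(km$nm1[[k]]))
          mut_specs[[length(mut_specs) + 1L]] <-
            cbind(data.frame(hap = row + 1L), as.data.frame(km$nm1[[k]]))
        if (!is.null(km$nm2[[k]]))
          mut_specs[[length(mut_specs) + 1L]] <-
            cbind(data.frame(hap = row + 2L), as.data.frame(km$nm2[[k]]))
        row <- row + 2L
      }
    }
    if (length(mut_specs)) {
      ms <- do.call(rbind, mut_specs)
      colnames(ms)[1] <- "hap"
      nmut <- nrow(ms)
      mchrom <- sample.int(length(chroms), nmut, replace = TRUE,
                           prob = clen / G_total)
      mpos <- as.integer(ceiling(runif(nmut) * clen[mchrom]))
      keyn <- paste(mchrom, mpos)
      ok <- !(keyn %in% site_key) & !duplicated(keyn)
      if (any(ok)) {
        ms <- ms[ok, , drop = FALSE]
        mchrom <- mchrom[ok]; mpos <- mpos[ok]; keyn <- keyn[ok]
        block <- matrix(0L, nrow(Hn), nrow(ms))
        block[cbind(ms$hap, seq_len(nrow(ms)))] <- 1L
        Hn <- cbind(Hn, block)
        site_chrom <- c(site_chrom, mchrom)
        site_pos <- c(site_pos, mpos)
        site_cat <- c(site_cat, as.character(ms$category))
        site_s <- c(site_s, ms$s)
        site_h <- c(site_h, ms$h)
        site_key <- c(site_key, keyn)
        site_origin <- c(site_origin, rep(gen, nrow(ms)))
      }
    }
    ## drop monomorphic columns
    cs <- colSums(Hn)
    keep <- cs > 0L & cs < nrow(Hn)
    Hn <- Hn[, keep, drop = FALSE]
    site_chrom <- site_chrom[keep]; site_pos <- site_pos[keep]
    site_cat <- site_cat[keep]; site_s <- site_s[keep]; site_h <- site_h[keep]
    site_key <- site_key[keep]; site_origin <- site_origin[keep]
    chrom_sites <- split(seq_along(site_chrom),
                         factor(site_chrom, levels = seq_along(chroms)))

    ids <- new_ids(n_kids)
    ped <- rbind(ped, data.frame(id = ids, sire = metas$sire, dam = metas$dam,
                                 sex = metas$sex, generation = gen,
                                 population = metas$pop,
                                 stringsAsFactors = FALSE))
    ind <- data.frame(id = ids, sex = metas$sex, pop = metas$pop,
                      stringsAsFactors = FALSE)
    ancestry <- do.call(rbind, kid_anc)
    H <- Hn
    pools <- split(seq_len(n_kids), ind$pop)
  }

  ## --- sample output --------------------------------------------------
  spops <- cfg$sample_pops
  if (is.null(spops)) spops <- setdiff(unique(ind$pop), cfg$outgroup_pop)
  sel <- which(ind$pop %in% spops)
  og_sel <- integer(0)
  if (!is.null(cfg$outgroup_pop)) {
    og_all <- which(ind$pop == cfg$outgroup_pop)
    og_sel <- utils::head(og_all, cfg$n_outgroup_samples)
  }
  take <- c(sel, og_sel)
  if (!length(take)) stop("no individuals to sample")
  n_out <- length(take)
  hap_rows <- as.vector(rbind(2L * take - 1L, 2L * take))
  D <- H[2L * take - 1L, , drop = FALSE] + H[2L * take, , drop = FALSE]
  D <- t(D)   # sites x samples
  L <- nrow(D)
  if (L == 0L) stop("simulation produced no segregating sites")

  ## REF/ALT assignment; truth ancestral allele is the '0' state
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  swap <- runif(L) >= cfg$ref_ancestral_prob
  D[swap, ] <- 2L - D[swap, , drop = FALSE]
  anc_truth <- ifelse(swap, "alt", "ref")

  ## synthetic INFO + depths
  depth <- matrix(rpois(L * n_out, cfg$mean_depth), L, n_out)
  if (cfg$missing_rate > 0) {
    mi <- runif(L * n_out) < cfg$missing_rate
    D[mi] <- NA_integer_
    depth[mi] <- 0L
  }
  info <- DataFrame(QD = pmax(0.5, rnorm(L, 25, 8)),
                    FS = round(rexp(L, 1 / 5), 3),
                    MQ = pmin(60, pmax(10, rnorm(L, 55, 4))),
                    QUAL = round(pmax(31, rnorm(L, 500, 150)), 1),
                    DP = rowSums(depth),
                    MQRankSum = rnorm(L, 0, 1.5),
                    ReadPosRankSum = rnorm(L, 0, 1.5))
  ids_out <- ind$id[take]
  gm <- GenotypeMatrix(D, chrom = chroms[site_chrom], pos = site_pos,
                       ref = ref, alt = alt,
                       samples = ids_out,
                       populations = ind$pop[take],
                       outgroup = ind$id[og_sel],
                       info = info, ancestral = "unknown", depth = depth,
                       seqlengths = cfg$chrom_lengths)
  metadata(gm)$seed <- cfg$seed

  o <- order(site_chrom, site_pos)
  truth_sites <- data.frame(chrom = chroms[site_chrom][o], pos = site_pos[o],
                            ancestral = anc_truth[o],
                            category = site_cat[o], s = site_s[o],
                            h = site_h[o], origin_gen = site_origin[o],
                            stringsAsFactors = FALSE)
  anc_ind <- ancestry[take, , drop = FALSE]
  fp <- rep(NA_real_, n_out)
  if (isTRUE(cfg$compute_fp))
    fp <- pedigreeInbreeding(ped, ids_out)
  truth_ind <- cbind(data.frame(id = ids_out, population = ind$pop[take],
                                F_p = fp, stringsAsFactors = FALSE),
                     as.data.frame(anc_ind))
  list(genotypes = gm, pedigree = ped,
       truth = list(sites = truth_sites, individuals = truth_ind))
}

.full_sibs <- function(ped, a, b) {
  ra <- ped[match(a, ped$id), ]
  rb <- ped[match(b, ped$id), ]
  !is.na(ra$sire) && !is.na(rb$sire) &&
    identical(ra$sire, rb$sire) && identical(ra$dam, rb$dam)
}

#' Pedigree inbreeding coefficient (Wright's F_p)
#'
#' F_p of an individual is the kinship coefficient of its parents,
#' computed by the standard recursive kinship algorithm (equivalent to
#' Wright's path counting) with founders assumed non-inbred and
#' unrelated.
#'
#' @param ped data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   and \code{generation}; parents must belong to earlier generations
#'   than their offspring (violations raise a validation error).
#' @param ids individual id(s) to evaluate.
#' @return numeric vector of F_p values (0 for founders).
#' @examples
#' ped <- data.frame(id = c("a", "b", "x", "y", "z"),
#'                   sire = c(NA, NA, "a", "a", "x"),
#'                   dam = c(NA, NA, "b", "b", "y"),
#'                   generation = c(0, 0, 1, 1, 2))
#' pedigreeInbreeding(ped, "z")  # offspring of full sibs: 0.25
#' @export
pedigreeInbreeding <- function(ped, ids) {
  idx <- match(ped$id, ped$id)
  sire <- match(ped$sire, ped$id)
  dam <- match(ped$dam, ped$id)
  gen <- ped$generation
  bad <- which((!is.na(sire) & gen[sire] >= gen) |
                 (!is.na(dam) & gen[dam] >= gen))
  if (length(bad))
    stop("invalid pedigree: parents of '", ped$id[bad[1]],
         "' do not precede it in generation order (cycle?)")
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(sire[i], dam[i]))
    } else {
      # recurse on the younger individual
      if (gen[i] < gen[j]) { t <- i; i <- j; j <- t }
      0.5 * (phi(sire[i], j) + phi(dam[i], j))
    }
    memo[[key]] <- v
    v
  }
  vapply(ids, function(id) {
    i <- match(id, ped$id)
    if (is.na(i)) stop("individual '", id, "' not in pedigree")
    phi(sire[i], dam[i])
  }, numeric(1))
}

#' Write simulator output to disk
#'
#' @param sim result of [simulate()].
#' @param dir output directory (created if absent). Writes
#'   \code{genotypes.vcf}, \code{pedigree.tsv}, \code{truth_sites.tsv},
#'   \code{truth_individuals.tsv}.
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVCF(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write.table(sim$pedigree, file.path(dir, "pedigree.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$sites, file.path(dir, "truth_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$individuals, file.path(dir, "truth_individuals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
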