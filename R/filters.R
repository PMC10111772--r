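#' Hard site-filter configuration
#'
#' Thresholds for the standard GATK-style hard filters applied to biallelic
#' SNPs, plus callset-level rules: overall-depth bounds expressed as
#' multiples of the mean per-site total depth, a per-site missing-call
#' ceiling, and an assembly-gap proximity exclusion.
#'
#' @param min_QD minimum quality-by-depth (sites with QD below are removed).
#' @param max_FS maximum Fisher-strand phred score.
#' @param min_MQ minimum RMS mapping quality.
#' @param min_QUAL minimum site QUAL.
#' @param min_DP minimum per-site total depth.
#' @param min_MQRankSum,min_ReadPosRankSum minimum rank-sum Z-scores.
#' @param depth_bounds overall-depth bounds as multiples of the mean
#'   per-site total depth across all individuals; sites outside
#'   \code{(mean*lo, mean*hi)} are removed.
#' @param max_missing maximum fraction of missing genotype calls per site
#'   (sites at or above are removed).
#' @param gap_bp exclusion distance: SNPs within this many bp of an
#'   assembly gap are removed.
#' @param biallelic_only retain biallelic SNPs only (enforced at VCF read).
#' @return a validated \code{FilterConfig} list.
#' @export
filterConfig <- function(min_QD = 2.0, max_FS = 60.0, min_MQ = 40.0,
                         min_QUAL = 30, min_DP = 4.0,
                         min_MQRankSum = -12.5, min_ReadPosRankSum = -8.0,
                         depth_bounds = c(1 / 3, 3),
                         max_missing = 0.10, gap_bp = 5L,
                         biallelic_only = TRUE) {
  cfg <- list(min_QD = min_QD, max_FS = max_FS, min_MQ = min_MQ,
              min_QUAL = min_QUAL, min_DP = min_DP,
              min_MQRankSum = min_MQRankSum,
              min_ReadPosRankSum = min_ReadPosRankSum,
              depth_bounds = depth_bounds, max_missing = max_missing,
              gap_bp = as.integer(gap_bp), biallelic_only = biallelic_only)
  stopifnot(all(vapply(cfg[1:7], is.finite, logical(1))),
            length(depth_bounds) == 2, all(is.finite(depth_bounds)),
            depth_bounds[1] < depth_bounds[2],
            max_missing >= 0, max_missing <= 1, gap_bp >= 0)
  structure(cfg, class = "FilterConfig")
}

#' Apply hard site filters
#'
#' Removes sites failing any enabled rule and reports per-rule removal
#' counts. INFO-based rules whose annotation is absent from the matrix are
#' skipped (with a message), never failing the run. Overall-depth bounds
#' are computed from the mean per-site total depth across all individuals
#' of the input; the absolute bounds actually applied are recorded in the
#' output metadata and reused on re-application, so filtering the same
#' matrix twice with the same configuration is a no-op.
#'
#' @param x a [GenotypeMatrix-class].
#' @param cfg a [filterConfig()].
#' @param gaps optional \code{GRanges} of assembly gaps (see
#'   [readGapsBed()], [gapsFromFasta()]); when \code{NULL} the gap rule is
#'   skipped with a warning-level log message.
#' @return list with \code{genotypes} (the filtered [GenotypeMatrix-class])
#'   and \code{report} (data.frame: rule, removed, skipped).
#' @export
applySiteFilters <- function(x, cfg = filterConfig(), gaps = NULL) {
  m <- mcols(rowRanges(x))
  n <- nrow(x)
  fails <- list()
  skipped <- character()

  info_rule <- function(field, fun) {
    v <- if (field %in% colnames(m)) as.numeric(m[[field]]) else NULL
    if (is.null(v) || all(is.na(v))) {
      skipped <<- c(skipped, field)
      return(rep(FALSE, n))
    }
    f <- fun(v)
    f & !is.na(f)
  }
  fails$QD <- info_rule("QD", function(v) v < cfg$min_QD)
  fails$FS <- info_rule("FS", function(v) v > cfg$max_FS)
  fails$MQ <- info_rule("MQ", function(v) v < cfg$min_MQ)
  fails$QUAL <- info_rule("QUAL", function(v) v < cfg$min_QUAL)
  fails$DP <- info_rule("DP", function(v) v < cfg$min_DP)
  fails$MQRankSum <- info_rule("MQRankSum", function(v) v < cfg$min_MQRankSum)
  fails$ReadPosRankSum <- info_rule("ReadPosRankSum",
                                    function(v) v < cfg$min_ReadPosRankSum)

  # overall depth relative to the callset mean
  dpv <- if ("DP" %in% colnames(m) && !all(is.na(m$DP))) as.numeric(m$DP)
         else if ("depth" %in% names(assays(x)))
           rowSums(assay(x, "depth"), na.rm = TRUE)
         else NULL
  if (is.null(dpv)) {
    skipped <- c(skipped, "overall_depth")
    fails$overall_depth <- rep(FALSE, n)
  } else {
    bounds <- metadata(x)$depth_bounds
    if (is.null(bounds))
      bounds <- mean(dpv, na.rm = TRUE) * cfg$depth_bounds
    f <- dpv <= bounds[1] | dpv >= bounds[2]
    fails$overall_depth <- f & !is.na(f)
  }

  miss <- rowMeans(is.na(dosages(x)))
  fails$missingness <- miss >= cfg$max_missing

  if (is.null(gaps)) {
    message("no gap intervals supplied; gap-proximity filter skipped")
    skipped <- c(skipped, "gap_proximity")
    fails$gap_proximity <- rep(FALSE, n)
  } else {
    hit <- GenomicRanges::distanceToNearest(rowRanges(x), gaps)
    near <- rep(FALSE, n)
    near[S4Vectors::queryHits(hit)] <-
      S4Vectors::mcols(hit)$distance < cfg$gap_bp
    fails$gap_proximity <- near
  }

  any_fail <- Reduce(`|`, fails)
  report <- data.frame(rule = names(fails),
                       removed = vapply(fails, sum, integer(1)),
                       skipped = names(fails) %in% skipped,
                       row.names = NULL)
  report <- rbind(report,
                  data.frame(rule = c("input_sites", "removed_total", "output_sites"),
                             removed = c(n, sum(any_fail), n - sum(any_fail)),
                             skipped = FALSE))
  out <- x[!any_fail, ]
  if (nrow(out) == 0L) warning("all sites removed by filters")
  if (!is.null(dpv) && is.null(metadata(out)$depth_bounds))
    metadata(out)$depth_bounds <- bounds
  list(genotypes = out, report = report)
}
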