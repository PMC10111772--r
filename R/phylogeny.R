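#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via \pkg{ape}, with two post-processing
#' steps customary for SNP distance trees: negative branch lengths are
#' clamped to zero with the deficit moved onto the adjacent (sibling)
#' edge so path lengths are preserved where possible, and the tree is
#' rooted on the outgroup for display when one is given.
#'
#' @param dm symmetric distance matrix (see [ibsMatrix()],
#'   [pDistanceMatrix()]); missing entries are an error naming the pairs.
#' @param outgroup optional tip name to root on.
#' @return an \pkg{ape} \code{phylo} tree.
#' @export
njTree <- function(dm, outgroup = NULL) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 samples for NJ")
  if (any(is.na(dm))) {
    bad <- which(is.na(dm), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("missing distances for pairs: ",
         paste(rownames(dm)[bad[, 1]], colnames(dm)[bad[, 2]],
               sep = "-", collapse = ", "))
  }
  tr <- ape::nj(stats::as.dist(dm))
  tr <- .clamp_negative_edges(tr)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label)
      stop("outgroup '", outgroup, "' not among tips")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

# move each negative branch's deficit to its sibling edge, then clamp
.clamp_negative_edges <- function(tr) {
  el <- tr$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs))
      el[sibs] <- el[sibs] + el[e] / length(sibs)
    el[e] <- 0
  }
  tr$edge.length <- pmax(el, 0)
  tr
}

#' Bootstrap support for the NJ tree
#'
#' Resamples sites with replacement, rebuilds the distance matrix and NJ
#' tree per replicate, and reports for each internal edge of the
#' reference tree the fraction of replicates containing the same
#' bipartition (via \code{ape::prop.clades}). A block bootstrap (blocks
#' of consecutive sites) is available for robustness to linkage.
#'
#' @param x a [GenotypeMatrix-class].
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed; identical seeds give identical supports.
#' @param outgroup optional tip to root on (also used per replicate).
#' @param distance \code{"p"} for p-distance (default; IBS distance is
#'   identical for biallelic dosages).
#' @param block_size resample blocks of this many consecutive sites
#'   instead of single sites (1 = ordinary bootstrap).
#' @return list: \code{tree} (reference NJ \code{phylo} with
#'   \code{node.label} holding support fractions) and \code{support}
#'   (numeric vector per internal node).
#' @export
bootstrapSupport <- function(x, n_reps = 100L, seed = 1L, outgroup = NULL,
                             distance = "p", block_size = 1L) {
  set.seed(seed)
  dm <- pDistanceMatrix(x)
  ref <- njTree(dm, outgroup = outgroup)
  n_sites <- nrow(x)
  idx_blocks <- split(seq_len(n_sites),
                      ceiling(seq_len(n_sites) / block_size))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    bl <- sample.int(length(idx_blocks), length(idx_blocks), replace = TRUE)
    idx <- unlist(idx_blocks[bl], use.names = FALSE)
    reps[[r]] <- njTree(pDistanceMatrix(x[idx, ]), outgroup = outgroup)
  }
  counts <- ape::prop.clades(ref, reps, rooted = !is.null(outgroup))
  counts[is.na(counts)] <- 0
  support <- counts / n_reps
  ref$node.label <- support
  list(tree = ref, support = support)
}

#' Write a tree in Newick format
#' @param tree a \code{phylo} object (support values in node labels kept).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
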