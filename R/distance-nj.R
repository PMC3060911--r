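#' Corrected pairwise distances from an alignment
#'
#' Computes the p-distance of every row pair over the columns where both rows
#' are ungapped, then applies a multiple-hit correction: Poisson
#' `d = -ln(1 - p)` for proteins or Jukes-Cantor
#' `d = -(3/4) ln(1 - 4p/3)` for nucleotides.  A p-distance at or beyond the
#' correction's singularity (1 and 3/4 respectively) is capped at `d_max`.
#'
#' @param aln a [ref_alignment()] or character matrix with at least 3 rows.
#' @param correction `"poisson"` or `"jc_nucleotide"`.
#' @param d_max cap applied at the singularity (default 5.0
#'   substitutions/site).
#' @param on_undefined what to do when a pair shares no ungapped column:
#'   `"error"` (default) or `"d_max"` (used by bootstrap resampling, where a
#'   replicate may drop all shared columns of a sparse pair).
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, correction = c("poisson", "jc_nucleotide"),
                            d_max = 5.0,
                            on_undefined = c("error", "d_max")) {
  correction <- match.arg(correction)
  on_undefined <- match.arg(on_undefined)
  mat <- if (inherits(aln, "ref_alignment")) aln$mat else aln
  n <- nrow(mat)
  if (is.null(n) || n < 3L) stop("distance_matrix needs at least 3 rows")
  ids <- rownames(mat)
  ok <- !(mat == "-" | mat == ".")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sing <- if (correction == "poisson") 1 else 0.75
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- ok[i, ] & ok[j, ]
      ns <- sum(shared)
      if (ns == 0L) {
        if (on_undefined == "error")
          stop("undefined distance: no shared ungapped columns for pair ",
               ids[i], " / ", ids[j])
        d <- d_max
      } else {
        p <- sum(mat[i, shared] != mat[j, shared]) / ns
        d <- if (p >= sing) d_max
             else if (correction == "poisson") -log(1 - p)
             else -0.75 * log(1 - 4 * p / 3)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-criterion join selection with the usual
#' branch-length updates), with negative estimated branch lengths clamped to
#' zero.  On an additive matrix the generating topology is recovered exactly,
#' which is this module's primary correctness oracle.
#'
#' @param D square symmetric distance matrix with zero diagonal and at least
#'   3 rows; dimnames become the tip labels.
#' @return an unrooted `phylo`.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || nrow(D) < 3L)
    stop("nj_tree needs a square matrix over at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  phy <- ape::nj(D)
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times; the support of each internal edge is the
#' percentage of replicate trees containing its bipartition, attached to the
#' tree's node labels as integers in `[0, 100]`.
#'
#' @param aln a [ref_alignment()].
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed integer seed for the column resampling.
#' @param correction distance correction, see [distance_matrix()].
#' @param on_undefined handling of pairs without shared ungapped columns,
#'   see [distance_matrix()]; resampled replicates always use `"d_max"`.
#' @return the full-data `phylo` with `node.label` carrying supports.
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, seed = 1L,
                              correction = c("poisson", "jc_nucleotide"),
                              on_undefined = c("error", "d_max")) {
  correction <- match.arg(correction)
  on_undefined <- match.arg(on_undefined)
  mat <- aln$mat
  full <- nj_tree(distance_matrix(mat, correction,
                                  on_undefined = on_undefined))
  bip <- tree_bipartitions(full)
  counts <- setNames(rep(0L, nrow(bip)), bip$key)
  nc <- ncol(mat)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(nc, nc, replace = TRUE)
      Dr <- distance_matrix(mat[, cols, drop = FALSE], correction,
                            on_undefined = "d_max")
      kr <- tree_bipartitions(nj_tree(Dr))$key
      hit <- bip$key %in% kr
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- as.integer(round(100 * counts / n_replicates))
  labels <- rep(NA_character_, full$Nnode)
  ntip <- length(full$tip.label)
  labels[bip$node - ntip] <- as.character(support)
  full$node.label <- labels
  full
}
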