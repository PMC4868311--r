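## Greedy RMSD-threshold clustering.  Both Rosetta-style fragment clustering
## (bulged vs non-bulged torso separation at 2 A) and Calibur-style decoy
## clustering reduce to the same center-based greedy algorithm: repeatedly
## promote the item with the most neighbors within the radius to cluster
## representative, remove it and its neighbors, and iterate.

#' Greedy RMSD-threshold clustering of coordinate sets
#'
#' @param items Named (or unnamed) list of n x 3 coordinate matrices, all
#'   with the same number of points.
#' @param radius Cluster radius in Angstrom (> 0); neighbors are items with
#'   superposition RMSD <= radius of the representative.
#' @return List of clusters, each a list with `representative` (item id),
#'   `members` (ids, representative included), `size`, and `avg_rmsd`
#'   (mean RMSD of members to the representative).  Clusters are ordered by
#'   decreasing size; ties in neighbor count are broken by input order.
#' @export
greedy_cluster <- function(items, radius) {
  stopifnot(radius > 0)
  n <- length(items)
  if (n == 0L) return(list())
  ids <- names(items)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  npts <- vapply(items, nrow, integer(1))
  if (length(unique(npts)) != 1L)
    stop("all coordinate sets must have the same number of points",
         call. = FALSE)

  # full pairwise superposition-RMSD matrix
  dm <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dm[i, j] <- dm[j, i] <- superpose_rmsd(items[[i]], items[[j]])
      }
    }
  }

  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(dm[i, remaining] <= radius), integer(1))
    center <- remaining[which.max(counts)]  # ties -> lowest input index
    members <- remaining[dm[center, remaining] <= radius]
    clusters[[length(clusters) + 1L]] <- list(
      representative = ids[center],
      members = ids[members],
      size = length(members),
      avg_rmsd = mean(dm[center, members]))
    remaining <- setdiff(remaining, members)
  }
  clusters[order(vapply(clusters, `[[`, integer(1), "size"),
                 decreasing = TRUE)]
}

#' Cluster decoy models with a minimum-size filter
#'
#' Calibur-style clustering of decoy loop conformations: the greedy
#' algorithm of [greedy_cluster()] on loop C-alpha coordinates, followed by
#' removal of clusters holding less than `min_fraction` of the models.
#' The boundary is inclusive: a cluster of size exactly
#' `ceiling(min_fraction * N)` survives (for 1000 models at 1 percent,
#' clusters of 10 or more are kept).
#'
#' @param models Named list of n x 3 C-alpha coordinate matrices.
#' @param threshold Cluster radius in Angstrom.
#' @param min_fraction Minimum surviving cluster size as a fraction of the
#'   total model count, in [0, 1); default 0.01.
#' @return List of surviving clusters as in [greedy_cluster()]; empty list
#'   when no cluster survives (reported downstream as "N/A").
#' @export
cluster_decoys <- function(models, threshold = 2.0, min_fraction = 0.01) {
  stopifnot(min_fraction >= 0, min_fraction < 1)
  clusters <- greedy_cluster(models, radius = threshold)
  floor_size <- max(1L, ceiling(min_fraction * length(models)))
  Filter(function(cl) cl$size >= floor_size, clusters)
}
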