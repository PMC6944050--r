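#' Agglomerative clustering on a distance matrix
#'
#' Hierarchical clustering of sequence-sets from their pairwise distance
#' matrix, cut at `k` clusters. Average linkage is the default for a
#' precomputed metric; complete and single linkage are available.
#' Clusters are renumbered in order of first appearance of their members
#' so the assignment is deterministic.
#'
#' @param D Labeled square symmetric distance matrix
#'   (see [pairwise_distances()]).
#' @param k Number of clusters, 1 <= k <= nrow(D).
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (set ids), `cluster_of` (named integer vector, clusters 1..k), `k`,
#'   `linkage`, and the `hclust` tree as `tree`.
#' @export
hierarchical_cluster <- function(D, k, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  check_distance_matrix(D)
  n <- nrow(D)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) stop("k must be between 1 and ", n)
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  raw <- stats::cutree(tree, k = k)
  # renumber by first appearance in label order
  first <- unique(unname(raw))
  cl <- match(raw, first)
  names(cl) <- rownames(D)
  structure(list(labels = rownames(D), cluster_of = cl, k = k,
                 linkage = linkage, tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d set(s), k=%d, linkage=%s\n",
              length(x$labels), x$k, x$linkage))
  print(x$cluster_of)
  invisible(x)
}

#' Classical 2D projection of a distance matrix
#'
#' Classical (Torgerson) metric multidimensional scaling: the squared
#' distance matrix is double-centered, and the top two eigenpairs give
#' the coordinates (eigenvector times square root of eigenvalue).
#' Non-positive eigenvalues yield a zero axis. Orientation is fixed by
#' making the first nonzero coordinate of each axis positive, so the
#' embedding is reproducible. When the distances are exactly
#' 2-embeddable the pairwise Euclidean distances of the coordinates
#' reproduce `D`.
#'
#' @param D Labeled square symmetric distance matrix with >= 2 sets.
#' @return Numeric n x 2 matrix of coordinates, rownames = set ids.
#' @export
embed_2d <- function(D) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need >= 2 sets to embed")
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  coords <- matrix(0, n, 2L, dimnames = list(rownames(D), c("x", "y")))
  tol <- max(abs(e$values), 0) * 1e-12
  for (j in 1:2) {
    if (e$values[j] > tol) {
      v <- e$vectors[, j] * sqrt(e$values[j])
      nz <- which(v != 0)
      if (length(nz) > 0L && v[nz[1L]] < 0) v <- -v
      coords[, j] <- v
    }
  }
  coords
}

#' Dispersion map of each cluster
#'
#' The dispersion map pictures a cluster by its medoid (the member
#' minimizing total distance to co-members; ties go to the
#' lexicographically smallest id), every member's distance to that
#' medoid, the mean/max spread, and the members' 2D coordinates. A tight
#' map indicates a compact cluster; heavy tails suggest sub-clusters.
#'
#' @param D Labeled distance matrix.
#' @param assignment A [hierarchical_cluster()] result consistent with
#'   `D`.
#' @param coords Optional n x 2 coordinate matrix from [embed_2d()].
#' @param mode `"exact"` (distances from the observed sets) or
#'   `"limiting"` (tagged by [limiting_dispersion_map()]).
#' @return List of `dispersion_map` objects, one per cluster: `cluster`,
#'   `mode`, `medoid_id`, `member_distances` (named, to the medoid),
#'   `spread` (`mean`, `max`), `coords2d`.
#' @export
dispersion_map <- function(D, assignment, coords = NULL, mode = "exact") {
  check_distance_matrix(D)
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!setequal(assignment$labels, rownames(D))) {
    stop("assignment labels do not match the distance matrix")
  }
  lapply(seq_len(assignment$k), function(ci) {
    members <- sort(names(assignment$cluster_of)[assignment$cluster_of == ci])
    sub <- D[members, members, drop = FALSE]
    totals <- rowSums(sub)
    medoid <- members[which(totals == min(totals))][1L]  # members sorted: lexicographic tie-break
    md <- sub[, medoid]
    names(md) <- members
    structure(list(
      cluster = ci,
      mode = mode,
      medoid_id = medoid,
      member_distances = md,
      spread = list(mean = mean(md), max = max(md)),
      coords2d = if (!is.null(coords)) coords[members, , drop = FALSE]
    ), class = "dispersion_map")
  })
}

#' @export
print.dispersion_map <- function(x, ...) {
  cat(sprintf("<dispersion_map> cluster %d (%s): %d member(s), medoid '%s', spread mean=%g max=%g\n",
              x$cluster, x$mode, length(x$member_distances), x$medoid_id,
              x$spread$mean, x$spread$max))
  invisible(x)
}

#' Limiting dispersion map
#'
#' The limiting dispersion map of a clustering re-generates every
#' sequence-set from its estimated nucleotide composition at a length
#' factor `factor` (long sequences push each set's empirical composition
#' toward its limiting distribution), recomputes the distance matrix,
#' clustering, 2D embedding and dispersion maps on the regenerated data.
#' Comparing it with the exact map separates composition signal from
#' finite-length sampling noise.
#'
#' @param prototype_sets List of [seq_set()] objects (the observed data).
#' @param factor Length multiplier n' >= 1.
#' @param seed Integer seed for the regeneration.
#' @inheritParams cov_of_set
#' @param k,linkage Passed to [hierarchical_cluster()].
#' @return List with `maps` (dispersion maps, mode `"limiting"`),
#'   `assignment`, `coords`, `D`, `factor`, `seed`.
#' @export
limiting_dispersion_map <- function(prototype_sets, factor = 200, seed,
                                    words = one_grams(dna_alphabet()),
                                    phi = phi_identity(), centered = TRUE,
                                    k = 2L, linkage = "average") {
  stopifnot(is.list(prototype_sets), length(prototype_sets) >= 2L, factor >= 1)
  regen <- lapply(seq_along(prototype_sets), function(i) {
    prof <- estimate_composition(prototype_sets[[i]])
    generate_seq_set(prof, factor = factor, seed = seed, replicate = i,
                     set_id = prototype_sets[[i]]$set_id)
  })
  structs <- lapply(regen, cov_of_set, words = words, phi = phi,
                    centered = centered)
  D <- pairwise_distances(structs)
  assignment <- hierarchical_cluster(D, k = k, linkage = linkage)
  coords <- embed_2d(D)
  maps <- dispersion_map(D, assignment, coords, mode = "limiting")
  list(maps = maps, assignment = assignment, coords = coords, D = D,
       factor = factor, seed = as.integer(seed))
}
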