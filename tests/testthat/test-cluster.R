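dm <- function(values, labels) {
  matrix(values, length(labels), dimnames = list(labels, labels))
}

test_that("hierarchical clustering recovers obvious structure", {
  D2 <- dm(c(0, 2, 2, 0), c("a", "b"))
  a2 <- hierarchical_cluster(D2, k = 2)
  expect_equal(unname(a2$cluster_of), c(1L, 2L))

  D3 <- dm(c(0, 1, 10, 1, 0, 10, 10, 10, 0), c("a", "b", "c"))
  for (linkage in c("average", "complete", "single")) {
    a3 <- hierarchical_cluster(D3, k = 2, linkage = linkage)
    expect_equal(a3$cluster_of[["a"]], a3$cluster_of[["b"]])
    expect_false(a3$cluster_of[["a"]] == a3$cluster_of[["c"]])
  }

  a1 <- hierarchical_cluster(D3, k = 1)
  expect_equal(unname(a1$cluster_of), c(1L, 1L, 1L))
  expect_error(hierarchical_cluster(D3, k = 4), "between 1 and 3")
})

test_that("cluster assignment is invariant to label permutation", {
  set.seed(31)
  n <- 8
  pts <- c(rnorm(4, 0), rnorm(4, 10))
  D <- abs(outer(pts, pts, "-"))
  diag(D) <- 0
  labs <- paste0("s", 1:n)
  dimnames(D) <- list(labs, labs)
  a <- hierarchical_cluster(D, k = 2)
  perm <- sample(n)
  Dp <- D[perm, perm]
  ap <- hierarchical_cluster(Dp, k = 2)
  # same partition up to relabeling
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same <- a$cluster_of[[labs[i]]] == a$cluster_of[[labs[j]]]
    same_p <- ap$cluster_of[[labs[i]]] == ap$cluster_of[[labs[j]]]
    expect_equal(same, same_p)
  }
})

test_that("2D embedding reproduces embeddable distances", {
  D2 <- dm(c(0, 2, 2, 0), c("a", "b"))
  co <- embed_2d(D2)
  expect_equal(dim(co), c(2L, 2L))
  expect_equal(sqrt(sum((co[1, ] - co[2, ])^2)), 2, tolerance = 1e-9)
  expect_equal(co[, 2], c(a = 0, b = 0))

  zero <- dm(rep(0, 9), c("a", "b", "c"))
  expect_equal(unname(embed_2d(zero)), matrix(0, 3, 2))

  eq <- dm(c(0, 1, 1, 1, 0, 1, 1, 1, 0), c("a", "b", "c"))
  ce <- embed_2d(eq)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sqrt(sum((ce[i, ] - ce[j, ])^2)), 1, tolerance = 1e-9)
  }

  expect_error(embed_2d(dm(0, "a")), ">= 2")
})

test_that("2D embedding agrees with cmdscale up to axis sign", {
  set.seed(77)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(stats::dist(pts))
  labs <- paste0("s", 1:6)
  dimnames(D) <- list(labs, labs)
  co <- embed_2d(D)
  ref <- stats::cmdscale(D, k = 2)
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(co[, j], unname(ref[, j]), tolerance = 1e-8,
                                 check.attributes = FALSE)) ||
                isTRUE(all.equal(co[, j], unname(-ref[, j]), tolerance = 1e-8,
                                 check.attributes = FALSE)))
  }
  # distances reproduced
  expect_equal(unname(as.matrix(stats::dist(co))), unname(D), tolerance = 1e-9)
})

test_that("dispersion maps report medoid, spreads and coordinates", {
  D <- dm(c(0, 1, 1, 1, 0, 2, 1, 2, 0), c("a", "b", "c"))
  a1 <- hierarchical_cluster(D, k = 1)
  maps <- dispersion_map(D, a1, embed_2d(D))
  expect_length(maps, 1L)
  m <- maps[[1]]
  expect_equal(m$medoid_id, "a")          # row sums 2, 3, 3
  expect_equal(m$member_distances[["a"]], 0)
  expect_equal(m$spread$max, 1)
  expect_equal(m$spread$max, max(m$member_distances))
  expect_lte(m$spread$max, max(D))
  expect_equal(rownames(m$coords2d), sort(c("a", "b", "c")))

  # identical structures: zero spread
  z <- dm(rep(0, 4), c("a", "b"))
  mz <- dispersion_map(z, hierarchical_cluster(z, k = 1))[[1]]
  expect_equal(mz$spread$mean, 0)
  expect_equal(mz$spread$max, 0)

  # singleton cluster
  a2 <- hierarchical_cluster(D, k = 3)
  maps3 <- dispersion_map(D, a2)
  expect_true(all(vapply(maps3, function(m) m$spread$max == 0, logical(1))))
})

test_that("limiting dispersion maps separate distinct composition groups", {
  # prototypes: sequences long enough (2 kb) that the estimated compositions
  # reflect the group signal rather than counting noise
  protoA <- lapply(1:3, function(i) {
    generate_seq_set(synthetic_profile(c(0.4, 0.3, 0.2, 0.1), n_seq = 4,
                                       base_length = 2000,
                                       set_id = paste0("A", i)),
                     factor = 1, seed = 100 + i, set_id = paste0("A", i))
  })
  protoB <- lapply(1:3, function(i) {
    generate_seq_set(synthetic_profile(c(0.1, 0.2, 0.3, 0.4), n_seq = 4,
                                       base_length = 2000,
                                       set_id = paste0("B", i)),
                     factor = 1, seed = 200 + i, set_id = paste0("B", i))
  })
  sets <- c(protoA, protoB)
  lim <- limiting_dispersion_map(sets, factor = 100, seed = 42, k = 2)
  expect_equal(lim$factor, 100)
  expect_equal(lim$seed, 42L)
  expect_true(all(vapply(lim$maps, function(m) m$mode == "limiting",
                         logical(1))))
  cl <- lim$assignment$cluster_of
  expect_equal(length(unique(cl[paste0("A", 1:3)])), 1L)
  expect_equal(length(unique(cl[paste0("B", 1:3)])), 1L)
  expect_false(cl[["A1"]] == cl[["B1"]])

  # determinism under the same seed
  lim2 <- limiting_dispersion_map(sets, factor = 100, seed = 42, k = 2)
  expect_identical(lim$D, lim2$D)

  # longer regenerated sequences tighten clusters relative to their separation
  lim1 <- limiting_dispersion_map(sets, factor = 1, seed = 42, k = 2)
  rel_spread <- function(res) {
    meds <- vapply(res$maps, `[[`, character(1), "medoid_id")
    between <- res$D[meds[1], meds[2]]
    mean(vapply(res$maps, function(m) m$spread$mean, numeric(1))) / between
  }
  expect_lt(rel_spread(lim), rel_spread(lim1))
})
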