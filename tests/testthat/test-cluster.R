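test_that("complete and empty neighbour graphs give the trivial partitions", {
  d3 <- random_point_matrix(3) * 0   # all mutually identical
  cl <- daura_cluster(d3 + as.matrix(dist(cbind(c(0, 0.1, 0.2), 0, 0))),
                      cutoff = 1)
  expect_length(cl$clusters, 1)
  expect_identical(cl$clusters[[1]]$center, 1L)   # tie broken by lowest index
  expect_identical(cl$clusters[[1]]$members, 1:3)

  far <- as.matrix(dist(cbind(c(0, 10, 20, 30), 0, 0)))
  cl4 <- daura_cluster(far, cutoff = 1)
  expect_length(cl4$clusters, 4)
  expect_true(all(vapply(cl4$clusters, function(x) length(x$members), 1L) == 1))
})

test_that("the 6-point line example partitions as derived", {
  p <- c(0, 1, 2, 10, 11, 30)
  mat <- abs(outer(p, p, `-`))
  cl <- daura_cluster(mat, cutoff = 1.5)
  oracle <- oracle_daura(mat, 1.5)
  expect_length(cl$clusters, 3)
  expect_identical(cl$clusters[[1]]$members, 1:3)     # positions 0,1,2
  expect_identical(cl$clusters[[1]]$center, 2L)       # position 1
  expect_identical(cl$clusters[[2]]$members, 4:5)     # positions 10,11
  expect_identical(cl$clusters[[2]]$center, 4L)       # tie -> lowest index
  expect_identical(cl$clusters[[3]]$members, 6L)
  for (k in 1:3) {
    expect_identical(cl$clusters[[k]]$center, oracle[[k]]$center)
    expect_identical(cl$clusters[[k]]$members, oracle[[k]]$members)
  }
})

test_that("clustering matches the literal step-by-step oracle on random inputs", {
  set.seed(808)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    mat <- random_point_matrix(n)
    cutoff <- runif(1, 0.05, 0.9)
    got <- daura_cluster(mat, cutoff)$clusters
    want <- oracle_daura(mat, cutoff)
    expect_identical(length(got), length(want))
    for (k in seq_along(got)) {
      expect_identical(got[[k]]$center, want[[k]]$center)
      expect_identical(got[[k]]$members, want[[k]]$members)
    }
    # partition property
    members <- sort(unlist(lapply(got, `[[`, "members")))
    expect_identical(members, seq_len(n))
  }
})

test_that("clustering is deterministic and validates its input", {
  set.seed(11)
  mat <- random_point_matrix(12)
  a <- daura_cluster(mat, 0.3)
  b <- daura_cluster(mat, 0.3)
  expect_identical(a, b)
  bad <- mat; bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(daura_cluster(bad, 0.3), "not symmetric")
  expect_error(daura_cluster(-mat, 0.3), "negative")
  expect_error(daura_cluster(mat, 0), "positive")
})

test_that("cluster composition uses per-system denominators and sums to one", {
  p <- c(0, 0.01, 0.02, 5, 5.01)
  mat <- abs(outer(p, p, `-`))
  cl <- daura_cluster(mat, cutoff = 0.1)
  labels <- c("a", "a", "b", "a", "b")
  comp <- cluster_composition(cl, labels)
  for (s in c("a", "b"))
    expect_equal(sum(comp$fraction[comp$system == s]), 1, tolerance = 1e-12)
  # cluster 1 = {1,2,3}: holds 2/3 of system a and 1/2 of system b
  expect_equal(comp$fraction[comp$cluster == 1 & comp$system == "a"], 2 / 3)
  expect_equal(comp$fraction[comp$cluster == 1 & comp$system == "b"], 1 / 2)
  expect_error(cluster_composition(cl, labels[-1]), "labels length")

  one <- daura_cluster(matrix(0, 3, 3) + mat[1:3, 1:3], cutoff = 1)
  comp1 <- cluster_composition(one, c("a", "a", "b"))
  expect_equal(comp1$fraction, c(1, 1))
})

test_that("cut-off sweep counts are non-increasing and consistent with direct runs", {
  set.seed(909)
  for (rep in 1:5) {
    mat <- random_point_matrix(20)
    cutoffs <- sort(runif(6, 0.05, 1.2))
    sw <- cutoff_sweep(mat, cutoffs)
    expect_true(all(diff(sw$n_clusters) <= 0))
    for (i in seq_along(cutoffs))
      expect_identical(sw$n_clusters[i],
                       length(daura_cluster(mat, cutoffs[i])$clusters))
  }
  mat <- random_point_matrix(10)
  expect_identical(cutoff_sweep(mat, max(mat) + 1)$n_clusters, 1L)
  tiny <- min(mat[mat > 0]) / 2
  expect_identical(cutoff_sweep(mat, tiny)$n_clusters, 10L)
})

test_that("prefix clustering tracks when a second state first appears", {
  geo <- loop_system_geometry(c(0, 150))
  # deterministic two-state trajectory: state 2 only after half-time
  nfr <- 20
  frames <- lapply(seq_len(nfr), function(f)
    geo$states[[if (f <= nfr / 2) 1 else 2]])
  tr <- traj_from_frames(frames, top = geo$topology)
  inc <- incremental_cluster_count(tr, geo$flank_sel, geo$loop_sel,
                                   cutoff = 0.2, window = 40)
  early <- inc$n_clusters[inc$prefix_ps <= 90]
  late <- inc$n_clusters[inc$prefix_ps > 100]
  expect_true(all(early == 1))
  expect_true(all(late == 2))
  # final prefix reproduces the full-trajectory clustering
  M <- pairwise_rmsd_matrix(tr, geo$flank_sel, geo$loop_sel)
  expect_identical(inc$n_clusters[nrow(inc)],
                   length(daura_cluster(M, 0.2)$clusters))

  static <- traj_from_frames(rep(list(geo$states[[1]]), 10),
                             top = geo$topology)
  inc0 <- incremental_cluster_count(static, geo$flank_sel, geo$loop_sel,
                                    cutoff = 0.2, window = 30)
  expect_true(all(inc0$n_clusters == 1))
})
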