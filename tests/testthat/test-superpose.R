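rotz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)

test_that("kabsch_fit recovers identity and exact rigid motions", {
  set.seed(101)
  X <- matrix(rnorm(15), 5, 3)
  fit <- kabsch_fit(X, X)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$fit_rmsd, 0, tolerance = 1e-12)

  Y <- sweep(X %*% t(rotz90), 2, c(1, 2, 3), `+`)   # 90 deg about z + shift
  fit2 <- kabsch_fit(X, Y)
  expect_lt(fit2$fit_rmsd, 1e-12)
  expect_equal(fit2$rotation, rotz90, tolerance = 1e-9)
  expect_equal(apply_fit(X, fit2), Y, tolerance = 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch_fit refuses degenerate fit selections", {
  X <- matrix(rnorm(9), 3, 3)
  expect_error(kabsch_fit(X, X, fit_sel = 1:2), "at least 3 atoms")
  line <- cbind(0:3, 0, 0)
  expect_error(kabsch_fit(line, line + 0.1), "collinear")
})

test_that("kabsch_fit matches a brute-force rotation-grid search", {
  set.seed(202)
  grid <- random_rotation_grid(20000)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(3 * n), n, 3)
    Y <- matrix(rnorm(3 * n), n, 3)
    fit <- kabsch_fit(X, Y)
    oracle <- oracle_grid_min_rmsd(X, Y, grid)
    expect_lte(fit$fit_rmsd, oracle + 1e-9)   # exact optimum beats any grid
  }
})

test_that("rmsd reproduces the hand-computed displaced-atom value", {
  # flanking atoms identical in both frames -> fit is the identity;
  # 2-atom measure set with one atom displaced 0.3 nm:
  # sqrt((0.3^2 + 0) / 2) = 0.2121320...
  anchors <- anchor_coords()
  ref <- rbind(anchors, c(2, 2, 2), c(3, 3, 3))
  mob <- ref
  mob[6, 1] <- mob[6, 1] + 0.3
  value <- rmsd(mob, ref, fit_sel = 1:4, measure_sel = 5:6)
  expect_equal(value, sqrt(0.09 / 2), tolerance = 1e-9)
  expect_equal(value, 0.2121320, tolerance = 1e-6)
  expect_equal(rmsd(ref, ref, 1:4, 5:6), 0, tolerance = 1e-12)
  expect_error(rmsd(mob, ref, 1:4, integer(0)), "empty")
})

test_that("rmsd is symmetric and invariant under rigid motion of the mobile frame", {
  set.seed(303)
  for (rep in 1:10) {
    a <- matrix(rnorm(18), 6, 3)
    b <- matrix(rnorm(18), 6, 3)
    s <- 1:6
    expect_equal(rmsd(a, b, s, s), rmsd(b, a, s, s), tolerance = 1e-9)
    # rigid motion of the mobile frame changes nothing when fit = measure
    u <- rnorm(3); u <- u / sqrt(sum(u^2)); th <- runif(1, 0, pi)
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    a_moved <- sweep(a %*% t(R), 2, runif(3, -5, 5), `+`)
    expect_equal(rmsd(a_moved, b, s, s), rmsd(a, b, s, s), tolerance = 1e-9)
    expect_lt(rmsd(a_moved, a, s, s), 1e-9)
  }
})

test_that("rmsf is zero for static input and d for a symmetric oscillator", {
  anchors <- anchor_coords()
  static <- lapply(1:10, function(i) rbind(anchors, c(0.5, 0.5, 0.5)))
  expect_true(all(rmsf(traj_from_frames(static), 1:4, 1:5)$rmsf_nm < 1e-12))

  d <- 0.25
  osc <- lapply(1:10, function(i) {
    fr <- rbind(anchors, c(0.5, 0.5, 0.5))
    fr[5, 1] <- fr[5, 1] + d * (-1)^i
    fr
  })
  r <- rmsf(traj_from_frames(osc), 1:4, 1:5)
  expect_equal(r$rmsf_nm[5], d, tolerance = 1e-9)
  expect_true(all(r$rmsf_nm[1:4] < 1e-12))

  expect_error(rmsf(traj_from_frames(static[1]), 1:4, 1:5), "at least 2 frames")
})

test_that("rmsf of a Gaussian free atom matches the direct formula and sigma*sqrt(3)", {
  set.seed(404)
  sigma <- 0.05
  nfr <- 2000
  anchors <- anchor_coords()
  noise <- matrix(rnorm(nfr * 3, sd = sigma), nfr, 3)
  frames <- lapply(seq_len(nfr), function(i)
    rbind(anchors, c(0.5, 0.5, 0.5) + noise[i, ]))
  r <- rmsf(traj_from_frames(frames), fit_sel = 1:4, measure_sel = 5)
  # anchors are static so the fit is the identity: the direct evaluation of
  # the fluctuation formula on the raw free-atom track is the oracle
  devs <- sweep(noise, 2, colMeans(noise))
  oracle <- sqrt(mean(rowSums(devs^2)))
  expect_equal(r$rmsf_nm, oracle, tolerance = 1e-9)
  expect_equal(r$rmsf_nm, sigma * sqrt(3), tolerance = 0.05)
})

test_that("rmsf scales linearly with the coordinates", {
  set.seed(505)
  frames <- lapply(1:20, function(i)
    rbind(anchor_coords(), matrix(rnorm(6, sd = 0.1), 2, 3) + 0.5))
  r1 <- rmsf(traj_from_frames(frames), 1:4, 1:6)
  r3 <- rmsf(traj_from_frames(lapply(frames, `*`, 3)), 1:4, 1:6)
  expect_equal(r3$rmsf_nm, 3 * r1$rmsf_nm, tolerance = 1e-9)
  expect_true(all(r1$rmsf_nm >= 0))
})

test_that("rmsf supports mean-structure fitting as an alternative reference", {
  set.seed(606)
  frames <- lapply(1:15, function(i)
    rbind(anchor_coords() + matrix(rnorm(12, sd = 0.01), 4, 3),
          c(0.5, 0.5, 0.5) + rnorm(3, sd = 0.05)))
  tr <- traj_from_frames(frames)
  r_first <- rmsf(tr, 1:4, 1:5, reference = "first")
  r_mean <- rmsf(tr, 1:4, 1:5, reference = "mean")
  expect_true(all(r_mean$rmsf_nm >= 0))
  # both references agree on the scale of the free atom's fluctuation
  expect_equal(r_mean$rmsf_nm[5], r_first$rmsf_nm[5], tolerance = 0.1)
})

test_that("pairwise matrix entries equal independent direct rmsd calls", {
  set.seed(707)
  geo <- loop_system_geometry(c(0, 60, 180))
  sim <- generate_loop_ensemble(
    state_plan(geo, c(0.4, 0.3, 0.3), 8, seed = 9,
               rigid_motion = list(max_angle_deg = 10, max_shift_nm = 0.2)))
  tr <- sim$trajectory
  M <- pairwise_rmsd_matrix(tr, geo$flank_sel, geo$loop_sel)
  expect_equal(max(abs(M - t(M))), 0)
  expect_true(all(diag(M) == 0))
  for (i in 1:8) for (j in 1:8) {
    if (i == j) next
    direct <- rmsd(get_frame(tr, j), get_frame(tr, i),
                   geo$flank_sel, geo$loop_sel)
    expect_equal(M[i, j], direct, tolerance = 1e-9)
  }
  # third frame a rigid motion of the first: fit = measure gives zero
  fr <- lapply(1:3, function(i) matrix(rnorm(24), 8, 3))
  fr[[3]] <- sweep(fr[[1]] %*% t(rotz90), 2, c(1, 0, 2), `+`)
  M2 <- pairwise_rmsd_matrix(traj_from_frames(fr), 1:8, 1:8)
  expect_lt(M2[1, 3], 1e-9)
})
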