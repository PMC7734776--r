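# three-atom donor/hydrogen/acceptor geometry with controllable distance and
# hydrogen tilt off the donor->acceptor axis
dha_frame <- function(d_da, tilt_deg) {
  th <- tilt_deg * pi / 180
  rbind(c(0, 0, 0),                       # donor
        0.1 * c(cos(th), sin(th), 0),     # hydrogen
        c(d_da, 0, 0))                    # acceptor
}

dha_top <- topology(
  data.frame(name = c("N", "H", "O"), resnum = c(1L, 1L, 2L),
             resname = c("GLY", "GLY", "SER"),
             role = c("donor", "hydrogen", "acceptor")),
  bonds = data.frame(donor = 1L, hydrogen = 2L))

test_that("hydrogen-bond criteria accept ideal and reject broken geometries", {
  hb <- find_hbonds(dha_frame(0.30, 0), dha_top, groupA = 1:2, groupB = 3)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 0.30, tolerance = 1e-12)
  expect_equal(hb$angle, 0, tolerance = 1e-9)

  expect_equal(nrow(find_hbonds(dha_frame(0.40, 0), dha_top, 1:2, 3)), 0)
  expect_equal(nrow(find_hbonds(dha_frame(0.30, 45), dha_top, 1:2, 3)), 0)
  expect_equal(nrow(find_hbonds(dha_frame(0.30, 29.9), dha_top, 1:2, 3)), 1)

  # alternative near-linear donor-hydrogen-acceptor convention
  expect_equal(nrow(find_hbonds(dha_frame(0.30, 0), dha_top, 1:2, 3,
                                angle_convention = "DHA")), 1)
  expect_equal(nrow(find_hbonds(dha_frame(0.30, 45), dha_top, 1:2, 3,
                                angle_convention = "DHA")), 0)
})

test_that("hydrogen-bond detection matches the brute-force oracle and is group-symmetric", {
  set.seed(2024)
  for (rep in 1:30) {
    cfg <- random_hbond_config()
    got <- find_hbonds(cfg$frame, cfg$top, cfg$gA, cfg$gB)
    want <- oracle_hbonds(cfg$frame, cfg$top, cfg$gA, cfg$gB)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_identical(got$donor, as.integer(want[, 1]))
      expect_identical(got$hydrogen, as.integer(want[, 2]))
      expect_identical(got$acceptor, as.integer(want[, 3]))
    }
    swapped <- find_hbonds(cfg$frame, cfg$top, cfg$gB, cfg$gA)
    expect_identical(got, swapped)
  }
})

test_that("per-frame counts follow the trajectory and histograms conserve frames", {
  fr_on <- dha_frame(0.30, 0); fr_off <- dha_frame(0.45, 0)
  tr <- traj_from_frames(list(fr_on, fr_off, fr_on, fr_on), top = dha_top)
  series <- hbond_count_series(tr, 1:2, 3)
  expect_identical(series, c(1L, 0L, 1L, 1L))
  h <- hbond_histogram(series)
  expect_identical(h$n_frames, c(1L, 3L))
  expect_identical(sum(h$n_frames), 4L)
  expect_identical(hbond_histogram(c(0L, 0L, 4L, 4L, 4L))$n_frames,
                   c(2L, 0L, 0L, 0L, 3L))
  expect_error(hbond_histogram(integer(0)), "empty")
})

test_that("Coulomb and Lennard-Jones pair energies match closed forms", {
  dim1 <- generate_charged_dimer(1.0)
  e <- pairwise_nonbonded_energy(get_frame(dim1$trajectory, 1),
                                 dim1$trajectory$topology, 1, 2)
  expect_equal(e$e_coulomb, 138.935458, tolerance = 1e-6)
  expect_equal(e$e_lj, 0)
  expect_equal(e$e_total, e$e_coulomb + e$e_lj, tolerance = 1e-9)

  # LJ zero crossing at r = (C12/C6)^(1/6)
  c6 <- 2.5e-3; c12 <- 2.5e-6
  r0 <- (c12 / c6)^(1 / 6)
  dim2 <- generate_charged_dimer(r0, charges = c(0, 0),
                                 c6 = c(c6, c6), c12 = c(c12, c12))
  e2 <- pairwise_nonbonded_energy(get_frame(dim2$trajectory, 1),
                                  dim2$trajectory$topology, 1, 2)
  expect_equal(e2$e_lj, 0, tolerance = 1e-9)
  expect_equal(e2$e_coulomb, 0)

  # beyond the short-range cut-off nothing contributes
  dim3 <- generate_charged_dimer(1.5)
  e3 <- pairwise_nonbonded_energy(get_frame(dim3$trajectory, 1),
                                  dim3$trajectory$topology, 1, 2, cutoff = 1.4)
  expect_equal(e3$e_total, 0)

  expect_error(pairwise_nonbonded_energy(get_frame(dim1$trajectory, 1),
                                         dim1$trajectory$topology, 1, 1),
               "overlap")
})

test_that("group energies match the brute-force double loop and its symmetries", {
  set.seed(3030)
  for (rep in 1:25) {
    cfg <- random_energy_config()
    got <- pairwise_nonbonded_energy(cfg$frame, cfg$top, cfg$gA, cfg$gB)
    want <- oracle_energy(cfg$frame, cfg$top, cfg$gA, cfg$gB)
    expect_equal(got$e_coulomb, want$e_coulomb, tolerance = 1e-9)
    expect_equal(got$e_lj, want$e_lj, tolerance = 1e-9)
    swap <- pairwise_nonbonded_energy(cfg$frame, cfg$top, cfg$gB, cfg$gA)
    expect_equal(swap$e_coulomb, got$e_coulomb, tolerance = 1e-12)
    expect_equal(swap$e_lj, got$e_lj, tolerance = 1e-12)
  }
  # scaling all charges by c scales E_Coul by c^2 and leaves E_LJ alone
  cfg <- random_energy_config()
  top2 <- cfg$top; top2$atoms$charge <- 3 * top2$atoms$charge
  e1 <- pairwise_nonbonded_energy(cfg$frame, cfg$top, cfg$gA, cfg$gB)
  e9 <- pairwise_nonbonded_energy(cfg$frame, top2, cfg$gA, cfg$gB)
  expect_equal(e9$e_coulomb, 9 * e1$e_coulomb, tolerance = 1e-9)
  expect_equal(e9$e_lj, e1$e_lj)
})

test_that("energy histograms use half-open bins anchored at zero and conserve counts", {
  h <- energy_histogram(c(-950, -905), bin_width = 100)
  expect_identical(nrow(h), 1L)
  expect_equal(h$bin_lo, -1000)
  expect_equal(h$bin_hi, -900)
  expect_identical(h$n_frames, 2L)
  # a value exactly on an edge belongs to the higher bin
  edge <- energy_histogram(c(-900), bin_width = 100)
  expect_equal(edge$bin_lo, -900)
  set.seed(4040)
  vals <- rnorm(5000, -800, 300)
  h2 <- energy_histogram(vals, 10)
  expect_identical(sum(h2$n_frames), 5000L)
  k <- floor(vals / 10)
  expect_identical(h2$n_frames,
                   as.integer(table(k)[as.character(sort(unique(k)))]))
  expect_error(energy_histogram(numeric(0), 10), "empty")
  expect_error(energy_histogram(1, -5), "positive")
})
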