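test_that("topology validates roles, LJ signs and hydrogen bonding", {
  at <- data.frame(name = c("N", "H", "O"), resnum = 1:3, resname = "GLY",
                   role = c("donor", "hydrogen", "acceptor"))
  expect_s3_class(topology(at, data.frame(donor = 1L, hydrogen = 2L)),
                  "topology")
  expect_error(topology(at), "without a bonded donor")
  at2 <- at; at2$role[2] <- "wild"
  expect_error(topology(at2), "unknown hbond role")
  at3 <- at; at3$c6 <- c(-1, 0, 0)
  expect_error(topology(at3, data.frame(donor = 1L, hydrogen = 2L)),
               "non-negative")
  expect_error(
    topology(at, data.frame(donor = c(1L, 3L), hydrogen = c(2L, 2L))),
    "more than one donor")
})

test_that("sidecar round trip preserves the atom table and bonds", {
  at <- data.frame(name = c("N", "H", "CA", "O"), resnum = c(5L, 5L, 5L, 6L),
                   resname = c("GLY", "GLY", "GLY", "SER"),
                   charge = c(-0.28, 0.28, 0, -0.5),
                   c6 = c(2.4e-3, 0, 6.1e-3, 2.3e-3),
                   c12 = c(1.7e-6, 0, 9.7e-6, 1.5e-6),
                   role = c("donor", "hydrogen", "none", "acceptor"))
  top <- topology(at, data.frame(donor = 1L, hydrogen = 2L))
  path <- withr::local_tempfile()
  write_topology_sidecar(top, path)
  top2 <- read_topology_sidecar(path)
  expect_equal(top2$atoms$charge, top$atoms$charge)
  expect_equal(top2$atoms$c6, top$atoms$c6)
  expect_equal(top2$atoms$c12, top$atoms$c12)
  expect_identical(top2$atoms$role, top$atoms$role)
  expect_identical(top2$bonds, top$bonds)
})

test_that("selection grammar resolves names, residue ranges and conjunctions", {
  at <- data.frame(name = rep(c("N", "CA", "C"), 10),
                   resnum = rep(25:34, each = 3), resname = "GLY")
  top <- topology(at)
  ca <- select_atoms(top, "name CA and resid 25-29")
  expect_length(ca, 5)
  expect_true(all(top$atoms$name[ca] == "CA"))
  expect_true(all(top$atoms$resnum[ca] %in% 25:29))
  loop <- select_atoms(top, "resid 27-29")
  expect_length(loop, 9)
  expect_identical(as.integer(loop), sort(as.integer(loop)))
  multi <- select_atoms(top, "name N,C and resid 25,30-31")
  expect_length(multi, 6)
  expect_error(select_atoms(top, "name ZZ"), "matches no atoms")
  expect_error(select_atoms(top, "chain A"), "unknown selection keyword")
})

test_that("multi-model PDB read/write round trip holds to PDB precision", {
  geo <- loop_system_geometry(c(0, 120))
  sim <- generate_loop_ensemble(state_plan(geo, c(0.5, 0.5), 4, seed = 11))
  traj <- sim$trajectory
  pdb <- withr::local_tempfile(fileext = ".pdb")
  sc <- withr::local_tempfile()
  write_multimodel_pdb(traj, pdb)
  write_topology_sidecar(traj$topology, sc)
  back <- read_multimodel_pdb(pdb, sc)
  expect_equal(n_frames(back), 4)
  expect_lt(max(abs(back$coords - traj$coords)), 1e-4)   # 1e-3 angstrom
  expect_identical(back$topology$atoms$name, traj$topology$atoms$name)
  expect_identical(sum(grepl("^MODEL", readLines(pdb))), 4L)
  # angstrom -> nm conversion: raw PDB columns are 10x the stored nm values
  ln <- readLines(pdb)
  first_atom <- ln[grepl("^ATOM", ln)][1]
  x_ang <- as.numeric(substr(first_atom, 31, 38))
  expect_lt(abs(x_ang - traj$coords[1, 1, 1] * 10), 1e-3)
  expect_error(write_multimodel_pdb(traj, pdb, sel = integer(0)), "empty")
})

test_that("model atom-count mismatch is reported by model number", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL", "END")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, pdb)
  sc <- withr::local_tempfile()
  write_topology_sidecar(dummy_top(2), sc)
  expect_error(read_multimodel_pdb(pdb, sc), "model 2")
  # sidecar shorter than the PDB names the first uncovered atom
  sc1 <- withr::local_tempfile()
  write_topology_sidecar(dummy_top(1), sc1)
  writeLines(lines[c(1:3, 4)], pdb)   # single 2-atom model
  expect_error(read_multimodel_pdb(pdb, sc1), "no sidecar entry for atom 2")
})

test_that("concatenation conserves frames, coordinates and labels", {
  geo <- loop_system_geometry(c(0, 90))
  a <- generate_loop_ensemble(state_plan(geo, c(1, 0), 3, seed = 1,
                                         system_label = "apo"))$trajectory
  b <- generate_loop_ensemble(state_plan(geo, c(0, 1), 2, seed = 2,
                                         system_label = "lig"))$trajectory
  ens <- concatenate_trajectories(list(apo = a, lig = b))
  expect_equal(n_frames(ens), 5)
  expect_identical(ens$system, c(rep("apo", 3), rep("lig", 2)))
  expect_identical(ens$coords[, , 1:3], a$coords)   # bit-exact
  expect_identical(ens$coords[, , 4:5], b$coords)

  single <- concatenate_trajectories(list(solo = a))
  expect_identical(single$coords, a$coords)
  expect_identical(single$system, rep("solo", 3))

  small <- subset_trajectory(b, 1:5)
  expect_error(concatenate_trajectories(list(apo = a, lig = small)),
               "atoms over the common selection")
  # a shared selection reconciles topologies that differ elsewhere
  common <- seq_len(10)
  both <- concatenate_trajectories(list(apo = a, lig = b), sel = common)
  expect_equal(n_atoms(both$topology), 10)
  expect_equal(n_frames(both), 5)
})
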