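#' Synthetic loop/scaffold geometry with planted conformational states
#'
#' Builds a minimal receptor-like system: two rigid flanking strands of
#' C-alpha atoms (the scaffold) joined by a flexible loop (N, CA, C per
#' residue) laid out on a semicircular arc between the two anchor atoms.
#' Each planted conformational state is the arc rotated about the hinge
#' axis through the anchors by a per-state angle — a single-dihedral
#' deformation that leaves the scaffold untouched and gives direct control
#' over inter-state loop RMSD (for an arc of radius `r` over `n` atoms the
#' RMSD between states separated by `dtheta` is about
#' `r * sqrt(2) * sin(dtheta / 2)`).
#'
#' @param state_angles_deg numeric vector of hinge angles, one per state;
#'   state 1 is conventionally 0.
#' @param loop_res residue numbers of the loop (default 57:63).
#' @param flank_res_n,flank_res_c residue numbers of the N- and C-side
#'   flanking strands (defaults 50:56 and 64:70).
#' @param ca_spacing C-alpha spacing along the strands in nm (default
#'   0.35, the extended-chain value).
#' @return list with `topology`, `states` (list of full `n_atoms x 3`
#'   templates in nm, one per angle), `loop_sel` and `flank_sel` (atom
#'   selections), `loop_query` and `flank_query` (the equivalent
#'   [select_atoms()] expressions).
#' @export
loop_system_geometry <- function(state_angles_deg,
                                 loop_res = 57:63,
                                 flank_res_n = 50:56, flank_res_c = 64:70,
                                 ca_spacing = 0.35) {
  stopifnot(length(state_angles_deg) >= 1L)
  nfn <- length(flank_res_n); nfc <- length(flank_res_c)
  nloop_atoms <- 3L * length(loop_res)

  atoms <- rbind(
    data.frame(name = "CA", resnum = flank_res_n, resname = "ALA"),
    data.frame(name = rep(c("N", "CA", "C"), length(loop_res)),
               resnum = rep(loop_res, each = 3L), resname = "GLY"),
    data.frame(name = "CA", resnum = flank_res_c, resname = "ALA"))
  top <- topology(atoms)

  # scaffold: two strands advancing along x with an irregular 3D transverse
  # modulation (a straight scaffold would leave the superposition
  # undetermined about the hinge axis, which no real protein scaffold does)
  xs_n <- (seq_len(nfn) - 1) * ca_spacing
  anchor_a <- xs_n[nfn]
  gap <- 2.1
  anchor_b <- anchor_a + gap
  xs_c <- anchor_b + (seq_len(nfc) - 1) * ca_spacing
  base <- matrix(0, n_atoms(top), 3L)
  idx_n <- seq_len(nfn)
  idx_c <- nfn + nloop_atoms + seq_len(nfc)
  base[idx_n, 1] <- xs_n
  base[idx_c, 1] <- xs_c
  ks <- c(seq_len(nfn), nfn + seq_len(nfc))
  base[c(idx_n, idx_c), 2] <- 0.4 * cos(2.1 * ks) - 0.6
  base[c(idx_n, idx_c), 3] <- 0.4 * sin(2.1 * ks + 0.7)

  # loop arc in the xy-plane between the anchors
  r <- gap / 2
  tpar <- seq_len(nloop_atoms) / (nloop_atoms + 1L)
  arc <- cbind(anchor_a + r - r * cos(pi * tpar), r * sin(pi * tpar), 0)

  loop_sel <- nfn + seq_len(nloop_atoms)
  states <- lapply(state_angles_deg, function(ang) {
    th <- ang * pi / 180
    rot <- arc
    rot[, 2] <- arc[, 2] * cos(th)
    rot[, 3] <- arc[, 2] * sin(th)
    tmpl <- base
    tmpl[loop_sel, ] <- rot
    tmpl
  })

  rng <- function(v) paste0(min(v), "-", max(v))
  loop_query <- paste0("name N,CA,C and resid ", rng(loop_res))
  flank_query <- paste0("name CA and resid ", rng(flank_res_n), ",", rng(flank_res_c))
  list(topology = top, states = states,
       loop_sel = select_atoms(top, loop_query),
       flank_sel = select_atoms(top, flank_query),
       loop_query = loop_query, flank_query = flank_query)
}

#' Plan a synthetic multi-state trajectory
#'
#' A state plan fixes everything needed to generate one system's ensemble:
#' the planted state templates, their stationary occupancies (or a Markov
#' transition matrix), the thermal noise level, the frame count and the
#' seed. Generation is fully reproducible from the plan.
#'
#' @param geometry a [loop_system_geometry()] result (or a compatible list
#'   with `topology`, `states`, `loop_sel`).
#' @param occupancies per-state probabilities summing to 1. Under
#'   independent switching these are the sampling weights; under Markov
#'   switching they supply the initial state distribution.
#' @param n_frames frames to generate.
#' @param noise_sigma isotropic Gaussian noise per coordinate on loop
#'   atoms, nm (default 0.02 — intra-state spread well below a 0.2 nm
#'   clustering cut-off).
#' @param scaffold_sigma noise on scaffold atoms, nm (default: same as
#'   `noise_sigma`).
#' @param switching `"independent"` (default) for i.i.d. state draws, or a
#'   `K x K` Markov transition matrix with rows summing to 1 (gives the
#'   ensemble a time structure, e.g. a state first visited late in the
#'   run).
#' @param rigid_motion `NULL`, or `list(max_angle_deg=, max_shift_nm=)` to
#'   apply a small random global rigid motion to every frame (exercises
#'   the superposition stage; fitted RMSDs are invariant to it).
#' @param seed integer seed.
#' @param system_label label attached to every generated frame.
#' @param dt_ps frame spacing in ps (default 10).
#' @return object of class `"state_plan"`.
#' @export
state_plan <- function(geometry, occupancies, n_frames,
                       noise_sigma = 0.02, scaffold_sigma = noise_sigma,
                       switching = "independent", rigid_motion = NULL,
                       seed = 1L, system_label = "system", dt_ps = 10) {
  K <- length(geometry$states)
  stopifnot(K >= 1L, length(occupancies) == K, n_frames >= 1L,
            noise_sigma >= 0, scaffold_sigma >= 0)
  if (abs(sum(occupancies) - 1) > 1e-12)
    stop("occupancies must sum to 1 (got ", sum(occupancies), ")")
  if (any(occupancies < 0)) stop("negative occupancies")
  dims <- vapply(geometry$states, function(s) paste(dim(s), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("state templates differ in shape")
  if (!identical(switching, "independent")) {
    if (!is.matrix(switching) || any(dim(switching) != K))
      stop("switching must be 'independent' or a ", K, "x", K, " matrix")
    if (any(switching < 0) || any(abs(rowSums(switching) - 1) > 1e-12))
      stop("Markov transition matrix rows must be probabilities summing to 1")
  }
  if (!is.null(rigid_motion))
    stopifnot(is.list(rigid_motion),
              all(c("max_angle_deg", "max_shift_nm") %in% names(rigid_motion)))

  # separation check: planted states should be resolvable above the noise
  if (K >= 2L && noise_sigma > 0) {
    ls <- geometry$loop_sel
    dmin <- Inf
    for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
      dab <- sqrt(mean(rowSums(
        (geometry$states[[a]][ls, ] - geometry$states[[b]][ls, ])^2)))
      dmin <- min(dmin, dab)
    }
    if (dmin <= 4 * noise_sigma)
      warning(sprintf(paste0("minimum inter-state loop RMSD (%.3f nm) is within ",
                             "4 x noise sigma (%.3f nm): states may not be ",
                             "recoverable"), dmin, 4 * noise_sigma))
  }

  structure(list(geometry = geometry, occupancies = as.numeric(occupancies),
                 n_frames = as.integer(n_frames), noise_sigma = noise_sigma,
                 scaffold_sigma = scaffold_sigma, switching = switching,
                 rigid_motion = rigid_motion, seed = as.integer(seed),
                 system_label = system_label, dt_ps = dt_ps),
            class = "state_plan")
}

#' Generate a labelled multi-state loop ensemble from a plan
#'
#' Per frame, a planted state is drawn (independently or by the plan's
#' Markov chain), loop coordinates are the state template plus isotropic
#' Gaussian noise, scaffold coordinates are the scaffold template plus its
#' own (usually equal) noise, and optionally a small random global rigid
#' motion is applied to the whole frame. The RNG is consumed in a fixed
#' order (states, loop noise, scaffold noise, rigid motions), so two plans
#' differing only in `rigid_motion` share identical states and noise.
#'
#' @param plan a [state_plan()].
#' @return list with `trajectory` (a labelled [trajectory()]) and `states`
#'   (integer vector of true per-frame state labels, for recovery
#'   scoring).
#' @export
generate_loop_ensemble <- function(plan) {
  stopifnot(inherits(plan, "state_plan"))
  geo <- plan$geometry
  K <- length(geo$states)
  nf <- plan$n_frames
  na <- n_atoms(geo$topology)
  ls <- geo$loop_sel
  sc <- setdiff(seq_len(na), ls)

  set.seed(plan$seed)
  if (identical(plan$switching, "independent")) {
    states <- sample.int(K, nf, replace = TRUE, prob = plan$occupancies)
  } else {
    states <- integer(nf)
    states[1] <- sample.int(K, 1L, prob = plan$occupancies)
    for (f in seq_len(nf)[-1])
      states[f] <- sample.int(K, 1L, prob = plan$switching[states[f - 1L], ])
  }
  loop_noise <- array(stats::rnorm(length(ls) * 3L * nf, sd = plan$noise_sigma),
                      c(length(ls), 3L, nf))
  scaf_noise <- array(stats::rnorm(length(sc) * 3L * nf, sd = plan$scaffold_sigma),
                      c(length(sc), 3L, nf))

  coords <- array(NA_real_, c(na, 3L, nf))
  for (f in seq_len(nf)) {
    fr <- geo$states[[states[f]]]
    fr[ls, ] <- fr[ls, ] + loop_noise[, , f]
    fr[sc, ] <- fr[sc, ] + scaf_noise[, , f]
    coords[, , f] <- fr
  }
  if (!is.null(plan$rigid_motion)) {
    maxang <- plan$rigid_motion$max_angle_deg * pi / 180
    maxsh <- plan$rigid_motion$max_shift_nm
    for (f in seq_len(nf)) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      th <- stats::runif(1, -maxang, maxang)
      sh <- stats::runif(3, -maxsh, maxsh)
      R <- rotation_about_axis(ax, th)
      ctr <- colMeans(coords[, , f])
      coords[, , f] <- sweep(sweep(coords[, , f], 2, ctr) %*% t(R), 2,
                             ctr + sh, `+`)
    }
  }
  traj <- trajectory(geo$topology, coords,
                     times = (seq_len(nf) - 1) * plan$dt_ps,
                     system = plan$system_label)
  list(trajectory = traj, states = states)
}

# Rodrigues rotation matrix for unit axis u and angle theta
rotation_about_axis <- function(u, theta) {
  Kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * Kx + (1 - cos(theta)) * (Kx %*% Kx)
}

#' Default three-system study plan
#'
#' The bundled study conditions: four planted loop states over a common
#' geometry — S1, a core conformation shared by all systems; S2, a
#' satellite conformation close to S1 (loop RMSD about 0.6 nm, the same
#' meta-conformation); S3, visited only by the unliganded system; S4,
#' visited only by ligand A — and three systems mixing them as
#' `apo = 0.8*S3 + 0.2*S1`, `ligA = 0.25*S1 + 0.45*S2 + 0.30*S4`,
#' `ligB = 0.60*S1 + 0.40*S2`. Under clustering and ordination this yields
#' three meta-conformations with residencies apo 80%/20% (II/I), ligA
#' 70%/30% (I/III), ligB 100% (I), with the core state shared 20/25/60%
#' of the time by apo/ligA/ligB — the occupancy structure of a receptor
#' whose loop is remodelled differently by two binding partners.
#'
#' @param n_frames frames per system.
#' @param seed base seed; the three systems use `seed + 1:3`.
#' @param noise_sigma thermal noise, nm.
#' @param rigid_motion global per-frame rigid motion (default: small, on).
#' @return named list of three [state_plan()]s (`apo`, `ligA`, `ligB`)
#'   sharing one geometry (attached as attribute `"geometry"`).
#' @export
default_three_system_plans <- function(n_frames = 1000L, seed = 42L,
                                       noise_sigma = 0.02,
                                       rigid_motion = list(max_angle_deg = 8,
                                                           max_shift_nm = 0.3)) {
  geo <- loop_system_geometry(state_angles_deg = c(0, 45, 135, 225))
  plans <- list(
    apo  = state_plan(geo, c(0.20, 0.00, 0.80, 0.00), n_frames,
                      noise_sigma = noise_sigma, rigid_motion = rigid_motion,
                      seed = seed + 1L, system_label = "apo"),
    ligA = state_plan(geo, c(0.25, 0.45, 0.00, 0.30), n_frames,
                      noise_sigma = noise_sigma, rigid_motion = rigid_motion,
                      seed = seed + 2L, system_label = "ligA"),
    ligB = state_plan(geo, c(0.60, 0.40, 0.00, 0.00), n_frames,
                      noise_sigma = noise_sigma, rigid_motion = rigid_motion,
                      seed = seed + 3L, system_label = "ligB"))
  attr(plans, "geometry") <- geo
  plans
}

#' Hydrogen-bond fixture with a planted on/off schedule
#'
#' A three-atom system (donor N, its hydrogen, acceptor O) in which frames
#' scheduled "on" satisfy the bond criteria comfortably (donor--acceptor
#' distance `d_on`, hydrogen tilted `angle_deg` off the donor-acceptor
#' axis) and "off" frames fail on distance (`d_off`). The detector's
#' per-frame counts must reproduce the schedule exactly.
#'
#' @param schedule logical (or 0/1) vector, one entry per frame.
#' @param d_on,d_off donor--acceptor distances (nm) for on/off frames
#'   (defaults 0.29 / 0.45).
#' @param angle_deg hydrogen tilt off the donor-acceptor axis, degrees
#'   (default 5).
#' @return list with `trajectory`, `groupA` (donor side), `groupB`
#'   (acceptor side), `schedule` (logical).
#' @export
generate_hbond_fixture <- function(schedule, d_on = 0.29, d_off = 0.45,
                                   angle_deg = 5) {
  schedule <- as.logical(schedule)
  stopifnot(length(schedule) >= 1L, !anyNA(schedule))
  top <- topology(
    data.frame(name = c("N", "H", "O"), resnum = c(1L, 1L, 2L),
               resname = c("ALA", "ALA", "SER"),
               role = c("donor", "hydrogen", "acceptor")),
    bonds = data.frame(donor = 1L, hydrogen = 2L))
  th <- angle_deg * pi / 180
  hpos <- 0.1 * c(cos(th), sin(th), 0)        # N-H bond length 0.1 nm
  nf <- length(schedule)
  coords <- array(0, c(3L, 3L, nf))
  for (f in seq_len(nf)) {
    coords[2, , f] <- hpos
    coords[3, 1, f] <- if (schedule[f]) d_on else d_off
  }
  list(trajectory = trajectory(top, coords, system = "fixture"),
       groupA = c(1L, 2L), groupB = 3L, schedule = schedule)
}

#' Charged/Lennard-Jones dimer fixture at controlled separations
#'
#' Two single-atom groups placed on the x-axis at a series of separations,
#' so Coulomb and LJ energies have closed forms (`f q1 q2 / r` and
#' `C12/r^12 - C6/r^6` with geometric-mean combination) against which the
#' energy accounting can be checked frame by frame.
#'
#' @param separations numeric vector of separations in nm, one frame each.
#' @param charges length-2 charges in e (default `c(1, 1)`).
#' @param c6,c12 length-2 LJ parameters (defaults 0).
#' @return list with `trajectory`, `groupA`, `groupB`, `separations`.
#' @export
generate_charged_dimer <- function(separations, charges = c(1, 1),
                                   c6 = c(0, 0), c12 = c(0, 0)) {
  stopifnot(length(separations) >= 1L, all(separations > 0),
            length(charges) == 2L, length(c6) == 2L, length(c12) == 2L)
  top <- topology(data.frame(name = c("Q1", "Q2"), resnum = c(1L, 2L),
                             resname = "ION", charge = charges,
                             c6 = c6, c12 = c12))
  nf <- length(separations)
  coords <- array(0, c(2L, 3L, nf))
  coords[2, 1, ] <- separations
  list(trajectory = trajectory(top, coords, system = "dimer"),
       groupA = 1L, groupB = 2L, separations = separations)
}
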