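#' @title Electric conversion factor
#' @description `f = 1/(4 pi eps0)` in GROMACS units:
#'   138.935458 kJ mol^-1 nm e^-2. Multiplying `q_i q_j / r_ij` (charges in
#'   elementary charges, distance in nm) by `f` gives the Coulomb pair
#'   energy in kJ/mol.
#' @format single numeric value
#' @export
COULOMB_CONSTANT <- 138.935458

#' Geometric hydrogen-bond detection between two atom groups
#'
#' A donor/hydrogen pair in one group and an acceptor in the other form a
#' hydrogen bond when the donor--acceptor distance is at most `dist_cutoff`
#' and the hydrogen lies within `angle_cutoff` of the donor-to-acceptor
#' axis. Both directions (donor in A/acceptor in B and vice versa) are
#' searched; the candidate set is exhaustive over all flagged triples.
#'
#' @param frame `n_atoms x 3` coordinate matrix (nm).
#' @param top the [topology()] flagging donors, acceptors and hydrogens and
#'   listing donor--hydrogen bonds.
#' @param groupA,groupB atom index vectors (e.g. receptor and ligand).
#' @param dist_cutoff donor--acceptor distance cut-off in nm (default
#'   0.35).
#' @param angle_cutoff angular cut-off in degrees (default 30).
#' @param angle_convention `"ADH"` (default): the acceptor--donor--hydrogen
#'   angle at the donor must be `<= angle_cutoff` — the hydrogen points
#'   roughly along the donor-to-acceptor axis. `"DHA"`: the
#'   donor--hydrogen--acceptor angle at the hydrogen must be
#'   `>= 180 - angle_cutoff` (near-linear geometry). The `"ADH"` reading is
#'   the conventional one for a 30-degree cut-off; an H-vertex angle of
#'   30 degrees would describe a folded, non-bonding arrangement.
#' @return data.frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor` (atom indices), `distance` (donor--acceptor, nm), `angle`
#'   (degrees, in the chosen convention).
#' @export
find_hbonds <- function(frame, top, groupA, groupB,
                        dist_cutoff = 0.35, angle_cutoff = 30,
                        angle_convention = c("ADH", "DHA")) {
  angle_convention <- match.arg(angle_convention)
  stopifnot(is.matrix(frame), ncol(frame) == 3L)
  if (inherits(top, "trajectory")) top <- top$topology
  stopifnot(inherits(top, "topology"), nrow(frame) == n_atoms(top))
  groupA <- check_selection(groupA, n_atoms(top), "groupA")
  groupB <- check_selection(groupB, n_atoms(top), "groupB")

  roles <- top$atoms$role
  bonds <- top$bonds
  one_direction <- function(gd, ga) {
    don_h <- bonds[bonds$donor %in% gd[roles[gd] == "donor"] &
                     bonds$hydrogen %in% gd, , drop = FALSE]
    acc <- ga[roles[ga] == "acceptor"]
    if (!nrow(don_h) || !length(acc)) return(NULL)
    cand <- expand.grid(pair = seq_len(nrow(don_h)), acceptor = acc)
    D <- frame[don_h$donor[cand$pair], , drop = FALSE]
    H <- frame[don_h$hydrogen[cand$pair], , drop = FALSE]
    A <- frame[cand$acceptor, , drop = FALSE]
    da <- sqrt(rowSums((A - D)^2))
    keep <- da <= dist_cutoff
    if (!any(keep)) return(NULL)
    D <- D[keep, , drop = FALSE]; H <- H[keep, , drop = FALSE]
    A <- A[keep, , drop = FALSE]; cand <- cand[keep, , drop = FALSE]
    da <- da[keep]
    if (angle_convention == "ADH") {
      v1 <- H - D; v2 <- A - D
      cosang <- rowSums(v1 * v2) /
        pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), 1e-12)
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      ok <- ang <= angle_cutoff
    } else {
      v1 <- D - H; v2 <- A - H
      cosang <- rowSums(v1 * v2) /
        pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), 1e-12)
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      ok <- ang >= 180 - angle_cutoff
    }
    if (!any(ok)) return(NULL)
    data.frame(donor = don_h$donor[cand$pair][ok],
               hydrogen = don_h$hydrogen[cand$pair][ok],
               acceptor = cand$acceptor[ok],
               distance = da[ok], angle = ang[ok])
  }
  out <- rbind(one_direction(groupA, groupB), one_direction(groupB, groupA))
  if (is.null(out))
    out <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  out <- out[order(out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-frame hydrogen-bond counts over a trajectory
#'
#' @param traj a [trajectory()].
#' @param groupA,groupB,... passed to [find_hbonds()]; the trajectory's own
#'   topology is used.
#' @return integer vector, one count per frame.
#' @export
hbond_count_series <- function(traj, groupA, groupB, ...) {
  stopifnot(inherits(traj, "trajectory"))
  vapply(seq_len(n_frames(traj)), function(f)
    nrow(find_hbonds(get_frame(traj, f), traj$topology, groupA, groupB, ...)),
    1L)
}

#' Histogram of hydrogen-bond counts
#'
#' Tallies how many frames exhibit each number of hydrogen bonds (the
#' frequency-of-count summary of an interface). Counts from 0 to the
#' observed maximum are all reported, so gaps show as zeros; frequencies
#' sum to the frame count.
#'
#' @param series integer per-frame counts from [hbond_count_series()].
#' @return data.frame with columns `n_hbonds`, `n_frames`.
#' @export
hbond_histogram <- function(series) {
  if (!length(series)) stop("empty hydrogen-bond count series")
  if (any(series < 0)) stop("negative hydrogen-bond counts")
  tab <- tabulate(series + 1L, nbins = max(series) + 1L)
  data.frame(n_hbonds = seq_along(tab) - 1L, n_frames = tab)
}

#' Short-range non-bonded interaction energy between two groups
#'
#' Sums Coulomb and Lennard-Jones pair energies over all inter-group atom
#' pairs within a plain distance cut-off (no switching function, no
#' long-range correction — the short-range sum only):
#' `E_Coul = f * sum q_i q_j / r_ij` with `f =` [COULOMB_CONSTANT], and
#' `E_LJ = sum C12_ij / r_ij^12 - C6_ij / r_ij^6` with geometric-mean
#' combination `C6_ij = sqrt(C6_i C6_j)`, `C12_ij = sqrt(C12_i C12_j)`.
#' Groups must be disjoint (separate molecules), so covalent exclusions do
#' not arise.
#'
#' @param frame `n_atoms x 3` coordinate matrix (nm).
#' @param top the [topology()] carrying charges and C6/C12.
#' @param groupA,groupB disjoint atom index vectors.
#' @param cutoff pair distance cut-off in nm (default 1.4).
#' @return list of class `"energy_pair"` with `e_coulomb`, `e_lj`,
#'   `e_total` (kJ/mol), `e_total = e_coulomb + e_lj`.
#' @export
pairwise_nonbonded_energy <- function(frame, top, groupA, groupB,
                                      cutoff = 1.4) {
  stopifnot(is.matrix(frame), ncol(frame) == 3L)
  if (inherits(top, "trajectory")) top <- top$topology
  stopifnot(inherits(top, "topology"), nrow(frame) == n_atoms(top))
  groupA <- check_selection(groupA, n_atoms(top), "groupA")
  groupB <- check_selection(groupB, n_atoms(top), "groupB")
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: non-bonded energy is defined between disjoint groups")
  A <- frame[groupA, , drop = FALSE]; B <- frame[groupB, , drop = FALSE]
  r2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  r <- sqrt(pmax(r2, 0))
  if (any(r < 1e-9))
    stop("coincident atoms across groups (r = 0): energy is singular")
  mask <- r <= cutoff
  if (!any(mask)) {
    ec <- 0; el <- 0
  } else {
    q <- top$atoms$charge
    qq <- outer(q[groupA], q[groupB])
    ec <- COULOMB_CONSTANT * sum(qq[mask] / r[mask])
    c6 <- outer(top$atoms$c6[groupA], top$atoms$c6[groupB])
    c12 <- outer(top$atoms$c12[groupA], top$atoms$c12[groupB])
    c6ij <- sqrt(c6); c12ij <- sqrt(c12)
    r6 <- r[mask]^6
    el <- sum(c12ij[mask] / r6^2 - c6ij[mask] / r6)
  }
  structure(list(e_coulomb = ec, e_lj = el, e_total = ec + el),
            class = "energy_pair")
}

#' @export
print.energy_pair <- function(x, ...) {
  cat(sprintf("E_Coul = %.4f, E_LJ = %.4f, E_total = %.4f kJ/mol\n",
              x$e_coulomb, x$e_lj, x$e_total))
  invisible(x)
}

#' Per-frame non-bonded energy series over a trajectory
#'
#' @param traj a [trajectory()].
#' @param groupA,groupB,cutoff see [pairwise_nonbonded_energy()].
#' @return data.frame with columns `frame`, `time_ps`, `e_coulomb`, `e_lj`,
#'   `e_total`.
#' @export
nonbonded_energy_series <- function(traj, groupA, groupB, cutoff = 1.4) {
  stopifnot(inherits(traj, "trajectory"))
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    e <- pairwise_nonbonded_energy(get_frame(traj, f), traj$topology,
                                   groupA, groupB, cutoff)
    data.frame(frame = f, time_ps = traj$times[f], e_coulomb = e$e_coulomb,
               e_lj = e$e_lj, e_total = e$e_total)
  })
  do.call(rbind, rows)
}

#' Histogram of interaction energies in fixed-width bins
#'
#' Groups values into half-open bins `[k*w, (k+1)*w)` anchored at zero
#' (a value exactly on an edge falls in the higher bin). Typical widths:
#' 100 kJ/mol for a whole interface, 10 kJ/mol for a loop--ligand contact.
#' Bin counts sum to the number of values.
#'
#' @param values numeric energies (kJ/mol).
#' @param bin_width positive bin width (kJ/mol).
#' @return data.frame with columns `bin_lo`, `bin_hi`, `n_frames`, one row
#'   per occupied bin, ordered by `bin_lo`.
#' @export
energy_histogram <- function(values, bin_width) {
  if (!length(values)) stop("empty energy series")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number")
  k <- floor(values / bin_width)
  tab <- table(k)
  ks <- as.numeric(names(tab))
  out <- data.frame(bin_lo = ks * bin_width, bin_hi = (ks + 1) * bin_width,
                    n_frames = as.integer(tab))
  out[order(out$bin_lo), , drop = FALSE]
}
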