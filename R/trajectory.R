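#' Construct a trajectory
#'
#' A trajectory is an ordered set of frames over one topology. Coordinates
#' are stored in nanometres (the unit of every distance threshold in this
#' package); PDB input/output converts between angstroms and nm at the
#' boundary.
#'
#' @param top a [topology()].
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames`, in nm.
#' @param times numeric vector of frame times in ps (default `0, 10, 20,
#'   ...`, one saved frame per 10 ps).
#' @param system character vector of per-frame system labels, a single label
#'   recycled to all frames, or `NULL` for unlabeled frames.
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(top, coords, times = NULL, system = NULL) {
  stopifnot(inherits(top, "topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != n_atoms(top))
    stop("coordinate rows (", dim(coords)[1], ") do not match topology atom count (",
         n_atoms(top), ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * 10
  stopifnot(length(times) == nf)
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  if (!is.null(system)) {
    if (length(system) == 1L) system <- rep(system, nf)
    stopifnot(length(system) == nf)
    system <- as.character(system)
  }
  structure(list(topology = top, coords = coords,
                 times = as.numeric(times), system = system),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", n_atoms(x$topology), "atoms",
      sprintf("(%.0f-%.0f ps)", x$times[1], x$times[n_frames(x)]), "\n")
  if (!is.null(x$system)) {
    tb <- table(x$system)
    cat("  systems:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()]
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an `n_atoms x 3` coordinate matrix (nm)
#' @param traj a [trajectory()]
#' @param i frame index
#' @return numeric matrix
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Restrict a trajectory to a selection of atoms
#'
#' Subsets coordinates, the atom table, and the bond table (bonds with
#' either end outside the selection are dropped; a retained hydrogen whose
#' donor is dropped is an error, since the topology invariant would break).
#'
#' @param traj a [trajectory()]
#' @param sel atom indices (from [select_atoms()] or integer vector)
#' @return a new trajectory over the selected atoms only
#' @export
subset_trajectory <- function(traj, sel) {
  sel <- check_selection(sel, n_atoms(traj$topology))
  at <- traj$topology$atoms[sel, , drop = FALSE]
  bd <- traj$topology$bonds
  keep <- bd$donor %in% sel & bd$hydrogen %in% sel
  bd <- bd[keep, , drop = FALSE]
  remap <- match(seq_len(n_atoms(traj$topology)), sel)
  bd$donor <- remap[bd$donor]; bd$hydrogen <- remap[bd$hydrogen]
  trajectory(topology(at, if (nrow(bd)) bd else NULL),
             traj$coords[sel, , , drop = FALSE],
             times = traj$times, system = traj$system)
}

#' Read a multi-model PDB file with a topology sidecar
#'
#' One frame per `MODEL`/`ENDMDL` block (a bare single coordinate set reads
#' as one frame). Coordinates are converted from the PDB's angstroms to nm.
#' The sidecar supplies charges, Lennard-Jones parameters, hydrogen-bond
#' roles and donor--hydrogen bonds for every atom; see
#' [read_topology_sidecar()].
#'
#' @param path multi-model PDB file.
#' @param sidecar topology sidecar file.
#' @param times,system passed to [trajectory()].
#' @return a [trajectory()].
#' @export
read_multimodel_pdb <- function(path, sidecar, times = NULL, system = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  top <- read_topology_sidecar(sidecar)

  # pre-scan so an inter-model atom-count mismatch is reported by model number
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts)) {
    model_of <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_of, nbins = length(model_starts))
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop("model ", bad, " has ", counts[bad], " atoms but model 1 has ",
           counts[1])
    }
    natoms <- counts[1]
  } else {
    natoms <- sum(is_atom)
  }
  if (natoms == 0L) stop("no ATOM records in ", path)
  if (natoms != n_atoms(top)) {
    miss <- if (natoms > n_atoms(top)) {
      paste0("; no sidecar entry for atom ", n_atoms(top) + 1L, " of the PDB")
    } else ""
    stop("PDB has ", natoms, " atoms per model but sidecar describes ",
         n_atoms(top), " atoms", miss)
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                        # n_models x 3*natoms, angstrom
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(natoms, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) * 0.1
  trajectory(top, coords, times = times, system = system)
}

#' Write a trajectory (or a selection of it) as a multi-model PDB
#'
#' One `MODEL` block per frame; coordinates converted nm to angstrom at
#' fixed PDB column precision (3 decimals in angstrom), so a read/write
#' round trip reproduces coordinates to 1e-4 nm.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param sel atoms to write (default: all). An empty selection is an error.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path, sel = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(sel)) sel <- seq_len(n_atoms(traj$topology))
  sel <- check_selection(sel, n_atoms(traj$topology))
  at <- traj$topology$atoms[sel, , drop = FALSE]
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nf, 3L * length(sel))
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(traj$coords[sel, , f, drop = FALSE][, , 1])) * 10
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$resnum, resid = at$resname,
                   eleno = seq_along(sel), elety = at$name,
                   chain = at$chain, elesy = at$element)
  invisible(path)
}

#' Concatenate trajectories from several systems into one labelled ensemble
#'
#' Mirrors the treatment of independent simulation repeats as a single long
#' trajectory: the frames of each part are appended in order and tagged with
#' that part's system label, so downstream clustering can attribute every
#' frame to its originating system. Frame times are kept as-is, so times are
#' generally not monotone across the concatenation boundary (the ensemble is
#' an unordered sample of configurations once concatenated).
#'
#' @param parts list of [trajectory()] objects; names supply system labels
#'   unless `labels` is given.
#' @param labels character vector of system labels, one per part.
#' @param sel optional common atom selection applied to each part before
#'   concatenation (use when the parts' topologies differ outside a shared
#'   core, e.g. receptor atoms extracted from different complexes). Atom
#'   names over the common selection must agree across parts.
#' @return one [trajectory()] whose frames carry per-frame system labels;
#'   the topology is taken from the first part (restricted to `sel` if
#'   given).
#' @export
concatenate_trajectories <- function(parts, labels = names(parts), sel = NULL) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  if (is.null(labels) || any(!nzchar(labels)) || length(labels) != length(parts))
    stop("each part needs a non-empty system label")
  parts <- lapply(parts, function(p) {
    stopifnot(inherits(p, "trajectory"))
    if (is.null(sel)) p else subset_trajectory(p, sel)
  })
  ref_names <- parts[[1]]$topology$atoms$name
  for (k in seq_along(parts)[-1]) {
    nm <- parts[[k]]$topology$atoms$name
    if (length(nm) != length(ref_names))
      stop("part ", k, " has ", length(nm),
           " atoms over the common selection but part 1 has ", length(ref_names))
    if (!identical(nm, ref_names))
      stop("part ", k, " atom ordering differs from part 1 over the common selection")
  }
  coords <- array(unlist(lapply(parts, `[[`, "coords"), use.names = FALSE),
                  dim = c(length(ref_names), 3L,
                          sum(vapply(parts, n_frames, 1L))))
  # arrays concatenate along the last dimension only if rebuilt explicitly
  off <- 0L
  for (k in seq_along(parts)) {
    nf <- n_frames(parts[[k]])
    coords[, , off + seq_len(nf)] <- parts[[k]]$coords
    off <- off + nf
  }
  times <- unlist(lapply(parts, `[[`, "times"), use.names = FALSE)
  system <- rep(labels, vapply(parts, n_frames, 1L))
  out <- structure(list(topology = parts[[1]]$topology, coords = coords,
                        times = as.numeric(times), system = system),
                   class = "trajectory")
  out
}
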