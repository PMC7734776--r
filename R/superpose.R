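#' Least-squares rigid-body (Kabsch) superposition
#'
#' Finds the proper rotation and translation that minimize the sum of
#' squared deviations of the mobile structure's fit-selection atoms from the
#' reference's, via singular value decomposition of the 3x3 covariance with
#' the determinant-sign correction (so reflections are never returned).
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices (nm).
#' @param fit_sel atom indices used for the fit; at least 3 non-collinear
#'   atoms.
#' @return list of class `"kabsch_fit"` with elements `rotation` (3x3,
#'   `det = +1`), `translation` (length-3, nm) and `fit_rmsd` (nm). The
#'   transform maps mobile coordinates onto the reference:
#'   `x' = x %*% t(rotation) + translation` (rows are atoms).
#' @export
kabsch_fit <- function(mobile, reference, fit_sel = seq_len(nrow(mobile))) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  fit_sel <- check_selection(fit_sel, nrow(mobile), "fit selection")
  if (length(fit_sel) < 3L)
    stop("fit selection needs at least 3 atoms, got ", length(fit_sel))
  X <- mobile[fit_sel, , drop = FALSE]
  Y <- reference[fit_sel, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  if (qr(Xc)$rank < 2L)
    stop("degenerate (collinear) fit selection: cannot determine a unique rotation")
  A <- crossprod(Xc, Yc)                       # sum_i x_i y_i^T
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # y ~ R x
  tr <- cy - as.vector(R %*% cx)
  fitted <- Xc %*% t(R)
  fit_rmsd <- sqrt(sum((fitted - Yc)^2) / length(fit_sel))
  structure(list(rotation = R, translation = tr, fit_rmsd = fit_rmsd),
            class = "kabsch_fit")
}

#' Apply a superposition transform to coordinates
#' @param coords `n x 3` matrix (nm)
#' @param fit a [kabsch_fit()] result
#' @return transformed `n x 3` matrix
#' @export
apply_fit <- function(coords, fit) {
  stopifnot(inherits(fit, "kabsch_fit"))
  sweep(coords %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' RMSD of a frame against a reference after a least-squares fit
#'
#' Superposes the frame on the reference over `fit_sel` (e.g. the C-alpha
#' backbone of the regions flanking a loop) and evaluates
#' `sqrt( (1/N) * sum_i ||x_i - x_i(ref)||^2 )` over `measure_sel` (e.g. all
#' loop atoms). `fit_sel` and `measure_sel` may coincide, giving the usual
#' fitted RMSD.
#'
#' @param frame,reference `n_atoms x 3` coordinate matrices (nm).
#' @param fit_sel atoms for the superposition.
#' @param measure_sel atoms entering the deviation sum (default: `fit_sel`).
#' @return RMSD in nm.
#' @export
rmsd <- function(frame, reference, fit_sel, measure_sel = fit_sel) {
  measure_sel <- check_selection(measure_sel, nrow(frame), "measure selection")
  fit <- kabsch_fit(frame, reference, fit_sel)
  moved <- apply_fit(frame[measure_sel, , drop = FALSE], fit)
  sqrt(sum((moved - reference[measure_sel, , drop = FALSE])^2) /
         length(measure_sel))
}

#' Per-atom root-mean-square fluctuation over a trajectory
#'
#' Each frame is first superposed on a common reference over `fit_sel`;
#' the RMSF of an atom is then `sqrt( (1/T) * sum_t ||x(t) - xbar||^2 )`
#' where `xbar` is that atom's mean fitted position over the `T` frames —
#' the standard deviation of its position about its time average.
#'
#' @param traj a [trajectory()] with at least 2 frames (a single frame has
#'   no fluctuation and is refused rather than silently reported as zero).
#' @param fit_sel atoms used to superpose each frame.
#' @param measure_sel atoms whose fluctuation is reported.
#' @param reference fit target: `"first"` (default; each frame fitted to the
#'   first frame), `"mean"` (fitted iteratively to the mean structure), or
#'   an `n_atoms x 3` matrix.
#' @return data.frame with columns `atom`, `name`, `resnum`, `rmsf_nm`.
#' @export
rmsf <- function(traj, fit_sel, measure_sel = fit_sel, reference = "first") {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF needs at least 2 frames, got ", nf)
  na <- n_atoms(traj$topology)
  fit_sel <- check_selection(fit_sel, na, "fit selection")
  measure_sel <- check_selection(measure_sel, na, "measure selection")

  fit_to <- function(ref) {
    fitted <- array(NA_real_, c(length(measure_sel), 3L, nf))
    for (f in seq_len(nf)) {
      fr <- get_frame(traj, f)
      tfm <- kabsch_fit(fr, ref, fit_sel)
      fitted[, , f] <- apply_fit(fr[measure_sel, , drop = FALSE], tfm)
    }
    fitted
  }

  if (is.matrix(reference)) {
    fitted <- fit_to(reference)
  } else if (identical(reference, "first")) {
    fitted <- fit_to(get_frame(traj, 1L))
  } else if (identical(reference, "mean")) {
    # fit to first, then refit to the resulting mean until stable
    ref <- get_frame(traj, 1L)
    for (it in 1:10) {
      fitted_all <- array(NA_real_, c(na, 3L, nf))
      for (f in seq_len(nf)) {
        fr <- get_frame(traj, f)
        fitted_all[, , f] <- apply_fit(fr, kabsch_fit(fr, ref, fit_sel))
      }
      newref <- apply(fitted_all, c(1, 2), mean)
      if (max(abs(newref - ref)) < 1e-10) { ref <- newref; break }
      ref <- newref
    }
    fitted <- fit_to(ref)
  } else stop("reference must be 'first', 'mean', or a coordinate matrix")

  mean_pos <- apply(fitted, c(1, 2), mean)
  dev2 <- sweep(fitted, c(1, 2), mean_pos)^2
  vals <- sqrt(apply(dev2, 1, sum) / nf)
  at <- traj$topology$atoms[measure_sel, , drop = FALSE]
  data.frame(atom = measure_sel, name = at$name, resnum = at$resnum,
             rmsf_nm = as.numeric(vals))
}

#' All-against-all RMSD matrix over a trajectory
#'
#' `M[i, j]` is the RMSD of frame `j` measured against frame `i` over
#' `measure_sel` after a least-squares fit over `fit_sel` (see [rmsd()]).
#' Computed in compiled code; the result is symmetrized (the two directions
#' agree analytically; symmetrization removes rounding asymmetry) with a
#' zero diagonal.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param fit_sel,measure_sel see [rmsd()].
#' @return symmetric `n_frames x n_frames` matrix (nm).
#' @export
pairwise_rmsd_matrix <- function(traj, fit_sel, measure_sel = fit_sel) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  na <- n_atoms(traj$topology)
  fit_sel <- check_selection(fit_sel, na, "fit selection")
  measure_sel <- check_selection(measure_sel, na, "measure selection")
  if (length(fit_sel) < 3L) stop("fit selection needs at least 3 atoms")
  fitc <- aperm(traj$coords[fit_sel, , , drop = FALSE], c(2, 1, 3))
  measc <- aperm(traj$coords[measure_sel, , , drop = FALSE], c(2, 1, 3))
  M <- cpp_pairwise_rmsd(fitc, measc)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}
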