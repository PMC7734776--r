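# Independent oracles and small fixture builders shared across tests.
# Every oracle is a deliberately naive, literal implementation kept separate
# from the package's code paths.

# -- simple topology / trajectory builders -----------------------------------

dummy_top <- function(n, prefix = "A") {
  topology(data.frame(name = paste0(prefix, seq_len(n)),
                      resnum = seq_len(n), resname = "GLY"))
}

# trajectory from a list of n x 3 coordinate matrices
traj_from_frames <- function(frames, top = dummy_top(nrow(frames[[1]])),
                             system = NULL) {
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  trajectory(top, coords, system = system)
}

# 4 non-coplanar anchor atoms (well-conditioned fits)
anchor_coords <- function() {
  matrix(c(0, 0, 0,
           1, 0, 0,
           0, 1, 0,
           0, 0, 1), 4, 3, byrow = TRUE)
}

# -- rotation-grid superposition oracle --------------------------------------

# n uniformly random rotation matrices, flattened column-major (n x 9)
random_rotation_grid <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
}

# minimum RMSD of mobile onto reference over a rotation grid, each rotation
# paired with its optimal translation (centroid alignment):
#   sum ||R x - y||^2 = |X|^2 + |Y|^2 - 2 tr(R A),  A = sum x y^T
oracle_grid_min_rmsd <- function(mobile, reference, grid) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  A <- crossprod(X, Y)
  vals <- grid %*% as.vector(t(A))
  ms <- (sum(X^2) + sum(Y^2) - 2 * max(vals)) / nrow(X)
  sqrt(max(ms, 0))
}

# -- literal neighbour-count clustering oracle -------------------------------

# step-by-step simulation of the published rules: every remaining structure
# is a candidate centre; count neighbours within the cut-off (self included);
# promote the candidate with the most neighbours (lowest index on ties);
# remove the cluster; repeat.
oracle_daura <- function(mat, cutoff) {
  remaining <- seq_len(nrow(mat))
  clusters <- list()
  while (length(remaining) > 0) {
    best_i <- NA; best_count <- -1; best_members <- NULL
    for (i in remaining) {
      nb <- remaining[mat[i, remaining] <= cutoff]
      if (length(nb) > best_count) {
        best_count <- length(nb); best_i <- i; best_members <- nb
      }
    }
    clusters[[length(clusters) + 1]] <- list(center = best_i,
                                             members = best_members)
    remaining <- setdiff(remaining, best_members)
  }
  sizes <- sapply(clusters, function(cl) length(cl$members))
  centers <- sapply(clusters, function(cl) cl$center)
  clusters[order(-sizes, centers)]
}

# distance matrix of random points (a valid, exactly symmetric input)
random_point_matrix <- function(n, dim = 3) {
  as.matrix(dist(matrix(stats::runif(n * dim), n, dim)))
}

# -- brute-force hydrogen-bond oracle ----------------------------------------

oracle_hbonds <- function(frame, top, gA, gB,
                          dist_cutoff = 0.35, angle_cutoff = 30) {
  hits <- NULL
  bonds <- top$bonds
  for (dir in 1:2) {
    gd <- if (dir == 1) gA else gB
    ga <- if (dir == 1) gB else gA
    for (bi in seq_len(nrow(bonds))) {
      d <- bonds$donor[bi]; h <- bonds$hydrogen[bi]
      if (!(d %in% gd) || !(h %in% gd)) next
      if (top$atoms$role[d] != "donor") next
      for (a in ga) {
        if (top$atoms$role[a] != "acceptor") next
        vda <- frame[a, ] - frame[d, ]
        dist <- sqrt(sum(vda^2))
        if (dist > dist_cutoff) next
        vdh <- frame[h, ] - frame[d, ]
        cosang <- sum(vdh * vda) / (sqrt(sum(vdh^2)) * dist)
        ang <- acos(min(1, max(-1, cosang))) * 180 / pi
        if (ang <= angle_cutoff) hits <- rbind(hits, c(d, h, a))
      }
    }
  }
  if (is.null(hits)) hits <- matrix(integer(0), 0, 3)
  hits[order(hits[, 1], hits[, 3]), , drop = FALSE]
}

# a random two-group configuration with donors, hydrogens and acceptors
random_hbond_config <- function(n_per_group = 15, box = 0.8) {
  mk_group <- function() {
    n_d <- 3; n_a <- 4; n_rest <- n_per_group - 2 * n_d - n_a
    data.frame(name = "X", resnum = 1L, resname = "GLY",
               role = c(rep(c("donor", "hydrogen"), n_d),
                        rep("acceptor", n_a), rep("none", n_rest)))
  }
  at <- rbind(mk_group(), mk_group())
  at$resnum <- seq_len(nrow(at))
  don <- which(at$role == "donor")
  bonds <- data.frame(donor = don, hydrogen = don + 1L)
  top <- topology(at, bonds)
  frame <- matrix(stats::runif(nrow(at) * 3, 0, box), nrow(at), 3)
  # hydrogens placed near their donors (bond-length scale)
  for (bi in seq_len(nrow(bonds))) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    frame[bonds$hydrogen[bi], ] <- frame[bonds$donor[bi], ] + 0.1 * u
  }
  list(frame = frame, top = top, gA = seq_len(n_per_group),
       gB = n_per_group + seq_len(n_per_group))
}

# -- brute-force non-bonded energy oracle ------------------------------------

oracle_energy <- function(frame, top, gA, gB, cutoff = 1.4) {
  f <- 138.935458
  ec <- 0; el <- 0
  for (i in gA) for (j in gB) {
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    if (r > cutoff) next
    ec <- ec + f * top$atoms$charge[i] * top$atoms$charge[j] / r
    c6 <- sqrt(top$atoms$c6[i] * top$atoms$c6[j])
    c12 <- sqrt(top$atoms$c12[i] * top$atoms$c12[j])
    el <- el + c12 / r^12 - c6 / r^6
  }
  list(e_coulomb = ec, e_lj = el, e_total = ec + el)
}

random_energy_config <- function(nA = 12, nB = 12, box = 2.0) {
  n <- nA + nB
  at <- data.frame(name = "X", resnum = seq_len(n), resname = "GLY",
                   charge = stats::runif(n, -1, 1),
                   c6 = stats::runif(n, 0, 0.01),
                   c12 = stats::runif(n, 0, 1e-5))
  top <- topology(at)
  frame <- matrix(stats::runif(n * 3, 0, box), n, 3)
  list(frame = frame, top = top, gA = seq_len(nA), gB = nA + seq_len(nB))
}

# -- similarity-transform Procrustes residual --------------------------------

# relative residual of the best similarity transform (rotation/reflection +
# scale + translation) mapping B onto A
procrustes_residual <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  sv <- svd(crossprod(Bc, Ac))
  R <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / sum(Bc^2)
  sqrt(sum((Ac - s * Bc %*% R)^2) / sum(Ac^2))
}
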