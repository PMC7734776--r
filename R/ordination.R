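#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds cluster-centre dissimilarities in a low-dimensional space so that
#' the rank order of embedded distances matches the rank order of the input
#' dissimilarities as closely as possible. The implementation follows
#' Kruskal's scheme: start from a random configuration, compute disparities
#' by monotone (isotonic) regression of embedded distances on the
#' dissimilarity ranks, take a steepest-descent step on stress-1
#' `sqrt( sum (d - dhat)^2 / sum d^2 )` with a back-tracking line search
#' (so stress never increases between iterations), and stop when the stress
#' improvement drops below `tol`. Tied dissimilarities share one disparity
#' value (the pooled fit under the monotonicity constraint), so an exactly
#' embeddable configuration with repeated distances is reproduced up to a
#' similarity transform rather than merely up to rank order.
#'
#' A deterministic classical-scaling (Torgerson) start plus several random
#' restarts are run and the lowest-stress solution kept (the classical
#' start wins ties, anchoring metrically faithful distance ratios when the
#' rank order alone would leave them free).
#' The result is deterministic given `seed`: the final configuration is
#' centred, rotated to its principal axes (sign-fixed), and scaled so the
#' root-mean-square embedded distance equals that of the input.
#'
#' @param d symmetric dissimilarity matrix (or `dist`) over at least 3
#'   items; not all zero.
#' @param dim embedding dimension (default 2).
#' @param seed integer seed controlling the random starts.
#' @param max_iter maximum descent iterations per restart (default 500).
#' @param tol stress-improvement convergence tolerance (default 1e-6).
#' @param n_restarts random restarts (default 4).
#' @return object of class `"nmds_embedding"`: list with `points`
#'   (`n x dim` matrix), `stress` (final stress-1), `seed`, `iterations`
#'   (of the winning restart), `stress_trace` (per-iteration stress of the
#'   winning restart, non-increasing), `restart_stress` (final stress of
#'   every start: the classical start first, then the random restarts).
#' @export
nonmetric_mds <- function(d, dim = 2L, seed = 1L, max_iter = 500L,
                          tol = 1e-6, n_restarts = 4L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 points to embed, got ", n)
  if (max(abs(d - t(d))) > 1e-9) stop("dissimilarity matrix is not symmetric")
  if (all(d <= 0)) stop("all dissimilarities are zero: nothing to embed")
  pair_i <- row(d)[lower.tri(d)]
  pair_j <- col(d)[lower.tri(d)]
  delta <- d[lower.tri(d)]

  pair_dist <- function(X) {
    dx <- X[pair_i, , drop = FALSE] - X[pair_j, , drop = FALSE]
    sqrt(rowSums(dx^2))
  }
  # tie blocks of equal dissimilarity share one disparity: isotonic
  # (weighted PAVA) regression of the per-block mean embedded distance
  tie_block <- match(delta, sort(unique(delta)))
  block_w <- tabulate(tie_block)
  disparities <- function(dd) {
    block_mean <- tapply_sum(dd, tie_block, length(block_w)) / block_w
    pava_weighted(block_mean, block_w)[tie_block]
  }
  stress_of <- function(dd, dhat) sqrt(sum((dd - dhat)^2) / sum(dd^2))

  run_once <- function(X0) {
    X <- X0
    dd <- pair_dist(X)
    if (all(dd == 0)) dd <- dd + 1e-12
    dhat <- disparities(dd)
    s <- stress_of(dd, dhat)
    trace <- s
    step <- 0.2
    iters <- 0L
    for (it in seq_len(max_iter)) {
      iters <- it
      if (s < 1e-12) break
      # majorization (Guttman transform) proposal: a large, usually
      # stress-reducing move; accepted only if stress-1 actually drops
      bw <- dhat / pmax(dd, 1e-12)
      Bf <- matrix(0, n, n)
      Bf[cbind(pair_i, pair_j)] <- -bw
      Bf[cbind(pair_j, pair_i)] <- -bw
      diag(Bf) <- -rowSums(Bf)
      Xg <- (Bf %*% X) / n
      ddg <- pair_dist(Xg)
      if (any(ddg > 0)) {
        dhg <- disparities(ddg)
        sg <- stress_of(ddg, dhg)
        if (sg < s) {
          gain <- s - sg
          X <- Xg; dd <- ddg; dhat <- dhg; s <- sg
          trace <- c(trace, s)
          if (gain < tol) break
          next
        }
      }
      # gradient of stress-1 w.r.t. the configuration, dhat held fixed
      Sstar <- sum((dd - dhat)^2); Tstar <- sum(dd^2)
      w <- ((dd - dhat) - (Sstar / Tstar) * dd) / (s * Tstar * pmax(dd, 1e-12))
      G <- matrix(0, n, ncol(X))
      diffs <- X[pair_i, , drop = FALSE] - X[pair_j, , drop = FALSE]
      wd <- w * diffs
      for (k in seq_len(ncol(X))) {
        G[, k] <- G[, k] +
          tapply_sum(wd[, k], pair_i, n) - tapply_sum(wd[, k], pair_j, n)
      }
      gn <- sqrt(sum(G^2))
      if (gn < 1e-14) break
      scale0 <- sqrt(sum(X^2) / n)
      improved <- FALSE
      for (half in 0:30) {
        Xn <- X - (step * scale0 / gn) * G
        ddn <- pair_dist(Xn)
        if (all(ddn == 0)) { step <- step / 2; next }
        dhn <- disparities(ddn)
        sn <- stress_of(ddn, dhn)
        if (sn <= s) { improved <- TRUE; break }
        step <- step / 2
      }
      if (!improved) break
      X <- Xn; dd <- ddn; dhat <- dhn
      gain <- s - sn
      s <- sn
      trace <- c(trace, s)
      step <- min(step * 1.5, 1)
      if (gain < tol) break
    }
    list(X = X, stress = s, trace = trace, iterations = iters)
  }

  # restart 0 starts from classical (Torgerson) scaling: among the many
  # rank-preserving solutions a small configuration admits, it anchors the
  # metrically faithful one; seeded random restarts can still win on stress
  set.seed(as.integer(seed))
  starts <- c(list(classical_start(d, dim)),
              lapply(seq_len(n_restarts), function(r)
                matrix(stats::runif(n * dim, -1, 1), n, dim)))
  best <- NULL
  restart_stress <- numeric(length(starts))
  for (r in seq_along(starts)) {
    if (is.null(starts[[r]])) { restart_stress[r] <- NA_real_; next }
    res <- run_once(starts[[r]])
    restart_stress[r] <- res$stress
    if (is.null(best) || res$stress < best$stress - 1e-9) best <- res
  }

  # canonical orientation: centre, principal axes, fixed signs, input scale
  X <- sweep(best$X, 2, colMeans(best$X))
  sv <- svd(X)
  X <- X %*% sv$v
  for (k in seq_len(ncol(X))) {
    lead <- which(abs(X[, k]) > 1e-12)[1]
    if (!is.na(lead) && X[lead, k] < 0) X[, k] <- -X[, k]
  }
  dd <- pair_dist(X)
  if (mean(dd^2) > 0) X <- X * sqrt(mean(delta^2) / mean(dd^2))
  rownames(X) <- rownames(d)

  structure(list(points = X, stress = best$stress, seed = as.integer(seed),
                 iterations = best$iterations, stress_trace = best$trace,
                 restart_stress = restart_stress),
            class = "nmds_embedding")
}

# classical (Torgerson) scaling start; NULL when degenerate
classical_start <- function(d, dim) {
  x <- tryCatch(suppressWarnings(stats::cmdscale(d, k = dim)),
                error = function(e) NULL)
  if (is.null(x) || ncol(x) < dim || !all(is.finite(x))) return(NULL)
  if (all(abs(x) < 1e-12)) return(NULL)
  unname(x)
}

# weighted pool-adjacent-violators: least-squares non-decreasing fit to y
pava_weighted <- function(y, w) {
  vals <- numeric(0); ws <- numeric(0); counts <- integer(0)
  for (i in seq_along(y)) {
    cv <- y[i]; cw <- w[i]; cn <- 1L
    while (length(vals) && vals[length(vals)] > cv) {
      m <- length(vals)
      cv <- (vals[m] * ws[m] + cv * cw) / (ws[m] + cw)
      cw <- ws[m] + cw
      cn <- counts[m] + cn
      vals <- vals[-m]; ws <- ws[-m]; counts <- counts[-m]
    }
    vals <- c(vals, cv); ws <- c(ws, cw); counts <- c(counts, cn)
  }
  rep(vals, counts)
}

# grouped sums of x by integer index 1..n (dense, fast, no factor overhead)
tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  for (v in seq_along(x)) out[idx[v]] <- out[idx[v]] + x[v]
  out
}

#' @export
print.nmds_embedding <- function(x, ...) {
  cat("Non-metric MDS embedding:", nrow(x$points), "points in",
      ncol(x$points), "dimensions\n")
  cat(sprintf("  stress-1 = %.4g after %d iterations (seed %d)\n",
              x$stress, x$iterations, x$seed))
  invisible(x)
}

#' Group embedded cluster centres into meta-clusters
#'
#' Replaces by-eye circling of the ordination plot with a deterministic
#' rule: meta-clusters are the connected components of the embedded points
#' under single linkage at `linkage_threshold` (two points are linked when
#' their embedded distance is at most the threshold). Meta-clusters are
#' numbered by their lowest-numbered member cluster.
#'
#' @param embedding a [nonmetric_mds()] result.
#' @param linkage_threshold positive distance threshold in embedding units
#'   (the embedding is scaled to the input dissimilarity scale, so for an
#'   RMSD-based ordination the threshold is in nm-like units).
#' @return object of class `"meta_clustering"`: list with `assignment`
#'   (integer meta-cluster id per embedded point) and `linkage_threshold`.
#' @export
group_metaclusters <- function(embedding, linkage_threshold) {
  stopifnot(inherits(embedding, "nmds_embedding"))
  if (!is.numeric(linkage_threshold) || length(linkage_threshold) != 1L ||
      linkage_threshold <= 0)
    stop("linkage_threshold must be a single positive number")
  X <- embedding$points
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  assignment <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (assignment[i]) next
    comp <- comp + 1L
    queue <- i
    assignment[i] <- comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(D[v, ] <= linkage_threshold & assignment == 0L)
      assignment[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  structure(list(assignment = assignment,
                 linkage_threshold = linkage_threshold),
            class = "meta_clustering")
}

#' @export
print.meta_clustering <- function(x, ...) {
  cat("Meta-clustering:", max(x$assignment), "meta-cluster(s) over",
      length(x$assignment), "embedded clusters (linkage threshold",
      x$linkage_threshold, ")\n")
  invisible(x)
}

#' Per-system residence fractions in each meta-cluster
#'
#' For each system, the fraction of that system's frames whose cluster
#' belongs to each meta-cluster — the fraction of time the loop resided in
#' that meta-conformation. Only the embedded (top-K) clusters are covered
#' by the meta-clustering; frames in clusters beyond the top K are reported
#' explicitly in an `"unassigned"` row per system, so per-system fractions
#' including the remainder sum to 1.
#'
#' @param meta a [group_metaclusters()] result over the first
#'   `length(meta$assignment)` clusters of `clustering`.
#' @param clustering the [daura_cluster()] result.
#' @param labels per-frame system labels.
#' @return data.frame with columns `system`, `meta_cluster` (integer as
#'   character, or `"unassigned"`), `n_frames`, `fraction`.
#' @export
metacluster_occupancy <- function(meta, clustering, labels) {
  stopifnot(inherits(meta, "meta_clustering"),
            inherits(clustering, "daura_clustering"))
  k <- length(meta$assignment)
  if (k > length(clustering$clusters))
    stop("meta-clustering covers ", k, " clusters but only ",
         length(clustering$clusters), " exist")
  if (length(labels) != clustering$total_frames)
    stop("labels length != total frames")
  labels <- as.character(labels)
  assign <- cluster_assignment(clustering)
  meta_of_frame <- ifelse(assign <= k,
                          as.character(meta$assignment[pmin(assign, k)]),
                          "unassigned")
  systems <- sort(unique(labels))
  metas <- c(as.character(sort(unique(meta$assignment))), "unassigned")
  tab <- table(factor(labels, levels = systems),
               factor(meta_of_frame, levels = metas))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("system", "meta_cluster", "n_frames")
  totals <- table(factor(labels, levels = systems))
  out$fraction <- out$n_frames / as.numeric(totals[out$system])
  out <- out[order(out$system, out$meta_cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}
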