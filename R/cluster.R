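#' Greedy neighbour-count (Daura/GROMOS) RMSD clustering
#'
#' The classic conformational clustering rule: every structure starts as a
#' candidate centre; the structure with the most neighbours within the RMSD
#' cut-off (the count includes the structure itself) becomes the centre of
#' the next cluster, it and its neighbours are removed, and the procedure
#' repeats until every structure is assigned. Ties in neighbour count are
#' broken by the lowest frame index, making the result deterministic.
#'
#' Clusters are numbered by descending member count (ties by earliest
#' centre index), so "cluster 1" is always the most populated conformation
#' and the member count of a cluster is proportional to the time the system
#' resided in that conformation.
#'
#' @param mat square symmetric distance matrix with zero diagonal and no
#'   negative entries (nm), e.g. from [pairwise_rmsd_matrix()].
#' @param cutoff neighbour cut-off in nm (default 0.2, the value at which
#'   loop conformations are resolved without over-differentiation).
#' @return object of class `"daura_clustering"`: list with `clusters` (list
#'   of `list(center, members)`, frame indices), `cutoff`, `total_frames`.
#' @export
daura_cluster <- function(mat, cutoff = 0.2) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number")
  if (any(mat < 0)) stop("distance matrix has negative entries")
  if (max(abs(mat - t(mat))) > 1e-9) stop("distance matrix is not symmetric")
  if (max(abs(diag(mat))) > 1e-9) stop("distance matrix diagonal is not zero")
  n <- nrow(mat)
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining)) {
    adj <- mat[remaining, remaining, drop = FALSE] <= cutoff
    counts <- rowSums(adj)
    best <- which.max(counts)            # first max = lowest frame index
    members <- remaining[adj[best, ]]
    clusters[[length(clusters) + 1L]] <-
      list(center = remaining[best], members = members)
    remaining <- remaining[!adj[best, ]]
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), 1L)
  centers <- vapply(clusters, `[[`, 1L, "center")
  ord <- order(-sizes, centers)
  structure(list(clusters = clusters[ord], cutoff = cutoff, total_frames = n),
            class = "daura_clustering")
}

#' @export
print.daura_clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 1L)
  cat("Daura clustering:", length(x$clusters), "clusters over",
      x$total_frames, "frames (cutoff", x$cutoff, "nm)\n")
  k <- min(length(sizes), 10L)
  cat("  sizes:", paste(sizes[seq_len(k)], collapse = ", "),
      if (length(sizes) > k) "..." else "", "\n")
  invisible(x)
}

#' Per-frame cluster assignment vector
#' @param clustering a [daura_cluster()] result
#' @return integer vector: cluster number (1 = largest) of each frame
#' @export
cluster_assignment <- function(clustering) {
  stopifnot(inherits(clustering, "daura_clustering"))
  out <- integer(clustering$total_frames)
  for (k in seq_along(clustering$clusters))
    out[clustering$clusters[[k]]$members] <- k
  if (any(out == 0L)) stop("internal error: unassigned frames")   # invariant
  out
}

#' Cluster composition by originating system
#'
#' For each cluster and each system label, the fraction of that *system's*
#' frames that fall in the cluster (denominators are per-system frame
#' totals, so statements like "82.5% of the apo structures are in cluster
#' 2" read off directly; each system's fractions sum to 1 over clusters).
#'
#' @param clustering a [daura_cluster()] result.
#' @param labels character vector of per-frame system labels, length
#'   `total_frames`.
#' @return data.frame with columns `cluster`, `system`, `n_frames`,
#'   `fraction`, ordered by cluster then system.
#' @export
cluster_composition <- function(clustering, labels) {
  stopifnot(inherits(clustering, "daura_clustering"))
  if (length(labels) != clustering$total_frames)
    stop("labels length (", length(labels), ") != total frames (",
         clustering$total_frames, ")")
  labels <- as.character(labels)
  assign <- cluster_assignment(clustering)
  systems <- sort(unique(labels))
  totals <- table(factor(labels, levels = systems))
  tab <- table(factor(assign, levels = seq_along(clustering$clusters)),
               factor(labels, levels = systems))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("cluster", "system", "n_frames")
  out$cluster <- as.integer(as.character(out$cluster))
  out$fraction <- out$n_frames / as.numeric(totals[out$system])
  out <- out[order(out$cluster, out$system), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster counts over a range of cut-offs
#'
#' Re-runs [daura_cluster()] at each cut-off. A larger cut-off merges
#' conformations (fewer clusters, more cross-system overlap); a smaller one
#' over-differentiates; the count is non-increasing in the cut-off.
#'
#' @param mat distance matrix as in [daura_cluster()].
#' @param cutoffs positive cut-offs (nm).
#' @return data.frame with columns `cutoff`, `n_clusters`.
#' @export
cutoff_sweep <- function(mat, cutoffs) {
  stopifnot(is.numeric(cutoffs), length(cutoffs) >= 1L, all(cutoffs > 0))
  data.frame(cutoff = cutoffs,
             n_clusters = vapply(cutoffs, function(co)
               length(daura_cluster(mat, co)$clusters), 1L))
}

#' Cluster count over growing trajectory prefixes (convergence diagnostic)
#'
#' Clusters the sub-trajectory of the first `window`, `2*window`, ... ps
#' and reports the cluster count per prefix. When sampling approaches
#' convergence the count levels off; the count is *reported*, never
#' asserted to be monotone (the greedy clustering gives no such guarantee).
#'
#' @param traj a [trajectory()] whose frame times are non-decreasing.
#' @param fit_sel,measure_sel see [pairwise_rmsd_matrix()].
#' @param cutoff clustering cut-off (nm).
#' @param window prefix step in ps; must give at least 2 prefixes.
#' @return data.frame with columns `prefix_ps`, `n_frames`, `n_clusters`.
#' @export
incremental_cluster_count <- function(traj, fit_sel, measure_sel = fit_sel,
                                      cutoff = 0.2, window) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.unsorted(traj$times))
    stop("prefix clustering needs non-decreasing frame times")
  tmax <- max(traj$times)
  ends <- seq(window, tmax, by = window)
  if (tmax > ends[length(ends)] + 1e-9) ends <- c(ends, tmax)
  if (length(ends) < 2L)
    stop("window ", window, " ps gives fewer than 2 prefixes")
  M <- pairwise_rmsd_matrix(traj, fit_sel, measure_sel)
  out <- lapply(ends, function(e) {
    idx <- which(traj$times <= e + 1e-9)
    nc <- if (length(idx) < 2L) length(idx)
          else length(daura_cluster(M[idx, idx, drop = FALSE], cutoff)$clusters)
    data.frame(prefix_ps = e, n_frames = length(idx), n_clusters = nc)
  })
  do.call(rbind, out)
}

#' Coordinates of cluster-centre frames as a trajectory
#'
#' Extracts the central structure of each of the first `k` clusters (the
#' representative conformations) as a new trajectory, e.g. for export with
#' [write_multimodel_pdb()] or for ordination of centre--centre distances.
#'
#' @param traj the clustered [trajectory()].
#' @param clustering a [daura_cluster()] result over the same frames.
#' @param k number of top clusters (default: all).
#' @return a [trajectory()] of `k` frames in cluster order; system labels
#'   carry each centre's originating system when `traj` is labelled.
#' @export
cluster_centers <- function(traj, clustering, k = length(clustering$clusters)) {
  stopifnot(inherits(traj, "trajectory"), inherits(clustering, "daura_clustering"))
  k <- min(k, length(clustering$clusters))
  centers <- vapply(clustering$clusters[seq_len(k)], `[[`, 1L, "center")
  structure(list(topology = traj$topology,
                 coords = traj$coords[, , centers, drop = FALSE],
                 times = traj$times[centers],
                 system = if (!is.null(traj$system)) traj$system[centers]),
            class = "trajectory")
}
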