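#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the analysis in one validated object. The
#' defaults are the working parameters of the whole pipeline: 0.2 nm
#' clustering cut-off, 30 degrees / 0.35 nm hydrogen-bond criteria, 1.4 nm
#' non-bonded cut-off, 100 and 10 kJ/mol histogram bin widths, and the top
#' 25 clusters carried into the ordination.
#'
#' @param out_dir output directory (created if absent).
#' @param plans named list of [state_plan()]s (one per system), e.g. from
#'   [default_three_system_plans()]; names are the system labels.
#' @param loop_query,flank_query selection expressions for the loop
#'   (measured) and flanking (fitted) atoms. Defaults are taken from the
#'   plans' shared geometry when available.
#' @param cluster_cutoff Daura clustering cut-off, nm.
#' @param mds_seed,mds_tol,mds_max_iter,mds_restarts ordination controls
#'   (see [nonmetric_mds()]).
#' @param top_k number of largest clusters embedded; frames in later
#'   clusters are reported as "unassigned" in occupancies.
#' @param meta_threshold single-linkage threshold for meta-cluster
#'   grouping, embedding units (input-dissimilarity scale).
#' @param hbond_dist,hbond_angle hydrogen-bond criteria (nm, degrees).
#' @param energy_cutoff non-bonded pair cut-off, nm.
#' @param ebin_wide,ebin_narrow energy histogram bin widths, kJ/mol.
#' @param hbond_schedule on/off schedule for the bundled hydrogen-bond
#'   fixture stage (default: a deterministic 200-frame pattern).
#' @param dimer_separations separations (nm) for the bundled charged-dimer
#'   energy stage.
#' @param write_rmsd_matrix write the full frame-frame RMSD matrix CSV
#'   (`TRUE`/`FALSE`/`"auto"` = only when the ensemble has at most 1500
#'   frames; the file grows quadratically).
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            plans = default_three_system_plans(),
                            loop_query = NULL, flank_query = NULL,
                            cluster_cutoff = 0.2,
                            mds_seed = 1L, mds_tol = 1e-6,
                            mds_max_iter = 500L, mds_restarts = 4L,
                            top_k = 25L, meta_threshold = 0.8,
                            hbond_dist = 0.35, hbond_angle = 30,
                            energy_cutoff = 1.4,
                            ebin_wide = 100, ebin_narrow = 10,
                            hbond_schedule = rep(c(TRUE, TRUE, TRUE, FALSE),
                                                 50L),
                            dimer_separations = seq(0.5, 2.0, by = 0.05),
                            write_rmsd_matrix = "auto") {
  stopifnot(is.list(plans), length(plans) >= 1L,
            all(vapply(plans, inherits, TRUE, "state_plan")))
  if (is.null(names(plans)) || any(!nzchar(names(plans))))
    stop("plans must be a named list (names are system labels)")
  geo <- attr(plans, "geometry")
  if (is.null(loop_query)) {
    if (is.null(geo)) stop("loop_query is required when plans carry no geometry")
    loop_query <- geo$loop_query
  }
  if (is.null(flank_query)) {
    if (is.null(geo)) stop("flank_query is required when plans carry no geometry")
    flank_query <- geo$flank_query
  }
  num <- list(cluster_cutoff = cluster_cutoff, mds_tol = mds_tol,
              mds_max_iter = mds_max_iter, mds_restarts = mds_restarts,
              top_k = top_k, meta_threshold = meta_threshold,
              hbond_dist = hbond_dist, hbond_angle = hbond_angle,
              energy_cutoff = energy_cutoff, ebin_wide = ebin_wide,
              ebin_narrow = ebin_narrow)
  for (nm in names(num))
    if (!is.numeric(num[[nm]]) || length(num[[nm]]) != 1L || num[[nm]] <= 0)
      stop("config parameter '", nm, "' must be a single positive number")
  structure(list(out_dir = out_dir, plans = plans,
                 loop_query = loop_query, flank_query = flank_query,
                 cluster_cutoff = cluster_cutoff, mds_seed = as.integer(mds_seed),
                 mds_tol = mds_tol, mds_max_iter = as.integer(mds_max_iter),
                 mds_restarts = as.integer(mds_restarts),
                 top_k = as.integer(top_k), meta_threshold = meta_threshold,
                 hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 energy_cutoff = energy_cutoff, ebin_wide = ebin_wide,
                 ebin_narrow = ebin_narrow,
                 hbond_schedule = as.logical(hbond_schedule),
                 dimer_separations = dimer_separations,
                 write_rmsd_matrix = write_rmsd_matrix),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate each system's ensemble, concatenate them into one labelled
#' ensemble, compute per-atom RMSF, build the loop RMSD matrix (flanking
#' fit), cluster it, ordinate the cluster-centre distances, group
#' meta-clusters and account their per-system occupancies, then run the
#' hydrogen-bond and non-bonded-energy stages on their bundled fixtures.
#' Every output is a plain-text CSV/JSON/PDB file under `out_dir`, and a
#' manifest records parameters, seeds and MD5 checksums of every file;
#' re-running the same configuration reproduces every output byte for
#' byte.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[loopstates] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  put_csv <- function(df, f) {
    utils::write.csv(df, pth(f), row.names = FALSE, quote = FALSE)
    files <<- c(files, f)
  }

  say("simulate: ", length(config$plans), " system(s)")
  sims <- lapply(config$plans, generate_loop_ensemble)
  ens <- concatenate_trajectories(lapply(sims, `[[`, "trajectory"),
                                  labels = names(config$plans))
  truth <- data.frame(frame = seq_len(n_frames(ens)),
                      system = ens$system,
                      true_state = unlist(lapply(sims, `[[`, "states"),
                                          use.names = FALSE))
  put_csv(truth, "true_states.csv")

  loop_sel <- select_atoms(ens$topology, config$loop_query)
  flank_sel <- select_atoms(ens$topology, config$flank_query)

  say("rmsf: ", length(union(loop_sel, flank_sel)), " measured atoms")
  rmsf_rows <- lapply(names(sims), function(lab) {
    r <- rmsf(sims[[lab]]$trajectory, fit_sel = flank_sel,
              measure_sel = sort(union(loop_sel, flank_sel)),
              reference = "first")
    cbind(system = lab, r)
  })
  put_csv(do.call(rbind, rmsf_rows), "rmsf.csv")

  say("cluster: RMSD matrix over ", n_frames(ens), " frames")
  M <- pairwise_rmsd_matrix(ens, fit_sel = flank_sel, measure_sel = loop_sel)
  wm <- config$write_rmsd_matrix
  if (isTRUE(wm) || (identical(wm, "auto") && n_frames(ens) <= 1500L)) {
    dfm <- as.data.frame(M)
    names(dfm) <- paste0(ens$system, ".", seq_len(ncol(M)))
    put_csv(dfm, "rmsd_matrix.csv")
  }
  cl <- daura_cluster(M, cutoff = config$cluster_cutoff)
  say("cluster: ", length(cl$clusters), " clusters at ",
      config$cluster_cutoff, " nm")
  assign <- cluster_assignment(cl)
  put_csv(data.frame(frame = seq_len(n_frames(ens)), time_ps = ens$times,
                     system = ens$system, cluster = assign),
          "cluster_membership.csv")
  put_csv(cluster_composition(cl, ens$system), "cluster_composition.csv")
  jsonlite::write_json(
    list(cutoff = cl$cutoff, total_frames = cl$total_frames,
         clusters = lapply(cl$clusters, function(x)
           list(center = x$center, size = length(x$members),
                members = x$members))),
    pth("clusters.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, "clusters.json")

  k <- min(config$top_k, length(cl$clusters))
  centers <- cluster_centers(ens, cl, k)
  write_multimodel_pdb(centers, pth("cluster_centers.pdb"))
  files <- c(files, "cluster_centers.pdb")

  say("mds: embedding ", k, " cluster centres")
  center_idx <- vapply(cl$clusters[seq_len(k)], `[[`, 1L, "center")
  Dc <- M[center_idx, center_idx, drop = FALSE]
  put_csv(as.data.frame(Dc), "center_rmsd_matrix.csv")
  if (k >= 3L) {
    emb <- nonmetric_mds(Dc, dim = 2L, seed = config$mds_seed,
                         max_iter = config$mds_max_iter, tol = config$mds_tol,
                         n_restarts = config$mds_restarts)
    meta <- group_metaclusters(emb, config$meta_threshold)
    sizes <- vapply(cl$clusters[seq_len(k)], function(x) length(x$members), 1L)
    put_csv(data.frame(cluster = seq_len(k), x = emb$points[, 1],
                       y = emb$points[, 2], meta_cluster = meta$assignment,
                       size = sizes,
                       center_system = if (!is.null(centers$system))
                         centers$system else NA_character_),
            "embedding.csv")
    occ <- metacluster_occupancy(meta, cl, ens$system)
    put_csv(occ, "metacluster_occupancy.csv")
    say("mds: stress-1 = ", signif(emb$stress, 4), "; ",
        max(meta$assignment), " meta-cluster(s)")
    mds_meta <- list(stress = emb$stress, seed = emb$seed,
                     iterations = emb$iterations,
                     meta_threshold = config$meta_threshold,
                     n_meta = max(meta$assignment))
  } else {
    say("mds: skipped (fewer than 3 clusters)")
    mds_meta <- list(skipped = TRUE, n_clusters = k)
  }

  say("hbonds: ", length(config$hbond_schedule), "-frame fixture")
  hb <- generate_hbond_fixture(config$hbond_schedule)
  hb_series <- hbond_count_series(hb$trajectory, hb$groupA, hb$groupB,
                                  dist_cutoff = config$hbond_dist,
                                  angle_cutoff = config$hbond_angle)
  put_csv(data.frame(frame = seq_along(hb_series), n_hbonds = hb_series),
          "hbond_series.csv")
  put_csv(hbond_histogram(hb_series), "hbond_histogram.csv")

  say("energies: ", length(config$dimer_separations), "-frame dimer fixture")
  dim_fix <- generate_charged_dimer(config$dimer_separations)
  en <- nonbonded_energy_series(dim_fix$trajectory, dim_fix$groupA,
                                dim_fix$groupB, cutoff = config$energy_cutoff)
  put_csv(en, "energy_series.csv")
  put_csv(energy_histogram(en$e_total, config$ebin_wide),
          "energy_histogram_wide.csv")
  put_csv(energy_histogram(en$e_total, config$ebin_narrow),
          "energy_histogram_narrow.csv")

  params <- config[setdiff(names(config), c("plans", "out_dir"))]
  manifest <- list(
    package = "loopstates",
    version = as.character(utils::packageVersion("loopstates")),
    parameters = params,
    systems = lapply(config$plans, function(p)
      list(label = p$system_label, n_frames = p$n_frames, seed = p$seed,
           occupancies = p$occupancies, noise_sigma = p$noise_sigma)),
    n_clusters = length(cl$clusters),
    mds = mds_meta,
    checksums = as.list(tools::md5sum(vapply(files, pth, ""))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  say("done: ", length(files) + 1L, " files in ", config$out_dir)
  invisible(manifest)
}
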