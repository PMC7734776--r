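#!/usr/bin/env Rscript
# Stage 4 -- ordination of cluster centres and meta-cluster occupancies.
#
# The centre-to-centre loop RMSD matrix is embedded in 2D by non-metric
# MDS; single-linkage components of the embedding at 0.8 (input scale)
# define the meta-conformations; per-system residence fractions follow.
# The study design plants three meta-conformations: one shared by all
# systems, one exclusive to apo, one exclusive to ligand A.

library(loopstates)

cl_dir <- "results/cluster"
if (!file.exists(file.path(cl_dir, "center_rmsd_matrix.csv")))
  stop("run analysis/03_cluster.R first (missing ", cl_dir, ")")
out <- "results/ordination"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

Dc <- as.matrix(read.csv(file.path(cl_dir, "center_rmsd_matrix.csv")))
dimnames(Dc) <- NULL
memb <- read.csv(file.path(cl_dir, "membership.csv"))

emb <- nonmetric_mds(Dc, dim = 2, seed = 1)
print(emb)
meta <- group_metaclusters(emb, linkage_threshold = 0.8)
print(meta)

# rebuild the clustering object from the membership table for accounting
clusters <- lapply(sort(unique(memb$cluster)), function(k)
  list(center = which(memb$cluster == k)[1],
       members = which(memb$cluster == k)))
clustering <- structure(list(clusters = clusters, cutoff = 0.2,
                             total_frames = nrow(memb)),
                        class = "daura_clustering")

occ <- metacluster_occupancy(meta, clustering, memb$system)
write.csv(occ, file.path(out, "metacluster_occupancy.csv"), row.names = FALSE)
write.csv(data.frame(cluster = seq_len(nrow(emb$points)),
                     x = emb$points[, 1], y = emb$points[, 2],
                     meta_cluster = meta$assignment),
          file.path(out, "embedding.csv"), row.names = FALSE)

cat("\nPer-system residence in each meta-conformation:\n")
print(subset(occ, fraction > 0))
cat("\nWrote ordination outputs to", out, "\n")
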