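# Two-round k-means binarization of the continuous heat map.

#' Clustering configuration for heat-map binarization
#'
#' @param atoms_per_cluster First-round cluster budget: `k1 =
#'   ceiling(n_protein_atoms / atoms_per_cluster)` (default 1000).
#' @param score_weight Multiplier applied to the standardized score dimension
#'   before clustering, biasing clusters towards score structure (default 5).
#' @param k_second_round Clusters in the second round over first-round mean
#'   scores (default 2: binding vs non-binding).
#' @param n_init k-means restarts (best of `n_init`).
#' @param candidate_distance Voxels farther than this (Angstrom) from every
#'   surface protein atom are excluded from clustering (default 6).
#' @param seed RNG seed for k-means initialization.
#' @return A list with class `vb_cluster_config`.
#' @export
cluster_config <- function(atoms_per_cluster = 1000, score_weight = 5,
                           k_second_round = 2, n_init = 10,
                           candidate_distance = 6, seed = 1) {
  structure(list(atoms_per_cluster = as.integer(atoms_per_cluster),
                 score_weight = score_weight,
                 k_second_round = as.integer(k_second_round),
                 n_init = as.integer(n_init),
                 candidate_distance = candidate_distance,
                 seed = as.integer(seed)),
            class = "vb_cluster_config")
}

# Voxel linear indices within `cutoff` of any of the given atom coordinates.
candidate_voxels <- function(spec, xyz, cutoff) {
  cx <- axis_centers(spec, 1)
  cy <- axis_centers(spec, 2)
  cz <- axis_centers(spec, 3)
  keep <- array(FALSE, spec$shape)
  c2 <- cutoff^2
  for (i in seq_len(nrow(xyz))) {
    p <- xyz[i, ]
    rx <- which(abs(cx - p[1]) <= cutoff)
    ry <- which(abs(cy - p[2]) <= cutoff)
    rz <- which(abs(cz - p[3]) <= cutoff)
    if (!length(rx) || !length(ry) || !length(rz)) next
    d2 <- outer(outer((cx[rx] - p[1])^2, (cy[ry] - p[2])^2, "+"),
                (cz[rz] - p[3])^2, "+")
    keep[rx, ry, rz] <- keep[rx, ry, rz] | (d2 <= c2)
  }
  which(keep)
}

#' Binarize a heat map by two rounds of k-means
#'
#' Candidate voxels (those within `candidate_distance` of a surface protein
#' atom) become points `(x, y, z, score)`; every dimension is standardized to
#' zero mean / unit variance and the score dimension is then inflated by
#' `score_weight`. Round one clusters the points into `k1 =
#' ceiling(n_atoms / atoms_per_cluster)` clusters; round two clusters the
#' first-round mean scores into two groups, and every point in the
#' higher-mean group is called binding. Degenerate inputs (no candidates, or
#' zero score variance) yield an all-zero mask. With `k1 = 1` the single
#' cluster is called binding iff its mean score exceeds 0.5.
#'
#' @param h A `vb_heatmap`.
#' @param s The typed `vb_structure` (protein atom count sets `k1`; surface
#'   atoms define the candidate region).
#' @param g The `vb_grid` the heat map is aligned with.
#' @param config A [cluster_config()].
#' @return List: `values` (3D binary array), `summary` (per-cluster table from
#'   [cluster_summary()]).
#' @export
binarize_heatmap <- function(h, s, g, config = cluster_config()) {
  stopifnot(inherits(h, "vb_heatmap"), inherits(s, "vb_structure"),
            inherits(g, "vb_grid"))
  spec <- g$spec
  if (!all(dim(h$values) == spec$shape)) {
    stop("heat map not aligned with grid")
  }
  out <- array(0L, spec$shape)
  a <- s$atoms
  prot <- a$molecule == MOL_PROTEIN
  n_atoms <- sum(prot)
  surf <- prot & (a$surface %in% TRUE)
  if (!any(surf)) {
    warning("no surface atoms; returning empty prediction")
    return(list(values = out, summary = NULL))
  }
  cand <- candidate_voxels(spec, as.matrix(a[surf, c("x", "y", "z")]),
                           config$candidate_distance)
  if (!length(cand)) {
    warning("no candidate voxels; returning empty prediction")
    return(list(values = out, summary = NULL))
  }
  score <- h$values[cand]
  if (stats::sd(score) == 0) {
    return(list(values = out, summary = NULL))
  }
  ijk <- arrayInd(cand, spec$shape)
  feats <- cbind(sweep(ijk - 0.5, 2, spec$origin, "+"), score)
  feats <- scale(feats)
  feats[is.nan(feats)] <- 0           # a flat spatial dimension carries no signal
  feats[, 4] <- feats[, 4] * config$score_weight
  k1 <- max(1L, as.integer(ceiling(n_atoms / config$atoms_per_cluster)))
  k1 <- min(k1, nrow(feats))
  set.seed(config$seed)
  if (k1 == 1L) {
    labels <- rep(1L, nrow(feats))
  } else {
    km <- stats::kmeans(feats, centers = k1, nstart = config$n_init,
                        iter.max = 100)
    labels <- km$cluster
  }
  summ <- cluster_summary(labels, score)
  if (k1 == 1L) {
    binding_clusters <- if (summ$mean_score[1] > 0.5) 1L else integer(0)
  } else if (nrow(summ) <= config$k_second_round) {
    # each first-round cluster is its own group; binding = highest mean
    binding_clusters <- summ$cluster[which.max(summ$mean_score)]
  } else {
    km2 <- stats::kmeans(matrix(summ$mean_score, ncol = 1),
                         centers = config$k_second_round,
                         nstart = config$n_init, iter.max = 100)
    grp_means <- tapply(summ$mean_score, km2$cluster, mean)
    top <- as.integer(names(grp_means)[which.max(grp_means)])
    binding_clusters <- summ$cluster[km2$cluster == top]
  }
  summ$binding <- summ$cluster %in% binding_clusters
  out[cand[labels %in% binding_clusters]] <- 1L
  list(values = out, summary = summ)
}

#' Per-cluster score summary
#'
#' @param labels Integer cluster labels from the first k-means round.
#' @param scores Heat-map scores of the clustered points.
#' @return Data frame: `cluster`, `size`, `mean_score` (and `binding` when
#'   produced by [binarize_heatmap()]).
#' @export
cluster_summary <- function(labels, scores) {
  if (inherits(scores, "vb_heatmap")) scores <- scores$values
  cl <- sort(unique(labels))
  data.frame(
    cluster = cl,
    size = as.integer(table(factor(labels, levels = cl))),
    mean_score = as.numeric(tapply(scores, factor(labels, levels = cl), mean))
  )
}
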