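# Fake prediction scaffolding: a box of surface protein atoms, an empty grid
# and a synthetic heat map.
fake_pred <- function(n_atoms, shape = c(20, 20, 20), seed = 42) {
  set.seed(seed)
  atoms <- make_structure(matrix(runif(n_atoms * 3, 0, shape[1]), ncol = 3))
  atoms$atoms$sasa <- 1
  atoms$atoms$surface <- TRUE
  atoms$atoms$type <- "C3P"
  spec <- structure(list(origin = c(0, 0, 0), shape = as.integer(shape),
                         voxel_size = 1, padding = 0, n_channels = 17L),
                    class = "vb_grid_spec")
  g <- structure(list(spec = spec, values = array(0L, c(shape, 17))),
                 class = "vb_grid")
  list(s = atoms, g = g, spec = spec)
}

blob_heatmap <- function(spec, lo = 9, hi = 12, bg = 0.05, fg = 0.9) {
  h <- array(bg, spec$shape)
  h[lo:hi, lo:hi, lo:hi] <- fg
  structure(list(spec = spec, values = h), class = "vb_heatmap")
}

blob_lin <- function(spec, lo = 9, hi = 12) {
  idx <- as.matrix(expand.grid(lo:hi, lo:hi, lo:hi))
  (idx[, 3] - 1) * prod(spec$shape[1:2]) + (idx[, 2] - 1) * spec$shape[1] +
    idx[, 1]
}

test_that("first-round k follows the atoms-per-1000 ceiling rule", {
  cc <- cluster_config()
  expect_equal(ceiling(1000 / cc$atoms_per_cluster), 1)
  expect_equal(ceiling(1001 / cc$atoms_per_cluster), 2)
  # observed through the clustering output: 1500 atoms -> 2 clusters
  fx <- fake_pred(1500)
  bin <- binarize_heatmap(blob_heatmap(fx$spec), fx$s, fx$g,
                          cluster_config(seed = 5))
  expect_equal(nrow(bin$summary), 2)
  fx1 <- fake_pred(900)
  bin1 <- binarize_heatmap(blob_heatmap(fx1$spec), fx1$s, fx1$g,
                           cluster_config(seed = 5))
  expect_equal(nrow(bin1$summary), 1)
})

test_that("a planted high-score blob is recovered exactly", {
  fx <- fake_pred(1500)
  h <- blob_heatmap(fx$spec)
  bin <- binarize_heatmap(h, fx$s, fx$g, cluster_config(seed = 5))
  expect_setequal(which(bin$values == 1L), blob_lin(fx$spec))
  expect_true(bin$summary$binding[which.max(bin$summary$mean_score)])
  # also with several first-round clusters (3500 atoms -> k1 = 4)
  fx4 <- fake_pred(3500)
  bin4 <- binarize_heatmap(h, fx4$s, fx4$g, cluster_config(seed = 5))
  expect_setequal(which(bin4$values == 1L), blob_lin(fx$spec))
})

test_that("degenerate heat maps yield an empty prediction", {
  fx <- fake_pred(1200)
  flat <- structure(list(spec = fx$spec, values = array(0.3, fx$spec$shape)),
                    class = "vb_heatmap")
  expect_equal(sum(binarize_heatmap(flat, fx$s, fx$g)$values), 0)
  # k1 = 1 single cluster: binding iff mean score > 0.5
  fx1 <- fake_pred(500)
  high <- structure(list(spec = fx1$spec,
                         values = array(0.9, fx1$spec$shape)),
                    class = "vb_heatmap")
  h <- high$values
  h[1] <- 0.89                                 # break exact zero variance
  high$values <- h
  expect_gt(sum(binarize_heatmap(high, fx1$s, fx1$g)$values), 0)
})

test_that("prediction is confined to the candidate region near the surface", {
  fx <- fake_pred(1500, shape = c(30, 30, 30))
  # push all atoms into one corner so part of the grid is out of range
  fx$s$atoms[, c("x", "y", "z")] <- fx$s$atoms[, c("x", "y", "z")] / 3
  h <- blob_heatmap(fx$spec, lo = 2, hi = 5)
  bin <- binarize_heatmap(h, fx$s, fx$g, cluster_config(seed = 5))
  cand <- voxbind:::candidate_voxels(
    fx$spec, as.matrix(fx$s$atoms[, c("x", "y", "z")]), 6)
  expect_true(all(which(bin$values == 1L) %in% cand))
})

test_that("standardization makes the call invariant to score shifts", {
  fx <- fake_pred(1500)
  h1 <- blob_heatmap(fx$spec, bg = 0.05, fg = 0.60)
  h2 <- blob_heatmap(fx$spec, bg = 0.35, fg = 0.90)   # +0.3 everywhere
  b1 <- binarize_heatmap(h1, fx$s, fx$g, cluster_config(seed = 5))
  b2 <- binarize_heatmap(h2, fx$s, fx$g, cluster_config(seed = 5))
  expect_identical(b1$values, b2$values)
})

test_that("cluster summaries partition the candidate points", {
  fx <- fake_pred(2500)
  bin <- binarize_heatmap(blob_heatmap(fx$spec), fx$s, fx$g,
                          cluster_config(seed = 7))
  cand <- voxbind:::candidate_voxels(
    fx$spec, as.matrix(fx$s$atoms[, c("x", "y", "z")]), 6)
  expect_equal(sum(bin$summary$size), length(cand))
  expect_true(all(bin$summary$mean_score >= 0 & bin$summary$mean_score <= 1))
  # direct cluster_summary arithmetic
  summ <- cluster_summary(c(1, 1, 2), c(0.8, 0.8, 0.1))
  expect_equal(summ$mean_score, c(0.8, 0.1))
  expect_equal(summ$size, c(2L, 1L))
})

test_that("binarization is deterministic given the seed", {
  fx <- fake_pred(2500)
  h <- blob_heatmap(fx$spec)
  b1 <- binarize_heatmap(h, fx$s, fx$g, cluster_config(seed = 11))
  b2 <- binarize_heatmap(h, fx$s, fx$g, cluster_config(seed = 11))
  expect_identical(b1$values, b2$values)
})
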