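typed_fixture <- function(seed = 17, n_residues = 8, dna_length = 4,
                          contact = 4) {
  s <- generate_complex(synth_spec(seed = seed, n_residues = n_residues,
                                   dna_length = dna_length,
                                   contact_distance = contact))
  assign_atom_types(flag_surface(compute_sasa(s)))
}

test_that("grid covers the protein bounding box plus padding", {
  s <- make_structure(rbind(c(0.2, 1, 1), c(10.2, 1, 1)))
  spec <- grid_spec(s, padding = 3)
  # 10-Angstrom extent + 3 padding each side + 1 -> 17 voxels
  expect_equal(spec$shape[1], 17L)
  expect_error(grid_spec(matrix(numeric(0), ncol = 3)), "empty coordinate")
})

test_that("voxelization writes one-hot channels for protein atoms only", {
  s <- typed_fixture()
  g <- voxelize(s)
  expect_equal(dim(g$values)[4], 17)
  per_voxel <- apply(g$values, 1:3, sum)
  expect_true(all(per_voxel <= 1))               # one-hot or empty
  n_prot <- sum(s$atoms$molecule == "PROTEIN")
  expect_lte(sum(g$values), n_prot)
  expect_gt(sum(g$values), 0)
})

test_that("a single typed atom occupies exactly its nearest voxel", {
  s <- make_structure(c(2.4, 2.4, 2.4))
  s$atoms$surface <- TRUE
  s$atoms$type <- "C3N"
  spec <- grid_spec(s, padding = 2)
  g <- voxelize(s, spec)
  expect_equal(sum(g$values), 1)
  idx <- which(g$values == 1, arr.ind = TRUE)
  expect_equal(unname(idx[1, 4]), match("C3N", list_atom_types()))
  ctr <- spec$origin + unname(idx[1, 1:3]) - 0.5
  expect_true(all(abs(ctr - 2.4) <= 0.5))
})

test_that("voxel collisions resolve to the atom nearest the centre", {
  s <- make_structure(rbind(c(2.31, 2.5, 2.5), c(2.49, 2.5, 2.5)))
  s$atoms$surface <- TRUE
  s$atoms$type <- c("C3N", "O3P")
  spec <- grid_spec(s, padding = 2)
  g <- voxelize(s, spec)
  expect_equal(sum(g$values), 1)
  # second atom (x = 2.49) is nearer the voxel centre at x = 2.5
  expect_equal(sum(g$values[, , , match("O3P", list_atom_types())]), 1)
})

test_that("binding rule examples evaluate as stated", {
  mk <- function(pd_x) {
    a <- rbind(make_structure(c(0, 0, 0))$atoms,
               make_structure(c(pd_x, 0, 0), element = "P", molecule = "DNA",
                              name = "P", resid = "DA")$atoms)
    a$serial <- 1:2
    voxbind:::new_structure("pair", a)
  }
  spec <- grid_spec(make_structure(rbind(c(-2, -2, -2), c(12, 2, 2))),
                    padding = 3)
  # P and D 4 apart: voxel between them satisfies all three distances
  m <- label_binding_voxels(mk(4), spec)
  v <- voxbind:::world_to_index(matrix(c(2, 0, 0), 1), spec)
  expect_equal(m$values[v[1], v[2], v[3]], 1L)
  # P and D 11 apart: mid voxel within 6 of both but the pair itself exceeds 6
  m2 <- label_binding_voxels(mk(11), spec)
  expect_equal(sum(m2$values), 0)
})

test_that("pair-marking labelling equals the exhaustive triple-loop oracle", {
  for (seed in 1:6) {
    s <- random_complex(seed)
    spec <- grid_spec(s, padding = 3)
    m <- label_binding_voxels(s, spec)
    expect_identical(m$values, mask_oracle(s, spec), label = paste("seed", seed))
  }
})

test_that("mask positivity is monotone in the cutoff", {
  s <- random_complex(99)
  spec <- grid_spec(s, padding = 3)
  m5 <- label_binding_voxels(s, spec, cutoff = 5)
  m6 <- label_binding_voxels(s, spec, cutoff = 6)
  expect_true(all(m6$values[m5$values == 1L] == 1L))
  expect_gte(sum(m6$values), sum(m5$values))
})

test_that("the rotation set is the 24-element proper cubic group", {
  rots <- enumerate_rotations()
  expect_length(rots, 24)
  keys <- vapply(rots, function(m) paste(m, collapse = ","), character(1))
  expect_equal(anyDuplicated(keys), 0)
  expect_true(all(vapply(rots, function(m) round(det(m)) == 1, logical(1))))
  expect_identical(rots[[1]], diag(1L, 3))
  # closure over all 576 products
  for (a in rots) {
    for (b in rots) {
      expect_true(paste(a %*% b, collapse = ",") %in% keys)
    }
  }
})

test_that("rotation of grids preserves content and inverts exactly", {
  s <- typed_fixture(seed = 23)
  g <- voxelize(s)
  m <- label_binding_voxels(s, g$spec)
  rots <- enumerate_rotations()
  counts <- apply(g$values, 4, sum)
  for (r in rots[c(1, 5, 9, 14, 20, 24)]) {
    gr <- rotate_grid(g, r)
    expect_equal(apply(gr$values, 4, sum), counts)   # channel multiset
    back <- rotate_grid(gr, t(r))                    # inverse = transpose
    expect_identical(back$values, g$values)
    expect_equal(back$spec$origin, g$spec$origin)
    mr <- rotate_grid(m, r)
    expect_equal(sum(mr$values), sum(m$values))
  }
  expect_identical(rotate_grid(g, rots[[1]])$values, g$values)
  expect_error(rotate_grid(g, matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3)),
               "not one of the 24")
})

test_that("rotating coordinates commutes with rotating the grid", {
  # half-integer coordinates keep atoms away from voxel boundaries under
  # every signed permutation, so the commutation is exact
  set.seed(41)
  xyz <- matrix(sample(-5:5, 30, replace = TRUE) + 0.5, ncol = 3)
  s <- make_structure(xyz)
  s$atoms$surface <- TRUE
  s$atoms$type <- sample(list_atom_types()[1:4], 10, replace = TRUE)
  g <- voxelize(s, grid_spec(s, padding = 3))
  for (r in enumerate_rotations()) {
    sr <- s
    rot <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(r)
    sr$atoms$x <- rot[, 1]; sr$atoms$y <- rot[, 2]; sr$atoms$z <- rot[, 3]
    direct <- voxelize(sr, grid_spec(sr, padding = 3))
    via_grid <- rotate_grid(g, r)
    expect_identical(direct$values, via_grid$values)
  }
})

test_that("archives round-trip bit-identically with one file per rotation", {
  s <- typed_fixture(seed = 29, n_residues = 5, dna_length = 2)
  g <- voxelize(s)
  m <- label_binding_voxels(s, g$spec)
  dir <- withr::local_tempdir()
  rots <- enumerate_rotations()
  paths <- vapply(seq_along(rots), function(i) {
    save_archive(rotate_grid(g, rots[[i]]), rotate_grid(m, rots[[i]]),
                 s$id, i - 1L, dir)
  }, character(1))
  expect_length(unique(paths), 24)
  back <- load_archive(paths[1])
  expect_identical(back$grid$values, g$values)
  expect_identical(back$mask$values, m$values)
  expect_equal(back$rotation_id, 0L)
  expect_error(save_archive(g, m, s$id, 24, dir), "0..23")
  expect_error(save_archive(g, m, s$id, -1, dir), "0..23")
})
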