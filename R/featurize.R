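# Voxelization at 1 Angstrom, triple 6-Angstrom binding-voxel labelling,
# the 24 proper cubic rotations, and archive persistence.

#' Grid specification covering a structure
#'
#' Builds the 1-Angstrom grid that covers the protein bounding box plus
#' `padding` Angstrom on every side. The origin is the world coordinate of the
#' lower corner of voxel (1,1,1); the centre of voxel `i` (1-based) lies at
#' `origin + i - 0.5`. World-to-index mapping is `floor(coord - origin) + 1`
#' with half-open cells.
#'
#' @param s A classified `vb_structure` with at least one protein atom, or a
#'   3 x n coordinate matrix.
#' @param padding Angstrom of margin beyond the protein bounding box
#'   (default 3).
#' @param n_channels Number of one-hot channels (16 atom types + 1
#'   non-surface sentinel).
#' @return A list with class `vb_grid_spec`: `origin` (length-3), `shape`
#'   (length-3 integer), `voxel_size` (fixed 1), `padding`, `n_channels`.
#' @export
grid_spec <- function(s, padding = 3, n_channels = 17) {
  if (inherits(s, "vb_structure")) {
    prot <- s$atoms$molecule == MOL_PROTEIN
    if (!any(prot)) stop("no protein atoms; cannot construct a grid")
    xyz <- as.matrix(s$atoms[prot, c("x", "y", "z")])
  } else {
    xyz <- as.matrix(s)
    if (!nrow(xyz)) stop("empty coordinate set; cannot construct a grid")
  }
  stopifnot(padding >= 0)
  lo <- floor(apply(xyz, 2, min)) - padding
  hi <- apply(xyz, 2, max)
  shape <- as.integer(floor(hi - lo) + padding + 1)
  structure(list(origin = as.numeric(lo), shape = shape, voxel_size = 1,
                 padding = padding, n_channels = as.integer(n_channels)),
            class = "vb_grid_spec")
}

# 1-based voxel index of world coordinates; NA when outside the grid.
world_to_index <- function(xyz, spec) {
  idx <- floor(sweep(xyz, 2, spec$origin)) + 1
  bad <- idx < 1 | sweep(idx, 2, spec$shape, ">")
  idx[rowSums(bad) > 0, ] <- NA
  storage.mode(idx) <- "integer"
  idx
}

# World coordinates of voxel centres along one axis.
axis_centers <- function(spec, axis) {
  spec$origin[axis] + seq_len(spec$shape[axis]) - 0.5
}

#' Voxelize a typed structure into a 4D one-hot grid
#'
#' Every protein atom marks the voxel nearest its centre on the channel of its
#' atom type (channels 1-16 in [list_atom_types()] order; channel 17 for
#' buried, `NON_SURFACE`, atoms). DNA atoms are never written: the network
#' must not see the binding partner. If two atoms fall into one voxel, the
#' atom whose centre is closest to the voxel centre wins; ties go to the lower
#' serial number.
#'
#' @param s A typed `vb_structure` (see [assign_atom_types()]).
#' @param spec A [grid_spec()]; defaults to one built from `s`.
#' @return A `vb_grid`: list of `spec` and a 4D integer array `values` with
#'   dimensions `c(spec$shape, spec$n_channels)`.
#' @export
voxelize <- function(s, spec = grid_spec(s)) {
  stopifnot(inherits(s, "vb_structure"), inherits(spec, "vb_grid_spec"))
  a <- s$atoms
  prot <- which(a$molecule == MOL_PROTEIN & !is.na(a$type))
  if (!length(prot)) stop("no typed protein atoms to voxelize")
  codes <- list_atom_types()
  chan <- match(a$type[prot], codes)
  chan[a$type[prot] == NON_SURFACE] <- spec$n_channels
  if (anyNA(chan)) stop("atom with unknown type code encountered")
  xyz <- as.matrix(a[prot, c("x", "y", "z")])
  idx <- world_to_index(xyz, spec)
  if (anyNA(idx)) stop("protein atom outside grid bounds; spec too small")
  centers <- sweep(idx - 0.5, 2, spec$origin, "+")
  d2 <- rowSums((xyz - centers)^2)
  # Losers first, winners last: the final write per voxel is the atom nearest
  # the voxel centre, ties broken towards the lower serial.
  ord <- order(d2, a$serial[prot], decreasing = TRUE)
  vox <- (idx[, 1] - 1L) + spec$shape[1] * (idx[, 2] - 1L) +
    spec$shape[1] * spec$shape[2] * (idx[, 3] - 1L)
  values <- array(0L, c(spec$shape, spec$n_channels))
  nvox <- prod(spec$shape)
  for (k in ord) {
    v <- vox[k]
    values[v + 1L + nvox * (seq_len(spec$n_channels) - 1L)] <- 0L
    values[v + 1L + nvox * (chan[k] - 1L)] <- 1L
  }
  structure(list(spec = spec, values = values), class = "vb_grid")
}

#' Label binding voxels by the triple 6-Angstrom rule
#'
#' A voxel is a binding voxel iff there exist a protein atom P and a DNA atom
#' D with: distance(voxel centre, P) <= cutoff, distance(voxel centre, D) <=
#' cutoff, and distance(P, D) <= cutoff. Implementation iterates over the
#' protein-DNA atom pairs already within the cutoff and marks the voxels in
#' the intersection of the two atom-centred balls.
#'
#' @param s A classified `vb_structure` with at least one DNA atom.
#' @param spec The grid specification shared with the input grid.
#' @param cutoff Distance cutoff in Angstrom (default 6).
#' @return A `vb_mask`: list of `spec`, 3D integer array `values` in {0,1}
#'   and `cutoff`.
#' @export
label_binding_voxels <- function(s, spec, cutoff = 6) {
  stopifnot(inherits(s, "vb_structure"), inherits(spec, "vb_grid_spec"),
            cutoff > 0)
  a <- s$atoms
  pm <- as.matrix(a[a$molecule == MOL_PROTEIN, c("x", "y", "z")])
  dm <- as.matrix(a[a$molecule == MOL_DNA, c("x", "y", "z")])
  if (!nrow(dm)) stop("no DNA atoms; complex should have failed screening")
  if (!nrow(pm)) stop("no protein atoms")
  values <- array(0L, spec$shape)
  cx <- axis_centers(spec, 1)
  cy <- axis_centers(spec, 2)
  cz <- axis_centers(spec, 3)
  c2 <- cutoff^2
  # protein-DNA pairs within cutoff
  for (ip in seq_len(nrow(pm))) {
    p <- pm[ip, ]
    dd2 <- (dm[, 1] - p[1])^2 + (dm[, 2] - p[2])^2 + (dm[, 3] - p[3])^2
    near <- which(dd2 <= c2)
    if (!length(near)) next
    # voxels within cutoff of P (bounding sub-box, then exact ball test)
    rx <- which(abs(cx - p[1]) <= cutoff)
    ry <- which(abs(cy - p[2]) <= cutoff)
    rz <- which(abs(cz - p[3]) <= cutoff)
    if (!length(rx) || !length(ry) || !length(rz)) next
    gx <- cx[rx]; gy <- cy[ry]; gz <- cz[rz]
    dxp <- outer(outer((gx - p[1])^2, (gy - p[2])^2, "+"), (gz - p[3])^2, "+")
    inP <- dxp <= c2
    if (!any(inP)) next
    sub <- values[rx, ry, rz, drop = FALSE]
    todo <- inP & sub == 0L
    if (!any(todo)) next
    for (id in near) {
      d <- dm[id, ]
      dxd <- outer(outer((gx - d[1])^2, (gy - d[2])^2, "+"),
                   (gz - d[3])^2, "+")
      sub[todo & dxd <= c2] <- 1L
      todo <- todo & sub == 0L
      if (!any(todo)) break
    }
    values[rx, ry, rz] <- sub
  }
  structure(list(spec = spec, values = values, cutoff = cutoff),
            class = "vb_mask")
}

#' The 24 proper rotations of the cube
#'
#' Enumerates the full proper (determinant +1) rotation group of the cube as
#' signed permutation matrices in a fixed, deterministic order with the
#' identity first.
#'
#' @return A list of 24 integer 3x3 matrices, class `vb_rotations`.
#' @export
enumerate_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1),
                       KEEP.OUT.ATTRS = FALSE)
  signs <- signs[order(-signs$s1, -signs$s2, -signs$s3), ]
  out <- list()
  for (p in perms) {
    for (r in seq_len(nrow(signs))) {
      m <- matrix(0L, 3, 3)
      for (i in 1:3) m[i, p[i]] <- as.integer(signs[r, i])
      if (round(det(m)) == 1) out[[length(out) + 1L]] <- m
    }
  }
  structure(out, class = "vb_rotations")
}

# Decompose a signed permutation matrix: axis i of the rotated array takes
# source axis perm[i], reversed when sign[i] < 0. Errors on non-members.
rotation_axes <- function(r) {
  rots <- enumerate_rotations()
  if (!any(vapply(rots, function(m) all(m == r), logical(1)))) {
    stop("matrix is not one of the 24 proper cubic rotations")
  }
  perm <- apply(r != 0, 1, which)
  sgn <- r[cbind(1:3, perm)]
  list(perm = perm, sgn = sgn)
}

#' Rotate a voxel grid or binding mask
#'
#' Applies one of the 24 cubic rotations to the spatial dimensions (channel
#' dimension untouched). The voxel multiset is preserved; the grid spec's
#' shape is permuted and its origin re-anchored so voxel centres map exactly
#' to rotated world coordinates (`new origin = min(R c0, R c1)` over the two
#' opposite box corners).
#'
#' @param g A `vb_grid` or `vb_mask`.
#' @param r An integer matrix from [enumerate_rotations()].
#' @return An object of the same class as `g`.
#' @export
rotate_grid <- function(g, r) {
  ax <- rotation_axes(r)
  spec <- g$spec
  c0 <- spec$origin
  c1 <- spec$origin + spec$shape
  rc0 <- as.numeric(r %*% c0)
  rc1 <- as.numeric(r %*% c1)
  spec$origin <- pmin(rc0, rc1)
  spec$shape <- spec$shape[ax$perm]
  v <- g$values
  is4d <- length(dim(v)) == 4
  perm <- if (is4d) c(ax$perm, 4) else ax$perm
  v <- aperm(v, perm)
  for (i in 1:3) {
    if (ax$sgn[i] < 0) {
      ix <- rev(seq_len(dim(v)[i]))
      v <- switch(i,
                  if (is4d) v[ix, , , , drop = FALSE] else v[ix, , , drop = FALSE],
                  if (is4d) v[, ix, , , drop = FALSE] else v[, ix, , drop = FALSE],
                  if (is4d) v[, , ix, , drop = FALSE] else v[, , ix, drop = FALSE])
    }
  }
  out <- g
  out$spec <- spec
  out$values <- v
  out
}

#' Persist / load a grid-mask archive
#'
#' Saves an aligned input grid and binding mask as one compressed archive
#' named `<pdb_id>_r<rotation_id>.rds` plus a JSON sidecar with the grid
#' geometry and the channel legend. `load_archive()` inverts exactly.
#'
#' @param g A `vb_grid`.
#' @param m The aligned `vb_mask`.
#' @param pdb_id Structure identifier used in the file name.
#' @param rotation_id Integer 0-23.
#' @param dir Output directory (created if missing).
#' @return Path to the archive file.
#' @export
save_archive <- function(g, m, pdb_id, rotation_id, dir) {
  stopifnot(inherits(g, "vb_grid"), inherits(m, "vb_mask"))
  if (!is.numeric(rotation_id) || rotation_id < 0 || rotation_id > 23 ||
      rotation_id != round(rotation_id)) {
    stop("rotation_id must be an integer in 0..23")
  }
  if (!all(dim(m$values) == dim(g$values)[1:3])) {
    stop("grid and mask are not aligned")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- sprintf("%s_r%02d", pdb_id, as.integer(rotation_id))
  path <- file.path(dir, paste0(base, ".rds"))
  saveRDS(list(input = g$values, mask = m$values, spec = g$spec,
               cutoff = m$cutoff, pdb_id = pdb_id,
               rotation_id = as.integer(rotation_id)),
          path, compress = "gzip")
  sidecar <- list(pdb_id = pdb_id, rotation_id = as.integer(rotation_id),
                  origin = g$spec$origin, shape = g$spec$shape,
                  n_channels = g$spec$n_channels,
                  channels = c(list_atom_types(), NON_SURFACE),
                  cutoff = m$cutoff)
  jsonlite::write_json(sidecar, file.path(dir, paste0(base, ".json")),
                       auto_unbox = TRUE, digits = NA)
  path
}

#' @rdname save_archive
#' @param path Archive path as returned by `save_archive()`.
#' @export
load_archive <- function(path) {
  x <- readRDS(path)
  list(
    grid = structure(list(spec = x$spec, values = x$input), class = "vb_grid"),
    mask = structure(list(spec = x$spec, values = x$mask, cutoff = x$cutoff),
                     class = "vb_mask"),
    pdb_id = x$pdb_id, rotation_id = x$rotation_id
  )
}
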