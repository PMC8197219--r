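# Deterministic synthetic fixtures: toy protein-DNA complexes with standard
# nomenclature, and planted-pattern voxel tasks for training sanity checks.
# Geometry is idealized, not physical: fixtures exercise pipeline mechanics.

#' Specification of a synthetic protein-DNA complex
#'
#' @param seed RNG seed; the same spec always yields the same complex.
#' @param n_residues Number of protein residues (>= 3).
#' @param dna_length Nucleotides per DNA strand (>= 2; two strands are built).
#' @param contact_distance Target minimum protein-DNA atom separation in
#'   Angstrom, achieved within +/- 0.5.
#' @param residue_alphabet Residue names to draw from (standard 3-letter
#'   codes).
#' @return A list with class `vb_synth_spec`.
#' @export
synth_spec <- function(seed = 1, n_residues = 12, dna_length = 6,
                       contact_distance = 4,
                       residue_alphabet = AMINO_ACIDS) {
  stopifnot(n_residues >= 3, dna_length >= 2, contact_distance > 0,
            all(residue_alphabet %in% AMINO_ACIDS))
  structure(list(seed = as.integer(seed), n_residues = as.integer(n_residues),
                 dna_length = as.integer(dna_length),
                 contact_distance = contact_distance,
                 residue_alphabet = residue_alphabet),
            class = "vb_synth_spec")
}

runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Heavy-atom names for a residue, from the shipped typing table (OXT excluded
# so fixtures are always typeable mid-chain).
residue_atoms <- function(resid, table) {
  at <- table$atom[table$resid == resid]
  setdiff(at, "OXT")
}

#' Generate a synthetic protein-DNA complex
#'
#' The protein is a compact coil: consecutive CA positions 3.8 Angstrom apart,
#' confined to a ball, with each residue's full set of standard heavy atoms
#' scattered within 1.8 Angstrom of its CA (so parsing, SASA, typing and
#' screening all succeed). DNA is a pair of straight antiparallel strands of
#' pseudo-nucleotides with standard atom names, translated along an approach
#' axis until the minimum protein-DNA distance is within +/- 0.5 Angstrom of
#' `contact_distance`.
#'
#' @param spec A [synth_spec()].
#' @return A classified `vb_structure`.
#' @export
generate_complex <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "vb_synth_spec"))
  set.seed(spec$seed)
  table <- default_atom_types()
  r_max <- 2.5 * spec$n_residues^(1 / 3) + 2
  # CA trace: self-avoiding-ish walk inside a ball
  ca <- matrix(0, spec$n_residues, 3)
  for (i in 2:spec$n_residues) {
    for (try in 1:200) {
      cand <- ca[i - 1, ] + 3.8 * runit()
      if (sqrt(sum(cand^2)) <= r_max &&
          all(sqrt(rowSums(sweep(ca[seq_len(i - 2), , drop = FALSE], 2,
                                 cand)^2)) > 3.0 | i <= 2)) {
        ca[i, ] <- cand
        break
      }
      if (try == 200) stop("could not place residue ", i,
                           "; geometry parameters infeasible")
    }
  }
  resids <- sample(spec$residue_alphabet, spec$n_residues, replace = TRUE)
  rows <- list()
  serial <- 0L
  for (i in seq_len(spec$n_residues)) {
    atoms <- residue_atoms(resids[i], table)
    for (nm in atoms) {
      serial <- serial + 1L
      off <- if (nm == "CA") c(0, 0, 0) else 1.8 * runit() * stats::runif(1)^(1 / 3)
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, resid = resids[i], chain = "A",
        resno = i, insert = "",
        x = ca[i, 1] + off[1], y = ca[i, 2] + off[2], z = ca[i, 3] + off[3],
        element = substr(nm, 1, 1), stringsAsFactors = FALSE
      )
    }
  }
  prot <- do.call(rbind, rows)
  # DNA: two antiparallel strands along a random axis v, approached along u
  dna_names <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'",
                 "C1'", "N1")
  bases <- c("DA", "DC", "DG", "DT")
  u <- runit()
  v <- runit()
  v <- v - sum(v * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  centroid <- colMeans(prot[, c("x", "y", "z")])
  start <- centroid + (r_max + spec$contact_distance + 6) * u
  dna_rows <- list()
  dser <- 0L
  for (strand in 1:2) {
    chain <- c("B", "C")[strand]
    side <- (strand - 1.5) * 2          # -1, +1
    for (j in seq_len(spec$dna_length)) {
      base <- bases[(j + strand) %% 4 + 1]
      center <- start + (j - (spec$dna_length + 1) / 2) * 3.4 * v +
        side * 2.0 * w
      for (nm in dna_names) {
        dser <- dser + 1L
        off <- 1.2 * runit() * stats::runif(1)^(1 / 3)
        dna_rows[[dser]] <- data.frame(
          serial = nrow(prot) + dser, name = nm, resid = base, chain = chain,
          resno = j, insert = "",
          x = center[1] + off[1], y = center[2] + off[2], z = center[3] + off[3],
          element = substr(gsub("[0-9']", "", nm), 1, 1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  dna <- do.call(rbind, dna_rows)
  # Slide the DNA along -u until min distance hits the target
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  for (iter in 1:40) {
    dxyz <- as.matrix(dna[, c("x", "y", "z")])
    dmin <- min_cross_dist(pxyz, dxyz)
    gap <- dmin - spec$contact_distance
    if (abs(gap) <= 0.3) break
    shift <- -gap * u
    dna$x <- dna$x + shift[1]
    dna$y <- dna$y + shift[2]
    dna$z <- dna$z + shift[3]
  }
  atoms <- rbind(prot, dna)
  atoms$molecule <- NA_character_
  atoms$sasa <- NA_real_
  atoms$surface <- NA
  atoms$type <- NA_character_
  classify_molecules(new_structure(sprintf("synth%04d", spec$seed), atoms))
}

min_cross_dist <- function(a, b) {
  m <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    m <- min(m, min(d2))
  }
  sqrt(m)
}

#' Generate a planted-pattern voxel task
#'
#' Builds `n_samples` (grid, mask) pairs for model sanity checks: each grid
#' carries sparse one-hot background occupancy on channels other than
#' `pattern_channel`, plus a compact motif of voxels on `pattern_channel`;
#' the mask marks every voxel within Chebyshev distance `mask_radius` of a
#' motif voxel. The mapping "dilate the motif channel" is learnable by a tiny
#' UNET in a few hundred CPU steps.
#'
#' @param seed RNG seed (dataset is reproducible).
#' @param n_samples Number of pairs.
#' @param grid_shape Spatial dimensions (each >= 8).
#' @param pattern_channel Channel carrying the motif (1-based).
#' @param n_channels Total channels (default 17, matching the featurizer).
#' @param background_density Probability a voxel carries background occupancy.
#' @param motif_size Number of motif voxels per sample.
#' @param mask_radius Chebyshev radius of the positive neighbourhood.
#' @return List of samples, each `list(x = 4D integer array, y = 3D integer
#'   array)`.
#' @export
generate_planted_task <- function(seed = 1, n_samples = 40,
                                  grid_shape = c(12, 12, 12),
                                  pattern_channel = 3, n_channels = 17,
                                  background_density = 0.05, motif_size = 4,
                                  mask_radius = 2) {
  stopifnot(all(grid_shape >= 8), pattern_channel <= n_channels)
  set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    x <- array(0L, c(grid_shape, n_channels))
    nvox <- prod(grid_shape)
    bg <- which(stats::runif(nvox) < background_density)
    bg_ch <- sample(setdiff(seq_len(n_channels), pattern_channel),
                    length(bg), replace = TRUE)
    x[bg + nvox * (bg_ch - 1L)] <- 1L
    margin <- mask_radius + 1L
    center <- vapply(grid_shape, function(n) {
      sample(seq(margin + 1L, n - margin), 1)
    }, numeric(1))
    motif <- matrix(rep(center, each = motif_size), motif_size, 3) +
      matrix(sample(-1:1, motif_size * 3, replace = TRUE), motif_size, 3)
    motif[1, ] <- center
    motif <- unique(motif)
    y <- array(0L, grid_shape)
    for (r in seq_len(nrow(motif))) {
      m <- motif[r, ]
      lin <- m[1] + grid_shape[1] * (m[2] - 1L) + prod(grid_shape[1:2]) * (m[3] - 1L)
      x[lin + nvox * (seq_len(n_channels) - 1L)] <- 0L
      x[lin + nvox * (pattern_channel - 1L)] <- 1L
      rx <- pmax(1, m[1] - mask_radius):pmin(grid_shape[1], m[1] + mask_radius)
      ry <- pmax(1, m[2] - mask_radius):pmin(grid_shape[2], m[2] + mask_radius)
      rz <- pmax(1, m[3] - mask_radius):pmin(grid_shape[3], m[3] + mask_radius)
      y[rx, ry, rz] <- 1L
    }
    list(x = x, y = y)
  })
}
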