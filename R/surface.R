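# Shrake-Rupley solvent-accessible surface area on the protein in isolation.

# Van der Waals radii (Angstrom) for the elements seen in protein heavy atoms,
# plus a common-metal radius. Deliberately small and explicit; configurable
# through sasa_params().
DEFAULT_VDW <- c(
  C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
  ZN = 2.0, MG = 2.0, CA = 2.0, FE = 2.0, MN = 2.0, "NA" = 2.0, K = 2.0,
  CU = 2.0, NI = 2.0, CO = 2.0, CD = 2.0, SE = 1.9
)

#' Parameters for the SASA calculation
#'
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points Number of deterministic golden-spiral test points per
#'   atom sphere; more points, finer area quantum. Minimum 92.
#' @param radii_table Named vector mapping element symbols to van der Waals
#'   radii in Angstrom.
#' @param surface_threshold Area (Angstrom^2) strictly above which an atom is
#'   called a surface atom. The default 0 treats any solvent accessibility as
#'   surface.
#' @return A list with class `vb_sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii_table = DEFAULT_VDW, surface_threshold = 0) {
  stopifnot(probe_radius > 0, n_sphere_points >= 92, all(radii_table > 0))
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii_table = radii_table,
                 surface_threshold = surface_threshold),
            class = "vb_sasa_params")
}

# Deterministic, near-uniform unit-sphere point set (golden spiral / Fibonacci
# lattice). No RNG involved, so SASA values are exactly reproducible.
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes SASA for every protein atom with the protein considered in
#' isolation: DNA and other molecules are excluded both as centers and as
#' occluders, so the DNA-facing surface is still "surface". For each atom a
#' sphere of radius r + probe is sampled at `n_sphere_points` golden-spiral
#' points; the accessible fraction is the share of points not inside any
#' neighbouring atom's expanded sphere, and SASA = fraction * 4 pi (r+probe)^2.
#'
#' @param s A classified `vb_structure`.
#' @param params A [sasa_params()] object.
#' @return The structure with `$atoms$sasa` filled for protein atoms.
#' @export
compute_sasa <- function(s, params = sasa_params()) {
  stopifnot(inherits(s, "vb_structure"), inherits(params, "vb_sasa_params"))
  a <- s$atoms
  if (all(is.na(a$molecule))) {
    stop("molecule classes not set; run classify_molecules() first")
  }
  idx <- which(a$molecule == MOL_PROTEIN)
  if (!length(idx)) {
    return(s)
  }
  el <- a$element[idx]
  radii <- params$radii_table[el]
  if (anyNA(radii)) {
    i <- idx[which(is.na(radii))[1]]
    stop("no van der Waals radius for element '", a$element[i],
         "' (atom ", a$name[i], ", serial ", a$serial[i], ")")
  }
  xyz <- as.matrix(a[idx, c("x", "y", "z")])
  pts <- golden_spiral(params$n_sphere_points)
  exp_r <- radii + params$probe_radius
  n <- length(idx)
  # Neighbour candidates: atoms whose expanded spheres can intersect.
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- exp_r[i]
    cand <- which(d2[i, ] < (ri + exp_r)^2)
    cand <- cand[cand != i]
    if (!length(cand)) {
      sasa[i] <- 4 * pi * ri^2
      next
    }
    p <- sweep(pts * ri, 2, xyz[i, ], "+")   # test points in world coords
    free <- rep(TRUE, nrow(p))
    for (j in cand) {
      if (!any(free)) break
      dx <- p[free, 1] - xyz[j, 1]
      dy <- p[free, 2] - xyz[j, 2]
      dz <- p[free, 3] - xyz[j, 3]
      free[free] <- (dx * dx + dy * dy + dz * dz) >= exp_r[j]^2
    }
    sasa[i] <- 4 * pi * ri^2 * sum(free) / nrow(p)
  }
  a$sasa[idx] <- sasa
  s$atoms <- a
  s
}

#' Flag surface atoms
#'
#' Protein atoms with SASA strictly above `surface_threshold` are surface;
#' DNA and other atoms are never surface.
#'
#' @inheritParams compute_sasa
#' @return The structure with logical `$atoms$surface` filled.
#' @export
flag_surface <- function(s, params = sasa_params()) {
  stopifnot(inherits(s, "vb_structure"))
  a <- s$atoms
  prot <- a$molecule == MOL_PROTEIN
  if (any(prot & is.na(a$sasa))) {
    stop("sasa not computed; run compute_sasa() first")
  }
  a$surface <- FALSE
  a$surface[prot] <- a$sasa[prot] > params$surface_threshold
  s$atoms <- a
  s
}
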