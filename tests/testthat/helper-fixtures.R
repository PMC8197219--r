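# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately take a different computational route than the
# implementation they check.

# Minimal structure builder from a coordinate matrix.
make_structure <- function(xyz, element = "C", molecule = "PROTEIN",
                           name = "CA", resid = "ALA", id = "fix") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  voxbind:::new_structure(id, data.frame(
    serial = seq_len(n),
    name = rep_len(name, n), resid = rep_len(resid, n),
    chain = "A", resno = seq_len(n), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep_len(element, n),
    molecule = rep_len(molecule, n),
    sasa = NA_real_, surface = NA, type = NA_character_,
    stringsAsFactors = FALSE
  ))
}

# Random protein + DNA cloud in a small box (for mask-oracle comparisons).
random_complex <- function(seed, n_protein = 25, n_dna = 25, box = 6) {
  set.seed(seed)
  p <- make_structure(matrix(runif(n_protein * 3, 0, box), ncol = 3))
  d <- matrix(runif(n_dna * 3, 0, box), ncol = 3)
  atoms <- rbind(p$atoms,
                 make_structure(d, element = "P", molecule = "DNA",
                                name = "P", resid = "DA")$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  voxbind:::new_structure(paste0("rand", seed), atoms)
}

# Exhaustive triple-loop oracle for the binding-voxel rule: for every voxel,
# scan all (protein, DNA) pairs directly.
mask_oracle <- function(s, spec, cutoff = 6) {
  a <- s$atoms
  pm <- as.matrix(a[a$molecule == "PROTEIN", c("x", "y", "z")])
  dm <- as.matrix(a[a$molecule == "DNA", c("x", "y", "z")])
  c2 <- cutoff^2
  pd_ok <- as.matrix(dist(rbind(pm, dm)))[seq_len(nrow(pm)),
                                          nrow(pm) + seq_len(nrow(dm)),
                                          drop = FALSE]^2 <= c2
  out <- array(0L, spec$shape)
  for (k in seq_len(spec$shape[3])) {
    for (j in seq_len(spec$shape[2])) {
      for (i in seq_len(spec$shape[1])) {
        v <- spec$origin + c(i, j, k) - 0.5
        dp <- (pm[, 1] - v[1])^2 + (pm[, 2] - v[2])^2 + (pm[, 3] - v[3])^2 <= c2
        if (!any(dp)) next
        dd <- (dm[, 1] - v[1])^2 + (dm[, 2] - v[2])^2 + (dm[, 3] - v[3])^2 <= c2
        if (!any(dd)) next
        if (any(pd_ok[dp, dd, drop = FALSE])) out[i, j, k] <- 1L
      }
    }
  }
  out
}

# Monte-Carlo surface-integration oracle for per-atom SASA.
sasa_mc_oracle <- function(xyz, radii, probe = 1.4, n_points = 100000,
                           seed = 1) {
  set.seed(seed)
  xyz <- matrix(xyz, ncol = 3)
  exp_r <- radii + probe
  vapply(seq_len(nrow(xyz)), function(i) {
    pts <- matrix(rnorm(3 * n_points), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * exp_r[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))[-i]) {
      free <- free & (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2 >= exp_r[j]^2
    }
    4 * pi * exp_r[i]^2 * mean(free)
  }, numeric(1))
}

# Trapezoidal ROC integration over all thresholds (independent of the
# rank-statistic implementation).
auc_trapezoid <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t),
                     numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t),
                     numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# A tiny hand-written PDB text (three lines, altloc A/B duplicate pair).
write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.000   6.000  -6.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      11.104   6.134  -6.504  0.50  0.00           C",
    "ATOM      3  CA BALA A   1      11.204   6.234  -6.604  0.50  0.00           C",
    "END"), path)
  path
}
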