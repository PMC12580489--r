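# The six Q2 aromaticity descriptors, frame canonicalization, benzene
# normalization, and the out-of-plane scan.
#
# Descriptor conventions (isolated here so the alternative readings are a
# one-function change):
#   Q2_ring_atoms    sum over ring atoms of the per-site spherical magnitude
#   Q2zz_ring_atoms  sum over ring atoms of the per-site Q20 (= Theta_zz)
#   Q2_origin        magnitude of the total quadrupole translated to (0,0,0)
#   Q2zz_origin      Q20 of that translated tensor
#   Q2_1, Q2_1zz     the same two quantities evaluated at (0, 0, 1 angstrom)
# Ring-atom sums cover the designated ring heavy atoms only; translated
# descriptors cover every site of the molecule.

CANON_TOL_ANG <- 1e-8

# rotation taking unit vector v onto unit vector w (Rodrigues; stable for
# the near-antiparallel case via an intermediate axis)
rotation_between <- function(v, w) {
  v <- v / sqrt(sum(v^2)); w <- w / sqrt(sum(w^2))
  c_ <- sum(v * w)
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to v
    axis <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * v) * v
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  u <- c(v[2] * w[3] - v[3] * w[2],
         v[3] * w[1] - v[1] * w[3],
         v[1] * w[2] - v[2] * w[1])
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Canonicalize a molecule's frame
#'
#' Puts a ring molecule into the descriptor reference frame: the ring-atom
#' centroid at the origin and the best-fit ring plane coincident with the
#' xy-plane (normal along +z).  The plane is the smallest principal
#' direction of the centered ring-atom coordinates; every site's position
#' and multipole components are rotated consistently via [rotate_site()].
#'
#' @param mol a [molecule_multipoles()] with `ring_atom_indices` set.
#' @param tol_ang tolerance (angstrom) for the already-canonical check.
#' @return the canonicalized molecule.
#' @export
canonicalize <- function(mol, tol_ang = CANON_TOL_ANG) {
  if (!length(mol$ring_atom_indices))
    dmaq2_stop("dmaq2_ring_error", "'%s': ring_atom_indices must be set", mol$name)
  pos <- site_positions(mol)
  ring <- pos[mol$ring_atom_indices, , drop = FALSE]
  centroid <- colMeans(ring)
  centered <- sweep(ring, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    dmaq2_stop("dmaq2_ring_error",
               "'%s': ring atoms are collinear/degenerate, no unique plane", mol$name)
  normal <- sv$v[, 3]
  if (normal[3] < 0) normal <- -normal
  R <- rotation_between(normal, c(0, 0, 1))
  apply_frame <- function(R) {
    lapply(mol$sites, function(s) {
      s2 <- rotate_site(multipole_site(s$label, s$position - centroid,
                                       s$components, s$max_rank), R)
      attr(s2, "ranks_dropped") <- NULL
      s2
    })
  }
  sites <- apply_frame(R)
  # the plane fit leaves the face sign ambiguous; resolve it from molecular
  # content so canonicalization is invariant under arbitrary rigid motion:
  # orient the total out-of-plane dipole (about the ring centroid) along +z.
  # Molecules without such a marker are z-mirror symmetric in the moments
  # used here, so either face gives identical descriptors.
  dz <- sum(vapply(sites, function(s) {
    site_component(s, "Q00") *
      convert_length(s$position[3], mol$length_unit, "bohr") +
      site_component(s, "Q10")
  }, numeric(1)))
  if (dz < -1e-9) sites <- apply_frame(diag(c(1, -1, -1)) %*% R)
  out <- molecule_multipoles(mol$name, sites, mol$ring_atom_indices,
                             mol$length_unit, mol$net_charge)
  stopifnot(is_canonical(out, tol_ang))
  out
}

#' Test whether a molecule is in the canonical frame
#'
#' @inheritParams canonicalize
#' @return `TRUE` when the ring centroid is at the origin and the ring
#'   plane is the xy-plane, both within `tol_ang` (angstrom).
#' @export
is_canonical <- function(mol, tol_ang = CANON_TOL_ANG) {
  if (!length(mol$ring_atom_indices)) return(FALSE)
  ring <- site_positions(mol)[mol$ring_atom_indices, , drop = FALSE]
  ring <- convert_length(ring, mol$length_unit, "angstrom")
  if (max(abs(colMeans(ring))) > tol_ang) return(FALSE)
  max(abs(ring[, 3])) <= tol_ang * max(1, max(abs(ring)))
}

#' Compute the six Q2 aromaticity descriptors
#'
#' Requires a canonical molecule (see [canonicalize()]).  Ring-atom sums
#' run over the designated ring atoms only; the origin and 1-angstrom
#' descriptors use every site of the molecule via [translate_quadrupole()].
#'
#' @param mol a canonical [molecule_multipoles()].
#' @param check verify canonicality first (default `TRUE`).
#' @return a one-row data frame: `molecule`, `Q2_ring_atoms`,
#'   `Q2zz_ring_atoms`, `Q2_origin`, `Q2zz_origin`, `Q2_1`, `Q2_1zz`
#'   (all e.a0^2).
#' @export
compute_descriptors <- function(mol, check = TRUE) {
  if (check && !is_canonical(mol))
    dmaq2_stop("dmaq2_frame_error",
               "'%s' is not canonical; call canonicalize() first", mol$name)
  ring_sites <- mol$sites[mol$ring_atom_indices]
  q2_ring <- sum(vapply(ring_sites, function(s) quadrupole_magnitude(site_q2(s)),
                        numeric(1)))
  q2zz_ring <- sum(vapply(ring_sites, function(s) site_component(s, "Q20"),
                          numeric(1)))
  at_origin <- translate_quadrupole(mol, c(0, 0, 0))
  z1 <- convert_length(1, "angstrom", mol$length_unit)
  at_1 <- translate_quadrupole(mol, c(0, 0, z1))
  data.frame(
    molecule = mol$name,
    Q2_ring_atoms = q2_ring,
    Q2zz_ring_atoms = q2zz_ring,
    Q2_origin = quadrupole_magnitude(at_origin),
    Q2zz_origin = unname(at_origin["Q20"]),
    Q2_1 = quadrupole_magnitude(at_1),
    Q2_1zz = unname(at_1["Q20"]),
    stringsAsFactors = FALSE
  )
}

#' Normalize descriptors against a reference molecule
#'
#' Divides each descriptor by the corresponding value of the reference
#' molecule (benzene in the original protocol), so the reference scores
#' exactly 1 in every descriptor.  Appends `_norm` columns.
#'
#' @param table descriptor data frame from [compute_descriptors()] (one or
#'   more rows).
#' @param reference name of the reference molecule (must be a row of
#'   `table`), or a one-row descriptor data frame.
#' @return `table` with six `_norm` columns and attribute `reference_name`.
#' @export
normalize_descriptors <- function(table, reference) {
  if (is.character(reference)) {
    i <- match(reference, table$molecule)
    if (is.na(i))
      dmaq2_stop("dmaq2_reference_error", "reference '%s' not in table", reference)
    ref <- table[i, , drop = FALSE]
  } else {
    ref <- reference
  }
  for (col in DESCRIPTOR_COLUMNS) {
    rv <- ref[[col]]
    if (!is.finite(rv) || rv == 0)
      dmaq2_stop("dmaq2_reference_error",
                 "reference descriptor '%s' is zero; normalization undefined", col)
    table[[paste0(col, "_norm")]] <- table[[col]] / rv
  }
  attr(table, "reference_name") <- ref$molecule[1]
  table
}

#' Scan the translated quadrupole along the ring normal
#'
#' Evaluates the magnitude and the Q20 (out-of-plane) component of the
#' molecule's total quadrupole at points (0, 0, z) on a grid above the ring
#' plane, and reports the height maximizing each series.  For benzene-like
#' systems the out-of-plane descriptors peak near z = 1 angstrom, the
#' height at which the 1-angstrom descriptors are defined.  Ties break
#' toward smaller z; only the +z face is scanned (the ring-plane mirror
#' makes -z redundant for Q20).
#'
#' @param mol a canonical [molecule_multipoles()].
#' @param z_min,z_max,step scan grid in angstrom (defaults 0.1-3.0 by 0.05).
#' @param check verify canonicality first.
#' @return list of class `z_scan_profile`: `z` (angstrom), `Q2`, `Q2zz`
#'   (e.a0^2), `argmax_Q2`, `argmax_Q2zz` (angstrom).
#' @export
scan_z <- function(mol, z_min = 0.1, z_max = 3.0, step = 0.05, check = TRUE) {
  if (!(z_min < z_max) || step <= 0)
    dmaq2_stop("dmaq2_grid_error", "need z_min < z_max and step > 0")
  if (check && !is_canonical(mol))
    dmaq2_stop("dmaq2_frame_error", "'%s' is not canonical", mol$name)
  z <- seq(z_min, z_max, by = step)
  if (!length(z)) dmaq2_stop("dmaq2_grid_error", "empty scan grid")
  vals <- vapply(z, function(zi) {
    p <- c(0, 0, convert_length(zi, "angstrom", mol$length_unit))
    q <- translate_quadrupole(mol, p)
    c(quadrupole_magnitude(q), unname(q["Q20"]))
  }, numeric(2))
  structure(list(
    z = z,
    Q2 = vals[1, ], Q2zz = vals[2, ],
    argmax_Q2 = z[which.max(vals[1, ])],
    argmax_Q2zz = z[which.max(vals[2, ])]
  ), class = "z_scan_profile")
}

#' @export
print.z_scan_profile <- function(x, ...) {
  cat(sprintf("<z_scan_profile> %d points on [%.3g, %.3g] A; argmax |Q2| = %.3g A, argmax Q2zz = %.3g A\n",
              length(x$z), min(x$z), max(x$z), x$argmax_Q2, x$argmax_Q2zz))
  invisible(x)
}
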