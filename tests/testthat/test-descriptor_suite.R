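# Frame canonicalization, the six descriptors, normalization, z-scan.

site_positions_of <- function(mol) {
  t(vapply(mol$sites, `[[`, numeric(3), "position"))
}

test_that("an already-canonical planar hexagon is returned unchanged", {
  mol <- make_ring_molecule()
  expect_true(is_canonical(mol))
  can <- canonicalize(mol)
  expect_equal(site_positions_of(can), site_positions_of(mol),
               tolerance = 1e-12)
})

test_that("descriptors are invariant under rigid motion + canonicalization", {
  base <- make_ring_molecule(ring_spec(sub_charge = -0.6, site_charge = 0.05))
  d0 <- compute_descriptors(canonicalize(base))
  set.seed(9)
  for (i in 1:5) {
    R <- random_rotation()
    shift <- runif(3, -5, 5)
    moved <- rigid_move(base, R, shift)
    d1 <- compute_descriptors(canonicalize(moved))
    for (col in c("Q2_ring_atoms", "Q2zz_ring_atoms", "Q2_origin",
                  "Q2zz_origin", "Q2_1", "Q2_1zz"))
      expect_equal(d1[[col]], d0[[col]], tolerance = 1e-8)
  }
})

test_that("flipping the ring normal leaves the Q2zz descriptors unchanged", {
  # z-mirror-symmetric content: either face of the plane fit is equivalent
  base <- make_ring_molecule(ring_spec(sub_charge = 0.4, pi_pair_charge = 0))
  d0 <- compute_descriptors(canonicalize(base))
  flip <- diag(c(1, -1, -1))  # proper rotation sending z to -z
  d1 <- compute_descriptors(canonicalize(rigid_move(base, flip, c(0, 0, 0))))
  expect_equal(d1$Q2zz_ring_atoms, d0$Q2zz_ring_atoms, tolerance = 1e-10)
  expect_equal(d1$Q2zz_origin, d0$Q2zz_origin, tolerance = 1e-10)
  expect_equal(d1$Q2_1zz, d0$Q2_1zz, tolerance = 1e-10)
})

test_that("degenerate (collinear) ring atoms are refused", {
  sites <- lapply(1:6, function(i)
    multipole_site(sprintf("C%d", i), c(i, 0, 0), c(0, 0, 0, 0, -0.4, 0, 0, 0, 0)))
  mol <- molecule_multipoles("line", sites, 1:6, "angstrom")
  expect_error(canonicalize(mol), class = "dmaq2_ring_error")
})

test_that("D6h ring of identical axial sites gives the hand-computed sums", {
  c_ <- -0.4
  mol <- make_ring_molecule(ring_spec(pi_pair_charge = 0, site_q20 = c_))
  d <- compute_descriptors(canonicalize(mol))
  expect_equal(d$Q2zz_ring_atoms, 6 * c_, tolerance = 1e-12)
  expect_equal(d$Q2_ring_atoms, 6 * abs(c_), tolerance = 1e-12)
  # at the symmetric center all m != 0 components cancel
  expect_equal(d$Q2_origin, abs(d$Q2zz_origin), tolerance = 1e-10)
})

test_that("ring of bare point charges matches the direct-sum closed forms", {
  q <- 0.3
  r_ang <- 1.39
  spec <- ring_spec(site_charge = q, site_q20 = 0, pi_pair_charge = 0)
  mol <- make_ring_molecule(spec)
  d <- compute_descriptors(canonicalize(mol))
  r <- r_ang * BOHR_PER_ANGSTROM
  expect_equal(d$Q2zz_origin, -3 * q * r^2, tolerance = 1e-10)
  z <- 1 * BOHR_PER_ANGSTROM
  expect_equal(d$Q2_1zz, 6 * q * (z^2 - r^2 / 2), tolerance = 1e-10)
})

test_that("translated descriptors match the brute-force oracle for charges", {
  for (seed in 1:4) {
    pc <- make_point_charge_molecule(12, seed = seed)
    mol <- pc$molecule
    mol$ring_atom_indices <- 1:6  # arbitrary designation; sums still defined
    got0 <- translate_quadrupole(mol, c(0, 0, 0))
    expect_equal(as.numeric(got0), as.numeric(pc$oracle(c(0, 0, 0))),
                 tolerance = 1e-10)
    z1 <- c(0, 0, 1 * BOHR_PER_ANGSTROM)
    expect_equal(as.numeric(translate_quadrupole(mol, z1)),
                 as.numeric(pc$oracle(z1)), tolerance = 1e-10)
  }
})

test_that("normalization divides by the reference and flags zeros", {
  mol <- make_ring_molecule(name = "ref")
  d <- compute_descriptors(canonicalize(mol))
  norm_cols <- paste0(c("Q2_ring_atoms", "Q2zz_ring_atoms", "Q2_origin",
                        "Q2zz_origin", "Q2_1", "Q2_1zz"), "_norm")

  self <- normalize_descriptors(d, "ref")
  expect_equal(unname(unlist(self[norm_cols])), rep(1, 6))

  half <- d
  half$molecule <- "half"
  for (col in c("Q2_ring_atoms", "Q2zz_ring_atoms", "Q2_origin",
                "Q2zz_origin", "Q2_1", "Q2_1zz"))
    half[[col]] <- 0.5 * d[[col]]
  both <- normalize_descriptors(rbind(d, half), "ref")
  expect_equal(unname(unlist(both[2, norm_cols])), rep(0.5, 6))

  # negative raw over negative reference is positive
  expect_lt(d$Q2zz_origin, 0)
  expect_gt(both$Q2zz_origin_norm[2], 0)

  zero_ref <- d
  zero_ref$Q2_1zz <- 0
  expect_error(normalize_descriptors(d, zero_ref),
               "Q2_1zz", class = "dmaq2_reference_error")
})

test_that("z-scan matches closed forms and refines consistently", {
  # single positive charge at the ring center: Q20(z) = q z^2, so the
  # argmax sits at the top of the grid
  s <- multipole_site("q", c(0, 0, 0), 1, max_rank = 0L)
  mol <- molecule_multipoles("one", list(s,
    multipole_site("C1", c(1, 0, 0), 0, max_rank = 0L),
    multipole_site("C2", c(-0.5, sqrt(3) / 2, 0), 0, max_rank = 0L),
    multipole_site("C3", c(-0.5, -sqrt(3) / 2, 0), 0, max_rank = 0L)),
    ring_atom_indices = 2:4, length_unit = "bohr")
  prof <- scan_z(mol, 0.1, 2.0, 0.1)
  zb <- convert_length(prof$z, "angstrom", "bohr")
  expect_equal(prof$Q2zz, zb^2, tolerance = 1e-12)
  expect_equal(prof$argmax_Q2zz, 2.0)

  # two +q charges at (0, 0, +/- h): profile equals the per-point charge sum
  h <- 0.8  # bohr
  mol2 <- mol
  mol2$sites[[1]] <- multipole_site("p1", c(0, 0, h), 0.5, max_rank = 0L)
  mol2$sites <- c(mol2$sites, list(multipole_site("p2", c(0, 0, -h), 0.5,
                                                  max_rank = 0L)))
  prof2 <- scan_z(mol2, 0.1, 2.0, 0.1)
  closed <- vapply(zb, function(z)
    0.5 * (2 * (h - z)^2) / 2 + 0.5 * (2 * (-h - z)^2) / 2, numeric(1))
  expect_equal(prof2$Q2zz, closed, tolerance = 1e-12)

  # synthetic pi-ring: coarse argmax within one step of a 10x finer scan
  ring <- make_ring_molecule(ring_spec(pi_pair_charge = -0.05))
  coarse <- scan_z(ring, 0.1, 3.0, 0.05)
  fine <- scan_z(ring, 0.1, 3.0, 0.005)
  expect_lte(abs(coarse$argmax_Q2 - fine$argmax_Q2), 0.05)
  expect_lte(abs(coarse$argmax_Q2zz - fine$argmax_Q2zz), 0.05)

  expect_error(scan_z(ring, 2, 1, 0.1), class = "dmaq2_grid_error")
})
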