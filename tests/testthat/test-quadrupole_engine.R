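# Rank-2 tensor algebra: angular factor, representation conversion,
# magnitude, rotation, and moment translation.

test_that("angular factor has the textbook values and symmetry", {
  expect_equal(angular_factor(0), 1.0)
  expect_equal(angular_factor(pi / 2), -0.5)
  expect_equal(angular_factor(acos(1 / sqrt(3))), 0, tolerance = 1e-15)
  th <- seq(0, pi, length.out = 181)
  expect_true(all(angular_factor(th) >= -0.5 - 1e-15 &
                  angular_factor(th) <= 1 + 1e-15))
  # symmetric about the ring plane
  expect_equal(angular_factor(pi / 2 + th), angular_factor(pi / 2 - th))
})

test_that("spherical <-> Cartesian conversion is exact and traceless", {
  th <- spherical_to_cartesian(spherical_quadrupole(Q20 = 1))
  expect_equal(diag(th), c(x = -0.5, y = -0.5, z = 1))
  expect_equal(th[upper.tri(th)], rep(0, 3))

  set.seed(11)
  for (i in 1:20) {
    q <- spherical_quadrupole(rnorm(5))
    th <- spherical_to_cartesian(q)
    expect_equal(sum(diag(th)), 0, tolerance = 1e-12)
    expect_equal(as.numeric(cartesian_to_spherical(th)), as.numeric(q),
                 tolerance = 1e-12)
  }
})

test_that("solid-harmonic and Cartesian charge sums give the same tensor", {
  # dual-formula oracle: both built straight from the charge definitions
  set.seed(5)
  for (rep in 1:5) {
    q <- runif(10, -1, 1)
    pos <- matrix(runif(30, -2, 2), 10, 3)
    via_harmonics <- oracle_spherical_q2(q, pos)
    via_cartesian <- cartesian_to_spherical(oracle_theta(q, pos))
    expect_equal(as.numeric(via_cartesian), unname(via_harmonics),
                 tolerance = 1e-12)
  }
})

test_that("magnitude is the 5-component norm and a rotation invariant", {
  expect_equal(quadrupole_magnitude(spherical_quadrupole(1, 0, 0, 0, 0)), 1.0)
  expect_equal(quadrupole_magnitude(spherical_quadrupole(3, 4, 0, 0, 0)), 5.0)
  set.seed(21)
  for (i in 1:20) {
    q <- spherical_quadrupole(rnorm(5))
    R <- random_rotation()
    th_rot <- R %*% spherical_to_cartesian(q) %*% t(R)
    expect_equal(quadrupole_magnitude(cartesian_to_spherical(th_rot)),
                 quadrupole_magnitude(q), tolerance = 1e-10)
  }
})

test_that("rotate_site transforms each rank correctly", {
  set.seed(31)
  s <- multipole_site("C1", c(1, 2, 3), rnorm(9))
  expect_equal(rotate_site(s, diag(3))$components, s$components)

  # 90-degree rotation about z maps a pure x-dipole onto a pure y-dipole
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  dip <- multipole_site("X", c(0, 0, 0), c(0, 0, 1, 0))  # Q11c = mu_x = 1
  rot <- rotate_site(dip, Rz)
  expect_equal(unname(rot$components[c("Q11c", "Q11s", "Q10")]),
               c(0, 1, 0), tolerance = 1e-15)

  # rank-2 magnitude preserved under random rotations
  for (i in 1:10) {
    R <- random_rotation()
    s2 <- rotate_site(s, R)
    expect_equal(quadrupole_magnitude(s2$components[5:9]),
                 quadrupole_magnitude(s$components[5:9]), tolerance = 1e-10)
    # monopole untouched
    expect_identical(unname(s2$components[["Q00"]]),
                     unname(s$components[["Q00"]]))
  }
  expect_error(rotate_site(s, diag(3) * 2), class = "dmaq2_type_error")
})

test_that("translation reproduces simple closed-form cases", {
  # unit charge on the z-axis at 1 bohr: Q20 about the origin = 1
  s <- multipole_site("q", c(0, 0, 1), 1, max_rank = 0L)
  q <- translate_quadrupole(list(s), c(0, 0, 0), unit = "bohr")
  expect_equal(unname(q["Q20"]), 1.0, tolerance = 1e-14)

  # evaluating at the site's own position returns its own components
  set.seed(41)
  s2 <- multipole_site("C1", c(0.3, -0.7, 1.1), rnorm(9))
  q2 <- translate_quadrupole(list(s2), s2$position, unit = "bohr")
  expect_equal(as.numeric(q2), unname(s2$components[5:9]), tolerance = 1e-12)

  # missing unit metadata is an error
  expect_error(translate_quadrupole(list(s), c(0, 0, 0)),
               class = "dmaq2_unit_error")
})

test_that("translation matches the direct charge-sum oracle", {
  set.seed(51)
  for (rep in 1:10) {
    q <- runif(20, -1, 1)
    pos <- matrix(runif(60, -3, 3), 20, 3)
    sites <- lapply(1:20, function(i)
      multipole_site(sprintf("X%d", i), pos[i, ], q[i], max_rank = 0L))
    pt <- runif(3, -2, 2)
    got <- translate_quadrupole(sites, pt, unit = "bohr")
    want <- cartesian_to_spherical(oracle_theta(q, pos, pt))
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-10)
  }
})

test_that("a charge-pair dipole translates exactly, not asymptotically", {
  # +/- m charges at a +/- delta z-hat realize a point dipole with zero
  # monopole and zero quadrupole about a; agreement must be exact for any
  # delta, including large ones
  set.seed(61)
  for (delta in c(1e-3, 0.5, 2)) {
    a <- runif(3, -2, 2)
    m <- 0.7
    pos <- rbind(a + c(0, 0, delta), a - c(0, 0, delta))
    q <- c(m, -m)
    sites <- list(multipole_site("p", pos[1, ], q[1], max_rank = 0L),
                  multipole_site("m", pos[2, ], q[2], max_rank = 0L))
    pt <- runif(3, -2, 2)
    got <- translate_quadrupole(sites, pt, unit = "bohr")
    # dipole-site formulation: one site at a carrying mu = 2 m delta z-hat
    dip_site <- multipole_site("d", a, c(0, 2 * m * delta, 0, 0), max_rank = 1L)
    via_dipole <- translate_quadrupole(list(dip_site), pt, unit = "bohr")
    expect_equal(as.numeric(got), as.numeric(via_dipole), tolerance = 1e-12)
    # and both match the brute-force charge sum
    expect_equal(as.numeric(got),
                 as.numeric(cartesian_to_spherical(oracle_theta(q, pos, pt))),
                 tolerance = 1e-12)
  }
})

test_that("translation is linear and origin-independent for neutral apolar sets", {
  set.seed(71)
  pcA <- make_point_charge_molecule(6, seed = 101)
  pcB <- make_point_charge_molecule(9, seed = 102)
  pt <- c(0.3, -0.4, 1.2)
  qA <- translate_quadrupole(pcA$molecule, pt)
  qB <- translate_quadrupole(pcB$molecule, pt)
  both <- molecule_multipoles("union", c(pcA$molecule$sites, pcB$molecule$sites),
                              length_unit = "bohr")
  expect_equal(as.numeric(translate_quadrupole(both, pt)),
               as.numeric(qA) + as.numeric(qB), tolerance = 1e-12)

  neutral <- make_point_charge_molecule(8, seed = 103, neutralize = TRUE,
                                        zero_dipole = TRUE)
  q1 <- translate_quadrupole(neutral$molecule, c(0, 0, 0))
  q2 <- translate_quadrupole(neutral$molecule, c(5, -3, 2))
  expect_equal(as.numeric(q1), as.numeric(q2), tolerance = 1e-10)
})

test_that("a charge in the ring plane contributes exactly -q r^2 / 2 to Q20", {
  # the sign structure behind the charged-substituent artifact: theta = 90
  # degrees sits in the negative lobe of the angular factor, so a negative
  # in-plane charge RAISES Q20 (the product of two negative signs)
  for (qc in c(1, -1, 0.37)) {
    r <- 2.4
    s <- multipole_site("sub", c(r, 0, 0), qc, max_rank = 0L)
    got <- translate_quadrupole(list(s), c(0, 0, 0), unit = "bohr")
    expect_equal(unname(got["Q20"]), -0.5 * qc * r^2, tolerance = 1e-14)
  }
  # the same charge on the z-axis contributes positively
  s <- multipole_site("ax", c(0, 0, 2.4), 1, max_rank = 0L)
  expect_gt(unname(translate_quadrupole(list(s), c(0, 0, 0), unit = "bohr")["Q20"]), 0)
})
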