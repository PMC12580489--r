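# Rank-2 tensor algebra for distributed multipoles.
#
# Two equivalent representations are used throughout:
#   spherical  - the five real components (Q20, Q21c, Q21s, Q22c, Q22s),
#                Stone's convention, e.a0^2;
#   Cartesian  - the traceless symmetric Buckingham tensor
#                Theta_ab = 1/2 sum q (3 r_a r_b - r^2 d_ab).
# The linear map between them (and its inverse) is exact:
#   Theta_zz = Q20,             Theta_xz = (sqrt(3)/2) Q21c,
#   Theta_yz = (sqrt(3)/2) Q21s, Theta_xx - Theta_yy = sqrt(3) Q22c,
#   Theta_xy = (sqrt(3)/2) Q22s, trace = 0.

SQ3 <- sqrt(3)

#' Angular factor of the out-of-plane quadrupole component
#'
#' The weight `(3 cos^2(theta) - 1) / 2` inside the Theta_zz integrand, as a
#' function of the polar angle from the ring normal (z axis).  It is
#' positive inside the cone theta < 54.7 degrees (and its mirror
#' theta > 125.3 degrees) and negative near the ring plane — the sign
#' structure responsible for the charged-substituent artifact: an in-plane
#' negative charge contributes positively to Theta_zz.
#'
#' @param theta polar angle(s) from the z axis, radians.
#' @return dimensionless value(s) in `[-0.5, 1]`.
#' @examples
#' angular_factor(0)                 # 1
#' angular_factor(pi / 2)            # -0.5
#' angular_factor(acos(1 / sqrt(3))) # 0 (the 54.7-degree node)
#' @export
angular_factor <- function(theta) {
  (3 * cos(theta)^2 - 1) / 2
}

#' Construct a spherical quadrupole
#'
#' @param Q20,Q21c,Q21s,Q22c,Q22s the five real spherical rank-2 components,
#'   e.a0^2. A length-5 vector may be passed as `Q20`.
#' @return named numeric vector of class `spherical_quadrupole`.
#' @export
spherical_quadrupole <- function(Q20 = 0, Q21c = 0, Q21s = 0,
                                 Q22c = 0, Q22s = 0) {
  if (length(Q20) == 5L) {
    v <- as.numeric(Q20)
  } else {
    v <- c(Q20, Q21c, Q21s, Q22c, Q22s)
  }
  if (any(!is.finite(v))) dmaq2_stop("dmaq2_type_error", "non-finite quadrupole component")
  structure(stats::setNames(v, STONE_NAMES[5:9]), class = "spherical_quadrupole")
}

#' Convert spherical rank-2 components to the traceless Cartesian tensor
#'
#' @param q a [spherical_quadrupole()] (or bare length-5 vector in Stone
#'   order).
#' @return 3x3 symmetric traceless matrix (Buckingham convention), e.a0^2.
#' @export
spherical_to_cartesian <- function(q) {
  q <- as.numeric(q)
  Q20 <- q[1]; Q21c <- q[2]; Q21s <- q[3]; Q22c <- q[4]; Q22s <- q[5]
  xx <- (-Q20 + SQ3 * Q22c) / 2
  yy <- (-Q20 - SQ3 * Q22c) / 2
  zz <- Q20
  xy <- SQ3 / 2 * Q22s
  xz <- SQ3 / 2 * Q21c
  yz <- SQ3 / 2 * Q21s
  matrix(c(xx, xy, xz,
           xy, yy, yz,
           xz, yz, zz), 3, 3,
         dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
}

#' Convert a traceless Cartesian quadrupole to spherical components
#'
#' Inverse of [spherical_to_cartesian()]; the trace-zero constraint closes
#' the 6-to-5 system.
#'
#' @param theta 3x3 symmetric (traceless to ~1e-10 relative) matrix.
#' @return a [spherical_quadrupole()].
#' @export
cartesian_to_spherical <- function(theta) {
  tr <- sum(diag(theta))
  scale <- max(abs(theta), 1e-300)
  if (abs(tr) > 1e-8 * max(scale, 1))
    dmaq2_stop("dmaq2_type_error", "Cartesian quadrupole is not traceless (trace %.3g)", tr)
  spherical_quadrupole(
    Q20  = theta[3, 3],
    Q21c = 2 / SQ3 * theta[1, 3],
    Q21s = 2 / SQ3 * theta[2, 3],
    Q22c = (theta[1, 1] - theta[2, 2]) / SQ3,
    Q22s = 2 / SQ3 * theta[1, 2]
  )
}

#' Magnitude of a rank-2 multipole
#'
#' The Euclidean norm of the five real spherical components (Stone's
#' convention).  This is a rotational invariant; it differs from the
#' Frobenius norm of the Cartesian tensor by a factor sqrt(3/2).
#'
#' @param q a [spherical_quadrupole()] or length-5 numeric vector.
#' @return non-negative scalar, e.a0^2.
#' @export
quadrupole_magnitude <- function(q) {
  sqrt(sum(as.numeric(q)^2))
}

check_rotation <- function(R) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-10 ||
      det(R) < 0)
    dmaq2_stop("dmaq2_type_error", "R must be a proper rotation (orthogonal, det +1)")
  R
}

#' Rotate a multipole site
#'
#' Applies a proper rotation to a site's position and multipole components:
#' rank 0 is invariant, the rank-1 block rotates as the Cartesian vector
#' (Q11c, Q11s, Q10), and the rank-2 block rotates by Cartesian conjugation
#' `R Theta R^T` followed by conversion back to spherical components.  Ranks
#' three and above are zeroed and flagged (they are never used downstream:
#' origin-shifted rank-2 moments depend only on site ranks <= 2).
#'
#' @param site a [multipole_site()].
#' @param R 3x3 proper rotation matrix.
#' @param about optional center of rotation (same unit as the site),
#'   default the origin.
#' @return the rotated site; attribute `ranks_dropped` is `TRUE` when
#'   ranks >= 3 were present and zeroed.
#' @export
rotate_site <- function(site, R, about = c(0, 0, 0)) {
  R <- check_rotation(R)
  pos <- as.numeric(R %*% (site$position - about)) + about
  comp <- site$components
  if (site$max_rank >= 1L) {
    mu <- site_dipole(site)
    mu2 <- as.numeric(R %*% mu)
    comp[c("Q11c", "Q11s", "Q10")] <- mu2
  }
  if (site$max_rank >= 2L) {
    th <- spherical_to_cartesian(site_q2(site))
    comp[STONE_NAMES[5:9]] <- as.numeric(cartesian_to_spherical(R %*% th %*% t(R)))
  }
  dropped <- FALSE
  if (site$max_rank >= 3L && any(comp[-seq_len(9)] != 0)) {
    comp[-seq_len(9)] <- 0
    dropped <- TRUE
  }
  out <- multipole_site(site$label, pos, comp, max_rank = site$max_rank)
  attr(out, "ranks_dropped") <- dropped
  out
}

#' Translate site multipoles to a common evaluation point
#'
#' Accumulates the rank-2 moment of a set of distributed-multipole sites
#' about an arbitrary point.  With displacement `a = r_site - point`, site
#' monopole `q`, Cartesian site dipole `mu` and site quadrupole `Theta`,
#' each site contributes
#' \deqn{\Theta_{\alpha\beta}(point) = \Theta_{\alpha\beta}(site)
#'   + \tfrac{3}{2}(a_\alpha \mu_\beta + a_\beta \mu_\alpha)
#'   - (a \cdot \mu)\,\delta_{\alpha\beta}
#'   + \tfrac{q}{2}(3 a_\alpha a_\beta - |a|^2 \delta_{\alpha\beta})}
#' and contributions sum.  The result is exact (not asymptotic) whenever
#' site ranks <= 2 fully describe the charge distribution; site ranks >= 3
#' never contribute to a translated rank-2 moment.
#'
#' All positions are converted to bohr before use, so the result is in
#' e.a0^2 regardless of the declared length unit.
#'
#' @param sites list of [multipole_site()] objects, or a
#'   [molecule_multipoles()] (whose unit metadata is then used).
#' @param point evaluation point, same unit as the sites.
#' @param unit length unit of site positions and `point` when `sites` is a
#'   bare list (`"angstrom"` or `"bohr"`).
#' @return a [spherical_quadrupole()], e.a0^2.
#' @export
translate_quadrupole <- function(sites, point = c(0, 0, 0), unit = NULL) {
  if (inherits(sites, "molecule_multipoles")) {
    unit <- sites$length_unit
    sites <- sites$sites
  }
  if (is.null(unit))
    dmaq2_stop("dmaq2_unit_error", "length unit metadata required for translation")
  unit <- match.arg(unit, c("angstrom", "bohr"))
  point_b <- convert_length(as.numeric(point), unit, "bohr")
  total <- matrix(0, 3, 3)
  I3 <- diag(3)
  for (s in sites) {
    a <- convert_length(s$position, unit, "bohr") - point_b
    qmono <- site_component(s, "Q00")
    mu <- site_dipole(s)
    th <- spherical_to_cartesian(site_q2(s))
    total <- total + th +
      1.5 * (outer(a, mu) + outer(mu, a)) - sum(a * mu) * I3 +
      qmono / 2 * (3 * outer(a, a) - sum(a * a) * I3)
  }
  cartesian_to_spherical(total)
}
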