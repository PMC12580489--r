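# Independent oracles used across the suite.  These deliberately avoid the
# package's computational paths: the quadrupole oracles work from the raw
# charge definitions, and the Ward oracle recomputes every candidate merge
# cost from the full cluster memberships.

# traceless Cartesian quadrupole of point charges about `point`, direct sum
oracle_theta <- function(q, pos, point = c(0, 0, 0)) {
  th <- matrix(0, 3, 3)
  for (i in seq_along(q)) {
    r <- pos[i, ] - point
    th <- th + q[i] / 2 * (3 * outer(r, r) - sum(r * r) * diag(3))
  }
  th
}

# real solid harmonics of rank 2 evaluated at a point (Stone order)
oracle_solid_harmonics_q2 <- function(r) {
  x <- r[1]; y <- r[2]; z <- r[3]
  rr <- x^2 + y^2 + z^2
  c(Q20 = (3 * z^2 - rr) / 2,
    Q21c = sqrt(3) * x * z,
    Q21s = sqrt(3) * y * z,
    Q22c = sqrt(3) / 2 * (x^2 - y^2),
    Q22s = sqrt(3) * x * y)
}

# spherical rank-2 moments of point charges via solid harmonics
oracle_spherical_q2 <- function(q, pos, point = c(0, 0, 0)) {
  out <- numeric(5)
  for (i in seq_along(q)) {
    out <- out + q[i] * oracle_solid_harmonics_q2(pos[i, ] - point)
  }
  names(out) <- c("Q20", "Q21c", "Q21s", "Q22c", "Q22s")
  out
}

# random proper rotation (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# exhaustive greedy Ward: at every step score all cluster pairs by the
# ESS difference computed from scratch over the member points
oracle_ward <- function(x) {
  n <- nrow(x)
  ess <- function(members) {
    if (length(members) == 1L) return(0)
    pts <- x[members, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }
  clusters <- lapply(seq_len(n), identity)    # member lists
  ids <- -seq_len(n)                          # hclust-style ids
  merges <- data.frame(a = integer(n - 1L), b = integer(n - 1L),
                       height = numeric(n - 1L), size = integer(n - 1L))
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merges$a[step] <- ids[i]; merges$b[step] <- ids[j]
    merges$height[step] <- best_d
    merges$size[step] <- length(clusters[[i]]) + length(clusters[[j]])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  merges
}

# rigidly move a molecule: rotate by R about the origin, then shift
rigid_move <- function(mol, R, shift) {
  sites <- lapply(mol$sites, function(s) {
    s2 <- dmaq2::rotate_site(s, R)
    s2$position <- s2$position + shift
    attr(s2, "ranks_dropped") <- NULL
    s2
  })
  dmaq2::molecule_multipoles(mol$name, sites, mol$ring_atom_indices,
                             mol$length_unit, mol$net_charge)
}
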