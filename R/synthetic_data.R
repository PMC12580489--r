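# Synthetic inputs with the physical / statistical structure the analysis
# assumes, plus exact point-charge oracles, so the whole workflow runs
# without any quantum-chemistry software.
#
# The generators are pure functions of (spec, seed): they save and restore
# the global RNG state.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# brute-force traceless quadrupole of point charges about `point` (bohr)
brute_force_quadrupole <- function(charges, positions, point = c(0, 0, 0)) {
  th <- matrix(0, 3, 3)
  for (i in seq_along(charges)) {
    r <- positions[i, ] - point
    th <- th + charges[i] / 2 * (3 * outer(r, r) - sum(r * r) * diag(3))
  }
  cartesian_to_spherical(th)
}

#' Random point-charge molecule with an exact quadrupole oracle
#'
#' Generates `n` rank-0 sites (point charges) at reproducible random
#' positions, together with a closure that evaluates the brute-force
#' traceless quadrupole \eqn{\Theta_{\alpha\beta} = \frac{1}{2}\sum_i q_i
#' (3 r_\alpha r_\beta - r^2 \delta_{\alpha\beta})} about any requested
#' point — the independent oracle against which the moment-translation
#' engine is checked.
#'
#' @param n number of charges.
#' @param box half-width of the sampling cube, bohr.
#' @param seed RNG seed.
#' @param neutralize if `TRUE`, shift charges to zero total charge (useful
#'   for origin-independence checks).
#' @param zero_dipole if `TRUE` (with `neutralize`), also remove the net
#'   dipole by adding a compensating +/- charge pair.
#' @return list with `molecule` (a [molecule_multipoles()], unit bohr) and
#'   `oracle(point)` returning a [spherical_quadrupole()].
#' @export
make_point_charge_molecule <- function(n, box = 3, seed = 1,
                                       neutralize = FALSE,
                                       zero_dipole = FALSE) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    pos <- matrix(stats::runif(3 * n, -box, box), n, 3)
    q <- stats::runif(n, -1, 1)
  })
  if (neutralize) q <- q - mean(q)
  if (neutralize && zero_dipole && n >= 1) {
    # cancel the residual dipole with a +/- pair along it
    mu <- colSums(q * pos)
    if (sqrt(sum(mu^2)) > 0) {
      d <- mu / 2
      pos <- rbind(pos, -d, d)   # -1 charge at -d, ... chosen so sum q r = 0
      q <- c(q, 1, -1)           # (+1)(-d) + (-1)(+d) = -mu
      n <- n + 2L
    }
  }
  sites <- lapply(seq_len(n), function(i) {
    multipole_site(sprintf("X%d", i), pos[i, ], q[i], max_rank = 0L)
  })
  mol <- molecule_multipoles("point_charges", sites, length_unit = "bohr",
                             net_charge = round(sum(q)))
  list(
    molecule = mol,
    oracle = function(point = c(0, 0, 0)) {
      brute_force_quadrupole(q, pos, as.numeric(point))
    }
  )
}

#' Specification of a synthetic ring molecule
#'
#' Describes a planar n-fold ring of multipole sites emulating the systems
#' of the substituted-benzene study: ring heavy atoms carrying a monopole
#' and an axial quadrupole, optional out-of-plane +/- charge pairs per site
#' emulating pi density, and an optional in-plane substituent site at
#' distance `sub_distance` carrying net charge (the configuration that
#' produces the angular-factor sign artifact).
#'
#' @param n_ring_sites ring size (default 6).
#' @param radius ring radius, angstrom (default 1.39, a benzene C-C bond
#'   length, which equals the circumradius of a regular hexagon).
#' @param site_charge per-ring-site monopole, e.
#' @param site_q20 per-ring-site axial quadrupole Q20, e.a0^2 (default
#'   -0.4: pi density above/below the nucleus makes Theta_zz negative).
#' @param pi_pair_charge,pi_pair_height out-of-plane pair: charge
#'   `+pi_pair_charge` at `+pi_pair_height` angstrom above each ring site
#'   and the opposite charge below (0 disables).
#' @param pi_mode `"charges"` adds the pair as two rank-0 sites;
#'   `"site_dipole"` folds the pair's exact moments about the ring site
#'   (a pure dipole Q10 = 2 q h) into the site expansion instead.
#' @param sub_charge,sub_distance in-plane substituent point charge (e) at
#'   `sub_distance` angstrom from the ring center along +x (`sub_charge =
#'   0` disables); `sub_dipole` an optional Cartesian dipole (e.a0) on it.
#' @return list of class `ring_spec`.
#' @export
ring_spec <- function(n_ring_sites = 6L, radius = 1.39,
                      site_charge = 0, site_q20 = -0.4,
                      pi_pair_charge = 0.05, pi_pair_height = 0.6,
                      pi_mode = c("charges", "site_dipole"),
                      sub_charge = 0, sub_distance = 2.4,
                      sub_dipole = c(0, 0, 0)) {
  pi_mode <- match.arg(pi_mode)
  if (radius <= 0) dmaq2_stop("dmaq2_type_error", "radius must be positive")
  if (n_ring_sites < 3L) dmaq2_stop("dmaq2_type_error", "need >= 3 ring sites")
  structure(as.list(environment()), class = "ring_spec")
}

#' Build a synthetic ring molecule from a spec
#'
#' The molecule is emitted directly in the canonical frame (ring centroid
#' at the origin, ring in the xy-plane) and passes [canonicalize()]
#' unchanged.  With a symmetric spec (no substituent) all m != 0 translated
#' components cancel at the ring center by n-fold symmetry.
#'
#' @param spec a [ring_spec()].
#' @param name molecule name.
#' @return a [molecule_multipoles()] with `length_unit = "angstrom"` and
#'   the ring sites designated as ring atoms.
#' @export
make_ring_molecule <- function(spec = ring_spec(), name = "synthetic_ring") {
  stopifnot(inherits(spec, "ring_spec"))
  n <- spec$n_ring_sites
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  sites <- list()
  for (i in seq_len(n)) {
    p <- c(spec$radius * cos(ang[i]), spec$radius * sin(ang[i]), 0)
    comp <- c(spec$site_charge, 0, 0, 0, spec$site_q20, 0, 0, 0, 0)
    if (spec$pi_pair_charge != 0 && spec$pi_mode == "site_dipole") {
      # exact moments of the +/- pair about the site: pure dipole 2 q h
      comp[2] <- 2 * spec$pi_pair_charge *
        convert_length(spec$pi_pair_height, "angstrom", "bohr")
    }
    sites[[length(sites) + 1L]] <- multipole_site(sprintf("C%d", i), p, comp)
  }
  if (spec$pi_pair_charge != 0 && spec$pi_mode == "charges") {
    for (i in seq_len(n)) {
      p <- c(spec$radius * cos(ang[i]), spec$radius * sin(ang[i]), 0)
      up <- p + c(0, 0, spec$pi_pair_height)
      dn <- p - c(0, 0, spec$pi_pair_height)
      sites[[length(sites) + 1L]] <-
        multipole_site(sprintf("Pi%d+", i), up, spec$pi_pair_charge, max_rank = 0L)
      sites[[length(sites) + 1L]] <-
        multipole_site(sprintf("Pi%d-", i), dn, -spec$pi_pair_charge, max_rank = 0L)
    }
  }
  if (spec$sub_charge != 0 || any(spec$sub_dipole != 0)) {
    comp <- c(spec$sub_charge,
              spec$sub_dipole[3], spec$sub_dipole[1], spec$sub_dipole[2],
              0, 0, 0, 0, 0)
    sites[[length(sites) + 1L]] <-
      multipole_site("Sub", c(spec$sub_distance, 0, 0), comp)
  }
  molecule_multipoles(name, sites, ring_atom_indices = seq_len(n),
                      length_unit = "angstrom")
}

#' Specification of a synthetic four-group descriptor dataset
#'
#' Gaussian groups in the six-descriptor space mimicking the cluster
#' structure found for substituted benzenes: neutral / weakly perturbed
#' near the benzene point (1, ..., 1); quinoidal with depressed
#' out-of-plane entries; cationic below 1; anionic above 1.  Means are
#' configuration, not claims about any published values.
#'
#' @param means numeric matrix, groups x 6 descriptors (rows named).
#' @param sigma per-group spherical standard deviation(s).
#' @param sizes per-group sample sizes.
#' @param seed RNG seed.
#' @return list of class `cluster_spec`.
#' @export
cluster_spec <- function(means = NULL,
                         sigma = 0.01,
                         sizes = c(neutral = 8L, quinoidal = 2L,
                                   cationic = 3L, anionic = 3L),
                         seed = 1L) {
  if (is.null(means)) {
    means <- rbind(
      neutral   = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
      quinoidal = c(0.95, 0.90, 0.95, 0.90, 0.85, 0.80),
      cationic  = c(0.80, 0.75, 0.85, 0.80, 0.75, 0.70),
      anionic   = c(1.20, 1.25, 1.15, 1.20, 1.25, 1.30)
    )
    colnames(means) <- DESCRIPTOR_COLUMNS
  }
  if (nrow(means) < 2L) dmaq2_stop("dmaq2_type_error", "need >= 2 groups")
  if (is.null(colnames(means))) {
    colnames(means) <- if (ncol(means) == 6L) DESCRIPTOR_COLUMNS
                       else paste0("D", seq_len(ncol(means)))
  }
  if (any(sigma <= 0)) dmaq2_stop("dmaq2_type_error", "sigma must be positive")
  sigma <- rep_len(sigma, nrow(means))
  sizes <- rep_len(as.integer(sizes), nrow(means))
  structure(list(means = means, sigma = sigma, sizes = sizes,
                 seed = as.integer(seed)), class = "cluster_spec")
}

#' Generate a labelled synthetic descriptor dataset
#'
#' @param spec a [cluster_spec()].
#' @return list: `table` (data frame `molecule` + 6 descriptor columns) and
#'   `labels` (integer group per row).
#' @export
make_cluster_dataset <- function(spec = cluster_spec()) {
  stopifnot(inherits(spec, "cluster_spec"))
  g <- nrow(spec$means)
  rows <- with_local_seed(spec$seed, {
    lapply(seq_len(g), function(k) {
      nk <- spec$sizes[k]
      sweep(matrix(stats::rnorm(nk * ncol(spec$means), sd = spec$sigma[k]),
                   nk, ncol(spec$means)),
            2, spec$means[k, ], "+")
    })
  })
  mat <- do.call(rbind, rows)
  labels <- rep(seq_len(g), spec$sizes)
  gname <- rownames(spec$means)
  if (is.null(gname)) gname <- paste0("g", seq_len(g))
  table <- data.frame(
    molecule = sprintf("%s_%02d", gname[labels],
                       unlist(lapply(spec$sizes, seq_len))),
    mat, stringsAsFactors = FALSE
  )
  names(table)[-1] <- colnames(spec$means)
  list(table = table, labels = labels)
}

#' Generate synthetic energy triples
#'
#' Total-energy records (neutral, cation, anion; hartree) for a series of
#' molecules, constructed so that IP > EA always holds (positive hardness),
#' with spreads on the scale of small-aromatic ionization energetics
#' (IP ~ 7-11 eV, EA ~ -1 to +3 eV).
#'
#' @param n number of records.
#' @param seed RNG seed.
#' @return data frame `name`, `E_neutral`, `E_cation`, `E_anion` (hartree).
#' @export
make_energy_records <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    e0 <- stats::runif(n, -350, -230)
    ip <- stats::runif(n, 7, 11) / EV_PER_HARTREE
    ea <- stats::runif(n, -1, 3) / EV_PER_HARTREE
  })
  data.frame(
    name = sprintf("mol_%02d", seq_len(n)),
    E_neutral = e0,
    E_cation = e0 + ip,
    E_anion = e0 - ea,
    stringsAsFactors = FALSE
  )
}

#' Write a complete synthetic fixture set
#'
#' Emits punch files for a reference ring plus perturbed derivatives, an
#' energy table and a literature-style descriptor table into `dir`, so the
#' full pipeline can be exercised from files alone.
#'
#' @param dir destination directory (created if needed).
#' @param n_derivatives number of non-reference molecules.
#' @param seed RNG seed.
#' @return invisibly, a list of the paths written.
#' @export
write_fixture_set <- function(dir, n_derivatives = 15L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  ref <- make_ring_molecule(ring_spec(), name = "benzene_like")
  paths$reference <- file.path(dir, "benzene_like.punch")
  write_punch(ref, paths$reference)
  specs <- with_local_seed(seed, {
    lapply(seq_len(n_derivatives), function(i) {
      ring_spec(
        site_q20 = -0.4 * stats::runif(1, 0.7, 1.3),
        pi_pair_charge = 0.05 * stats::runif(1, 0.5, 1.5),
        sub_charge = sample(c(-1, 0, 0, 1), 1) * stats::runif(1, 0.3, 1),
        sub_distance = stats::runif(1, 2.0, 2.8)
      )
    })
  })
  paths$derivatives <- character(n_derivatives)
  for (i in seq_len(n_derivatives)) {
    mol <- make_ring_molecule(specs[[i]], name = sprintf("deriv_%02d", i))
    paths$derivatives[i] <- file.path(dir, sprintf("deriv_%02d.punch", i))
    write_punch(mol, paths$derivatives[i])
  }
  en <- make_energy_records(n_derivatives + 1L, seed = seed + 1L)
  en$name <- c("benzene_like", sprintf("deriv_%02d", seq_len(n_derivatives)))
  paths$energies <- file.path(dir, "energies.tsv")
  utils::write.table(format(en, digits = 17), paths$energies, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
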