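# Adiabatic IP/EA and conceptual-DFT global reactivity indices.
#
# Working unit is eV (energies arrive in hartree and are converted with the
# fixed CODATA factor).  The indices obey two closed-form identities used as
# invariants throughout the tests:
#   omega_minus - omega_plus = chi      and      2 * eta * omega = chi^2.

#' Adiabatic ionization potential and electron affinity
#'
#' `IP = E_cation - E_neutral` and `EA = E_neutral - E_anion`, with each
#' species at its own optimized geometry (adiabatic scheme).  Energies are
#' supplied in hartree and converted to eV.  A negative EA (unbound anion)
#' is physical and allowed.
#'
#' @param record list or one-row data frame with `E_neutral`, `E_cation`,
#'   `E_anion` in hartree.
#' @return named numeric vector `c(IP = , EA = )` in eV.
#' @export
ip_ea <- function(record) {
  e <- vapply(c("E_neutral", "E_cation", "E_anion"),
              function(k) as.numeric(record[[k]]), numeric(1))
  if (any(!is.finite(e))) dmaq2_stop("dmaq2_type_error", "non-finite energy")
  c(IP = (e[["E_cation"]] - e[["E_neutral"]]) * EV_PER_HARTREE,
    EA = (e[["E_neutral"]] - e[["E_anion"]]) * EV_PER_HARTREE)
}

#' Conceptual-DFT reactivity indices from IP and EA
#'
#' Electronegativity `chi = (IP + EA)/2`, chemical hardness
#' `eta = (IP - EA)/2`, electrophilicity `omega = (IP + EA)^2 / (4 (IP - EA))`,
#' electron-donating power `omega_minus = (3 IP + EA)^2 / (16 (IP - EA))` and
#' electron-accepting power `omega_plus = (IP + 3 EA)^2 / (16 (IP - EA))`.
#'
#' @param IP,EA ionization potential and electron affinity, eV.
#' @return one-row data frame with columns `IP`, `EA`, `chi`, `eta`,
#'   `omega`, `omega_minus`, `omega_plus` (eV).
#' @examples
#' conceptual_dft(10, 2)  # chi 6, eta 4, omega 4.5, omega- 8, omega+ 2
#' @export
conceptual_dft <- function(IP, EA) {
  if (!is.finite(IP) || !is.finite(EA))
    dmaq2_stop("dmaq2_type_error", "IP and EA must be finite")
  if (IP == EA)
    dmaq2_stop("dmaq2_degenerate_hardness",
               "IP equals EA: zero hardness, omega indices undefined")
  d <- IP - EA
  data.frame(
    IP = IP, EA = EA,
    chi = (IP + EA) / 2,
    eta = d / 2,
    omega = (IP + EA)^2 / (4 * d),
    omega_minus = (3 * IP + EA)^2 / (16 * d),
    omega_plus = (IP + 3 * EA)^2 / (16 * d)
  )
}

#' Reactivity table for a set of molecules
#'
#' Convenience wrapper: applies [ip_ea()] and [conceptual_dft()] to each row
#' of an energy table.
#'
#' @param energies data frame with columns `name`, `E_neutral`, `E_cation`,
#'   `E_anion` (hartree), e.g. from [read_energy_table()].
#' @return data frame: `molecule`, `IP`, `EA`, `chi`, `eta`, `omega`,
#'   `omega_minus`, `omega_plus` (eV).
#' @export
reactivity_table <- function(energies) {
  rows <- lapply(seq_len(nrow(energies)), function(i) {
    v <- ip_ea(energies[i, ])
    cbind(molecule = energies$name[i],
          conceptual_dft(v[["IP"]], v[["EA"]]))
  })
  do.call(rbind, rows)
}

#' Pairwise R-squared between descriptor and reactivity columns
#'
#' For every (descriptor, reactivity-index) column pair, the squared
#' Pearson correlation over the molecules present in both tables, matching
#' the scatter-plot R^2 convention (OLS coefficient of determination with
#' intercept).  Missing cells are dropped pairwise-complete; the n actually
#' used is reported per cell.
#'
#' @param descriptors data frame with a `molecule` column plus numeric
#'   descriptor columns.
#' @param reactivity data frame with a `molecule` column plus numeric index
#'   columns.
#' @param min_n minimum shared molecules per pair (default 3).
#' @return list with matrices `r_squared` and `n` (descriptors x indices).
#' @export
correlate_reactivity <- function(descriptors, reactivity, min_n = 3L) {
  shared <- intersect(descriptors$molecule, reactivity$molecule)
  if (length(shared) < min_n)
    dmaq2_stop("dmaq2_correlation_error",
               "only %d shared molecules (need >= %d)", length(shared), min_n)
  dcols <- setdiff(names(descriptors), "molecule")
  rcols <- setdiff(names(reactivity), "molecule")
  D <- descriptors[match(shared, descriptors$molecule), dcols, drop = FALSE]
  R <- reactivity[match(shared, reactivity$molecule), rcols, drop = FALSE]
  r2 <- matrix(NA_real_, length(dcols), length(rcols),
               dimnames = list(dcols, rcols))
  nm <- matrix(0L, length(dcols), length(rcols),
               dimnames = list(dcols, rcols))
  for (i in seq_along(dcols)) {
    for (j in seq_along(rcols)) {
      x <- D[[i]]; y <- R[[j]]
      ok <- is.finite(x) & is.finite(y)
      nm[i, j] <- sum(ok)
      if (sum(ok) < min_n) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        dmaq2_stop("dmaq2_correlation_error",
                   "zero-variance column in pair (%s, %s)", dcols[i], rcols[j])
      r2[i, j] <- stats::cor(x[ok], y[ok])^2
    }
  }
  list(r_squared = r2, n = nm)
}
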