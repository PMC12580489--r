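#' Physical constants and unit conversion
#'
#' All tensor algebra in this package is carried out in atomic units:
#' lengths in bohr (a0), charges in e, quadrupoles in e.a0^2, energies in
#' hartree.  Conversion factors are fixed (CODATA 2018) so that results are
#' bit-reproducible across platforms.
#'
#' @name units
NULL

#' Bohr per angstrom (CODATA 2018).
#' @export
BOHR_PER_ANGSTROM <- 1.8897261254578281

#' Electronvolt per hartree (CODATA 2018).
#' @export
EV_PER_HARTREE <- 27.211386245988

#' Convert lengths between angstrom and bohr
#'
#' @param x numeric vector or matrix of lengths.
#' @param from,to `"angstrom"` or `"bohr"`.
#' @return `x` expressed in the `to` unit.
#' @examples
#' convert_length(1, "angstrom", "bohr")
#' @export
convert_length <- function(x, from, to) {
  from <- match.arg(from, c("angstrom", "bohr"))
  to <- match.arg(to, c("angstrom", "bohr"))
  if (from == to) return(x)
  if (from == "angstrom") x * BOHR_PER_ANGSTROM else x / BOHR_PER_ANGSTROM
}

# internal: stop with a classed error so callers/tests can discriminate
dmaq2_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "dmaq2_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
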