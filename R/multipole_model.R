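# Domain types and I/O for distributed-multipole data, energies and
# descriptor tables.
#
# Real spherical multipole components follow Stone's ordering:
#   rank 0: Q00
#   rank 1: Q10, Q11c, Q11s
#   rank 2: Q20, Q21c, Q21s, Q22c, Q22s
#   rank l: 2l+1 further components (retained verbatim, unused downstream)
# all in atomic units (e.a0^l).

STONE_NAMES <- c(
  "Q00",
  "Q10", "Q11c", "Q11s",
  "Q20", "Q21c", "Q21s", "Q22c", "Q22s"
)

stone_component_names <- function(max_rank) {
  if (max_rank <= 2) return(STONE_NAMES[seq_len((max_rank + 1)^2)])
  extra <- unlist(lapply(3:max_rank, function(l) {
    paste0("Q", l, "_", seq_len(2 * l + 1))
  }))
  c(STONE_NAMES, extra)
}

#' Create a multipole expansion site
#'
#' One expansion center of a distributed multipole analysis: a labelled
#' position carrying real spherical multipole components in Stone ordering.
#'
#' @param label short site label, typically element symbol plus index.
#' @param position numeric length-3 position of the site (unit is carried by
#'   the enclosing molecule).
#' @param components numeric vector of `(max_rank + 1)^2` real spherical
#'   components in Stone ordering (Q00; Q10, Q11c, Q11s; Q20, Q21c, Q21s,
#'   Q22c, Q22s; ...), atomic units.
#' @param max_rank highest multipole rank carried; inferred from
#'   `length(components)` when `NULL`.
#' @return an object of class `multipole_site`.
#' @examples
#' multipole_site("C1", c(0, 0, 0), c(-0.05, 0, 0, 0, -0.4, 0, 0, 0, 0))
#' @export
multipole_site <- function(label, position, components, max_rank = NULL) {
  position <- as.numeric(position)
  components <- as.numeric(components)
  if (length(position) != 3L || any(!is.finite(position)))
    dmaq2_stop("dmaq2_type_error", "site '%s': position must be a finite 3-vector", label)
  if (is.null(max_rank)) {
    max_rank <- as.integer(round(sqrt(length(components)))) - 1L
  }
  max_rank <- as.integer(max_rank)
  if (max_rank < 0L || length(components) != (max_rank + 1L)^2)
    dmaq2_stop("dmaq2_type_error",
               "site '%s': %d components inconsistent with rank %d (need %d)",
               label, length(components), max_rank, (max_rank + 1L)^2)
  n_low <- min(length(components), 9L)
  if (any(!is.finite(components[seq_len(n_low)])))
    dmaq2_stop("dmaq2_type_error", "site '%s': non-finite component of rank <= 2", label)
  names(components) <- stone_component_names(max_rank)
  structure(
    list(label = as.character(label), position = position,
         max_rank = max_rank, components = components),
    class = "multipole_site"
  )
}

# component accessor padding absent ranks with zero
site_component <- function(site, name) {
  i <- match(name, names(site$components))
  if (is.na(i)) 0 else unname(site$components[[i]])
}

# the five rank-2 components as a named numeric vector (zeros when absent)
site_q2 <- function(site) {
  vapply(STONE_NAMES[5:9], function(nm) site_component(site, nm), numeric(1))
}

site_dipole <- function(site) {
  # Cartesian dipole (mu_x, mu_y, mu_z) = (Q11c, Q11s, Q10)
  c(site_component(site, "Q11c"), site_component(site, "Q11s"),
    site_component(site, "Q10"))
}

#' Create a molecule of multipole sites
#'
#' @param name molecule name.
#' @param sites list of [multipole_site()] objects.
#' @param ring_atom_indices integer indices (into `sites`) of the ring heavy
#'   atoms, typically six. Required for descriptor computation; may be empty
#'   for plain containers.
#' @param length_unit `"angstrom"` or `"bohr"`; unit of all site positions.
#' @param net_charge net molecular charge in e; defaults to the rounded sum
#'   of site monopoles.
#' @return an object of class `molecule_multipoles`.
#' @export
molecule_multipoles <- function(name, sites, ring_atom_indices = integer(),
                                length_unit = c("angstrom", "bohr"),
                                net_charge = NULL) {
  length_unit <- match.arg(length_unit)
  if (!length(sites) || !all(vapply(sites, inherits, logical(1), "multipole_site")))
    dmaq2_stop("dmaq2_type_error", "'sites' must be a non-empty list of multipole_site")
  ring_atom_indices <- as.integer(ring_atom_indices)
  if (anyDuplicated(ring_atom_indices) ||
      any(ring_atom_indices < 1L | ring_atom_indices > length(sites)))
    dmaq2_stop("dmaq2_type_error",
               "ring_atom_indices must be distinct indices in 1..%d", length(sites))
  if (is.null(net_charge)) {
    net_charge <- as.integer(round(sum(vapply(sites, site_component, numeric(1), "Q00"))))
  }
  structure(
    list(name = as.character(name), sites = sites,
         ring_atom_indices = ring_atom_indices,
         length_unit = length_unit, net_charge = as.integer(net_charge)),
    class = "molecule_multipoles"
  )
}

#' @export
print.molecule_multipoles <- function(x, ...) {
  cat(sprintf("<molecule_multipoles> %s: %d sites (max rank %d), %d ring atoms, unit %s, charge %+d e\n",
              x$name, length(x$sites),
              max(vapply(x$sites, `[[`, integer(1), "max_rank")),
              length(x$ring_atom_indices), x$length_unit, x$net_charge))
  invisible(x)
}

site_positions <- function(mol) {
  t(vapply(mol$sites, `[[`, numeric(3), "position"))
}

# ---------------------------------------------------------------------------
# punch-dialect parsing

# tokenizes punch text, keeping the source line of every token
punch_tokens <- function(lines) {
  lines <- sub("!.*$", "", lines)
  toks <- lapply(seq_along(lines), function(i) {
    t <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    t <- t[nzchar(t)]
    if (length(t)) data.frame(tok = t, line = i) else NULL
  })
  do.call(rbind, c(toks, list(NULL)))
}

as_num_strict <- function(tok) {
  suppressWarnings(as.numeric(tok))
}

#' Parse a punch-dialect multipole file
#'
#' Reads the documented punch grammar: an optional leading line
#' `units angstrom|bohr`, then per site a header line
#' `label x y z rank k` followed by `(k+1)^2` whitespace-separated real
#' spherical components in Stone ordering; `!` starts a comment.  Content
#' that does not form a complete further site once a molecule is read is an
#' error, never silently ignored.
#'
#' @param file path to a punch file (or `NULL` when `text` given).
#' @param text character vector of punch lines, as an alternative to `file`.
#' @param name molecule name; defaults to the file base name or "molecule".
#' @param ring_atoms integer ring-atom site indices; ring designation is
#'   configuration, never inferred here (see [infer_ring_atoms()]).
#' @param default_unit unit assumed when the file declares none
#'   (angstrom, GDMA's customary output unit).
#' @return a [molecule_multipoles()] object.
#' @seealso [write_punch()]
#' @export
parse_multipole_file <- function(file = NULL, text = NULL, name = NULL,
                                 ring_atoms = integer(),
                                 default_unit = "angstrom") {
  if (is.null(text)) {
    if (is.null(file)) dmaq2_stop("dmaq2_parse_error", "either 'file' or 'text' required")
    text <- readLines(file, warn = FALSE)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(file))
  }
  if (is.null(name)) name <- "molecule"
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  tk <- punch_tokens(text)
  if (is.null(tk) || !nrow(tk))
    dmaq2_stop("dmaq2_parse_error", "empty punch input")

  unit <- default_unit
  pos <- 1L
  if (tolower(tk$tok[1]) == "units") {
    if (nrow(tk) < 2L)
      dmaq2_stop("dmaq2_parse_error", "line %d: 'units' without a unit keyword", tk$line[1])
    u <- tolower(tk$tok[2])
    if (!u %in% c("angstrom", "bohr"))
      dmaq2_stop("dmaq2_parse_error", "line %d: unknown unit keyword '%s'", tk$line[2], tk$tok[2])
    unit <- u
    pos <- 3L
  }

  sites <- list()
  n <- nrow(tk)
  while (pos <= n) {
    if (pos + 5L > n)
      dmaq2_stop("dmaq2_parse_error",
                 "line %d: incomplete site header (trailing content?)", tk$line[pos])
    label <- tk$tok[pos]
    xyz <- as_num_strict(tk$tok[pos + 1:3])
    if (any(is.na(xyz)))
      dmaq2_stop("dmaq2_parse_error",
                 "line %d: malformed site header for '%s' (non-numeric coordinate)",
                 tk$line[pos], label)
    if (tolower(tk$tok[pos + 4L]) != "rank")
      dmaq2_stop("dmaq2_parse_error",
                 "line %d: malformed site header for '%s' (expected 'rank', got '%s')",
                 tk$line[pos], label, tk$tok[pos + 4L])
    k <- as_num_strict(tk$tok[pos + 5L])
    if (is.na(k) || k != round(k) || k < 0)
      dmaq2_stop("dmaq2_parse_error",
                 "line %d: malformed rank '%s' for site '%s'",
                 tk$line[pos], tk$tok[pos + 5L], label)
    k <- as.integer(k)
    ncomp <- (k + 1L)^2
    if (pos + 5L + ncomp > n)
      dmaq2_stop("dmaq2_parse_error",
                 "line %d: site '%s' declares rank %d (%d components) but input ends early",
                 tk$line[pos], label, k, ncomp)
    comp <- as_num_strict(tk$tok[pos + 5L + seq_len(ncomp)])
    if (any(is.na(comp))) {
      bad <- which(is.na(comp))[1]
      dmaq2_stop("dmaq2_parse_error",
                 "line %d: non-numeric component %d of site '%s' ('%s')",
                 tk$line[pos + 5L + bad], bad, label, tk$tok[pos + 5L + bad])
    }
    sites[[length(sites) + 1L]] <- multipole_site(label, xyz, comp, max_rank = k)
    pos <- pos + 6L + ncomp
  }
  if (!length(sites))
    dmaq2_stop("dmaq2_parse_error", "no sites found in punch input")
  molecule_multipoles(name, sites, ring_atom_indices = ring_atoms,
                      length_unit = unit)
}

#' Write a molecule in the punch dialect
#'
#' Inverse of [parse_multipole_file()].  Numbers are written with 17
#' significant digits so that write-then-parse round-trips doubles exactly.
#'
#' @param mol a [molecule_multipoles()] object.
#' @param file destination path, or `NULL` to return the lines invisibly.
#' @return the punch lines, invisibly when written to `file`.
#' @export
write_punch <- function(mol, file = NULL) {
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(paste("units", mol$length_unit))
  for (s in mol$sites) {
    lines <- c(lines,
               paste(s$label, fmt(s$position[1]), fmt(s$position[2]),
                     fmt(s$position[3]), "rank", s$max_rank),
               paste(fmt(s$components), collapse = "  "))
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

# ---------------------------------------------------------------------------
# tabular I/O

#' Read a total-energy table
#'
#' Delimited table with columns `name`, `E_neutral`, `E_cation`, `E_anion`
#' (total electronic energies in hartree; the cation and anion entries come
#' from separately optimized geometries for the adiabatic scheme).
#'
#' @param file path to a whitespace- or tab-delimited table with a header.
#' @return data frame with the four columns, energies numeric.
#' @export
read_energy_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  need <- c("name", "E_neutral", "E_cation", "E_anion")
  if (!all(need %in% names(df)))
    dmaq2_stop("dmaq2_parse_error", "energy table must have columns: %s",
               paste(need, collapse = ", "))
  for (cc in need[-1]) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(!is.finite(df[[cc]])))
      dmaq2_stop("dmaq2_parse_error", "non-finite energy in column '%s'", cc)
  }
  df[, need]
}

# canonical descriptor column order for reports
DESCRIPTOR_COLUMNS <- c("Q2_ring_atoms", "Q2zz_ring_atoms", "Q2_origin",
                        "Q2zz_origin", "Q2_1", "Q2_1zz")

#' Write a descriptor table
#'
#' Serializes a molecules-by-descriptors table as tab-separated text with a
#' deterministic column order (`molecule`, the six Q2 descriptors, their
#' `_norm` variants, then any remaining columns in alphabetical order) and
#' full double precision, so [read_descriptor_table()] reproduces the values
#' exactly.  Missing cells are written as the empty field.
#'
#' @param table data frame; one row per molecule, a `molecule` name column
#'   plus named numeric descriptor columns.
#' @param file destination path.
#' @return the reordered table, invisibly.
#' @export
write_descriptor_report <- function(table, file) {
  if (!is.data.frame(table) || !nrow(table) || !ncol(table))
    dmaq2_stop("dmaq2_io_error", "descriptor table is empty")
  if (anyDuplicated(names(table)))
    dmaq2_stop("dmaq2_io_error", "descriptor table has duplicate column names")
  canon <- c("molecule", DESCRIPTOR_COLUMNS, paste0(DESCRIPTOR_COLUMNS, "_norm"))
  ord <- c(intersect(canon, names(table)),
           sort(setdiff(names(table), canon)))
  table <- table[, ord, drop = FALSE]
  out <- table
  for (cc in names(out)) {
    if (is.numeric(out[[cc]])) {
      v <- sprintf("%.17g", out[[cc]])
      v[is.na(out[[cc]])] <- ""
      out[[cc]] <- v
    }
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(table)
}

#' Read a descriptor table written by [write_descriptor_report()]
#'
#' Also reads any delimited molecules-by-descriptors table with a `molecule`
#' (or first) name column, e.g. literature aromaticity-index tables (HOMA,
#' AIvib, BVI, Iring, MCI, NICS0, NICS1, NICS1zz).  Empty fields become `NA`.
#'
#' @param file path to the table.
#' @param sep field separator, tab by default.
#' @return data frame with a `molecule` character column and numeric
#'   descriptor columns.
#' @export
read_descriptor_table <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  if (!"molecule" %in% names(df)) names(df)[1] <- "molecule"
  df$molecule <- as.character(df$molecule)
  for (cc in setdiff(names(df), "molecule")) df[[cc]] <- as.numeric(df[[cc]])
  df
}

# ---------------------------------------------------------------------------

#' Heuristic six-membered-ring detection
#'
#' Optional helper that looks for exactly one 6-cycle of heavy-atom sites
#' whose consecutive distances lie in a bonding window (1.20-1.60 angstrom).
#' It is never applied implicitly: descriptor computation requires ring
#' atoms to be designated explicitly.
#'
#' @param mol a [molecule_multipoles()] object.
#' @param d_min,d_max bonding-distance window in angstrom.
#' @return integer vector of six site indices (in ring order).
#' @export
infer_ring_atoms <- function(mol, d_min = 1.20, d_max = 1.60) {
  pos <- site_positions(mol)
  pos_ang <- convert_length(pos, mol$length_unit, "angstrom")
  heavy <- which(!grepl("^H", vapply(mol$sites, `[[`, character(1), "label")))
  if (length(heavy) < 6L)
    dmaq2_stop("dmaq2_ring_error", "fewer than 6 heavy-atom sites")
  d <- as.matrix(stats::dist(pos_ang[heavy, , drop = FALSE]))
  adj <- d >= d_min & d <= d_max
  nh <- length(heavy)
  cycles <- list()
  # DFS for 6-cycles, canonicalized to avoid duplicates
  path <- integer(6)
  visit <- function(start, v, depth) {
    path[depth] <<- v
    if (depth == 6L) {
      if (adj[v, start]) {
        cyc <- path
        # canonical form: rotate to min, pick lexicographically smaller direction
        i0 <- which.min(cyc)
        r1 <- cyc[((seq_len(6) + i0 - 2L) %% 6L) + 1L]
        r2 <- rev(cyc)
        i0 <- which.min(r2)
        r2 <- r2[((seq_len(6) + i0 - 2L) %% 6L) + 1L]
        key <- paste(if (paste(r1, collapse = ",") < paste(r2, collapse = ","))
          r1 else r2, collapse = ",")
        cycles[[key]] <<- cyc
      }
      return(invisible())
    }
    for (w in seq_len(nh)) {
      if (adj[v, w] && !(w %in% path[seq_len(depth)]) && w > start)
        visit(start, w, depth + 1L)
    }
  }
  for (s in seq_len(nh)) visit(s, s, 1L)
  if (length(cycles) != 1L)
    dmaq2_stop("dmaq2_ring_error",
               "expected exactly one heavy-atom 6-cycle, found %d", length(cycles))
  heavy[cycles[[1]]]
}
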