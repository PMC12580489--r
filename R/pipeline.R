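# Orchestration: a declarative run configuration and the two drivers tying
# the stages together (descriptor stage; full descriptor -> reactivity ->
# chemometrics analysis).  The numbered scripts under analysis/ are thin
# wrappers over these functions.

#' Create a run configuration
#'
#' @param inputs named list of punch inputs: either file paths or
#'   [molecule_multipoles()] objects; names are molecule names.
#' @param reference name of the normalization reference molecule (benzene
#'   role); `NULL` disables normalization.
#' @param ring_atoms named list of integer ring-atom index vectors per
#'   molecule (unnamed single vector applies to all); `NULL` uses indices
#'   already present on molecule objects.
#' @param unit length-unit override for parsed files (`NULL`: per-file
#'   metadata / dialect default).
#' @param z_grid numeric `c(min, max, step)` in angstrom for [scan_z()].
#' @param k number of clusters for the dendrogram cut.
#' @param seed seed for any stochastic stage.
#' @param energies energy table (data frame or file path) for the
#'   reactivity stage; `NULL` skips it.
#' @param out_dir directory for written artifacts; `NULL` writes nothing.
#' @return list of class `run_config`.
#' @export
run_config <- function(inputs, reference = NULL, ring_atoms = NULL,
                       unit = NULL, z_grid = c(0.1, 3.0, 0.05),
                       k = 4L, seed = 1L, energies = NULL, out_dir = NULL) {
  if (!length(inputs)) dmaq2_stop("dmaq2_config_error", "no inputs")
  if (!is.null(reference) && !reference %in% names(inputs))
    dmaq2_stop("dmaq2_config_error",
               "reference '%s' is not among the inputs", reference)
  structure(list(inputs = inputs, reference = reference,
                 ring_atoms = ring_atoms, unit = unit, z_grid = z_grid,
                 k = as.integer(k), seed = as.integer(seed),
                 energies = energies, out_dir = out_dir),
            class = "run_config")
}

load_config_molecule <- function(config, name) {
  x <- config$inputs[[name]]
  ra <- integer()
  if (!is.null(config$ring_atoms)) {
    ra <- if (is.list(config$ring_atoms)) config$ring_atoms[[name]]
          else config$ring_atoms
    if (is.null(ra)) ra <- integer()
  }
  if (inherits(x, "molecule_multipoles")) {
    if (length(ra)) x$ring_atom_indices <- as.integer(ra)
    return(x)
  }
  parse_multipole_file(file = x, name = name, ring_atoms = ra,
                       default_unit = if (is.null(config$unit)) "angstrom"
                                      else config$unit)
}

#' Run the descriptor stage of the workflow
#'
#' Loads (or accepts) each molecule, canonicalizes its frame, computes the
#' six Q2 descriptors, and — when a reference is configured — appends the
#' benzene-normalized columns.  Output ordering follows the input order,
#' so re-runs are bit-identical.
#'
#' @param config a [run_config()].
#' @return descriptor data frame (raw + `_norm` columns); attribute
#'   `conventions` records the convention choices in force.
#' @export
run_descriptors <- function(config) {
  rows <- lapply(names(config$inputs), function(nm) {
    mol <- load_config_molecule(config, nm)
    if (!length(mol$ring_atom_indices))
      dmaq2_stop("dmaq2_config_error", "molecule '%s': ring atoms not designated", nm)
    compute_descriptors(canonicalize(mol))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(config$reference))
    tab <- normalize_descriptors(tab, config$reference)
  attr(tab, "conventions") <- list(
    magnitude = "euclidean norm of the 5 real spherical components",
    ring_atom_sum = "sum of per-site magnitudes (ring heavy atoms only)",
    translated = "magnitude/Q20 of the summed translated tensor, all sites",
    length_factor_bohr_per_angstrom = BOHR_PER_ANGSTROM
  )
  tab
}

#' Run the full analysis workflow
#'
#' Descriptors (raw + normalized) for every input molecule, reactivity
#' indices from the configured energy table, the R-squared screen between
#' the two, and the chemometric stage (z-score, PCA, Ward clustering, cut
#' at `k`).  When `config$out_dir` is set, every stage's table is written
#' there together with a JSON-free plain-text run manifest recording the
#' convention choices.
#'
#' @param config a [run_config()].
#' @return list: `descriptors`, `reactivity` (or `NULL`), `r_squared` (or
#'   `NULL`), `pca`, `dendrogram`, `clusters`.
#' @export
run_full_analysis <- function(config) {
  descriptors <- run_descriptors(config)

  reactivity <- NULL
  r2 <- NULL
  if (!is.null(config$energies)) {
    en <- if (is.character(config$energies)) read_energy_table(config$energies)
          else config$energies
    reactivity <- reactivity_table(en)
    desc_cols <- intersect(c("molecule", paste0(DESCRIPTOR_COLUMNS, "_norm"),
                             DESCRIPTOR_COLUMNS), names(descriptors))
    r2 <- correlate_reactivity(descriptors[, desc_cols, drop = FALSE],
                               reactivity)
  }

  use <- if (all(paste0(DESCRIPTOR_COLUMNS, "_norm") %in% names(descriptors)))
    paste0(DESCRIPTOR_COLUMNS, "_norm") else DESCRIPTOR_COLUMNS
  m <- as.matrix(descriptors[, use, drop = FALSE])
  rownames(m) <- descriptors$molecule
  z <- zscore(m)
  pc <- pca(z)
  dend <- ward_hca(z)
  clusters <- cut_clusters(dend, min(config$k, nrow(m)))

  out <- list(descriptors = descriptors, reactivity = reactivity,
              r_squared = r2, pca = pc, dendrogram = dend,
              clusters = clusters)
  if (!is.null(config$out_dir)) write_analysis_artifacts(out, config)
  out
}

write_analysis_artifacts <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_descriptor_report(out$descriptors, p("descriptors.tsv"))
  if (!is.null(out$reactivity))
    utils::write.table(format(out$reactivity, digits = 17), p("reactivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$r_squared)) {
    utils::write.table(round(out$r_squared$r_squared, 6), p("r_squared.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(out$r_squared$n, p("r_squared_n.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  scores <- data.frame(molecule = rownames(out$pca$scores),
                       out$pca$scores[, 1:2, drop = FALSE])
  utils::write.table(format(scores, digits = 10), p("pca_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$dendrogram$merges, p("dendrogram_merges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(molecule = names(out$clusters),
                                cluster = unname(out$clusters)),
                     p("clusters.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- c(
    "dmaq2 run manifest",
    sprintf("k = %d, seed = %d", config$k, config$seed),
    sprintf("reference = %s",
            if (is.null(config$reference)) "(none)" else config$reference),
    "magnitude convention: euclidean norm of 5 real spherical components",
    "ring-atom sums: per-site magnitudes over designated ring atoms",
    "z-score: population (divide-by-n) standard deviation",
    "ward heights: delta-ESS (hclust ward.D on squared distances = 2x)",
    sprintf("bohr per angstrom = %.16g", BOHR_PER_ANGSTROM),
    sprintf("eV per hartree = %.12g", EV_PER_HARTREE)
  )
  writeLines(manifest, p("run_manifest.txt"))
  invisible(NULL)
}
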