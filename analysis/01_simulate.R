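#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# The real study derives site multipoles from DFT densities partitioned by
# GDMA; here the synthetic-data module builds a benzene-like reference ring
# plus a family of perturbed derivatives (varied site quadrupoles, pi
# density, charged in-plane substituents) and matching energy triples, so
# every later stage runs from plain text files with no quantum chemistry.

library(dmaq2)

seed <- 20260925
fix_dir <- file.path("results", "fixtures")
paths <- write_fixture_set(fix_dir, n_derivatives = 15L, seed = seed)

cat("wrote", length(paths$derivatives) + 1L, "punch files and",
    basename(paths$energies), "to", fix_dir, "\n")

ref <- parse_multipole_file(paths$reference, ring_atoms = 1:6)
cat(sprintf("reference '%s': %d sites, unit %s, net charge %+d e\n",
            ref$name, length(ref$sites), ref$length_unit, ref$net_charge))
stopifnot(is_canonical(ref))
cat("reference is canonical (ring centroid at origin, ring in xy-plane)\n")
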