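# Fixtures built in code; nothing is read from disk except files the tests
# themselves write to tempdir().

toy_catalogue <- function() {
  catalogue(data.frame(
    id = c("Sec61a1", "Sec61b", "Sec61g", "Hspa5", "Psma1", "Psma2", "Xbp1"),
    subsystems = c("translocation", "translocation", "translocation",
                   "protein_folding;UPR", "ERAD", "ERAD", "UPR"),
    functional_groups = c("sec61_pore", "sec61_pore", "sec61_pore",
                          "chaperones", "", "", ""),
    complexes = c("SEC61", "SEC61", "SEC61", "", "PSMA", "PSMA", ""),
    core = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE))
}

toy_interactions <- function() {
  interactions(c("Sec61a1", "Hspa5"), c("Hspa5", "Xbp1"),
               interaction_class = c("protein_protein", "protein_DNA"),
               provenance = "toy")
}

# Catalogue of n components carved into complexes with the given sizes;
# used by the enrichment calibration tests.
complex_catalogue <- function(n, complex_sizes) {
  ids <- sprintf("G%03d", seq_len(n))
  complexes <- rep("", n)
  idx <- 0
  for (k in seq_along(complex_sizes)) {
    complexes[idx + seq_len(complex_sizes[k])] <- sprintf("CPX%02d", k)
    idx <- idx + complex_sizes[k]
  }
  catalogue(data.frame(id = ids, subsystems = "other",
                       complexes = complexes, stringsAsFactors = FALSE))
}

# Small expression matrix with two clean modules and independent background.
module_expression <- function(n_per_module = 6, n_background = 4,
                              n_samples = 20, noise_sd = 0.2, seed = 1) {
  spec <- synthetic_spec(n_genes = 2 * n_per_module + n_background,
                         n_samples = n_samples,
                         module_sizes = c(n_per_module, n_per_module),
                         noise_sd = noise_sd, regulators = NULL, seed = seed)
  generate_modular_expression(spec)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
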