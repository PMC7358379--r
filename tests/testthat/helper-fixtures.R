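# In-code fixtures shared across test files. Everything is built at test
# time; nothing is read from disk except files the tests themselves write.

# One plex, two groups in duplicate plus two pooled-reference channels.
tiny_design <- function(plex = "p1") {
  plex_design(plex, c("126", "127N", "127C", "128N", "128C", "129N"),
              c("T_1", "T_2", "C_1", "C_2", paste0(plex, "_ref1"),
                paste0(plex, "_ref2")),
              c("TREAT", "TREAT", "DMSO", "DMSO", "POOLED_REF", "POOLED_REF"),
              c(1L, 2L, 1L, 2L, 1L, 2L))
}

# Reporter table straight from a matrix (rows named by accession, columns in
# design channel order).
table_from_matrix <- function(design, mat, localization = NULL) {
  acc <- rownames(mat)
  colnames(mat) <- design$channel
  ann <- data.frame(
    accession = acc, gene_symbol = paste0("G_", acc),
    localization = if (is.null(localization)) rep("unknown", length(acc))
                   else localization,
    psm_count = NA_integer_, stringsAsFactors = FALSE)
  structure(list(plex_id = design_plex_id(design), accessions = acc,
                 annotations = ann, intensities = mat),
            class = "reporter_table")
}

# Write a data frame as the TSV dialect the readers expect.
write_fixture_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  path
}

# A single-plex design holding all six groups in triplicate plus two pooled
# channels; within one plex the reference factor cancels in group
# comparisons, so t-tests are calibrated at their nominal level.
singleplex_design <- function(treatments = c("FCCP", "dinoterb",
                                             "picoxystrobin", "pinacyanol",
                                             "triclocarban"),
                              control = "DMSO", reps = 3L) {
  groups <- c(control, treatments)
  n <- length(groups) * reps
  plex_design("mono", sprintf("ch%02d", seq_len(n + 2L)),
              c(paste(rep(groups, each = reps), rep(seq_len(reps),
                                                    length(groups)),
                      sep = "_"), "pool_a", "pool_b"),
              c(rep(groups, each = reps), "POOLED_REF", "POOLED_REF"),
              c(rep(seq_len(reps), length(groups)), 1L, 2L))
}
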