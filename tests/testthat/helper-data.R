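# Small in-code fixtures shared across tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(L, ids = "P1") {
  data.frame(id = ids, sequence = paste(sample(AA20, L, replace = TRUE),
                                        collapse = ""))
}

# A protein with known sites at given positions: the residue at each site is
# forced to S (or the given residues).
protein_with_sites <- function(L, positions, residues = "S", id = "P1") {
  chars <- sample(AA20, L, replace = TRUE)
  residues <- rep_len(residues, length(positions))
  chars[positions + 1L] <- residues
  list(proteome = data.frame(id = id, sequence = paste(chars, collapse = "")),
       psites = data.frame(protein_id = id, position = as.integer(positions),
                           residue = residues))
}

full_coverage <- function(proteome) {
  data.frame(protein_id = proteome$id, start = 0L,
             end = nchar(proteome$sequence))
}

# Linearly separable labeled windows: positives are poly-S + noise windows,
# negatives poly-L + noise, each group_id holding a few windows.
separable_windows <- function(n_groups = 10L, per_group = 4L) {
  mk <- function(base, label, prefix) {
    rows <- list()
    for (g in seq_len(n_groups)) for (i in seq_len(per_group)) {
      chars <- rep(base, 17L)
      idx <- sample(17L, 5L)
      chars[idx] <- sample(AA20, 5L, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        window = paste(chars, collapse = ""), label = label,
        group_id = paste0(prefix, g), start = 0L)
    }
    do.call(rbind, rows)
  }
  rbind(mk("S", "positive", "pos"), mk("L", "negative", "neg"))
}
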