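# Independent oracles, deliberately coded differently from the package
# implementation, plus small fixture helpers shared across test files.

# residue-by-residue mass summation oracle for b/y ions (no cumsum)
oracle_fragment_mz <- function(sequence, ion_type, ordinal, charge) {
  res <- strsplit(sequence, "")[[1]]
  masses <- vapply(res, function(r) hlaswath::AA_MONO[[r]], 0)
  piece <- if (ion_type == "b") masses[seq_len(ordinal)]
           else masses[(length(masses) - ordinal + 1):length(masses)]
  neutral <- sum(piece) + if (ion_type == "y") 18.010565 else 0
  (neutral + charge * 1.007276) / charge
}

random_peptide <- function(min_len = 8, max_len = 12) {
  paste(sample(names(hlaswath::AA_MONO),
               sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

# consensus entry with peaks exactly on the theoretical singly charged
# b/y ladder; intensities supplied or drawn
ladder_entry <- function(sequence, charge = 2, intensities = NULL,
                         irt = 50, allele = "A02") {
  theo <- hlaswath::theoretical_fragments(sequence, c("b", "y"), 1L)
  if (is.null(intensities)) intensities <- seq_len(nrow(theo)) * 100
  sp <- hlaswath::peak_spectrum(
    sequence, charge,
    data.frame(mz = theo$mz, intensity = intensities), irt = irt)
  hlaswath::build_consensus(list(sp), allele = allele)
}
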