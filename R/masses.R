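# Monoisotopic residue masses and b/y fragment-ion m/z computation.
# Only the 20 standard residues are supported; no neutral losses,
# no a/x/c/z series (library generation selects b/y ions only).

#' Monoisotopic residue masses (Da)
#'
#' Named vector of monoisotopic masses for the 20 standard amino-acid
#' residues (residue = amino acid minus water).
#'
#' @format Named numeric vector, names are one-letter residue codes.
#' @export
AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276
WATER_MASS  <- 18.010565

.residue_masses <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(AA_MONO))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue '%s' at position %d in '%s'",
                 res[bad[1]], bad[1], sequence), call. = FALSE)
  }
  unname(AA_MONO[res])
}

#' Peptide neutral monoisotopic mass
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence) {
  sum(.residue_masses(sequence)) + WATER_MASS
}

#' Precursor m/z of a peptide ion
#'
#' @param sequence Peptide sequence.
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
precursor_mz <- function(sequence, charge) {
  stopifnot(length(charge) == 1, charge >= 1)
  (peptide_mass(sequence) + charge * PROTON_MASS) / charge
}

#' b/y fragment-ion m/z
#'
#' Computes monoisotopic m/z for b or y ions of a peptide:
#' b_k = (sum of the first k residue masses + z * proton) / z,
#' y_k = (sum of the last k residue masses + water + z * proton) / z.
#'
#' @param sequence Peptide sequence (standard residues only).
#' @param ion_type `"b"` or `"y"` (recycled against `ordinal`/`charge`).
#' @param ordinal Fragment ordinal, 1 <= ordinal <= nchar(sequence) - 1.
#' @param charge Fragment charge (>= 1).
#' @return Numeric vector of m/z values (Th).
#' @examples
#' fragment_mz("KLEEQARAK", "y", 1, 1)  # 147.1128 (C-terminal K)
#' @export
fragment_mz <- function(sequence, ion_type, ordinal, charge = 1L) {
  n <- nchar(sequence)
  args <- data.frame(ion_type = ion_type, ordinal = ordinal, charge = charge,
                     stringsAsFactors = FALSE)
  if (any(!args$ion_type %in% c("b", "y")))
    stop("ion_type must be 'b' or 'y'", call. = FALSE)
  if (any(args$ordinal < 1 | args$ordinal > n - 1))
    stop(sprintf("ordinal must be in [1, %d] for '%s'", n - 1, sequence),
         call. = FALSE)
  if (any(args$charge < 1)) stop("charge must be >= 1", call. = FALSE)
  m <- .residue_masses(sequence)
  pre <- cumsum(m)            # pre[k]  = mass of first k residues
  suf <- rev(cumsum(rev(m)))  # suf[k'] = mass of residues k'..n
  neutral <- ifelse(args$ion_type == "b",
                    pre[args$ordinal],
                    suf[n - args$ordinal + 1] + WATER_MASS)
  (neutral + args$charge * PROTON_MASS) / args$charge
}

#' Theoretical b/y fragment table for a peptide
#'
#' Enumerates all b/y fragments over the requested ion types, ordinals and
#' fragment charges.
#'
#' @param sequence Peptide sequence.
#' @param ion_types Character subset of `c("b","y")`.
#' @param charges Integer vector of fragment charges.
#' @return data.frame with columns `ion_type`, `ordinal`, `charge`, `mz`.
#' @export
theoretical_fragments <- function(sequence, ion_types = c("b", "y"),
                                  charges = c(1L, 2L)) {
  n <- nchar(sequence)
  if (n < 2) stop("sequence must have >= 2 residues", call. = FALSE)
  grid <- expand.grid(ordinal = seq_len(n - 1), ion_type = ion_types,
                      charge = as.integer(charges),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mz <- fragment_mz(sequence, grid$ion_type, grid$ordinal, grid$charge)
  grid[, c("ion_type", "ordinal", "charge", "mz")]
}
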