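# Target-decoy FDR at peptide level and the annotation-corrected FDR.
#
# FDR estimator is the plain target-decoy ratio decoys/targets (no +1
# pseudocount, no pi0 correction). The corrected FDR (cFDR) re-counts
# decoys and targets after removing every peptide that failed HLA-allele
# annotation; because contaminant/noise sequences rarely carry an allele
# motif, the surviving decoy count drops faster than the target count.

#' Filter identified peptides by probability and length
#'
#' Keeps peptides with search probability >= `min_probability` and sequence
#' length within `[min_len, max_len]` (class I default 8-12 residues).
#' Decoy rows are filtered by the same criteria but never removed for being
#' decoys - they are needed for FDR accounting downstream.
#'
#' @param peptides data.frame with at least `sequence` and `probability`
#'   columns (an `is_decoy` column, if present, is carried through).
#' @param min_probability Probability floor (default 0.7).
#' @param min_len,max_len Allowed residue-length range (defaults 8 and 12).
#' @return The filtered data.frame.
#' @export
filter_peptides <- function(peptides, min_probability = 0.7,
                            min_len = 8L, max_len = 12L) {
  len <- nchar(peptides$sequence)
  keep <- peptides$probability >= min_probability &
    len >= min_len & len <= max_len
  peptides[keep, , drop = FALSE]
}

#' Collapse spectrum-level rows to peptide level
#'
#' Keeps the best (highest) probability per distinct (sequence, charge)
#' pair, so FDR accounting is peptide-level rather than PSM-level.
#'
#' @param peptides Identification data.frame with `sequence`, `charge`,
#'   `probability` columns.
#' @return One row per (sequence, charge), best probability retained.
#' @export
collapse_psms <- function(peptides) {
  key <- paste(peptides$sequence, peptides$charge, sep = "/")
  ord <- order(key, -peptides$probability)
  x <- peptides[ord, , drop = FALSE]
  x[!duplicated(key[ord]), , drop = FALSE]
}

#' Target-decoy FDR threshold
#'
#' Scans thresholds at the observed probability values and returns the
#' lowest (most permissive) threshold at which decoys/targets <= `target_fdr`.
#' When several thresholds achieve the bound the one maximizing the target
#' count is chosen (deterministic tie-break).
#'
#' @param peptides data.frame with `probability` and logical `is_decoy`.
#' @param target_fdr Desired FDR, in (0, 1).
#' @return List of class `fdr_result`: `threshold_probability`, `n_targets`,
#'   `n_decoys`, `fdr`. If no threshold achieves the bound a warning is
#'   signalled and `n_targets` is 0.
#' @export
fdr_threshold <- function(peptides, target_fdr) {
  stopifnot(target_fdr > 0, target_fdr < 1)
  p <- peptides$probability
  d <- as.logical(peptides$is_decoy)
  thr <- sort(unique(p), decreasing = TRUE)
  best <- NULL
  for (t in thr) {
    nt <- sum(p >= t & !d)
    nd <- sum(p >= t & d)
    fdr <- if (nt == 0) { if (nd == 0) 0 else Inf } else nd / nt
    if (fdr <= target_fdr && (is.null(best) || nt > best$n_targets)) {
      best <- list(threshold_probability = t, n_targets = nt,
                   n_decoys = nd, fdr = fdr)
    }
  }
  if (is.null(best)) {
    warning("no threshold achieves FDR <= ", target_fdr, call. = FALSE)
    best <- list(threshold_probability = Inf, n_targets = 0L,
                 n_decoys = 0L, fdr = 0)
  }
  structure(best, class = "fdr_result")
}

#' Annotation-corrected FDR (cFDR)
#'
#' Restricts the FDR-passing set (targets and decoys, both scored by the
#' same binding predictor) to peptides with annotation status `annotated`
#' and recomputes decoys/targets on the survivors.
#'
#' @param peptides_passing data.frame of FDR-passing peptides with
#'   `sequence` and logical `is_decoy`.
#' @param annotation Annotation data.frame from [annotate_peptides()]; must
#'   cover every passing sequence.
#' @return List of class `fdr_result` with `n_targets`, `n_decoys`, `fdr`
#'   (the cFDR), `threshold_probability` = NA.
#' @export
corrected_fdr <- function(peptides_passing, annotation) {
  idx <- match(peptides_passing$sequence, annotation$sequence)
  if (anyNA(idx))
    stop("annotation missing for peptide ",
         peptides_passing$sequence[which(is.na(idx))[1]], call. = FALSE)
  ann <- annotation$status[idx] == "annotated"
  d <- as.logical(peptides_passing$is_decoy)
  nt <- sum(ann & !d)
  nd <- sum(ann & d)
  fdr <- if (nt == 0) { if (nd == 0) 0 else Inf } else nd / nt
  if (!is.finite(fdr)) warning("no annotated targets remain", call. = FALSE)
  structure(list(threshold_probability = NA_real_, n_targets = nt,
                 n_decoys = nd, fdr = fdr), class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("FDR result: %d targets, %d decoys, FDR = %.4g",
              x$n_targets, x$n_decoys, x$fdr))
  if (is.finite(x$threshold_probability))
    cat(sprintf(" at probability >= %.4g", x$threshold_probability))
  cat("\n")
  invisible(x)
}
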