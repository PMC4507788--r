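# Consensus spectral-library entries.
#
# Replicate fragment spectra of the same peptide ion are reduced to one
# consensus spectrum: peaks are matched across replicates within a fragment
# m/z tolerance, the consensus intensity is the median of the matched
# intensities, and (with >= 3 replicates) peaks seen in fewer than half the
# replicates are voted out as noise. The consensus retention time is the
# median replicate iRT.

#' Construct a fragment peak spectrum
#'
#' @param sequence Peptide sequence.
#' @param charge Precursor charge.
#' @param peaks data.frame with `mz` and `intensity` columns (sorted by mz
#'   on construction).
#' @param rt_seconds Observed retention time (seconds), optional.
#' @param irt Normalized retention time, optional.
#' @param precursor_mz Override for the precursor m/z (default computed
#'   from sequence and charge).
#' @return Object of class `peak_spectrum`.
#' @export
peak_spectrum <- function(sequence, charge, peaks, rt_seconds = NA_real_,
                          irt = NA_real_, precursor_mz = NULL) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) stop("negative peak intensity", call. = FALSE)
  pm <- if (is.null(precursor_mz)) precursor_mz(sequence, charge) else precursor_mz
  peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(sequence = sequence, charge = as.integer(charge),
                 precursor_mz = pm, peaks = peaks,
                 rt_seconds = rt_seconds, irt = irt),
            class = "peak_spectrum")
}

.spectrum_rt_value <- function(s) {
  if (is.finite(s$irt)) s$irt else s$rt_seconds
}

#' Build a consensus spectrum from replicate spectra
#'
#' All replicates must share sequence and precursor charge. Pooled peaks
#' are clustered greedily along the m/z axis (cluster break when the gap to
#' the next peak exceeds `fragment_tol`); within a cluster each replicate
#' contributes its most intense peak. With `n >= 3` replicates, clusters
#' supported by fewer than 50% of replicates are dropped.
#'
#' @param replicates List of [peak_spectrum()] objects.
#' @param fragment_tol Fragment matching tolerance in Th (default 0.05).
#' @param allele HLA allele label carried into the library entry.
#' @return Object of class `consensus_entry`: `sequence`, `charge`,
#'   `precursor_mz`, `peaks` (consensus m/z = median, intensity = median of
#'   per-replicate intensities), `irt` (median replicate iRT),
#'   `n_replicates`, `allele`.
#' @export
build_consensus <- function(replicates, fragment_tol = 0.05,
                            allele = NA_character_) {
  stopifnot(length(replicates) >= 1)
  seqs <- vapply(replicates, `[[`, "", "sequence")
  chgs <- vapply(replicates, `[[`, 0L, "charge")
  if (length(unique(seqs)) != 1 || length(unique(chgs)) != 1)
    stop("replicates mix sequences or charges", call. = FALSE)
  n <- length(replicates)

  pooled <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- replicates[[i]]$peaks
    if (nrow(p) == 0) return(NULL)
    cbind(p, rep = i)
  }))
  peaks <- if (is.null(pooled) || nrow(pooled) == 0) {
    data.frame(mz = numeric(), intensity = numeric())
  } else {
    pooled <- pooled[order(pooled$mz), , drop = FALSE]
    cl <- cumsum(c(1, diff(pooled$mz) > fragment_tol))
    out <- lapply(split(pooled, cl), function(g) {
      # one peak per replicate within a cluster: keep its most intense
      g <- g[order(g$rep, -g$intensity), , drop = FALSE]
      g <- g[!duplicated(g$rep), , drop = FALSE]
      if (n >= 3 && nrow(g) / n < 0.5) return(NULL)
      data.frame(mz = stats::median(g$mz),
                 intensity = stats::median(g$intensity))
    })
    out <- do.call(rbind, out)
    if (is.null(out)) data.frame(mz = numeric(), intensity = numeric())
    else out[order(out$mz), , drop = FALSE]
  }
  rownames(peaks) <- NULL
  rts <- vapply(replicates, .spectrum_rt_value, 0)
  structure(list(sequence = seqs[1], charge = chgs[1],
                 precursor_mz = replicates[[1]]$precursor_mz,
                 peaks = peaks,
                 irt = stats::median(rts),
                 n_replicates = n, allele = allele),
            class = "consensus_entry")
}

#' Group spectra by peptide ion and build all consensus entries
#'
#' @param spectra List of [peak_spectrum()] objects.
#' @param fragment_tol Fragment matching tolerance in Th.
#' @param alleles Optional named character vector mapping sequence ->
#'   allele label.
#' @return Named list of `consensus_entry` objects, keyed `"<sequence>/<charge>"`,
#'   sorted by key.
#' @export
build_consensus_library <- function(spectra, fragment_tol = 0.05,
                                    alleles = NULL) {
  keys <- vapply(spectra, function(s) paste0(s$sequence, "/", s$charge), "")
  groups <- split(spectra, keys)
  out <- lapply(groups, function(g) {
    al <- if (is.null(alleles)) NA_character_
          else unname(alleles[g[[1]]$sequence])
    build_consensus(g, fragment_tol = fragment_tol, allele = al)
  })
  out[order(names(out))]
}

#' Merge consensus libraries
#'
#' Union by (sequence, charge). On collision the entry with more replicates
#' wins; ties go to the entry with the higher total peak intensity. Allele
#' labels are preserved from the winning entry.
#'
#' @param libraries List of consensus-entry collections (each a list as
#'   returned by [build_consensus_library()]).
#' @return Merged collection, keyed and sorted like the inputs.
#' @export
merge_libraries <- function(libraries) {
  merged <- list()
  for (lib in libraries) {
    for (e in lib) {
      key <- paste0(e$sequence, "/", e$charge)
      old <- merged[[key]]
      if (is.null(old)) {
        merged[[key]] <- e
      } else {
        better <- e$n_replicates > old$n_replicates ||
          (e$n_replicates == old$n_replicates &&
             sum(e$peaks$intensity) > sum(old$peaks$intensity))
        if (better) merged[[key]] <- e
      }
    }
  }
  merged[order(names(merged))]
}

#' @export
print.consensus_entry <- function(x, ...) {
  cat(sprintf("Consensus %s/%d (%s): %d peaks, iRT %.2f, %d replicate(s)\n",
              x$sequence, x$charge,
              if (is.na(x$allele)) "unassigned" else x$allele,
              nrow(x$peaks), x$irt, x$n_replicates))
  invisible(x)
}
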