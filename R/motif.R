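# Motif-based mock HLA binding predictor.
#
# Stands in for an external neural-network predictor behind the same
# interface: (peptides, alleles) -> IC50 matrix in nM. Each allele is a
# position-weight model over a 9-residue core with two strong anchor
# positions (P2 and the C-terminus, the textbook class I anchors) plus
# small deterministic non-anchor preferences so affinity distributions are
# non-degenerate. The summed position score is mapped to IC50 through a
# decreasing logistic calibrated so anchor-matched peptides land in the
# 10-500 nM binder range and motif-free peptides above 5000 nM.

.ANCHOR_WEIGHT <- 3

.motif_ic50_scale <- function(raw_score, ic50_min = 10, ic50_max = 50000,
                              k = 3, theta = 3) {
  ic50_min + (ic50_max - ic50_min) / (1 + exp(k * (raw_score - theta)))
}

#' Construct one allele motif model
#'
#' @param allele Allele name (e.g. `"A02"`).
#' @param anchor_residues Named list mapping anchor position (as character,
#'   e.g. `"2"`, `"9"`) to the preferred residues at that position.
#' @param length Core length (default 9).
#' @param nonanchor_sd Scale of the small deterministic non-anchor
#'   preferences (default 0.15).
#' @return Object of class `motif_model` with a `length x 20` position
#'   weight matrix.
#' @export
motif_model <- function(allele, anchor_residues, length = 9L,
                        nonanchor_sd = 0.15) {
  aa <- names(AA_MONO)
  w <- matrix(0, nrow = length, ncol = base::length(aa),
              dimnames = list(NULL, aa))
  # deterministic mild non-anchor preferences, fixed by the allele name
  seed <- sum(utf8ToInt(allele)) * 131 %% .Machine$integer.max
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  w[] <- stats::runif(base::length(w), 0, nonanchor_sd)
  anchors <- as.integer(names(anchor_residues))
  for (i in seq_along(anchors)) {
    w[anchors[i], ] <- 0
    w[anchors[i], anchor_residues[[i]]] <- .ANCHOR_WEIGHT
  }
  structure(list(allele = allele, length = as.integer(length),
                 position_weights = w, anchor_positions = anchors,
                 anchor_residues = anchor_residues),
            class = "motif_model")
}

#' Default three-allele motif model set
#'
#' A02-like (L/M at P2, V/L at P-Omega), A03-like (L/V at P2, K/R at
#' P-Omega) and B07-like (P/A at P2, L/F at P-Omega) models with disjoint
#' anchor-pair signatures.
#'
#' @param alleles Which of the built-in alleles to return.
#' @return Named list of [motif_model()] objects.
#' @export
default_motif_models <- function(alleles = c("A02", "A03", "B07")) {
  all <- list(
    A02 = motif_model("A02", list(`2` = c("L", "M"), `9` = c("V", "L"))),
    A03 = motif_model("A03", list(`2` = c("L", "V"), `9` = c("K", "R"))),
    B07 = motif_model("B07", list(`2` = c("P", "A"), `9` = c("L", "F")))
  )
  missing <- setdiff(alleles, names(all))
  if (length(missing) > 0)
    stop("no built-in motif model for allele(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  all[alleles]
}

# raw motif score of a peptide against one model; peptides shorter than the
# core map their C-terminal residue to the last core position, longer
# peptides take the best-scoring 9-mer core window.
.motif_raw_score <- function(peptide, model) {
  w <- model$position_weights
  L <- model$length
  res <- strsplit(peptide, "")[[1]]
  n <- length(res)
  score_core <- function(core) {
    sum(w[cbind(seq_len(L), match(core, colnames(w)))])
  }
  if (n == L) {
    score_core(res)
  } else if (n < L) {
    idx <- c(seq_len(n - 1), L)  # keep N-terminal register, pin C-terminus
    sum(w[cbind(idx, match(res, colnames(w)))])
  } else {
    max(vapply(seq_len(n - L + 1),
               function(i) score_core(res[i:(i + L - 1)]), 0))
  }
}

#' Predict IC50 values with the mock motif predictor
#'
#' @param peptides Character vector of peptide sequences (8-12 residues;
#'   off-core lengths are handled by a best 9-mer core scan).
#' @param alleles Alleles to predict for; every allele must have a model in
#'   `model_set`.
#' @param model_set Named list of [motif_model()] objects.
#' @param noise_sd_log10 Log10-normal multiplicative prediction noise
#'   (default 0: fully deterministic).
#' @return Numeric matrix of IC50 (nM), peptides x alleles.
#' @export
mock_predict <- function(peptides, alleles,
                         model_set = default_motif_models(),
                         noise_sd_log10 = 0) {
  missing <- setdiff(alleles, names(model_set))
  if (length(missing) > 0)
    stop("unknown allele(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- vapply(alleles, function(a) {
    vapply(peptides,
           function(p) .motif_ic50_scale(.motif_raw_score(p, model_set[[a]])),
           0)
  }, numeric(length(peptides)))
  m <- matrix(m, nrow = length(peptides),
              dimnames = list(peptides, alleles))
  if (noise_sd_log10 > 0) {
    m <- m * 10^stats::rnorm(length(m), 0, noise_sd_log10)
  }
  m
}

#' Make a predictor function from a motif model set
#'
#' Returns a closure with the predictor interface used by
#' [annotate_peptides()].
#'
#' @inheritParams mock_predict
#' @return Function `(peptides, alleles) -> IC50 matrix`.
#' @export
mock_predictor <- function(model_set = default_motif_models(),
                           noise_sd_log10 = 0) {
  function(peptides, alleles) {
    mock_predict(peptides, alleles, model_set, noise_sd_log10)
  }
}

#' Wrap an external prediction command as a predictor
#'
#' The command is called as `cmd <peptide_file> <allele1,allele2,...>` with
#' one peptide per line in the file, and must print a headered TSV with
#' columns `peptide`, `allele`, `ic50_nM` to stdout.
#'
#' @param cmd Path to the executable.
#' @return Function `(peptides, alleles) -> IC50 matrix`.
#' @export
external_predictor <- function(cmd) {
  force(cmd)
  function(peptides, alleles) {
    pf <- tempfile("peptides_", fileext = ".txt")
    on.exit(unlink(pf))
    writeLines(peptides, pf)
    out <- system2(cmd, c(pf, paste(alleles, collapse = ",")),
                   stdout = TRUE)
    if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
      stop("external predictor failed with status ",
           attr(out, "status"), call. = FALSE)
    tab <- utils::read.table(text = out, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("peptide", "allele", "ic50_nM")
    if (!all(need %in% names(tab)))
      stop("external predictor output lacks columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
    m <- matrix(NA_real_, nrow = length(peptides), ncol = length(alleles),
                dimnames = list(peptides, alleles))
    m[cbind(match(tab$peptide, peptides), match(tab$allele, alleles))] <-
      tab$ic50_nM
    if (anyNA(m))
      stop("external predictor missing (peptide, allele) pairs", call. = FALSE)
    m
  }
}

#' Sample peptides from an allele motif
#'
#' Anchor positions draw one of the preferred residues with probability
#' `anchor_fidelity`; all other positions are uniform over the 20 residues.
#'
#' @param model A [motif_model()].
#' @param n Number of peptides.
#' @param anchor_fidelity Probability an anchor position carries a
#'   preferred residue (default 0.95).
#' @return Character vector of `n` peptides of the model's core length.
#' @export
sample_motif_peptides <- function(model, n, anchor_fidelity = 0.95) {
  aa <- colnames(model$position_weights)
  L <- model$length
  vapply(seq_len(n), function(i) {
    res <- sample(aa, L, replace = TRUE)
    for (j in seq_along(model$anchor_positions)) {
      if (stats::runif(1) < anchor_fidelity) {
        pref <- model$anchor_residues[[j]]
        res[model$anchor_positions[j]] <-
          pref[sample.int(length(pref), 1)]
      }
    }
    paste(res, collapse = "")
  }, "")
}
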