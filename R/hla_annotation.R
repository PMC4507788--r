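# HLA allele annotation of identified peptides.
#
# Each identified peptide gets a predicted binding affinity (IC50, nM) for
# every allele typed in the donor. The annotation score is the ratio of the
# second-lowest to the lowest IC50: the larger the ratio, the more clearly
# the peptide prefers a single allele. Peptides with score >= cutoff
# (default 3) are annotated to the best-predicted allele; the rest are
# curated as supertype binders, HLA-C binders, or non-annotated.

.strip_hla_prefix <- function(allele) sub("^HLA-?", "", allele)

.is_hla_c <- function(allele) grepl("^C", .strip_hla_prefix(allele))

#' Compute the HLA annotation score for one peptide
#'
#' The score is the second-lowest predicted IC50 divided by the lowest.
#' A peptide predicted against a single allele gets score `Inf` (always
#' annotatable); exact ties between the two lowest IC50 values give score 1
#' (never annotatable at any cutoff > 1).
#'
#' @param ic50 Named numeric vector of predicted IC50 values (nM), one per
#'   allele. All values must be positive and names unique and nonempty.
#' @return List with `best_allele`, `best_ic50`, `second_allele`,
#'   `second_ic50` (NA for single-allele input) and `score`.
#' @examples
#' compute_annotation_score(c(A03 = 278, B39 = 21400))$score  # 76.98
#' @export
compute_annotation_score <- function(ic50) {
  if (length(ic50) == 0) stop("empty allele map", call. = FALSE)
  nm <- names(ic50)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("IC50 vector must have unique, nonempty allele names", call. = FALSE)
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("all IC50 values must be positive and finite", call. = FALSE)
  ord <- order(ic50, nm)  # allele name breaks exact ties deterministically
  best <- ord[1]
  if (length(ic50) == 1) {
    return(list(best_allele = nm[best], best_ic50 = unname(ic50[best]),
                second_allele = NA_character_, second_ic50 = NA_real_,
                score = Inf))
  }
  second <- ord[2]
  list(best_allele = nm[best], best_ic50 = unname(ic50[best]),
       second_allele = nm[second], second_ic50 = unname(ic50[second]),
       score = unname(ic50[second] / ic50[best]))
}

.annotation_status <- function(score, best_allele, ic50, cutoff,
                               supertype_ic50, hla_c_whitelist) {
  best_is_c <- .is_hla_c(best_allele) &&
    !(.strip_hla_prefix(best_allele) %in% .strip_hla_prefix(hla_c_whitelist))
  if (score >= cutoff) {
    if (best_is_c) "hla_c_binder" else "annotated"
  } else if (sum(ic50 < supertype_ic50) >= 2) {
    "supertype"
  } else if (best_is_c) {
    "hla_c_binder"
  } else {
    "non_annotated"
  }
}

#' Annotate peptides to HLA alleles
#'
#' Runs the binding predictor on every (peptide, allele) pair, computes the
#' annotation score and assigns a curation status. Category precedence for
#' score < cutoff: supertype (>= 2 alleles with IC50 below
#' `supertype_ic50`), then HLA-C binder, then non-annotated. Peptides whose
#' best allele is an HLA-C allele are never annotated unless that allele is
#' whitelisted via `hla_c_whitelist` (e.g. `"C04"` for C1R-derived samples).
#'
#' @param peptides Character vector of peptide sequences.
#' @param donor_alleles Character vector of the donor's typed alleles.
#' @param predictor A predictor function `(peptides, alleles) -> matrix` of
#'   IC50 values (rows = peptides, columns = alleles), e.g.
#'   [mock_predictor()] or [external_predictor()].
#' @param cutoff Annotation score cutoff (default 3, inclusive: score >=
#'   cutoff annotates).
#' @param supertype_ic50 IC50 threshold (nM) defining a strong binder for
#'   the supertype category (default 500).
#' @param hla_c_whitelist HLA-C alleles allowed as annotation targets.
#' @return data.frame with one row per peptide: `sequence`, `best_allele`,
#'   `best_ic50`, `second_allele`, `second_ic50`, `score`, `status`, plus one
#'   `ic50.<allele>` column per donor allele.
#' @export
annotate_peptides <- function(peptides, donor_alleles, predictor,
                              cutoff = 3, supertype_ic50 = 500,
                              hla_c_whitelist = character()) {
  stopifnot(length(donor_alleles) >= 1, cutoff >= 1)
  peptides <- as.character(peptides)
  ic50 <- tryCatch(predictor(peptides, donor_alleles),
                   error = function(e) stop("predictor failure: ",
                                            conditionMessage(e), call. = FALSE))
  ic50 <- as.matrix(ic50)
  if (nrow(ic50) != length(peptides) || ncol(ic50) != length(donor_alleles))
    stop("predictor returned a matrix of wrong dimensions", call. = FALSE)
  bad <- which(apply(ic50, 1, function(v) any(!is.finite(v) | v <= 0)))
  if (length(bad) > 0)
    stop("predictor failure for peptide ", peptides[bad[1]], call. = FALSE)
  colnames(ic50) <- donor_alleles

  rows <- lapply(seq_along(peptides), function(i) {
    v <- ic50[i, ]
    sc <- compute_annotation_score(v)
    sc$status <- .annotation_status(sc$score, sc$best_allele, v, cutoff,
                                    supertype_ic50, hla_c_whitelist)
    sc
  })
  out <- data.frame(
    sequence = peptides,
    best_allele = vapply(rows, `[[`, "", "best_allele"),
    best_ic50 = vapply(rows, `[[`, 0, "best_ic50"),
    second_allele = vapply(rows, `[[`, "", "second_allele"),
    second_ic50 = vapply(rows, `[[`, 0, "second_ic50"),
    score = vapply(rows, `[[`, 0, "score"),
    status = vapply(rows, `[[`, "", "status"),
    stringsAsFactors = FALSE
  )
  aff <- as.data.frame(ic50)
  names(aff) <- paste0("ic50.", donor_alleles)
  cbind(out, aff)
}

#' Affinity-distribution summary for one allele
#'
#' Empirical CDF of the best-allele IC50 for all peptides annotated to a
#' given allele, with the 95th-percentile IC50 (smallest IC50 reaching
#' cumulative fraction >= 0.95) and the fraction of peptides predicted below
#' the conventional 500 nM binder threshold.
#'
#' @param records Annotation data.frame from [annotate_peptides()].
#' @param allele Allele to summarize.
#' @param binder_ic50 Binder threshold in nM (default 500).
#' @return List with `allele`, `n_peptides`, `ic50_cdf` (data.frame `ic50`,
#'   `cum_fraction`), `ic50_at_q95`, `frac_below_500nM`. When no peptide is
#'   annotated to the allele, `n_peptides` is 0, the other fields are NA and
#'   a warning is signalled.
#' @export
allele_summary <- function(records, allele, binder_ic50 = 500) {
  x <- records$best_ic50[records$status == "annotated" &
                         records$best_allele == allele]
  if (length(x) == 0) {
    warning("no annotated peptides for allele ", allele, call. = FALSE)
    return(list(allele = allele, n_peptides = 0L,
                ic50_cdf = data.frame(ic50 = numeric(), cum_fraction = numeric()),
                ic50_at_q95 = NA_real_, frac_below_500nM = NA_real_))
  }
  xs <- sort(x)
  cdf <- data.frame(ic50 = xs, cum_fraction = seq_along(xs) / length(xs))
  q95 <- xs[which(cdf$cum_fraction >= 0.95)[1]]
  list(allele = allele, n_peptides = length(x), ic50_cdf = cdf,
       ic50_at_q95 = q95, frac_below_500nM = mean(x < binder_ic50))
}

#' Percentile rank of a presented peptide within its source protein
#'
#' Predicts the IC50 of every same-length subpeptide (tile) of the source
#' protein for one allele and ranks the query among them (rank 1 = lowest
#' IC50, ties take the minimal rank). The percentile is (rank - 1) / number
#' of tiles, binned as top 1%, top 5%, top 10%, or below the 90th
#' percentile.
#'
#' @param peptide Query peptide (must occur in `protein`).
#' @param protein Source protein sequence.
#' @param allele Allele to score against.
#' @param predictor Predictor function as in [annotate_peptides()].
#' @return List with `bin` (one of `"top1"`, `"top5"`, `"top10"`,
#'   `"below90"`), `rank`, `n_tiles`, `percentile`.
#' @export
source_protein_rank <- function(peptide, protein, allele, predictor) {
  L <- nchar(peptide)
  if (!grepl(peptide, protein, fixed = TRUE))
    stop("peptide '", peptide, "' not found in protein", call. = FALSE)
  n_tiles <- nchar(protein) - L + 1
  tiles <- substring(protein, seq_len(n_tiles), seq_len(n_tiles) + L - 1)
  ic50 <- as.matrix(predictor(tiles, allele))[, 1]
  q <- ic50[match(peptide, tiles)]
  rank <- sum(ic50 < q) + 1L  # ties -> minimal rank
  pct <- (rank - 1) / n_tiles
  bin <- if (pct <= 0.01) "top1" else if (pct <= 0.05) "top5"
         else if (pct <= 0.10) "top10" else "below90"
  list(bin = bin, rank = rank, n_tiles = n_tiles, percentile = pct)
}

#' Build the affinity heat-map matrix
#'
#' Cell value is -log10(IC50 nM) so stronger binders are larger. Rows are
#' grouped by assigned allele (annotated peptides first, in the order of
#' `alleles`), sorted within each block by best IC50 ascending; peptides not
#' annotated are appended after the allele blocks, also sorted by best IC50.
#'
#' @param records Annotation data.frame from [annotate_peptides()].
#' @param alleles Column order of the matrix (defaults to the `ic50.*`
#'   columns found in `records`).
#' @return Numeric matrix (peptides x alleles) with sequences as row names
#'   and a `row_groups` attribute giving each row's block label.
#' @export
build_heatmap_matrix <- function(records, alleles = NULL) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  aff_cols <- grep("^ic50\\.", names(records), value = TRUE)
  if (is.null(alleles)) alleles <- sub("^ic50\\.", "", aff_cols)
  cols <- paste0("ic50.", alleles)
  if (any(!cols %in% names(records)))
    stop("missing affinity columns for alleles: ",
         paste(alleles[!cols %in% names(records)], collapse = ", "),
         call. = FALSE)
  ann <- records$status == "annotated"
  grp <- ifelse(ann, records$best_allele, "unassigned")
  grp <- factor(grp, levels = c(alleles, "unassigned"))
  ord <- order(grp, records$best_ic50)
  m <- -log10(as.matrix(records[ord, cols, drop = FALSE]))
  dimnames(m) <- list(records$sequence[ord], alleles)
  attr(m, "row_groups") <- as.character(grp[ord])
  m
}
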