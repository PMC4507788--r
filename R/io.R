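# Readers and writers for every interchange format.
#
# Dialects: identification TSV (sample_id, sequence, charge, probability,
# is_decoy, rt_seconds); OpenSWATH-style transition TSV; two-column
# swaths.txt window file (windows.R); sptxt-style spectral library; FASTA
# (via Biostrings); JSON reports. All writers emit LF; readers tolerate
# CRLF. Numeric serialization: m/z at 1e-4, intensities at 1e-2.

.ID_COLUMNS <- c("sample_id", "sequence", "charge", "probability",
                 "is_decoy", "rt_seconds")

#' Read an identification table
#'
#' @param path TSV with header columns `sample_id`, `sequence`, `charge`,
#'   `probability`, `is_decoy`, `rt_seconds`.
#' @return data.frame with typed columns (`is_decoy` logical).
#' @export
read_identifications <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(.ID_COLUMNS, names(x))
  if (length(missing) > 0)
    stop("identification file ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x$probability <- suppressWarnings(as.numeric(x$probability))
  bad <- which(!is.finite(x$probability) | x$probability < 0 |
                 x$probability > 1)
  if (length(bad) > 0)
    stop("malformed probability at line ", bad[1] + 1, " of ", path,
         call. = FALSE)
  x$is_decoy <- as.logical(x$is_decoy)
  if (anyNA(x$is_decoy))
    stop("malformed is_decoy flag in ", path, call. = FALSE)
  x$charge <- as.integer(x$charge)
  x[, .ID_COLUMNS]
}

#' Write an identification table
#' @param ids data.frame with the identification columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(ids, path) {
  utils::write.table(ids[, .ID_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# OpenSWATH transition-list column names, bit-exact.
.OSW_COLUMNS <- c("PrecursorMz", "ProductMz", "Tr_recalibrated",
                  "transition_name", "LibraryIntensity",
                  "transition_group_id", "decoy", "PeptideSequence",
                  "ProteinName", "FragmentType", "FragmentCharge",
                  "FragmentSeriesNumber")

#' Write an assay library as an OpenSWATH-style transition TSV
#'
#' Columns (in order): `PrecursorMz`, `ProductMz`, `Tr_recalibrated`,
#' `transition_name`, `LibraryIntensity`, `transition_group_id`, `decoy`
#' (0/1), `PeptideSequence`, `ProteinName`, `FragmentType`,
#' `FragmentCharge`, `FragmentSeriesNumber`. m/z values are written at
#' 1e-4, intensities at 1e-2 precision.
#'
#' @param assays Internal transition data.frame (see
#'   [select_transitions()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assay_tsv <- function(assays, path) {
  out <- data.frame(
    PrecursorMz = sprintf("%.4f", assays$precursor_mz),
    ProductMz = sprintf("%.4f", assays$fragment_mz),
    Tr_recalibrated = sprintf("%.4f", assays$irt),
    transition_name = assays$transition_name,
    LibraryIntensity = sprintf("%.2f", assays$library_intensity),
    transition_group_id = assays$transition_group_id,
    decoy = as.integer(assays$is_decoy),
    PeptideSequence = assays$sequence,
    ProteinName = assays$protein,
    FragmentType = assays$fragment_type,
    FragmentCharge = assays$fragment_charge,
    FragmentSeriesNumber = assays$fragment_ordinal,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an OpenSWATH-style transition TSV
#'
#' @param path Transition TSV written by [write_assay_tsv()].
#' @return Internal transition data.frame. Duplicate `transition_name`
#'   values (the per-row unique key) are an error.
#' @export
read_assay_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(.OSW_COLUMNS, names(x))
  if (length(missing) > 0)
    stop("assay file ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dup <- duplicated(x$transition_name)
  if (any(dup))
    stop("duplicate transition_name '", x$transition_name[which(dup)[1]],
         "' in ", path, call. = FALSE)
  pc <- sub("^DECOY_", "", x$transition_group_id)
  pc <- as.integer(sub("^.*_", "", pc))
  data.frame(
    sequence = x$PeptideSequence,
    precursor_mz = as.numeric(x$PrecursorMz),
    precursor_charge = pc,
    fragment_mz = as.numeric(x$ProductMz),
    fragment_type = x$FragmentType,
    fragment_ordinal = as.integer(x$FragmentSeriesNumber),
    fragment_charge = as.integer(x$FragmentCharge),
    library_intensity = as.numeric(x$LibraryIntensity),
    irt = as.numeric(x$Tr_recalibrated),
    is_decoy = x$decoy != 0,
    transition_group_id = x$transition_group_id,
    transition_name = x$transition_name,
    protein = x$ProteinName,
    stringsAsFactors = FALSE)
}

#' Read a protein FASTA
#'
#' Wrapped lines and mixed case are normalized to uppercase concatenated
#' sequences.
#'
#' @param path FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)),
                  sub("\\s.*$", "", names(x)))
}

#' Write a protein FASTA
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(proteins), path, width = 60)
  invisible(path)
}

#' Read an iRT landmark reference table
#' @param path TSV with columns `sequence`, `irt`.
#' @return data.frame `sequence`, `irt`.
#' @export
read_irt_reference <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("sequence", "irt") %in% names(x)))
    stop("iRT reference must have columns sequence, irt", call. = FALSE)
  x$irt <- as.numeric(x$irt)
  x[, c("sequence", "irt")]
}

#' Write an iRT landmark reference table
#' @param reference data.frame `sequence`, `irt`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_irt_reference <- function(reference, path) {
  utils::write.table(reference[, c("sequence", "irt")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON report
#' @param x List to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a consensus spectral library in sptxt-style text format
#'
#' One block per entry: `Name: <sequence>/<charge>`, `PrecursorMz:`,
#' `Charge:`, `iRT:`, `Allele:`, `NReplicates:`, `NumPeaks:`, then one
#' `mz<TAB>intensity` line per peak (m/z at 1e-4, intensity at 1e-2), and a
#' blank line between entries.
#'
#' @param entries Consensus-entry collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectral_library <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    writeLines(c(
      sprintf("Name: %s/%d", e$sequence, e$charge),
      sprintf("PrecursorMz: %.4f", e$precursor_mz),
      sprintf("Charge: %d", e$charge),
      sprintf("iRT: %.4f", e$irt),
      sprintf("Allele: %s", if (is.na(e$allele)) "NA" else e$allele),
      sprintf("NReplicates: %d", e$n_replicates),
      sprintf("NumPeaks: %d", nrow(e$peaks)),
      sprintf("%.4f\t%.2f", e$peaks$mz, e$peaks$intensity),
      ""), con)
  }
  invisible(path)
}

#' Read an sptxt-style spectral library
#'
#' @param path File written by [write_spectral_library()].
#' @return Named list of `consensus_entry` objects keyed
#'   `"<sequence>/<charge>"`.
#' @export
read_spectral_library <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  starts <- grep("^Name: ", lines)
  if (length(starts) == 0) stop("no entries in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1, length(lines))
  entries <- lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    field <- function(key) sub(paste0("^", key, ": "), "",
                               grep(paste0("^", key, ": "), blk, value = TRUE)[1])
    npeaks <- as.integer(field("NumPeaks"))
    peak_lines <- grep("^[0-9]", blk, value = TRUE)
    if (length(peak_lines) != npeaks)
      stop("entry '", field("Name"), "': NumPeaks mismatch in ", path,
           call. = FALSE)
    pk <- utils::read.table(text = peak_lines, sep = "\t",
                            col.names = c("mz", "intensity"))
    allele <- field("Allele")
    structure(list(
      sequence = sub("/.*$", "", field("Name")),
      charge = as.integer(field("Charge")),
      precursor_mz = as.numeric(field("PrecursorMz")),
      peaks = pk,
      irt = as.numeric(field("iRT")),
      n_replicates = as.integer(field("NReplicates")),
      allele = if (allele == "NA") NA_character_ else allele),
      class = "consensus_entry")
  })
  names(entries) <- vapply(entries, function(e)
    paste0(e$sequence, "/", e$charge), "")
  entries
}
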