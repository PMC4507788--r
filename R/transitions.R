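# Transition selection into a SWATH assay library, and decoy assays.
#
# Mirrors the standard assay-generation settings: b/y ions only, fragment
# charges 1-2, fragment m/z restricted to 350-2000 Th, exactly the 6 most
# intense annotated fragments per peptide ion, peptides with fewer than 6
# qualifying fragments dropped; fragments co-isolated with their own
# precursor (falling in the precursor's isolation window) can be excluded.

.assay_columns <- c("sequence", "precursor_mz", "precursor_charge",
                    "fragment_mz", "fragment_type", "fragment_ordinal",
                    "fragment_charge", "library_intensity", "irt",
                    "is_decoy", "transition_group_id", "transition_name",
                    "protein")

.empty_assays <- function() {
  as.data.frame(stats::setNames(
    list(character(), numeric(), integer(), numeric(), character(),
         integer(), integer(), numeric(), numeric(), logical(),
         character(), character(), character()),
    .assay_columns), stringsAsFactors = FALSE)
}

#' Select fragment-ion transitions for one consensus entry
#'
#' Consensus peaks are annotated against theoretical b/y fragment m/z
#' within `match_tolerance_th` (each peak takes its closest theoretical
#' ion; each ion keeps its most intense matching peak). Fragments outside
#' `mz_range`, and optionally fragments inside the precursor's own
#' isolation window, are discarded. The `max_transitions` most intense
#' survivors are emitted; entries with fewer than `min_transitions`
#' qualifying fragments yield no assay (`NULL`).
#'
#' @param entry A `consensus_entry`.
#' @param mz_range Allowed fragment m/z range (Th), default `c(350, 2000)`.
#' @param ion_types Fragment series, subset of `c("b","y")`.
#' @param fragment_charges Allowed fragment charges, default `c(1, 2)`.
#' @param min_transitions,max_transitions Assay size bounds (default 6/6).
#' @param match_tolerance_th Peak-annotation tolerance (Th, default 0.05).
#' @param excluded_windows Optional `window_scheme`; fragments falling in
#'   the precursor's own window are excluded.
#' @param protein Protein label written to the assay rows.
#' @return data.frame of transitions, or `NULL` when the entry is dropped.
#' @export
select_transitions <- function(entry, mz_range = c(350, 2000),
                               ion_types = c("b", "y"),
                               fragment_charges = c(1L, 2L),
                               min_transitions = 6L, max_transitions = 6L,
                               match_tolerance_th = 0.05,
                               excluded_windows = NULL,
                               protein = "synthetic") {
  stopifnot(min_transitions >= 1, max_transitions >= min_transitions)
  peaks <- entry$peaks
  if (nrow(peaks) == 0) return(NULL)
  theo <- theoretical_fragments(entry$sequence, ion_types, fragment_charges)
  names(theo)[names(theo) == "mz"] <- "theo_mz"

  # closest theoretical ion per peak, within tolerance
  ti <- vapply(peaks$mz, function(mz) {
    d <- abs(theo$theo_mz - mz)
    j <- which.min(d)
    if (d[j] <= match_tolerance_th) j else NA_integer_
  }, 0L)
  ann <- cbind(peaks, theo[ti, ], row.names = NULL)
  ann <- ann[!is.na(ti), , drop = FALSE]
  if (nrow(ann) > 0) {
    # one peak per theoretical ion: keep the most intense
    ion_key <- paste(ann$ion_type, ann$ordinal, ann$charge)
    ord <- order(ion_key, -ann$intensity)
    ann <- ann[ord, , drop = FALSE]
    ann <- ann[!duplicated(ion_key[ord]), , drop = FALSE]
  }
  keep <- ann$theo_mz >= mz_range[1] & ann$theo_mz <= mz_range[2]
  if (!is.null(excluded_windows)) {
    wi <- suppressWarnings(
      assign_precursor_window(entry$precursor_mz, excluded_windows))
    if (!is.na(wi)) {
      w <- excluded_windows$windows[wi, ]
      keep <- keep & !(ann$theo_mz >= w$start & ann$theo_mz < w$end)
    }
  }
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann) < min_transitions) return(NULL)
  ann <- ann[order(-ann$intensity), , drop = FALSE][seq_len(
    min(max_transitions, nrow(ann))), , drop = FALSE]
  ann <- ann[order(ann$theo_mz), , drop = FALSE]

  gid <- paste0(entry$sequence, "_", entry$charge)
  data.frame(
    sequence = entry$sequence,
    precursor_mz = entry$precursor_mz,
    precursor_charge = entry$charge,
    fragment_mz = ann$theo_mz,  # theoretical m/z, not the observed peak m/z
    fragment_type = ann$ion_type,
    fragment_ordinal = as.integer(ann$ordinal),
    fragment_charge = as.integer(ann$charge),
    library_intensity = ann$intensity,
    irt = entry$irt,
    is_decoy = FALSE,
    transition_group_id = gid,
    transition_name = sprintf("%s_%s%d^%d", gid, ann$ion_type,
                              ann$ordinal, ann$charge),
    protein = protein,
    stringsAsFactors = FALSE
  )
}

#' Build a full assay library from consensus entries
#'
#' Applies [select_transitions()] to every entry; entries that do not reach
#' `min_transitions` qualifying fragments are reported in the rejects log.
#'
#' @param entries Consensus-entry collection ([build_consensus_library()]).
#' @param ... Passed to [select_transitions()].
#' @return List with `assays` (row-bound transition data.frame) and
#'   `rejects` (data.frame `sequence`, `charge`, `reason`).
#' @export
build_assay_library <- function(entries, ...) {
  assays <- list()
  rejects <- list()
  for (e in entries) {
    a <- select_transitions(e, ...)
    if (is.null(a)) {
      rejects[[length(rejects) + 1]] <-
        data.frame(sequence = e$sequence, charge = e$charge,
                   reason = "fewer than min_transitions qualifying fragments",
                   stringsAsFactors = FALSE)
    } else {
      assays[[length(assays) + 1]] <- a
    }
  }
  list(
    assays = if (length(assays)) do.call(rbind, assays) else .empty_assays(),
    rejects = if (length(rejects)) do.call(rbind, rejects)
              else data.frame(sequence = character(), charge = integer(),
                              reason = character(), stringsAsFactors = FALSE)
  )
}

.shuffle_keep_cterm <- function(sequence) {
  n <- nchar(sequence)
  res <- strsplit(sequence, "")[[1]]
  head <- res[-n]
  paste0(paste(head[sample.int(length(head))], collapse = ""), res[n])
}

.reverse_keep_cterm <- function(sequence) {
  n <- nchar(sequence)
  res <- strsplit(sequence, "")[[1]]
  paste0(paste(rev(res[-n]), collapse = ""), res[n])
}

.seq_identity <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Generate decoy assays for an assay library
#'
#' Each target transition group gets a decoy with the peptide sequence
#' shuffled (C-terminal residue fixed; `method = "reverse"` reverses the
#' N-terminal part instead) and fragment m/z recomputed from the decoy
#' sequence for the same ion annotations. A candidate decoy is re-drawn
#' (up to `max_retries` times) and finally excluded when it (a) equals any
#' target sequence or exceeds `identity_threshold` fractional positional
#' identity to its target, (b) has every fragment m/z within
#' `similarity_threshold_th` of the corresponding target fragment
#' (`exclude_similar`), or (c) has a fragment outside `mz_range`.
#' Homopolymers are unshufflable and always excluded. Generation is
#' deterministic for a fixed `seed`.
#'
#' @param assays Target transition data.frame from [build_assay_library()].
#' @param method `"shuffle"` (default) or `"reverse"`.
#' @param similarity_threshold_th Fragment similarity threshold (Th).
#' @param identity_threshold Maximum allowed fractional sequence identity.
#' @param exclude_similar Drop decoys indistinguishable from their target.
#' @param mz_range Allowed decoy fragment m/z range.
#' @param seed Integer seed for the shuffles.
#' @param max_retries Shuffle attempts per peptide before exclusion.
#' @return List with `decoys` (transition data.frame, `is_decoy = TRUE`,
#'   group ids prefixed `DECOY_`) and `excluded` (data.frame `sequence`,
#'   `reason`).
#' @export
generate_decoy_assays <- function(assays, method = c("shuffle", "reverse"),
                                  similarity_threshold_th = 0.05,
                                  identity_threshold = 1,
                                  exclude_similar = TRUE,
                                  mz_range = c(350, 2000),
                                  seed = 1L, max_retries = 20L) {
  method <- match.arg(method)
  if (nrow(assays) == 0) stop("no target assays", call. = FALSE)
  target_seqs <- unique(assays$sequence)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))

  groups <- split(assays, assays$transition_group_id)
  groups <- groups[order(names(groups))]
  decoys <- list()
  excluded <- list()
  for (g in groups) {
    target <- g$sequence[1]
    decoy_seq <- NULL
    reason <- "retry limit reached"
    for (try in seq_len(max_retries)) {
      cand <- if (method == "shuffle") .shuffle_keep_cterm(target)
              else .reverse_keep_cterm(target)
      if (cand %in% target_seqs ||
          .seq_identity(cand, target) > identity_threshold) {
        reason <- "identical or above identity threshold"
        if (method == "reverse") break  # reverse is deterministic
        next
      }
      dmz <- fragment_mz(cand, g$fragment_type, g$fragment_ordinal,
                         g$fragment_charge)
      if (exclude_similar &&
          all(abs(dmz - g$fragment_mz) <= similarity_threshold_th)) {
        reason <- "fragment set indistinguishable from target"
        if (method == "reverse") break
        next
      }
      if (any(dmz < mz_range[1] | dmz > mz_range[2])) {
        reason <- "decoy fragment outside m/z range"
        if (method == "reverse") break
        next
      }
      decoy_seq <- cand
      break
    }
    if (is.null(decoy_seq)) {
      excluded[[length(excluded) + 1]] <-
        data.frame(sequence = target, reason = reason,
                   stringsAsFactors = FALSE)
      next
    }
    d <- g
    d$sequence <- decoy_seq
    d$fragment_mz <- fragment_mz(decoy_seq, g$fragment_type,
                                 g$fragment_ordinal, g$fragment_charge)
    # shuffling preserves composition, so the precursor m/z is unchanged
    d$is_decoy <- TRUE
    d$transition_group_id <- paste0("DECOY_", g$transition_group_id)
    d$transition_name <- paste0("DECOY_", g$transition_name)
    d$protein <- paste0("DECOY_", g$protein)
    decoys[[length(decoys) + 1]] <- d
  }
  list(
    decoys = if (length(decoys)) do.call(rbind, decoys) else .empty_assays(),
    excluded = if (length(excluded)) do.call(rbind, excluded)
               else data.frame(sequence = character(), reason = character(),
                               stringsAsFactors = FALSE)
  )
}
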