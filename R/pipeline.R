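# End-to-end orchestration: fixture or user inputs -> filter/FDR ->
# annotation -> corrected FDR -> iRT normalization -> consensus library ->
# assay library with decoys -> window scheme -> reports. Each stage writes
# its outputs before the next begins; the manifest records stages, paths,
# seed and a config hash so identical runs are reproducible byte for byte.

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.read_typing <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("sample_id", "alleles") %in% names(x)))
    stop("typing file must have columns sample_id, alleles", call. = FALSE)
  stats::setNames(lapply(strsplit(x$alleles, ","), trimws), x$sample_id)
}

#' Run the full pipeline on a sample directory
#'
#' Expects the documented fixture inputs in `sample_dir`:
#' `identifications.tsv`, `typing.tsv`, `spectra.sptxt`,
#' `irt_reference.tsv`. Stages: PSM collapse + probability/length filter;
#' target-decoy FDR thresholding; HLA annotation of the passing targets
#' and decoys; corrected FDR; iRT fit from landmark spectra; per-allele
#' consensus libraries merged into one; transition selection with
#' self-window exclusion; decoy assay generation; window scheme emission.
#'
#' @param config A [run_config()].
#' @param sample_dir Input directory.
#' @param outdir Output directory (created).
#' @param predictor Binding predictor; defaults to the mock motif
#'   predictor restricted to the typed alleles.
#' @return The manifest list, invisibly. Outputs written: `annotation.tsv`,
#'   `heatmap.tsv`, `library.sptxt`, `assays.tsv` (targets + decoys),
#'   `swaths.txt`, `report.json`, `manifest.json`.
#' @export
run_pipeline <- function(config, sample_dir, outdir, predictor = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, config_hash = .config_hash(config),
                   version = as.character(utils::packageVersion("hlaswath")),
                   stages = list())
  stage <- function(name, outputs) {
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(stage = name, outputs = outputs)
  }
  fail <- function(name, e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # -- stage: read inputs
  ids <- tryCatch(
    read_identifications(file.path(sample_dir, "identifications.tsv")),
    error = function(e) fail("read_inputs", e))
  typing <- .read_typing(file.path(sample_dir, "typing.tsv"))
  alleles <- typing[[1]]
  spectra_lib <- read_spectral_library(file.path(sample_dir, "spectra.sptxt"))
  irt_ref <- read_irt_reference(file.path(sample_dir, "irt_reference.tsv"))
  if (is.null(predictor))
    predictor <- mock_predictor(default_motif_models(alleles),
                                config$prediction_noise_sd_log10)
  stage("read_inputs", character())

  # -- stage: filter + FDR
  flt <- filter_peptides(collapse_psms(ids), config$min_probability,
                         config$min_length, config$max_length)
  fdr_results <- lapply(config$fdr_levels, function(q) fdr_threshold(flt, q))
  names(fdr_results) <- paste0("fdr_", config$fdr_levels)
  thr <- fdr_threshold(flt, config$target_fdr)
  passing <- flt[flt$probability >= thr$threshold_probability, , drop = FALSE]
  stage("fdr", character())

  # -- stage: annotation + corrected FDR
  ann <- tryCatch(
    annotate_peptides(passing$sequence, alleles, predictor,
                      cutoff = config$cutoff,
                      supertype_ic50 = config$supertype_ic50,
                      hla_c_whitelist = config$hla_c_whitelist),
    error = function(e) fail("annotate", e))
  cfdr <- corrected_fdr(passing, ann)
  ann_path <- file.path(outdir, "annotation.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hm <- build_heatmap_matrix(ann, alleles)
  hm_path <- file.path(outdir, "heatmap.tsv")
  utils::write.table(data.frame(sequence = rownames(hm),
                                group = attr(hm, "row_groups"),
                                round(unclass(hm), 4), check.names = FALSE),
                     hm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  stage("annotate", c(ann_path, hm_path))

  # -- stage: iRT normalization
  obs <- do.call(rbind, lapply(spectra_lib, function(e)
    data.frame(sequence = e$sequence, rt_seconds = e$irt,
               stringsAsFactors = FALSE)))
  irt_model <- tryCatch(fit_irt(obs, irt_ref),
                        error = function(e) fail("irt", e))
  stage("irt", character())

  # -- stage: consensus library (annotated target peptides only)
  ann_ok <- ann[ann$status == "annotated", , drop = FALSE]
  target_pass <- passing$sequence[!passing$is_decoy]
  lib_seqs <- intersect(ann_ok$sequence, target_pass)
  allele_of <- stats::setNames(ann_ok$best_allele, ann_ok$sequence)
  entries <- lapply(spectra_lib, function(e) {
    if (!e$sequence %in% lib_seqs) return(NULL)
    e$irt <- apply_irt(irt_model, e$irt)  # raw RT was stored in the field
    e$allele <- unname(allele_of[e$sequence])
    e
  })
  entries <- Filter(Negate(is.null), entries)
  per_allele <- split(entries, vapply(entries, `[[`, "", "allele"))
  merged <- merge_libraries(unname(per_allele))
  lib_path <- file.path(outdir, "library.sptxt")
  write_spectral_library(merged, lib_path)
  stage("library", lib_path)

  # -- stage: window scheme + assays + decoys
  scheme <- make_window_scheme(config$window_range_start,
                               config$window_range_end,
                               config$window_width,
                               config$window_left_overlap)
  sw_path <- file.path(outdir, "swaths.txt")
  write_swath_windows(scheme, sw_path)
  lib <- build_assay_library(
    merged, mz_range = c(config$fragment_mz_min, config$fragment_mz_max),
    min_transitions = config$min_transitions,
    max_transitions = config$max_transitions,
    match_tolerance_th = config$match_tolerance_th,
    excluded_windows = scheme)
  assays <- lib$assays
  if (nrow(assays) > 0) {
    dec <- generate_decoy_assays(
      assays, method = config$decoy_method,
      similarity_threshold_th = config$decoy_similarity_th,
      identity_threshold = config$decoy_identity_threshold,
      mz_range = c(config$fragment_mz_min, config$fragment_mz_max),
      seed = config$seed)
    assays <- rbind(assays, dec$decoys)
  }
  assay_path <- file.path(outdir, "assays.tsv")
  write_assay_tsv(assays, assay_path)
  stage("assays", c(sw_path, assay_path))

  # -- stage: report
  per_allele_counts <- table(ann_ok$best_allele)
  report <- list(
    n_identifications = nrow(ids),
    n_filtered = nrow(flt),
    fdr = lapply(fdr_results, unclass),
    threshold_probability = thr$threshold_probability,
    n_passing_targets = sum(!passing$is_decoy),
    n_passing_decoys = sum(passing$is_decoy),
    cfdr = cfdr$fdr,
    status_counts = as.list(table(ann$status)),
    annotated_per_allele = as.list(per_allele_counts),
    irt_model = unclass(irt_model),
    library_entries = length(merged),
    n_target_transitions = sum(!assays$is_decoy),
    n_decoy_transitions = sum(assays$is_decoy),
    n_rejected_peptides = nrow(lib$rejects),
    seed = config$seed)
  report_path <- file.path(outdir, "report.json")
  write_report(report, report_path)
  manifest_path <- file.path(outdir, "manifest.json")
  stage("report", report_path)
  write_report(manifest, manifest_path)
  invisible(manifest)
}
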