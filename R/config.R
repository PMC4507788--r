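# Run configuration: one flat list of tunables with validated defaults,
# serialized as JSON (lossless round trip, unknown keys rejected).

.CONFIG_DEFAULTS <- list(
  cutoff = 3,                 # annotation score cutoff (inclusive)
  supertype_ic50 = 500,       # nM, strong-binder threshold
  min_probability = 0.7,      # search probability export floor
  min_length = 8L,
  max_length = 12L,
  target_fdr = 0.01,          # peptide-level FDR used for the passing set
  fdr_levels = c(0.01, 0.05), # FDR levels reported
  hla_c_whitelist = character(),
  fragment_mz_min = 350,
  fragment_mz_max = 2000,
  min_transitions = 6L,
  max_transitions = 6L,
  match_tolerance_th = 0.05,
  decoy_method = "shuffle",
  decoy_similarity_th = 0.05,
  decoy_identity_threshold = 1,
  window_range_start = 400,
  window_range_end = 1200,
  window_width = 25,
  window_left_overlap = 1,
  prediction_noise_sd_log10 = 0,
  seed = 1L
)

#' Build a run configuration
#'
#' Starts from the package defaults and overrides the named values given;
#' unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults (see
#'   `hlaswath:::.CONFIG_DEFAULTS` for the full list).
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all config overrides must be named", call. = FALSE)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to JSON
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON file written by [write_run_config()].
#' @return List of class `run_config` (unknown keys rejected).
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$hla_c_whitelist <- as.character(x$hla_c_whitelist)
  for (k in c("min_length", "max_length", "min_transitions",
              "max_transitions", "seed"))
    if (!is.null(x[[k]])) x[[k]] <- as.integer(x[[k]])
  do.call(run_config, x)
}
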