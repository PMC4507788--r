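# Synthetic fixture generation: every input the pipeline needs, with
# ground truth, fully determined by one seed.
#
# The stated world: three class I alleles (A02/A03/B07) with disjoint
# anchor-pair motifs; 9-mer targets sampled from the motifs; decoys are
# C-terminus-fixed shuffles of targets; search probabilities Beta(8,2) for
# targets (mass above the 0.7 export floor) and Beta(2,8) for decoys; a
# 120-minute gradient with RT linear in iRT; fragment spectra with
# log-normal intensities and Poisson-count uniform noise peaks; the 11 iRT
# landmark peptides spiked into every sample.

#' Fixture specification
#'
#' Collects every tunable of the synthetic-data generators, with defaults
#' reflecting the conditions the pipeline is designed for.
#'
#' @param seed Integer master seed; fixed seed gives byte-identical output.
#' @param n_peptides_per_allele Targets sampled per allele (default 100).
#' @param alleles Allele names (must have built-in motif models).
#' @param decoy_fraction Decoys as a fraction of targets (default 0.1).
#' @param target_prob_shape,decoy_prob_shape Beta shape pairs for target and
#'   decoy search probabilities.
#' @param rt_gradient_minutes Chromatographic gradient length (default 120).
#' @param rt_slope,rt_intercept Planted RT(iRT) line, seconds
#'   (defaults 36 s per iRT unit, 1200 s offset: landmarks span the
#'   gradient).
#' @param rt_noise_sd RT noise (seconds, default 0).
#' @param prediction_noise_sd_log10 Mock-predictor noise (default 0).
#' @param intensity_sdlog Log-normal fragment intensity spread (default 1).
#' @param noise_peak_lambda Poisson mean of extra noise peaks per spectrum
#'   (default 0).
#' @param charge Precursor charge of generated ions (default 2).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_peptides_per_allele = 100L,
                         alleles = c("A02", "A03", "B07"),
                         decoy_fraction = 0.1,
                         target_prob_shape = c(8, 2),
                         decoy_prob_shape = c(2, 8),
                         rt_gradient_minutes = 120,
                         rt_slope = 36, rt_intercept = 1200,
                         rt_noise_sd = 0,
                         prediction_noise_sd_log10 = 0,
                         intensity_sdlog = 1,
                         noise_peak_lambda = 0,
                         charge = 2L) {
  structure(list(seed = as.integer(seed),
                 n_peptides_per_allele = as.integer(n_peptides_per_allele),
                 alleles = alleles, decoy_fraction = decoy_fraction,
                 target_prob_shape = target_prob_shape,
                 decoy_prob_shape = decoy_prob_shape,
                 rt_gradient_minutes = rt_gradient_minutes,
                 rt_slope = rt_slope, rt_intercept = rt_intercept,
                 rt_noise_sd = rt_noise_sd,
                 prediction_noise_sd_log10 = prediction_noise_sd_log10,
                 intensity_sdlog = intensity_sdlog,
                 noise_peak_lambda = noise_peak_lambda,
                 charge = as.integer(charge)),
            class = "fixture_spec")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a synthetic identification table with ground truth
#'
#' Targets are sampled from each allele's motif; decoys are shuffled
#' targets (C-terminus fixed) flagged `is_decoy = TRUE`. Probabilities are
#' drawn from the spec's Beta distributions, retention times uniformly over
#' the gradient.
#'
#' @param spec A [fixture_spec()].
#' @param sample_id Sample identifier written to every row.
#' @return List with `identifications` (data.frame `sample_id`, `sequence`,
#'   `charge`, `probability`, `is_decoy`, `rt_seconds`) and `truth`
#'   (data.frame `sequence`, `allele`).
#' @export
generate_identifications <- function(spec, sample_id = "S1") {
  models <- default_motif_models(spec$alleles)
  .with_seed(spec$seed, {
    targets <- unlist(lapply(models, function(m)
      sample_motif_peptides(m, spec$n_peptides_per_allele)))
    truth <- data.frame(
      sequence = unname(targets),
      allele = rep(spec$alleles, each = spec$n_peptides_per_allele),
      stringsAsFactors = FALSE)
    truth <- truth[!duplicated(truth$sequence), , drop = FALSE]

    n_decoys <- round(spec$decoy_fraction * nrow(truth))
    decoys <- character(0)
    if (n_decoys > 0) {
      src <- sample(truth$sequence, n_decoys)
      decoys <- vapply(src, .shuffle_keep_cterm, "")
      decoys <- setdiff(unique(decoys), truth$sequence)
    }
    seqs <- c(truth$sequence, decoys)
    is_decoy <- c(rep(FALSE, nrow(truth)), rep(TRUE, length(decoys)))
    prob <- ifelse(is_decoy,
                   stats::rbeta(length(seqs), spec$decoy_prob_shape[1],
                                spec$decoy_prob_shape[2]),
                   stats::rbeta(length(seqs), spec$target_prob_shape[1],
                                spec$target_prob_shape[2]))
    ids <- data.frame(
      sample_id = sample_id,
      sequence = seqs,
      charge = spec$charge,
      probability = round(prob, 6),
      is_decoy = is_decoy,
      rt_seconds = round(stats::runif(length(seqs), 0,
                                      spec$rt_gradient_minutes * 60), 2),
      stringsAsFactors = FALSE)
    list(identifications = ids, truth = truth)
  })
}

#' Generate synthetic fragment spectra with iRT landmarks
#'
#' Each peptide gets peaks at its theoretical singly charged b/y m/z with
#' log-normal intensities plus a Poisson-count of uniform noise peaks; its
#' retention time follows the planted RT(iRT) line with optional Gaussian
#' noise. The 11 landmark peptides are always included.
#'
#' @param peptides Character vector of peptide sequences.
#' @param spec A [fixture_spec()] (seed, charge, RT line, noise levels).
#' @param irt_reference Landmark reference table
#'   (default [default_irt_reference()]).
#' @return List with `spectra` (list of [peak_spectrum()]; landmarks
#'   carry charge 2 and their names are in `landmark_sequences`) and
#'   `truth` (data.frame `sequence`, `irt` of the planted coordinates).
#' @export
generate_spectra <- function(peptides, spec,
                             irt_reference = default_irt_reference()) {
  .with_seed(spec$seed + 1L, {
    irt_true <- stats::runif(length(peptides), 0, 100)
    all_seqs <- c(peptides, irt_reference$sequence)
    all_irt <- c(irt_true, irt_reference$irt)
    spectra <- lapply(seq_along(all_seqs), function(i) {
      s <- all_seqs[i]
      theo <- theoretical_fragments(s, c("b", "y"), 1L)
      int <- stats::rlnorm(nrow(theo), meanlog = log(1000),
                           sdlog = spec$intensity_sdlog)
      peaks <- data.frame(mz = theo$mz, intensity = int)
      n_noise <- stats::rpois(1, spec$noise_peak_lambda)
      if (n_noise > 0) {
        peaks <- rbind(peaks, data.frame(
          mz = stats::runif(n_noise, 200, 1500),
          intensity = stats::rlnorm(n_noise, log(100), 0.5)))
      }
      rt <- spec$rt_intercept + spec$rt_slope * all_irt[i] +
        stats::rnorm(1, 0, spec$rt_noise_sd)
      peak_spectrum(s, spec$charge, peaks, rt_seconds = rt)
    })
    list(spectra = spectra,
         truth = data.frame(sequence = all_seqs, irt = all_irt,
                            stringsAsFactors = FALSE),
         landmark_sequences = irt_reference$sequence)
  })
}

#' Generate synthetic source proteins embedding given peptides
#'
#' Each peptide is embedded once in a random flanking context, yielding a
#' protein in which it occurs as a substring.
#'
#' @param peptides Peptides to embed.
#' @param spec A [fixture_spec()] (seed).
#' @param flank_length Residues of random sequence on each side.
#' @return Named character vector of protein sequences (names
#'   `SYNPROT_<i>`).
#' @export
generate_source_proteins <- function(peptides, spec, flank_length = 30L) {
  aa <- names(AA_MONO)
  .with_seed(spec$seed + 2L, {
    prots <- vapply(peptides, function(p) {
      paste0(paste(sample(aa, flank_length, TRUE), collapse = ""), p,
             paste(sample(aa, flank_length, TRUE), collapse = ""))
    }, "")
    stats::setNames(unname(prots),
                    paste0("SYNPROT_", seq_along(peptides)))
  })
}

#' Write a complete fixture sample directory
#'
#' Writes identifications.tsv, typing.tsv, spectra.sptxt, irt_reference.tsv,
#' proteins.fasta (synthetic source proteins) and ground_truth.json into
#' `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @param sample_id Sample identifier.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(spec, dir, sample_id = "S1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- generate_identifications(spec, sample_id)
  spct <- generate_spectra(ids$truth$sequence, spec)
  prots <- generate_source_proteins(ids$truth$sequence, spec)

  write_identifications(ids$identifications,
                        file.path(dir, "identifications.tsv"))
  utils::write.table(
    data.frame(sample_id = sample_id,
               alleles = paste(spec$alleles, collapse = ",")),
    file.path(dir, "typing.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  entries <- lapply(spct$spectra, function(s) {
    structure(list(sequence = s$sequence, charge = s$charge,
                   precursor_mz = s$precursor_mz, peaks = s$peaks,
                   irt = s$rt_seconds,  # raw RT; normalized downstream
                   n_replicates = 1L, allele = NA_character_),
              class = "consensus_entry")
  })
  write_spectral_library(entries, file.path(dir, "spectra.sptxt"))
  write_irt_reference(default_irt_reference(),
                      file.path(dir, "irt_reference.tsv"))
  write_fasta(prots, file.path(dir, "proteins.fasta"))
  write_report(list(seed = spec$seed, alleles = spec$alleles,
                    truth = spct$truth,
                    generating_allele = ids$truth),
               file.path(dir, "ground_truth.json"))
  invisible(dir)
}
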