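test_that("mock predictor honors motif construction", {
  models <- default_motif_models()
  # anchor-perfect A02 peptide: minimal IC50 among the model alleles
  pep <- "GLGGGGGGV"  # L at P2, V at P9
  ic50 <- mock_predict(pep, c("A02", "A03", "B07"), models)
  expect_equal(colnames(ic50)[which.min(ic50)], "A02")
  expect_lt(ic50[1, "A02"], 500)
  expect_gt(ic50[1, "A02"], 5)
  # scrambled anchors: non-binder for every allele
  bad <- mock_predict("GGGGGGGGG", c("A02", "A03", "B07"), models)
  expect_true(all(bad > 500))
  # determinism at zero noise
  expect_identical(mock_predict(pep, "A02", models),
                   mock_predict(pep, "A02", models))
  expect_error(mock_predict(pep, "B99", models), "unknown allele")
})

test_that("off-length peptides are scored via the 9-mer core scan", {
  models <- default_motif_models("A02")
  long <- paste0("GGG", "GLGGGGGGV")  # 12-mer containing a perfect core
  expect_lt(mock_predict(long, "A02", models)[1, 1], 500)
  short <- "GLGGGGGV"                 # 8-mer, C-terminus pinned to P9
  expect_lt(mock_predict(short, "A02", models)[1, 1], 500)
})

test_that("generate_identifications is seed-deterministic with ground truth", {
  spec <- fixture_spec(seed = 5, n_peptides_per_allele = 30)
  a <- generate_identifications(spec)
  b <- generate_identifications(spec)
  expect_identical(a, b)
  expect_equal(nrow(a$truth), sum(!a$identifications$is_decoy))
  expect_true(all(a$truth$allele %in% spec$alleles))
  # decoy_fraction 0 -> no decoy rows
  s0 <- fixture_spec(seed = 5, n_peptides_per_allele = 30,
                     decoy_fraction = 0)
  expect_false(any(generate_identifications(s0)$identifications$is_decoy))
  # 3 alleles x 100 -> 300 target rows (minus rare duplicate collisions)
  s3 <- fixture_spec(seed = 6, n_peptides_per_allele = 100)
  n_t <- sum(!generate_identifications(s3)$identifications$is_decoy)
  expect_lte(n_t, 300)
  expect_gte(n_t, 290)
})

test_that("planted probability mixture yields the analytic FDR", {
  # decoys ~ Beta(2,8), targets ~ Beta(8,2); at threshold t the expected
  # FDR is decoy_frac * (1 - pbeta(t,2,8)) / (1 - pbeta(t,8,2))
  spec <- fixture_spec(seed = 20, n_peptides_per_allele = 500,
                       decoy_fraction = 0.5)
  ids <- generate_identifications(spec)$identifications
  t <- 0.5
  nt <- sum(!ids$is_decoy & ids$probability >= t)
  nd <- sum(ids$is_decoy & ids$probability >= t)
  n_targets <- sum(!ids$is_decoy); n_decoys <- sum(ids$is_decoy)
  exp_fdr <- (n_decoys * (1 - pbeta(t, 2, 8))) /
    (n_targets * (1 - pbeta(t, 8, 2)))
  obs_fdr <- nd / nt
  # binomial error on the decoy count dominates
  se <- sqrt(n_decoys * (1 - pbeta(t, 2, 8))) / (n_targets * (1 - pbeta(t, 8, 2)))
  expect_lt(abs(obs_fdr - exp_fdr), 4 * se)
})

test_that("zero-noise spectra are fully annotatable and recover the RT line", {
  spec <- fixture_spec(seed = 8, n_peptides_per_allele = 5)
  ids <- generate_identifications(spec)
  sp <- generate_spectra(ids$truth$sequence, spec)
  # every generated peptide yields a full 6-transition assay
  entries <- build_consensus_library(sp$spectra)
  entries <- entries[!grepl(paste(sp$landmark_sequences, collapse = "|"),
                            names(entries))]
  lib <- build_assay_library(entries)
  expect_equal(nrow(lib$rejects), 0)
  expect_true(all(table(lib$assays$transition_group_id) == 6))
  # landmark RTs recover the planted line exactly at zero noise
  obs <- do.call(rbind, lapply(sp$spectra, function(s)
    data.frame(sequence = s$sequence, rt_seconds = s$rt_seconds)))
  m <- fit_irt(obs[obs$sequence %in% sp$landmark_sequences, ])
  expect_equal(m$slope, 1 / spec$rt_slope, tolerance = 1e-9)
  expect_equal(m$intercept, -spec$rt_intercept / spec$rt_slope,
               tolerance = 1e-6)
})

test_that("fixture directories are complete and byte-identical per seed", {
  spec <- fixture_spec(seed = 14, n_peptides_per_allele = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_dir(spec, d1)
  write_fixture_dir(spec, d2)
  files <- c("identifications.tsv", "typing.tsv", "spectra.sptxt",
             "irt_reference.tsv", "proteins.fasta", "ground_truth.json")
  expect_setequal(list.files(d1), files)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # embedded peptides are substrings of their synthetic proteins
  prots <- read_fasta(file.path(d1, "proteins.fasta"))
  truth <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_true(all(mapply(grepl, truth$generating_allele$sequence,
                         prots[seq_len(nrow(truth$generating_allele))],
                         MoreArgs = list(fixed = TRUE))))
})
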