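make_peps <- function(n, prob, decoy = FALSE, len = 9) {
  data.frame(sequence = replicate(n, paste(sample(LETTERS[1:20], len,
                                                  TRUE), collapse = "")),
             charge = 2L, probability = prob,
             is_decoy = decoy, stringsAsFactors = FALSE)
}

test_that("filter_peptides applies probability and length cuts", {
  df <- data.frame(
    sequence = c("SHORTPE", "GOODPEPTI", "LOWPROBPE", "LONGPEPTIDEEE"),
    charge = 2L,
    probability = c(0.99, 0.95, 0.69, 0.99),
    is_decoy = FALSE, stringsAsFactors = FALSE)
  out <- filter_peptides(df)
  expect_equal(out$sequence, "GOODPEPTI")  # 7-mer, p<0.7 and 13-mer removed

  # brute-force filter oracle on a random table
  set.seed(21)
  big <- data.frame(
    sequence = replicate(1000, paste(sample(LETTERS[1:20],
                                            sample(6:15, 1), TRUE),
                                     collapse = "")),
    charge = 2L, probability = runif(1000), is_decoy = FALSE,
    stringsAsFactors = FALSE)
  out <- filter_peptides(big)
  oracle <- sum(big$probability >= 0.7 &
                  nchar(big$sequence) >= 8 & nchar(big$sequence) <= 12)
  expect_equal(nrow(out), oracle)
})

test_that("collapse_psms keeps the best probability per sequence+charge", {
  df <- data.frame(sequence = c("AAPEPTIDE", "AAPEPTIDE", "AAPEPTIDE"),
                   charge = c(2L, 2L, 3L),
                   probability = c(0.8, 0.95, 0.7),
                   is_decoy = FALSE, stringsAsFactors = FALSE)
  out <- collapse_psms(df)
  expect_equal(nrow(out), 2)
  expect_equal(out$probability[out$charge == 2], 0.95)
})

test_that("fdr_threshold: no decoys gives FDR 0 at the loosest threshold", {
  set.seed(1)
  df <- make_peps(50, runif(50, 0.7, 1))
  r <- fdr_threshold(df, 0.01)
  expect_equal(r$fdr, 0)
  expect_equal(r$n_targets, 50)
  expect_equal(r$threshold_probability, min(df$probability))
})

test_that("fdr_threshold counts 99 targets + 1 decoy as ~1.01%", {
  set.seed(2)
  df <- rbind(make_peps(99, runif(99, 0.8, 1)),
              make_peps(1, 0.85, decoy = TRUE))
  r <- fdr_threshold(df, 0.05)
  expect_equal(r$n_targets, 99)
  expect_equal(r$n_decoys, 1)
  expect_equal(r$fdr, 1 / 99, tolerance = 1e-12)
})

test_that("fdr_threshold matches an exhaustive scan and is monotone", {
  set.seed(3)
  df <- rbind(make_peps(400, rbeta(400, 8, 2)),
              make_peps(80, rbeta(80, 2, 6), decoy = TRUE))
  for (q in c(0.01, 0.05, 0.1, 0.3)) {
    r <- fdr_threshold(df, q)
    if (r$n_targets > 0) {
      expect_lte(r$fdr, q)
      # exhaustive oracle: best achievable target count at this q
      best <- 0
      for (t in unique(df$probability)) {
        nt <- sum(df$probability >= t & !df$is_decoy)
        nd <- sum(df$probability >= t & df$is_decoy)
        if (nt > 0 && nd / nt <= q) best <- max(best, nt)
      }
      expect_equal(r$n_targets, best)
    }
  }
  n_pass <- vapply(c(0.01, 0.05, 0.1, 0.3),
                   function(q) fdr_threshold(df, q)$n_targets, 0)
  expect_true(all(diff(n_pass) >= 0))
})

test_that("corrected_fdr removes non-annotated peptides from both counts", {
  ann <- data.frame(
    sequence = c("TARGETAAA", "TARGETBBB", "DECOYAAAA", "DECOYBBBB"),
    status = c("annotated", "annotated", "non_annotated", "non_annotated"),
    stringsAsFactors = FALSE)
  passing <- data.frame(
    sequence = ann$sequence,
    is_decoy = c(FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  r <- corrected_fdr(passing, ann)
  expect_equal(r$fdr, 0)          # all decoys fail annotation
  expect_equal(r$n_targets, 2)
  expect_error(
    corrected_fdr(data.frame(sequence = "MISSINGPEP", is_decoy = FALSE),
                  ann),
    "MISSINGPEP")
})

test_that("cFDR halves the FDR when decoys pass annotation at half rate", {
  # constructed fixture: passing set at exactly 1% and 5% FDR; targets
  # annotated at rate 0.8, decoys at 0.4
  run_case <- function(n_decoys, seed) {
    set.seed(seed)
    n_t <- 10000
    passing <- rbind(make_peps(n_t, runif(n_t, 0.9, 1)),
                     make_peps(n_decoys, runif(n_decoys, 0.9, 1),
                               decoy = TRUE))
    ann <- data.frame(
      sequence = passing$sequence,
      status = ifelse(
        runif(nrow(passing)) < ifelse(passing$is_decoy, 0.4, 0.8),
        "annotated", "non_annotated"),
      stringsAsFactors = FALSE)
    corrected_fdr(passing, ann)$fdr
  }
  # binomial error on 100 decoys at rate .4 dominates: ~3 sd tolerance
  expect_equal(run_case(100, 17), 0.005, tolerance = 0.45)
  expect_equal(run_case(500, 18), 0.025, tolerance = 0.2)
})

test_that("identical inputs give identical FDR results", {
  set.seed(4)
  df <- rbind(make_peps(200, rbeta(200, 8, 2)),
              make_peps(30, rbeta(30, 2, 6), decoy = TRUE))
  expect_identical(fdr_threshold(df, 0.05), fdr_threshold(df, 0.05))
})
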