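test_that("entries with fewer than min_transitions are dropped", {
  # only 5 annotatable fragments -> no assay
  seqn <- "ALMNQRTSV"
  theo <- theoretical_fragments(seqn, c("b", "y"), 1L)
  theo <- theo[theo$mz >= 350 & theo$mz <= 2000, ][1:5, ]
  sp <- peak_spectrum(seqn, 2, data.frame(mz = theo$mz,
                                          intensity = 1:5 * 10), irt = 40)
  e <- build_consensus(list(sp), allele = "A02")
  expect_null(select_transitions(e))
  lib <- build_assay_library(list(e))
  expect_equal(nrow(lib$assays), 0)
  expect_equal(lib$rejects$sequence, seqn)
})

test_that("fragments outside 350-2000 Th are excluded", {
  e <- ladder_entry("ALMNQRTSVK", 2)
  e$peaks <- rbind(e$peaks, data.frame(mz = 2100, intensity = 1e9))
  a <- select_transitions(e, match_tolerance_th = 0.05)
  expect_true(all(a$fragment_mz >= 350 & a$fragment_mz <= 2000))
  expect_false(any(a$fragment_mz > 2000))
})

test_that("the six most intense annotatable fragments are selected", {
  set.seed(10)
  for (i in 1:20) {
    pep <- random_peptide(9, 12)
    theo <- theoretical_fragments(pep, c("b", "y"), 1L)
    # keep only peaks far from every other theoretical ion (charges 1-2)
    # so the peak -> ion annotation is unambiguous
    all_theo <- theoretical_fragments(pep, c("b", "y"), 1:2)
    sep <- vapply(seq_len(nrow(theo)), function(j)
      sum(abs(all_theo$mz - theo$mz[j]) < 0.2) == 1, TRUE)
    theo <- theo[sep, , drop = FALSE]
    ok <- theo$mz >= 350 & theo$mz <= 2000
    if (sum(ok) < 7) next
    int <- runif(nrow(theo), 1, 1e4)
    sp <- peak_spectrum(pep, 2, data.frame(mz = theo$mz, intensity = int),
                        irt = 30)
    e <- build_consensus(list(sp))
    a <- select_transitions(e)
    expect_equal(nrow(a), 6)
    # exhaustive ranking oracle
    want <- sort(int[ok], decreasing = TRUE)[1:6]
    expect_equal(sort(a$library_intensity, decreasing = TRUE), want,
                 tolerance = 1e-9)
  }
})

test_that("self-window exclusion removes co-isolated fragments", {
  scheme <- make_window_scheme(400, 1200, 25, 1)
  pep <- "ALMNQRTSVK"
  e <- ladder_entry(pep, 2)
  wi <- assign_precursor_window(e$precursor_mz, scheme)
  w <- scheme$windows[wi, ]
  a <- select_transitions(e, excluded_windows = scheme,
                          min_transitions = 1L, max_transitions = 20L)
  expect_false(any(a$fragment_mz >= w$start & a$fragment_mz < w$end))
  # without the scheme those fragments are eligible
  a0 <- select_transitions(e, min_transitions = 1L, max_transitions = 20L)
  expect_gte(nrow(a0), nrow(a))
})

test_that("transition constraints hold across a random library", {
  set.seed(123)
  entries <- lapply(1:200, function(i) ladder_entry(random_peptide(8, 12)))
  lib <- build_assay_library(entries)
  a <- lib$assays
  expect_true(all(a$fragment_type %in% c("b", "y")))
  expect_true(all(a$fragment_charge %in% c(1L, 2L)))
  expect_true(all(a$fragment_mz >= 350 & a$fragment_mz <= 2000))
  expect_true(all(table(a$transition_group_id) == 6))
  # dropped peptides appear in rejects, retained ones do not
  expect_equal(length(unique(a$transition_group_id)) + nrow(lib$rejects),
               length(entries))
})
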