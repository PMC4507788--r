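test_that("annotation score is second-best over best IC50", {
  s <- compute_annotation_score(c(A03 = 278, B39 = 21400))
  expect_equal(s$best_allele, "A03")
  expect_equal(s$best_ic50, 278)
  expect_equal(s$second_ic50, 21400)
  expect_equal(s$score, 21400 / 278)
  expect_equal(round(s$score), 77)

  # tie gives score exactly 1; single allele gives +Inf
  expect_equal(compute_annotation_score(c(A02 = 500, B07 = 500))$score, 1)
  expect_equal(compute_annotation_score(c(A02 = 10))$score, Inf)
})

test_that("score equals sorted-vector ratio on random affinity vectors", {
  set.seed(101)
  for (i in 1:50) {
    v <- stats::setNames(round(runif(4, 1, 50000), 3),
                         c("A02", "A03", "B07", "B35"))
    s <- compute_annotation_score(v)
    sv <- sort(v)  # brute-force sort oracle
    expect_equal(s$score, unname(sv[2] / sv[1]))
    expect_equal(s$best_allele, names(sv)[1])
  }
})

test_that("score is invariant under positive rescaling of all IC50s", {
  set.seed(5)
  for (i in 1:20) {
    v <- stats::setNames(runif(4, 1, 1e4), c("A01", "A02", "B07", "B44"))
    s1 <- compute_annotation_score(v)
    s2 <- compute_annotation_score(v * runif(1, 0.01, 100))
    expect_equal(s1$score, s2$score, tolerance = 1e-12)
    expect_equal(s1$best_allele, s2$best_allele)
  }
})

test_that("invalid affinity vectors are rejected", {
  expect_error(compute_annotation_score(numeric()), "empty")
  expect_error(compute_annotation_score(c(A02 = -1, B07 = 10)), "positive")
  expect_error(compute_annotation_score(c(A02 = 0, B07 = 10)), "positive")
  expect_error(compute_annotation_score(c(1, 2)), "allele names")
  expect_error(compute_annotation_score(c(A02 = 1, A02 = 2)), "unique")
})

fixed_predictor <- function(tbl) {
  function(peptides, alleles) {
    m <- tbl[peptides, alleles, drop = FALSE]
    m
  }
}

test_that("annotate_peptides reproduces the worked example and categories", {
  tbl <- matrix(
    c(29000, 278, 21400, 45000,   # KLEEQARAK: best A03
      100, 40000, 120, 30000,     # supertype: A02 100, B35 120, score 1.2
      5000, 6000, 7000, 8000),    # weak everywhere, score 1.2 -> non_annotated
    nrow = 3, byrow = TRUE,
    dimnames = list(c("KLEEQARAK", "SUPERPEPT", "WEAKPEPTI"),
                    c("A02", "A03", "B35", "B39")))
  ann <- annotate_peptides(rownames(tbl), colnames(tbl),
                           fixed_predictor(tbl))
  expect_equal(ann$status, c("annotated", "supertype", "non_annotated"))
  expect_equal(ann$best_allele[1], "A03")
  expect_equal(round(ann$score[1]), 77)
  expect_true(all(paste0("ic50.", colnames(tbl)) %in% names(ann)))
})

test_that("HLA-C best binders are excluded unless whitelisted", {
  tbl <- matrix(c(50, 9000), nrow = 1,
                dimnames = list("CPEPTIDEL", c("C04", "B27")))
  ann <- annotate_peptides("CPEPTIDEL", c("C04", "B27"),
                           fixed_predictor(tbl))
  expect_equal(ann$status, "hla_c_binder")
  ann_wl <- annotate_peptides("CPEPTIDEL", c("C04", "B27"),
                              fixed_predictor(tbl),
                              hla_c_whitelist = "C04")
  expect_equal(ann_wl$status, "annotated")
  expect_equal(ann_wl$best_allele, "C04")
})

test_that("statuses partition the peptides and cutoff is monotone", {
  set.seed(33)
  spec <- fixture_spec(seed = 9, n_peptides_per_allele = 60)
  ids <- generate_identifications(spec)
  pred <- mock_predictor()
  counts <- vapply(c(2, 3, 5, 10), function(cut) {
    ann <- annotate_peptides(ids$truth$sequence, spec$alleles, pred,
                             cutoff = cut)
    expect_equal(sum(table(ann$status)), nrow(ids$truth))
    expect_true(all(ann$score[ann$status == "annotated"] >= cut))
    sum(ann$status == "annotated")
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that(">=90% of motif-sampled peptides are annotated to their allele", {
  set.seed(12)
  spec <- fixture_spec(seed = 12, n_peptides_per_allele = 70)
  ids <- generate_identifications(spec)
  ann <- annotate_peptides(ids$truth$sequence, spec$alleles,
                           mock_predictor())
  hit <- ann$status == "annotated" &
    ann$best_allele == ids$truth$allele[match(ann$sequence,
                                              ids$truth$sequence)]
  expect_gte(mean(hit), 0.9)
})

test_that("allele_summary matches order-statistic oracles", {
  mk <- function(ic50, allele = "B07") {
    data.frame(sequence = paste0("P", seq_along(ic50)),
               best_allele = allele, best_ic50 = ic50,
               score = 10, status = "annotated",
               stringsAsFactors = FALSE)
  }
  # degenerate distribution
  s <- allele_summary(mk(rep(100, 20)), "B07")
  expect_equal(s$ic50_at_q95, 100)
  expect_equal(s$frac_below_500nM, 1.0)
  # integers 1..100: q95 is the 95th order statistic
  s <- allele_summary(mk(1:100), "B07")
  expect_equal(s$ic50_at_q95, 95)
  expect_equal(s$frac_below_500nM, 1.0)
  expect_equal(s$ic50_cdf$cum_fraction[100], 1.0)
  expect_true(all(diff(s$ic50_cdf$cum_fraction) >= 0))
  # random instance against an independent sort
  set.seed(8)
  x <- round(rlnorm(137, log(300), 1), 2)
  s <- allele_summary(mk(x), "B07")
  xs <- sort(x)
  expect_equal(s$ic50_at_q95, xs[ceiling(0.95 * length(x))])
  # empty summary signals, not crashes
  expect_warning(s0 <- allele_summary(mk(1:5, "A02"), "B57"), "no annotated")
  expect_equal(s0$n_peptides, 0L)
})

test_that("source_protein_rank bins by exhaustive tiling", {
  pred <- mock_predictor()
  # single-tile protein: the query is trivially top1
  pep <- "ALMNQRTSV"  # A02 anchors M at P2, V at P9
  r <- source_protein_rank(pep, pep, "A02", pred)
  expect_equal(r$bin, "top1")
  expect_equal(r$n_tiles, 1L)

  # query at the motif optimum of a 50-residue protein
  set.seed(3)
  flank <- function(n) paste(sample(c("G", "S", "T", "D", "E"), n, TRUE),
                             collapse = "")
  prot <- paste0(flank(20), pep, flank(21))
  r <- source_protein_rank(pep, prot, "A02", pred)
  # exhaustive tiling oracle
  tiles <- substring(prot, 1:(nchar(prot) - 8), 9:nchar(prot))
  ic50 <- mock_predict(tiles, "A02")[, 1]
  expect_equal(r$n_tiles, length(tiles))
  expect_equal(r$rank, sum(ic50 < ic50[match(pep, tiles)]) + 1L)
  expect_equal(r$bin, "top1")

  # a median-ranked query falls below the 90th percentile
  med_tile <- tiles[order(ic50)][ceiling(length(tiles) / 2)]
  rm <- source_protein_rank(med_tile, prot, "A02", pred)
  expect_equal(rm$bin, "below90")
  expect_error(source_protein_rank("WWWWWWWWW", prot, "A02", pred),
               "not found")
})

test_that("heat-map matrix is -log10 affinity with allele-block rows", {
  tbl <- matrix(c(1, 1000,
                  10, 20,
                  2000, 5), nrow = 3, byrow = TRUE,
                dimnames = list(c("PEPTIDEA", "PEPTIDEB", "PEPTIDEC"),
                                c("A02", "B07")))
  ann <- annotate_peptides(rownames(tbl), colnames(tbl),
                           fixed_predictor(tbl))
  hm <- build_heatmap_matrix(ann, c("A02", "B07"))
  expect_equal(dim(hm), c(3L, 2L))
  expect_equal(hm["PEPTIDEA", "A02"], 0)        # IC50 1 nM -> 0
  expect_equal(hm["PEPTIDEA", "B07"], -3)       # 1000 nM -> -3
  # blocks: A02 peptides first (PEPTIDEA best 1 nM before supertype-free rows)
  grp <- attr(hm, "row_groups")
  ann_rows <- ann$status == "annotated"
  for (al in c("A02", "B07")) {
    blk <- rownames(hm)[grp == al]
    lab <- ann$sequence[ann_rows & ann$best_allele == al]
    expect_setequal(blk, lab)
  }
  # within-block best-affinity ordering
  a02 <- rownames(hm)[grp == "A02"]
  expect_equal(a02, a02[order(ann$best_ic50[match(a02, ann$sequence)])])
})
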