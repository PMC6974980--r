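fixture_setup <- function() {
  locus <- make_fixture_locus()
  edit <- make_fixture_edit(locus)
  list(
    locus = locus, edit = edit,
    patterns = derive_patterns(locus, edit),
    hdr = fixture_hdr_amplicon(locus, edit)
  )
}

test_that("the rule cascade classifies the five canonical reads", {
  fx <- fixture_setup()
  wt <- fx$locus$amplicon_seq
  hdr <- fx$hdr

  # (1) exact wild-type amplicon -> WT
  c1 <- classify_read(wt, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(c1$category), "WT")
  expect_true(c1$wt_pattern_hit)

  # (2) all intended substitutions, nothing else -> Correct_HDR
  c2 <- classify_read(hdr, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(c2$category), "Correct_HDR")
  expect_equal(c2$protein_check, "pass")

  # (3) HDR substitutions plus a 2-nt frameshift deletion elsewhere in the
  # CDS -> Incorrect_HDR
  c3_seq <- paste0(substr(hdr, 1, 54), substr(hdr, 57, nchar(hdr)))
  c3 <- classify_read(c3_seq, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(c3$category), "Incorrect_HDR")
  expect_equal(c3$protein_check, "fail")

  # (4) 25-nt deletion spanning the protospacer, no HDR bases -> Others
  c4_seq <- paste0(substr(wt, 1, 29), substr(wt, 55, nchar(wt)))
  c4 <- classify_read(c4_seq, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(c4$category), "Others")
  expect_false(c4$wt_pattern_hit || c4$hdr_pattern_hit)

  # (5) HDR substitutions plus one extra synonymous third-position change
  # (GAG -> GAA at codon 17) -> still Correct_HDR
  c5_seq <- hdr
  substr(c5_seq, 61, 61) <- "A"
  c5 <- classify_read(c5_seq, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(c5$category), "Correct_HDR")
})

test_that("classification handles orientation, stray-protein and unmapped reads", {
  fx <- fixture_setup()

  # reverse-complement reads are recognised after flipping
  rc_read <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fx$hdr)))
  cc <- classify_read(rc_read, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(cc$category), "Correct_HDR")
  expect_equal(cc$orientation, "-")

  # HDR pattern with an extra *non-synonymous* substitution -> Incorrect_HDR
  bad <- fx$hdr
  substr(bad, 59, 59) <- "C" # codon 17 GAG -> CAG, E -> Q
  cb <- classify_read(bad, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(cb$category), "Incorrect_HDR")

  # missing expected residue change (HDR pattern without the edit base would
  # be the WT pattern, so plant hdr coding-bar changes only): neither pattern
  # matches -> Others
  cb_only <- fx$locus$amplicon_seq
  substr(cb_only, 31, 31) <- "A"
  substr(cb_only, 34, 34) <- "G"
  co <- classify_read(cb_only, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(co$category), "Others")

  # unrelated sequence -> Others with reason "unmapped"
  set.seed(21)
  junk <- random_dna(110)
  cj <- classify_read(junk, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(cj$category), "Others")
  expect_equal(cj$reason, "unmapped")
  expect_lt(cj$identity_pct, 60)

  # a pattern longer than the read is not an exception, just Others
  stub <- substr(fx$locus$amplicon_seq, 1, 15)
  cs <- classify_read(stub, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(cs$category), "Others")
})

test_that("WT precedence holds when both patterns occur in one read", {
  fx <- fixture_setup()
  both <- paste0(fx$locus$amplicon_seq, fx$hdr)
  cb <- classify_read(both, fx$locus, fx$patterns, fx$edit)
  expect_equal(as.character(cb$category), "WT")
})

test_that("summarize_calls computes counts and percentages over assembled reads", {
  fx <- fixture_setup()
  reads <- c(rep(fx$locus$amplicon_seq, 9), fx$hdr)
  calls <- classify_reads(reads, fx$locus, fx$patterns, fx$edit)
  rep10 <- summarize_calls(calls, "toy", n_unmerged = 3)
  expect_equal(rep10$total_assembled, 10)
  expect_equal(rep10$n_unmerged, 3)
  expect_equal(unname(rep10$percentages["Correct_HDR"]), 10)
  expect_equal(unname(rep10$percentages["WT"]), 90)
  expect_equal(sum(rep10$percentages), 100)

  all_wt <- summarize_calls(
    classify_reads(rep(fx$locus$amplicon_seq, 5), fx$locus, fx$patterns, fx$edit),
    "wt"
  )
  expect_equal(unname(all_wt$percentages["WT"]), 100)
  expect_equal(sum(all_wt$counts[c("Correct_HDR", "Incorrect_HDR", "Others")]), 0)

  expect_error(summarize_calls(calls[0, ], "empty"), "no calls")
})

test_that("fold_change reproduces the published ratios", {
  mk <- function(pct_correct) {
    # synthetic report with a given Correct_HDR percentage
    structure(
      list(
        condition = "x",
        counts = c(WT = 0, Correct_HDR = 0, Incorrect_HDR = 0, Others = 0),
        total_assembled = 10000, n_unmerged = 0,
        percentages = c(
          WT = 100 - pct_correct, Correct_HDR = pct_correct,
          Incorrect_HDR = 0, Others = 0
        )
      ),
      class = "efficiency_report"
    )
  }
  # 11.82% vs 0.54%: printed as "22-fold"
  expect_equal(fold_change(mk(11.82), mk(0.54)), 21.9, tolerance = 0.01)
  # 17.86% vs 0.60%: upper end of the printed 22-57-fold range
  expect_equal(fold_change(mk(17.86), mk(0.60)), 29.8, tolerance = 0.01)
  expect_equal(fold_change(mk(5), mk(5)), 1.0)
  fz <- fold_change(mk(5), mk(0))
  expect_true(is.na(fz))
  expect_true(attr(fz, "undefined"))
})

test_that("chi_square_rescue matches the closed-form Pearson statistic", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- chi_square_rescue(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  skew <- matrix(c(90, 10, 10, 90), 2)
  r2 <- chi_square_rescue(skew)
  expect_equal(r2$statistic, 128)
  expect_equal(r2$df, 1)
  expect_equal(r2$statistic, oracle_pearson_chisq(skew))

  # identical column distributions in a 3x2 table -> statistic 0
  same <- cbind(c(30, 50, 20), c(60, 100, 40))
  expect_equal(chi_square_rescue(same)$statistic, 0)

  expect_error(chi_square_rescue(matrix(c(0, 0, 5, 5), 2)), "empty row or column")

  set.seed(22)
  for (i in 1:10) {
    tab <- matrix(sample(5:80, 6), 3)
    expect_equal(chi_square_rescue(tab)$statistic, oracle_pearson_chisq(tab))
  }
})

test_that("determinism: identical reads and config give identical reports", {
  cl1 <- run_closed_loop(7, 500, 0.005)
  cl2 <- run_closed_loop(7, 500, 0.005)
  expect_identical(cl1$pip$report, cl2$pip$report)
  expect_identical(cl1$pip$calls$category, cl2$pip$calls$category)
})

test_that("WT-to-Others leakage follows the closed form 1 - (1-e)^L", {
  e <- 0.005
  cl <- run_closed_loop(31, 20000, e, class_proportions = c(WT = 1))
  patt <- derive_patterns(cl$locus, cl$edit)
  L <- nchar(patt$wt_pattern)
  expected <- 1 - (1 - e)^L
  tab <- table(cl$pip$calls$category)
  measured <- 1 - tab[["WT"]] / sum(tab)
  expect_lt(abs(measured - expected) / expected, 0.20)
})

test_that("error-free recovery matches the configured proportions to sampling noise", {
  cl <- run_closed_loop(51, 20000, 0)
  props <- cl$sim$config$class_proportions
  want <- c(
    WT = unname(props["WT"]),
    Correct_HDR = unname(props["Correct_HDR"]),
    Incorrect_HDR = unname(props["Incorrect_HDR_substitution"] +
      props["Incorrect_HDR_indel"]),
    Others = unname(props["NHEJ_indel"])
  )
  got <- cl$pip$report$percentages / 100
  for (cls in names(want)) {
    se <- sqrt(want[[cls]] * (1 - want[[cls]]) / 20000)
    expect_lt(abs(got[[cls]] - want[[cls]]), 3 * se)
  }
})

test_that("Correct_HDR attrition under sequencing error follows the closed form", {
  # a correct-HDR read survives classification as Correct_HDR iff no error
  # hits the guide-window pattern and no non-synonymous error hits the
  # covered CDS outside it; both terms are computable exactly from the locus
  e <- 0.002
  cl <- run_closed_loop(41, 20000, e)
  locus <- cl$locus
  patt <- derive_patterns(locus, cl$edit)
  hdr <- locus$amplicon_seq
  for (k in seq_len(nrow(cl$edit$substitutions))) {
    substr(hdr, cl$edit$substitutions$pos[k], cl$edit$substitutions$pos[k]) <-
      cl$edit$substitutions$alt[k]
  }
  gc <- Biostrings::GENETIC_CODE
  surv <- (1 - e)^nchar(patt$wt_pattern)
  for (s in seq(locus$cds[1], locus$cds[2] - 2, by = 3)) {
    for (off in 0:2) {
      p <- s + off
      if (p >= patt$interval[1] && p <= patt$interval[2]) next
      cod <- substr(hdr, s, s + 2)
      aa <- gc[[cod]]
      k_ns <- sum(vapply(setdiff(c("A", "C", "G", "T"), substr(cod, off + 1, off + 1)),
        function(b) {
          alt <- cod
          substr(alt, off + 1, off + 1) <- b
          gc[[alt]] != aa
        }, logical(1)
      ))
      surv <- surv * (1 - e * k_ns / 3)
    }
  }
  truth_correct <- cl$sim$truth$read_id[cl$sim$truth$true_class == "Correct_HDR"]
  calls <- cl$pip$calls
  measured <- mean(calls$category[calls$read_id %in% truth_correct] == "Correct_HDR")
  expect_lt(abs(measured - surv) / surv, 0.20)
})
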