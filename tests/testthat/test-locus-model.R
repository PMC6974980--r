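test_that("reference_locus enforces interval, adjacency and PAM invariants", {
  locus <- make_fixture_locus()
  expect_s3_class(locus, "reference_locus")
  amp <- locus$amplicon_seq

  # PAM not adjacent to the protospacer
  expect_error(
    reference_locus("x", amp,
      cds = c(11, 100), protospacer = c(29, 48),
      pam = c(50, 52), guide_strand = "+"
    ),
    "adjacent"
  )
  # PAM without GG
  bad <- amp
  substr(bad, 50, 51) <- "AT"
  expect_error(
    reference_locus("x", bad,
      cds = c(11, 100), protospacer = c(29, 48),
      pam = c(49, 51), guide_strand = "+"
    ),
    "GG"
  )
  # interval out of bounds
  expect_error(
    reference_locus("x", amp,
      cds = c(11, 200), protospacer = c(29, 48),
      pam = c(49, 51), guide_strand = "+"
    ),
    "bounds"
  )
  # non-DNA characters
  expect_error(
    reference_locus("x", paste0(substr(amp, 1, 109), "X"),
      cds = c(11, 100),
      protospacer = c(29, 48), pam = c(49, 51), guide_strand = "+"
    ),
    "invalid character"
  )
})

test_that("minus-strand guides validate the complementary PAM", {
  # guide on the minus strand: PAM is 5' of the protospacer on the top
  # strand; guide-strand NGG reads as CCN on the top strand
  amp <- paste0("AAAA", "CCT", paste(rep("ACGTT", 4), collapse = ""), "GGGTTTAAA")
  locus <- reference_locus("m", amp,
    cds = c(1, 30), protospacer = c(8, 27),
    pam = c(5, 7), guide_strand = "-"
  )
  expect_s3_class(locus, "reference_locus")
  expect_error(
    reference_locus("m", sub("AAAACCT", "AAAACAT", amp),
      cds = c(1, 30),
      protospacer = c(8, 27), pam = c(5, 7), guide_strand = "-"
    ),
    "GG"
  )
})

test_that("edit_spec validates reference bases, roles and coding-bar synonymy", {
  locus <- make_fixture_locus()
  edit <- make_fixture_edit(locus)
  expect_equal(nrow(edit$substitutions), 3)

  # wrong reference base
  bad <- data.frame(pos = 44, ref = "A", alt = "G", role = "edit")
  expect_error(edit_spec(bad, locus = locus), "mismatch")
  # missing role
  bad <- data.frame(pos = 44, ref = "C", alt = "G", role = "")
  expect_error(edit_spec(bad, locus = locus), "role")
  # a non-synonymous change mislabelled as coding_bar
  bad <- data.frame(pos = 44, ref = "C", alt = "G", role = "coding_bar")
  expect_error(edit_spec(bad, locus = locus), "synonymous")
})

test_that("derive_patterns extracts the guide window and applies the edit", {
  locus <- make_fixture_locus()
  edit <- make_fixture_edit(locus)
  ps <- derive_patterns(locus, edit, flank = 0)

  expect_equal(ps$interval, c(29, 51))
  expect_equal(ps$wt_pattern, substr(locus$amplicon_seq, 29, 51))
  # HDR pattern differs at exactly the three substituted positions
  wt <- strsplit(ps$wt_pattern, "")[[1]]
  hdr <- strsplit(ps$hdr_pattern, "")[[1]]
  expect_equal(which(wt != hdr), sort(edit$substitutions$pos) - 28)
  expect_equal(hdr[edit$substitutions$pos - 28], edit$substitutions$alt)

  # flank extends the window symmetrically, clipped to the amplicon
  ps6 <- derive_patterns(locus, edit, flank = 6)
  expect_equal(ps6$interval, c(23, 57))
  expect_identical(derive_patterns(locus, edit, flank = 6), ps6) # deterministic

  # substitution outside the window is a configuration error naming it
  far <- edit_spec(
    data.frame(pos = 15, ref = substr(locus$amplicon_seq, 15, 15), alt = "A", role = "edit"),
    locus = NULL
  )
  expect_error(derive_patterns(locus, far), "15")
  # no substitutions at all
  empty <- edit_spec(
    data.frame(pos = integer(), ref = character(), alt = character(), role = character())
  )
  expect_error(derive_patterns(locus, empty), "no substitutions")
})

test_that("translate_cds handles strand, frame and partial coverage", {
  # plus strand, frame 0
  loc <- reference_locus("t",
    paste0("AAAA", "ATGGCC", "ACGTACGTACGTACGTACGT", "TGGAAAA"),
    cds = c(5, 10), cds_frame = 0, cds_strand = "+",
    protospacer = c(11, 30), pam = c(31, 33), guide_strand = "+"
  )
  expect_equal(translate_cds(loc)$protein, "MA")

  # minus strand: reverse complement of ATGGCC is GGCCAT -> "GH"
  loc_m <- reference_locus("t", loc$amplicon_seq,
    cds = c(5, 10), cds_frame = 0, cds_strand = "-",
    protospacer = c(11, 30), pam = c(31, 33), guide_strand = "+"
  )
  expect_equal(translate_cds(loc_m)$protein, "GH")

  # frame 1 on a 7-nt window: translation starts at the second base
  loc_f <- reference_locus("t", paste0("AAAT", "GGCC", "ACGTACGTACGTACGTACGT", "TGGAA"),
    cds = c(2, 8), cds_frame = 1, cds_strand = "+",
    protospacer = c(9, 28), pam = c(29, 31), guide_strand = "+"
  )
  # CDS window is "AATGGCC"; frame 1 -> ATG GCC -> "MA"
  expect_equal(translate_cds(loc_f)$protein, "MA")

  # partial coverage: only complete covered codons are translated
  locus <- make_fixture_locus()
  tr <- translate_cds(locus)
  expect_equal(nchar(tr$protein), 30)
  expect_equal(substr(tr$protein, 1, 6), "MAKLDF")
  part <- translate_cds(locus,
    seq = substr(locus$amplicon_seq, 15, 40),
    region = c(15, 40)
  )
  # positions 15..40 cover codons 3 (17..19) through 10 (38..40)
  expect_equal(part$codon_start, 3)
  expect_equal(part$protein, substr(tr$protein, 3, 10))

  # shorter than one codon: empty, flagged
  tiny <- translate_cds(locus, seq = "AT", region = c(12, 13))
  expect_true(tiny$empty)
  expect_equal(tiny$protein, "")
})

test_that("coding-bar substitutions are synonymous by construction", {
  locus <- make_fixture_locus()
  edit <- make_fixture_edit(locus)
  cb <- edit$substitutions[edit$substitutions$role == "coding_bar", ]
  seq <- locus$amplicon_seq
  for (k in seq_len(nrow(cb))) {
    substr(seq, cb$pos[k], cb$pos[k]) <- cb$alt[k]
  }
  expect_equal(translate_cds(locus, seq)$protein, translate_cds(locus)$protein)
})
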