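test_that("lssDNA donor assembly reproduces the printed length arithmetic", {
  ll <- make_long_locus()
  core <- c(ll$locus$protospacer[1], ll$locus$protospacer[1] + 24L) # 25-nt core
  donor <- build_lssdna_donor(ll$locus, ll$edit, arm_len = 137, core = core)

  # (299 - 25) / 2 = 137-nt symmetric arms around a 25-nt core
  expect_equal(nchar(donor$sequence), 299)
  expect_equal(donor$left_arm_len, 137)
  expect_equal(donor$right_arm_len, 137)

  # arms are exact reference copies; core carries the substitutions
  amp <- ll$locus$amplicon_seq
  expect_equal(substr(donor$sequence, 1, 137), substr(amp, core[1] - 137, core[1] - 1))
  expect_equal(
    substr(donor$sequence, 163, 299),
    substr(amp, core[2] + 1, core[2] + 137)
  )
  for (k in seq_len(nrow(ll$edit$substitutions))) {
    p <- ll$edit$substitutions$pos[k] - core[1] + 138L
    expect_equal(substr(donor$sequence, p, p), ll$edit$substitutions$alt[k])
  }

  # length bookkeeping for the default core
  d2 <- build_lssdna_donor(ll$locus, ll$edit, arm_len = 150)
  core2 <- hdrquant:::core_interval(ll$locus, ll$edit)
  expect_equal(nchar(d2$sequence), 300 + core2[2] - core2[1] + 1)

  # antisense donors are the reverse complement of the sense donor
  da <- build_lssdna_donor(ll$locus, ll$edit, arm_len = 137, strand = "antisense", core = core)
  expect_equal(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(da$sequence))),
    donor$sequence
  )

  # arms beyond the reference context are refused with the shortfall
  expect_error(
    build_lssdna_donor(ll$locus, ll$edit, arm_len = 200, core = core),
    "short by"
  )
})

test_that("ssODN arm splitting is symmetric by default and explicit when asymmetric", {
  ll <- make_long_locus()
  core <- c(ll$locus$protospacer[1], ll$locus$protospacer[1] + 24L)

  d <- build_ssodn(ll$locus, ll$edit, total_len = 105, core = core)
  expect_equal(nchar(d$sequence), 105)
  expect_equal(d$left_arm_len, 40) # (105 - 25) / 2
  expect_equal(d$right_arm_len, 40)

  expect_error(
    build_ssodn(ll$locus, ll$edit, total_len = 26, core = core),
    "no room"
  )
  expect_error(
    build_ssodn(ll$locus, ll$edit,
      total_len = 129, symmetry = "asymmetric",
      core = core
    ),
    "asym_split"
  )
  da <- build_ssodn(ll$locus, ll$edit,
    total_len = 129, symmetry = "asymmetric",
    asym_split = c(36, 68), core = core
  )
  expect_equal(nchar(da$sequence), 129)
  expect_equal(c(da$left_arm_len, da$right_arm_len), c(36, 68))
})

test_that("donors align back to the reference recovering exactly the edit", {
  ll <- make_long_locus()
  donor <- build_lssdna_donor(ll$locus, ll$edit, arm_len = 100)
  aln <- global_align(donor$sequence, ll$locus$amplicon_seq)
  subs <- aln$diffs[aln$diffs$type == "substitution", ]
  expect_equal(sort(subs$start), sort(ll$edit$substitutions$pos))
  expect_equal(
    subs$alt[order(subs$start)],
    ll$edit$substitutions$alt[order(ll$edit$substitutions$pos)]
  )
  expect_false(any(aln$diffs$type == "insertion"))
  # deletions only in the padded flanks the donor does not reach (their exact
  # placement can slide within the repetitive pad at equal score); none touch
  # the embedded locus region
  dels <- aln$diffs[aln$diffs$type == "deletion", ]
  pad <- 145L
  locus_region <- c(pad + 1L, pad + 110L)
  expect_true(all(dels$end < locus_region[1] | dels$start > locus_region[2]))
})

test_that("silence_pam picks deterministic minimal synonymous changes", {
  # GG spanning Pro(CCG)/Ala(GCA): wobble CCG -> CCA, G>A at the first G
  pa <- make_pro_ala_locus()
  s <- silence_pam(pa)
  expect_equal(nrow(s), 1)
  expect_equal(s$pos, 26)
  expect_equal(s$ref, "G")
  expect_equal(s$alt, "A")
  # result is synonymous
  seq <- pa$amplicon_seq
  substr(seq, 26, 26) <- "A"
  expect_equal(translate_cds(pa, seq)$protein, translate_cds(pa)$protein)

  # PAM inside a Trp codon, seed outside the CDS: no silent option exists
  expect_error(silence_pam(make_trp_locus()), "no synonymous")

  # non-coding PAM: first G of GG mutated to A
  nc <- silence_pam(make_noncoding_pam_locus())
  expect_equal(nc$pos, 22)
  expect_equal(nc$alt, "A")

  # main fixture: the Gly GGA codon under the PAM has no GG-destroying
  # synonymous alternative, so silencing falls back to the seed region and
  # picks the lexicographically smallest wobble codon (ACA -> ACC)
  locus <- make_fixture_locus()
  sf <- silence_pam(locus, make_fixture_edit(locus))
  expect_equal(nrow(sf), 1)
  expect_equal(sf$pos, 43)
  expect_equal(sf$alt, "C")
  expect_true(sf$pos %in% 37:48) # inside the 12-nt seed
  seq <- locus$amplicon_seq
  substr(seq, sf$pos, sf$pos) <- sf$alt
  expect_equal(translate_cds(locus, seq)$protein, translate_cds(locus)$protein)
})

test_that("design_coding_bar finds the PvuI Coding-bar in the Arg-Ser-Asp window", {
  locus <- make_fixture_locus()
  # intended edit only (codon 12 Pro -> Ala); the Coding-bar is to be designed
  edit0 <- edit_spec(
    data.frame(pos = 44, ref = "C", alt = "G", role = "edit"),
    expected_residue_changes = data.frame(
      codon_index = 12, ref_aa = "P", alt_aa = "A"
    ),
    locus = locus
  )
  enzymes <- load_enzymes()
  cands <- design_coding_bar(locus, edit0, enzymes, window = c(29, 37), max_changes = 2)
  expect_gt(length(cands), 0)

  keys <- coding_bar_candidate_keys(cands)
  # CGC->CGA (31C>A) + TCT->TCG (34T>G) creates CGATCG at position 29
  expect_true("PvuI|29|+|31C>A;34T>G" %in% keys)

  # every candidate is synonymous and de novo
  wt_prot <- translate_cds(locus)$protein
  for (cd in cands) {
    seq <- locus$amplicon_seq
    for (k in seq_len(nrow(cd$substitutions))) {
      substr(seq, cd$substitutions$pos[k], cd$substitutions$pos[k]) <-
        cd$substitutions$alt[k]
    }
    expect_equal(translate_cds(locus, seq)$protein, wt_prot)
  }

  # ordering: fewest changes first, then position, then enzyme name
  n_changes <- vapply(cands, `[[`, integer(1), "n_changes")
  expect_true(!is.unsorted(n_changes))

  # an enzyme whose site pre-exists in the window is never reported
  pre <- restriction_enzyme("PreExisting", substr(locus$amplicon_seq, 30, 35))
  cands_pre <- design_coding_bar(locus, edit0, list(pre), window = c(29, 37))
  expect_length(cands_pre, 0)

  # max_changes 0: only sites created by the edit itself qualify
  cands0 <- design_coding_bar(locus, edit0, enzymes, window = c(29, 37), max_changes = 0)
  expect_true(all(vapply(cands0, `[[`, integer(1), "n_changes") == 0L))

  expect_error(design_coding_bar(locus, edit0, list(), window = c(29, 37)), "empty")
})

test_that("verify_donor passes round-trips and catches planted defects", {
  ll <- make_long_locus()
  donor <- build_lssdna_donor(ll$locus, ll$edit, arm_len = 120)
  rep <- verify_donor(donor, ll$locus, ll$edit)
  expect_true(attr(rep, "all_pass"))
  expect_setequal(
    rep$check,
    c("arm_identity", "substitutions_present", "no_recut", "protein_as_expected")
  )

  # donor with the wild-type core: re-cut target intact, substitutions absent
  wt_donor <- donor
  core_len <- donor$core[2] - donor$core[1] + 1L
  substr(wt_donor$sequence, 121, 120 + core_len) <-
    substr(ll$locus$amplicon_seq, donor$core[1], donor$core[2])
  rep_wt <- verify_donor(wt_donor, ll$locus, ll$edit)
  expect_false(rep_wt$pass[rep_wt$check == "no_recut"])
  expect_false(rep_wt$pass[rep_wt$check == "substitutions_present"])

  # one mutated arm base is caught and located
  bad <- donor
  cur <- substr(bad$sequence, 17, 17)
  substr(bad$sequence, 17, 17) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  rep_bad <- verify_donor(bad, ll$locus, ll$edit)
  row <- rep_bad[rep_bad$check == "arm_identity", ]
  expect_false(row$pass)
  expect_match(row$detail, "17")

  # antisense donors verify identically
  da <- build_lssdna_donor(ll$locus, ll$edit, arm_len = 120, strand = "antisense")
  expect_true(attr(verify_donor(da, ll$locus, ll$edit), "all_pass"))
})
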