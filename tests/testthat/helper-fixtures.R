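# Hand-constructed loci with fully known geometry, used across the suite.

# Main fixture: 110-nt amplicon, CDS 11..100 (30 codons, frame 0, + strand),
# protospacer 29..48, PAM 49..51 (GG at 50-51). The guide window contains an
# Arg-Ser-Asp codon run (codons 7-9) for Coding-bar design and a Pro codon
# (12) carrying the intended non-synonymous edit.
fixture_codons <- c(
  "ATG", "GCC", "AAA", "CTG", "GAT", "TTC", "CGC", "TCT", "GAC", "GTT",
  "ACA", "CCA", "TTG", "GGA", "TGG", "AAT", "GAG", "CTT", "ACC", "GGC",
  "TCA", "ATC", "GTA", "AAG", "CAT", "GGA", "TTT", "CCC", "AGA", "TGT"
)

make_fixture_locus <- function() {
  amp <- paste0("GATTACAGAT", paste(fixture_codons, collapse = ""), "TTGACCTGCA")
  reference_locus(
    gene_name = "fixture",
    amplicon_seq = amp,
    cds = c(11L, 100L), cds_frame = 0L, cds_strand = "+",
    protospacer = c(29L, 48L), pam = c(49L, 51L), guide_strand = "+"
  )
}

# Intended edit: codon 12 CCA -> GCA (Pro -> Ala, position 44) plus two
# synonymous Coding-bar substitutions creating a de novo PvuI site CGATCG:
# codon 7 CGC -> CGA (position 31) and codon 8 TCT -> TCG (position 34).
make_fixture_edit <- function(locus = make_fixture_locus()) {
  subs <- data.frame(
    pos = c(44L, 31L, 34L),
    ref = c("C", "C", "T"),
    alt = c("G", "A", "G"),
    role = c("edit", "coding_bar", "coding_bar"),
    stringsAsFactors = FALSE
  )
  edit_spec(
    subs,
    expected_residue_changes = data.frame(
      codon_index = 12L, ref_aa = "P", alt_aa = "A", stringsAsFactors = FALSE
    ),
    introduced_enzyme = "PvuI",
    locus = locus
  )
}

# PAM whose GG spans a Pro(CCG)/Ala(GCA) codon boundary: silencing must pick
# the wobble CCG -> CCA change.
make_pro_ala_locus <- function() {
  amp <- paste0("ACGT", "ACGTACGTACGTACGTACG", "CCG", "GCA", "TTT", "AAAA")
  reference_locus(
    gene_name = "proala", amplicon_seq = amp,
    cds = c(24L, 32L), cds_frame = 0L, cds_strand = "+",
    protospacer = c(5L, 24L), pam = c(25L, 27L), guide_strand = "+"
  )
}

# PAM fully inside a Trp codon with no coding seed bases: no synonymous
# silencing exists.
make_trp_locus <- function() {
  amp <- paste0("ACGTACGTACGTACGTACGT", "TGG", "ATGTTTA")
  reference_locus(
    gene_name = "trp", amplicon_seq = amp,
    cds = c(21L, 23L), cds_frame = 0L, cds_strand = "+",
    protospacer = c(1L, 20L), pam = c(21L, 23L), guide_strand = "+"
  )
}

# PAM in non-coding sequence: silencing mutates the first G of GG to A.
make_noncoding_pam_locus <- function() {
  amp <- paste0("ACGTACGTACGTACGTACGT", "TGG", "ATGTTTA")
  reference_locus(
    gene_name = "noncoding", amplicon_seq = amp,
    cds = c(24L, 29L), cds_frame = 0L, cds_strand = "+",
    protospacer = c(1L, 20L), pam = c(21L, 23L), guide_strand = "+"
  )
}

# Embed the fixture locus in a longer reference context (for donor arms),
# shifting all coordinates.
make_long_locus <- function(pad = 145L) {
  base <- make_fixture_locus()
  padseq <- paste(rep_len(c("A", "C", "G", "T"), pad), collapse = "")
  locus <- reference_locus(
    gene_name = "fixture_long",
    amplicon_seq = paste0(padseq, base$amplicon_seq, padseq),
    cds = base$cds + pad, cds_frame = 0L, cds_strand = "+",
    protospacer = base$protospacer + pad, pam = base$pam + pad,
    guide_strand = "+"
  )
  edit0 <- make_fixture_edit(base)
  subs <- edit0$substitutions
  subs$pos <- subs$pos + pad
  edit <- edit_spec(subs, edit0$expected_residue_changes,
    introduced_enzyme = edit0$introduced_enzyme, locus = locus
  )
  list(locus = locus, edit = edit)
}

fixture_hdr_amplicon <- function(locus = make_fixture_locus(),
                                 edit = make_fixture_edit(locus)) {
  s <- locus$amplicon_seq
  for (k in seq_len(nrow(edit$substitutions))) {
    substr(s, edit$substitutions$pos[k], edit$substitutions$pos[k]) <-
      edit$substitutions$alt[k]
  }
  s
}

# Full closed-loop run: simulate a locus + reads, then merge/classify.
run_closed_loop <- function(seed, n_reads, per_base_error,
                            class_proportions = NULL, locus_seed = seed) {
  le <- simulate_locus(locus_seed)
  args <- list(seed = seed, n_reads = n_reads, per_base_error = per_base_error)
  if (!is.null(class_proportions)) args$class_proportions <- class_proportions
  cfg <- do.call(simulation_config, args)
  sim <- simulate_reads(le$locus, le$edit, cfg)
  pip <- run_pipeline(
    sim$r1$seq, sim$r2$seq, le$locus, le$edit,
    r1_qual = sim$r1$qual, r2_qual = sim$r2$qual, id = sim$r1$id,
    condition = paste0("seed", seed)
  )
  list(locus = le$locus, edit = le$edit, sim = sim, pip = pip)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
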