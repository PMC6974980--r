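#!/usr/bin/env Rscript

# Donor design study: build the canonical single-stranded donor layouts
# around a simulated knock-in locus, pick a synonymous Coding-bar restriction
# site, silence the PAM, and verify every design against the reference.
# Writes results/donors.fasta and results/coding_bar_candidates.tsv.

suppressMessages(library(hdrquant))
dir.create("results", showWarnings = FALSE)
set.seed(1)

le <- simulate_locus(1, amplicon_len = 450)
locus <- le$locus
edit <- le$edit
core <- c(locus$protospacer[1], locus$protospacer[1] + 24L) # 25-nt core

cat("Locus:", locus$gene_name, "-", nchar(locus$amplicon_seq), "nt amplicon;",
  "guide at", locus$protospacer[1], "-", locus$protospacer[2], "\n")
cat("Edit:", nrow(edit$substitutions), "substitutions,",
  "expected residue change",
  paste0(
    edit$expected_residue_changes$ref_aa, edit$expected_residue_changes$codon_index,
    edit$expected_residue_changes$alt_aa
  ),
  "| Coding-bar enzyme:", edit$introduced_enzyme, "\n\n")

# PAM / seed silencing to protect donor and repaired allele from re-cutting
silenced <- tryCatch(silence_pam(locus, edit), error = function(e) {
  cat("PAM silencing:", conditionMessage(e), "\n")
  NULL
})
if (!is.null(silenced)) {
  cat(
    "PAM/seed silencing substitution:",
    sprintf("%d%s>%s", silenced$pos, silenced$ref, silenced$alt), "\n"
  )
  edit <- edit_spec(
    rbind(edit$substitutions, silenced),
    edit$expected_residue_changes,
    introduced_enzyme = edit$introduced_enzyme, locus = locus
  )
}

donors <- list(
  lssDNA_299 = build_lssdna_donor(locus, edit, arm_len = 137, core = core),
  lssDNA_arm150 = build_lssdna_donor(locus, edit, arm_len = 150, core = core),
  ssODN_105_sym = build_ssodn(locus, edit, total_len = 105, core = core),
  ssODN_129_asym = build_ssodn(locus, edit,
    total_len = 129, symmetry = "asymmetric",
    asym_split = c(36, 68), core = core
  ),
  lssDNA_299_antisense = build_lssdna_donor(locus, edit,
    arm_len = 137, core = core, strand = "antisense"
  )
)

cat("\nDonor designs:\n")
for (nm in names(donors)) {
  d <- donors[[nm]]
  v <- verify_donor(d, locus, edit)
  cat(sprintf(
    "  %-22s %4d nt (arms %d/%d, %s)  verification: %s\n",
    nm, nchar(d$sequence), d$left_arm_len, d$right_arm_len, d$strand,
    if (attr(v, "all_pass")) "PASS" else "FAIL"
  ))
}
write_donor_fasta(donors, "results/donors.fasta")

# Coding-bar candidate table over the protospacer-proximal codons
window <- c(locus$protospacer[1], locus$protospacer[1] + 14L)
subs <- le$edit$substitutions
edit0 <- edit_spec(subs[subs$role == "edit", ],
  le$edit$expected_residue_changes,
  locus = locus
)
cands <- design_coding_bar(locus, edit0, load_enzymes(), window, max_changes = 2)
cat("\n", length(cands), "Coding-bar candidates in the guide window;",
  "best:", cands[[1]]$enzyme, "site at", cands[[1]]$site_position,
  "with", cands[[1]]$n_changes, "synonymous change(s)\n")
write_coding_bar_tsv(cands, "results/coding_bar_candidates.tsv")

cat("\nwrote results/donors.fasta and results/coding_bar_candidates.tsv\n")
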