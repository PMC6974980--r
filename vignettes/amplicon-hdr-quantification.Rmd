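---
title: "Quantifying HDR knock-in outcomes from amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying HDR knock-in outcomes from amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrquant)
```

## The problem

CRISPR/Cas9 knock-ins repair a targeted double-strand break from a supplied
homologous donor (homology-directed repair, HDR). In practice most breaks are
instead resealed by non-homologous end joining (NHEJ), which leaves indels,
and even reads that carry the intended substitutions may carry secondary
damage. Deep sequencing of a short amplicon spanning the cut site is the
standard way to quantify how a donor design performed, but it requires an
explicit, reproducible rule for turning each read into an editing-outcome
call.

hdrquant models the full desk-side loop: describing the locus and the edit,
designing single-stranded donors, merging read pairs, aligning them to the
reference, classifying every read, and genotyping pooled samples by
restriction digestion. A seeded simulator generates reads with known truth so
each stage is testable without any external data.

## Locus model and classifier patterns

A `reference_locus` holds the amplicon sequence, the coding window (with
strand and frame), and the guide annotation: a 20-nt protospacer plus the
3-nt NGG PAM. All coordinates in the package are **1-based closed** intervals
(the R/Bioconductor convention); a single consistent convention is used
everywhere, including the YAML configuration files, to avoid off-by-one
ambiguity.

The classifier operates on the guide-covered window: `derive_patterns()`
extracts the reference sequence of protospacer + PAM (the *WT pattern*) and
the same window with all intended substitutions applied (the *HDR pattern*).
The window can be widened symmetrically with `flank` when assayed
substitutions sit near but outside the protospacer; the default flank is 0,
and whether PAM bases belong in the window is exposed through this
configuration rather than hard-coded, since conventions differ between
laboratories.

## The classification rule cascade

`classify_reads()` applies three rules, strictly in order:

1. **WT** — the WT pattern occurs as an exact substring of the merged read.
   Exactness is at the heart of the method: reads extend well beyond the
   guide window, so substring occurrence (not whole-read equality) is the
   right reading of "exact match".
2. **Correct_HDR / Incorrect_HDR** — otherwise, if the HDR pattern occurs
   exactly, the read is aligned globally to the reference, its CDS is
   reconstructed through the alignment and translated with the standard
   genetic code. If the protein equals the wild type except for exactly the
   expected residue changes, the read is Correct_HDR; additional synonymous
   nucleotide changes are invisible at the protein level and therefore
   tolerated by design. Any other protein difference (including frameshifts
   from secondary indels) gives Incorrect_HDR.
3. **Others** — neither pattern matches: indels through the guide window,
   chimeric or foreign sequence. Reads whose best global identity falls
   below `identity_floor` (default 60%) are flagged "unmapped"; the floor is
   a free parameter because no published threshold exists for this bucket.

Both read orientations are tried; WT takes precedence when both patterns
occur. One deliberate conservatism: if a read matches the HDR pattern but its
alignment does not cover every expected residue change, the read goes to
Others with `protein_check = "not_applicable"` — Incorrect_HDR is never
assigned on missing evidence. With fully overlapping read pairs over a short
amplicon this case is essentially unreachable, but it matters for truncated
inputs.

Percentage denominators are assembled reads only; unmerged pairs are counted
and reported separately, mirroring how retention after assembly is usually
reported.

## Read merging and alignment

`merge_pairs()` re-implements overlap-consensus merging (no external binary):
read 2 is reverse-complemented and slid against read 1; among shifts with
overlap ≥ `min_overlap` (default 10 nt) and mismatch density ≤
`max_mismatch_density` (default 0.25 — the published merger's defaults, since
the study reports none), the longest overlap wins, and each overlap base is
taken from the mate with the higher quality (ties to read 1). Contract
equivalence with the published merger, not bit-equivalence, is the goal.

`global_align()` is an affine-gap Needleman–Wunsch (Gotoh) alignment written
in C++: match +5, mismatch −4, gap open 10, gap extension 0.5 per gap base —
the EMBOSS nucleotide defaults. A gap of length $L$ costs
$10 + 0.5L$. Tie-breaking is deterministic (substitution preferred over
gaps; gap-in-query preferred over gap-in-reference), so diffs are
reproducible run to run. `N` bases always score as mismatches and never count
toward identity. The implementation is checked in the test suite against two
independent oracles: exhaustive enumeration of all alignment paths for short
sequences, and an established S4 alignment library for random pairs.

## Donor design

`build_lssdna_donor()` and `build_ssodn()` assemble
`left arm + edited core + right arm`, where the core is the guide window
extended to contain every substitution (guaranteeing the classifier patterns
lie inside the donor) and arms are exact reference copies. The canonical
layouts — a ~300-nt long ssDNA with symmetric arms and 105/129-nt ssODNs —
fall out of the length arithmetic. The default asymmetric split is 36/68 and
always user-overridable, since only total lengths are conventionally
reported.

`silence_pam()` protects the donor and the repaired allele from re-cutting.
The search is deterministic: among synonymous codon replacements that destroy
the PAM's GG it prefers (1) fewest nucleotide changes, (2) changes confined
to wobble positions, (3) the lexicographically smallest resulting codon. If
no synonymous PAM-breaking change exists (e.g. the GG sits in a tryptophan
codon, which has no synonymous alternative), the same search runs over the
seed region, defined here as the 12 PAM-proximal protospacer bases — a
common convention, adopted because "seed" is rarely defined precisely. In
non-coding context the first G of the GG is mutated to A (arbitrary but
fixed). When neither window admits a silent change the function refuses
rather than silently altering the protein.

`design_coding_bar()` searches combinations of at most `max_changes`
synonymous codon replacements for a *Coding-bar*: a silent sequence barcode
creating a de novo restriction site (IUPAC-aware, both strands) so the
knock-in can be genotyped by digestion. Sites already present in the
unedited reference across the scanned window are excluded, and candidates
are ordered by number of nucleotide changes, then site position, then enzyme
name. The test suite proves the enumeration complete against brute force on
a 9-codon window.

## Restriction genotyping of pools

`digest_seq()` predicts cut positions (site start + top-strand cut offset;
blunt mid-site when an offset is unknown, which shifts fragment sizes by at
most the site length and never flips a positive/negative call) and
`genotype_pool()` models the pooled-embryo screen: a pool is positive when
the fraction of molecules carrying the introduced site reaches
`detection_threshold` (default 0.05, approximating gel sensitivity — the
band-detection floor of an agarose gel is not quantified in the literature,
so it is an explicit parameter). Pools of mosaic embryos are modelled through
the mean of per-embryo edited fractions (`pool_fraction()`), not individual
genotypes.

## The synthetic-data generator

`simulate_reads()` emulates a 250-nt amplicon sequenced as fully overlapping
150-nt read pairs — one published run geometry mentions single-end
200-cycle sequencing while also describing read-pair assembly; the generator
keeps overlapping pairs and notes the discrepancy rather than resolving it.
Molecule classes and their defaults:

* **WT** (0.70) — the reference amplicon;
* **Correct_HDR** (0.12) — all intended substitutions applied;
* **Incorrect_HDR_substitution** (0.02) — HDR plus one extra non-synonymous
  change at a non-wobble CDS position outside the guide window;
* **Incorrect_HDR_indel** (0.04) — HDR plus a 1-2-nt frameshift deletion in
  the CDS just *outside* the guide window. Placing it inside the window
  would destroy the HDR pattern and make the class inexpressible under the
  cascade; incorrect-HDR clones reported in the field indeed carry their
  indels outside the sequenced guide window;
* **NHEJ_indel** (0.12) — an indel centred at the cut site (3 bp 5′ of the
  PAM), deletion with probability 0.7, length drawn from
  {1: .30, 2: .20, 3: .15, 5: .10, 7: .10, 10: .10, 25: .05}; no indel
  spectrum is published for these loci, so a short-dominated spectrum with a
  25-nt tail echoing a known 25-bp founder deletion was fixed once.

Sequencing error is uniform per base (default 0.001) and independent of the
constant written quality (default Phred 35) — realistic position-dependent,
substitution-biased error profiles, PCR chimeras and donor concatemers are
deliberately out of scope. Everything is reproducible from the seed,
byte-identically for the FASTQ output.

`simulate_locus()` draws the amplicon itself: a central CDS spanning most of
the amplicon interior (as for an exon-targeted amplicon), a codon-aligned
protospacer with forced NGG, one non-synonymous edit in the seed codon
nearest the PAM, and a Coding-bar chosen by `design_coding_bar()` and
re-validated against the whole wild-type amplicon.

## What passing tests do and do not show

Because errors are uniform and molecules are drawn i.i.d., closed forms
predict the classifier's behaviour exactly, and the suite verifies them:

* a read whose guide window (length $L$, here 23 nt) is hit by an error
  cannot match either pattern exactly, so WT→Others leakage is
  $1-(1-e)^L$ (≈ 2.3% at $e = 0.001$);
* a Correct_HDR read additionally flips to Incorrect_HDR when a
  non-synonymous error lands in its covered CDS outside the window; the
  survival probability is $(1-e)^L \prod_p (1 - e\,k_p/3)$ with $k_p$ the
  number of amino-acid-changing substitutions at CDS position $p$.

At error 0, recovery of the configured class proportions is exact up to
binomial sampling noise, and per-read calls agree with the simulation truth.
At realistic error rates the attrition above is a property of the *method*
(exact pattern matching plus a protein-level rule), not of the
implementation; analyses of real data inherit it, which is one reason
published correct-HDR percentages should be read as slightly conservative.
None of this says anything about error profiles the generator does not
model, nor about loci whose guide window harbours repeats (where an indel
can slide without breaking the pattern).

## Numerical and design choices

* Problem sizes: recovery and goodness-of-fit studies use 20,000 read pairs
  per seed and ~10-20 seeds; oracle equivalence for the aligner enumerates
  all sequence pairs up to length 6 over a two-letter alphabet.
* Degenerate inputs: empty reads are unmerged with a reason, never an
  exception; a pattern longer than the read classifies as Others; zero
  denominators in fold changes return an undefined flag rather than
  infinity; enzymes that cut the wild-type amplicon make the pooled assay
  error out as uninformative.
* No quality filtering is applied before classification (none is described
  for the method being modelled); an optional Phred floor could be layered
  on the merge step but is off by default.
* The genetic code is the standard table only; translation of ambiguous
  codons yields `X`, which never matches an expected residue.

## Known limitations

* The protein rule condemns reads with any non-synonymous sequencing error
  in the covered CDS; with long coding windows this biases Correct_HDR
  downward by roughly $0.1 e \cdot L_{CDS}$ in relative terms.
* Pools are modelled through a single edited fraction; linkage between
  molecules of one embryo is ignored.
* The simulator plants at most one secondary event per molecule and no
  donor-integration artefacts.
* Indel left-alignment of the aligner's diffs follows the package's fixed
  tie-break, which may differ from other tools' placement in repeat regions
  (the category calls do not depend on placement).
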