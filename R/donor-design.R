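# Donor template construction and verification: long ssDNA donors with
# symmetric homology arms, symmetric/asymmetric ssODNs, silent PAM/seed
# mutations and synonymous Coding-bar restriction sites.

# Minimal donor core for substitution-only edits: the guide-covered window
# extended to contain every substitution, so the classifier patterns are
# guaranteed to lie inside the donor.
#' @noRd
core_interval <- function(locus, edit) {
  lo <- min(locus$protospacer[1], locus$pam[1], edit$substitutions$pos)
  hi <- max(locus$protospacer[2], locus$pam[2], edit$substitutions$pos)
  c(as.integer(lo), as.integer(hi))
}

#' @noRd
new_donor_template <- function(sequence, donor_kind, left_arm_len, right_arm_len,
                               strand, edit, core) {
  structure(
    list(
      sequence = sequence,
      donor_kind = donor_kind,
      left_arm_len = as.integer(left_arm_len),
      right_arm_len = as.integer(right_arm_len),
      strand = strand,
      applied_substitutions = edit$substitutions,
      core = as.integer(core)
    ),
    class = "donor_template"
  )
}

#' @export
print.donor_template <- function(x, ...) {
  cat(sprintf(
    "<donor_template> %s, %d nt (%d/%d nt arms, %s strand), %d substitution(s)\n",
    x$donor_kind, nchar(x$sequence), x$left_arm_len, x$right_arm_len,
    x$strand, nrow(x$applied_substitutions)
  ))
  invisible(x)
}

#' @noRd
assemble_donor <- function(locus, edit, core, left_arm, right_arm, kind, strand) {
  n <- nchar(locus$amplicon_seq)
  if (core[1] - left_arm < 1L || core[2] + right_arm > n) {
    short_l <- max(0L, left_arm - (core[1] - 1L))
    short_r <- max(0L, core[2] + right_arm - n)
    stop(
      "homology arms exceed the available reference context (short by ",
      short_l, " nt left, ", short_r, " nt right)",
      call. = FALSE
    )
  }
  left <- substr(locus$amplicon_seq, core[1] - left_arm, core[1] - 1L)
  right <- substr(locus$amplicon_seq, core[2] + 1L, core[2] + right_arm)
  core_seq <- apply_subs(
    substr(locus$amplicon_seq, core[1], core[2]),
    edit$substitutions,
    offset = core[1] - 1L
  )
  seq <- paste0(left, core_seq, right)
  if (strand == "antisense") seq <- rc(seq)
  new_donor_template(seq, kind, left_arm, right_arm, strand, edit, core)
}

#' Build a long single-stranded DNA donor with symmetric homology arms
#'
#' Assembles `left arm + edited core + right arm`, where the core is the
#' guide-covered window (extended to contain every substitution, or supplied
#' explicitly) with all edit substitutions applied, and each arm is `arm_len`
#' bases of reference sequence. With 150-nt arms this reproduces the
#' ~300-500-nt single-stranded donors used for knock-ins.
#'
#' @inheritParams derive_patterns
#' @param arm_len Homology arm length in nt (>= 1), identical on both sides.
#' @param strand `"sense"` (same strand as the amplicon) or `"antisense"`.
#' @param core Integer `c(start, end)` donor core in amplicon coordinates;
#'   defaults to the minimal window covering protospacer, PAM and all
#'   substitutions.
#'
#' @return A `donor_template`.
#' @export
build_lssdna_donor <- function(locus, edit, arm_len,
                               strand = c("sense", "antisense"),
                               core = core_interval(locus, edit)) {
  strand <- match.arg(strand)
  stopifnot(arm_len >= 1L)
  assemble_donor(locus, edit, core, arm_len, arm_len, "lssDNA", strand)
}

#' Build a single-stranded oligodeoxynucleotide (ssODN) donor
#'
#' Assembles a short single-stranded donor of `total_len` nt around the edited
#' core. Symmetric designs split the remaining length evenly (arms differ by
#' at most 1 nt); asymmetric designs use the supplied `asym_split`.
#'
#' @inheritParams build_lssdna_donor
#' @param total_len Total donor length in nt (>= core length + 2).
#' @param symmetry `"symmetric"` or `"asymmetric"`.
#' @param asym_split Integer `c(left, right)` arm lengths, required when
#'   `symmetry = "asymmetric"`; must sum to `total_len` minus the core length.
#'
#' @return A `donor_template`.
#' @export
build_ssodn <- function(locus, edit, total_len,
                        symmetry = c("symmetric", "asymmetric"),
                        asym_split = NULL,
                        strand = c("sense", "antisense"),
                        core = core_interval(locus, edit)) {
  symmetry <- match.arg(symmetry)
  strand <- match.arg(strand)
  core_len <- core[2] - core[1] + 1L
  if (total_len < core_len + 2L) {
    stop(
      "total_len ", total_len, " leaves no room for homology arms around a ",
      core_len, "-nt core",
      call. = FALSE
    )
  }
  if (symmetry == "symmetric") {
    left <- (total_len - core_len) %/% 2L
    right <- total_len - core_len - left
  } else {
    if (is.null(asym_split)) {
      stop("asym_split = c(left, right) is required for asymmetric ssODNs",
        call. = FALSE
      )
    }
    if (sum(asym_split) != total_len - core_len) {
      stop("asym_split must sum to total_len - core length (",
        total_len - core_len, ")",
        call. = FALSE
      )
    }
    left <- asym_split[1]
    right <- asym_split[2]
  }
  assemble_donor(locus, edit, core, left, right, "ssODN", strand)
}

#' Find a minimal silent substitution that prevents donor re-cutting
#'
#' Cas9 re-cuts a repaired allele (and the donor itself) whenever the
#' protospacer + NGG PAM survive the edit. This picks the minimal
#' substitution set that destroys the PAM's GG (or, failing that, a seed-region
#' base: the 12 PAM-proximal protospacer bases) while leaving the encoded
#' protein unchanged when the affected bases are coding. The choice is
#' deterministic: fewest nucleotide changes first, then changes confined to
#' wobble (third codon) positions, then the lexicographically smallest
#' resulting codon. Outside coding sequence the first G of the GG dinucleotide
#' is mutated to A.
#'
#' @inheritParams derive_patterns
#' @return A substitutions data.frame (`pos`, `ref`, `alt`,
#'   `role = "pam_silencing"`), ready to merge into an [edit_spec()].
#' @export
silence_pam <- function(locus, edit = NULL) {
  # top-strand positions of the PAM's GG (guide orientation positions 2-3)
  if (locus$guide_strand == "+") {
    gg_pos <- c(locus$pam[1] + 1L, locus$pam[1] + 2L)
  } else {
    gg_pos <- c(locus$pam[1] + 1L, locus$pam[1]) # guide pos 2 then 3
  }
  taken <- if (is.null(edit)) integer() else edit$substitutions$pos
  in_cds <- vapply(gg_pos, function(p) !is.null(codon_info(locus, p)), logical(1))

  if (!any(in_cds)) {
    # non-coding context: first G of GG (guide orientation) -> A
    p <- gg_pos[1]
    ref <- substr(locus$amplicon_seq, p, p)
    alt <- if (ref == "G") "A" else "T" # complement of G -> A on top strand
    return(substitution_frame(p, ref, alt, "pam_silencing"))
  }

  pam_destroyed <- function(seq) {
    g <- substring(seq, gg_pos, gg_pos)
    if (locus$guide_strand == "+") any(g != "G") else any(g != "C")
  }
  candidates_for <- function(positions, need_destroy_pam) {
    out <- list()
    infos <- unique(Filter(Negate(is.null), lapply(positions, codon_info, locus = locus)))
    infos <- infos[!duplicated(vapply(infos, function(x) x$top_span[1], integer(1)))]
    for (info in infos) {
      for (alt_codon in syn_codons(info$codon)) {
        subs <- codon_replacement_subs(locus, info, alt_codon, "pam_silencing")
        if (nrow(subs) == 0L || any(subs$pos %in% taken)) next
        if (need_destroy_pam) {
          if (!pam_destroyed(apply_subs(locus$amplicon_seq, subs))) next
        } else {
          if (!any(subs$pos %in% positions)) next
        }
        wobble <- all(vapply(subs$pos, function(p) {
          ci <- codon_info(locus, p)
          !is.null(ci) && ci$pos_in_codon == 3L
        }, logical(1)))
        out[[length(out) + 1L]] <- list(
          subs = subs, n = nrow(subs), wobble = wobble, codon = alt_codon
        )
      }
    }
    if (!length(out)) {
      return(NULL)
    }
    ord <- order(
      vapply(out, `[[`, integer(1), "n"),
      !vapply(out, `[[`, logical(1), "wobble"),
      vapply(out, `[[`, character(1), "codon")
    )
    out[[ord[1]]]$subs
  }

  hit <- candidates_for(gg_pos, need_destroy_pam = TRUE)
  if (!is.null(hit)) {
    return(hit)
  }
  # seed fallback: 12 PAM-proximal protospacer bases
  seed <- if (locus$guide_strand == "+") {
    (locus$protospacer[2] - 11L):locus$protospacer[2]
  } else {
    locus$protospacer[1]:(locus$protospacer[1] + 11L)
  }
  hit <- candidates_for(seed, need_destroy_pam = FALSE)
  if (!is.null(hit)) {
    return(hit)
  }
  stop(
    "no synonymous substitution can break the PAM or a seed base at this ",
    "locus (e.g. PAM inside a Trp codon); the donor will remain re-cuttable",
    call. = FALSE
  )
}

#' Design synonymous Coding-bar restriction sites
#'
#' Searches for combinations of at most `max_changes` synonymous codon
#' substitutions inside `window` that create a de novo restriction site
#' (IUPAC-aware, both strands) for one of the supplied enzymes — a
#' "Coding-bar": a silent sequence barcode that makes the knock-in genotypable
#' by digestion without altering the protein. Sites already matching the
#' unedited reference in the scanned window are excluded. The intended edit
#' substitutions are applied before scanning, so with `max_changes = 0` only
#' sites created by the edit itself qualify.
#'
#' @inheritParams derive_patterns
#' @param enzymes List of [restriction_enzyme()] objects (non-empty).
#' @param window Integer `c(start, end)` within the CDS to place synonymous
#'   changes in.
#' @param max_changes Maximum number of codons substituted (each to a
#'   synonymous alternative).
#'
#' @return A list of candidates (class `coding_bar_candidates`), each with
#'   `substitutions` (data.frame, role `"coding_bar"`), `enzyme`,
#'   `site_position`, `strand` and `n_changes` (nucleotide changes), sorted by
#'   `n_changes`, then site position, then enzyme name.
#' @export
design_coding_bar <- function(locus, edit, enzymes, window, max_changes = 2L) {
  if (length(enzymes) == 0L) stop("empty enzyme list", call. = FALSE)
  window <- as.integer(window)
  if (window[1] < locus$cds[1] || window[2] > locus$cds[2]) {
    stop("window must lie within the CDS", call. = FALSE)
  }
  base_seq <- apply_subs(locus$amplicon_seq, edit$substitutions)
  taken <- edit$substitutions$pos

  # complete reading-frame codons whose top-strand span lies inside `window`
  infos <- list()
  p <- window[1]
  while (p <= window[2]) {
    ci <- codon_info(locus, p)
    if (!is.null(ci) && ci$top_span[1] >= window[1] && ci$top_span[2] <= window[2] &&
      !any(ci$top_span[1]:ci$top_span[2] %in% taken)) {
      key <- as.character(ci$top_span[1])
      if (is.null(infos[[key]])) infos[[key]] <- ci
    }
    p <- p + 1L
  }
  infos <- infos[order(as.integer(names(infos)))]

  # per-codon synonymous replacement substitution sets (relative to base_seq,
  # whose bases at these codons equal the reference since edits are excluded)
  per_codon <- lapply(infos, function(ci) {
    # current codon in the edited base sequence (may differ from reference
    # only through edits, which are excluded above)
    alts <- syn_codons(ci$codon)
    lapply(alts, function(ac) codon_replacement_subs(locus, ci, ac, "coding_bar"))
  })
  per_codon <- lapply(per_codon, function(l) Filter(function(s) nrow(s) > 0L, l))

  site_len_max <- max(vapply(enzymes, function(e) nchar(e$recognition), integer(1)))
  scan_lo <- max(1L, window[1] - site_len_max + 1L)
  scan_hi <- min(nchar(locus$amplicon_seq), window[2] + site_len_max - 1L)
  wt_scan <- substr(locus$amplicon_seq, scan_lo, scan_hi)

  # enumerate subsets of <= max_changes codons x synonymous alternatives
  combos <- list(substitution_frame()) # zero-change combination
  idx <- seq_along(per_codon)
  if (max_changes >= 1L) {
    for (i in idx) {
      for (s in per_codon[[i]]) combos[[length(combos) + 1L]] <- s
    }
  }
  if (max_changes >= 2L && length(idx) >= 2L) {
    for (i in idx[-length(idx)]) {
      for (j in idx[idx > i]) {
        for (si in per_codon[[i]]) {
          for (sj in per_codon[[j]]) {
            combos[[length(combos) + 1L]] <- rbind(si, sj)
          }
        }
      }
    }
  }
  if (max_changes > 2L) {
    stop("max_changes > 2 not supported", call. = FALSE)
  }

  edited_scans <- vapply(combos, function(s) {
    substr(apply_subs(base_seq, s), scan_lo, scan_hi)
  }, character(1))

  out <- list()
  for (enz in enzymes) {
    pats <- list(c(enz$recognition, "+"))
    rcpat <- rc(enz$recognition)
    if (rcpat != enz$recognition) pats <- c(pats, list(c(rcpat, "-")))
    for (ps in pats) {
      if (length(scan_site_starts(wt_scan, ps[1])[[1]]) > 0L) next # not de novo
      hits <- scan_site_starts(edited_scans, ps[1])
      for (k in seq_along(combos)) {
        for (h in hits[[k]]) {
          out[[length(out) + 1L]] <- list(
            substitutions = combos[[k]],
            enzyme = enz$name,
            site_position = scan_lo + h - 1L,
            strand = ps[2],
            n_changes = nrow(combos[[k]])
          )
        }
      }
    }
  }
  if (length(out)) {
    key <- vapply(out, function(cd) {
      paste(cd$enzyme, cd$site_position, cd$strand,
        paste(cd$substitutions$pos, cd$substitutions$alt, collapse = ";"),
        sep = "|"
      )
    }, character(1))
    out <- out[!duplicated(key)]
    ord <- order(
      vapply(out, `[[`, integer(1), "n_changes"),
      vapply(out, `[[`, integer(1), "site_position"),
      vapply(out, `[[`, character(1), "enzyme")
    )
    out <- out[ord]
  }
  structure(out, class = "coding_bar_candidates")
}

#' @export
print.coding_bar_candidates <- function(x, ...) {
  cat(sprintf("<coding_bar_candidates> %d candidate(s)\n", length(x)))
  for (cd in head(x, 10)) {
    cat(sprintf(
      "  %s site at %d (%s), %d nt change(s): %s\n",
      cd$enzyme, cd$site_position, cd$strand, cd$n_changes,
      paste(sprintf("%d%s>%s", cd$substitutions$pos, cd$substitutions$ref,
        cd$substitutions$alt
      ), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Verify a donor template against its locus and edit specification
#'
#' Checks that (1) the homology arms match the reference flanks exactly,
#' (2) every intended substitution is present in the donor core, (3) the
#' intact guide target (protospacer + PAM as in the reference) is absent from
#' the donor on both strands, so neither the donor nor the repaired allele is
#' re-cut, and (4) the edited CDS translates to the wild-type protein except
#' for exactly the expected residue changes.
#'
#' @param donor A `donor_template`.
#' @inheritParams derive_patterns
#' @return A data.frame (class `donor_verification`) with columns `check`,
#'   `pass`, `detail`; attribute `all_pass`.
#' @export
verify_donor <- function(donor, locus, edit) {
  seq <- donor$sequence
  if (donor$strand == "antisense") seq <- rc(seq)
  core <- donor$core
  la <- donor$left_arm_len
  ra <- donor$right_arm_len
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE
    )
  }

  exp_left <- substr(locus$amplicon_seq, core[1] - la, core[1] - 1L)
  exp_right <- substr(locus$amplicon_seq, core[2] + 1L, core[2] + ra)
  got_left <- substr(seq, 1L, la)
  got_right <- substr(seq, nchar(seq) - ra + 1L, nchar(seq))
  mism <- function(a, b) which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  ok_l <- identical(got_left, exp_left)
  ok_r <- identical(got_right, exp_right)
  add(
    "arm_identity", ok_l && ok_r,
    if (ok_l && ok_r) {
      ""
    } else if (!ok_l) {
      paste0("left arm mismatch at arm position(s) ", paste(mism(got_left, exp_left), collapse = ","))
    } else {
      paste0("right arm mismatch at arm position(s) ", paste(mism(got_right, exp_right), collapse = ","))
    }
  )

  core_seq <- substr(seq, la + 1L, la + (core[2] - core[1] + 1L))
  subs <- edit$substitutions
  present <- substring(core_seq, subs$pos - core[1] + 1L, subs$pos - core[1] + 1L) == subs$alt
  add(
    "substitutions_present", all(present),
    if (all(present)) "" else paste0("missing at ", paste(subs$pos[!present], collapse = ","))
  )

  target <- substr(
    locus$amplicon_seq,
    min(locus$protospacer[1], locus$pam[1]),
    max(locus$protospacer[2], locus$pam[2])
  )
  recut <- grepl(target, seq, fixed = TRUE) || grepl(rc(target), seq, fixed = TRUE)
  add("no_recut", !recut, if (recut) "intact protospacer+PAM present in donor" else "")

  wt_prot <- translate_cds(locus)$protein
  ed_prot <- translate_cds(locus, apply_subs(locus$amplicon_seq, subs))$protein
  diffs <- which(strsplit(wt_prot, "")[[1]] != strsplit(ed_prot, "")[[1]])
  exp <- edit$expected_residue_changes
  ok_prot <- identical(sort(diffs), sort(as.integer(exp$codon_index))) &&
    all(substring(ed_prot, exp$codon_index, exp$codon_index) == exp$alt_aa)
  add(
    "protein_as_expected", ok_prot,
    if (ok_prot) "" else paste0("residue changes at codon(s) ", paste(diffs, collapse = ","))
  )

  res <- do.call(rbind, checks)
  class(res) <- c("donor_verification", class(res))
  attr(res, "all_pass") <- all(res$pass)
  res
}
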