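# Reference locus, edit specification and derived classifier patterns.

#' Describe a reference amplicon locus
#'
#' A reference locus bundles everything the pipeline needs to know about one
#' targeted amplicon: the sequence itself, the coding window and reading
#' frame, and the guide RNA (protospacer + PAM) annotation. All intervals are
#' 1-based closed coordinates within the amplicon.
#'
#' @param gene_name Gene label used in reports.
#' @param amplicon_seq Upper-case A/C/G/T amplicon sequence.
#' @param cds Integer vector `c(start, end)`: coding window within the
#'   amplicon.
#' @param cds_frame Offset (0-2) of the first complete codon within `cds`,
#'   counted in the reading direction.
#' @param cds_strand `"+"` or `"-"`: strand of the coding sequence relative to
#'   the amplicon.
#' @param protospacer Integer vector `c(start, end)` of the 20-nt protospacer.
#' @param pam Integer vector `c(start, end)` of the 3-nt NGG PAM, adjacent to
#'   the protospacer 3' end on `guide_strand`.
#' @param guide_strand `"+"` or `"-"`: strand the guide RNA matches.
#'
#' @return An object of class `reference_locus`.
#' @examples
#' amp <- paste0(
#'   strrep("ACGT", 10),
#'   "ATGGCCAAACTGGATCGATACGTGAAGCTTTGGCCTAAGGACGTC",
#'   strrep("TGCA", 10)
#' )
#' # toy locus: CDS 41..85, guide covering positions 51..70 with PAM 71..73
#' @export
reference_locus <- function(gene_name, amplicon_seq, cds, cds_frame = 0L,
                            cds_strand = c("+", "-"), protospacer, pam,
                            guide_strand = c("+", "-")) {
  cds_strand <- match.arg(cds_strand)
  guide_strand <- match.arg(guide_strand)
  amplicon_seq <- toupper(amplicon_seq)
  locus <- structure(
    list(
      gene_name = as.character(gene_name),
      amplicon_seq = amplicon_seq,
      cds = as.integer(cds),
      cds_frame = as.integer(cds_frame),
      cds_strand = cds_strand,
      protospacer = as.integer(protospacer),
      pam = as.integer(pam),
      guide_strand = guide_strand
    ),
    class = "reference_locus"
  )
  validate_reference_locus(locus)
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(
    sprintf(
      "<reference_locus> %s: %d nt amplicon, CDS [%d,%d] (%s, frame %d), guide [%d,%d]%s/PAM [%d,%d]\n",
      x$gene_name, nchar(x$amplicon_seq), x$cds[1], x$cds[2], x$cds_strand,
      x$cds_frame, x$protospacer[1], x$protospacer[2], x$guide_strand,
      x$pam[1], x$pam[2]
    )
  )
  invisible(x)
}

#' @noRd
validate_reference_locus <- function(locus) {
  check_dna(locus$amplicon_seq, "amplicon_seq")
  n <- nchar(locus$amplicon_seq)
  ivs <- list(cds = locus$cds, protospacer = locus$protospacer, pam = locus$pam)
  for (nm in names(ivs)) {
    iv <- ivs[[nm]]
    if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 1L || iv[2] > n) {
      stop(nm, " interval [", paste(iv, collapse = ","),
        "] out of amplicon bounds [1,", n, "]",
        call. = FALSE
      )
    }
  }
  if (diff(locus$protospacer) + 1L != 20L) {
    stop("protospacer must be 20 nt", call. = FALSE)
  }
  if (diff(locus$pam) + 1L != 3L) {
    stop("PAM must be 3 nt", call. = FALSE)
  }
  if (!locus$cds_frame %in% 0:2) {
    stop("cds_frame must be 0, 1 or 2", call. = FALSE)
  }
  if (locus$guide_strand == "+") {
    if (locus$pam[1] != locus$protospacer[2] + 1L) {
      stop("PAM must be adjacent to the protospacer 3' end", call. = FALSE)
    }
    gg <- substr(locus$amplicon_seq, locus$pam[1] + 1L, locus$pam[1] + 2L)
    if (gg != "GG") stop("PAM positions 2-3 must be GG (found ", gg, ")", call. = FALSE)
  } else {
    if (locus$pam[2] != locus$protospacer[1] - 1L) {
      stop("PAM must be adjacent to the protospacer 3' end", call. = FALSE)
    }
    # guide-strand GG at PAM positions 2-3 is CC on the amplicon top strand
    cc <- substr(locus$amplicon_seq, locus$pam[1], locus$pam[1] + 1L)
    if (cc != "CC") stop("PAM positions 2-3 must be GG on the guide strand", call. = FALSE)
  }
  locus
}

# Blunt Cas9 cut site: the cut falls after this top-strand position
# (3 bp 5' of the PAM on the guide strand).
#' @noRd
cut_site <- function(locus) {
  if (locus$guide_strand == "+") {
    locus$protospacer[2] - 3L
  } else {
    locus$protospacer[1] + 2L
  }
}

#' Specify an intended edit
#'
#' An edit specification lists the point substitutions a donor introduces,
#' the protein-level change they are expected to cause, and the role of each
#' substitution: `"edit"` (the intended, possibly non-synonymous change),
#' `"coding_bar"` (synonymous changes creating a de novo restriction site for
#' genotyping) and/or `"pam_silencing"` (changes that destroy the PAM or seed
#' so the donor and the repaired allele are not re-cut). Roles may be combined
#' with commas.
#'
#' @param substitutions data.frame with columns `pos` (amplicon coordinate),
#'   `ref`, `alt` (single bases) and `role`.
#' @param expected_residue_changes data.frame with columns `codon_index`
#'   (1-based within the CDS reading frame), `ref_aa`, `alt_aa`; may be empty
#'   for pure restriction-site knock-ins.
#' @param introduced_enzyme Optional name of the restriction enzyme whose site
#'   the edit introduces.
#' @param locus Optional [reference_locus()]; when given, the specification is
#'   validated against it (reference bases match; coding-bar substitutions
#'   alone leave the protein unchanged).
#'
#' @return An object of class `edit_spec`.
#' @export
edit_spec <- function(substitutions,
                      expected_residue_changes = NULL,
                      introduced_enzyme = NULL,
                      locus = NULL) {
  stopifnot(is.data.frame(substitutions))
  need <- c("pos", "ref", "alt", "role")
  miss <- setdiff(need, names(substitutions))
  if (length(miss)) stop("substitutions lacks column(s): ", paste(miss, collapse = ", "))
  substitutions$pos <- as.integer(substitutions$pos)
  if (anyDuplicated(substitutions$pos)) {
    stop("duplicate substitution positions", call. = FALSE)
  }
  known <- c("edit", "coding_bar", "pam_silencing")
  roles <- strsplit(substitutions$role, ",[ ]*")
  if (any(lengths(roles) == 0L) || !all(unlist(roles) %in% known)) {
    stop(
      "every substitution needs >= 1 role tag from {",
      paste(known, collapse = ", "), "}",
      call. = FALSE
    )
  }
  if (is.null(expected_residue_changes)) {
    expected_residue_changes <- data.frame(
      codon_index = integer(), ref_aa = character(), alt_aa = character(),
      stringsAsFactors = FALSE
    )
  }
  substitutions <- substitutions[order(substitutions$pos), , drop = FALSE]
  rownames(substitutions) <- NULL
  edit <- structure(
    list(
      substitutions = substitutions,
      expected_residue_changes = expected_residue_changes,
      introduced_enzyme = introduced_enzyme
    ),
    class = "edit_spec"
  )
  if (!is.null(locus)) validate_edit_spec(edit, locus)
  edit
}

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf(
    "<edit_spec> %d substitution(s), %d expected residue change(s)%s\n",
    nrow(x$substitutions), nrow(x$expected_residue_changes),
    if (is.null(x$introduced_enzyme)) "" else paste0(", enzyme ", x$introduced_enzyme)
  ))
  invisible(x)
}

#' @noRd
edit_subs_with_role <- function(edit, role) {
  keep <- vapply(
    strsplit(edit$substitutions$role, ",[ ]*"),
    function(r) role %in% r, logical(1)
  )
  edit$substitutions[keep, , drop = FALSE]
}

#' Validate an edit specification against a locus
#'
#' Checks that every substitution's reference base matches the amplicon and
#' that the coding-bar substitutions, applied alone, leave the translated CDS
#' unchanged (synonymy).
#'
#' @inheritParams edit_spec
#' @param edit An [edit_spec()].
#' @return `edit`, invisibly, or an error.
#' @export
validate_edit_spec <- function(edit, locus) {
  subs <- edit$substitutions
  found <- substring(locus$amplicon_seq, subs$pos, subs$pos)
  bad <- which(found != subs$ref)
  if (length(bad)) {
    stop(
      "substitution ref base mismatch at position ", subs$pos[bad[1]],
      ": spec says ", subs$ref[bad[1]], ", amplicon has ", found[bad[1]],
      call. = FALSE
    )
  }
  cb <- edit_subs_with_role(edit, "coding_bar")
  if (nrow(cb)) {
    wt_prot <- translate_cds(locus)$protein
    cb_prot <- translate_cds(locus, apply_subs(locus$amplicon_seq, cb))$protein
    if (wt_prot != cb_prot) {
      stop("coding_bar substitutions are not synonymous", call. = FALSE)
    }
  }
  invisible(edit)
}

#' Derive the WT and HDR classifier patterns
#'
#' The classifier works on the guide-covered window of the amplicon: the
#' reference sequence of that window is the WT pattern and the same window
#' with all intended substitutions applied is the HDR pattern. The window is
#' the protospacer plus PAM, optionally extended by `flank` bases on each side
#' (clipped to the amplicon) so that edits near but outside the protospacer
#' can be assayed.
#'
#' @inheritParams validate_edit_spec
#' @param flank Non-negative number of bases to extend the window by on each
#'   side.
#'
#' @return An object of class `pattern_set` with elements `wt_pattern`,
#'   `hdr_pattern` and `interval` (amplicon coordinates, + orientation).
#' @export
derive_patterns <- function(locus, edit, flank = 0L) {
  stopifnot(flank >= 0L)
  lo <- max(1L, min(locus$protospacer[1], locus$pam[1]) - as.integer(flank))
  hi <- min(
    nchar(locus$amplicon_seq),
    max(locus$protospacer[2], locus$pam[2]) + as.integer(flank)
  )
  subs <- edit$substitutions
  outside <- subs$pos < lo | subs$pos > hi
  if (any(outside)) {
    stop(
      "substitution(s) at position(s) ",
      paste(subs$pos[outside], collapse = ", "),
      " fall outside the pattern interval [", lo, ",", hi,
      "]; increase `flank`",
      call. = FALSE
    )
  }
  if (nrow(subs) == 0L) {
    stop("edit has no substitutions inside the pattern interval", call. = FALSE)
  }
  wt <- substr(locus$amplicon_seq, lo, hi)
  hdr <- apply_subs(wt, subs, offset = lo - 1L)
  stopifnot(wt != hdr)
  structure(
    list(wt_pattern = wt, hdr_pattern = hdr, interval = c(lo, hi)),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf(
    "<pattern_set> interval [%d,%d]\n  WT : %s\n  HDR: %s\n",
    x$interval[1], x$interval[2], x$wt_pattern, x$hdr_pattern
  ))
  invisible(x)
}

#' Translate the coding window of a locus
#'
#' Translates the in-frame codons of the CDS (or of the part of it covered by
#' `region`) with the standard genetic code, honouring `cds_strand` and
#' `cds_frame`. Incomplete terminal codons are dropped.
#'
#' @inheritParams validate_edit_spec
#' @param seq Ungapped DNA string covering `region` in amplicon coordinates;
#'   defaults to the reference amplicon itself.
#' @param region Integer `c(start, end)`: the amplicon interval `seq` covers.
#'
#' @return A list with `protein` (amino-acid string, `""` and `empty = TRUE`
#'   if less than one complete codon is covered), `codon_start` (1-based index
#'   of the first translated codon within the CDS reading frame) and `empty`.
#' @export
translate_cds <- function(locus, seq = locus$amplicon_seq,
                          region = c(1L, nchar(locus$amplicon_seq))) {
  region <- as.integer(region)
  if (nchar(seq) != region[2] - region[1] + 1L) {
    stop("`seq` length does not match `region`", call. = FALSE)
  }
  a <- max(region[1], locus$cds[1])
  b <- min(region[2], locus$cds[2])
  empty <- list(protein = "", codon_start = NA_integer_, empty = TRUE)
  if (b < a) {
    return(empty)
  }
  if (locus$cds_strand == "+") {
    first <- locus$cds[1] + locus$cds_frame
    i1 <- max(1L, as.integer(ceiling((a - first) / 3)) + 1L)
    i2 <- as.integer(floor((b - first + 1) / 3))
    if (i2 < i1) {
      return(empty)
    }
    s <- first + 3L * (i1 - 1L)
    e <- first + 3L * i2 - 1L
    dna <- substr(seq, s - region[1] + 1L, e - region[1] + 1L)
    list(protein = translate_str(dna), codon_start = i1, empty = FALSE)
  } else {
    anchor <- locus$cds[2] - locus$cds_frame
    # codon i occupies top-strand positions [anchor - 3i + 1, anchor - 3(i-1)]
    i1 <- max(1L, as.integer(ceiling((anchor - b) / 3)) + 1L)
    i2 <- as.integer(floor((anchor - a + 1) / 3))
    if (i2 < i1) {
      return(empty)
    }
    s <- anchor - 3L * i2 + 1L
    e <- anchor - 3L * (i1 - 1L)
    dna <- substr(seq, s - region[1] + 1L, e - region[1] + 1L)
    list(protein = translate_str(rc(dna)), codon_start = i1, empty = FALSE)
  }
}

# Codon geometry helper: reading-frame codon containing top-strand position
# `pos`, or NULL if `pos` is outside a complete codon. `top_span` is the
# top-strand interval; `codon` is read in the coding direction; `pos_in_codon`
# is the 1-based offset of `pos` within the codon in the coding direction.
#' @noRd
codon_info <- function(locus, pos) {
  if (pos < locus$cds[1] || pos > locus$cds[2]) {
    return(NULL)
  }
  if (locus$cds_strand == "+") {
    first <- locus$cds[1] + locus$cds_frame
    i <- as.integer(floor((pos - first) / 3)) + 1L
    s <- first + 3L * (i - 1L)
    e <- s + 2L
    if (i < 1L || e > locus$cds[2]) {
      return(NULL)
    }
    codon <- substr(locus$amplicon_seq, s, e)
    list(index = i, top_span = c(s, e), codon = codon, pos_in_codon = pos - s + 1L)
  } else {
    anchor <- locus$cds[2] - locus$cds_frame
    i <- as.integer(floor((anchor - pos) / 3)) + 1L
    e <- anchor - 3L * (i - 1L)
    s <- e - 2L
    if (i < 1L || s < locus$cds[1]) {
      return(NULL)
    }
    codon <- rc(substr(locus$amplicon_seq, s, e))
    list(index = i, top_span = c(s, e), codon = codon, pos_in_codon = e - pos + 1L)
  }
}

# Top-strand substitutions needed to replace the codon at `info` with
# `new_codon` (given in coding orientation).
#' @noRd
codon_replacement_subs <- function(locus, info, new_codon, role) {
  top_new <- if (locus$cds_strand == "+") new_codon else rc(new_codon)
  top_old <- substr(locus$amplicon_seq, info$top_span[1], info$top_span[2])
  pos <- info$top_span[1]:info$top_span[2]
  old_b <- strsplit(top_old, "")[[1]]
  new_b <- strsplit(top_new, "")[[1]]
  keep <- old_b != new_b
  substitution_frame(pos[keep], old_b[keep], new_b[keep], rep(role, sum(keep)))
}
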