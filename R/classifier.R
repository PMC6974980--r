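# Rule-based categorisation of merged amplicon reads into
# WT / Correct_HDR / Incorrect_HDR / Others, and per-condition summaries.

CATEGORY_LEVELS <- c("WT", "Correct_HDR", "Incorrect_HDR", "Others")

# Reconstruct the read's version of the CDS from a gapped alignment: the
# query bases aligned to reference CDS positions, keeping insertions anchored
# inside the CDS and dropping deleted positions. Returns the reconstructed
# sequence (top-strand orientation) and the covered reference interval.
#' @noRd
reconstruct_cds <- function(aligned_ref, aligned_query, locus) {
  r <- strsplit(aligned_ref, "")[[1]]
  q <- strsplit(aligned_query, "")[[1]]
  ref_pos <- cumsum(r != "-")
  qcov <- which(q != "-")
  if (!length(qcov)) {
    return(list(seq = "", cover = c(NA_integer_, NA_integer_)))
  }
  a <- max(1L, ref_pos[qcov[1]])
  b <- ref_pos[qcov[length(qcov)]]
  a <- max(a, locus$cds[1])
  b <- min(b, locus$cds[2])
  if (b < a) {
    return(list(seq = "", cover = c(NA_integer_, NA_integer_)))
  }
  # anchor of every column: its reference position (insertions inherit the
  # position of the preceding reference base)
  in_cds_ref <- r != "-" & ref_pos >= a & ref_pos <= b
  ins_in_cds <- r == "-" & ref_pos >= a & ref_pos < b
  keep <- (in_cds_ref | ins_in_cds) & q != "-"
  list(seq = paste(q[keep], collapse = ""), cover = c(a, b))
}

# Protein-level check for reads carrying the HDR pattern: translate the
# read's CDS (covered window) and require equality with the wild-type protein
# except for exactly the expected residue changes. Extra synonymous
# nucleotide changes are invisible at this level and therefore allowed.
#' @noRd
protein_check <- function(aligned_ref, aligned_query, locus, edit, wt_translation) {
  rec <- reconstruct_cds(aligned_ref, aligned_query, locus)
  if (is.na(rec$cover[1])) {
    return("not_applicable")
  }
  a <- rec$cover[1]
  b <- rec$cover[2]
  # codon range fully covered by [a, b]
  if (locus$cds_strand == "+") {
    first <- locus$cds[1] + locus$cds_frame
    i1 <- max(1L, as.integer(ceiling((a - first) / 3)) + 1L)
    i2 <- as.integer(floor((b - first + 1) / 3))
    grid_start <- first + 3L * (i1 - 1L)
    grid_end <- first + 3L * i2 - 1L
  } else {
    anchor <- locus$cds[2] - locus$cds_frame
    i1 <- max(1L, as.integer(ceiling((anchor - b) / 3)) + 1L)
    i2 <- as.integer(floor((anchor - a + 1) / 3))
    grid_start <- anchor - 3L * i2 + 1L
    grid_end <- anchor - 3L * (i1 - 1L)
  }
  if (i2 < i1) {
    return("not_applicable")
  }
  exp <- locus_expected_in_range(edit, i1, i2)
  if (is.null(exp)) {
    return("not_applicable")
  } # an expected change is outside the evidence

  # trim the reconstructed sequence to the codon grid using column anchors
  r <- strsplit(aligned_ref, "")[[1]]
  q <- strsplit(aligned_query, "")[[1]]
  ref_pos <- cumsum(r != "-")
  in_grid_ref <- r != "-" & ref_pos >= grid_start & ref_pos <= grid_end
  ins_in_grid <- r == "-" & ref_pos >= grid_start & ref_pos < grid_end
  keep <- (in_grid_ref | ins_in_grid) & q != "-"
  dna <- paste(q[keep], collapse = "")
  if (locus$cds_strand == "-") dna <- rc(dna)
  got <- translate_str(dna)

  wt_sub <- substr(wt_translation$protein, i1, i2)
  want <- wt_sub
  if (nrow(exp)) {
    for (k in seq_len(nrow(exp))) {
      substr(want, exp$codon_index[k] - i1 + 1L, exp$codon_index[k] - i1 + 1L) <-
        exp$alt_aa[k]
    }
  }
  if (identical(got, want)) "pass" else "fail"
}

# Expected residue changes restricted to codons [i1, i2]; NULL if any
# expected change lies outside (missing evidence).
#' @noRd
locus_expected_in_range <- function(edit, i1, i2) {
  exp <- edit$expected_residue_changes
  if (nrow(exp) == 0L) {
    return(exp)
  }
  if (any(exp$codon_index < i1 | exp$codon_index > i2)) {
    return(NULL)
  }
  exp
}

#' Classify merged reads into editing-outcome categories
#'
#' Applies the rule cascade, in order, to every merged read:
#' \enumerate{
#'   \item the WT pattern occurs as an exact substring of the read: `WT` (no
#'     editing event);
#'   \item otherwise, the HDR pattern occurs as an exact substring: the read
#'     is aligned globally to the reference, its CDS is reconstructed and
#'     translated, and if the protein equals the wild type except for exactly
#'     the expected residue changes (extra synonymous nucleotide changes
#'     allowed) the read is `Correct_HDR`, else `Incorrect_HDR`;
#'   \item otherwise `Others` (mainly insertions, deletions, and unmapped
#'     reads: global identity below `identity_floor` percent).
#' }
#' Both orientations are considered: the reverse complement is tried when
#' neither pattern matches forward. Reads whose HDR pattern matches but whose
#' alignment does not cover every expected residue change are placed in
#' `Others` (`protein_check = "not_applicable"`) rather than condemned as
#' `Incorrect_HDR` on missing evidence.
#'
#' @param seqs Character vector of merged read sequences.
#' @param locus A [reference_locus()].
#' @param patterns A [derive_patterns()] pattern set.
#' @param edit The [edit_spec()] the donor was built from.
#' @param identity_floor Percent global identity below which a pattern-less
#'   read is reported as unmapped.
#' @param ids Read identifiers.
#' @param align_others Also align rule-3 reads to record identity and diffs
#'   (set `FALSE` to skip the alignments; category is unaffected, identity is
#'   `NA` and no unmapped reason is assigned).
#'
#' @return An object of class `editing_calls`: a data.frame with columns
#'   `read_id`, `category` (factor: WT, Correct_HDR, Incorrect_HDR, Others),
#'   `wt_pattern_hit`, `hdr_pattern_hit`, `orientation`, `protein_check`,
#'   `identity_pct`, `reason`, and a list-column `diffs` of alignment events.
#' @export
classify_reads <- function(seqs, locus, patterns, edit,
                           identity_floor = 60, ids = NULL,
                           align_others = TRUE) {
  n <- length(seqs)
  if (n == 0L) stop("no reads to classify", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  seqs <- toupper(seqs)
  ref <- locus$amplicon_seq
  wt_translation <- translate_cds(locus)

  work <- seqs
  orientation <- rep("+", n)
  wt_hit <- grepl(patterns$wt_pattern, work, fixed = TRUE)
  hdr_hit <- grepl(patterns$hdr_pattern, work, fixed = TRUE)
  flip <- which(!wt_hit & !hdr_hit & nchar(work) > 0L)
  if (length(flip)) {
    rcs <- rc(work[flip])
    wt_rc <- grepl(patterns$wt_pattern, rcs, fixed = TRUE)
    hdr_rc <- grepl(patterns$hdr_pattern, rcs, fixed = TRUE)
    use <- wt_rc | hdr_rc
    work[flip[use]] <- rcs[use]
    orientation[flip[use]] <- "-"
    wt_hit[flip] <- wt_rc
    hdr_hit[flip] <- hdr_rc
  }

  category <- rep("Others", n)
  prot <- rep("not_applicable", n)
  identity <- rep(NA_real_, n)
  reason <- rep("", n)
  diffs <- vector("list", n)

  category[wt_hit] <- "WT"
  reason[wt_hit] <- "wt_pattern"

  idx2 <- which(!wt_hit & hdr_hit)
  if (length(idx2)) {
    aln <- align_to_reference(work[idx2], ref)
    for (k in seq_along(idx2)) {
      i <- idx2[k]
      st <- alignment_stats(aln$ref[k], aln$query[k])
      identity[i] <- st$identity_pct
      diffs[[i]] <- st$diffs
      prot[i] <- protein_check(aln$ref[k], aln$query[k], locus, edit, wt_translation)
      category[i] <- switch(prot[i],
        pass = "Correct_HDR",
        fail = "Incorrect_HDR",
        not_applicable = "Others"
      )
      reason[i] <- switch(prot[i],
        pass = "hdr_pattern+protein_ok",
        fail = "hdr_pattern+protein_changed",
        not_applicable = "incomplete_protein_evidence"
      )
    }
  }

  idx3 <- which(!wt_hit & !hdr_hit)
  if (length(idx3) && align_others) {
    ok <- idx3[nchar(work[idx3]) > 0L]
    if (length(ok)) {
      aln <- align_to_reference(work[ok], ref)
      for (k in seq_along(ok)) {
        i <- ok[k]
        st <- alignment_stats(aln$ref[k], aln$query[k])
        identity[i] <- st$identity_pct
        diffs[[i]] <- st$diffs
      }
      # a pattern-less read may still be a reverse-orientation molecule
      low <- ok[identity[ok] < identity_floor]
      if (length(low)) {
        aln_rc <- align_to_reference(rc(work[low]), ref)
        for (k in seq_along(low)) {
          i <- low[k]
          st <- alignment_stats(aln_rc$ref[k], aln_rc$query[k])
          if (st$identity_pct > identity[i]) {
            identity[i] <- st$identity_pct
            diffs[[i]] <- st$diffs
            orientation[i] <- if (orientation[i] == "+") "-" else "+"
          }
        }
      }
      reason[ok] <- ifelse(identity[ok] < identity_floor, "unmapped", "no_pattern")
    }
    empty <- idx3[nchar(work[idx3]) == 0L]
    reason[empty] <- "empty_read"
  } else if (length(idx3)) {
    reason[idx3] <- "no_pattern"
  }

  calls <- data.frame(
    read_id = ids,
    category = factor(category, levels = CATEGORY_LEVELS),
    wt_pattern_hit = wt_hit,
    hdr_pattern_hit = hdr_hit,
    orientation = orientation,
    protein_check = prot,
    identity_pct = identity,
    reason = reason,
    stringsAsFactors = FALSE
  )
  calls$diffs <- diffs
  class(calls) <- c("editing_calls", class(calls))
  calls
}

#' Classify a single merged read
#'
#' @inheritParams classify_reads
#' @param seq One merged read sequence.
#' @return A one-row `editing_calls` data.frame.
#' @export
classify_read <- function(seq, locus, patterns, edit, identity_floor = 60) {
  classify_reads(seq, locus, patterns, edit, identity_floor = identity_floor)
}

#' Summarise editing calls for one condition
#'
#' @param calls An `editing_calls` data.frame.
#' @param condition Condition label (donor / locus description).
#' @param n_unmerged Number of read pairs that failed assembly; reported
#'   separately and excluded from percentage denominators (percentages are
#'   over assembled reads).
#'
#' @return An `efficiency_report`: condition, per-category counts and
#'   percentages, total assembled reads, unmerged count.
#' @export
summarize_calls <- function(calls, condition = "condition", n_unmerged = 0L) {
  if (NROW(calls) == 0L) stop("no calls to summarise", call. = FALSE)
  counts <- table(factor(calls$category, levels = CATEGORY_LEVELS))
  counts <- setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  structure(
    list(
      condition = condition,
      counts = counts,
      total_assembled = total,
      n_unmerged = as.integer(n_unmerged),
      percentages = 100 * counts / total
    ),
    class = "efficiency_report"
  )
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf(
    "<efficiency_report> %s: %d assembled reads (%d unmerged)\n",
    x$condition, x$total_assembled, x$n_unmerged
  ))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-14s %8d  %6.2f%%\n", nm, x$counts[[nm]], x$percentages[[nm]]))
  }
  invisible(x)
}

#' Fold change of a category percentage between two conditions
#'
#' @param report_a,report_b [summarize_calls()] reports; the ratio is
#'   `a / b`.
#' @param category One of `WT`, `Correct_HDR`, `Incorrect_HDR`, `Others`.
#' @return The ratio of percentages, or `NA` (with attribute
#'   `undefined = TRUE`) when the denominator percentage is zero.
#' @export
fold_change <- function(report_a, report_b, category = "Correct_HDR") {
  stopifnot(category %in% CATEGORY_LEVELS)
  pa <- report_a$percentages[[category]]
  pb <- report_b$percentages[[category]]
  if (pb == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  pa / pb
}

#' Pearson chi-square test on a phenotype-by-condition contingency table
#'
#' Compares rescue-class (or any categorical outcome) distributions between
#' conditions with Pearson's chi-square test without continuity correction.
#'
#' @param table Matrix of counts (classes x conditions).
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
chi_square_rescue <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has an empty row or column", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(ct$expected <= 0)) {
    stop("all expected counts must be positive", call. = FALSE)
  }
  list(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value)
  )
}

#' Run the full merge-classify-summarise pipeline
#'
#' Convenience wrapper: merge read pairs, classify the assembled reads and
#' summarise them into an efficiency report.
#'
#' @inheritParams merge_pairs
#' @inheritParams classify_reads
#' @param condition Condition label for the report.
#' @param flank Pattern flank passed to [derive_patterns()].
#' @return A list with `merges`, `calls` and `report`.
#' @export
run_pipeline <- function(r1_seq, r2_seq, locus, edit,
                         r1_qual = NULL, r2_qual = NULL, id = NULL,
                         condition = "condition", flank = 0L,
                         min_overlap = 10L, max_mismatch_density = 0.25,
                         identity_floor = 60) {
  patterns <- derive_patterns(locus, edit, flank = flank)
  merges <- merge_pairs(r1_seq, r2_seq, r1_qual, r2_qual,
    id = id,
    min_overlap = min_overlap, max_mismatch_density = max_mismatch_density
  )
  ok <- merges$merged
  calls <- classify_reads(
    merges$seq[ok], locus, patterns, edit,
    identity_floor = identity_floor, ids = merges$id[ok]
  )
  report <- summarize_calls(calls, condition, n_unmerged = sum(!ok))
  list(merges = merges, calls = calls, report = report)
}

#' Stacked-bar plot of category percentages across conditions
#'
#' @param reports List of `efficiency_report` objects.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_reports <- function(reports) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_reports requires ggplot2", call. = FALSE)
  }
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      condition = r$condition,
      category = factor(names(r$percentages), levels = rev(CATEGORY_LEVELS)),
      pct = unname(r$percentages),
      stringsAsFactors = FALSE
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(
    x = condition, y = pct,
    fill = category
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of assembled reads", fill = NULL) +
    ggplot2::theme_minimal()
}
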