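# Paired-read merging (overlap consensus) and global alignment of merged
# reads to the reference amplicon.

#' Merge overlapping paired-end reads
#'
#' Read 2 is reverse-complemented and slid against read 1; among all shifts
#' with overlap of at least `min_overlap` and mismatch density at most
#' `max_mismatch_density`, the largest overlap wins. Within the overlap each
#' base is taken from the mate with the higher quality (ties go to read 1).
#' Pairs with no qualifying shift are flagged unmerged and excluded from
#' downstream classification denominators.
#'
#' @param r1_seq,r2_seq Character vectors of read sequences (read 2 in
#'   sequencing orientation, i.e. reverse-complement of the molecule).
#' @param r1_qual,r2_qual Phred+33 quality strings; default constant high
#'   quality.
#' @param id Read identifiers.
#' @param min_overlap Minimum overlap in nt.
#' @param max_mismatch_density Maximum fraction of mismatching bases in the
#'   overlap.
#'
#' @return A data.frame with columns `id`, `merged`, `seq`, `overlap_len`,
#'   `n_overlap_mismatches`. For merged pairs
#'   `nchar(seq) == nchar(r1) + nchar(r2) - overlap_len`.
#' @export
merge_pairs <- function(r1_seq, r2_seq, r1_qual = NULL, r2_qual = NULL,
                        id = NULL, min_overlap = 10L,
                        max_mismatch_density = 0.25) {
  n <- length(r1_seq)
  stopifnot(length(r2_seq) == n)
  if (is.null(id)) id <- sprintf("pair%06d", seq_len(n))
  if (is.null(r1_qual)) r1_qual <- strrep("I", nchar(r1_seq))
  if (is.null(r2_qual)) r2_qual <- strrep("I", nchar(r2_seq))
  if (any(nchar(r1_qual) != nchar(r1_seq)) || any(nchar(r2_qual) != nchar(r2_seq))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  nz <- nchar(r2_seq) > 0L
  r2rc <- character(n)
  r2rc[nz] <- rc(r2_seq[nz])
  q2r <- character(n)
  q2r[nz] <- rev_string(r2_qual[nz])
  res <- merge_scan_cpp(
    r1_seq, r2rc, r1_qual, q2r,
    as.integer(min_overlap), max_mismatch_density
  )
  data.frame(
    id = id, merged = res$merged, seq = res$seq,
    overlap_len = res$overlap_len,
    n_overlap_mismatches = res$n_overlap_mismatches,
    stringsAsFactors = FALSE
  )
}

# Vectorised global alignment of many queries against one reference.
# Returns gapped strings; scoring matches EMBOSS-style nucleotide defaults.
#' @noRd
align_to_reference <- function(queries, reference, match = 5, mismatch = -4,
                               gap_open = 10, gap_extend = 0.5) {
  align_affine_cpp(queries, reference, match, mismatch, gap_open, gap_extend)
}

# Per-column comparison of one gapped pair: identity (percent of alignment
# columns with identical non-gap, non-N bases) and diff events in reference
# coordinates.
#' @noRd
alignment_stats <- function(aligned_ref, aligned_query) {
  r <- strsplit(aligned_ref, "")[[1]]
  q <- strsplit(aligned_query, "")[[1]]
  ncol <- length(r)
  ref_pos <- cumsum(r != "-")
  ident <- 100 * sum(r == q & r != "-" & r != "N" & q != "N") / ncol

  diffs <- list()
  is_sub <- r != "-" & q != "-" & r != q
  if (any(is_sub)) {
    diffs[[length(diffs) + 1L]] <- data.frame(
      type = "substitution", start = ref_pos[is_sub], end = ref_pos[is_sub],
      ref = r[is_sub], alt = q[is_sub], stringsAsFactors = FALSE
    )
  }
  # runs of gaps in the reference = insertions in the query
  ins <- r == "-" & q != "-"
  if (any(ins)) {
    rl <- rle(ins)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      pos <- if (starts[k] == 1L) 0L else ref_pos[starts[k] - 1L]
      diffs[[length(diffs) + 1L]] <- data.frame(
        type = "insertion", start = pos, end = pos, ref = "",
        alt = paste(q[starts[k]:ends[k]], collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  del <- q == "-" & r != "-"
  if (any(del)) {
    rl <- rle(del)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      diffs[[length(diffs) + 1L]] <- data.frame(
        type = "deletion", start = ref_pos[starts[k]], end = ref_pos[ends[k]],
        ref = paste(r[starts[k]:ends[k]], collapse = ""), alt = "",
        stringsAsFactors = FALSE
      )
    }
  }
  diffs <- if (length(diffs)) do.call(rbind, diffs) else data.frame(
    type = character(), start = integer(), end = integer(),
    ref = character(), alt = character(), stringsAsFactors = FALSE
  )
  diffs <- diffs[order(diffs$start, diffs$type), , drop = FALSE]
  rownames(diffs) <- NULL
  list(identity_pct = ident, diffs = diffs)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch global alignment of a query against a reference
#' under affine gap costs (a gap of length L costs
#' `gap_open + gap_extend * L`). Defaults follow the EMBOSS nucleotide
#' convention: match +5, mismatch -4, gap open 10, gap extend 0.5. `N` bases
#' always score as mismatches and never count towards identity.
#'
#' @param query,reference Non-empty A/C/G/T/N strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#'
#' @return An object of class `alignment_result`: `aligned_ref` and
#'   `aligned_query` (equal-length gapped strings), `score`, `identity_pct`
#'   (percent over alignment columns) and `diffs` (data.frame of substitution
#'   /insertion/deletion events in reference coordinates; insertions are
#'   anchored to the reference base immediately 5' of the inserted sequence).
#' @examples
#' aln <- global_align("ACGT", "ACT")
#' aln$score # 4.5: three matches minus one length-1 affine gap
#' @export
global_align <- function(query, reference, match = 5, mismatch = -4,
                         gap_open = 10, gap_extend = 0.5) {
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    stop("query and reference must be non-empty", call. = FALSE)
  }
  check_dna(query, "query", alphabet = "ACGTN")
  check_dna(reference, "reference", alphabet = "ACGTN")
  aln <- align_to_reference(query, reference, match, mismatch, gap_open, gap_extend)
  st <- alignment_stats(aln$ref[1], aln$query[1])
  structure(
    list(
      aligned_ref = aln$ref[1], aligned_query = aln$query[1],
      score = aln$score[1], identity_pct = st$identity_pct, diffs = st$diffs
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> score %.1f, identity %.1f%%, %d event(s)\n",
    x$score, x$identity_pct, nrow(x$diffs)
  ))
  invisible(x)
}

#' Write a human-readable pairwise alignment
#'
#' Dumps an alignment in a simple Needle-style block format for inspection.
#'
#' @param x An `alignment_result`.
#' @param file Path or connection; `""` prints to the console.
#' @param width Bases per block line.
#' @export
write_alignment_text <- function(x, file = "", width = 60L) {
  n <- nchar(x$aligned_ref)
  lines <- c(sprintf("# score %.1f  identity %.1f%%", x$score, x$identity_pct))
  for (s in seq(1L, n, by = width)) {
    e <- min(n, s + width - 1L)
    a <- substr(x$aligned_ref, s, e)
    b <- substr(x$aligned_query, s, e)
    marks <- paste(ifelse(strsplit(a, "")[[1]] == strsplit(b, "")[[1]], "|", " "),
      collapse = ""
    )
    lines <- c(lines, sprintf("ref   %s", a), sprintf("      %s", marks),
      sprintf("query %s", b), ""
    )
  }
  writeLines(lines, file)
  invisible(x)
}

#' Read a FASTQ file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] (gzip-transparent).
#'
#' @param path FASTQ path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = sub(" .*", "", names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path (plain text; `.gz` paths are compressed).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(
    paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
    con
  )
  invisible(path)
}

#' Write merged reads or donors as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path
  )
  invisible(path)
}
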