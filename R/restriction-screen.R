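# In-silico restriction genotyping: IUPAC-aware site finding, digestion
# fragment prediction, and pooled-sample positive/negative calls.

#' Find restriction sites in a sequence
#'
#' Scans the top strand for the (possibly degenerate) recognition site.
#' Palindromic sites are reported once; for non-palindromic sites the bottom
#' strand is also searched and hits are reported in top-strand coordinates
#' with a strand tag.
#'
#' @param seq A/C/G/T string.
#' @param enzyme A [restriction_enzyme()].
#' @return data.frame with columns `pos` (1-based start of the match on the
#'   top strand) and `strand`.
#' @examples
#' find_sites("ACGATCGT", get_enzyme("PvuI")) # PvuI CGATCG at position 2
#' @export
find_sites <- function(seq, enzyme) {
  check_dna(seq, "seq")
  top <- scan_site_starts(seq, enzyme$recognition)[[1]]
  res <- data.frame(pos = top, strand = rep("+", length(top)))
  rcsite <- rc(enzyme$recognition)
  if (rcsite != enzyme$recognition) {
    bot <- scan_site_starts(seq, rcsite)[[1]]
    res <- rbind(res, data.frame(pos = bot, strand = rep("-", length(bot))))
  }
  res <- res[order(res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict digestion fragments of a linear sequence
#'
#' Cut positions are site start + top-strand cut offset; enzymes with an
#' unknown offset are assumed to cut blunt at mid-site (this shifts fragment
#' sizes by at most the site length and never changes whether a sequence is
#' cut). Fragment lengths always sum to the sequence length.
#'
#' @inheritParams find_sites
#' @param label Optional sequence label carried into the result.
#' @return A `digest_result`: `label`, `enzyme`, `cut_positions` (number of
#'   bases 5' of each cut) and `fragment_lengths`.
#' @export
digest_seq <- function(seq, enzyme, label = NULL) {
  sites <- find_sites(seq, enzyme)
  site_len <- nchar(enzyme$recognition)
  offset <- enzyme$cut_offset_top
  if (is.na(offset)) offset <- site_len %/% 2L
  off <- ifelse(sites$strand == "+", offset, site_len - offset)
  cuts <- sort(unique(sites$pos - 1L + off))
  cuts <- cuts[cuts > 0L & cuts < nchar(seq)]
  structure(
    list(
      label = label %||% "sequence",
      enzyme = enzyme$name,
      cut_positions = cuts,
      fragment_lengths = diff(c(0L, cuts, nchar(seq)))
    ),
    class = "digest_result"
  )
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf(
    "<digest_result> %s + %s: %d cut(s), fragments %s\n",
    x$label, x$enzyme, length(x$cut_positions),
    paste(x$fragment_lengths, collapse = "/")
  ))
  invisible(x)
}

#' Genotype a pooled sample by diagnostic digestion
#'
#' Models the restriction screen used on pooled embryos: a fraction
#' `edited_fraction` of the amplified molecules carries the introduced site;
#' the pool is called positive when that fraction reaches the detection
#' threshold of the gel readout. The enzyme must cut the edited amplicon and
#' not the wild-type one, otherwise the assay is uninformative.
#'
#' @param wt_amplicon,edited_amplicon Amplicon sequences.
#' @inheritParams find_sites
#' @param edited_fraction Fraction of molecules carrying the introduced site
#'   (for a pool of embryos with known mosaic fractions, see
#'   [pool_fraction()]).
#' @param detection_threshold Smallest edited fraction the gel can detect.
#' @return A `pool_call`: `edited_fraction`, `call`
#'   (`"positive"`/`"negative"`), `detection_threshold`, and `bands`
#'   (expected gel pattern: fragment lengths with relative abundances).
#' @export
genotype_pool <- function(wt_amplicon, edited_amplicon, enzyme,
                          edited_fraction, detection_threshold = 0.05) {
  stopifnot(edited_fraction >= 0, edited_fraction <= 1)
  wt_digest <- digest_seq(wt_amplicon, enzyme, "WT")
  ed_digest <- digest_seq(edited_amplicon, enzyme, "edited")
  if (length(wt_digest$cut_positions) > 0L) {
    stop(
      "assay uninformative: ", enzyme$name, " cuts the wild-type amplicon",
      call. = FALSE
    )
  }
  if (length(ed_digest$cut_positions) == 0L) {
    stop(
      "assay uninformative: ", enzyme$name, " does not cut the edited amplicon",
      call. = FALSE
    )
  }
  bands <- rbind(
    data.frame(
      length = nchar(wt_amplicon), abundance = 1 - edited_fraction,
      source = "uncut"
    ),
    data.frame(
      length = ed_digest$fragment_lengths,
      abundance = edited_fraction,
      source = "digest"
    )
  )
  bands <- bands[bands$abundance > 0, , drop = FALSE]
  rownames(bands) <- NULL
  structure(
    list(
      edited_fraction = edited_fraction,
      call = if (edited_fraction >= detection_threshold) "positive" else "negative",
      detection_threshold = detection_threshold,
      bands = bands
    ),
    class = "pool_call"
  )
}

#' @export
print.pool_call <- function(x, ...) {
  cat(sprintf(
    "<pool_call> %s (edited fraction %.3f, threshold %.3f)\n",
    x$call, x$edited_fraction, x$detection_threshold
  ))
  invisible(x)
}

#' Edited fraction of a pool from per-embryo mosaic fractions
#'
#' Pools are modelled through their aggregate edited fraction: with equal
#' genomic input per embryo, the mean of the per-embryo mosaic fractions.
#'
#' @param mosaic_fractions Numeric vector, one entry per pooled embryo.
#' @return The pool's edited fraction.
#' @export
pool_fraction <- function(mosaic_fractions) {
  stopifnot(
    length(mosaic_fractions) >= 1L,
    all(mosaic_fractions >= 0), all(mosaic_fractions <= 1)
  )
  mean(mosaic_fractions)
}
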