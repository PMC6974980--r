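# Low-level DNA helpers shared across modules. Sequences are plain upper-case
# character strings; all intervals are 1-based and closed.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' @noRd
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
rev_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

# Translate an in-frame DNA string with the standard genetic code.
# Incomplete terminal codons are dropped; codons with ambiguous bases give "X".
#' @noRd
translate_str <- function(seq) {
  n_codons <- nchar(seq) %/% 3L
  if (n_codons == 0L) {
    return("")
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' @noRd
syn_codons <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  alts <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
  setdiff(alts, codon)
}

# Apply point substitutions (1-based positions relative to `offset` + 1) to a
# sequence. `subs` is a data.frame with columns pos, ref, alt.
#' @noRd
apply_subs <- function(seq, subs, offset = 0L) {
  if (is.null(subs) || nrow(subs) == 0L) {
    return(seq)
  }
  for (k in seq_len(nrow(subs))) {
    p <- subs$pos[k] - offset
    if (p < 1L || p > nchar(seq)) {
      stop("substitution position ", subs$pos[k], " outside sequence", call. = FALSE)
    }
    if (substr(seq, p, p) != subs$ref[k]) {
      stop(
        "reference base mismatch at position ", subs$pos[k], ": expected ",
        subs$ref[k], ", found ", substr(seq, p, p),
        call. = FALSE
      )
    }
    substr(seq, p, p) <- subs$alt[k]
  }
  seq
}

#' @noRd
substitution_frame <- function(pos = integer(), ref = character(),
                               alt = character(), role = character()) {
  data.frame(
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    role = as.character(role), stringsAsFactors = FALSE
  )
}

#' @noRd
check_dna <- function(seq, what = "sequence", alphabet = "ACGT") {
  bad <- regexpr(sprintf("[^%s]", alphabet), seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(
      what, " contains invalid character '",
      substr(seq[i], bad[i], bad[i]), "' at position ", bad[i],
      call. = FALSE
    )
  }
  invisible(seq)
}

# IUPAC recognition string -> regular expression (character classes).
#' @noRd
iupac_to_regex <- function(site) {
  chars <- strsplit(site, "")[[1]]
  bad <- !chars %in% names(IUPAC_CODES)
  if (any(bad)) {
    stop("invalid IUPAC code '", chars[which(bad)[1]], "' in recognition site ",
      site,
      call. = FALSE
    )
  }
  paste(vapply(chars, function(ch) {
    exp <- IUPAC_CODES[[ch]]
    if (nchar(exp) == 1L) exp else paste0("[", exp, "]")
  }, character(1)), collapse = "")
}

# All start positions (1-based, possibly overlapping) where an IUPAC site
# matches the top strand of `seq`. Vectorised over `seq`.
#' @noRd
scan_site_starts <- function(seq, site) {
  rx <- iupac_to_regex(site)
  lapply(gregexpr(sprintf("(?=%s)", rx), seq, perl = TRUE), function(m) {
    m <- as.integer(m)
    m[m > 0L]
  })
}
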