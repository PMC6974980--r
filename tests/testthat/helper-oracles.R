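# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# ---- exhaustive global-alignment oracle (affine gaps) -----------------------
# Enumerates every monotone alignment path between sequences of lengths
# (l1, l2) as a move string over {M, I, D}; each maximal gap run of length L
# costs open + ext * L. Paths are cached per shape and deduplicated by
# (aligned pairs, gap cost).

.path_cache <- new.env(parent = emptyenv())

enumerate_alignment_paths <- function(l1, l2) {
  key <- paste(l1, l2)
  if (!is.null(.path_cache[[key]])) {
    return(.path_cache[[key]])
  }
  paths <- list()
  recurse <- function(i, j, moves) {
    if (i == l1 && j == l2) {
      paths[[length(paths) + 1L]] <<- moves
      return(invisible())
    }
    if (i < l1 && j < l2) recurse(i + 1L, j + 1L, c(moves, "M"))
    if (i < l1) recurse(i + 1L, j, c(moves, "I")) # query base vs gap
    if (j < l2) recurse(i, j + 1L, c(moves, "D")) # gap vs subject base
  }
  recurse(0L, 0L, character())
  parsed <- lapply(paths, function(mv) {
    im <- cumsum(mv == "M" | mv == "I")
    jm <- cumsum(mv == "M" | mv == "D")
    pairs <- cbind(im[mv == "M"], jm[mv == "M"])
    rl <- rle(mv)
    gaps <- rl$lengths[rl$values != "M"]
    list(pairs = pairs, n_gap_runs = length(gaps), gap_len = sum(gaps))
  })
  keys <- vapply(parsed, function(p) {
    paste(p$n_gap_runs, p$gap_len, paste(t(p$pairs), collapse = ","))
  }, character(1))
  parsed <- parsed[!duplicated(keys)]
  .path_cache[[key]] <- parsed
  parsed
}

# Best affine-gap global alignment score for a single pair of sequences.
oracle_align_score <- function(s1, s2, match = 5, mismatch = -4,
                               gap_open = 10, gap_ext = 0.5) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  best <- -Inf
  for (p in enumerate_alignment_paths(length(a), length(b))) {
    k <- nrow(p$pairs)
    m <- if (k) sum(a[p$pairs[, 1]] == b[p$pairs[, 2]]) else 0L
    sc <- match * m + mismatch * (k - m) -
      p$n_gap_runs * gap_open - p$gap_len * gap_ext
    if (sc > best) best <- sc
  }
  best
}

# Vectorised oracle over every sequence pair of shape (l1, l2) drawn from an
# alphabet: returns a matrix of best scores (rows = seqs1, cols = seqs2).
oracle_align_scores_all <- function(l1, l2, alphabet = c("A", "C"),
                                    match = 5, mismatch = -4,
                                    gap_open = 10, gap_ext = 0.5) {
  seqs1 <- do.call(
    expand.grid, c(rep(list(alphabet), l1), stringsAsFactors = FALSE)
  )
  seqs2 <- do.call(
    expand.grid, c(rep(list(alphabet), l2), stringsAsFactors = FALSE)
  )
  m1 <- as.matrix(seqs1)
  m2 <- as.matrix(seqs2)
  best <- matrix(-Inf, nrow(m1), nrow(m2))
  for (p in enumerate_alignment_paths(l1, l2)) {
    k <- nrow(p$pairs)
    mm <- matrix(0L, nrow(m1), nrow(m2))
    if (k) {
      for (r in seq_len(k)) {
        mm <- mm + outer(m1[, p$pairs[r, 1]], m2[, p$pairs[r, 2]], "==")
      }
    }
    sc <- match * mm + mismatch * (k - mm) -
      p$n_gap_runs * gap_open - p$gap_len * gap_ext
    best <- pmax(best, sc)
  }
  list(
    scores = best,
    seqs1 = apply(m1, 1, paste, collapse = ""),
    seqs2 = apply(m2, 1, paste, collapse = "")
  )
}

# ---- alignment-free merge oracle -------------------------------------------
# Exhaustive shift scan in plain R (independent of the C++ kernel).
oracle_merge <- function(r1, r2, min_overlap = 10L, max_density = 0.25) {
  s2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r2)))
  a <- strsplit(r1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  for (o in seq.int(min(length(a), length(b)), min_overlap)) {
    if (o < min_overlap) break
    mm <- sum(a[(length(a) - o + 1):length(a)] != b[1:o])
    if (mm <= floor(max_density * o)) {
      return(list(
        merged = TRUE, overlap = o,
        seq_len = length(a) + length(b) - o
      ))
    }
  }
  list(merged = FALSE, overlap = 0L, seq_len = NA_integer_)
}

# ---- restriction-site oracle ------------------------------------------------
# IUPAC-aware scan through Biostrings::matchPattern (the implementation uses
# a regex scanner).
oracle_find_sites <- function(seq, recognition) {
  subj <- Biostrings::DNAString(seq)
  hits <- Biostrings::start(Biostrings::matchPattern(
    recognition, subj,
    fixed = "subject"
  ))
  sort(hits)
}

# ---- brute-force Coding-bar enumeration ------------------------------------
# Exhaustively enumerates 0-2 synonymous codon replacements among the
# complete reading-frame codons inside `window` (skipping codons touched by
# the edit) and scans each variant against the enzymes with matchPattern.
# Returns a sorted character vector of candidate keys.
oracle_coding_bar_keys <- function(locus, edit, enzymes, window, max_changes = 2L) {
  base_seq <- locus$amplicon_seq
  for (k in seq_len(nrow(edit$substitutions))) {
    substr(base_seq, edit$substitutions$pos[k], edit$substitutions$pos[k]) <-
      edit$substitutions$alt[k]
  }
  stopifnot(locus$cds_strand == "+", locus$cds_frame == 0L)
  first <- locus$cds[1]
  starts <- seq(first, locus$cds[2] - 2L, by = 3L)
  starts <- starts[starts >= window[1] & starts + 2L <= window[2]]
  starts <- starts[vapply(starts, function(s) {
    !any(s:(s + 2L) %in% edit$substitutions$pos)
  }, logical(1))]

  gc <- Biostrings::GENETIC_CODE
  codon_alts <- lapply(starts, function(s) {
    cod <- substr(locus$amplicon_seq, s, s + 2L)
    setdiff(names(gc)[gc == gc[[cod]]], cod)
  })

  site_len_max <- max(vapply(enzymes, function(e) nchar(e$recognition), integer(1)))
  scan_lo <- max(1L, window[1] - site_len_max + 1L)
  scan_hi <- min(nchar(locus$amplicon_seq), window[2] + site_len_max - 1L)
  wt_scan <- substr(locus$amplicon_seq, scan_lo, scan_hi)

  variants <- list(list(seq = base_seq, subs = ""))
  add_variant <- function(vlist, codon_idx, alt) {
    s <- starts[codon_idx]
    old <- substr(locus$amplicon_seq, s, s + 2L)
    lapply(vlist, function(v) {
      seq <- v$seq
      substr(seq, s, s + 2L) <- alt
      changed <- which(strsplit(old, "")[[1]] != strsplit(alt, "")[[1]])
      sub_str <- paste(
        sprintf(
          "%d%s>%s", s + changed - 1L,
          substring(old, changed, changed), substring(alt, changed, changed)
        ),
        collapse = ";"
      )
      list(seq = seq, subs = paste(c(v$subs[v$subs != ""], sub_str), collapse = ";"))
    })
  }
  all_variants <- variants
  if (max_changes >= 1L) {
    for (i in seq_along(starts)) {
      for (alt in codon_alts[[i]]) {
        all_variants <- c(all_variants, add_variant(variants, i, alt))
      }
    }
  }
  if (max_changes >= 2L) {
    for (i in seq_along(starts)) {
      for (j in seq_along(starts)) {
        if (j <= i) next
        for (ai in codon_alts[[i]]) {
          vi <- add_variant(variants, i, ai)
          for (aj in codon_alts[[j]]) {
            all_variants <- c(all_variants, add_variant(vi, j, aj))
          }
        }
      }
    }
  }

  keys <- character()
  for (enz in enzymes) {
    pats <- list(c(enz$recognition, "+"))
    rcp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(enz$recognition)))
    if (rcp != enz$recognition) pats <- c(pats, list(c(rcp, "-")))
    for (ps in pats) {
      if (length(oracle_find_sites(wt_scan, ps[1])) > 0L) next
      for (v in all_variants) {
        hits <- oracle_find_sites(substr(v$seq, scan_lo, scan_hi), ps[1])
        for (h in hits) {
          keys <- c(keys, paste(enz$name, scan_lo + h - 1L, ps[2], v$subs, sep = "|"))
        }
      }
    }
  }
  sort(unique(keys))
}

coding_bar_candidate_keys <- function(candidates) {
  sort(unique(vapply(candidates, function(cd) {
    ord <- order(cd$substitutions$pos)
    paste(cd$enzyme, cd$site_position, cd$strand,
      paste(
        sprintf(
          "%d%s>%s", cd$substitutions$pos[ord],
          cd$substitutions$ref[ord], cd$substitutions$alt[ord]
        ),
        collapse = ";"
      ),
      sep = "|"
    )
  }, character(1))))
}

# Hand-rolled Pearson chi-square (oracle for chi_square_rescue).
oracle_pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp)^2 / exp)
}
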