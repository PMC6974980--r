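# Seeded generator for loci, edits and paired amplicon reads with truth
# tables, emulating a knock-in amplicon sequencing experiment at desk scale.

SIM_CLASSES <- c(
  "WT", "Correct_HDR", "Incorrect_HDR_substitution",
  "Incorrect_HDR_indel", "NHEJ_indel"
)

#' Configure a read simulation
#'
#' Defaults describe the emulated experiment: a 250-nt amplicon containing a
#' coding window and a guide site, fully overlapping 150-nt read pairs,
#' uniform per-base sequencing error, and molecule classes drawn from
#' wild type, correct HDR, HDR with a secondary substitution or indel, and
#' NHEJ indels at the cut site. The default class proportions and error rate
#' are the package's standard desk-scale study condition; the NHEJ indel
#' length spectrum ranges from 1 to 25 nt with short deletions dominating.
#'
#' @param seed Integer seed; the same seed gives byte-identical FASTQ output.
#' @param n_reads Number of read pairs to emit.
#' @param amplicon_len,read_len Amplicon and read lengths in nt; reads must
#'   overlap (`2 * read_len > amplicon_len`).
#' @param class_proportions Named numeric vector over the molecule classes
#'   (must sum to 1).
#' @param per_base_error Uniform per-base substitution error rate in
#'   `[0, 0.2]`, independent of the written qualities.
#' @param indel_len_distribution Named numeric vector: NHEJ indel length ->
#'   probability.
#' @param quality_mean Constant Phred score written for every base.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_reads = 20000L,
                              amplicon_len = 250L,
                              read_len = 150L,
                              class_proportions = c(
                                WT = 0.70,
                                Correct_HDR = 0.12,
                                Incorrect_HDR_substitution = 0.02,
                                Incorrect_HDR_indel = 0.04,
                                NHEJ_indel = 0.12
                              ),
                              per_base_error = 0.001,
                              indel_len_distribution = c(
                                `1` = 0.30, `2` = 0.20, `3` = 0.15, `5` = 0.10,
                                `7` = 0.10, `10` = 0.10, `25` = 0.05
                              ),
                              quality_mean = 35L) {
  if (!all(names(class_proportions) %in% SIM_CLASSES)) {
    stop(
      "class_proportions names must be in {",
      paste(SIM_CLASSES, collapse = ", "), "}",
      call. = FALSE
    )
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  if (per_base_error < 0 || per_base_error > 0.2) {
    stop("per_base_error must be in [0, 0.2]", call. = FALSE)
  }
  if (abs(sum(indel_len_distribution) - 1) > 1e-8) {
    stop("indel_len_distribution must sum to 1", call. = FALSE)
  }
  if (2L * read_len <= amplicon_len) {
    stop("reads must overlap: 2 * read_len must exceed amplicon_len", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_reads = as.integer(n_reads),
      amplicon_len = as.integer(amplicon_len),
      read_len = as.integer(read_len),
      class_proportions = class_proportions,
      per_base_error = per_base_error,
      indel_len_distribution = indel_len_distribution,
      quality_mean = as.integer(quality_mean)
    ),
    class = "simulation_config"
  )
}

#' Simulate a reference locus and a matching edit specification
#'
#' Draws a random amplicon with an internal coding window, a valid
#' NGG-adjacent protospacer inside the CDS, and an edit specification
#' containing one non-synonymous substitution in the PAM-proximal (seed)
#' region plus synonymous Coding-bar substitutions creating a de novo site
#' for one of the bundled enzymes (via [design_coding_bar()], checked against
#' the whole wild-type amplicon). Fully reproducible from the seed; amplicons
#' that admit no Coding-bar are resampled, with an error after `max_attempts`.
#'
#' @param seed Integer seed.
#' @param amplicon_len Amplicon length (>= 100 nt).
#' @param max_attempts Resampling budget.
#' @return A list with elements `locus` ([reference_locus()]) and `edit`
#'   ([edit_spec()]).
#' @export
simulate_locus <- function(seed, amplicon_len = 250L, max_attempts = 30L) {
  stopifnot(amplicon_len >= 100L)
  withr::with_seed(seed, {
    enzymes <- load_enzymes()
    for (attempt in seq_len(max_attempts)) {
      res <- try(simulate_locus_once(amplicon_len, enzymes), silent = TRUE)
      if (!inherits(res, "try-error") && !is.null(res)) {
        return(res)
      }
    }
    stop(
      "could not place a guide site with a Coding-bar in ", max_attempts,
      " attempts",
      call. = FALSE
    )
  })
}

#' @noRd
simulate_locus_once <- function(amplicon_len, enzymes) {
  amp <- paste(sample(DNA_BASES, amplicon_len, replace = TRUE), collapse = "")
  cds1 <- 10L
  cds2 <- cds1 + 3L * ((amplicon_len - 6L - cds1 + 1L) %/% 3L) - 1L
  n_codons <- (cds2 - cds1 + 1L) %/% 3L
  # protospacer on a codon boundary, roughly central, with >= 24 nt of CDS
  # downstream of the PAM for secondary events
  ps <- cds1 + 3L * max(4L, (n_codons %/% 2L) - 8L)
  if (ps + 22L + 24L > cds2) {
    return(NULL)
  }
  pam <- c(ps + 20L, ps + 22L)
  substr(amp, pam[1] + 1L, pam[1] + 2L) <- "GG"
  locus <- reference_locus(
    gene_name = "simlocus", amplicon_seq = amp,
    cds = c(cds1, cds2), cds_frame = 0L, cds_strand = "+",
    protospacer = c(ps, ps + 19L), pam = pam, guide_strand = "+"
  )

  # one non-synonymous substitution in the seed codon closest to the PAM
  info <- codon_info(locus, ps + 17L)
  sub_edit <- NULL
  for (p_in_codon in 1:2) {
    pos <- info$top_span[1] + p_in_codon - 1L
    ref <- substr(amp, pos, pos)
    for (alt in setdiff(DNA_BASES, ref)) {
      new_codon <- info$codon
      substr(new_codon, p_in_codon, p_in_codon) <- alt
      old_aa <- Biostrings::GENETIC_CODE[[info$codon]]
      new_aa <- Biostrings::GENETIC_CODE[[new_codon]]
      if (new_aa != old_aa && new_aa != "*") {
        sub_edit <- list(
          subs = substitution_frame(pos, ref, alt, "edit"),
          change = data.frame(
            codon_index = info$index, ref_aa = old_aa, alt_aa = new_aa,
            stringsAsFactors = FALSE
          )
        )
        break
      }
    }
    if (!is.null(sub_edit)) break
  }
  if (is.null(sub_edit)) {
    return(NULL)
  }
  edit0 <- edit_spec(sub_edit$subs, sub_edit$change, locus = locus)

  # synonymous Coding-bar inside the protospacer, de novo across the whole
  # wild-type amplicon
  window <- c(ps, ps + 14L)
  cands <- design_coding_bar(locus, edit0, enzymes, window, max_changes = 2L)
  for (cand in cands) {
    if (cand$n_changes == 0L) next # want a genuine synonymous barcode
    enz <- enzymes[[cand$enzyme]]
    if (nrow(find_sites(locus$amplicon_seq, enz)) > 0L) next
    subs <- rbind(sub_edit$subs, cand$substitutions)
    edit <- edit_spec(subs, sub_edit$change,
      introduced_enzyme = cand$enzyme, locus = locus
    )
    edited <- apply_subs(locus$amplicon_seq, edit$substitutions)
    if (nrow(find_sites(edited, enz)) == 0L) next
    return(list(locus = locus, edit = edit))
  }
  NULL
}

#' Simulate paired amplicon reads with a truth table
#'
#' For each molecule a class is drawn from the configured proportions and the
#' corresponding sequence is built: wild type; all HDR substitutions; HDR
#' plus one extra non-synonymous (non-wobble) CDS substitution outside the
#' guide window; HDR plus a frameshift indel in the CDS just outside the
#' guide window; or an NHEJ indel centred at the cut site with length drawn
#' from the configured spectrum (deletions dominate; insertions are random
#' sequence). The molecule is read as a fully overlapping pair of `read_len`
#' reads, uniform substitution errors are injected at `per_base_error`
#' (independently of the constant written qualities), and a truth record is
#' kept per pair.
#'
#' @param locus,edit As returned by [simulate_locus()].
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, writes `R1.fastq`,
#'   `R2.fastq`, `truth.tsv` and `locus.yaml` there.
#'
#' @return A list with `r1`, `r2` (data.frames `id`/`seq`/`qual`), `truth`
#'   (data.frame `read_id`/`true_class`/`detail`), `locus`, `edit`, `config`.
#' @export
simulate_reads <- function(locus, edit, config, out_dir = NULL) {
  amp_len <- nchar(locus$amplicon_seq)
  if (2L * config$read_len <= amp_len) {
    stop("reads must overlap: 2 * read_len must exceed the amplicon length",
      call. = FALSE
    )
  }
  withr::with_seed(config$seed, {
    n <- config$n_reads
    props <- config$class_proportions
    classes <- sample(names(props), n, replace = TRUE, prob = props)
    wt <- locus$amplicon_seq
    hdr <- apply_subs(wt, edit$substitutions)
    patt <- derive_patterns(locus, edit, flank = 0L)
    lo <- patt$interval[1]
    hi <- patt$interval[2]
    cut <- cut_site(locus)

    mols <- character(n)
    detail <- character(n)
    mols[classes == "WT"] <- wt
    mols[classes == "Correct_HDR"] <- hdr

    idx <- which(classes == "Incorrect_HDR_substitution")
    if (length(idx)) {
      pool <- secondary_sub_pool(locus, lo, hi)
      if (nrow(pool) == 0L) {
        stop("no secondary-substitution sites available at this locus", call. = FALSE)
      }
      pick <- sample.int(nrow(pool), length(idx), replace = TRUE)
      variants <- vapply(seq_len(nrow(pool)), function(k) {
        s <- hdr
        substr(s, pool$pos[k], pool$pos[k]) <- pool$alt[k]
        s
      }, character(1))
      mols[idx] <- variants[pick]
      detail[idx] <- sprintf("extra_sub:%d%s>%s", pool$pos[pick], pool$ref[pick], pool$alt[pick])
    }

    idx <- which(classes == "Incorrect_HDR_indel")
    if (length(idx)) {
      del_start <- hi + 4L
      if (del_start + 2L > locus$cds[2]) {
        stop("no room for a secondary indel downstream of the guide window", call. = FALSE)
      }
      lens <- sample(c(1L, 2L), length(idx), replace = TRUE)
      variants <- vapply(c(1L, 2L), function(L) {
        paste0(substr(hdr, 1L, del_start - 1L), substr(hdr, del_start + L, nchar(hdr)))
      }, character(1))
      mols[idx] <- variants[lens]
      detail[idx] <- sprintf("frameshift_del:%d+%d", del_start, lens)
    }

    idx <- which(classes == "NHEJ_indel")
    if (length(idx)) {
      lens <- as.integer(sample(names(config$indel_len_distribution),
        length(idx),
        replace = TRUE, prob = config$indel_len_distribution
      ))
      is_del <- runif(length(idx)) < 0.7
      for (k in seq_along(idx)) {
        L <- lens[k]
        if (is_del[k]) {
          d0 <- max(1L, cut - (L %/% 2L))
          d0 <- min(d0, nchar(wt) - L - 1L)
          mols[idx[k]] <- paste0(substr(wt, 1L, d0), substr(wt, d0 + L + 1L, nchar(wt)))
          detail[idx[k]] <- sprintf("nhej_del:%d+%d", d0 + 1L, L)
        } else {
          insert <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
          mols[idx[k]] <- paste0(substr(wt, 1L, cut), insert, substr(wt, cut + 1L, nchar(wt)))
          detail[idx[k]] <- sprintf("nhej_ins:%d+%d", cut, L)
        }
      }
    }

    mlen <- nchar(mols)
    r1 <- substr(mols, 1L, pmin(config$read_len, mlen))
    r2 <- rc(substr(mols, pmax(1L, mlen - config$read_len + 1L), mlen))
    r1 <- inject_errors(r1, config$per_base_error)
    r2 <- inject_errors(r2, config$per_base_error)
    qc <- intToUtf8(config$quality_mean + 33L)
    ids <- sprintf("sim_%07d", seq_len(n))
    out <- list(
      r1 = data.frame(
        id = ids, seq = r1, qual = strrep(qc, nchar(r1)),
        stringsAsFactors = FALSE
      ),
      r2 = data.frame(
        id = ids, seq = r2, qual = strrep(qc, nchar(r2)),
        stringsAsFactors = FALSE
      ),
      truth = data.frame(
        read_id = ids, true_class = classes, detail = detail,
        stringsAsFactors = FALSE
      ),
      locus = locus, edit = edit, config = config
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fastq(out$r1, file.path(out_dir, "R1.fastq"))
      write_fastq(out$r2, file.path(out_dir, "R2.fastq"))
      write.table(out$truth, file.path(out_dir, "truth.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      write_locus_config(locus, edit, file.path(out_dir, "locus.yaml"))
    }
    out
  })
}

# Candidate (pos, alt) pairs for secondary non-synonymous substitutions:
# non-wobble positions of complete CDS codons lying entirely outside the
# guide window [lo, hi], mutated so that the encoded amino acid changes.
#' @noRd
secondary_sub_pool <- function(locus, lo, hi) {
  out <- list()
  p <- locus$cds[1]
  while (p <= locus$cds[2]) {
    info <- codon_info(locus, p)
    if (is.null(info) || info$pos_in_codon != 1L) {
      p <- p + 1L
      next
    }
    span <- info$top_span
    if (span[2] < lo || span[1] > hi) {
      old_aa <- Biostrings::GENETIC_CODE[[info$codon]]
      for (j in 1:2) {
        pos <- if (locus$cds_strand == "+") span[1] + j - 1L else span[2] - j + 1L
        ref <- substr(locus$amplicon_seq, pos, pos)
        for (alt in setdiff(DNA_BASES, ref)) {
          codon <- info$codon
          substr(codon, j, j) <- if (locus$cds_strand == "+") alt else rc(alt)
          if (Biostrings::GENETIC_CODE[[codon]] != old_aa) {
            out[[length(out) + 1L]] <- data.frame(
              pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    p <- span[2] + 1L
  }
  if (length(out)) do.call(rbind, out) else data.frame(
    pos = integer(), ref = character(), alt = character(),
    stringsAsFactors = FALSE
  )
}

#' @noRd
inject_errors <- function(seqs, rate) {
  if (rate <= 0) {
    return(seqs)
  }
  lens <- nchar(seqs)
  k <- rbinom(length(seqs), lens, rate)
  for (i in which(k > 0L)) {
    pos <- sample.int(lens[i], k[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  seqs
}

#' Map simulation truth classes to classifier categories
#'
#' The generator's five molecule classes collapse onto the four classifier
#' categories: NHEJ indels destroy the guide-window pattern and are expected
#' to be called `Others`; both incorrect-HDR classes are expected to be
#' called `Incorrect_HDR`.
#'
#' @param true_class Character vector of simulation classes.
#' @return Character vector of expected categories.
#' @export
truth_to_category <- function(true_class) {
  map <- c(
    WT = "WT", Correct_HDR = "Correct_HDR",
    Incorrect_HDR_substitution = "Incorrect_HDR",
    Incorrect_HDR_indel = "Incorrect_HDR",
    NHEJ_indel = "Others"
  )
  unname(map[true_class])
}
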