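# Structured configuration IO: locus + edit specifications as YAML, with the
# amplicon either inline or in a FASTA file referenced by path. All
# coordinates in config files are 1-based closed, matching the package.

#' Write a locus + edit configuration
#'
#' @param locus A [reference_locus()].
#' @param edit An [edit_spec()].
#' @param path Output YAML path.
#' @param fasta Optional path for the amplicon FASTA; when `NULL` the
#'   sequence is stored inline in the YAML.
#' @export
write_locus_config <- function(locus, edit, path, fasta = NULL) {
  loc <- list(
    gene_name = locus$gene_name,
    cds = as.list(locus$cds),
    cds_frame = locus$cds_frame,
    cds_strand = locus$cds_strand,
    protospacer = as.list(locus$protospacer),
    pam = as.list(locus$pam),
    guide_strand = locus$guide_strand
  )
  if (is.null(fasta)) {
    loc$amplicon_seq <- locus$amplicon_seq
  } else {
    write_fasta(setNames(locus$amplicon_seq, locus$gene_name), fasta)
    loc$amplicon_fasta <- fasta
  }
  ed <- list(
    substitutions = lapply(seq_len(nrow(edit$substitutions)), function(i) {
      as.list(edit$substitutions[i, ])
    }),
    expected_residue_changes = lapply(
      seq_len(nrow(edit$expected_residue_changes)),
      function(i) as.list(edit$expected_residue_changes[i, ])
    ),
    introduced_enzyme = edit$introduced_enzyme
  )
  yaml::write_yaml(list(locus = loc, edit = ed), path)
  invisible(path)
}

#' Read a locus + edit configuration
#'
#' @param path YAML path written by [write_locus_config()] (or by hand, same
#'   schema). A relative `amplicon_fasta` path is resolved against the YAML's
#'   directory.
#' @return A list with elements `locus` and `edit`.
#' @export
read_locus_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  loc <- cfg$locus
  seq <- loc$amplicon_seq
  if (is.null(seq)) {
    fp <- loc$amplicon_fasta
    if (!file.exists(fp)) fp <- file.path(dirname(path), fp)
    seq <- as.character(Biostrings::readDNAStringSet(fp)[[1]])
  }
  locus <- reference_locus(
    gene_name = loc$gene_name, amplicon_seq = seq,
    cds = unlist(loc$cds), cds_frame = loc$cds_frame,
    cds_strand = loc$cds_strand,
    protospacer = unlist(loc$protospacer), pam = unlist(loc$pam),
    guide_strand = loc$guide_strand
  )
  subs <- do.call(rbind, lapply(cfg$edit$substitutions, as.data.frame))
  erc <- if (length(cfg$edit$expected_residue_changes)) {
    do.call(rbind, lapply(cfg$edit$expected_residue_changes, as.data.frame))
  } else {
    NULL
  }
  edit <- edit_spec(subs, erc,
    introduced_enzyme = cfg$edit$introduced_enzyme, locus = locus
  )
  list(locus = locus, edit = edit)
}

#' Write donor templates as FASTA
#'
#' Headers encode kind, arm lengths and strand
#' (`name|kind|arms=left/right|strand`).
#'
#' @param donors Named list of `donor_template` objects.
#' @param path Output FASTA path.
#' @export
write_donor_fasta <- function(donors, path) {
  seqs <- vapply(donors, `[[`, character(1), "sequence")
  names(seqs) <- vapply(seq_along(donors), function(i) {
    d <- donors[[i]]
    nm <- names(donors)[i] %||% sprintf("donor%d", i)
    sprintf(
      "%s|%s|arms=%d/%d|%s", nm, d$donor_kind, d$left_arm_len,
      d$right_arm_len, d$strand
    )
  }, character(1))
  write_fasta(seqs, path)
}

#' Write Coding-bar candidates as TSV
#'
#' @param candidates A `coding_bar_candidates` list.
#' @param path Output TSV path.
#' @export
write_coding_bar_tsv <- function(candidates, path) {
  df <- do.call(rbind, lapply(candidates, function(cd) {
    data.frame(
      enzyme = cd$enzyme, site_position = cd$site_position,
      strand = cd$strand, n_changes = cd$n_changes,
      substitutions = paste(
        sprintf("%d%s>%s", cd$substitutions$pos, cd$substitutions$ref, cd$substitutions$alt),
        collapse = ";"
      ),
      stringsAsFactors = FALSE
    )
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
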