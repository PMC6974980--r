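# Restriction enzymes: a minimal REBASE-style table of named IUPAC
# recognition sites with top-strand cut offsets.

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition site (may contain degenerate codes).
#' @param cut_offset_top Number of bases 5' of the top-strand cut within the
#'   recognition site (e.g. 1 for `C^TCGAG`). `NA` means unknown; digestion
#'   then assumes a blunt mid-site cut.
#'
#' @return An object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top = NA_integer_) {
  recognition <- toupper(recognition)
  chars <- strsplit(recognition, "")[[1]]
  bad <- !chars %in% names(IUPAC_CODES)
  if (any(bad)) {
    stop("invalid IUPAC code '", chars[which(bad)[1]], "' in recognition site",
      call. = FALSE
    )
  }
  structure(
    list(
      name = as.character(name),
      recognition = recognition,
      cut_offset_top = as.integer(cut_offset_top)
    ),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf(
    "<restriction_enzyme> %s %s (cut offset %s)\n",
    x$name, x$recognition,
    if (is.na(x$cut_offset_top)) "unknown" else x$cut_offset_top
  ))
  invisible(x)
}

#' Load the bundled restriction enzyme table
#'
#' Reads the package's minimal enzyme table (name, IUPAC site, top-strand cut
#' offset), which includes the enzymes commonly used for knock-in genotyping
#' (XhoI, BamHI, PflFI `GACNNNGTC`, PvuI `CGATCG`, ...).
#'
#' @param path Path to a tab-separated enzyme table; defaults to the bundled
#'   one.
#' @return A named list of [restriction_enzyme()] objects.
#' @export
load_enzymes <- function(path = system.file("extdata", "restriction_enzymes.tsv",
                           package = "hdrquant"
                         )) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  enz <- lapply(seq_len(nrow(tab)), function(i) {
    restriction_enzyme(tab$name[i], tab$recognition[i], tab$cut_offset_top[i])
  })
  names(enz) <- tab$name
  enz
}

#' Look up one bundled enzyme by name
#'
#' @param name Enzyme name as listed in the bundled table.
#' @return A [restriction_enzyme()].
#' @export
get_enzyme <- function(name) {
  enz <- load_enzymes()
  if (!name %in% names(enz)) {
    stop(
      "unknown enzyme '", name, "'; bundled: ",
      paste(names(enz), collapse = ", "),
      call. = FALSE
    )
  }
  enz[[name]]
}
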