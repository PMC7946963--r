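#' Parse an annotated peptide sequence into a modified peptide
#'
#' Peptides carrying phosphorylation marks are written in one of two common
#' dialects: `"prefix_p"`, where a lowercase `p` precedes the modified
#' residue (`"SDDpSDIVTLEPPK"`), and `"lowercase"`, where the modified
#' residue itself is lowercase (`"LNSSGSSEDsFVEIR"`). Both mark
#' phosphorylation of the following/flagged Ser, Thr or Tyr.
#'
#' @param text Annotated sequence string. Uppercase one-letter amino-acid
#'   codes, with phospho marks in either dialect.
#' @param dialect One of `"auto"`, `"prefix_p"`, `"lowercase"`. `"auto"`
#'   accepts both notations in the same string.
#' @param offset 1-based coordinate of the first residue in the parent
#'   protein (`numbering_offset`); used when reporting protein coordinates.
#'
#' @return A `fir_peptide`: residues, integer phospho positions (1-based,
#'   counting each residue once regardless of modification), and the
#'   numbering offset.
#' @examples
#' p <- parse_modified_sequence("SDDpSDIVTLEPPK")
#' length(p)          # 13 residues
#' phospho_sites(p)   # 4
#' @export
parse_modified_sequence <- function(text, dialect = c("auto", "prefix_p", "lowercase"),
                                    offset = 1L) {
  dialect <- match.arg(dialect)
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    abort("`text` must be a non-empty sequence string.", class = "firclaw_parse_error")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  residues <- character(0)
  phospho <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "p" && dialect %in% c("auto", "prefix_p")) {
      nxt <- if (i < length(chars)) chars[i + 1L] else NA_character_
      if (is.na(nxt) || !nxt %in% c("S", "T", "Y")) {
        abort(sprintf("Position %d: 'p' must be followed by S, T or Y.", i),
              class = "firclaw_parse_error")
      }
      residues <- c(residues, nxt)
      phospho <- c(phospho, length(residues))
      i <- i + 2L
    } else if (ch %in% c("s", "t", "y") && dialect %in% c("auto", "lowercase")) {
      residues <- c(residues, toupper(ch))
      phospho <- c(phospho, length(residues))
      i <- i + 1L
    } else if (ch %in% AA_CODES) {
      residues <- c(residues, ch)
      i <- i + 1L
    } else {
      abort(sprintf("Position %d: unrecognized character '%s'.", i, ch),
            class = "firclaw_parse_error")
    }
  }
  new_fir_peptide(residues, phospho, offset)
}

new_fir_peptide <- function(residues, phospho = integer(0), offset = 1L) {
  stopifnot(all(residues %in% AA_CODES))
  phospho <- sort(unique(as.integer(phospho)))
  if (length(phospho) && (any(phospho < 1L) || any(phospho > length(residues)))) {
    abort("Phospho positions must lie within the peptide.",
          class = "firclaw_parse_error")
  }
  if (length(phospho) && !all(residues[phospho] %in% c("S", "T", "Y"))) {
    abort("Phosphorylation is only defined on S, T or Y residues.",
          class = "firclaw_parse_error")
  }
  structure(
    list(residues = residues, phospho = phospho, offset = as.integer(offset)),
    class = "fir_peptide"
  )
}

#' Construct a modified peptide from a plain sequence and phospho positions
#'
#' @param sequence Plain uppercase amino-acid string.
#' @param phospho Integer vector of 1-based phospho positions (S/T/Y only).
#' @param offset Parent-protein coordinate of residue 1.
#' @return A `fir_peptide`.
#' @export
fir_peptide <- function(sequence, phospho = integer(0), offset = 1L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_CODES)
  if (length(bad)) {
    abort(sprintf("Position %d: unrecognized character '%s'.", bad[1], chars[bad[1]]),
          class = "firclaw_parse_error")
  }
  new_fir_peptide(chars, phospho, offset)
}

#' Render a modified peptide back to an annotated string
#'
#' Inverse of [parse_modified_sequence()]: `parse(render(p))` returns `p`
#' in either dialect.
#'
#' @param p A `fir_peptide`.
#' @param dialect `"prefix_p"` or `"lowercase"`.
#' @return Single annotated string.
#' @export
render_modified_sequence <- function(p, dialect = c("prefix_p", "lowercase")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(p, "fir_peptide"))
  out <- p$residues
  if (length(p$phospho)) {
    if (dialect == "prefix_p") {
      out[p$phospho] <- paste0("p", out[p$phospho])
    } else {
      out[p$phospho] <- tolower(out[p$phospho])
    }
  }
  paste(out, collapse = "")
}

#' @export
length.fir_peptide <- function(x) length(x$residues)

#' @export
print.fir_peptide <- function(x, ...) {
  cat("<fir_peptide> ", render_modified_sequence(x), "\n", sep = "")
  cat(length(x), " residues; ", length(x$phospho), " phospho site(s)",
      if (length(x$phospho)) paste0(" at ", paste(x$phospho, collapse = ", ")),
      "; offset ", x$offset, "\n", sep = "")
  invisible(x)
}

#' @export
as.character.fir_peptide <- function(x, ...) render_modified_sequence(x)

#' @export
`==.fir_peptide` <- function(e1, e2) {
  identical(e1$residues, e2$residues) && identical(e1$phospho, e2$phospho)
}

#' Phosphorylated positions of a modified peptide
#' @param p A `fir_peptide`.
#' @return Integer vector of 1-based positions.
#' @export
phospho_sites <- function(p) p$phospho

is_phospho <- function(p, pos) pos %in% p$phospho

as_fir_peptide <- function(x, ...) {
  if (inherits(x, "fir_peptide")) x else parse_modified_sequence(x, ...)
}
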