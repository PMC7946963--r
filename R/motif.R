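#' FIR/LIR core motif grammar
#'
#' The consensus FIP200-Claw-binding FIR core is a five-residue window
#' psi-Theta-x-x-Gamma:
#' * psi — the anchor: acidic Asp/Glu, or phosphorylated Ser/Thr (Mode II).
#'   Unmodified Ser/Thr can be admitted as a *conditional* anchor (a site
#'   that would bind once phosphorylated). Phospho-Tyr never satisfies psi.
#' * Theta — bulky hydrophobic Ile/Leu/Val or aromatic Phe/Tyr/Trp; fills
#'   the large hydrophobic pocket (LHP) of the Claw.
#' * Gamma — small hydrophobic Leu/Ile/Val; docks the small hydrophobic
#'   groove (SHG).
#' Canonical LIR motifs are the aromatic-Theta subset of this grammar,
#' so every LIR hit is also a FIR hit.
#'
#' Each hit carries an *extension profile* over the residues immediately
#' N-terminal of psi (default window 4): counts of acidic residues,
#' phospho-S/T, and unmodified S/T. An acidic or phospho residue in that
#' window (`acidic_ok`) marks the preceding acidic stretch that supports
#' effective Claw binding; an S/T immediately before psi is flagged as an
#' `enhancer_site` (its phosphorylation further strengthens binding in
#' either mode).
#'
#' @name fir_grammar
NULL

PSI_ACIDIC <- c("D", "E")
THETA_ALIPHATIC <- c("I", "L", "V")
THETA_AROMATIC <- c("F", "Y", "W")
GAMMA_SET <- c("L", "I", "V")

#' Scan a peptide for FIR core motifs
#'
#' Reports every 5-residue window satisfying the psi-Theta-x-x-Gamma
#' grammar, in ascending position; overlapping hits are all reported.
#'
#' @param seq A `fir_peptide` or an annotated sequence string (parsed with
#'   [parse_modified_sequence()]).
#' @param allow_conditional If `TRUE`, unmodified Ser/Thr is admitted at
#'   psi and the hit is classed `conditional_II`.
#' @param window N-terminal extension window length preceding psi
#'   (truncated at the sequence start).
#' @param theta Theta residue class: `"fir"` (Ile/Leu/Val/Phe/Tyr/Trp) or
#'   `"lir"` (aromatic Phe/Tyr/Trp only).
#'
#' @return A tibble, one row per hit: `psi_pos` (1-based peptide index),
#'   `protein_pos` (psi_pos + offset - 1), `core` (5 residues, phospho in
#'   lowercase), `psi`, `psi_class` (`acidic`/`phospho`/`conditional`),
#'   `theta`, `theta_class` (`aliphatic`/`aromatic`), `gamma`, `mode`
#'   (`I`/`II`/`conditional_II`), extension counts `n_acidic`,
#'   `n_phospho`, `n_st_unmod`, and flags `acidic_ok`, `enhancer_site`.
#' @examples
#' scan_fir_cores("TASDDSDIVTLEPPK")           # Mode I hit at psi = D7
#' scan_fir_cores("SSEDpSFVEIRMAE")            # Mode II hit at psi = pS5
#' scan_fir_cores("CGWTVI")                    # no hit: no anchor before W
#' @export
scan_fir_cores <- function(seq, allow_conditional = FALSE, window = 4L,
                           theta = c("fir", "lir")) {
  theta <- match.arg(theta)
  p <- as_fir_peptide(seq)
  n <- length(p)
  theta_set <- if (theta == "lir") THETA_AROMATIC else c(THETA_ALIPHATIC, THETA_AROMATIC)
  hits <- list()
  if (n >= 5L) {
    for (i in seq_len(n - 4L)) {
      cls <- psi_class_at(p, i, allow_conditional)
      if (is.na(cls)) next
      th <- p$residues[i + 1L]
      if (!th %in% theta_set) next
      gm <- p$residues[i + 4L]
      if (!gm %in% GAMMA_SET) next
      hits[[length(hits) + 1L]] <- fir_match_row(p, i, cls, th, gm, window)
    }
  }
  if (!length(hits)) return(empty_fir_matches())
  bind_rows(hits)
}

#' Scan a peptide for canonical LIR cores
#'
#' The LIR grammar is the aromatic-Theta restriction of the FIR grammar
#' (Theta in Phe/Tyr/Trp); every LIR hit is therefore also a FIR hit.
#'
#' @inheritParams scan_fir_cores
#' @return Same shape as [scan_fir_cores()].
#' @export
scan_lir_cores <- function(seq, allow_conditional = FALSE, window = 4L) {
  scan_fir_cores(seq, allow_conditional = allow_conditional,
                 window = window, theta = "lir")
}

psi_class_at <- function(p, i, allow_conditional) {
  res <- p$residues[i]
  if (res %in% PSI_ACIDIC) return("acidic")
  if (res %in% c("S", "T")) {
    if (is_phospho(p, i)) return("phospho")   # pY excluded by construction
    if (allow_conditional) return("conditional")
  }
  NA_character_
}

fir_match_row <- function(p, i, psi_class, th, gm, window) {
  core_res <- p$residues[i:(i + 4L)]
  core_mod <- (i:(i + 4L)) %in% p$phospho
  core_res[core_mod] <- tolower(core_res[core_mod])
  ext <- extension_profile(p, i, window)
  prev <- if (i > 1L) p$residues[i - 1L] else NA_character_
  tibble(
    psi_pos = i,
    protein_pos = i + p$offset - 1L,
    core = paste(core_res, collapse = ""),
    psi = if (core_mod[1]) core_res[1] else p$residues[i],
    psi_class = psi_class,
    theta = th,
    theta_class = if (th %in% THETA_AROMATIC) "aromatic" else "aliphatic",
    gamma = gm,
    mode = switch(psi_class, acidic = "I", phospho = "II",
                  conditional = "conditional_II"),
    window = as.integer(ext$window),
    n_acidic = ext$n_acidic,
    n_phospho = ext$n_phospho,
    n_st_unmod = ext$n_st_unmod,
    acidic_ok = ext$acidic_ok,
    enhancer_site = !is.na(prev) && prev %in% c("S", "T")
  )
}

extension_profile <- function(p, psi_pos, window = 4L) {
  lo <- max(1L, psi_pos - as.integer(window))
  idx <- if (psi_pos > 1L) lo:(psi_pos - 1L) else integer(0)
  res <- p$residues[idx]
  ph <- idx %in% p$phospho
  n_acidic <- sum(res %in% PSI_ACIDIC)
  n_phospho <- sum(ph & res %in% c("S", "T"))
  n_st_unmod <- sum(!ph & res %in% c("S", "T"))
  list(window = length(idx), n_acidic = n_acidic, n_phospho = n_phospho,
       n_st_unmod = n_st_unmod, acidic_ok = (n_acidic + n_phospho) >= 1L)
}

empty_fir_matches <- function() {
  tibble(
    psi_pos = integer(0), protein_pos = integer(0), core = character(0),
    psi = character(0), psi_class = character(0), theta = character(0),
    theta_class = character(0), gamma = character(0), mode = character(0),
    window = integer(0), n_acidic = integer(0), n_phospho = integer(0),
    n_st_unmod = integer(0), acidic_ok = logical(0), enhancer_site = logical(0)
  )
}

#' Classify scanned motif hits into binding modes with a rationale
#'
#' Mode follows the anchor class: acidic psi is Mode I
#' (phosphorylation-independent), phospho-S/T psi is Mode II
#' (phosphorylation-dependent), unmodified S/T psi is `conditional_II`.
#' The preceding acidic stretch is reported as a confidence flag rather
#' than a hard filter: a hit without any acidic/phospho residue in its
#' extension window is labeled `"core-only, low-confidence"` but keeps
#' its mode.
#'
#' @param matches A tibble from [scan_fir_cores()] or [scan_lir_cores()].
#' @return The input with `confidence` and `rationale` columns appended.
#' @export
classify_mode <- function(matches) {
  stopifnot(is.data.frame(matches))
  if (!nrow(matches)) {
    return(mutate(matches, confidence = character(0), rationale = character(0)))
  }
  mutate(matches,
    confidence = ifelse(.data$acidic_ok, "high", "core-only, low-confidence"),
    rationale = paste0(
      "psi=", .data$psi, " (", .data$psi_class, ") => mode ", .data$mode,
      "; extension ", .data$n_acidic, " acidic + ", .data$n_phospho,
      " phospho (acidic_ok=", .data$acidic_ok, ")",
      ifelse(.data$enhancer_site, "; S/T enhancer site precedes psi", "")
    )
  )
}

#' Scan a FASTA file (or named sequences) for FIR cores
#'
#' @param fasta Path to a FASTA file, or a named character vector of plain
#'   amino-acid sequences. Alignment-style headers (`>id/99-113`) set the
#'   record's numbering offset to the span start.
#' @param phospho Optional phospho annotations: a TSV path or data frame
#'   with columns `id` and `position` (1-based protein coordinates).
#'   Out-of-range positions raise a per-record warning and are skipped.
#' @param offsets Optional named integer vector giving the protein
#'   coordinate of each record's first residue (default 1).
#' @param allow_conditional,window Passed to [scan_fir_cores()].
#' @param theta `"fir"` or `"lir"` grammar.
#' @return A tibble: `id`, then the columns of [classify_mode()], ordered
#'   by record then position.
#' @export
scan_fasta <- function(fasta, phospho = NULL, offsets = NULL,
                       allow_conditional = FALSE, window = 4L,
                       theta = c("fir", "lir")) {
  theta <- match.arg(theta)
  seqs <- read_sequences(fasta)
  header_offsets <- attr(seqs, "offsets")
  ph <- read_phospho_table(phospho)
  out <- imap(seqs, function(s, id) {
    off <- if (!is.null(offsets) && id %in% names(offsets)) {
      as.integer(offsets[[id]])
    } else if (!is.null(header_offsets) && id %in% names(header_offsets)) {
      as.integer(header_offsets[[id]])
    } else 1L
    marks <- integer(0)
    if (!is.null(ph)) {
      rows <- ph[ph$id == id, , drop = FALSE]
      if (nrow(rows)) {
        local_pos <- rows$position - off + 1L
        ok <- local_pos >= 1L & local_pos <= nchar(s)
        if (any(ok)) {
          chars <- strsplit(s, "")[[1]][local_pos[ok]]
          ok2 <- chars %in% c("S", "T", "Y")
          if (any(!ok2)) {
            warn(sprintf("Record '%s': phospho position(s) %s are not S/T/Y; skipped.",
                         id, paste(rows$position[ok][!ok2], collapse = ", ")))
          }
          marks <- local_pos[ok][ok2]
        }
        if (any(!ok)) {
          warn(sprintf("Record '%s': phospho position(s) %s out of range; skipped.",
                       id, paste(rows$position[!ok], collapse = ", ")))
        }
      }
    }
    p <- fir_peptide(s, phospho = marks, offset = off)
    m <- scan_fir_cores(p, allow_conditional = allow_conditional,
                        window = window, theta = theta)
    if (nrow(m)) mutate(m, id = id, .before = 1) else NULL
  })
  out <- bind_rows(out)
  if (!nrow(out)) {
    return(mutate(classify_mode(empty_fir_matches()), id = character(0), .before = 1))
  }
  classify_mode(out)
}

read_sequences <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    set <- Biostrings::readAAStringSet(fasta)
    seqs <- as.character(set)
    # keep first token of the header as record id, as scanners usually do;
    # an alignment-style "id/start-end" suffix sets the numbering offset
    ids <- sub("\\s.*$", "", names(seqs))
    span <- regmatches(ids, regexec("^(.*)/(\\d+)-(\\d+)$", ids))
    offs <- integer(0)
    for (k in seq_along(span)) {
      if (length(span[[k]])) {
        ids[k] <- span[[k]][2]
        offs[ids[k]] <- as.integer(span[[k]][3])
      }
    }
    names(seqs) <- ids
    if (length(offs)) attr(seqs, "offsets") <- offs
    return(seqs)
  }
  if (is.character(fasta)) {
    if (length(fasta) == 1 && is.null(names(fasta)) && grepl("[./\\\\]", fasta)) {
      abort(sprintf("Cannot read FASTA file '%s': no such file.", fasta))
    }
    if (is.null(names(fasta)) && length(fasta) > 0) {
      names(fasta) <- paste0("seq", seq_along(fasta))
    }
    return(fasta)
  }
  abort("`fasta` must be a file path or a named character vector.")
}

read_phospho_table <- function(phospho) {
  if (is.null(phospho)) return(NULL)
  tab <- if (is.character(phospho)) {
    readr::read_tsv(phospho, col_types = readr::cols(
      id = readr::col_character(), position = readr::col_integer()))
  } else {
    as_tibble(phospho)
  }
  stopifnot(all(c("id", "position") %in% names(tab)))
  tab
}
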