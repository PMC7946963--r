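#' Mass constants for peptide arithmetic
#'
#' Monoisotopic residue masses (Da) for the 20 standard amino acids, plus
#' the constants used throughout: water 18.010565 Da, proton 1.007276 Da,
#' and the phosphate adduct HPO3 79.966331 Da. Monoisotopic (not average)
#' masses are used throughout, matching high-resolution Orbitrap work.
#'
#' @format Named numeric vector (`RESIDUE_MASS`) and scalars.
#' @name mass_constants
NULL

RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MASS_PHOSPHO <- 79.966331

#' Monoisotopic mass of a (phospho)peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus 79.966331 Da
#' per phospho mark.
#'
#' @param p A `fir_peptide` or annotated sequence string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("G")                 # 75.03203
#' monoisotopic_mass("LNSSGSSEDsFVEIR")   # doubly protonated: m/z 853.87
#' @export
monoisotopic_mass <- function(p) {
  p <- as_fir_peptide(p)
  unknown <- setdiff(p$residues, names(RESIDUE_MASS))
  if (length(unknown)) {
    abort(sprintf("No monoisotopic mass for residue(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  sum(RESIDUE_MASS[p$residues]) + MASS_WATER + MASS_PHOSPHO * length(p$phospho)
}

#' m/z of a charged ion
#'
#' `(mass + z * 1.007276) / z` for protonated species `[M+zH]^z+`.
#'
#' @param mass Neutral mass (Da).
#' @param z Positive integer charge.
#' @return m/z in Thomson.
#' @export
mz <- function(mass, z = 1L) {
  if (any(z <= 0)) abort("Charge `z` must be >= 1.")
  (mass + z * MASS_PROTON) / z
}

#' Theoretical b/y fragment ladder of a peptide
#'
#' All b_i and y_i ions for i in 1..n-1 at the requested charges (HCD
#' b/y series only; no neutral losses). `contains_mod` marks ions whose
#' residue span includes a phospho site, the ions that localize the site.
#'
#' @param p A `fir_peptide` or annotated string; length >= 2.
#' @param charges Integer vector of charges.
#' @return A tibble: `series` (`"b"`/`"y"`), `index`, `charge`, `mz`,
#'   `contains_mod`, and the residue span `start`,`end` (1-based).
#' @examples
#' fragment_ladder("LNSSGSSEDsFVEIR")  # y6 carries the phosphate
#' @export
fragment_ladder <- function(p, charges = 1L) {
  p <- as_fir_peptide(p)
  n <- length(p)
  if (n < 2L) abort("Fragment ladders need at least 2 residues.")
  res_mass <- unname(RESIDUE_MASS[p$residues])
  res_mass[p$phospho] <- res_mass[p$phospho] + MASS_PHOSPHO
  csum <- cumsum(res_mass)
  total <- csum[n]
  idx <- seq_len(n - 1L)
  b_neutral <- csum[idx]                          # b_i: residues 1..i, no water
  y_neutral <- total - csum[n - idx] + MASS_WATER # y_i: last i residues + water
  grid <- tidyr::expand_grid(index = idx, charge = as.integer(charges))
  b <- mutate(grid,
    series = "b", start = 1L, end = .data$index,
    mz = (b_neutral[.data$index] + .data$charge * MASS_PROTON) / .data$charge)
  y <- mutate(grid,
    series = "y", start = n - .data$index + 1L, end = n,
    mz = (y_neutral[.data$index] + .data$charge * MASS_PROTON) / .data$charge)
  out <- bind_rows(b, y)
  out$contains_mod <- map_lgl(seq_len(nrow(out)), function(k) {
    any(p$phospho >= out$start[k] & p$phospho <= out$end[k])
  })
  arrange(select(out, "series", "index", "charge", "mz", "contains_mod",
                 "start", "end"),
          .data$series, .data$index, .data$charge)
}

#' Annotate a peak list against a theoretical fragment ladder
#'
#' Each ladder ion is matched to the nearest peak within tolerance
#' (tie-break: smallest absolute m/z error, then higher intensity).
#' `site_support` counts matched ions that are *site-determining*: ions
#' whose residue span separates the annotated phospho site from at least
#' one alternative S/T/Y placement, so observing them localizes the site.
#'
#' @param ladder Tibble from [fragment_ladder()].
#' @param peaks Data frame (or CSV path) with columns `mz`, `intensity`.
#' @param tol Match tolerance, > 0.
#' @param tol_unit `"ppm"` or `"Da"`.
#' @param peptide Optional `fir_peptide` the ladder came from; required to
#'   compute `site_support` (candidate sites = all S/T/Y residues).
#' @return A list with `annotations` (ladder with matched `obs_mz`,
#'   `intensity`, `error` columns; unmatched ions have `NA`) and
#'   `site_support` (integer, `NA` when `peptide` is absent).
#' @export
match_peaks <- function(ladder, peaks, tol = 10, tol_unit = c("ppm", "Da"),
                        peptide = NULL) {
  tol_unit <- match.arg(tol_unit)
  if (tol <= 0) abort("`tol` must be > 0.")
  if (is.character(peaks)) {
    peaks <- readr::read_csv(peaks, col_types = readr::cols())
  }
  peaks <- as_tibble(peaks)
  ann <- as_tibble(ladder)
  ann$obs_mz <- NA_real_
  ann$intensity <- NA_real_
  ann$error <- NA_real_
  if (nrow(peaks)) {
    for (k in seq_len(nrow(ann))) {
      lim <- if (tol_unit == "ppm") ann$mz[k] * tol * 1e-6 else tol
      d <- abs(peaks$mz - ann$mz[k])
      ok <- which(d <= lim)
      if (!length(ok)) next
      best <- ok[order(d[ok], -peaks$intensity[ok])][1]
      ann$obs_mz[k] <- peaks$mz[best]
      ann$intensity[k] <- peaks$intensity[best]
      ann$error[k] <- peaks$mz[best] - ann$mz[k]
    }
  }
  support <- NA_integer_
  if (!is.null(peptide)) {
    p <- as_fir_peptide(peptide)
    candidates <- which(p$residues %in% c("S", "T", "Y"))
    determining <- map_lgl(seq_len(nrow(ann)), function(k) {
      inside <- candidates >= ann$start[k] & candidates <= ann$end[k]
      any(inside) && any(!inside)   # span separates candidate placements
    })
    support <- sum(determining & !is.na(ann$obs_mz))
  }
  list(annotations = ann, site_support = support)
}
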