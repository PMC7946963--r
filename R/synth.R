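#' Synthetic inputs with truth tables
#'
#' Seeded generators for every input class the pipeline consumes:
#' random proteomes with implanted FIR cores, FP titrations from stated
#' affinities, MS peak lists from theoretical ladders, and toy
#' coordinate sets with known geometry. Each generator emits the
#' generating truth alongside the data (never embedded in it), so every
#' downstream stage can be scored without external references.
#'
#' @name synth
NULL

#' Generate a random proteome with implanted FIR cores
#'
#' Background residues are drawn uniformly over the 20 amino acids (no
#' attempt to mimic disorder propensity). Each record gets one implanted
#' core of the requested mode at a known position, preceded by an acidic
#' doublet so the extension profile is informative. Accidental cores
#' elsewhere in the background are possible and are *not* suppressed;
#' the truth table records the implants only.
#'
#' @param n Number of records.
#' @param length Record length (>= 10).
#' @param modes Modes to implant, recycled over records: `"I"`, `"II"`,
#'   or `"conditional_II"`.
#' @param seed RNG seed.
#' @return List with `sequences` (named character, plain letters),
#'   `phospho` (tibble `id`, `position` for Mode II implants) and
#'   `truth` (tibble `id`, `psi_pos`, `mode`, `core`).
#' @export
gen_motif_fasta <- function(n = 10, length = 200, modes = c("I", "II"),
                            seed = 1L) {
  stopifnot(length >= 10, n >= 1)
  modes <- rep_len(modes, n)
  with_preserved_seed(seed, {
    seqs <- character(n)
    truth <- list()
    phospho <- list()
    for (k in seq_len(n)) {
      id <- sprintf("synth%03d", k)
      bg <- sample(AA_CODES, length, replace = TRUE)
      # implant: ..acidic doublet.. psi Theta x x Gamma
      pos <- sample(seq(5, length - 4), 1)   # psi position, room for extension
      mode <- modes[k]
      psi <- switch(mode, I = sample(c("D", "E"), 1),
                    II = sample(c("S", "T"), 1),
                    conditional_II = sample(c("S", "T"), 1))
      core <- c(psi,
                sample(c(THETA_ALIPHATIC, THETA_AROMATIC), 1),
                sample(AA_CODES, 2, replace = TRUE),
                sample(GAMMA_SET, 1))
      bg[pos:(pos + 4)] <- core
      bg[(pos - 2):(pos - 1)] <- sample(c("D", "E"), 2, replace = TRUE)
      seqs[k] <- paste(bg, collapse = "")
      names(seqs)[k] <- id
      if (mode == "II") {
        phospho[[length(phospho) + 1L]] <- tibble(id = id, position = pos)
      }
      core_str <- core
      if (mode == "II") core_str[1] <- tolower(core_str[1])
      truth[[k]] <- tibble(id = id, psi_pos = pos, mode = mode,
                           core = paste(core_str, collapse = ""))
    }
    list(sequences = seqs,
         phospho = if (length(phospho)) bind_rows(phospho) else
           tibble(id = character(0), position = integer(0)),
         truth = bind_rows(truth))
  })
}

#' Titration presets carrying the study's measured affinities
#'
#' Named one-site FP titration scenarios. The truth Kd of each preset is
#' the corresponding measured affinity: phospho-Optineurin LIR vs FIP200
#' Claw ~12 uM, unphosphorylated Optineurin LIR ~307 uM, phospho-CCPG1
#' FIR2 vs GABARAP ~9 uM, unphosphorylated CCPG1 FIR2 vs GABARAP ~27 uM.
#' All use the FITC-peptide working concentration Lt = 0.25 uM and 12
#' two-fold-spaced protein concentrations (0.5-1024 uM; the weak
#' 307 uM preset extends to 2048 uM so the curve approaches
#' saturation), 3 replicates, and Gaussian noise of 1% of the signal
#' span by default.
#'
#' @param name One of `"pOPTN_FIP200"`, `"OPTN_FIP200"`,
#'   `"pCCPG1_GABARAP"`, `"CCPG1_GABARAP"`.
#' @param seed RNG seed.
#' @param noise_frac Noise SD as a fraction of `A_bound - A_free`.
#' @param replicates Replicate curves.
#' @return A `titration_curve` (see [simulate_titration()]); the preset
#'   truth is in `attr(x, "truth")`.
#' @export
gen_titration_preset <- function(name = c("pOPTN_FIP200", "OPTN_FIP200",
                                          "pCCPG1_GABARAP", "CCPG1_GABARAP"),
                                 seed = 1L, noise_frac = 0.01,
                                 replicates = 3L) {
  name <- match.arg(name)
  kd <- c(pOPTN_FIP200 = 12, OPTN_FIP200 = 307,
          pCCPG1_GABARAP = 9, CCPG1_GABARAP = 27)[[name]]
  Pt <- if (name == "OPTN_FIP200") 2^(0:11) else 0.5 * 2^(0:11)
  A_free <- 50; A_bound <- 250
  curve <- simulate_titration(
    Kd = kd, Pt = Pt, Lt = 0.25, A_free = A_free, A_bound = A_bound,
    noise_sd = noise_frac * (A_bound - A_free),
    replicates = replicates, seed = seed)
  attr(curve, "truth")$preset <- name
  curve
}

#' Generate a synthetic peak list from a fragment ladder
#'
#' Samples a fraction of the theoretical b/y ions, jitters them within
#' the stated ppm, and adds decoy peaks kept more than three times the
#' tolerance away from every true ion.
#'
#' @param p A `fir_peptide` or annotated string.
#' @param fraction Fraction of ladder ions planted, in (0, 1].
#' @param decoys Number of decoy peaks.
#' @param jitter_ppm Maximum |jitter| applied to planted peaks (ppm).
#' @param charges Ladder charges.
#' @param seed RNG seed.
#' @return List with `peaks` (tibble `mz`, `intensity`) and `truth`
#'   (planted ladder subset plus `decoy_count`).
#' @export
gen_spectrum <- function(p, fraction = 0.8, decoys = 20, jitter_ppm = 5,
                         charges = 1L, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  p <- as_fir_peptide(p)
  ladder <- fragment_ladder(p, charges)
  with_preserved_seed(seed, {
    n_plant <- max(1L, round(fraction * nrow(ladder)))
    planted <- ladder[sort(sample(nrow(ladder), n_plant)), ]
    jit <- stats::runif(n_plant, -jitter_ppm, jitter_ppm) * 1e-6 * planted$mz
    peaks <- tibble(mz = planted$mz + jit,
                    intensity = stats::runif(n_plant, 1e3, 1e5))
    lo <- min(ladder$mz) * 0.8
    hi <- max(ladder$mz) * 1.2
    guard <- 3 * jitter_ppm * 1e-6 * hi
    dec <- numeric(0)
    while (length(dec) < decoys) {
      cand <- stats::runif(decoys, lo, hi)
      ok <- map_lgl(cand, function(m) all(abs(ladder$mz - m) > guard))
      dec <- c(dec, cand[ok])[seq_len(min(decoys, length(dec) + sum(ok)))]
    }
    if (length(dec)) {
      peaks <- bind_rows(peaks, tibble(mz = dec,
                                       intensity = stats::runif(length(dec), 1e2, 5e3)))
    }
    peaks <- arrange(peaks, .data$mz)
    list(peaks = peaks,
         truth = list(planted = planted, decoy_count = length(dec),
                      jitter_ppm = jitter_ppm, seed = seed))
  })
}

#' Toy coordinate fixtures with known geometry
#'
#' Three synthetic structures for exercising the interface machinery:
#' * `sphere_pair` — two isolated carbon atoms at a given separation
#'   (analytic SASA known; zero buried area when far apart).
#' * `beta_pair` — two idealized antiparallel strands whose backbone N/O
#'   atoms form a regular hydrogen-bond ladder (N...O 2.9 A).
#' * `claw_mock` — a labeled mock of the Claw FIR-docking site: pocket
#'   residues carrying the deposited numbering (Y1564...F1582) arranged
#'   around two sites, with a peptide chain placing Ile 106 in the LHP
#'   and Leu 109 in the SHG, plus a Lys/phospho-Ser salt-bridge pair.
#'
#' @param kind `"sphere_pair"`, `"beta_pair"` or `"claw_mock"`.
#' @param separation Center distance for `sphere_pair` (A).
#' @param n_res Residues per strand for `beta_pair`.
#' @return List with `model` (a [structure_model()]) and `truth`
#'   (expected contacts/H-bond pairs or analytic areas).
#' @export
gen_toy_structure <- function(kind = c("sphere_pair", "beta_pair", "claw_mock"),
                              separation = 10, n_res = 6) {
  kind <- match.arg(kind)
  switch(kind,
    sphere_pair = toy_sphere_pair(separation),
    beta_pair = toy_beta_pair(n_res),
    claw_mock = toy_claw_mock()
  )
}

toy_sphere_pair <- function(separation) {
  model <- structure_model(tibble(
    chain = c("A", "B"), resno = c(1L, 1L), resid = "ALA",
    elety = "CA", x = c(0, separation), y = 0, z = 0, element = "C"))
  r <- VDW_RADII[["C"]] + 1.4
  list(model = model,
       truth = list(separation = separation,
                    isolated_area = 4 * pi * r^2,
                    solvent_radius = r))
}

toy_beta_pair <- function(n_res) {
  rows <- list()
  hb_truth <- list()
  for (i in seq_len(n_res)) {
    x0 <- 3.5 * i   # extended-strand rise per residue
    rows[[length(rows) + 1L]] <- tibble(
      chain = "A", resno = i, resid = "ALA",
      elety = c("N", "CA", "C", "O"),
      x = c(x0, x0 + 1.0, x0 + 2.1, x0 + 2.1),
      y = c(0, -1.0, 0, 1.3), z = 0,
      element = c("N", "C", "C", "O"))
    # strand B runs antiparallel above strand A; carbonyls face down
    rows[[length(rows) + 1L]] <- tibble(
      chain = "B", resno = 100L + (n_res - i + 1L), resid = "ALA",
      elety = c("N", "CA", "C", "O"),
      x = c(x0 + 2.1, x0 + 1.1, x0, x0),
      y = c(4.2, 5.2, 4.2, 2.9), z = 0,
      element = c("N", "C", "C", "O"))
    hb_truth[[length(hb_truth) + 1L]] <- tibble(
      donor = c(sprintf("A:%d:N", i), sprintf("B:%d:N", 100L + (n_res - i + 1L))),
      acceptor = c(sprintf("B:%d:O", 100L + (n_res - i + 1L)), sprintf("A:%d:O", i)),
      distance = 2.9)
  }
  list(model = structure_model(bind_rows(rows)),
       truth = list(hbonds = bind_rows(hb_truth), n_expected = 2L * n_res))
}

toy_claw_mock <- function() {
  lhp_def <- tibble(resno = LHP_RESIDUES,
                    resid = c("CYS", "ALA", "PHE", "VAL", "PHE"))
  shg_def <- tibble(resno = SHG_RESIDUES, resid = c("TYR", "LYS"))
  ring <- function(def, center) {
    k <- nrow(def)
    ang <- 2 * pi * (seq_len(k) - 1) / k
    bind_rows(lapply(seq_len(k), function(j) {
      cb <- center + c(3 * cos(ang[j]), 3 * sin(ang[j]), 0)
      ca <- center + c(4.5 * cos(ang[j]), 4.5 * sin(ang[j]), 0)
      tibble(chain = "A", resno = def$resno[j], resid = def$resid[j],
             elety = c("CA", "CB"),
             x = c(ca[1], cb[1]), y = c(ca[2], cb[2]), z = c(ca[3], cb[3]),
             element = "C")
    }))
  }
  claw <- bind_rows(
    ring(lhp_def, c(0, 0, 0)),
    ring(shg_def, c(10, 0, 0)),
    # K1569 side-chain amine positioned for a salt bridge with pSer phosphate
    tibble(chain = "A", resno = 1569L, resid = "LYS",
           elety = c("CA", "NZ"), x = c(5, 5), y = c(9, 7), z = 0,
           element = c("C", "N"))
  )
  peptide <- bind_rows(
    tibble(chain = "B", resno = 104L, resid = "SEP",
           elety = c("CA", "P", "O1P"), x = c(5, 5, 5), y = c(6, 4.5, 4.2),
           z = c(3, 3, 0.3), element = c("C", "P", "O")),
    tibble(chain = "B", resno = 105L, resid = "ASP",
           elety = "CA", x = 2.5, y = 5, z = 3, element = "C"),
    tibble(chain = "B", resno = 106L, resid = "ILE",
           elety = c("CA", "CB"), x = c(0, 0), y = c(3, 0), z = c(3, 1),
           element = "C"),
    tibble(chain = "B", resno = 109L, resid = "LEU",
           elety = c("CA", "CB"), x = c(10, 10), y = c(3, 0), z = c(3, 1),
           element = "C")
  )
  truth <- list(
    contacts = tibble(
      peptide_resno = c(106L, 109L),
      pocket = c("LHP", "SHG")),
    salt_bridge = tibble(cation_resno = 1569L, anion_resno = 104L)
  )
  list(model = structure_model(bind_rows(claw, peptide)), truth = truth)
}

#' Serialize a structure model to PDB text
#'
#' Writes ATOM records through bio3d so toy models round-trip through
#' [read_structure()].
#'
#' @param model A `structure_model`.
#' @param file Optional path; when `NULL` the lines are returned.
#' @return PDB lines (invisibly when `file` is given).
#' @export
write_structure <- function(model, file = NULL) {
  tmp <- file %||% tempfile(fileext = ".pdb")
  bio3d::write.pdb(
    file = tmp,
    xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(model)),
    resno = model$resno, resid = model$resid, eleno = model$eleno,
    elety = model$elety, chain = model$chain, o = model$o, b = model$b,
    elesy = model$element)
  lines <- readLines(tmp, warn = FALSE)
  if (is.null(file)) { unlink(tmp); return(lines) }
  invisible(lines)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of plain sequences.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(sequences, file) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}
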