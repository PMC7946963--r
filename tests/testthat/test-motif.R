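test_that("printed FIR/LIR peptides yield their known cores and modes", {
  ccpg1 <- scan_fir_cores("TASDDSDIVTLEPPK")
  expect_equal(nrow(ccpg1), 1)
  expect_equal(ccpg1$psi_pos, 7L)
  expect_equal(ccpg1$core, "DIVTL")
  expect_equal(ccpg1$mode, "I")
  expect_true(ccpg1$acidic_ok)
  expect_true(ccpg1$enhancer_site)   # S104-equivalent precedes the anchor

  optn <- scan_fir_cores("SSEDpSFVEIRMAE")
  expect_equal(nrow(optn), 1)
  expect_equal(optn$psi_pos, 5L)
  expect_equal(optn$core, "sFVEI")
  expect_equal(optn$mode, "II")
  expect_equal(optn$n_acidic, 2L)    # E and D in the extension window

  # canonical CCPG1 LIR has a Trp Theta but no acidic/phospho anchor at psi
  expect_equal(nrow(scan_fir_cores("CGWTVI")), 0)
  expect_equal(nrow(scan_fir_cores("CGWTVI", allow_conditional = TRUE)), 0)
})

test_that("conditional anchors are admitted only on request and promote on phosphorylation", {
  unmod <- scan_fir_cores("SSEDSFVEIRMAE")
  expect_equal(nrow(unmod), 0)
  cond <- scan_fir_cores("SSEDSFVEIRMAE", allow_conditional = TRUE)
  expect_equal(cond$mode, "conditional_II")
  expect_equal(cond$psi_pos, 5L)

  # phospho monotonicity: adding a mark never removes a strict hit,
  # and promotes conditional_II -> II at the marked anchor
  set.seed(21)
  for (k in 1:40) {
    p <- random_peptide(sample(5:80, 1), p_phospho = 0.2)
    before <- scan_fir_cores(p)
    sty <- setdiff(which(p$residues %in% c("S", "T")), p$phospho)
    if (!length(sty)) next
    p2 <- fir_peptide(paste(p$residues, collapse = ""),
                      phospho = sort(c(p$phospho, sty[sample(length(sty), 1)])))
    after <- scan_fir_cores(p2)
    expect_true(all(before$psi_pos %in% after$psi_pos))
  }
})

test_that("scanner matches the exhaustive window oracle on random sequences", {
  set.seed(31)
  for (k in 1:250) {
    p <- random_peptide(sample(5:120, 1))
    for (ac in c(FALSE, TRUE)) {
      expect_identical(
        scan_fir_cores(p, allow_conditional = ac)$psi_pos,
        oracle_scan_positions(p$residues, p$phospho, ac, "fir"),
        info = paste("seq", k))
      expect_identical(
        scan_lir_cores(p, allow_conditional = ac)$psi_pos,
        oracle_scan_positions(p$residues, p$phospho, ac, "lir"))
    }
  }
})

test_that("LIR hits are a subset of FIR hits on any input", {
  set.seed(41)
  for (k in 1:60) {
    p <- random_peptide(sample(5:150, 1))
    fir <- scan_fir_cores(p, allow_conditional = TRUE)$psi_pos
    lir <- scan_lir_cores(p, allow_conditional = TRUE)$psi_pos
    expect_true(all(lir %in% fir))
  }
  expect_equal(scan_lir_cores("SSEDpSFVEIRMAE")$theta_class, "aromatic")
  expect_equal(nrow(scan_lir_cores("TASDDSDIVTLEPPK")), 0)  # aliphatic Theta excluded
})

test_that("numbering offsets map anchors onto protein coordinates", {
  fir2 <- fir_peptide("TASDDSDIVTLEPPK", phospho = 6L, offset = 99L)
  expect_equal(scan_fir_cores(fir2)$protein_pos, 105L)   # CCPG1 D105
  lir <- fir_peptide("SSEDSFVEIRMAE", phospho = 5L, offset = 173L)
  expect_equal(scan_fir_cores(lir)$protein_pos, 177L)    # Optineurin pS177
})

test_that("classify_mode reports confidence without changing the mode", {
  hits <- classify_mode(scan_fir_cores("AAAADIVTLAAA"))   # bare core, no extension acidity
  expect_equal(hits$mode, "I")
  expect_equal(hits$confidence, "core-only, low-confidence")
  rich <- classify_mode(scan_fir_cores("TASDDSDIVTLEPPK"))
  expect_equal(rich$confidence, "high")
  expect_match(rich$rationale, "mode I")
})

test_that("scan_fasta reports per-record protein coordinates and skips bad phospho rows", {
  seqs <- c(CCPG1_FIR2 = "TASDDSDIVTLEPPK", OPTN_LIR = "SSEDSFVEIRMAE")
  ph <- data.frame(id = c("CCPG1_FIR2", "OPTN_LIR"), position = c(104L, 177L))
  rep <- scan_fasta(seqs, phospho = ph,
                    offsets = c(CCPG1_FIR2 = 99L, OPTN_LIR = 173L))
  expect_equal(nrow(rep), 2)
  expect_equal(rep$mode, c("I", "II"))
  expect_equal(rep$protein_pos, c(105L, 177L))

  expect_warning(
    rep2 <- scan_fasta(seqs, phospho = data.frame(id = "OPTN_LIR", position = 999L),
                       offsets = c(OPTN_LIR = 173L)),
    "out of range")
  expect_equal(sum(rep2$mode == "II"), 0)

  # empty input: empty report, no error
  empty <- scan_fasta(character(0))
  expect_equal(nrow(empty), 0)
})

test_that("scan_fasta recovers implanted motifs from the generator", {
  g <- gen_motif_fasta(n = 12, length = 150, modes = c("I", "II"), seed = 5L)
  rep <- scan_fasta(g$sequences, phospho = g$phospho)
  found <- dplyr::inner_join(g$truth, rep, by = c("id", "psi_pos" = "psi_pos"))
  expect_equal(nrow(found), nrow(g$truth))
  expect_equal(found$mode.x, found$mode.y)
  expect_equal(found$core.x, found$core.y)

  # with zero implants the scanner equals the oracle's incidental hits
  set.seed(6)
  for (k in 1:10) {
    res <- sample(c("A","C","G","H","K","M","N","P","Q","R"), 80, replace = TRUE)
    p <- fir_peptide(paste(res, collapse = ""))
    expect_identical(scan_fir_cores(p)$psi_pos,
                     oracle_scan_positions(res, integer(0), FALSE, "fir"))
  }
})
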