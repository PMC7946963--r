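# Expected values below were frozen from an independent proteomics mass
# calculator (and the glycine/"PEPTIDE" values are standard reference
# masses), not from this package.

test_that("monoisotopic masses match independent reference values", {
  expect_equal(monoisotopic_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("PEPTIDE"), 799.35996, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("LNSSGSSEDsFVEIR"), 1705.719625,
               tolerance = 1e-5)
  expect_error(monoisotopic_mass(fir_peptide("ACDG")), NA)
})

test_that("the phospho delta and charged-ion arithmetic are exact", {
  delta <- monoisotopic_mass("LNSSGSSEDsFVEIR") -
    monoisotopic_mass("LNSSGSSEDSFVEIR")
  expect_equal(delta, 79.966331, tolerance = 1e-9)

  m <- monoisotopic_mass("LNSSGSSEDsFVEIR")
  expect_equal(round(mz(m, 2), 2), 853.87)
  expect_equal(mz(1705.7196, 2), 853.867, tolerance = 1e-3)
  expect_equal(mz(500, 1) - 500, 1.007276)
  expect_lt(mz(500, 2), mz(500, 1))
  expect_error(mz(500, 0))
  # round trip mass = z*mz - z*proton
  expect_equal(2 * mz(m, 2) - 2 * 1.007276, m, tolerance = 1e-9)
})

test_that("additivity: mass(p + q) = mass(p) + mass(q) - water", {
  set.seed(8)
  for (k in 1:20) {
    p <- random_peptide(sample(2:15, 1))
    q <- random_peptide(sample(2:15, 1))
    pq <- fir_peptide(paste(c(p$residues, q$residues), collapse = ""),
                      phospho = c(p$phospho, q$phospho + length(p)))
    expect_equal(monoisotopic_mass(pq),
                 monoisotopic_mass(p) + monoisotopic_mass(q) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("fragment ladders localize the phosphosite and obey complementarity", {
  l <- fragment_ladder("LNSSGSSEDsFVEIR")
  y6 <- l[l$series == "y" & l$index == 6, ]
  expect_equal(y6$start, 10L)
  expect_true(y6$contains_mod)
  expect_equal(y6$mz, 830.3808, tolerance = 1e-4)   # independent oracle value
  b9 <- l[l$series == "b" & l$index == 9, ]
  expect_equal(b9$mz, 877.35338, tolerance = 1e-4)
  expect_false(any(l$contains_mod[l$series == "b" & l$index <= 9]))

  # b_i + y_(n-i) at 1+ equals M + 2 protons, randomized peptides
  set.seed(9)
  for (k in 1:60) {
    p <- random_peptide(sample(2:30, 1))
    M <- monoisotopic_mass(p)
    l <- fragment_ladder(p)
    n <- length(p)
    b <- l[l$series == "b", ]; y <- l[l$series == "y", ]
    expect_true(all(abs(b$mz[b$index] + y$mz[n - b$index] -
                          (M + 2 * 1.007276)) < 1e-4))
  }
  expect_error(fragment_ladder("G"), "at least 2")
})

test_that("peak matching recovers planted ions and rejects decoys", {
  p <- parse_modified_sequence("LNSSGSSEDsFVEIR")
  sp <- gen_spectrum(p, fraction = 1, decoys = 25, jitter_ppm = 5, seed = 3)
  ladder <- fragment_ladder(p)
  res <- match_peaks(ladder, sp$peaks, tol = 10, tol_unit = "ppm", peptide = p)
  expect_true(all(!is.na(res$annotations$obs_mz)))   # 100% planted recall
  expect_gt(res$site_support, 0)

  shifted <- dplyr::mutate(sp$peaks, mz = mz + 1)
  res1 <- match_peaks(ladder, shifted, tol = 10, tol_unit = "ppm", peptide = p)
  expect_true(all(is.na(res1$annotations$obs_mz)))

  decoys_only <- sp$peaks[-seq_len(nrow(ladder)), ]
  set.seed(2); dec <- tibble::tibble(mz = runif(30, 2000, 3000), intensity = 1)
  res2 <- match_peaks(ladder, dec, tol = 10, peptide = p)
  expect_equal(res2$site_support, 0L)

  res3 <- match_peaks(ladder, tibble::tibble(mz = numeric(0), intensity = numeric(0)),
                      tol = 10, peptide = p)
  expect_true(all(is.na(res3$annotations$obs_mz)))
})

test_that("peak ties break on smallest error then higher intensity", {
  ladder <- fragment_ladder("ACDEFG")[1:2, ]
  target <- ladder$mz[1]
  peaks <- tibble::tibble(
    mz = c(target + 2e-4, target, target),
    intensity = c(10, 5, 50))
  res <- match_peaks(ladder, peaks, tol = 0.01, tol_unit = "Da")
  # the two exact hits tie on error; higher intensity wins
  expect_equal(res$annotations$intensity[1], 50)
  expect_equal(res$annotations$error[1], 0)
})
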