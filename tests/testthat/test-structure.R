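test_that("PDB parsing resolves altlocs, drops waters, keeps phospho-residues", {
  toy <- gen_toy_structure("claw_mock")
  txt <- write_structure(toy$model)
  m <- read_structure(paste(txt, collapse = "\n"))
  expect_equal(nrow(m), nrow(toy$model))
  expect_true("SEP" %in% m$resid)
  expect_equal(max(abs(m$x - toy$model$x)), 0, tolerance = 1e-3)

  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   2       1.000   2.000   3.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   2       9.000   9.000   9.000  0.40  0.00           C",
    "HETATM    4  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O")
  m2 <- read_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(m2), 2)                     # water dropped, one altloc kept
  expect_equal(m2$x[m2$elety == "CA"], 1.000)   # highest occupancy (A) kept
  m3 <- read_structure(paste(lines, collapse = "\n"), keep_water = TRUE)
  expect_equal(nrow(m3), 3)
})

test_that("malformed records are reported with their line number", {
  bad <- c("REMARK ok",
           "ATOM      1  N   ALA A   1      11.104   6.134", # truncated
           "END")
  expect_error(read_structure(paste(bad, collapse = "\n")), "line 2")
  bad2 <- c("ATOM      1  N   ALA A   1      xx.xxx   6.134  -6.504  1.00  0.00")
  expect_error(read_structure(bad2), "line 1")
})

test_that("SASA reproduces closed-form sphere areas", {
  one <- structure_model(tibble::tibble(
    chain = "A", resno = 1L, resid = "ALA", elety = "CA",
    x = 0, y = 0, z = 0, element = "C"))
  s <- sasa(one, n_points = 960)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 1e-9)  # isolated C, probe 1.4

  far <- gen_toy_structure("sphere_pair", separation = 100)
  expect_equal(sasa(far$model, n_points = 960)$total,
               2 * far$truth$isolated_area, tolerance = 1e-9)

  expect_error(sasa(structure_model(tibble::tibble(
    chain = "A", resno = 1L, resid = "UNK", elety = "XX",
    x = 0, y = 0, z = 0, element = "X"))), "X")
})

test_that("two overlapping spheres agree with the spherical-cap formula", {
  for (d in c(2.0, 3.5, 5.0)) {
    pair <- gen_toy_structure("sphere_pair", separation = d)
    num <- sasa(pair$model, n_points = 3840)$total
    R <- pair$truth$solvent_radius
    exact <- 2 * two_sphere_accessible(R, R, d)
    expect_equal(num, exact, tolerance = 0.01)   # within 1% at 3840 points
  }
})

test_that("SASA agrees with an independent Monte Carlo oracle on a strand pair", {
  bp <- gen_toy_structure("beta_pair", n_res = 4)
  m <- bp$model
  xyz <- as.matrix(m[, c("x", "y", "z")])
  radii <- c(C = 1.70, N = 1.55, O = 1.52)[m$element]
  num <- sasa(m, n_points = 3840)$total
  oracle <- mc_sasa(xyz, radii, probe = 1.4, n_points = 8000)
  expect_equal(num, oracle, tolerance = 0.02)

  # occlusion never increases another atom's exposure
  solo <- sasa(m, sel = which(m$chain == "A"), n_points = 960)$per_atom$area
  joint <- sasa(m, n_points = 960)$per_atom$area[m$chain == "A"]
  expect_true(all(joint <= solo + 1e-9))
})

test_that("buried surface area is symmetric, decomposable, and zero at distance", {
  far <- gen_toy_structure("sphere_pair", separation = 100)
  b0 <- buried_surface(far$model, "A", "B", n_points = 960)
  expect_equal(b0$bsa_sum, 0, tolerance = 1e-9)

  bp <- gen_toy_structure("beta_pair")
  ab <- buried_surface(bp$model, "A", "B", n_points = 960)
  ba <- buried_surface(bp$model, "B", "A", n_points = 960)
  expect_gt(ab$bsa_sum, 0)
  expect_equal(ab$bsa_sum, ba$bsa_sum, tolerance = 1e-9)
  expect_equal(ab$bsa_half, ab$bsa_sum / 2)
  expect_equal(sum(ab$per_residue$buried), ab$bsa_sum, tolerance = 1e-9)
  expect_error(buried_surface(bp$model, "A", "A"), "disjoint")
})

test_that("interface reports are invariant under rigid motion", {
  bp <- gen_toy_structure("beta_pair")
  moved <- rigid_motion(bp$model)
  b1 <- buried_surface(bp$model, "A", "B", n_points = 960)
  b2 <- buried_surface(moved, "A", "B", n_points = 960)
  expect_equal(b1$bsa_sum, b2$bsa_sum, tolerance = 5e-3)

  h1 <- hydrogen_bonds(bp$model, "A", "B")
  h2 <- hydrogen_bonds(moved, "A", "B")
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$distance), sort(h2$distance), tolerance = 1e-9)

  cm <- gen_toy_structure("claw_mock")
  s1 <- salt_bridges(cm$model, "A", "B")
  s2 <- salt_bridges(rigid_motion(cm$model), "A", "B")
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(s1$distance, s2$distance, tolerance = 1e-9)
})

test_that("the ideal antiparallel strand pair shows its full backbone H-bond ladder", {
  bp <- gen_toy_structure("beta_pair")
  hb <- hydrogen_bonds(bp$model, "A", "B")
  expect_equal(nrow(hb), bp$truth$n_expected)
  expect_true(all(hb$class == "backbone-backbone"))
  expect_equal(sort(unique(round(hb$distance, 3))), 2.9)
  expect_equal(nrow(hydrogen_bonds(bp$model, "A", "B", d_max = 0.5)), 0)
})

test_that("salt bridges respect residue chemistry and the distance cutoff", {
  mk_pair <- function(d) structure_model(tibble::tibble(
    chain = c("A", "B"), resno = c(1L, 2L), resid = c("LYS", "ASP"),
    elety = c("NZ", "OD1"), x = c(0, d), y = 0, z = 0,
    element = c("N", "O")))
  expect_equal(nrow(salt_bridges(mk_pair(3.0), "A", "B")), 1)
  expect_equal(nrow(salt_bridges(mk_pair(5.0), "A", "B")), 0)

  cm <- gen_toy_structure("claw_mock")
  sb <- salt_bridges(cm$model, "A", "B")
  expect_equal(sb$cation_resno, cm$truth$salt_bridge$cation_resno)
  expect_equal(sb$anion_resno, cm$truth$salt_bridge$anion_resno)
  expect_equal(sb$anion_resid, "SEP")   # phosphate oxygen as anion
})

test_that("Kabsch superposition matches the quaternion oracle", {
  cm <- gen_toy_structure("claw_mock")$model
  expect_equal(superpose(cm, cm)$rmsd, 0, tolerance = 1e-12)

  moved <- rigid_motion(cm, angle = 1.3, axis = c(1, 2, 0.5), shift = c(3, 9, -2))
  sp <- superpose(cm, moved)
  expect_lt(sp$rmsd, 1e-6)

  set.seed(12)
  for (k in 1:10) {
    sigma <- runif(1, 0.1, 1.5)
    noisy <- moved
    noisy$x <- noisy$x + rnorm(nrow(noisy), 0, sigma)
    noisy$y <- noisy$y + rnorm(nrow(noisy), 0, sigma)
    noisy$z <- noisy$z + rnorm(nrow(noisy), 0, sigma)
    sp <- superpose(cm, noisy,
                    mapping = tibble::tibble(a = seq_len(nrow(cm)),
                                             b = seq_len(nrow(cm))))
    P <- as.matrix(cm[, c("x", "y", "z")])
    Q <- as.matrix(noisy[, c("x", "y", "z")])
    expect_equal(sp$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-8)
  }

  line <- structure_model(tibble::tibble(
    chain = "A", resno = 1:4, resid = "ALA", elety = "CA",
    x = 1:4, y = 0, z = 0, element = "C"))
  expect_error(superpose(line, line,
                         mapping = tibble::tibble(a = 1:4, b = 1:4)),
               "Degenerate")
})

test_that("pocket contacts recover the planted LHP/SHG docking", {
  cm <- gen_toy_structure("claw_mock")
  pc <- pocket_contacts(cm$model, "B")
  i106 <- pc[pc$peptide_resno == 106, ]
  expect_setequal(i106$claw_resno, c(1565, 1567, 1574, 1576, 1582))
  expect_true(all(i106$pocket == "LHP"))
  l109 <- pc[pc$peptide_resno == 109, ]
  expect_setequal(l109$claw_resno, c(1564, 1581))
  expect_true(all(l109$pocket == "SHG"))

  # peptide far away: empty table (pocket set still present)
  far <- cm$model
  bidx <- far$chain == "B"
  far$z[bidx] <- far$z[bidx] + 100
  expect_equal(nrow(pocket_contacts(far, "B")), 0)

  # missing pocket residues raise a warning naming them
  trimmed <- cm$model[cm$model$resno != 1582 | cm$model$chain != "A", ]
  expect_warning(pocket_contacts(trimmed, "B"), "1582")
})

test_that("the buried-area convention calibrates against a reference value", {
  bp <- gen_toy_structure("beta_pair")
  b <- buried_surface(bp$model, "A", "B", n_points = 960)
  expect_equal(calibrate_bsa_convention(b, b$bsa_sum * 1.02), "sum")
  expect_equal(calibrate_bsa_convention(b, b$bsa_half * 1.02), "half")
})
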