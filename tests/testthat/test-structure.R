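# Structure parsing, torsions, rings and hydrogen-bond detection.

test_that("PDB round trip preserves structures and model indexing", {
  h <- make_peptide(3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structures(h, f)
  h2 <- read_structure(f)
  expect_equal(length(unique(h2$atoms$resno)), 3)
  expect_equal(coords(h2), coords(h), tolerance = 1e-3, ignore_attr = TRUE)

  # two-model ensemble: model selection returns the right conformer
  hb <- set_coords(h, coords(h) + 1.0)
  write_structures(list(h, hb), f)
  m2 <- read_structure(f, model = 2)
  expect_equal(coords(m2), coords(hb), tolerance = 1e-3, ignore_attr = TRUE)
  ens <- read_ensemble(f)
  expect_length(ens, 2)
  expect_error(read_structure(f, model = 3), "2 model")
})

test_that("structures without explicit amide hydrogens are rejected", {
  h <- make_peptide(3)
  stripped <- h$atoms[h$atoms$elesy != "H", ]
  expect_error(as_structure(stripped), "no explicit hydrogens")
  expect_error(as_structure(stripped), "residue 2")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structures(as_structure(stripped, check = FALSE), f)
  expect_error(read_structure(f), "no explicit hydrogens")
})

test_that("backbone torsions match the angles the fixture was built at", {
  helix <- make_peptide(5, phi = -57, psi = -47)
  tor <- backbone_torsions(helix)
  expect_equal(tor$phi[2:5], rep(-57, 4), tolerance = 1e-6)
  expect_equal(tor$psi[1:4], rep(-47, 4), tolerance = 1e-6)
  expect_true(is.na(tor$phi[1]) && is.na(tor$psi[5]))

  strand <- make_peptide(5, phi = -139, psi = 135)
  tor <- backbone_torsions(strand, residue = 3)
  expect_equal(tor$phi, -139, tolerance = 1e-6)
  expect_equal(tor$psi, 135, tolerance = 1e-6)
})

test_that("degenerate collinear atoms give a dihedral error", {
  expect_error(
    amideshift:::dihedral4(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
    "collinear"
  )
})

test_that("torsions and bond geometry are invariant under rigid motions", {
  s <- make_peptide(sequence = "AAFSADA")
  s2 <- rigid_move(s)
  t1 <- backbone_torsions(s); t2 <- backbone_torsions(s2)
  expect_equal(t2$phi, t1$phi, tolerance = 1e-8)
  expect_equal(t2$psi, t1$psi, tolerance = 1e-8)
  h1 <- detect_hbonds(s); h2 <- detect_hbonds(s2)
  expect_equal(h2$r_ho, h1$r_ho, tolerance = 1e-8)
  expect_equal(h2$angle_nho, h1$angle_nho, tolerance = 1e-8)
  expect_equal(h2$angle_hoc, h1$angle_hoc, tolerance = 1e-8)
})

test_that("aromatic rings are found with correct multiplicity and planes", {
  expect_equal(find_rings(make_peptide(sequence = "AAFAA"))$kind, "PHE6")
  expect_setequal(find_rings(make_peptide(sequence = "AAWAA"))$kind,
                  c("TRP5", "TRP6"))
  expect_equal(find_rings(make_peptide(sequence = "AAHAA"))$kind, "HIS5")
  expect_equal(nrow(find_rings(make_peptide(4))), 0)

  # planar hexagon at known coordinates: SVD normal equals the edge cross
  # product direction to 1e-10
  ang <- seq(0, 300, by = 60) * pi / 180
  hexa <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  axis <- c(0.3, -0.5, 0.8)
  R <- amideshift:::rotation_about_axis(axis, 37)
  hexa <- hexa %*% t(R)
  atoms <- tibble::tibble(
    eleno = 1:6, elety = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    resid = "PHE", chain = "A", resno = 1L,
    x = hexa[, 1], y = hexa[, 2], z = hexa[, 3], elesy = "C"
  )
  s <- as_structure(atoms, check = FALSE)
  rg <- suppressWarnings(find_rings(s))
  nrm <- c(rg$nx, rg$ny, rg$nz)
  oracle <- amideshift:::vcross(hexa[2, ] - hexa[1, ], hexa[3, ] - hexa[2, ])
  oracle <- oracle / sqrt(sum(oracle^2))
  expect_lt(min(sum(abs(nrm - oracle)), sum(abs(nrm + oracle))), 1e-10)
  expect_equal(c(rg$cx, rg$cy, rg$cz), colMeans(hexa), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("incomplete rings are skipped with a warning", {
  s <- make_peptide(sequence = "AAFAA")
  s$atoms <- s$atoms[s$atoms$elety != "CZ", ]
  expect_warning(rg <- find_rings(s), "skipped")
  expect_equal(nrow(rg), 0)
})

test_that("ring normals are antipodally stable for the downstream |cos|", {
  s <- make_peptide(sequence = "AAFAA")
  rg1 <- find_rings(s)
  s2 <- s
  # reverse ring atom order
  ring_rows <- which(s2$atoms$elety %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  s2$atoms[ring_rows, ] <- s2$atoms[rev(ring_rows), ]
  rg2 <- find_rings(s2)
  n1 <- c(rg1$nx, rg1$ny, rg1$nz)
  n2 <- c(rg2$nx, rg2$ny, rg2$nz)
  expect_equal(abs(sum(n1 * n2)), 1, tolerance = 1e-10)
})

test_that("hydrogen-bond detection returns one gated record per amide proton", {
  helix <- make_peptide(12)
  hb <- detect_hbonds(helix)
  expect_equal(hb$resno, 2:12)           # residue 1 has no amide proton
  expect_equal(sum(hb$acceptor_class == "BACKBONE_AMIDE"), 8)
  # i -> i-4 pattern for interior donors
  bonded <- hb[hb$acceptor_class == "BACKBONE_AMIDE", ]
  expect_equal(bonded$acceptor_resno, bonded$resno - 4)

  # prolines are excluded from the donor list
  pro <- make_peptide(sequence = "AAPAA")
  expect_false(3 %in% detect_hbonds(pro)$resno)
})

test_that("exact dimer geometry is recovered and far acceptors gate to NONE", {
  d <- make_amide_dimer(1.9, 150, angle_nho = 170)
  hb <- detect_hbonds(d)
  probe <- hb[hb$resno == 12, ]
  expect_equal(probe$acceptor_class, "BACKBONE_AMIDE")
  expect_equal(probe$r_ho, 1.9, tolerance = 1e-6)
  expect_equal(probe$angle_nho, 170, tolerance = 1e-6)
  expect_equal(probe$angle_hoc, 150, tolerance = 1e-6)

  far <- detect_hbonds(make_amide_dimer(5, 150))
  expect_equal(far$acceptor_class[far$resno == 12], "NONE")
  expect_true(is.na(far$r_ho[far$resno == 12]))
})

test_that("the nearest gated acceptor wins across classes (brute-force oracle)", {
  # donor H at origin pointing +z to N; SER OG at 1.9 A, a distant-residue
  # backbone O at 2.4 A, both inside the gate
  og <- 1.9 * c(sin(30 * pi / 180), 0, -cos(30 * pi / 180))
  obb <- c(0, 0, -2.4)
  atoms <- tibble::tibble(
    eleno = 1:12,
    elety = c("N", "CA", "C", "O",            # residue 1 (far away)
              "N", "H", "CA",                 # residue 2: donor
              "CA", "CB", "OG",               # residue 3: SER acceptor
              "C", "O"),                      # residue 5: backbone acceptor
    resid = c(rep("ALA", 4), rep("ALA", 3), rep("SER", 3), rep("ALA", 2)),
    chain = "A",
    resno = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 5L, 5L),
    x = c(20, 21, 22, 23, 0, 0, 1.2, og[1] + 2.2, og[1] + 1.0, og[1],
          obb[1] + 1.23, obb[1]),
    y = c(20, 20, 20, 20, 0, 0, -0.5, og[2] + 1.2, og[2] + 1.0, og[2],
          obb[2], obb[2]),
    z = c(20, 20, 20, 20, 1.01, 0, 0.6, og[3] - 1.2, og[3] - 1.0, og[3],
          obb[3], obb[3]),
    elesy = c("N", "C", "C", "O", "N", "H", "C", "C", "C", "O", "C", "O")
  )
  s <- as_structure(atoms, check = FALSE)
  hb <- detect_hbonds(s)
  probe <- hb[hb$resno == 2, ]
  # brute-force oracle: minimum r_HO over all gate-passing candidates
  cand_r <- c(OG = sqrt(sum(og^2)), O = sqrt(sum(obb^2)))
  expect_equal(probe$acceptor_atom, names(which.min(cand_r)))
  expect_equal(probe$acceptor_class, "ALCOHOL")
  expect_equal(probe$r_ho, 1.9, tolerance = 1e-9)
})
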