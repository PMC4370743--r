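test_that("A-form generator produces the expected duplex geometry", {
  h <- generate_aform_helix(12)
  expect_equal(h$n_nucleotides, 24)
  expect_equal(nrow(h$phosphates), 24)

  h1 <- generate_aform_helix(1)
  expect_equal(h1$n_nucleotides, 2)
  expect_equal(nrow(h1$phosphates), 2)

  # consecutive intra-strand P-P distance: chord of the helical step,
  # sqrt((2 r sin(twist/2))^2 + rise^2), computed independently here
  chord <- sqrt((2 * 9.4 * sin(32.7 / 2 * pi / 180))^2 + 2.81^2)
  D <- pairwise_phosphate_distances(h)
  for (i in 1:11) expect_equal(D[i, i + 1], chord, tolerance = 1e-9)

  # determinism
  expect_identical(generate_aform_helix(5), generate_aform_helix(5))

  expect_error(generate_aform_helix(0), class = "tbion_bad_argument")
})

test_that("the two strands are related by the duplex dyad", {
  h <- generate_aform_helix(7)
  n <- 7
  D <- pairwise_phosphate_distances(h)
  # a dyad is an involutive isometry mapping strand 1 residue i to strand 2
  # residue n + i, so all these distance identities must hold exactly
  for (i in 1:n) for (j in 1:n) {
    expect_equal(D[n + i, n + j], D[i, j], tolerance = 1e-6)
    expect_equal(D[n + i, j], D[i, n + j], tolerance = 1e-6)
  }
})

test_that("pairwise phosphate distances match a brute-force double loop", {
  expect_equal(pairwise_phosphate_distances(two_phos_structure(10))[1, 2], 10)
  expect_equal(pairwise_phosphate_distances(sphere_structure()),
               matrix(0, 1, 1))

  set.seed(42)
  pts <- matrix(runif(30, -20, 20), ncol = 3)
  s <- rna_structure(
    atoms = data.frame(element = "P", elety = "P", nt = 1:10,
                       x = pts[, 1], y = pts[, 2], z = pts[, 3], radius = 2),
    phosphates = data.frame(nt = 1:10, x = pts[, 1], y = pts[, 2],
                            z = pts[, 3], charge = -1, radius = 2),
    resnames = rep("A", 10), source = "toy")
  D <- pairwise_phosphate_distances(s)
  for (i in 1:10) for (j in 1:10)
    expect_equal(D[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)), tolerance = 1e-12)
})

test_that("PDB parsing builds the coarse-grained charge model", {
  # single residue with a P atom -> one phosphate at the P position
  txt <- pdb_text(c(
    pdb_atom_line(1, "P", "G", "A", 5, 1.5, 2.5, 3.5),
    pdb_atom_line(2, "C4'", "G", "A", 5, 4, 5, 6, element = "C")))
  s <- parse_pdb(txt)
  expect_equal(s$n_nucleotides, 1)
  expect_equal(nrow(s$phosphates), 1)
  expect_equal(unlist(s$phosphates[1, c("x", "y", "z")]),
               c(x = 1.5, y = 2.5, z = 3.5))
  expect_equal(s$phosphates$charge, -1)

  # 5'-OH terminus: first residue lacks P -> 1 phosphate, 2 nucleotides,
  # and residues are renumbered 1..N regardless of author numbering
  txt2 <- pdb_text(c(
    pdb_atom_line(1, "C4'", "G", "A", 17, 0, 0, 0, element = "C"),
    pdb_atom_line(2, "P", "C", "A", 18, 5, 0, 0),
    pdb_atom_line(3, "C4'", "C", "A", 18, 6, 1, 0, element = "C")))
  s2 <- parse_pdb(txt2)
  expect_equal(s2$n_nucleotides, 2)
  expect_equal(nrow(s2$phosphates), 1)
  expect_equal(s2$phosphates$nt, 2)

  # unknown residues are skipped with a warning; waters never survive
  txt3 <- pdb_text(c(
    pdb_atom_line(1, "P", "G", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "O", "HOH", "A", 2, 9, 9, 9)))
  expect_warning(s3 <- parse_pdb(txt3), "HOH")
  expect_equal(s3$n_nucleotides, 1)

  # nothing parseable -> structured empty-structure error (the per-residue
  # skip warning still fires on the way)
  suppressWarnings(
    expect_error(parse_pdb(pdb_text(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0))),
                 class = "tbion_empty_structure"))
})

test_that("alternate locations keep the highest occupancy, first on tie", {
  txt <- pdb_text(c(
    pdb_atom_line(1, "P", "G", "A", 1, 0, 0, 0, occ = 0.3, alt = "A"),
    pdb_atom_line(2, "P", "G", "A", 1, 9, 9, 9, occ = 0.7, alt = "B"),
    pdb_atom_line(3, "C4'", "G", "A", 1, 1, 1, 1, occ = 0.5, alt = "A"),
    pdb_atom_line(4, "C4'", "G", "A", 1, 8, 8, 8, occ = 0.5, alt = "B")))
  s <- parse_pdb(txt)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$phosphates$x, 9)  # occupancy 0.7 wins
  expect_equal(s$atoms$x[s$atoms$elety == "C4'"], 1)  # tie -> first record
})

test_that("write/parse round-trip preserves the phosphate model", {
  h <- generate_aform_helix(3)
  f <- tempfile(fileext = ".pdb")
  write_pdb(h, f)
  s <- parse_pdb(f)
  expect_equal(s$n_nucleotides, h$n_nucleotides)
  expect_equal(nrow(s$phosphates), nrow(h$phosphates))
  expect_equal(as.matrix(s$phosphates[, c("x", "y", "z")]),
               as.matrix(h$phosphates[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)  # PDB prints 3 decimals
  # a second round-trip is exact: the format is now the fixed point
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(s, f2)
  s2 <- parse_pdb(f2)
  expect_equal(s2$phosphates, s$phosphates, tolerance = 1e-12)
  unlink(c(f, f2))
})
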