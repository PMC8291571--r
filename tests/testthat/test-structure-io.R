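test_that("PDB round-trip preserves coordinates to PDB precision and assignments exactly", {
  m <- seeded_complex(11, n_residues = 3, n_waters = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- read_pdb(f, ligand_resnames = "LIG")
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_lte(max(abs(atom_coords(m2$atoms) - atom_coords(m$atoms))), 1e-3)
  expect_identical(m2$atoms$chain_id, m$atoms$chain_id)
  expect_identical(m2$atoms$res_seq, m$atoms$res_seq)
  expect_identical(m2$atoms$res_name, m$atoms$res_name)
  expect_identical(m2$atoms$mol_class, m$atoms$mol_class)
})

test_that("residue classification covers protein, ligand, water and other", {
  m <- seeded_complex(3, n_residues = 3, n_waters = 1)
  rt <- residue_table(m)
  expect_equal(sum(rt$mol_class == "protein"), 3)
  expect_equal(sum(rt$mol_class == "ligand"), 1)
  expect_equal(sum(rt$mol_class == "water"), 1)

  # a standard residue missing backbone atoms is classified "other"
  a <- m$atoms
  a <- a[!(a$res_seq == 2 & a$mol_class == "protein" & a$name == "CA"), ]
  rt2 <- residue_table(protofibril(a, ligand_resnames = "LIG"))
  expect_equal(rt2$mol_class[rt2$chain_id == "A" & rt2$res_seq == 2], "other")
})

test_that("read_pdb agrees with an independent PDB reader on a shared file", {
  skip_if_not_installed("bio3d")
  m <- seeded_complex(5, n_residues = 4, n_waters = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  ref <- bio3d::read.pdb(f)
  m2 <- read_pdb(f, ligand_resnames = "LIG")
  expect_equal(nrow(m2$atoms), nrow(ref$atom))
  expect_equal(atom_coords(m2$atoms),
               unname(as.matrix(ref$atom[, c("x", "y", "z")])),
               ignore_attr = TRUE)
  expect_equal(m2$atoms$res_seq, ref$atom$resno)
})

test_that("read_pdb rejects empty and malformed files with line context", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    junk", "END"), f)
  expect_error(read_pdb(f), "no ATOM/HETATM")

  writeLines(c("ATOM      1  N   GLY A   1      xxxxxxx   0.000   0.000  1.00  0.00           N"),
             f)
  expect_error(read_pdb(f), "line 1")
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BGLY A   1       1.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AGLY A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  C   GLY A   1       4.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  m <- read_pdb(f)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x[m$atoms$name == "N"], 1.0)   # higher occupancy wins
  expect_equal(m$atoms$x[m$atoms$name == "CA"], 2.0)  # tie: first encountered
})

test_that("Kabsch superposition recovers identity, translations and planted rotations", {
  withr::local_seed(1)
  pts <- matrix(rnorm(15, sd = 3), ncol = 3)

  tf <- kabsch_superpose(pts, pts)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(tf$fit_rmsd, 0, tolerance = 1e-10)

  shifted <- sweep(pts, 2, c(0, 0, 4.8), "+")
  tf2 <- kabsch_superpose(pts, shifted)
  expect_equal(tf2$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf2$translation, c(0, 0, 4.8), tolerance = 1e-10)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tf3 <- kabsch_superpose(pts, pts %*% t(R))
  expect_lt(max(abs(tf3$rotation - R)), 1e-8)
  expect_lt(tf3$fit_rmsd, 1e-8)
  expect_equal(det(tf3$rotation), 1, tolerance = 1e-8)
})

test_that("Kabsch fit is optimal against random rigid transforms and rejects degeneracy", {
  withr::local_seed(7)
  mob <- matrix(rnorm(21, sd = 2), ncol = 3)
  tgt <- mob %*% t(random_rotation()) +
    matrix(rep(rnorm(3), each = 7), ncol = 3) +
    matrix(rnorm(21, sd = 0.1), ncol = 3)  # noise so the fit is nontrivial
  best <- kabsch_superpose(mob, tgt)$fit_rmsd
  for (i in 1:100) {
    R <- random_rotation()
    t0 <- rnorm(3)
    moved <- sweep(mob %*% t(R), 2, t0, "+")
    expect_gte(sqrt(mean(rowSums((moved - tgt)^2))) + 1e-12, best)
  }

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
  expect_error(kabsch_superpose(mob[1:2, ], tgt[1:2, ]), "at least 3")
})

test_that("protofibril extension by pure translation reproduces exact stack offsets", {
  sp <- fixture_spec(sequence = c("GLY", "ALA", "SER"), n_chains = 3,
                     chain_rise = 4.8, chain_twist = 0)
  p3 <- build_peptide(sp)
  p5 <- extend_protofibril(p3, 5)
  pa <- model_atoms(p5, "protein")
  expect_equal(length(unique(pa$chain_id)), 5)
  base <- atom_coords(pa[pa$chain_id == "A", , drop = FALSE])
  for (k in 4:5) {
    cid <- c("D", "E")[k - 3]
    xyz <- atom_coords(pa[pa$chain_id == cid, , drop = FALSE])
    off <- matrix(rep(c(0, 0, 4.8 * (k - 1)), each = nrow(base)), ncol = 3)
    expect_lt(max(abs(xyz - (base + off))), 1e-6)
  }
  # original atoms unmoved, per-chain atom count conserved
  expect_equal(unname(atom_coords(model_atoms(p5, "protein")[seq_len(nrow(p3$atoms)), ])),
               unname(atom_coords(p3$atoms)))
  expect_true(all(table(pa$chain_id) == nrow(base)))
})

test_that("protofibril extension applies a screw operator exactly and validates inputs", {
  sp <- fixture_spec(sequence = c("GLY", "ALA"), n_chains = 2,
                     chain_rise = 4.8, chain_twist = 10)
  p2 <- build_peptide(sp)
  p3 <- extend_protofibril(p2, 3)
  pa <- model_atoms(p3, "protein")
  base <- atom_coords(pa[pa$chain_id == "A", , drop = FALSE])
  th <- 2 * 10 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expected <- base %*% t(Rz)
  expected[, 3] <- expected[, 3] + 2 * 4.8
  expect_lt(max(abs(atom_coords(pa[pa$chain_id == "C", , drop = FALSE]) - expected)),
            1e-6)

  expect_identical(extend_protofibril(p2, 2), p2)
  expect_error(extend_protofibril(p2, 1), "less than")
  bad <- p2
  bad$atoms$res_name[bad$atoms$chain_id == "B" & bad$atoms$res_seq == 2] <- "VAL"
  bad <- protofibril(bad$atoms)
  expect_error(extend_protofibril(bad, 3), "mismatched")
})
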