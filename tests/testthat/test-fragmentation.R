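test_that("peptide bonds are detected by the C-N distance rule", {
  sp <- fixture_spec(sequence = c("GLY", "ALA", "SER"))
  m <- build_peptide(sp)
  bonds <- find_peptide_bonds(m, "A")
  expect_equal(nrow(bonds), 2)
  expect_equal(bonds$length, c(1.33, 1.33), tolerance = 1e-9)

  m1 <- build_peptide(fixture_spec(sequence = "GLY"))
  expect_equal(nrow(find_peptide_bonds(m1, "A")), 0)

  # stretching the middle bond to ~3 A turns it into a chain break
  a <- m$atoms
  shift <- a$res_seq == 3 & a$chain_id == "A"
  third_n <- a[a$res_seq == 3 & a$name == "N", ]
  second_c <- a[a$res_seq == 2 & a$name == "C", ]
  dir <- unname(unlist(third_n[, c("x", "y", "z")]) -
                  unlist(second_c[, c("x", "y", "z")]))
  dir <- dir / sqrt(sum(dir^2)) * (3.0 - 1.33)
  a$x[shift] <- a$x[shift] + dir[1]
  a$y[shift] <- a$y[shift] + dir[2]
  a$z[shift] <- a$z[shift] + dir[3]
  m_broken <- protofibril(a)
  expect_warning(bonds2 <- find_peptide_bonds(m_broken, "A"), "chain break")
  expect_equal(nrow(bonds2), 1)
  expect_equal(nrow(attr(bonds2, "breaks")), 1)
  expect_equal(attr(bonds2, "breaks")$length, 3.0, tolerance = 1e-9)
})

test_that("monopeptide hydrogen capping yields n fragments with one cap per cut side", {
  m <- build_peptide(fixture_spec(sequence = c("GLY", "ALA", "SER")))
  frags <- fragment_chain(m, "A", scheme = "hydrogen", order = "monopeptide")
  expect_length(frags, 3)
  expect_equal(sum(vapply(frags, function(f) nrow(f$caps), 0L)), 4)
  expect_equal(vapply(frags, function(f) nrow(f$caps), 0L), c(1L, 2L, 1L))

  m1 <- build_peptide(fixture_spec(sequence = "ALA"))
  f1 <- fragment_chain(m1, "A")
  expect_length(f1, 1)
  expect_equal(nrow(f1[[1]]$caps), 0)
  expect_equal(atom_coords(f1[[1]]$core), atom_coords(m1$atoms))
})

test_that("link hydrogens lie on the replaced bond vector at their prescribed lengths", {
  m <- build_peptide(fixture_spec(sequence = c("GLY", "GLY", "GLY")))
  frags <- fragment_chain(m, "A", scheme = "hydrogen")
  for (f in frags) {
    for (i in seq_len(nrow(f$caps))) {
      cap <- f$caps[i, ]
      heavy <- f$core[f$core$element != "H", ]
      d <- sqrt((heavy$x - cap$x)^2 + (heavy$y - cap$y)^2 + (heavy$z - cap$z)^2)
      anchor <- heavy[which.min(d), ]
      expected <- if (anchor$name == "C") 1.09 else 1.01
      expect_equal(min(d), expected, tolerance = 1e-6)
    }
  }

  # forced placement geometry: C at origin, N at (1.33, 0, 0) -> H at (1.09, 0, 0)
  c2 <- m$atoms[m$atoms$res_seq == 2 & m$atoms$name == "C", ]
  n3 <- m$atoms[m$atoms$res_seq == 3 & m$atoms$name == "N", ]
  u <- c(n3$x - c2$x, n3$y - c2$y, n3$z - c2$z) / 1.33
  cap <- frags[[2]]$caps[2, ]
  expect_equal(c(cap$x, cap$y, cap$z),
               c(c2$x, c2$y, c2$z) + 1.09 * u, tolerance = 1e-9)
})

test_that("fragmentation conserves the atom multiset and total formal charge", {
  seqs <- c("GLY", "ASP", "ALA", "LYS", "GLU")  # net formal charge -1
  m <- build_peptide(fixture_spec(sequence = seqs))
  chain_atoms <- m$atoms[m$atoms$chain_id == "A", ]
  for (scheme in c("hydrogen", "methylamide")) {
    for (order in c("monopeptide", "dipeptide")) {
      frags <- fragment_chain(m, "A", scheme = scheme, order = order)
      if (order == "monopeptide") {
        cores <- do.call(rbind, lapply(frags, `[[`, "core"))
        expect_identical(atom_multiset_key(cores), atom_multiset_key(chain_atoms))
        expect_equal(sum(vapply(frags, `[[`, 0L, "net_charge")), -1L)
      } else {
        # overlapping windows count interior residues twice
        expect_equal(sum(vapply(frags, `[[`, 0L, "net_charge")),
                     sum(fragdecomp:::FORMAL_CHARGES[seqs]) +
                       sum(fragdecomp:::FORMAL_CHARGES[seqs[2:4]]))
      }
    }
  }
})

test_that("dipeptide windows overlap and their cores are unions of monopeptide cores", {
  m <- build_peptide(fixture_spec(sequence = c("GLY", "ALA", "SER", "VAL")))
  mono <- fragment_chain(m, "A", order = "monopeptide")
  di <- fragment_chain(m, "A", order = "dipeptide")
  expect_length(di, 3)
  for (i in seq_along(di)) {
    expect_identical(
      atom_multiset_key(di[[i]]$core),
      sort(c(atom_multiset_key(mono[[i]]$core),
             atom_multiset_key(mono[[i + 1]]$core))))
  }
  m1 <- build_peptide(fixture_spec(sequence = "GLY"))
  expect_error(fragment_chain(m1, "A", order = "dipeptide"), "at least 2")
})

test_that("methylamide caps reuse neighbour geometry and are deterministic", {
  m <- build_peptide(fixture_spec(sequence = c("ALA", "GLY", "SER")))
  f2a <- fragment_chain(m, "A", scheme = "methylamide")[[2]]
  f2b <- fragment_chain(m, "A", scheme = "methylamide")[[2]]
  expect_identical(f2a$caps, f2b$caps)  # bitwise-identical caps

  caps <- f2a$caps
  expect_setequal(unique(caps$name),
                  c("CAC", "OAC", "CME", "HM1", "HM2", "HM3", "NMA", "HNM"))
  # cap heavy atoms sit on the original neighbour positions
  cac <- caps[caps$name == "CAC", ]
  c1 <- m$atoms[m$atoms$res_seq == 1 & m$atoms$name == "C", ]
  expect_equal(c(cac$x, cac$y, cac$z), c(c1$x, c1$y, c1$z))
  nma <- caps[caps$name == "NMA", ]
  n3 <- m$atoms[m$atoms$res_seq == 3 & m$atoms$name == "N", ]
  expect_equal(c(nma$x, nma$y, nma$z), c(n3$x, n3$y, n3$z))

  # synthetic methyl hydrogens: exact 1.09 A bonds
  cme <- caps[caps$name == "CME", ]
  for (h in c("HM1", "HM2", "HM3")) {
    hm <- caps[caps$name == h, ]
    for (j in seq_len(nrow(hm))) {
      k <- which.min((cme$x - hm$x[j])^2 + (cme$y - hm$y[j])^2 +
                       (cme$z - hm$z[j])^2)
      d <- sqrt((cme$x[k] - hm$x[j])^2 + (cme$y[k] - hm$y[j])^2 +
                  (cme$z[k] - hm$z[j])^2)
      expect_equal(d, 1.09, tolerance = 1e-6)
    }
  }
  hnm <- caps[caps$name == "HNM", ]
  expect_equal(sqrt((hnm$x - nma$x)^2 + (hnm$y - nma$y)^2 + (hnm$z - nma$z)^2),
               1.01, tolerance = 1e-6)
})

test_that("unknown residues without a charge rule are rejected, overrides accepted", {
  m <- build_peptide(fixture_spec(sequence = c("GLY", "ALA")))
  m$atoms$res_name[m$atoms$res_seq == 2] <- "XYZ"
  m2 <- protofibril(m$atoms)
  expect_equal(residue_table(m2)$mol_class, c("protein", "other"))
  m$atoms$res_name[m$atoms$res_seq == 2] <- "HIP"
  m3 <- protofibril(m$atoms)
  frags <- fragment_chain(m3, "A")
  expect_equal(vapply(frags, `[[`, 0L, "net_charge"), c(0L, 1L))
  frags2 <- fragment_chain(m3, "A", charge_rules = c(HIP = 0))
  expect_equal(vapply(frags2, `[[`, 0L, "net_charge"), c(0L, 0L))
})

test_that("water selection honours the ligand-distance cutoff", {
  sp <- fixture_spec(sequence = c("GLY", "GLY"), ligand = "two_atom_probe",
                     n_waters = 5, seed = 3)
  base <- build_complex(fixture_spec(sequence = c("GLY", "GLY"),
                                     ligand = "two_atom_probe"))
  lig <- model_atoms(base, "ligand")
  centre <- colMeans(atom_coords(lig))
  # planted: 2 oxygens within 6 A of the ligand, 3 beyond
  pos <- rbind(centre + c(0, 4, 0), centre + c(0, -4, 2),
               centre + c(12, 0, 0), centre + c(0, 14, 0), centre + c(0, 0, 16))
  m <- build_complex(sp, water_positions = pos)
  w2 <- fragment_waters(m, cutoff = 6)
  expect_length(w2, 2)
  expect_equal(attr(w2, "excluded"), 3L)
  expect_true(all(vapply(w2, function(f) nrow(f$core), 0L) == 3L))
  expect_true(all(vapply(w2, `[[`, 0L, "net_charge") == 0L))

  expect_length(fragment_waters(m, cutoff = Inf), 5)
  expect_length(fragment_waters(base, cutoff = 6), 0)

  bad <- m
  bad$atoms$element[bad$atoms$res_name == "HOH" & bad$atoms$name == "O" &
                      bad$atoms$res_seq == 1] <- "N"
  expect_error(fragment_waters(protofibril(bad$atoms, ligand_resnames = "LIG"),
                               cutoff = Inf), "oxygen")
})

test_that("fragments export as multi-structure XYZ blocks", {
  m <- build_peptide(fixture_spec(sequence = c("GLY", "ALA")))
  frags <- fragment_chain(m, "A")
  f <- withr::local_tempfile(fileext = ".xyz")
  write_fragments_xyz(frags, f)
  lines <- readLines(f)
  n1 <- nrow(fragment_atoms(frags[[1]]))
  expect_equal(as.integer(lines[1]), n1)
  expect_match(lines[2], "A:1 charge=0 multiplicity=1")
  expect_equal(length(lines),
               sum(vapply(frags, function(fr) nrow(fragment_atoms(fr)) + 2L, 0L)))
})
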