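# shared fixture builders for the test suite (everything generated in code)

# a small complex with seeded random charges planted on protein and ligand
# atoms; Lennard-Jones left at the built-in element defaults
seeded_complex <- function(seed, n_residues = 4, n_chains = 1, n_waters = 0,
                           charge_spread = 0.3) {
  aa_pool <- c("GLY", "ALA", "SER", "VAL", "THR", "LEU", "ASP", "LYS")
  withr::local_seed(seed)
  sp <- fixture_spec(sequence = sample(aa_pool, n_residues, replace = TRUE),
                     n_chains = n_chains, ligand = "two_atom_probe",
                     n_waters = n_waters, seed = seed)
  m <- build_complex(sp)
  a <- m$atoms
  prot <- a$mol_class == "protein"
  lig <- a$mol_class == "ligand"
  a$charge[prot] <- round(stats::runif(sum(prot), -charge_spread, charge_spread), 4)
  a$charge[lig] <- c(0.4, -0.4)
  m$atoms <- a
  m
}

# a complex with everything zeroed except a +1 charge on one protein atom
# and a -1 charge on the first ligand atom, the pair separated by exactly
# `r` Angstrom: the Coulomb energy has the closed form -332.0636 / r
planted_pair_complex <- function(r = 3.320636) {
  sp0 <- fixture_spec(sequence = c("GLY", "GLY", "GLY"),
                      ligand = "two_atom_probe")
  pep <- build_peptide(sp0)
  centroid <- colMeans(atom_coords(pep$atoms))
  carrier <- pep$atoms[pep$atoms$name == "CA" & pep$atoms$res_seq == 2, ]
  p <- c(carrier$x, carrier$y, carrier$z)
  # two_atom_probe atoms sit at centre +/- (0.7, 0, 0); aim C1 at p + (0, r, 0)
  centre <- p + c(0, r, 0) + c(0.7, 0, 0)
  sp <- fixture_spec(sequence = c("GLY", "GLY", "GLY"),
                     ligand = "two_atom_probe",
                     ligand_offset = centre - centroid)
  m <- build_complex(sp)
  a <- m$atoms
  a$charge <- 0
  a$lj_epsilon <- 0
  a$charge[a$mol_class == "protein" & a$name == "CA" & a$res_seq == 2] <- 1
  a$charge[a$mol_class == "ligand" & a$name == "C1"] <- -1
  m$atoms <- a
  m
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# random parameterized atom set for algebraic-identity checks; atoms sit on
# a jittered grid so no pair is unphysically close (which would blow up the
# r^-12 term and drown the identity in cancellation noise)
random_atom_set <- function(n, offset = c(0, 0, 0)) {
  grid <- as.matrix(expand.grid(x = seq(0, 6, 2), y = seq(0, 6, 2),
                                z = seq(0, 6, 2)))
  xyz <- grid[sample(nrow(grid), n), ] +
    matrix(stats::runif(3 * n, -0.3, 0.3), ncol = 3)
  xyz <- sweep(xyz, 2, offset, "+")
  data.frame(serial = seq_len(n), name = paste0("X", seq_len(n)),
             element = "C", alt_loc = "", res_name = "XXX", chain_id = "X",
             res_seq = 1L, ins_code = "", x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], occupancy = 1,
             charge = round(stats::runif(n, -0.5, 0.5), 3),
             lj_sigma = stats::runif(n, 2.5, 3.5),
             lj_epsilon = stats::runif(n, 0.02, 0.2),
             stringsAsFactors = FALSE)
}

atom_multiset_key <- function(atoms) {
  sort(paste(atoms$chain_id, atoms$res_seq, atoms$name, atoms$serial))
}

# a single-atom ligand probe as an atom data frame
point_charge_lig <- function(q, xyz) {
  data.frame(serial = 1L, name = "C1", element = "C", alt_loc = "",
             res_name = "LIG", chain_id = "L", res_seq = 1L, ins_code = "",
             x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
             charge = q, lj_sigma = 0, lj_epsilon = 0,
             stringsAsFactors = FALSE)
}

# unit positive probe at the origin plus 1-2 TIP3P waters at symmetric poses
# (copy 2 is copy 1 rotated 180 degrees about z, so both waters present the
# same distances to the probe)
water_probe_model <- function(n_copies = 1) {
  lig <- data.frame(serial = 1L, name = "C1", element = "C", alt_loc = "",
                    res_name = "LIG", chain_id = "L", res_seq = 1L,
                    ins_code = "", x = 0, y = 0, z = 0, occupancy = 1,
                    stringsAsFactors = FALSE)
  w1 <- fragdecomp:::water_atoms(c(0.8, 3.7, 1.1), 1L)
  waters <- w1
  if (n_copies == 2) {
    w2 <- w1
    w2$x <- -w2$x; w2$y <- -w2$y
    w2$res_seq <- 2L
    waters <- rbind(w1, w2)
  }
  atoms <- rbind(lig, waters)
  atoms$serial <- seq_len(nrow(atoms))
  m <- assign_parameters(protofibril(atoms, ligand_resnames = "LIG"))
  m$atoms$charge[m$atoms$mol_class == "ligand"] <- 1
  m$atoms$lj_epsilon[m$atoms$mol_class == "ligand"] <- 0
  m
}

# independent hand evaluation of the probe-water Coulomb sum
hand_water_coulomb <- function(model, first_only = FALSE) {
  a <- model$atoms
  wat <- a[a$mol_class == "water", ]
  if (first_only) wat <- wat[wat$res_seq == 1L, ]
  probe <- a[a$mol_class == "ligand", ]
  sum(332.0636 * probe$charge * wat$charge /
        sqrt((wat$x - probe$x)^2 + (wat$y - probe$y)^2 + (wat$z - probe$z)^2))
}
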