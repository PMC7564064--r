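# Shared in-code fixtures. Molecule sets for field/PLS tests are built
# without the structure backend so the numerical engine is exercised
# independently of RDKit.

# Minimal mol_tbl with hand-set atoms; params default to simple values.
toy_mol <- function(id, xyz, steric = 8, hydrophobic = 0.5, charge = 0,
                    donor = FALSE, acceptor = FALSE) {
  n <- nrow(xyz)
  atoms <- tibble::tibble(
    element = rep("C", n), mass = rep(12.011, n), aromatic = FALSE,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n), steric = rep_len(steric, n),
    hydrophobic = rep_len(hydrophobic, n),
    donor = rep_len(donor, n), acceptor = rep_len(acceptor, n)
  )
  tibble::tibble(
    id = id, smiles = NA_character_, n_atoms = n, n_heavy = n,
    formal_charge = 0L, molar_mass = sum(atoms$mass),
    energy_initial = NA_real_, energy_final = NA_real_,
    molblock = NA_character_, atoms = list(atoms)
  )
}

toy_mol_tbl <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- c("mol_tbl", class(tibble::tibble()))
  out
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

rotate_mols <- function(mols, R, shift = c(0, 0, 0)) {
  mols$atoms <- lapply(mols$atoms, function(a) {
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% R
    a$x <- xyz[, 1] + shift[1]
    a$y <- xyz[, 2] + shift[2]
    a$z <- xyz[, 3] + shift[3]
    a
  })
  mols
}

# Small dense regression fixture for PLS tests.
pls_fixture <- function(n = 15, p = 40, noise = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("V", seq_len(p))
  beta <- rnorm(p) * 0.3
  y <- as.numeric(X %*% beta + rnorm(n) * noise)
  list(X = X, y = y, beta = beta)
}
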