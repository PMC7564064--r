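#' Generate a synthetic field-QSAR benchmark set
#'
#' Builds toy rigid molecules on a common 4-atom scaffold with two
#' substituent sites. Substituent atoms get randomized per-atom parameters
#' (steric volume, hydrophobicity, partial charge, donor/acceptor flags);
#' partial charges are re-centered so every molecule is neutral. The
#' response is a planted linear functional of the similarity fields -- unit
#' weights on steric-field lattice points near site 1 and hydrophobic-field
#' points near site 2 -- plus Gaussian noise. With `sigma = NULL` the noise
#' level is set from the signal-to-noise ratio `snr` as
#' `sd(signal) / snr`. Everything is a pure function of `seed`.
#'
#' @param n_molecules Number of molecules (default 20).
#' @param snr Signal-to-noise ratio used when `sigma` is `NULL`
#'   (default 3).
#' @param sigma Noise standard deviation; overrides `snr` when given.
#' @param seed Integer seed.
#' @param spacing,margin Lattice parameters (defaults 2 and 3 Angstrom).
#' @param alpha Field attenuation (default 0.3).
#' @return A list of class `synthetic_qsar`: `molecules` (a `mol_tbl`),
#'   `fields`, `response`, `signal`, `planted_coef`, `sigma`, `seed`, and
#'   the planted region centers `site_s` / `site_h`.
#' @export
generate_synthetic_qsar <- function(n_molecules = 20, snr = 3, sigma = NULL,
                                    seed = 1, spacing = 2, margin = 3,
                                    alpha = 0.3) {
  stopifnot(n_molecules >= 4, is.null(sigma) || sigma >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  scaffold <- matrix(c(0, 0, 0,
                       1.5, 0, 0,
                       3, 0, 0,
                       1.5, 1.5, 0), ncol = 3, byrow = TRUE)
  site1 <- c(0, -1.8, 0)
  site2 <- c(3, 1.8, 0)
  rows <- purrr::map(seq_len(n_molecules), function(i) {
    sub_params <- tibble::tibble(
      steric = stats::runif(2, 5, 60),
      hydrophobic = stats::rnorm(2, 0, 15),
      charge = stats::runif(2, -0.3, 0.3),
      donor = stats::runif(2) < 0.3,
      acceptor = stats::runif(2) < 0.3
    )
    atoms <- tibble::tibble(
      element = "C",
      mass = 12.011,
      aromatic = FALSE,
      x = c(scaffold[, 1], site1[1], site2[1]),
      y = c(scaffold[, 2], site1[2], site2[2]),
      z = c(scaffold[, 3], site1[3], site2[3]),
      charge = c(rep(0.05, 4), sub_params$charge),
      steric = c(rep(4, 4), sub_params$steric),
      hydrophobic = c(rep(0.2, 4), sub_params$hydrophobic),
      donor = c(rep(FALSE, 4), sub_params$donor),
      acceptor = c(rep(FALSE, 4), sub_params$acceptor)
    )
    atoms$charge <- atoms$charge - mean(atoms$charge)  # neutral molecule
    tibble::tibble(
      id = sprintf("syn%03d", i), smiles = NA_character_,
      n_atoms = nrow(atoms), n_heavy = nrow(atoms), formal_charge = 0L,
      molar_mass = sum(atoms$mass), energy_initial = NA_real_,
      energy_final = NA_real_, molblock = NA_character_,
      atoms = list(atoms)
    )
  })
  mols <- new_mol_tbl(dplyr::bind_rows(rows))
  fields <- compute_fields(mols, spacing = spacing, margin = margin,
                           alpha = alpha)
  pts <- fields$grid$points
  near <- function(center, radius = 2.5) {
    sqrt(colSums((t(pts) - center)^2)) <= radius
  }
  w <- numeric(ncol(fields$X))
  w[fields$field_of_column == "S" & near(site1)[fields$point_of_column]] <- 1
  w[fields$field_of_column == "H" & near(site2)[fields$point_of_column]] <- 1
  signal <- as.numeric(fields$X %*% w)
  if (is.null(sigma)) sigma <- stats::sd(signal) / snr
  response <- signal + stats::rnorm(n_molecules, 0, sigma)
  structure(list(molecules = mols, fields = fields, response = response,
                 signal = signal, planted_coef = w, sigma = sigma,
                 seed = seed, site_s = site1, site_h = site2),
            class = "synthetic_qsar")
}

#' @export
print.synthetic_qsar <- function(x, ...) {
  cat("<synthetic_qsar> ", nrow(x$molecules), " molecules, sigma = ",
      signif(x$sigma, 4), ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
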