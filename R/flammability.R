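#' Default char-forming-tendency (CFT) table
#'
#' Char residue is estimated from additive functional-group contributions.
#' For phthalic acid esters the benzene-1,2-diester (phthalate) moiety is the
#' only char-forming group and contributes 2 in total, matched at most once
#' per molecule; plain alkyl/alkenyl chains contribute nothing.
#'
#' @return Tibble with columns `pattern` (SMARTS), `cft` (contribution) and
#'   `once` (logical; count at most one match).
#' @export
default_cft_table <- function() {
  tibble::tibble(
    pattern = "[#6]OC(=O)c1ccccc1C(=O)O[#6]",
    cft = 2,
    once = TRUE
  )
}

#' Char residue from functional-group contributions
#'
#' `CR = 1200 * sum(CFT_i) / M`, where `M` is the molar mass in g/mol and
#' the CFT sum collects the char-forming-group contributions of the
#' molecule.
#'
#' @param mass Molar masses in g/mol (named vector or a `mol_tbl`, in which
#'   case the CFT sum is resolved by substructure matching against
#'   `cft_table`).
#' @param sigma_cft Total CFT contribution per molecule; either a single
#'   value recycled over molecules or a vector. Ignored when `mass` is a
#'   `mol_tbl` and `cft_table` is given.
#' @param cft_table A CFT table (see [default_cft_table()]); only used for
#'   `mol_tbl` input.
#' @return Numeric vector of char residues (dimensionless).
#' @export
char_residue <- function(mass, sigma_cft = 2, cft_table = default_cft_table()) {
  if (inherits(mass, "mol_tbl")) {
    mols <- mass
    mass <- molar_mass(mols)
    sigma_cft <- rep(0, nrow(mols))
    for (k in seq_len(nrow(cft_table))) {
      hits <- match_substructure(mols, cft_table$pattern[k])$n_matches
      if (cft_table$once[k]) hits <- pmin(hits, 1L)
      sigma_cft <- sigma_cft + hits * cft_table$cft[k]
    }
  }
  stopifnot(is.numeric(mass), all(sigma_cft >= 0))
  if (any(mass <= 0)) stop("molar mass must be positive", call. = FALSE)
  1200 * sigma_cft / mass
}

#' Limited oxygen index from char residue
#'
#' The empirical halogen-free correlation `LOI = 17.5 + 0.4 * CR`, in
#' oxygen volume percent. Values of 22-27% indicate practically useful
#' flame retardancy.
#'
#' @param cr Char residue (>= 0).
#' @param digits Decimal places for the reported value (`NULL` keeps the
#'   raw value).
#' @return LOI in %.
#' @export
loi <- function(cr, digits = NULL) {
  stopifnot(all(cr >= 0))
  out <- 17.5 + 0.4 * cr
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Add char residue and LOI columns to a property table
#'
#' @param data A data frame with a molar-mass column.
#' @param mass Column holding molar mass in g/mol (tidy-eval).
#' @param sigma_cft Total CFT contribution per molecule (default 2, the
#'   phthalate-moiety contribution).
#' @return `data` with `CR` and `LOI` columns appended.
#' @export
add_flammability <- function(data, mass = molar_mass, sigma_cft = 2) {
  m <- dplyr::pull(data, {{ mass }})
  cr <- char_residue(m, sigma_cft)
  dplyr::mutate(data, CR = cr, LOI = loi(cr))
}
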