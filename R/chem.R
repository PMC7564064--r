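#' Minimization settings for 3D conformer preparation
#'
#' Defaults follow common force-field practice for small esters: an energy
#' convergence tolerance of 0.005 kcal/mol and at most 10,000 iterations.
#' The seed controls the distance-geometry embedding, making conformers
#' bitwise reproducible.
#'
#' @param convergence Energy tolerance in kcal/mol (> 0).
#' @param max_iterations Maximum minimizer iterations (>= 1).
#' @param seed Integer random seed for the embedding.
#' @return A list of settings.
#' @export
minimization_settings <- function(convergence = 0.005, max_iterations = 10000,
                                  seed = 42) {
  stopifnot(convergence > 0, max_iterations >= 1)
  list(convergence = convergence, max_iterations = max_iterations,
       seed = as.integer(seed))
}

new_mol_tbl <- function(x) {
  class(x) <- c("mol_tbl", class(tibble::tibble()))
  x
}

#' Parse molecular structures from SMILES or MOL blocks
#'
#' Returns one row per molecule with the element list, formal charge and
#' molar mass populated; 3D coordinates are unset until
#' [embed_structures()] is called, and per-atom field parameters until
#' [assign_field_params()]. Implicit hydrogens are made explicit, so atom
#' counts and masses include hydrogen. Atom order is deterministic for
#' identical input text.
#'
#' @param structures A character vector of SMILES (optionally named by id),
#'   or a data frame with columns `id` and `smiles` (or `molblock`).
#' @param ids Optional character ids when `structures` is unnamed.
#' @param add_hs Make implicit hydrogens explicit (default `TRUE`).
#' @return A `mol_tbl` tibble with columns `id`, `smiles`, `n_atoms`,
#'   `n_heavy`, `formal_charge`, `molar_mass` and a list-column `atoms`
#'   (element, mass, aromatic flag, and placeholders for coordinates and
#'   field parameters).
#' @examples
#' \dontrun{
#' parse_structures(c(DMP = "COC(=O)c1ccccc1C(=O)OC"))
#' }
#' @export
parse_structures <- function(structures, ids = NULL, add_hs = TRUE) {
  df <- as_structure_df(structures, ids)
  res <- backend_call(df, tasks = "parse", settings = list(add_hs = add_hs))
  collect_backend(df, res)
}

as_structure_df <- function(structures, ids = NULL) {
  if (is.data.frame(structures)) {
    stopifnot("id" %in% names(structures))
    return(tibble::as_tibble(structures))
  }
  stopifnot(is.character(structures))
  if (is.null(ids)) ids <- names(structures)
  if (is.null(ids)) ids <- paste0("mol", seq_along(structures))
  tibble::tibble(id = ids, smiles = unname(structures))
}

collect_backend <- function(df, res) {
  bad <- purrr::keep(res, ~ !isTRUE(.x$ok))
  if (length(bad) > 0) {
    msgs <- purrr::map_chr(bad, ~ paste0(.x$id, ": ", .x$error))
    stop("structure parsing failed for:\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }
  rows <- purrr::map2(df$id, res, function(id, r) {
    n <- length(r$symbol)
    atoms <- tibble::tibble(
      element = unlist(r$symbol),
      mass = unlist(r$mass),
      aromatic = unlist(r$aromatic),
      x = if (is.null(r$coords)) NA_real_ else purrr::map_dbl(r$coords, 1),
      y = if (is.null(r$coords)) NA_real_ else purrr::map_dbl(r$coords, 2),
      z = if (is.null(r$coords)) NA_real_ else purrr::map_dbl(r$coords, 3),
      charge = if (is.null(r$charge)) NA_real_ else unlist(r$charge),
      steric = if (is.null(r$steric)) NA_real_ else unlist(r$steric),
      hydrophobic = if (is.null(r$hydrophobic)) NA_real_ else unlist(r$hydrophobic),
      donor = if (is.null(r$donor)) NA else unlist(r$donor),
      acceptor = if (is.null(r$acceptor)) NA else unlist(r$acceptor)
    )
    tibble::tibble(
      id = id,
      smiles = r$canonical_smiles,
      n_atoms = n,
      n_heavy = r$n_heavy,
      formal_charge = r$formal_charge,
      molar_mass = sum(atoms$mass),
      energy_initial = r$energy_initial %||% NA_real_,
      energy_final = r$energy_final %||% NA_real_,
      molblock = r$molblock %||% NA_character_,
      atoms = list(atoms)
    )
  })
  new_mol_tbl(dplyr::bind_rows(rows))
}

#' Molar mass of parsed molecules
#'
#' Sum of standard atomic weights over all atoms, implicit hydrogens
#' included.
#'
#' @param mols A `mol_tbl` from [parse_structures()].
#' @return Named numeric vector of masses in g/mol.
#' @export
molar_mass <- function(mols) {
  stopifnot(inherits(mols, "mol_tbl"))
  stats::setNames(mols$molar_mass, mols$id)
}

#' Generate seeded 3D conformers and minimize them
#'
#' Embeds each molecule with a seeded distance-geometry method and relaxes
#' it with the MMFF94 force field until the energy tolerance or iteration
#' cap in `settings` is reached. Identical seeds give identical
#' coordinates; the minimized energy never exceeds the initial embedding
#' energy.
#'
#' @param mols A `mol_tbl`.
#' @param settings See [minimization_settings()].
#' @return The `mol_tbl` with coordinates set and `energy_initial` /
#'   `energy_final` (kcal/mol) populated.
#' @export
embed_structures <- function(mols, settings = minimization_settings()) {
  stopifnot(inherits(mols, "mol_tbl"))
  df <- tibble::tibble(id = mols$id, smiles = mols$smiles)
  res <- backend_call(df, tasks = c("parse", "embed"), settings = settings)
  out <- collect_backend(df, res)
  out
}

#' Assign partial charges and per-atom field parameters
#'
#' Populates the five per-atom inputs of the similarity fields: Gasteiger
#' iterative partial charges (electrostatic), the cube of the Bondi van der
#' Waals radius (steric), Crippen atomic logP contributions (hydrophobic),
#' and hydrogen-bond donor/acceptor flags from substructure rules (N/O/S
#' with an attached hydrogen donate; neutral N and O accept).
#'
#' @param mols A `mol_tbl` with 3D coordinates (see [embed_structures()]).
#' @return The `mol_tbl` with the parameter columns of each `atoms` tibble
#'   filled in.
#' @export
assign_field_params <- function(mols) {
  stopifnot(inherits(mols, "mol_tbl"))
  if (anyNA(purrr::map_dbl(mols$atoms, ~ .x$x[1]))) {
    stop("molecules must be embedded in 3D before assigning field ",
         "parameters; run embed_structures() first", call. = FALSE)
  }
  df <- tibble::tibble(id = mols$id, smiles = mols$smiles)
  res <- backend_call(df, tasks = c("parse", "params"),
                      settings = list(add_hs = TRUE))
  out <- mols
  out$atoms <- purrr::map2(mols$atoms, res, function(atoms, r) {
    stopifnot(nrow(atoms) == length(r$symbol))
    atoms$charge <- unlist(r$charge)
    atoms$steric <- unlist(r$steric)
    atoms$hydrophobic <- unlist(r$hydrophobic)
    atoms$donor <- unlist(r$donor)
    atoms$acceptor <- unlist(r$acceptor)
    atoms
  })
  out
}

#' Count substructure matches of a SMARTS pattern
#'
#' @param mols A `mol_tbl`.
#' @param smarts A SMARTS pattern.
#' @return Tibble with `id`, `n_matches`, and the 1-based atom indices of
#'   the first match as a list-column `match`.
#' @export
match_substructure <- function(mols, smarts) {
  stopifnot(inherits(mols, "mol_tbl"))
  df <- tibble::tibble(id = mols$id, smiles = mols$smiles)
  res <- backend_call(df, tasks = "parse", match_smarts = smarts)
  tibble::tibble(
    id = df$id,
    n_matches = purrr::map_int(res, ~ as.integer(.x$n_matches %||% 0L)),
    match = purrr::map(res, ~ unlist(.x$match) + 1L)
  )
}

#' Read a SMILES file
#'
#' Expects one molecule per line as `SMILES<TAB>id` (id optional).
#'
#' @param path File path.
#' @inheritParams parse_structures
#' @return A `mol_tbl`.
#' @export
read_smiles <- function(path, add_hs = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  smiles <- purrr::map_chr(parts, 1)
  ids <- purrr::map_chr(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i)
  })
  parse_structures(smiles, ids, add_hs = add_hs)
}

#' Write molecules to an SD file with computed per-atom properties
#'
#' Coordinates come from the embedded conformer; the per-atom parameters are
#' stored as whitespace-separated SDF data fields.
#'
#' @param mols An embedded `mol_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  stopifnot(inherits(mols, "mol_tbl"))
  if (anyNA(mols$molblock)) {
    stop("molecules carry no 3D molblock; run embed_structures() first",
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  fmt_field <- function(name, value) {
    c(sprintf(">  <%s>", name), paste(signif(value, 8), collapse = " "), "")
  }
  for (i in seq_len(nrow(mols))) {
    block <- sub("\n$", "", mols$molblock[i])
    writeLines(block, con)
    atoms <- mols$atoms[[i]]
    if (!anyNA(atoms$charge)) {
      writeLines(fmt_field("ecoqsar_charge", atoms$charge), con)
      writeLines(fmt_field("ecoqsar_steric", atoms$steric), con)
      writeLines(fmt_field("ecoqsar_hydrophobic", atoms$hydrophobic), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
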