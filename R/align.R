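# Least-squares rigid superposition (Kabsch). P and Q are n x 3 matrices of
# paired coordinates; returns the rotation R and translation applied to the
# full coordinate set `coords` so the mapped atoms of P best fit Q.
kabsch_transform <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, center_from = cp, center_to = cq)
}

apply_transform <- function(coords, tf) {
  sweep(sweep(coords, 2, tf$center_from) %*% tf$rotation, 2, tf$center_to, "+")
}

#' Align molecules onto a template by skeleton superposition
#'
#' Each molecule is rigidly rotated and translated to minimize the RMSD
#' between its mapped skeleton atoms and the corresponding atoms of the
#' template (least-squares/Kabsch superposition). The common phthalate core
#' is the usual skeleton for PAE sets; mappings can be generated with
#' [core_mapping()].
#'
#' @param mols An embedded `mol_tbl`.
#' @param template Id of the template molecule (kept fixed).
#' @param mapping A tibble with columns `id`, `mol_atom`, `ref_atom`
#'   (1-based atom indices pairing each molecule onto the template); at
#'   least 3 pairs per molecule. Defaults to [core_mapping()] on the
#'   phthalate diester core.
#' @return The `mol_tbl` with transformed coordinates and an `rmsd` column
#'   (over mapped atoms, in Angstrom).
#' @export
align_to_template <- function(mols, template, mapping = NULL) {
  stopifnot(inherits(mols, "mol_tbl"), template %in% mols$id)
  if (is.null(mapping)) mapping <- core_mapping(mols)
  if (!"ref_atom" %in% names(mapping)) {
    if (!"core_pos" %in% names(mapping)) {
      stop("mapping needs either a 'ref_atom' or a 'core_pos' column",
           call. = FALSE)
    }
    tmpl <- mapping[mapping$id == template, , drop = FALSE]
    mapping$ref_atom <- tmpl$mol_atom[match(mapping$core_pos, tmpl$core_pos)]
  }
  ref_atoms <- mols$atoms[[match(template, mols$id)]]
  ref_xyz <- as.matrix(ref_atoms[, c("x", "y", "z")])
  if (anyNA(ref_xyz)) stop("template has no 3D coordinates", call. = FALSE)
  out <- mols
  out$rmsd <- NA_real_
  for (i in seq_len(nrow(mols))) {
    map_i <- mapping[mapping$id == mols$id[i], , drop = FALSE]
    if (nrow(map_i) < 3) {
      stop("alignment mapping for '", mols$id[i],
           "' has fewer than 3 atom pairs", call. = FALSE)
    }
    if (anyDuplicated(map_i$mol_atom) || anyDuplicated(map_i$ref_atom)) {
      stop("alignment mapping for '", mols$id[i], "' is not injective",
           call. = FALSE)
    }
    xyz <- as.matrix(mols$atoms[[i]][, c("x", "y", "z")])
    if (anyNA(xyz)) stop("molecule '", mols$id[i], "' has no 3D coordinates",
                         call. = FALSE)
    tf <- kabsch_transform(xyz[map_i$mol_atom, , drop = FALSE],
                           ref_xyz[map_i$ref_atom, , drop = FALSE])
    new_xyz <- apply_transform(xyz, tf)
    out$atoms[[i]][, c("x", "y", "z")] <- new_xyz
    dev <- new_xyz[map_i$mol_atom, , drop = FALSE] -
      ref_xyz[map_i$ref_atom, , drop = FALSE]
    out$rmsd[i] <- sqrt(mean(rowSums(dev^2)))
  }
  out
}

#' Build an alignment mapping from a common substructure
#'
#' Matches `smarts` in every molecule and pairs the matched atoms
#' positionally, so all molecules map onto the same core atoms of the
#' template.
#'
#' @param mols A `mol_tbl`.
#' @param smarts Core pattern; default is the phthalate diester skeleton.
#' @return A mapping tibble usable by [align_to_template()] (`ref_atom`
#'   refers to match positions of the template's own core match).
#' @export
core_mapping <- function(mols, smarts = "[#6]OC(=O)c1ccccc1C(=O)O[#6]") {
  matches <- match_substructure(mols, smarts)
  if (any(matches$n_matches == 0)) {
    stop("core pattern not found in: ",
         paste(matches$id[matches$n_matches == 0], collapse = ", "),
         call. = FALSE)
  }
  # pair every molecule's k-th core atom with the template's k-th core atom;
  # ref_atom indices are resolved against the chosen template at align time
  purrr::map2_dfr(matches$id, matches$match, function(id, idx) {
    tibble::tibble(id = id, mol_atom = idx, core_pos = seq_along(idx))
  })
}
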