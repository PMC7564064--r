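#' Build a rectangular field lattice around aligned molecules
#'
#' @param mols An aligned, embedded `mol_tbl`.
#' @param spacing Lattice spacing in Angstrom (default 2.0).
#' @param margin Margin beyond the union bounding box in Angstrom
#'   (default 4.0).
#' @return A `field_grid` object: origin, spacing, per-axis point counts
#'   and the lattice point coordinates.
#' @export
field_grid <- function(mols, spacing = 2, margin = 4) {
  stopifnot(inherits(mols, "mol_tbl"), spacing > 0, margin >= 0)
  xyz <- do.call(rbind, purrr::map(mols$atoms,
                                   ~ as.matrix(.x[, c("x", "y", "z")])))
  if (anyNA(xyz)) stop("molecules must be embedded before building a grid",
                       call. = FALSE)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  axes <- purrr::map2(lo, counts, ~ .x + spacing * (seq_len(.y) - 1))
  pts <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  structure(list(origin = lo, spacing = spacing, counts = counts,
                 points = pts),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat("<field_grid> ", paste(x$counts, collapse = " x "),
      " points, spacing ", x$spacing, " A\n", sep = "")
  invisible(x)
}

grid_identical <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    identical(a$counts, b$counts)
}

#' Default probe-atom properties for the similarity fields
#'
#' A unit probe: charge +1 e, radius 1 Angstrom (steric weight = radius
#' cubed), hydrophobicity +1, donor and acceptor strength +1.
#'
#' @return Named numeric vector with elements `S`, `E`, `H`, `D`, `A`.
#' @export
default_probe <- function() {
  c(S = 1, E = 1, H = 1, D = 1, A = 1)
}

#' Compute Gaussian similarity-index fields on a lattice
#'
#' For every lattice point q and field F in steric (S), electrostatic (E),
#' hydrophobic (H), H-bond donor (D) and acceptor (A), the similarity index
#' is `A_F(q) = -sum_atoms w_probe,F * w_atom,F * exp(-alpha * r^2)`, with
#' `r` the probe-atom distance. The Gaussian attenuation avoids the
#' singularities of Lennard-Jones/Coulomb potentials, so no cutoff inside
#' the molecule is needed.
#'
#' @param mols Aligned, parameterized `mol_tbl` (see
#'   [assign_field_params()]).
#' @param grid A `field_grid`; built from `mols` when `NULL`.
#' @param alpha Attenuation factor (default 0.3).
#' @param probe Probe weights per field, see [default_probe()].
#' @param spacing,margin Passed to [field_grid()] when `grid` is `NULL`.
#' @return A `comsia_fields` object: descriptor matrix `X` (molecules x
#'   (points * 5 fields), columns labelled `field@point`), the grid, and
#'   metadata.
#' @export
compute_fields <- function(mols, grid = NULL, alpha = 0.3,
                           probe = default_probe(), spacing = 2, margin = 4) {
  stopifnot(inherits(mols, "mol_tbl"))
  if (is.null(grid)) grid <- field_grid(mols, spacing, margin)
  fields <- c("S", "E", "H", "D", "A")
  stopifnot(all(fields %in% names(probe)))
  pts <- grid$points
  np <- nrow(pts)
  lo_box <- apply(pts, 2, min)
  hi_box <- apply(pts, 2, max)
  X <- matrix(0, nrow(mols), np * length(fields))
  for (i in seq_len(nrow(mols))) {
    at <- mols$atoms[[i]]
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (anyNA(xyz)) stop("molecule '", mols$id[i], "' is not embedded",
                         call. = FALSE)
    if (nrow(xyz) > 0 &&
        (any(sweep(xyz, 2, lo_box) < -1e-9) ||
         any(sweep(xyz, 2, hi_box) > 1e-9))) {
      stop("grid does not enclose molecule '", mols$id[i], "'",
           call. = FALSE)
    }
    if (anyNA(at$charge)) {
      stop("molecule '", mols$id[i], "' lacks field parameters; run ",
           "assign_field_params() first", call. = FALSE)
    }
    # squared distances: points x atoms
    d2 <- outer(rowSums(pts^2), rowSums(xyz^2), "+") - 2 * pts %*% t(xyz)
    G <- exp(-alpha * d2)
    W <- cbind(S = at$steric, E = at$charge, H = at$hydrophobic,
               D = as.numeric(at$donor), A = as.numeric(at$acceptor))
    vals <- -G %*% W %*% diag(probe[fields])
    X[i, ] <- as.numeric(vals)
  }
  colnames(X) <- as.character(outer(seq_len(np), fields,
                                    function(p, f) paste0(f, "@", p)))
  rownames(X) <- mols$id
  structure(list(X = X, grid = grid, fields = fields, alpha = alpha,
                 probe = probe,
                 field_of_column = rep(fields, each = np),
                 point_of_column = rep(seq_len(np), times = length(fields))),
            class = "comsia_fields")
}

#' @export
print.comsia_fields <- function(x, ...) {
  cat("<comsia_fields> ", nrow(x$X), " molecules x ", ncol(x$X),
      " descriptors (", nrow(x$grid$points), " points x ",
      length(x$fields), " fields)\n", sep = "")
  invisible(x)
}
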