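#' StDev*Coeff contour map of a field QSAR model
#'
#' Maps each retained lattice column's `coefficient * standard deviation`
#' back onto the lattice and marks favored/disfavored regions: favored
#' points are positive values above the `favored` percentile of the
#' positive values, disfavored points are negative values below the
#' `disfavored` percentile of the negative values (the customary 80/20
#' contour levels).
#'
#' @param model A `comsia_model`.
#' @param field One of `"S"`, `"E"`, `"H"`, `"D"`, `"A"`.
#' @param favored,disfavored Percentiles (default 80 and 20).
#' @return A `comsia_map` tibble: lattice coordinates, `stdev_coeff`, and
#'   logical `favored` / `disfavored` masks (dropped columns carry 0).
#' @export
contour_map <- function(model, field, favored = 80, disfavored = 20) {
  stopifnot(inherits(model, "comsia_model"), field %in% model$fields)
  np <- nrow(model$grid$points)
  vals <- numeric(np)
  sel <- model$field_of_column == field
  vals[model$point_of_column[sel]] <-
    (model$pls$coef * model$column_sd)[sel]
  pos <- vals[vals > 0]
  neg <- vals[vals < 0]
  fav_cut <- if (length(pos)) stats::quantile(pos, favored / 100) else Inf
  dis_cut <- if (length(neg)) stats::quantile(neg, disfavored / 100) else -Inf
  out <- tibble::tibble(
    point = seq_len(np),
    x = model$grid$points[, 1],
    y = model$grid$points[, 2],
    z = model$grid$points[, 3],
    field = field,
    stdev_coeff = vals,
    favored = vals > 0 & vals > fav_cut,
    disfavored = vals < 0 & vals < dis_cut
  )
  attr(out, "grid") <- model$grid
  class(out) <- c("comsia_map", class(tibble::tibble()))
  out
}

#' Export a contour map as an OpenDX grid file
#'
#' Writes the lattice values in the plain-text OpenDX "regular positions"
#' format readable by common molecular viewers.
#'
#' @param map A `comsia_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(map, path) {
  stopifnot(inherits(map, "comsia_map"))
  grid <- attr(map, "grid")
  n <- grid$counts
  # OpenDX expects z fastest; our lattice is x fastest, so reorder
  idx <- order(map$x, map$y, map$z)
  vals <- map$stdev_coeff[idx]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.0 0.0", grid$spacing),
    sprintf("delta 0.0 %.6f 0.0", grid$spacing),
    sprintf("delta 0.0 0.0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))
  ), con)
  triples <- split(vals, ceiling(seq_along(vals) / 3))
  writeLines(vapply(triples, function(v)
    paste(sprintf("%.6e", v), collapse = " "), character(1)), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Export a contour map as a point-list CSV
#'
#' @param map A `comsia_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.comsia_map <- function(object, slice = NULL, ...) {
  zs <- sort(unique(object$z))
  if (is.null(slice)) slice <- zs[ceiling(length(zs) / 2)]
  dat <- dplyr::filter(object, abs(.data$z - slice) < 1e-9)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$stdev_coeff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac") +
    ggplot2::labs(title = paste0(dat$field[1], " field, z = ",
                                 signif(slice, 3), " A"),
                  fill = "StDev*Coeff") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
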