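#' Min-max normalization of effect indices
#'
#' Rescales each scored column to \[0, 1\]. Positive indices (larger is
#' better, e.g. LOI or fish LC50) use `(x - min) / (max - min)`; inverse
#' indices (smaller is better, e.g. logBCF) use `(max - x) / (max - min)`,
#' so 1 is always the ideal end.
#'
#' @param data A data frame of molecules by raw index columns.
#' @param directions Named character vector mapping column names to
#'   `"positive"` or `"inverse"`; only named columns are normalized.
#' @return `data` with the named columns replaced by their normalized
#'   values.
#' @export
normalize_indices <- function(data, directions) {
  stopifnot(is.data.frame(data), length(directions) >= 1,
            !is.null(names(directions)),
            all(directions %in% c("positive", "inverse")))
  missing_cols <- setdiff(names(directions), names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data
  for (col in names(directions)) {
    x <- data[[col]]
    if (anyNA(x)) stop("missing values in scored column '", col, "'",
                       call. = FALSE)
    rng <- range(x)
    if (rng[1] == rng[2]) {
      stop("degenerate (constant) index column '", col,
           "' cannot be normalized", call. = FALSE)
    }
    out[[col]] <- if (directions[[col]] == "positive") {
      (x - rng[1]) / (rng[2] - rng[1])
    } else {
      (rng[2] - x) / (rng[2] - rng[1])
    }
  }
  out
}

#' Ideal-point comprehensive score
#'
#' Scores each molecule by its weighted distance from the all-ideal point
#' `C*` in normalized index space; smaller is better. The default metric is
#' the euclidean distance `Z = sqrt(sum_j lambda_j (C_ij - C*_j)^2)`; the
#' `"manhattan"` variant `Z = sum_j lambda_j |C_ij - C*_j|` is also
#' available. Default weights are 40% flammability, 30% biotoxicity, 30%
#' enrichment.
#'
#' @param data Data frame with an id column and raw index columns.
#' @param weights Named numeric weights, one per scored index; must sum
#'   to 1.
#' @param directions Named directions as in [normalize_indices()]; defaults
#'   to `"positive"` for every weighted column.
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @param ideal Ideal point value(s) `C*` (default 1).
#' @param id Id column (tidy-eval; default `molecule`).
#' @return A tibble of class `ideal_scores`: id column, normalized index
#'   columns, and the comprehensive value `Z`.
#' @examples
#' tbl <- tibble::tibble(molecule = c("a", "b", "c"),
#'                       f = c(1, 2, 3), t = c(3, 1, 2), e = c(2, 3, 1))
#' ideal_point_score(tbl, c(f = 0.4, t = 0.3, e = 0.3),
#'                   directions = c(f = "positive", t = "positive",
#'                                  e = "inverse"))
#' @export
ideal_point_score <- function(data, weights, directions = NULL,
                              metric = c("euclidean", "manhattan"),
                              ideal = 1, id = molecule) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(weights), !is.null(names(weights)), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("index weights must sum to 1 (got ", sum(weights), ")",
         call. = FALSE)
  }
  if (is.null(directions)) {
    directions <- stats::setNames(rep("positive", length(weights)),
                                  names(weights))
  }
  if (!setequal(names(weights), names(directions))) {
    stop("weights and directions must name the same index columns",
         call. = FALSE)
  }
  ids <- dplyr::pull(data, {{ id }})
  norm <- normalize_indices(data, directions)
  C <- as.matrix(norm[names(weights)])
  ideal <- rep_len(ideal, length(weights))
  dev <- sweep(C, 2, ideal)
  z <- switch(metric,
    euclidean = sqrt(as.numeric(abs(dev)^2 %*% weights)),
    manhattan = as.numeric(abs(dev) %*% weights)
  )
  out <- tibble::tibble(molecule = ids)
  out <- dplyr::bind_cols(out, tibble::as_tibble(C))
  out$Z <- z
  attr(out, "weights") <- weights
  attr(out, "directions") <- directions
  attr(out, "metric") <- metric
  class(out) <- c("ideal_scores", class(tibble::tibble()))
  out
}

#' Rank molecules by comprehensive score
#'
#' Ascending in `Z` (closest to ideal first); ties broken by molecule id.
#'
#' @param scores An `ideal_scores` tibble (or any data frame with
#'   `molecule` and `Z`).
#' @return The sorted tibble with a `rank` column.
#' @export
rank_by_score <- function(scores) {
  out <- dplyr::arrange(scores, .data$Z, .data$molecule)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' @export
autoplot.ideal_scores <- function(object, ...) {
  dat <- rank_by_score(object)
  dat$molecule <- factor(dat$molecule, levels = rev(dat$molecule))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$Z, y = .data$molecule)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "comprehensive evaluation value Z (smaller = better)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
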