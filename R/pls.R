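# NIPALS PLS1 kernel. X: n x p, y: length n. Returns regression coefficients
# on the original (uncentered) scale. For a univariate response each
# component is exact (no inner iteration).
nipals_kernel <- function(X, y, ncomp) {
  Xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, Xm)
  yc <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  scores <- matrix(0, nrow(X), ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- crossprod(Xc, t) / tt
    q <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pl)
    yc <- yc - q * t
    W[, a] <- w
    P[, a] <- pl
    qv[a] <- q
    scores[, a] <- t
    used <- a
  }
  if (used == 0L) stop("response has no covariance with the descriptors",
                       call. = FALSE)
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  qv <- qv[seq_len(used)]
  scores <- scores[, seq_len(used), drop = FALSE]
  R <- W %*% solve(t(P) %*% W)
  coef <- as.numeric(R %*% qv)
  list(coef = coef, intercept = ym - sum(Xm * coef), ncomp = used,
       weights = W, loadings = P, y_loadings = qv, scores = scores,
       x_means = Xm, y_mean = ym)
}

#' Fit a PLS1 latent-variable regression (NIPALS)
#'
#' @param X Descriptor matrix (rows = samples).
#' @param y Numeric response.
#' @param ncomp Number of latent components; must not exceed
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return A `pls_model` with coefficients, intercept, fitted values and
#'   the latent decomposition.
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  if (ncomp < 1 || ncomp > min(nrow(X) - 1, ncol(X))) {
    stop("ncomp must be between 1 and min(nrow(X) - 1, ncol(X)) = ",
         min(nrow(X) - 1, ncol(X)), call. = FALSE)
  }
  k <- nipals_kernel(X, y, ncomp)
  fitted <- as.numeric(X %*% k$coef + k$intercept)
  rss <- sum((y - fitted)^2)
  ss <- sum((y - mean(y))^2)
  structure(c(k, list(fitted = fitted, y = y, r2 = 1 - rss / ss,
                      column_names = colnames(X))),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coef)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coef), call. = FALSE)
  }
  as.numeric(newdata %*% object$coef + object$intercept)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$ncomp, " components, ", length(x$coef),
      " descriptors, r2 = ", signif(x$r2, 4), "\n", sep = "")
  invisible(x)
}

#' Leave-one-out cross-validated q2
#'
#' Refits the PLS model with each sample excluded and predicts the held-out
#' response; `q2 = 1 - PRESS / SS` with `SS` the total squared deviation of
#' `y` about its mean. Values above 0.5 are conventionally taken as
#' evidence of predictive ability.
#'
#' @inheritParams pls_fit
#' @return A list with `q2`, `press`, `ss` and the vector of held-out
#'   predictions.
#' @export
loo_q2 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  preds <- vapply(seq_len(n), function(i) {
    k <- nipals_kernel(X[-i, , drop = FALSE], y[-i],
                       min(ncomp, n - 2, ncol(X)))
    sum(X[i, ] * k$coef) + k$intercept
  }, numeric(1))
  press <- sum((y - preds)^2)
  ss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / ss, press = press, ss = ss, predictions = preds)
}

#' Fit a CoMSIA-style field QSAR model
#'
#' Joins the similarity-field descriptors to a response with NIPALS PLS.
#' Near-constant lattice columns are dropped first: a column is retained
#' only if its value range is at least `energy_cutoff * cutoff_fraction`
#' (the filtering analog of the customary column-energy threshold). The
#' number of latent components is chosen by maximizing the leave-one-out
#' q2 over `1..max_ncomp`, capped at `n - 2` components unless
#' `allow_large_ncomp` is set.
#'
#' @param fields A `comsia_fields` object for the training molecules.
#' @param y Numeric response (one per molecule).
#' @param ncomp Fixed number of components; `NULL` (default) selects by
#'   LOO q2.
#' @param max_ncomp Largest candidate component count (default
#'   `nrow - 2`).
#' @param energy_cutoff Column-filter energy threshold (default 125.4, in
#'   kJ/mol-equivalent units of the customary setting).
#' @param cutoff_fraction Fraction of `energy_cutoff` a column's range must
#'   reach to be retained (default `1e-5`).
#' @param allow_large_ncomp Permit more than `n - 2` components (not
#'   recommended for small training sets).
#' @return A `comsia_model` with the PLS fit, LOO statistics, field
#'   contribution fractions and the grid needed for prediction.
#' @export
comsia_fit <- function(fields, y, ncomp = NULL, max_ncomp = NULL,
                       energy_cutoff = 125.4, cutoff_fraction = 1e-5,
                       allow_large_ncomp = FALSE) {
  stopifnot(inherits(fields, "comsia_fields"))
  X <- fields$X
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 3)
  rng <- apply(X, 2, function(col) diff(range(col)))
  mask <- rng >= energy_cutoff * cutoff_fraction
  if (!any(mask)) stop("column filter removed every descriptor; lower ",
                       "cutoff_fraction", call. = FALSE)
  Xf <- X[, mask, drop = FALSE]
  cap <- if (allow_large_ncomp) n - 1L else max(1L, n - 2L)
  hi <- min(max_ncomp %||% cap, cap, ncol(Xf), n - 1L)
  if (is.null(ncomp)) {
    q2s <- vapply(seq_len(hi), function(a) loo_q2(Xf, y, a)$q2, numeric(1))
    ncomp <- which.max(q2s)
  } else if (ncomp > cap && !allow_large_ncomp) {
    stop("ncomp = ", ncomp, " exceeds the n - 2 cap for ", n,
         " training molecules; set allow_large_ncomp = TRUE to override",
         call. = FALSE)
  }
  fit <- pls_fit(Xf, y, ncomp)
  cv <- loo_q2(Xf, y, ncomp)
  structure(list(pls = fit, mask = mask, grid = fields$grid,
                 fields = fields$fields, alpha = fields$alpha,
                 probe = fields$probe,
                 field_of_column = fields$field_of_column[mask],
                 point_of_column = fields$point_of_column[mask],
                 column_sd = apply(Xf, 2, stats::sd),
                 y = y, q2 = cv$q2, press = cv$press,
                 molecule = rownames(X)),
            class = "comsia_model")
}

#' @export
print.comsia_model <- function(x, ...) {
  g <- glance(x)
  cat("<comsia_model> ", g$n_train, " molecules, ", g$ncomp,
      " components, ", sum(x$mask), " retained descriptors\n",
      "  q2 (LOO) = ", signif(g$q2, 4), ", r2 = ", signif(g$r2, 4),
      ", SEE = ", signif(g$see, 4), "\n", sep = "")
  invisible(x)
}

#' Predict the response for new molecules or fields
#'
#' @param object A `comsia_model`.
#' @param newdata A `comsia_fields` object computed on the model's own grid
#'   (or an aligned, parameterized `mol_tbl`, for which fields are computed
#'   on that grid).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.comsia_model <- function(object, newdata, ...) {
  if (inherits(newdata, "mol_tbl")) {
    newdata <- compute_fields(newdata, grid = object$grid,
                              alpha = object$alpha, probe = object$probe)
  }
  stopifnot(inherits(newdata, "comsia_fields"))
  if (!grid_identical(newdata$grid, object$grid)) {
    stop("field grid mismatch: prediction fields must be computed on the ",
         "model's training grid", call. = FALSE)
  }
  predict(object$pls, newdata$X[, object$mask, drop = FALSE])
}

#' Fit and external-validation statistics of a field QSAR model
#'
#' `r2 = 1 - RSS/SS`; `SEE = sqrt(RSS / (m - n - 1))`;
#' `F = (r2/n) / ((1 - r2)/(m - n - 1))`. With an external test set,
#' `r2_pred = 1 - PRESS_test / SD_test` where `SD_test` sums squared
#' deviations of the test responses about the training mean, and
#' `SEP = sqrt(PRESS_test / m_test)`.
#'
#' @param model A `comsia_model`.
#' @param test_fields Optional `comsia_fields` for an external test set.
#' @param test_y Test responses matching `test_fields`.
#' @return One-row tibble with `ncomp`, `q2`, `r2`, `see`, `f_stat`,
#'   `r2_pred`, `sep` and the conventional acceptance flags
#'   (`q2 > 0.5`, `r2 > 0.9`, `r2_pred > 0.6`).
#' @export
model_stats <- function(model, test_fields = NULL, test_y = NULL) {
  stopifnot(inherits(model, "comsia_model"))
  fit <- model$pls
  m <- length(fit$y)
  n <- fit$ncomp
  if (m - n - 1 <= 0) {
    stop("SEE/F undefined: m - n - 1 <= 0 for m = ", m, ", n = ", n,
         call. = FALSE)
  }
  rss <- sum((fit$y - fit$fitted)^2)
  r2 <- fit$r2
  see <- sqrt(rss / (m - n - 1))
  f_stat <- (r2 / n) / ((1 - r2) / (m - n - 1))
  r2_pred <- sep <- NA_real_
  if (!is.null(test_fields)) {
    stopifnot(!is.null(test_y))
    pred <- predict(model, test_fields)
    press <- sum((test_y - pred)^2)
    sd_test <- sum((test_y - mean(fit$y))^2)
    r2_pred <- 1 - press / sd_test
    sep <- sqrt(press / length(test_y))
  }
  tibble::tibble(ncomp = n, q2 = model$q2, r2 = r2, see = see,
                 f_stat = f_stat, r2_pred = r2_pred, sep = sep,
                 predictive = model$q2 > 0.5, well_fitted = r2 > 0.9,
                 externally_valid = !is.na(r2_pred) & r2_pred > 0.6)
}

#' Per-field contribution fractions
#'
#' Contribution of field F is `sum_{cols in F} |coef * sd|` over the total,
#' in percent; fractions sum to 100. Reported in the order S, E, H, D, A.
#'
#' @param model A `comsia_model`.
#' @return Tibble with `field` and `fraction` (%).
#' @export
field_fractions <- function(model) {
  stopifnot(inherits(model, "comsia_model"))
  w <- abs(model$pls$coef * model$column_sd)
  tot <- sum(w)
  frac <- vapply(model$fields, function(f) {
    if (tot == 0) 0 else 100 * sum(w[model$field_of_column == f]) / tot
  }, numeric(1))
  tibble::tibble(field = model$fields, fraction = unname(frac))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.comsia_model <- function(x, ...) {
  pts <- x$grid$points[x$point_of_column, , drop = FALSE]
  coef <- x$pls$coef
  sds <- x$column_sd
  tibble::tibble(
    term = x$pls$column_names,
    field = x$field_of_column,
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    estimate = coef,
    column_sd = sds,
    stdev_coeff = coef * sds
  )
}

#' @export
glance.comsia_model <- function(x, ...) {
  fit <- x$pls
  m <- length(fit$y)
  n <- fit$ncomp
  rss <- sum((fit$y - fit$fitted)^2)
  tibble::tibble(n_train = m, ncomp = n, q2 = x$q2, r2 = fit$r2,
                 see = sqrt(rss / (m - n - 1)),
                 n_descriptors = sum(x$mask))
}

#' @export
autoplot.comsia_model <- function(object, ...) {
  dat <- tibble::tibble(observed = object$pls$y,
                        fitted = object$pls$fitted,
                        molecule = object$molecule %||%
                          as.character(seq_along(object$pls$y)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(colour = "#d95f02", size = 2) +
    ggplot2::labs(x = "observed response", y = "fitted response") +
    ggplot2::theme_minimal()
}
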