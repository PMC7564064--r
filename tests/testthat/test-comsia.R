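test_that("superposition recovers rigid motions exactly", {
  set.seed(1)
  xyz <- matrix(rnorm(24), ncol = 3)
  mols <- toy_mol_tbl(toy_mol("ref", xyz),
                      toy_mol("moved", xyz %*% rotation_z(1.1) +
                                matrix(rep(c(3, -1, 2), each = 8), ncol = 3)))
  mapping <- tidyr::expand_grid(id = c("ref", "moved")) |>
    dplyr::reframe(mol_atom = 1:8, ref_atom = 1:8, .by = id)
  aligned <- align_to_template(mols, "ref", mapping)
  expect_equal(aligned$rmsd, c(0, 0), tolerance = 1e-6)
  expect_equal(as.matrix(aligned$atoms[[2]][, c("x", "y", "z")]),
               xyz, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("superposition agrees with an independent Procrustes oracle", {
  set.seed(7)
  target <- matrix(rnorm(30), ncol = 3)
  moving <- target %*% rotation_z(0.6) + 0.05 * matrix(rnorm(30), ncol = 3)
  mols <- toy_mol_tbl(toy_mol("t", target), toy_mol("m", moving))
  mapping <- tibble::tibble(id = rep(c("t", "m"), each = 10),
                            mol_atom = rep(1:10, 2),
                            ref_atom = rep(1:10, 2))
  aligned <- align_to_template(mols, "t", mapping)
  proc <- vegan::procrustes(target, moving, scale = FALSE,
                            symmetric = FALSE)
  # vegan reports rotated coordinates centered at the origin; shift back
  # onto the target centroid before comparing
  got <- as.matrix(aligned$atoms[[2]][, c("x", "y", "z")])
  expect_equal(sweep(got, 2, colMeans(target)), unclass(proc$Yrot),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("alignment validates mappings", {
  mols <- toy_mol_tbl(toy_mol("a", diag(3)), toy_mol("b", diag(3)))
  short <- tibble::tibble(id = c("a", "a", "a", "b", "b"),
                          mol_atom = c(1, 2, 3, 1, 2),
                          ref_atom = c(1, 2, 3, 1, 2))
  expect_error(align_to_template(mols, "a", short), "fewer than 3")
  dup <- tibble::tibble(id = rep(c("a", "b"), each = 3),
                        mol_atom = c(1, 2, 3, 1, 2, 2),
                        ref_atom = c(1, 2, 3, 1, 2, 3))
  expect_error(align_to_template(mols, "a", dup), "injective")
})

test_that("field values follow the Gaussian similarity closed form", {
  grid <- list(origin = c(0, 0, 0), spacing = 2, counts = c(3L, 3L, 3L))
  axes <- lapply(grid$origin, function(o) o + 2 * (0:2))
  grid$points <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]],
                                       z = axes[[3]]))
  class(grid) <- "field_grid"
  mol <- toy_mol_tbl(toy_mol("one", matrix(c(2, 2, 2), ncol = 3),
                             steric = 5, hydrophobic = 1.5, charge = 0.2,
                             donor = TRUE, acceptor = FALSE))
  fl <- compute_fields(mol, grid, alpha = 0.3)
  # at the atom's own lattice point: -w_probe * w_atom
  at_atom <- which(apply(grid$points, 1, function(p)
    all(p == c(2, 2, 2))))
  expect_equal(fl$X[1, paste0("S@", at_atom)], -5)
  expect_equal(fl$X[1, paste0("H@", at_atom)], -1.5)
  expect_equal(fl$X[1, paste0("E@", at_atom)], -0.2)
  expect_equal(fl$X[1, paste0("D@", at_atom)], -1)
  expect_equal(fl$X[1, paste0("A@", at_atom)], 0)
  # exp(-alpha r^2) decay at a neighbor 2 A away
  neighbor <- which(apply(grid$points, 1, function(p)
    all(p == c(0, 2, 2))))
  expect_equal(fl$X[1, paste0("S@", neighbor)], -5 * exp(-0.3 * 4))
})

test_that("fields are linear in atom parameters and zero for empty molecules", {
  xyz <- matrix(c(0, 0, 0, 1.5, 0, 0), ncol = 3, byrow = TRUE)
  mols <- toy_mol_tbl(toy_mol("a", xyz, steric = 10),
                      toy_mol("b", xyz, steric = 20))
  fl <- compute_fields(mols, margin = 3)
  sidx <- fl$field_of_column == "S"
  expect_equal(2 * fl$X[1, sidx], fl$X[2, sidx], tolerance = 1e-12)
  empty <- toy_mol_tbl(toy_mol("e", matrix(numeric(0), ncol = 3)))
  fe <- compute_fields(empty, fl$grid)
  expect_true(all(fe$X == 0))
})

test_that("fields are equivariant under a rigid motion of molecules and grid", {
  syn <- generate_synthetic_qsar(n_molecules = 5, seed = 3)
  R <- rotation_z(0.9)
  shift <- c(2, -1, 4)
  moved <- rotate_mols(syn$molecules, R, shift)
  grid2 <- syn$fields$grid
  grid2$points <- sweep(grid2$points %*% R, 2, shift, "+")
  f2 <- compute_fields(moved, grid2, alpha = syn$fields$alpha)
  expect_equal(unname(f2$X), unname(syn$fields$X), tolerance = 1e-10)
})

test_that("a non-enclosing grid is rejected", {
  mol <- toy_mol_tbl(toy_mol("far", matrix(c(50, 50, 50), ncol = 3)))
  near <- toy_mol_tbl(toy_mol("near", matrix(c(0, 0, 0), ncol = 3)))
  grid <- field_grid(near, margin = 2)
  expect_error(compute_fields(mol, grid), "enclose")
})

test_that("PLS recovers exact linear responses and nests correctly", {
  set.seed(5)
  X <- matrix(rnorm(60), 12, 5) %*% matrix(rnorm(45), 5, 9)  # rank 5
  colnames(X) <- paste0("c", 1:9)
  beta <- rnorm(9)
  y <- as.numeric(X %*% beta)
  fit <- pls_fit(X, y, 5)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  r2s <- vapply(1:5, function(k) pls_fit(X, y, k)$r2, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
  expect_error(pls_fit(X, y, 12), "ncomp")
})

test_that("PLS matches an independent reference implementation", {
  fx <- pls_fixture()
  suppressMessages({
    ref <- mixOmics::pls(fx$X, matrix(fx$y, ncol = 1), ncomp = 3,
                         scale = FALSE, mode = "regression")
  })
  for (k in c(1L, 3L)) {
    fit <- pls_fit(fx$X, fx$y, k)
    mine <- predict(fit, fx$X)
    theirs <- predict(ref, fx$X)$predict[, 1, k]
    expect_equal(mine, unname(theirs), tolerance = 1e-8)
  }
})

test_that("LOO q2 equals an explicit refit loop and ranks fixtures sensibly", {
  fx <- pls_fixture(noise = 0.2)
  fast <- loo_q2(fx$X, fx$y, 3)
  # independent oracle: rebuild the full model object for every fold
  preds <- vapply(seq_along(fx$y), function(i) {
    fit <- pls_fit(fx$X[-i, ], fx$y[-i], 3)
    predict(fit, fx$X[i, , drop = FALSE])
  }, numeric(1))
  press <- sum((fx$y - preds)^2)
  q2_oracle <- 1 - press / sum((fx$y - mean(fx$y))^2)
  expect_equal(fast$q2, q2_oracle, tolerance = 1e-10)
  # near-noiseless low-dimensional fixture: held-out prediction is exact
  strong <- pls_fixture(n = 20, p = 5, noise = 1e-6, seed = 2)
  expect_gt(loo_q2(strong$X, strong$y, 5)$q2, 0.99)
})

test_that("permuted responses show no leave-one-out predictivity", {
  syn <- generate_synthetic_qsar(n_molecules = 20, snr = 3, seed = 11)
  model <- comsia_fit(syn$fields, syn$response, ncomp = 2)
  Xf <- syn$fields$X[, model$mask, drop = FALSE]
  set.seed(99)
  q2s <- vapply(1:100, function(i) {
    loo_q2(Xf, sample(syn$response), 2)$q2
  }, numeric(1))
  expect_lt(stats::quantile(q2s, 0.95), 0.2)
  expect_lt(mean(q2s), 0)
})

test_that("model statistics follow the stated conventions", {
  mols <- generate_synthetic_qsar(n_molecules = 14, snr = 10, seed = 21)
  model <- comsia_fit(mols$fields, mols$response, ncomp = 3)
  st <- model_stats(model)
  fit <- model$pls
  m <- length(fit$y)
  rss <- sum((fit$y - fit$fitted)^2)
  expect_equal(st$see, sqrt(rss / (m - 3 - 1)))
  expect_equal(st$f_stat, (st$r2 / 3) / ((1 - st$r2) / (m - 3 - 1)))
  # external set identical to training: r2_pred near r2, SEP near RMS error
  st2 <- model_stats(model, mols$fields, mols$response)
  expect_equal(st2$sep, sqrt(rss / m))
  expect_equal(st2$r2_pred, 1 - rss / sum((fit$y - mean(fit$y))^2))
})

test_that("component count is capped for small training sets", {
  syn <- generate_synthetic_qsar(n_molecules = 8, snr = 10, seed = 2)
  expect_error(comsia_fit(syn$fields, syn$response, ncomp = 7),
               "allow_large_ncomp")
  fit <- comsia_fit(syn$fields, syn$response)
  expect_lte(fit$pls$ncomp, 6)
})

test_that("field contributions sum to 100 and isolate single-field signals", {
  syn <- generate_synthetic_qsar(n_molecules = 15, snr = 5, seed = 13)
  model <- comsia_fit(syn$fields, syn$response)
  fr <- field_fractions(model)
  expect_equal(sum(fr$fraction), 100, tolerance = 0.1)
  expect_equal(fr$field, c("S", "E", "H", "D", "A"))
  # molecules varying only in steric parameters: all weight lands on S
  xyz <- matrix(c(0, 0, 0), ncol = 3)
  mols <- toy_mol_tbl(lapply(1:6, function(i)
    toy_mol(paste0("m", i), xyz, steric = 5 * i)))
  fl <- compute_fields(mols, margin = 3)
  y <- as.numeric(fl$X %*% (fl$field_of_column == "S"))
  m2 <- comsia_fit(fl, y, ncomp = 1)
  fr2 <- field_fractions(m2)
  expect_equal(fr2$fraction[fr2$field == "S"], 100, tolerance = 1e-6)
})

test_that("contour maps mark percentile regions and recover planted signal", {
  syn <- generate_synthetic_qsar(n_molecules = 25, sigma = 0, seed = 17)
  model <- comsia_fit(syn$fields, syn$response)
  map <- contour_map(model, "S")
  pos <- map$stdev_coeff[map$stdev_coeff > 0]
  expect_equal(sum(map$favored),
               sum(pos > stats::quantile(pos, 0.8)))
  # planted steric region sits at site_s: favored centroid within 1 spacing
  fav <- map[map$favored, ]
  centroid <- c(mean(fav$x), mean(fav$y), mean(fav$z))
  expect_lt(sqrt(sum((centroid - syn$site_s)^2)),
            model$grid$spacing)
  # zeroed coefficients give empty masks
  zero <- model
  zero$pls$coef[] <- 0
  mz <- contour_map(zero, "S")
  expect_equal(sum(mz$favored) + sum(mz$disfavored), 0)
})

test_that("contour map exports parse as OpenDX and CSV", {
  syn <- generate_synthetic_qsar(n_molecules = 10, snr = 5, seed = 19)
  model <- comsia_fit(syn$fields, syn$response, ncomp = 2)
  map <- contour_map(model, "H")
  dx <- tempfile(fileext = ".dx")
  write_dx(map, dx)
  txt <- readLines(dx)
  expect_match(txt[1], "gridpositions counts")
  items <- as.integer(sub(".*items (\\d+) data.*", "\\1",
                          grep("items", txt, value = TRUE)))
  expect_equal(items, nrow(map))
  csv <- tempfile(fileext = ".csv")
  write_map_csv(map, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(map))
})

test_that("prediction reproduces fitted values and guards the grid", {
  syn <- generate_synthetic_qsar(n_molecules = 12, snr = 5, seed = 23)
  model <- comsia_fit(syn$fields, syn$response, ncomp = 2)
  expect_equal(predict(model, syn$fields), model$pls$fitted,
               tolerance = 1e-12)
  # the column-mean profile predicts the training mean
  Xf <- syn$fields$X[, model$mask, drop = FALSE]
  expect_equal(predict(model$pls, matrix(colMeans(Xf), nrow = 1)),
               mean(syn$response), tolerance = 1e-10)
  other <- generate_synthetic_qsar(n_molecules = 5, seed = 1, spacing = 1.5)
  expect_error(predict(model, other$fields), "grid mismatch")
})

test_that("planted functionals are recovered above the q2 threshold", {
  syn <- generate_synthetic_qsar(n_molecules = 20, snr = 3, seed = 31)
  model <- comsia_fit(syn$fields, syn$response, max_ncomp = 5)
  expect_gt(model$q2, 0.5)
  # the fitted functional tracks the planted one
  expect_gt(cor(model$pls$fitted, syn$signal), 0.9)
})

test_that("column filtering changes the fit only marginally", {
  syn <- generate_synthetic_qsar(n_molecules = 18, snr = 5, seed = 37)
  loose <- comsia_fit(syn$fields, syn$response, ncomp = 3,
                      cutoff_fraction = 0)
  tight <- comsia_fit(syn$fields, syn$response, ncomp = 3,
                      cutoff_fraction = 1e-3)
  expect_lt(sum(tight$mask), sum(loose$mask))
  expect_lt(abs(loose$pls$r2 - tight$pls$r2), 0.05)
})

test_that("tidy/glance/autoplot expose the model in broom style", {
  syn <- generate_synthetic_qsar(n_molecules = 10, snr = 5, seed = 41)
  model <- comsia_fit(syn$fields, syn$response, ncomp = 2)
  td <- tidy(model)
  expect_true(all(c("term", "field", "estimate", "stdev_coeff") %in%
                    names(td)))
  expect_equal(nrow(td), sum(model$mask))
  gl <- glance(model)
  expect_equal(gl$ncomp, 2L)
  expect_s3_class(ggplot2::autoplot(model), "ggplot")
  expect_s3_class(ggplot2::autoplot(contour_map(model, "S")), "ggplot")
})
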