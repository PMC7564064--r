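test_that("derivative enumeration builds canonically named products", {
  plan <- tibble::tibble(parent = c("DMP", "DAP", "DAP"),
                         group1 = c("NO2", "NO2", NA),
                         group2 = c(NA, "OCH3", "CH2NO2"))
  d <- enumerate_derivatives(plan)
  expect_equal(d$molecule,
               c("DMP-1-NO2", "DAP-1-NO2-2-OCH3", "DAP-2-CH2NO2"))
  expect_true(all(d$ok))
  # nitro adds NO2 (3 heavy atoms) to DMP's 14
  expect_equal(d$n_heavy[1], 17L)
  # deterministic and order-stable
  expect_identical(enumerate_derivatives(plan)$smiles, d$smiles)
  expect_equal(nrow(enumerate_derivatives(plan[0, ])), 0)
})

test_that("single mode crosses parents, sites and groups", {
  d <- enumerate_derivatives(groups = c("CH3", "SH"), mode = "single",
                             parse = FALSE)
  expect_equal(nrow(d), 2 * 2 * 2)  # 2 parents x 2 sites x 2 groups
  expect_true("DMP-1-CH3" %in% d$molecule)
  expect_true("DAP-2-SH" %in% d$molecule)
})

test_that("a bad product is reported in-band without aborting the batch", {
  lib <- dplyr::bind_rows(substituent_library(),
                          tibble::tibble(group = "broken", prefix = "C(",
                                         suffix = "C("))
  plan <- tibble::tibble(parent = c("DMP", "DMP"),
                         group1 = c("CH3", NA),
                         group2 = c(NA, "broken"))
  d <- enumerate_derivatives(plan, library = lib)
  expect_equal(d$ok, c(TRUE, FALSE))
  expect_match(d$error[2], "unparsable")
  expect_error(enumerate_derivatives(
    tibble::tibble(parent = "DMP", group1 = "XYZ", group2 = NA)), "XYZ")
})

test_that("endpoint evaluation computes signed percent changes vs parent", {
  syn <- generate_synthetic_qsar(n_molecules = 8, snr = 10, seed = 5)
  model <- comsia_fit(syn$fields, syn$response, ncomp = 2)
  mols <- syn$molecules
  parent_of <- stats::setNames(rep(mols$id[1], nrow(mols)), mols$id)
  rec <- evaluate_derivatives(mols, list(Z = model, LOI = model),
                              parent_of)
  expect_equal(rec$Z_change_pct[1], 0)   # parent vs itself
  expect_equal(rec$LOI_change_pct[1], 0)
  pred <- predict(model, syn$fields)
  # Z improves by decreasing: positive change when prediction fell
  expect_equal(rec$Z_change_pct,
               -(pred - pred[1]) / abs(pred[1]) * 100)
  # LOI improves by increasing: opposite sign convention
  expect_equal(rec$LOI_change_pct,
               (pred - pred[1]) / abs(pred[1]) * 100)
  expect_error(evaluate_derivatives(mols, list(Z = "nope"), parent_of),
               "endpoint")
})

test_that("the screening funnel reproduces the 22 -> 7 selection", {
  eff <- ecoqsar_fixture("derivative_effects")
  scr <- suppressWarnings(screen_derivatives(eff))
  expect_equal(sum(scr$pass), 7)
  expect_setequal(
    scr$molecule[scr$pass],
    c("DAP-2-CH2NO2", "DAP-1-NO2-2-CH2C6H5", "DAP-1-NO2-2-CH2CH3",
      "DAP-1-NO2-2-CH2NO2", "DAP-1-NO2-2-NO2", "DAP-1-NO2-2-OCH3",
      "DAP-2-CH=CH2-1-NO2"))
  # parents never pass; without the LOI threshold all 22 derivatives pass
  expect_false(any(scr$pass[scr$molecule %in% c("DMP", "DAP")]))
  loose <- suppressWarnings(
    screen_derivatives(eff, screen_rules(loi_improvement_min = 0)))
  expect_equal(sum(loose$pass), 22)
})

test_that("the eco screen narrows the seven survivors to six", {
  eff <- ecoqsar_fixture("derivative_effects")
  eco <- ecoqsar_fixture("derivative_eco")
  joined <- dplyr::left_join(eff, eco, by = "molecule")
  scr <- screen_derivatives(joined)
  expect_equal(sum(scr$pass, na.rm = TRUE), 6)
  # the semi-volatility band is what removes DAP-2-CH2NO2 (logKOA 6.282)
  row <- scr[scr$molecule == "DAP-2-CH2NO2", ]
  expect_false(row$pass_koa_band)
  expect_true(row$pass_loi_improvement)
})

test_that("screening respects boundaries and is monotone in thresholds", {
  rec <- tibble::tibble(molecule = c("d1", "d2"),
                        z_decrease_pct = c(10, 10),
                        loi_increase_pct = c(6, 6),
                        lc50_increase_pct = c(5, 5),
                        bcf_decrease_pct = c(5, 5),
                        log_bcf = c(3.29, 3.31))
  scr <- suppressWarnings(screen_derivatives(rec))
  expect_equal(scr$pass, c(TRUE, FALSE))  # 3.31 breaches the 3.30 cap
  # a record identical to its parent (all zero changes) fails
  parent_like <- tibble::tibble(molecule = "p", z_decrease_pct = 0,
                                loi_increase_pct = 0,
                                lc50_increase_pct = 0,
                                bcf_decrease_pct = 0, log_bcf = 1)
  expect_false(suppressWarnings(screen_derivatives(parent_like))$pass)
  # relaxing any threshold never removes a survivor
  eff <- ecoqsar_fixture("derivative_effects")
  base <- suppressWarnings(screen_derivatives(eff))
  for (rules in list(screen_rules(loi_improvement_min = 2),
                     screen_rules(bcf_cap = 10),
                     screen_rules(koa_band = c(0, 100)))) {
    relaxed <- suppressWarnings(screen_derivatives(eff, rules))
    expect_true(all(relaxed$pass[base$pass]))
  }
})

test_that("missing rule columns are skipped with a warning", {
  rec <- tibble::tibble(molecule = "d", z_decrease_pct = 1,
                        loi_increase_pct = 6, lc50_increase_pct = 1,
                        bcf_decrease_pct = 1, log_bcf = 1)
  w <- capture_warnings(screen_derivatives(rec))
  expect_match(w, "freq", all = FALSE)
  expect_match(w, "koa", all = FALSE)
})
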