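#' Substituent library for PAE modification
#'
#' The eight hydrophobic/bulky groups used for flame-retardant PAE design,
#' as SMILES fragments writable before (prefix) or after (suffix) a parent
#' attachment carbon.
#'
#' @return Tibble with `group`, `prefix` and `suffix` fragment SMILES.
#' @export
substituent_library <- function() {
  tibble::tribble(
    ~group,       ~prefix,            ~suffix,
    "CH3",        "C",                "C",
    "CH2CH3",     "CC",               "CC",
    "CH2C6H5",    "c1ccccc1C",        "Cc1ccccc1",
    "NO2",        "[O-][N+](=O)",     "[N+](=O)[O-]",
    "CH2NO2",     "[O-][N+](=O)C",    "C[N+](=O)[O-]",
    "SH",         "S",                "S",
    "OCH3",       "CO",               "OC",
    "CH=CH2",     "C=C",              "C=C"
  )
}

#' Parent molecules and modification sites
#'
#' The two design parents: dimethyl phthalate (DMP) and diallyl phthalate
#' (DAP). Modification sites 1 and 2 are the terminal side-chain carbons of
#' the two ester arms; substituents replace one hydrogen there. The base
#' SMILES is written so site 1 is the first atom and site 2 the last, which
#' lets fragments attach as string prefixes/suffixes. The mapping is an
#' editable convention: supply your own tibble with the same columns to
#' change it.
#'
#' @return Tibble with `parent` and `base` SMILES.
#' @export
parent_templates <- function() {
  tibble::tribble(
    ~parent, ~base,
    "DMP",   "COC(=O)c1ccccc1C(=O)OC",
    "DAP",   "C=CCOC(=O)c1ccccc1C(=O)OCC=C"
  )
}

#' Enumerate substituted derivatives of a parent molecule
#'
#' Builds one product per requested (site, group) in single mode or per
#' (site-1 group, site-2 group) pair in double mode, named
#' `parent-site-group` (e.g. `DAP-1-NO2-2-OCH3`). Products that violate
#' valence rules are reported with `ok = FALSE`; the rest of the batch
#' continues.
#'
#' @param plan Tibble with columns `parent`, `group1` (site-1 group or
#'   `NA`), `group2` (site-2 group or `NA`); alternatively use
#'   `mode = "single"` with `groups` to cross all sites and groups.
#' @param parents Parent templates, see [parent_templates()].
#' @param library Substituent library, see [substituent_library()].
#' @param groups For `mode = "single"`: character vector of group labels.
#' @param mode `"plan"` (default, use `plan`) or `"single"`.
#' @param parse Parse each product through the structure backend
#'   (`TRUE` by default); with `FALSE` only SMILES strings are built.
#' @return Tibble with `molecule`, `parent`, `group1`, `group2`, `smiles`,
#'   and (if parsed) `ok`, `error`, `n_heavy`, `molar_mass`.
#' @export
enumerate_derivatives <- function(plan = NULL, parents = parent_templates(),
                                  library = substituent_library(),
                                  groups = NULL, mode = c("plan", "single"),
                                  parse = TRUE) {
  mode <- match.arg(mode)
  if (mode == "single") {
    stopifnot(!is.null(groups))
    plan <- dplyr::bind_rows(
      tidyr::expand_grid(parent = parents$parent, group1 = groups,
                         group2 = NA_character_),
      tidyr::expand_grid(parent = parents$parent, group1 = NA_character_,
                         group2 = groups)
    )
  }
  if (is.null(plan) || nrow(plan) == 0) {
    return(tibble::tibble(molecule = character(), parent = character(),
                          group1 = character(), group2 = character(),
                          smiles = character()))
  }
  stopifnot(all(c("parent", "group1", "group2") %in% names(plan)))
  bad_groups <- setdiff(stats::na.omit(c(plan$group1, plan$group2)),
                        library$group)
  if (length(bad_groups) > 0) {
    stop("unknown substituent group(s): ",
         paste(unique(bad_groups), collapse = ", "), call. = FALSE)
  }
  rows <- purrr::pmap_dfr(plan, function(parent, group1, group2, ...) {
    base <- parents$base[match(parent, parents$parent)]
    if (is.na(base)) stop("unknown parent '", parent, "'", call. = FALSE)
    pre <- if (!is.na(group1)) library$prefix[match(group1, library$group)] else ""
    suf <- if (!is.na(group2)) library$suffix[match(group2, library$group)] else ""
    name <- paste0(parent,
                   if (!is.na(group1)) paste0("-1-", group1) else "",
                   if (!is.na(group2)) paste0("-2-", group2) else "")
    tibble::tibble(molecule = name, parent = parent,
                   group1 = group1, group2 = group2,
                   smiles = paste0(pre, base, suf))
  })
  rows <- dplyr::distinct(rows, .data$molecule, .keep_all = TRUE)
  if (!parse) return(rows)
  res <- backend_call(tibble::tibble(id = rows$molecule,
                                     smiles = rows$smiles),
                      tasks = "parse")
  rows$ok <- purrr::map_lgl(res, ~ isTRUE(.x$ok))
  rows$error <- purrr::map_chr(res, ~ .x$error %||% NA_character_)
  rows$n_heavy <- purrr::map_int(res, ~ as.integer(.x$n_heavy %||% NA))
  rows$molar_mass <- purrr::map_dbl(res,
                                    ~ if (isTRUE(.x$ok)) sum(unlist(.x$mass)) else NA_real_)
  rows$smiles <- purrr::map2_chr(rows$smiles, res,
                                 ~ .y$canonical_smiles %||% .x)
  rows
}

#' Predict endpoint values for derivatives and compare with parents
#'
#' Runs each derivative through the fitted field models (one per endpoint),
#' then computes percent changes against the parent with the customary sign
#' conventions: "decreasing" columns are positive when the value fell,
#' "increasing" columns positive when it rose, both relative to
#' `|parent value|`.
#'
#' @param derivatives An embedded, parameterized `mol_tbl` of derivatives
#'   (ids following the `parent-site-group` convention, plus the parents
#'   themselves).
#' @param models Named list of fitted `comsia_model` objects, e.g.
#'   `list(Z = ..., LOI = ..., logLC50 = ..., logBCF = ...)`.
#' @param parent_of Named character vector mapping each derivative id to
#'   its parent id (parents map to themselves).
#' @param decreasing Endpoints whose improvement is a decrease (default
#'   `c("Z", "logBCF")`); the rest improve by increasing.
#' @return Tibble with one row per molecule, predicted endpoint columns and
#'   `<endpoint>_change_pct` columns.
#' @export
evaluate_derivatives <- function(derivatives, models, parent_of,
                                 decreasing = c("Z", "logBCF")) {
  stopifnot(inherits(derivatives, "mol_tbl"), length(models) >= 1,
            !is.null(names(models)))
  out <- tibble::tibble(molecule = derivatives$id,
                        parent = unname(parent_of[derivatives$id]))
  if (anyNA(out$parent)) {
    stop("parent_of does not cover: ",
         paste(out$molecule[is.na(out$parent)], collapse = ", "),
         call. = FALSE)
  }
  for (ep in names(models)) {
    model <- models[[ep]]
    if (!inherits(model, "comsia_model")) {
      stop("missing or invalid model for endpoint '", ep, "'",
           call. = FALSE)
    }
    pred <- predict(model, derivatives)
    out[[ep]] <- pred
    parent_val <- pred[match(out$parent, out$molecule)]
    delta <- (pred - parent_val) / abs(parent_val) * 100
    if (ep %in% decreasing) delta <- -delta
    out[[paste0(ep, "_change_pct")]] <- delta
  }
  out
}

#' Eco-friendliness screening rules for derivative records
#'
#' @param z_decreased,loi_increased,lc50_increased,bcf_decreased Require
#'   strict improvement over the parent (defaults `TRUE`).
#' @param loi_improvement_min Minimum LOI improvement in % (default 5) for
#'   a clearly flame-retardant derivative.
#' @param bcf_cap Upper bound on logBCF (default 3.30, the conventional
#'   non-bioaccumulative limit).
#' @param koa_band Semi-volatility band for logKOA (default `c(6.5, 10)`).
#' @param freq_positive Require a positive lowest vibrational frequency
#'   (structural stability; default `TRUE`).
#' @return A `screen_rules` list.
#' @export
screen_rules <- function(z_decreased = TRUE, loi_increased = TRUE,
                         lc50_increased = TRUE, bcf_decreased = TRUE,
                         loi_improvement_min = 5, bcf_cap = 3.30,
                         koa_band = c(6.5, 10), freq_positive = TRUE) {
  stopifnot(is.finite(loi_improvement_min), is.finite(bcf_cap),
            length(koa_band) == 2, koa_band[1] < koa_band[2])
  structure(list(z_decreased = z_decreased, loi_increased = loi_increased,
                 lc50_increased = lc50_increased,
                 bcf_decreased = bcf_decreased,
                 loi_improvement_min = loi_improvement_min,
                 bcf_cap = bcf_cap, koa_band = koa_band,
                 freq_positive = freq_positive),
            class = "screen_rules")
}

#' Screen derivative records against design rules
#'
#' Applies the multi-criterion funnel: strict improvement of the
#' comprehensive value, flammability, biotoxicity and enrichment over the
#' parent; an LOI improvement threshold; the non-bioaccumulation cap on
#' logBCF; the semi-volatility band on logKOA; and positive lowest
#' frequency. Rules whose input columns are absent are skipped with a
#' warning. Per-rule pass flags are retained.
#'
#' @param records Tibble of derivative records. Recognized columns:
#'   `z_change_pct` (or `z_decrease_pct`), `loi_increase_pct`,
#'   `lc50_increase_pct`, `bcf_decrease_pct`, `log_bcf`, `log_koa`,
#'   `freq`. Parent rows (all change columns `NA`) always fail.
#' @param rules A [screen_rules()] object.
#' @return `records` with `pass_*` flag columns and an overall `pass`.
#' @export
screen_derivatives <- function(records, rules = screen_rules()) {
  stopifnot(is.data.frame(records), inherits(rules, "screen_rules"))
  out <- tibble::as_tibble(records)
  n <- nrow(out)
  get_col <- function(...) {
    for (nm in c(...)) if (nm %in% names(out)) return(out[[nm]])
    NULL
  }
  checks <- list()
  add_rule <- function(name, enabled, col, test) {
    if (!enabled) return()
    if (is.null(col)) {
      warning("rule '", name, "' skipped: required column absent",
              call. = FALSE)
      return()
    }
    checks[[name]] <<- test(col) & !is.na(col)
  }
  add_rule("z_decreased", rules$z_decreased,
           get_col("z_decrease_pct", "Z_change_pct"), function(x) x > 0)
  add_rule("loi_increased", rules$loi_increased,
           get_col("loi_increase_pct", "LOI_change_pct"), function(x) x > 0)
  add_rule("lc50_increased", rules$lc50_increased,
           get_col("lc50_increase_pct", "logLC50_change_pct"),
           function(x) x > 0)
  add_rule("bcf_decreased", rules$bcf_decreased,
           get_col("bcf_decrease_pct", "logBCF_change_pct"),
           function(x) x > 0)
  add_rule("loi_improvement", is.finite(rules$loi_improvement_min),
           get_col("loi_increase_pct", "LOI_change_pct"),
           function(x) x > rules$loi_improvement_min)
  add_rule("bcf_cap", is.finite(rules$bcf_cap),
           get_col("log_bcf", "logBCF"), function(x) x < rules$bcf_cap)
  add_rule("koa_band", TRUE, get_col("log_koa", "logKOA"),
           function(x) x >= rules$koa_band[1] & x <= rules$koa_band[2])
  add_rule("freq_positive", rules$freq_positive, get_col("freq", "Freq"),
           function(x) x > 0)
  if (length(checks) == 0) {
    warning("no screening rule could be evaluated", call. = FALSE)
    out$pass <- rep(NA, n)
    return(out)
  }
  for (nm in names(checks)) out[[paste0("pass_", nm)]] <- checks[[nm]]
  out$pass <- Reduce(`&`, checks)
  out
}
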