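#' Default end-to-end pipeline configuration
#'
#' Drives every stage from the packaged reference tables: ideal-point
#' scoring of the 17 PAEs, the derivative screening funnel, and the
#' modified-group coupling analysis. Table references of the form
#' `"fixture:<name>"` resolve through [ecoqsar_fixture()]; plain strings
#' are read as CSV paths.
#'
#' @param out_dir Output directory for per-stage CSVs and the report.
#' @param seed Seed for any stochastic stage.
#' @return A config list for [run_pipeline()].
#' @export
default_config <- function(out_dir = tempfile("ecoqsar_run_"), seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    score = list(
      table = "fixture:pae_properties",
      weights = c(loi = 0.4, lc50 = 0.3, log_bcf = 0.3),
      directions = c(loi = "positive", lc50 = "positive",
                     log_bcf = "inverse"),
      metric = "euclidean"
    ),
    screen = list(
      effects = "fixture:derivative_effects",
      eco = "fixture:derivative_eco"
    ),
    coupling = list(
      records = "fixture:group_coupling",
      effects = "fixture:derivative_effects"
    )
  )
}

resolve_table <- function(ref) {
  if (is.data.frame(ref)) return(tibble::as_tibble(ref))
  stopifnot(is.character(ref), length(ref) == 1)
  if (startsWith(ref, "fixture:")) {
    return(ecoqsar_fixture(sub("^fixture:", "", ref)))
  }
  tibble::as_tibble(utils::read.csv(ref, stringsAsFactors = FALSE))
}

#' Validate a pipeline configuration
#'
#' @param config A config list (see [default_config()]) or the path to a
#'   YAML file holding one.
#' @return Character vector of problems; empty when the config is
#'   runnable.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$out_dir)) note("out_dir: missing output directory")
  sc <- config$score
  if (!is.null(sc)) {
    w <- unlist(sc$weights)
    if (is.null(w) || abs(sum(w) - 1) > 1e-9) {
      note(sprintf("score$weights: must sum to 1 (got %s)",
                   if (is.null(w)) "none" else format(sum(w))))
    }
    if (!is.null(sc$metric) &&
        !sc$metric %in% c("euclidean", "manhattan")) {
      note("score$metric: must be 'euclidean' or 'manhattan'")
    }
    if (is.character(sc$table) && !startsWith(sc$table, "fixture:") &&
        !file.exists(sc$table)) {
      note(paste0("score$table: file not found: ", sc$table))
    }
  }
  for (stage in c("screen", "coupling")) {
    for (key in names(config[[stage]])) {
      ref <- config[[stage]][[key]]
      if (is.character(ref) && !startsWith(ref, "fixture:") &&
          !file.exists(ref)) {
        note(paste0(stage, "$", key, ": file not found: ", ref))
      }
    }
  }
  problems
}

#' Run the multi-effect design pipeline
#'
#' Executes the configured stages in order -- comprehensive scoring,
#' (optional) synthetic field-QSAR fit, derivative screening, group
#' coupling analysis -- writing one CSV per stage plus a plain-text report
#' into `out_dir`. Identical config and seed give byte-identical numeric
#' outputs.
#'
#' @inheritParams validate_config
#' @return Invisibly, a named list of the per-stage tibbles.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  report <- c(paste("ecoqsar pipeline,", format(Sys.time())),
              paste("seed:", config$seed %||% "none"))
  save_stage <- function(name, tbl) {
    utils::write.csv(as.data.frame(tbl),
                     file.path(config$out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    out[[name]] <<- tbl
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(config$score)) {
    run_stage("score", function() {
      sc <- config$score
      tbl <- resolve_table(sc$table)
      weights <- unlist(sc$weights)
      directions <- unlist(sc$directions)
      scores <- ideal_point_score(tbl, weights, directions,
                                  metric = sc$metric %||% "euclidean")
      save_stage("score", rank_by_score(scores))
      report <<- c(report, sprintf(
        "score: %d molecules; best %s (Z = %.3f)", nrow(scores),
        out$score$molecule[1], out$score$Z[1]))
    })
  }
  if (!is.null(config$qsar)) {
    run_stage("qsar", function() {
      qc <- config$qsar
      syn <- generate_synthetic_qsar(
        n_molecules = qc$n_molecules %||% 20,
        snr = qc$snr %||% 3,
        seed = qc$seed %||% config$seed %||% 1)
      model <- comsia_fit(syn$fields, syn$response)
      save_stage("qsar_stats", model_stats(model))
      save_stage("qsar_field_fractions", field_fractions(model))
      map <- contour_map(model, "S")
      write_dx(map, file.path(config$out_dir, "qsar_map_S.dx"))
      report <<- c(report, sprintf(
        "qsar: synthetic fit, ncomp = %d, q2 = %.3f",
        model$pls$ncomp, model$q2))
    })
  }
  if (!is.null(config$screen)) {
    run_stage("screen", function() {
      scn <- config$screen
      records <- resolve_table(scn$effects)
      if (!is.null(scn$eco)) {
        eco <- resolve_table(scn$eco)
        records <- dplyr::left_join(records, eco, by = "molecule")
      }
      rules <- do.call(screen_rules, scn$rules %||% list())
      screened <- suppressWarnings(screen_derivatives(records, rules))
      save_stage("screen", screened)
      report <<- c(report, sprintf(
        "screen: %d records, %d pass", nrow(screened),
        sum(screened$pass, na.rm = TRUE)))
    })
  }
  if (!is.null(config$coupling)) {
    run_stage("coupling", function() {
      cp <- config$coupling
      records <- resolve_table(cp$records)
      effects <- resolve_table(cp$effects)
      summaries <- suppressWarnings(group_summaries(records, effects))
      save_stage("coupling", summaries)
      r1 <- pearson_r(summaries$group_properties,
                      summaries$comprehensive_effect)
      r2 <- pearson_r(summaries$comprehensive_effect,
                      summaries$weighted_comprehensive_effect)
      save_stage("coupling_correlations",
                 dplyr::bind_rows(
                   dplyr::mutate(r1, comparison =
                     "group properties vs comprehensive effect"),
                   dplyr::mutate(r2, comparison =
                     "comprehensive vs weighted comprehensive")))
      report <<- c(report, sprintf(
        "coupling: %d groups; R(properties, effect) = %.4f",
        nrow(summaries), r1$r))
    })
  }
  writeLines(report, file.path(config$out_dir, "report.txt"))
  invisible(out)
}
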