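#' Percent increase relative to a baseline
#'
#' `(value - baseline) / baseline * 100`. Group volumes use the hydrogen
#' baseline (1.0 per site, 2.0 for two sites); logP uses the parent
#' molecule's value.
#'
#' @param value,baseline Numeric vectors.
#' @return Percent increase (negative for decreases).
#' @export
percent_increase <- function(value, baseline) {
  if (any(baseline == 0)) stop("baseline must be non-zero", call. = FALSE)
  (value - baseline) / baseline * 100
}

#' Coupling value of a modified group
#'
#' Weighted combination of the group's volume-increase and
#' hydrophobicity-increase percentages, with weights taken from the
#' multi-effect field model's steric and hydrophobic contribution fractions
#' (as decimals of 100%, not renormalized):
#' `coupling = w_steric * dvol% + w_hydrophobic * dlogP%`.
#'
#' @param vol_increase_pct Volume increase vs the hydrogen baseline, in %.
#' @param logp_increase_pct logP increase vs the parent, in %.
#' @param w_steric Steric field fraction (default 0.229).
#' @param w_hydrophobic Hydrophobic field fraction (default 0.449).
#' @return Coupling value in %.
#' @export
coupling_value <- function(vol_increase_pct, logp_increase_pct,
                           w_steric = 0.229, w_hydrophobic = 0.449) {
  w_steric * vol_increase_pct + w_hydrophobic * logp_increase_pct
}

#' Group-wise effect averages and the weighted comprehensive effect
#'
#' Averages, over all derivatives carrying a given modified group, the
#' comprehensive-effect reduction, the group-property coupling value, the
#' flame-retardancy increase, the biotoxicity improvement and the
#' enrichment reduction; the weighted comprehensive effect recombines the
#' three single effects with the 40/30/30 weights. Derivatives missing
#' from the effect table are skipped with a warning; groups with no
#' remaining members are omitted.
#'
#' @param coupling_records Tibble with columns `group`, `molecule`,
#'   `coupling_value` (one row per derivative-group membership).
#' @param effect_table Tibble with `molecule`, `z_decrease_pct`,
#'   `loi_increase_pct`, `lc50_increase_pct`, `bcf_decrease_pct`.
#' @param weights Flammability/biotoxicity/enrichment weights
#'   (default `c(0.4, 0.3, 0.3)`).
#' @return Tibble with one row per group: `comprehensive_effect`,
#'   `group_properties`, `flame_retardancy`, `biotoxicity`,
#'   `concentration`, `weighted_comprehensive_effect` (all %).
#' @export
group_summaries <- function(coupling_records, effect_table,
                            weights = c(0.4, 0.3, 0.3)) {
  stopifnot(all(c("group", "molecule", "coupling_value") %in%
                  names(coupling_records)),
            length(weights) == 3)
  missing_mols <- setdiff(coupling_records$molecule, effect_table$molecule)
  if (length(missing_mols) > 0) {
    warning("no effect data for: ", paste(missing_mols, collapse = ", "),
            "; these members are skipped", call. = FALSE)
    coupling_records <- dplyr::filter(coupling_records,
                                      !.data$molecule %in% missing_mols)
  }
  joined <- dplyr::inner_join(coupling_records, effect_table,
                              by = "molecule")
  out <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      comprehensive_effect = mean(.data$z_decrease_pct),
      group_properties = mean(.data$coupling_value),
      flame_retardancy = mean(.data$loi_increase_pct),
      biotoxicity = mean(.data$lc50_increase_pct),
      concentration = mean(.data$bcf_decrease_pct),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      weighted_comprehensive_effect =
        weights[1] * .data$flame_retardancy +
        weights[2] * .data$biotoxicity +
        weights[3] * .data$concentration
    )
  out
}

#' Pearson correlation with small-sample critical values
#'
#' Computes the sample Pearson correlation and flags significance against
#' the two-sided critical values of R for the sample size (derived from the
#' t distribution with n - 2 degrees of freedom; for n = 8 these are
#' 0.7067 at P = 0.05 and 0.8343 at P = 0.01).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `r`, `n`, `critical_05`, `critical_01`,
#'   `significant_05`, `significant_01`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input; correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- length(x) - 2
  crit <- function(p) {
    t <- stats::qt(1 - p / 2, df)
    t / sqrt(t^2 + df)
  }
  c05 <- crit(0.05)
  c01 <- crit(0.01)
  tibble::tibble(r = r, n = length(x), critical_05 = c05,
                 critical_01 = c01,
                 significant_05 = abs(r) > c05,
                 significant_01 = abs(r) > c01)
}
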