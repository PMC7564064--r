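.fixture_md5 <- c(
  derivative_eco = "9ff152a039b170bafe58bc133c0e3699",
  derivative_effects = "21d451ba8553727e104eba0619e093f1",
  group_coupling = "78987e2d105e55f2a2f6ab9254d0dc31",
  group_volumes = "e782e600fe438c105f7ad555759bb4ae",
  pae_properties = "9a748684e37b1c97a2c504e64fd093bc",
  parent_reference = "cbdc3345784dd95fa9c8d4ded6f11457"
)

#' Load a packaged reference table
#'
#' The package ships the screening-study reference data as plain CSV:
#'
#' * `pae_properties` — 17 phthalate esters with LOI, fish LC50 (mg/L),
#'   logBCF, logHL, logKOA, the comprehensive value Z, SMILES and the
#'   training/test split used for the field models.
#' * `derivative_effects` — the 22 improved derivatives (plus the DMP/DAP
#'   parents) with predicted Z, LOI, logLC50, logBCF and percent changes.
#' * `derivative_eco` — eco-screen inputs for DAP and 7 derivatives:
#'   logHL, logKOA, lowest frequency, HOMO-LUMO energy gap.
#' * `group_coupling` — per-derivative modified-group volume/logP increase
#'   percentages and coupling values.
#' * `group_volumes` — relative substituent volumes (H baseline = 1.0).
#' * `parent_reference` — parent logP and volume baselines.
#'
#' Files are checksum-verified on load, so silent edits fail loudly.
#'
#' @param name Fixture name (see above).
#' @param check Verify the MD5 checksum (default `TRUE`).
#' @return A tibble.
#' @export
ecoqsar_fixture <- function(name, check = TRUE) {
  if (!name %in% names(.fixture_md5)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_md5), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "ecoqsar")
  if (!nzchar(path)) stop("fixture file missing from installation")
  if (check) {
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, unname(.fixture_md5[name]))) {
      stop("checksum mismatch for fixture '", name,
           "': file has been modified", call. = FALSE)
    }
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}
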