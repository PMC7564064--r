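#' Locate the Python interpreter used for the RDKit backend
#'
#' Structure handling (SMILES/molblock parsing, seeded 3D embedding,
#' Gasteiger charges, per-atom Crippen logP contributions) is delegated to
#' RDKit through a small JSON bridge script shipped with the package. The
#' interpreter is resolved from, in order: `options(ecoqsar.python=)`, the
#' `ECOQSAR_PYTHON` environment variable, `python3` and `python` on the PATH.
#'
#' @return Path to the Python executable.
#' @export
ecoqsar_python <- function() {
  opt <- getOption("ecoqsar.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("ECOQSAR_PYTHON", "")
  if (nzchar(env)) return(env)
  for (cand in c("python3", "python")) {
    hit <- Sys.which(cand)
    if (nzchar(hit)) return(unname(hit))
  }
  stop("No Python interpreter found; set options(ecoqsar.python=) to a ",
       "Python with RDKit installed.", call. = FALSE)
}

backend_script <- function() {
  path <- system.file("python", "rdkit_backend.py", package = "ecoqsar")
  if (!nzchar(path)) stop("rdkit_backend.py not found in the installed package")
  path
}

#' Is the RDKit backend usable?
#'
#' @return `TRUE` if a Python interpreter with RDKit can be invoked.
#' @export
rdkit_available <- function() {
  cached <- .ecoqsar_env$rdkit_ok
  if (!is.null(cached)) return(cached)
  ok <- tryCatch({
    py <- ecoqsar_python()
    status <- suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                                       stdout = FALSE, stderr = FALSE))
    identical(status, 0L)
  }, error = function(e) FALSE)
  .ecoqsar_env$rdkit_ok <- ok
  ok
}

.ecoqsar_env <- new.env(parent = emptyenv())

# One batched round-trip through the bridge. `molecules` is a data frame with
# an `id` column and either `smiles` or `molblock`; returns the parsed JSON
# list, one element per molecule, in input order.
backend_call <- function(molecules, tasks = "parse", settings = list(),
                         match_smarts = NULL) {
  stopifnot(is.data.frame(molecules), nrow(molecules) >= 1)
  entries <- purrr::pmap(molecules, function(...) {
    row <- list(...)
    keep <- intersect(names(row), c("id", "smiles", "molblock"))
    row[keep]
  })
  request <- list(molecules = entries, tasks = as.list(tasks),
                  settings = settings)
  if (!is.null(match_smarts)) request$match_smarts <- match_smarts
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  out <- suppressWarnings(
    system2(ecoqsar_python(), shQuote(backend_script()),
            stdin = infile, stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RDKit backend failed: ", paste(out, collapse = "\n"), call. = FALSE)
  }
  jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)$molecules
}
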