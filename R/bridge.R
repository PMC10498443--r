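# Interface to the bundled RDKit helper used for reading chemical formats
# and for MMFF94 atom typing / parameter assignment.

the <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for parsing and MMFF94 typing
#'
#' The helper script shipped with the package requires a Python 3
#' interpreter with the `rdkit` package importable. The interpreter is
#' located once per session (`python3`, then `python` on `PATH`) and can be
#' overridden with the `CONFSMITH_PYTHON` environment variable.
#'
#' @return Path to the interpreter.
#' @export
find_python <- function() {
  if (!is.null(the$python)) return(the$python)
  cand <- Sys.getenv("CONFSMITH_PYTHON", "")
  if (!nzchar(cand)) {
    for (p in c("python3", "python")) {
      hit <- Sys.which(p)
      if (nzchar(hit)) { cand <- hit; break }
    }
  }
  if (!nzchar(cand)) {
    stop("no python interpreter found; set CONFSMITH_PYTHON", call. = FALSE)
  }
  the$python <- cand
  cand
}

bridge_script <- function() {
  p <- system.file("python", "chembridge.py", package = "confsmith")
  if (!nzchar(p)) stop("chembridge.py not found in installed package")
  p
}

#' Run one request against the RDKit helper
#'
#' @param req A list serialisable to JSON (`cmd` plus payload).
#' @return Parsed JSON response (lists, not simplified).
#' @keywords internal
bridge_call <- function(req) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(find_python(), shQuote(bridge_script()),
                    stdin = infile, stdout = outfile, stderr = FALSE)
  if (!identical(status, 0L)) {
    stop("chemistry helper failed (exit status ", status, ")", call. = FALSE)
  }
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}
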