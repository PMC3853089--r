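# Accession-based regression inputs.  The reference structures are not
# shipped (they are too large for a text-only test fixture); they are read
# from tests/testthat/accession/<ID>.pdb when the user has placed them
# there, otherwise a download from the RCSB is attempted once per session.
# Without either source the accession regressions fail with a clear message.
.accession_cache <- new.env(parent = emptyenv())

fetch_accession <- function(id) {
  key <- toupper(id)
  if (!is.null(.accession_cache[[key]])) return(.accession_cache[[key]])
  local <- testthat::test_path("accession", paste0(key, ".pdb"))
  txt <- NULL
  if (file.exists(local)) {
    txt <- readLines(local, warn = FALSE)
  } else {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", key)
    tf <- tempfile(fileext = ".pdb")
    ok <- tryCatch({
      suppressWarnings(utils::download.file(url, tf, quiet = TRUE,
                                            method = "libcurl",
                                            extra = "--max-time 20"))
      TRUE
    }, error = function(e) FALSE)
    if (ok && file.exists(tf) && file.size(tf) > 10000)
      txt <- readLines(tf, warn = FALSE)
  }
  .accession_cache[[key]] <- txt
  txt
}

require_accession <- function(id) {
  txt <- fetch_accession(id)
  if (is.null(txt)) {
    stop(sprintf(paste0(
      "reference structure %s unavailable: not in tests/testthat/accession/ ",
      "and the RCSB is unreachable from this environment"), id),
      call. = FALSE)
  }
  txt
}
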