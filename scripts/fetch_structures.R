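#!/usr/bin/env Rscript
# Downloads the crystal structures used by the reproduction tests into
# inst/extdata/pdb/ (run from the repository root; network required):
#   Rscript scripts/fetch_structures.R
# Afterwards reinstall the package so the files are available via
# system.file(), then run the test suite.

entries <- c("1j7v", "2aca", "2arz", "2g2x", "1ufa", "1xwm", "1zyl", "3kh5")
dest_dir <- file.path("inst", "extdata", "pdb")
dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)

for (id in entries) {
  dest <- file.path(dest_dir, paste0(id, ".pdb"))
  if (file.exists(dest)) {
    message(id, ": already present")
    next
  }
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  message("fetching ", url)
  ok <- tryCatch({
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
    TRUE
  }, error = function(e) {
    message(id, ": download failed (", conditionMessage(e), ")")
    FALSE
  })
  if (!ok && file.exists(dest)) unlink(dest)
}
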