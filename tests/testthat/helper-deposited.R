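# Locate a locally provided copy of a deposited PDB entry (e.g. "6hwj").
# The numeric cross-checks against deposited coordinates are optional
# extras on top of the synthetic-data suite: they run whenever the files
# have been placed in tests/testthat/deposited/ or in the directory named
# by KINCONF_DEPOSITED_DIR, and fail with a pointer to that convention
# otherwise. Coordinates are never downloaded at test time.
deposited_structure_path <- function(id) {
  dirs <- c(Sys.getenv("KINCONF_DEPOSITED_DIR", unset = NA),
            testthat::test_path("deposited"))
  dirs <- dirs[!is.na(dirs)]
  for (d in dirs) {
    for (ext in c(".pdb", ".cif", ".pdb.gz", ".cif.gz")) {
      for (case in c(tolower(id), toupper(id))) {
        p <- file.path(d, paste0(case, ext))
        if (file.exists(p)) return(p)
      }
    }
  }
  NA_character_
}

deposited_missing_msg <- function(ids) {
  paste0("deposited coordinate file(s) ", paste(ids, collapse = ", "),
         " not found; place them under tests/testthat/deposited/ or set ",
         "KINCONF_DEPOSITED_DIR to run this numeric cross-check")
}
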