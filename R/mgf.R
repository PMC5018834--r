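#' Read a Mascot generic format (MGF) file
#'
#' Parses BEGIN IONS / END IONS blocks with PEPMASS, CHARGE and TITLE
#' headers followed by "m/z intensity" peak lines.
#'
#' @param path Path to an MGF file.
#' @return A list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  nblock <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (ln != "BEGIN IONS") {
      stop(sprintf("malformed MGF at line %d: expected BEGIN IONS, got '%s'",
                   i, ln), call. = FALSE)
    }
    nblock <- nblock + 1L
    begin_line <- i
    i <- i + 1L
    pepmass <- NA_real_; charge <- NA_integer_; title <- ""
    mz <- numeric(); intensity <- numeric()
    closed <- FALSE
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (grepl("^PEPMASS=", ln)) {
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]+")[[1]][1])
      } else if (grepl("^CHARGE=", ln)) {
        charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
      } else if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^[0-9]", ln)) {
        parts <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
        if (length(parts) < 2 || any(is.na(parts[1:2]))) {
          stop(sprintf("malformed MGF peak at line %d: '%s'", i, ln),
               call. = FALSE)
        }
        mz <- c(mz, parts[1]); intensity <- c(intensity, parts[2])
      }
      # other KEY=VALUE headers ignored
      i <- i + 1L
    }
    if (!closed) {
      stop(sprintf("malformed MGF: block starting at line %d lacks END IONS",
                   begin_line), call. = FALSE)
    }
    if (is.na(pepmass)) {
      stop(sprintf("malformed MGF: block %d (line %d) missing PEPMASS",
                   nblock, begin_line), call. = FALSE)
    }
    spectra[[nblock]] <- spectrum(mz, intensity, precursor_mz = pepmass,
                                  precursor_charge = charge, title = title)
  }
  spectra
}

#' Write spectra to a Mascot generic format (MGF) file
#'
#' Fields round-trip through [read_mgf()] to 1e-6.
#'
#' @param spectra A list of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    stopifnot(inherits(sp, "spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.na(sp$precursor_charge)) {
      writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
    }
    if (length(sp$mz) > 0) {
      writeLines(sprintf("%.6f %.6f", sp$mz, sp$intensity), con)
    }
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}
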