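#' Construct a fragmentation spectrum
#'
#' @param mz Numeric vector of peak m/z values (> 0).
#' @param intensity Numeric vector of peak intensities (>= 0).
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge state.
#' @param title Free-text spectrum title.
#' @return An object of class `spectrum`; peaks are stored sorted by m/z.
#' @export
spectrum <- function(mz, intensity = rep(1, length(mz)),
                     precursor_mz = NA_real_, precursor_charge = NA_integer_,
                     title = "") {
  stopifnot(length(mz) == length(intensity))
  if (any(mz <= 0)) stop("all peak m/z must be > 0", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  o <- order(mz)
  structure(list(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o],
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 title = title),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum '%s': %d peaks, precursor %.4f (z=%s)\n",
              x$title, length(x$mz), x$precursor_mz,
              ifelse(is.na(x$precursor_charge), "?", x$precursor_charge)))
  invisible(x)
}

#' Match theoretical ions against a spectrum
#'
#' Each theoretical ion is matched to the nearest spectrum peak within
#' `tol_ppm`. A peak may satisfy several ions, but each (peak, ion) pair
#' appears at most once. This is a transparent tolerance-based matcher, not
#' a probabilistic search engine.
#'
#' @param spec A `spectrum`.
#' @param ions Fragment table from [theoretical_fragments()].
#' @param tol_ppm Matching tolerance in ppm (default 10, Q-Exactive-class).
#' @return An object of class `annotated_spectrum`: list with the input
#'   `spectrum`, `ions` and `matches` (data frame: `peak`, `ion` row index,
#'   `label`, `series`, `index_b`, `index_y`, `charge`, `mz_theoretical`,
#'   `mz_observed`, `ppm_error`).
#' @export
match_spectrum <- function(spec, ions, tol_ppm = 10) {
  stopifnot(inherits(spec, "spectrum"), tol_ppm > 0)
  ions <- as.data.frame(ions)
  m <- length(spec$mz)
  rows <- list()
  if (m > 0 && nrow(ions) > 0) {
    idx <- findInterval(ions$mz, spec$mz)
    for (k in seq_len(nrow(ions))) {
      cand <- unique(pmin(pmax(c(idx[k], idx[k] + 1L), 1L), m))
      err <- (spec$mz[cand] - ions$mz[k]) / ions$mz[k] * 1e6
      best <- which.min(abs(err))
      if (abs(err[best]) <= tol_ppm) {
        rows[[length(rows) + 1L]] <- data.frame(
          peak = cand[best], ion = k, label = ions$label[k],
          series = ions$series[k], index_b = ions$index_b[k],
          index_y = ions$index_y[k], charge = ions$charge[k],
          mz_theoretical = ions$mz[k], mz_observed = spec$mz[cand[best]],
          ppm_error = err[best], stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak = integer(), ion = integer(), label = character(),
               series = character(), index_b = integer(), index_y = integer(),
               charge = integer(), mz_theoretical = numeric(),
               mz_observed = numeric(), ppm_error = numeric())
  rownames(matches) <- NULL
  structure(list(spectrum = spec, ions = ions, matches = matches),
            class = "annotated_spectrum")
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat(sprintf("annotated spectrum: %d/%d ions matched over %d peaks\n",
              nrow(x$matches), nrow(x$ions), length(x$spectrum$mz)))
  invisible(x)
}

#' Localize an O-HexNAc site from a modified/unmodified spectrum pair
#'
#' Backbone y ions observed specifically in the modified spectrum confine the
#' modification to the peptide region N-terminal of their first residue: a
#' modification-specific y_j restricts the site to peptide-local positions
#' 1..(n-j). The y33 ion of the H2A G37-K74 peptide confines the HexNAc to
#' protein residues 37-41, whose only Ser/Thr is Ser40.
#'
#' @param mod_annot `annotated_spectrum` of the modified precursor.
#' @param unmod_annot `annotated_spectrum` of the unmodified precursor, built
#'   against the same peptide's ladders.
#' @param pep The `peptide` both spectra were annotated against.
#' @return A list of class `localization_result`: `window` (1-based protein
#'   coordinates, first/last), `candidate_sites` (protein positions of S/T in
#'   the window), `call` (protein position or `"ambiguous"`), `evidence`
#'   (labels of the modification-specific y ions used).
#' @export
localize_glycosite <- function(mod_annot, unmod_annot, pep) {
  stopifnot(inherits(mod_annot, "annotated_spectrum"),
            inherits(unmod_annot, "annotated_spectrum"),
            inherits(pep, "peptide"))
  n <- nchar(pep$sequence)
  key <- function(a) {
    m <- a$matches
    m <- m[m$series == "y", , drop = FALSE]
    paste(m$index_y, m$charge, sep = "/")
  }
  mod_y <- mod_annot$matches[mod_annot$matches$series == "y", , drop = FALSE]
  specific <- mod_y[!(paste(mod_y$index_y, mod_y$charge, sep = "/") %in%
                        key(unmod_annot)), , drop = FALSE]
  if (nrow(specific) > 0) {
    jmax <- max(specific$index_y)
    window_local <- c(1L, n - jmax)
    evidence <- unique(specific$label[specific$index_y == jmax])
  } else {
    window_local <- c(1L, n)
    evidence <- character()
  }
  window <- window_local + pep$start - 1L
  aa <- strsplit(pep$sequence, "", fixed = TRUE)[[1]]
  local_sites <- which(aa %in% c("S", "T"))
  local_sites <- local_sites[local_sites >= window_local[1] &
                               local_sites <= window_local[2]]
  candidates <- local_sites + pep$start - 1L
  call <- if (length(candidates) == 1L) candidates else "ambiguous"
  structure(list(window = window, candidate_sites = candidates,
                 call = call, evidence = evidence),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("glycosite window %d-%d; candidates {%s}; call: %s\n",
              x$window[1], x$window[2],
              paste(x$candidate_sites, collapse = ","),
              paste(x$call, collapse = ",")))
  invisible(x)
}
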