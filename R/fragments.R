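#' Enumerate theoretical HCD fragment ions
#'
#' Generates the b series (prefix ions), y series (suffix ions, + water) and,
#' optionally, internal by-type ions (double backbone cleavage; b-type
#' terminus, no water) of a peptide, at all charge states 1..`max_charge`.
#'
#' O-HexNAc is labile under HCD, so by default (`glycan_retained = FALSE`)
#' HexNAc deltas are omitted from fragment masses while the precursor retains
#' them; set `glycan_retained = TRUE` for the intact-glycan ladder. Other
#' modification deltas are always retained by the fragments spanning them.
#'
#' @param pep A `peptide`.
#' @param max_charge Highest charge state to emit (>= 1).
#' @param include_internal Also emit internal by ions (span
#'   `(n - index_y + 1) .. index_b` in peptide-local coordinates).
#' @param glycan_retained Keep HexNAc deltas on fragments.
#' @param include_oxonium Also emit the HexNAc oxocarbenium reporter ion
#'   (m/z 204.0866, singly charged) when the peptide carries a HexNAc.
#' @return A data frame with columns `series` ("b", "y", "internal_by",
#'   "oxonium"), `index_b`, `index_y`, `charge`, `mz`, `span_first`,
#'   `span_last` (1-based peptide-local), and `label` (e.g. "y33^2+",
#'   "y33-b15^1+").
#' @examples
#' p <- peptide("GNYSERVGAGAPVYLAAVLEYLTAEILELAGNAARDNK", start = 37)
#' frags <- theoretical_fragments(p, max_charge = 2)
#' subset(frags, series == "y" & index_y == 33)
#' @export
theoretical_fragments <- function(pep, max_charge = 1L, include_internal = FALSE,
                                  glycan_retained = FALSE,
                                  include_oxonium = FALSE) {
  stopifnot(inherits(pep, "peptide"), max_charge >= 1)
  mt <- mass_table()
  aa <- strsplit(pep$sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  res <- unname(mt$residues[aa])

  mods <- pep$mods
  if (!glycan_retained && nrow(mods) > 0) {
    mods <- mods[mods$label != "HexNAc", , drop = FALSE]
  }
  # per-residue retained delta, peptide-local
  delta_local <- numeric(n)
  if (nrow(mods) > 0) {
    loc <- mods$site - pep$start + 1L
    for (k in seq_along(loc)) delta_local[loc[k]] <- delta_local[loc[k]] + mods$delta[k]
  }
  cum <- cumsum(res + delta_local)
  span_sum <- function(a, b) cum[b] - if (a > 1) cum[a - 1] else 0

  rows <- list()
  emit <- function(series, ib, iy, a, b, neutral) {
    for (z in seq_len(max_charge)) {
      lab <- switch(series,
        b = sprintf("b%d^%d+", ib, z),
        y = sprintf("y%d^%d+", iy, z),
        internal_by = sprintf("y%d-b%d^%d+", iy, ib, z))
      rows[[length(rows) + 1L]] <<- data.frame(
        series = series, index_b = ib, index_y = iy, charge = z,
        mz = ion_mz(neutral, z), span_first = a, span_last = b,
        label = lab, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n - 1L)) emit("b", i, NA_integer_, 1L, i, span_sum(1L, i))
  for (j in seq_len(n - 1L)) {
    emit("y", NA_integer_, j, n - j + 1L, n, span_sum(n - j + 1L, n) + mt$water)
  }
  if (include_internal) {
    for (j in seq_len(n - 1L)) {
      a <- n - j + 1L
      for (i in a:(n - 1L)) {
        if (i < a) next
        emit("internal_by", i, j, a, i, span_sum(a, i))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (include_oxonium && any(pep$mods$label == "HexNAc")) {
    out <- rbind(out, data.frame(
      series = "oxonium", index_b = NA_integer_, index_y = NA_integer_,
      charge = 1L, mz = ion_mz(mt$hexnac, 1L),
      span_first = NA_integer_, span_last = NA_integer_,
      label = "HexNAc-oxonium^1+", stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Pair precursor ions separated by a fixed neutral-mass delta
#'
#' Finds all (light, heavy) ion pairs whose neutral-mass difference equals
#' `delta` within `tol_ppm` parts per million of the heavy neutral mass.
#' Charges may differ between partners; the comparison is on neutral masses.
#' Used to pair the unmodified and O-HexNAc precursors (delta 203.079373 Da).
#'
#' @param ions Data frame with columns `mz` and `charge`.
#' @param delta Neutral-mass difference in Da (default: one HexNAc).
#' @param tol_ppm Tolerance in ppm of the heavy neutral mass.
#' @return Data frame of pairs sorted by light neutral mass, with columns
#'   `light_mz`, `light_charge`, `heavy_mz`, `heavy_charge`, `light_mass`,
#'   `heavy_mass`, `delta_found`.
#' @examples
#' pair_precursors(data.frame(mz = c(1327.02, 1394.72), charge = c(3, 3)),
#'                 tol_ppm = 20)
#' @export
pair_precursors <- function(ions, delta = mass_table()$hexnac, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  ions <- as.data.frame(ions)
  if (nrow(ions) == 0) {
    return(data.frame(light_mz = numeric(), light_charge = integer(),
                      heavy_mz = numeric(), heavy_charge = integer(),
                      light_mass = numeric(), heavy_mass = numeric(),
                      delta_found = numeric()))
  }
  mass <- neutral_mass(ions$mz, ions$charge)
  out <- list()
  for (i in seq_along(mass)) {
    for (j in seq_along(mass)) {
      if (i == j) next
      d <- mass[j] - mass[i]
      if (d <= 0) next
      if (abs(d - delta) <= tol_ppm * 1e-6 * mass[j]) {
        out[[length(out) + 1L]] <- data.frame(
          light_mz = ions$mz[i], light_charge = ions$charge[i],
          heavy_mz = ions$mz[j], heavy_charge = ions$charge[j],
          light_mass = mass[i], heavy_mass = mass[j], delta_found = d)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(light_mz = numeric(), light_charge = integer(),
                      heavy_mz = numeric(), heavy_charge = integer(),
                      light_mass = numeric(), heavy_mass = numeric(),
                      delta_found = numeric()))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$light_mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}
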