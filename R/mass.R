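#' Monoisotopic mass table
#'
#' Residue and constant monoisotopic masses used by all mass arithmetic in
#' the package: the 20 standard amino acid residue masses (Da), the mass of
#' water (added once per peptide), the proton mass (charge carrier), and the
#' HexNAc (O-GlcNAc) modification delta of 203.079373 Da.
#'
#' @return A list with components `residues` (named numeric vector, one-letter
#'   codes), `water`, `proton` and `hexnac`, all in Da.
#' @examples
#' mt <- mass_table()
#' mt$residues[["G"]] + mt$water  # neutral mass of free glycine
#' @export
mass_table <- function() {
  list(
    residues = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
      V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
      I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
      K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
      F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    water  = 18.010565,
    proton = 1.007276,
    hexnac = 203.079373
  )
}

.check_residues <- function(sequence, what = "sequence") {
  mt <- mass_table()
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(aa %in% names(mt$residues)))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue '%s' at position %d in %s",
                 aa[bad[1]], bad[1], what), call. = FALSE)
  }
  aa
}

#' Construct a peptide
#'
#' A peptide is a span of a parent protein with optional modifications.
#' Modification sites are given in 1-based protein coordinates and must fall
#' inside the span.
#'
#' @param sequence One-letter amino acid string (standard residues only).
#' @param start 1-based start position in the parent protein.
#' @param mods Optional data frame with columns `site` (1-based protein
#'   coordinate), `delta` (mass shift, Da) and `label`.
#' @return An object of class `peptide` with fields `sequence`, `start`,
#'   `end`, `mods`.
#' @examples
#' p <- peptide("GNYSERVGAGAPVYLAAVLEYLTAEILELAGNAARDNK", start = 37)
#' p$end  # 74
#' @export
peptide <- function(sequence, start = 1L, mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0)
  .check_residues(sequence, "peptide")
  start <- as.integer(start)
  end <- start + nchar(sequence) - 1L
  if (is.null(mods)) {
    mods <- data.frame(site = integer(), delta = numeric(),
                       label = character(), stringsAsFactors = FALSE)
  } else {
    mods <- as.data.frame(mods)
    stopifnot(all(c("site", "delta") %in% names(mods)))
    if (is.null(mods$label)) mods$label <- rep("mod", nrow(mods))
    if (any(mods$site < start | mods$site > end)) {
      stop("modification site outside peptide span", call. = FALSE)
    }
  }
  structure(list(sequence = sequence, start = start, end = end, mods = mods),
            class = "peptide")
}

#' Attach one O-HexNAc modification to a peptide
#'
#' @param pep A `peptide`.
#' @param site 1-based protein coordinate of the modified Ser/Thr.
#' @return The peptide with a HexNAc (+203.079373 Da) modification added.
#' @export
add_hexnac <- function(pep, site) {
  mt <- mass_table()
  pep$mods <- rbind(pep$mods,
                    data.frame(site = as.integer(site), delta = mt$hexnac,
                               label = "HexNAc", stringsAsFactors = FALSE))
  pep
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("peptide %s (%d-%d)", x$sequence, x$start, x$end))
  if (nrow(x$mods) > 0) {
    cat(" +", paste(sprintf("%s@%d", x$mods$label, x$mods$site), collapse = ","))
  }
  cat("\n")
  invisible(x)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water plus all modification deltas.
#'
#' @param pep A `peptide` or a plain sequence string (no modifications).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")  # 75.03203
#' @export
peptide_mass <- function(pep) {
  if (is.character(pep)) pep <- peptide(pep)
  stopifnot(inherits(pep, "peptide"))
  mt <- mass_table()
  aa <- strsplit(pep$sequence, "", fixed = TRUE)[[1]]
  sum(mt$residues[aa]) + mt$water + sum(pep$mods$delta)
}

#' m/z of a protonated ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (>= 0).
#' @param charge Positive integer charge state.
#' @return (neutral_mass + charge * proton) / charge.
#' @examples
#' ion_mz(3978.0486, 3)  # 1327.02 at 2 d.p.
#' @export
ion_mz <- function(neutral_mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  if (any(neutral_mass < 0)) stop("neutral mass must be >= 0", call. = FALSE)
  mt <- mass_table()
  (neutral_mass + charge * mt$proton) / charge
}

#' Neutral mass from an observed m/z and charge
#'
#' @param mz Observed m/z.
#' @param charge Positive integer charge state.
#' @return z * mz - z * proton, in Da.
#' @export
neutral_mass <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  mt <- mass_table()
  charge * mz - charge * mt$proton
}
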