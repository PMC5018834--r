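#' In-silico protease digestion
#'
#' Digests a protein with Lys-C (Achromobacter protease I), which cleaves
#' C-terminal to every lysine including Lys-Pro bonds. With 0 missed
#' cleavages the peptides are the maximal spans ending at K or at the protein
#' C-terminus; their concatenation reconstructs the protein. Positions are
#' 1-based inclusive in protein coordinates (for histones, position 1 is the
#' residue after the cleaved initiator Met).
#'
#' @param protein Protein sequence (one-letter string, standard residues).
#' @param enzyme Currently only `"lysC"`.
#' @param missed_cleavages Non-negative integer; peptides spanning up to this
#'   many internal cleavage sites are also emitted.
#' @return A data frame with columns `sequence`, `start`, `end`,
#'   `missed` (number of internal cleavage sites spanned), ordered by
#'   `start` then `missed`.
#' @examples
#' digest("AKGK")   # AK (1-2), GK (3-4)
#' digest("AKPG")   # Lys-C cleaves K-P: AK (1-2), PG (3-4)
#' @export
digest <- function(protein, enzyme = "lysC", missed_cleavages = 0L) {
  enzyme <- match.arg(enzyme, "lysC")
  stopifnot(missed_cleavages >= 0)
  if (!is.character(protein) || length(protein) != 1L || nchar(protein) == 0) {
    stop("protein must be a non-empty sequence string", call. = FALSE)
  }
  aa <- .check_residues(protein, "protein")
  n <- length(aa)
  cut_after <- which(aa == "K")          # cleave after every K, incl. K-P
  cut_after <- cut_after[cut_after < n]  # terminal K ends the last peptide
  bounds <- c(0L, cut_after, n)          # peptide i spans bounds[i]+1 .. bounds[i+1]
  np <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(np)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > np) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(aa[s:e], collapse = ""),
        start = s, end = e, missed = m, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
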